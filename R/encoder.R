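# Nested-GNN encoder: GCN base layers with a virtual node, followed by
# k-hop subgraph pooling, so every node representation summarizes its
# k-hop neighborhood subgraph.

#' Encoder configuration
#'
#' @param kHops Hop radius of the pooled subgraphs (default 3).
#' @param nLayers Number of GCN base layers (default 3).
#' @param hiddenDim Embedding width d (default 128, matching the 128-D
#'   fusion space).
#' @param activation `"relu"` or `"identity"`.
#' @param useVirtualNode Insert a virtual node exchanging global
#'   information between layers (default TRUE).
#' @param gcnMode `"normalized"` (symmetric degree normalization with
#'   self-loops, the standard GCN convention; default) or `"literal"`
#'   (plain unnormalized neighbor sum with no self-term, exactly as the
#'   base-layer update is written).
#' @return A list of class `encoderConfig`.
#' @export
encoderConfig <- function(kHops = 3L, nLayers = 3L, hiddenDim = 128L,
                          activation = c("relu", "identity"),
                          useVirtualNode = TRUE,
                          gcnMode = c("normalized", "literal")) {
  activation <- match.arg(activation)
  gcnMode <- match.arg(gcnMode)
  stopifnot(kHops >= 0, nLayers >= 0, hiddenDim >= 1)
  structure(
    list(
      kHops = as.integer(kHops), nLayers = as.integer(nLayers),
      hiddenDim = as.integer(hiddenDim), activation = activation,
      useVirtualNode = useVirtualNode, gcnMode = gcnMode
    ),
    class = "encoderConfig"
  )
}

.activate <- function(x, activation) {
  switch(activation, relu = reluFn(x), identity = x)
}

#' One GCN base layer
#'
#' In `"literal"` mode each node's new representation is the activated
#' sum of its neighbors' transformed representations (no self-term, no
#' normalization); isolated nodes get the zero vector before
#' activation. In `"normalized"` mode the update is
#' sigma(D^-1/2 (A+I) D^-1/2 H W), the standard GCN propagation.
#'
#' @param H N x d input representations.
#' @param graph The [MolecularGraph-class] providing the edges.
#' @param W d x d weight matrix.
#' @param activation `"relu"` or `"identity"`.
#' @param mode `"normalized"` or `"literal"`.
#' @return N x d matrix.
#' @export
baseGcnLayer <- function(H, graph, W, activation = "relu",
                         mode = c("normalized", "literal")) {
  mode <- match.arg(mode)
  stopifnot(nrow(H) == numNodes(graph), ncol(H) == nrow(W))
  P <- if (mode == "literal") {
    adjacencyMatrix(graph)
  } else {
    normalizedAdjacency(graph)
  }
  .activate(P %*% H %*% W, activation)
}

#' Subgraph pooling
#'
#' Row u of the output is the elementwise sum of the rows of `H`
#' indexed by the u-th subgraph set.
#'
#' @param H N x d matrix.
#' @param subgraphSets List of integer index vectors, one per node.
#' @return N x d matrix.
#' @export
subgraphPool <- function(H, subgraphSets) {
  stopifnot(length(subgraphSets) == nrow(H))
  out <- matrix(0, nrow(H), ncol(H))
  for (u in seq_along(subgraphSets)) {
    out[u, ] <- colSums(H[subgraphSets[[u]], , drop = FALSE])
  }
  out
}

#' Virtual-node update
#'
#' The virtual node aggregates all node representations and scatters
#' the result back: vNew = sigma(vPrev W0 + (sum_i H_i) W1), and every
#' node row receives vNew additively.
#'
#' @param H N x d node representations.
#' @param vPrev Length-d previous virtual-node state.
#' @param W0,W1 d x d weight matrices.
#' @param activation `"relu"` or `"identity"`.
#' @return List with `H` (N x d, updated) and `v` (length d).
#' @export
virtualNodeStep <- function(H, vPrev, W0, W1, activation = "relu") {
  stopifnot(length(vPrev) == ncol(H), all(dim(W0) == ncol(H)),
            all(dim(W1) == ncol(H)))
  s <- colSums(H)
  vNew <- as.numeric(.activate(
    matrix(vPrev, 1) %*% W0 + matrix(s, 1) %*% W1, activation
  ))
  list(H = sweep(H, 2, vNew, "+"), v = vNew)
}

#' Initialize encoder parameters
#'
#' Glorot-uniform weights: an input projection from the raw feature
#' width to `hiddenDim`, and per layer a GCN weight plus (if enabled)
#' the two virtual-node weights.
#'
#' @param inputDim Raw node-feature width (78 for drugs, 54 for
#'   proteins).
#' @param config An [encoderConfig()].
#' @param seed Integer seed.
#' @return Parameter list.
#' @export
initEncoderParams <- function(inputDim, config, seed = 1L) {
  d <- config$hiddenDim
  withLocalSeed(seed, {
    layers <- lapply(seq_len(config$nLayers), function(l) {
      lay <- list(W = glorotMatrix(d, d))
      if (config$useVirtualNode) {
        lay$W0 <- glorotMatrix(d, d)
        lay$W1 <- glorotMatrix(d, d)
      }
      lay
    })
    list(Win = glorotMatrix(inputDim, d), layers = layers)
  })
}

#' Encode a molecular graph into node embeddings
#'
#' Projects raw features to `hiddenDim`, stacks `nLayers` of
#' [baseGcnLayer()] followed by [virtualNodeStep()] (virtual-node state
#' starts at zero and is excluded from pooling sets), then applies one
#' [subgraphPool()] over the k-hop sets.
#'
#' @param graph A featurized [MolecularGraph-class].
#' @param params Parameters from [initEncoderParams()].
#' @param config An [encoderConfig()].
#' @return N x d numeric matrix of node embeddings.
#' @export
encodeGraph <- function(graph, params, config) {
  if (numNodes(graph) == 0) stop("empty graph", call. = FALSE)
  cache <- encodeForward(
    nodeFeatures(graph),
    if (config$gcnMode == "literal") adjacencyMatrix(graph)
    else normalizedAdjacency(graph),
    kHopMatrix(graph, config$kHops),
    params, config
  )
  cache$Hp
}

# ---- forward/backward used by the trainer ------------------------------
# X: raw features, P: propagation matrix, S: pooling membership matrix.
encodeForward <- function(X, P, S, params, config) {
  act <- config$activation
  H <- X %*% params$Win
  d <- ncol(H)
  caches <- vector("list", length(params$layers))
  v <- numeric(d)
  for (l in seq_along(params$layers)) {
    lay <- params$layers[[l]]
    Hin <- H
    PH <- P %*% Hin
    Z <- PH %*% lay$W
    Hn <- .activate(Z, act)
    if (config$useVirtualNode) {
      s <- colSums(Hn)
      u <- as.numeric(matrix(v, 1) %*% lay$W0 + matrix(s, 1) %*% lay$W1)
      vNew <- as.numeric(.activate(matrix(u, 1), act))
      H <- sweep(Hn, 2, vNew, "+")
      caches[[l]] <- list(Hin = Hin, PH = PH, Z = Z, Hn = Hn, s = s,
                          u = u, vPrev = v)
      v <- vNew
    } else {
      H <- Hn
      caches[[l]] <- list(Hin = Hin, PH = PH, Z = Z, Hn = Hn)
    }
  }
  list(X = X, P = P, S = S, H = H, Hp = S %*% H, layerCaches = caches)
}

.actGrad <- function(pre, activation) {
  switch(activation, relu = (pre > 0) * 1, identity = pre * 0 + 1)
}

# Backward pass matching encodeForward; dHp is the gradient w.r.t. the
# pooled output. Returns gradients for Win and each layer's weights.
encodeBackward <- function(cache, params, config, dHp) {
  act <- config$activation
  S <- cache$S
  P <- cache$P
  dH <- t(S) %*% dHp
  grads <- list(layers = vector("list", length(params$layers)))
  dvCarry <- numeric(ncol(dH))
  for (l in rev(seq_along(params$layers))) {
    lay <- params$layers[[l]]
    lc <- cache$layerCaches[[l]]
    g <- list()
    if (config$useVirtualNode) {
      dHn <- dH
      dv <- colSums(dH) + dvCarry
      du <- dv * as.numeric(.actGrad(matrix(lc$u, 1), act))
      g$W0 <- outer(lc$vPrev, du)
      g$W1 <- outer(lc$s, du)
      dvCarry <- as.numeric(lay$W0 %*% du)
      ds <- as.numeric(lay$W1 %*% du)
      dHn <- sweep(dHn, 2, ds, "+")
    } else {
      dHn <- dH
    }
    dZ <- dHn * .actGrad(lc$Z, act)
    g$W <- t(lc$PH) %*% dZ
    dH <- t(P) %*% (dZ %*% t(lay$W))
    grads$layers[[l]] <- g
  }
  grads$Win <- t(cache$X) %*% dH
  grads
}
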