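# Independent reference implementations (plain loops, no shared code
# with the package internals) and small fixture builders.

# Random undirected graph as a MolecularGraph with random features.
randomTestGraph <- function(n, pEdge = 0.3, nfeat = 4, kind = "drug") {
  edges <- NULL
  if (n > 1) {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < pEdge
    edges <- pairs[keep, , drop = FALSE]
  }
  molecularGraph(
    matrix(rnorm(n * nfeat), n, nfeat),
    edges,
    rep("C", n),
    kind
  )
}

# Plain breadth-first search k-hop oracle.
bfsKHop <- function(edges, n, node, k) {
  adj <- vector("list", n)
  if (!is.null(edges) && nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  dist <- rep(Inf, n)
  dist[node] <- 0
  frontier <- node
  while (length(frontier) > 0) {
    nxt <- integer()
    for (u in frontier) {
      for (v in adj[[u]]) {
        if (dist[v] > dist[u] + 1) {
          dist[v] <- dist[u] + 1
          nxt <- c(nxt, v)
        }
      }
    }
    frontier <- nxt
  }
  sort(which(dist <= k))
}

# Per-row loop oracle for subgraph pooling.
loopPool <- function(H, sets) {
  out <- matrix(0, nrow(H), ncol(H))
  for (u in seq_along(sets)) {
    for (k in sets[[u]]) out[u, ] <- out[u, ] + H[k, ]
    }
  out
}

# Literal GCN base layer via explicit neighbor loops.
loopGcnLiteral <- function(H, edges, W, act = function(x) pmax(x, 0)) {
  n <- nrow(H)
  out <- matrix(0, n, ncol(W))
  nbrs <- vector("list", n)
  if (!is.null(edges) && nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      i <- edges[r, 1]; j <- edges[r, 2]
      nbrs[[i]] <- c(nbrs[[i]], j)
      nbrs[[j]] <- c(nbrs[[j]], i)
    }
  }
  for (u in seq_len(n)) {
    acc <- numeric(ncol(W))
    for (j in nbrs[[u]]) acc <- acc + as.numeric(W %*% H[j, ])
    out[u, ] <- act(acc)
  }
  out
}

# Direct transcription of the virtual-node update with loops.
loopVirtualNode <- function(H, vPrev, W0, W1, act = function(x) pmax(x, 0)) {
  d <- ncol(H)
  s <- numeric(d)
  for (i in seq_len(nrow(H))) s <- s + H[i, ]
  u <- numeric(d)
  for (i in seq_len(d)) {
    u[i] <- sum(vPrev * W0[, i]) + sum(s * W1[, i])
  }
  v <- act(u)
  Hout <- H
  for (r in seq_len(nrow(H))) Hout[r, ] <- Hout[r, ] + v
  list(H = Hout, v = v)
}

sigm <- function(x) 1 / (1 + exp(-x))

# Triple-loop transcription of one cross-AFT branch (query n, key n',
# dimension i), residual included.
loopAftBranch <- function(Hq, Hk, WQ, WK, WV, wTab) {
  Q <- Hq %*% WQ; K <- Hk %*% WK; V <- Hk %*% WV
  Nq <- nrow(Hq); Nk <- nrow(Hk); d <- ncol(Hq)
  Y <- matrix(0, Nq, d)
  for (n in seq_len(Nq)) {
    for (i in seq_len(d)) {
      num <- 0; den <- 0
      for (np in seq_len(Nk)) {
        e <- exp(K[np, i] + wTab[n, np])
        num <- num + e * V[np, i]
        den <- den + e
      }
      Y[n, i] <- sigm(Q[n, i]) * num / den + Hq[n, i]
    }
  }
  Y
}

# Loop transcription of the implicit attention tensor.
loopImplicitAttention <- function(Hq, Hk, WQ, WK, WV, wTab) {
  Q <- Hq %*% WQ; K <- Hk %*% WK
  Nq <- nrow(Hq); Nk <- nrow(Hk); d <- ncol(Hq)
  a <- array(0, c(Nq, Nk, d))
  for (n in seq_len(Nq)) {
    for (i in seq_len(d)) {
      den <- 0
      for (np in seq_len(Nk)) den <- den + exp(K[np, i] + wTab[n, np])
      for (np in seq_len(Nk)) {
        a[n, np, i] <- sigm(Q[n, i]) * exp(K[np, i] + wTab[n, np]) / den
      }
    }
  }
  a
}

# Mann-Whitney pairwise-concordance AUROC oracle.
concordanceAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) {
    for (q in neg) {
      tot <- tot + (p > q) + 0.5 * (p == q)
    }
  }
  tot / (length(pos) * length(neg))
}

# Small prepared toy pair for model-level tests (shared fixture).
makeToyPair <- function(cfg, seed = 5L) {
  set.seed(seed)
  dg <- smilesToGraph("CC(=O)OC")
  sq <- "ARNDCEQGILKMFPSTVAR"
  coords <- matrix(cumsum(rnorm(19 * 3, sd = 2)), 19, 3)
  cm <- distanceMapToContactMap(as.matrix(dist(coords)), 8)
  pg <- contactMapToGraph(cm, residueFeatures(sq), strsplit(sq, "")[[1]])
  list(
    drug = prepareGraphInput(dg, "CC(=O)OC", cfg),
    prot = prepareGraphInput(pg, sq, cfg),
    drugGraph = dg, protGraph = pg, drugSeq = "CC(=O)OC", protSeq = sq
  )
}

smallModelConfig <- function(...) {
  modelConfig(
    encoder = encoderConfig(kHops = 2, nLayers = 2, hiddenDim = 6),
    maxDrugLen = 64, maxProtLen = 64, mlpHidden = 8, dropout = 0,
    ...
  )
}
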