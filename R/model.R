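# Full model composition: two NGNN encoders, the cross-AFT exchange,
# pretrained-feature fusion and the MLP head, with a hand-written
# backward pass used by the CPU trainer.

#' Model configuration
#'
#' Bundles the encoder configuration, interaction-module limits,
#' fusion/MLP sizes and the three ablation toggles (base GNN vs nested
#' GNN, with/without cross-AFT, with/without pretrained features).
#'
#' @param encoder An [encoderConfig()]; its `hiddenDim` is the shared
#'   embedding width d.
#' @param maxDrugLen,maxProtLen Pairwise-bias table maxima (defaults
#'   128 and 1024); longer inputs are rejected.
#' @param mlpHidden MLP hidden width (default 64; head is
#'   2*fusionDim -> mlpHidden -> 1).
#' @param dropout Dropout rate on the MLP hidden layer during training
#'   (default 0.1).
#' @param pooling Node-axis pooling before fusion: `"mean"` (default)
#'   or `"sum"`.
#' @param useNgnn TRUE for k-hop subgraph pooling; FALSE bypasses it
#'   (plain GCN encoder).
#' @param useCrossAft Toggle the interaction module.
#' @param usePretrained Toggle the pretrained-embedding fusion.
#' @param drugEmbedDim,protEmbedDim Provider vector lengths (512 and
#'   768).
#' @param fusionDim Fusion space width (128).
#' @return A list of class `modelConfig`.
#' @export
modelConfig <- function(encoder = encoderConfig(),
                        maxDrugLen = 128L, maxProtLen = 1024L,
                        mlpHidden = 64L, dropout = 0.1,
                        pooling = c("mean", "sum"),
                        useNgnn = TRUE, useCrossAft = TRUE,
                        usePretrained = TRUE,
                        drugEmbedDim = 512L, protEmbedDim = 768L,
                        fusionDim = 128L) {
  pooling <- match.arg(pooling)
  structure(
    list(
      encoder = encoder, maxDrugLen = as.integer(maxDrugLen),
      maxProtLen = as.integer(maxProtLen),
      mlpHidden = as.integer(mlpHidden), dropout = dropout,
      pooling = pooling, useNgnn = useNgnn, useCrossAft = useCrossAft,
      usePretrained = usePretrained,
      drugEmbedDim = as.integer(drugEmbedDim),
      protEmbedDim = as.integer(protEmbedDim),
      fusionDim = as.integer(fusionDim)
    ),
    class = "modelConfig"
  )
}

#' Initialize all model parameters
#'
#' Parameter groups are created only for enabled components, so the
#' ablation toggles are visible in the parameter structure itself.
#'
#' @param config A [modelConfig()].
#' @param seed Integer seed (fanned out to per-group sub-seeds).
#' @return Nested parameter list with elements `drug`, `prot`,
#'   optionally `aft`, and `fusion`.
#' @export
initModelParams <- function(config, seed = 1L) {
  enc <- config$encoder
  d <- enc$hiddenDim
  fd <- config$fusionDim
  params <- list(
    drug = initEncoderParams(ATOM_FEATURE_DIM, enc, subSeed(seed, "drug")),
    prot = initEncoderParams(RESIDUE_FEATURE_DIM, enc, subSeed(seed, "prot"))
  )
  if (config$useCrossAft) {
    params$aft <- initAftParams(
      d, config$maxDrugLen, config$maxProtLen, subSeed(seed, "aft")
    )
  }
  fcIn <- if (config$usePretrained) d + fd else d
  params$fusion <- withLocalSeed(subSeed(seed, "fusion"), {
    fus <- list(
      Wfcd = glorotMatrix(fcIn, fd), bfcd = numeric(fd),
      Wfcp = glorotMatrix(fcIn, fd), bfcp = numeric(fd),
      mlp = list(
        W1 = glorotMatrix(2L * fd, config$mlpHidden),
        b1 = numeric(config$mlpHidden),
        W2 = as.numeric(glorotMatrix(config$mlpHidden, 1L)),
        b2 = 0
      )
    )
    if (config$usePretrained) {
      fus$Wmapd <- glorotMatrix(config$drugEmbedDim, fd)
      fus$bmapd <- numeric(fd)
      fus$Wmapp <- glorotMatrix(config$protEmbedDim, fd)
      fus$bmapp <- numeric(fd)
    }
    fus
  })
  params
}

# Fixed min-max scaling of the 7 continuous residue-feature columns
# (48..54) using the spread of the 20 standard residues, so model
# inputs are O(1) regardless of the raw units (Da, pH, index points).
.scaleProteinFeatures <- function(X) {
  ref <- .aaProps[1:20, , drop = FALSE]
  lo <- apply(ref, 2, min)
  hi <- apply(ref, 2, max)
  cols <- 48:54
  for (j in seq_along(cols)) {
    X[, cols[j]] <- (X[, cols[j]] - lo[j]) / (hi[j] - lo[j])
  }
  X
}

#' Prepare one molecule for the model
#'
#' Precomputes everything static about a featurized graph: the
#' propagation matrix of the configured GCN mode, the k-hop pooling
#' membership matrix (identity when the nested pooling is ablated),
#' and the provider embedding. Protein continuous feature columns are
#' min-max scaled with fixed residue-table constants.
#'
#' @param graph A [MolecularGraph-class].
#' @param seq The sequence string handed to the embedding provider
#'   (SMILES or residue sequence).
#' @param config A [modelConfig()].
#' @param provider Embedding function `(seq, dim, namespace)`; default
#'   [stubEmbed()].
#' @return List with `X`, `P`, `S`, `emb`, `n`.
#' @export
prepareGraphInput <- function(graph, seq, config, provider = stubEmbed) {
  enc <- config$encoder
  X <- nodeFeatures(graph)
  isDrug <- graphKind(graph) == "drug"
  if (!isDrug) X <- .scaleProteinFeatures(X)
  P <- if (enc$gcnMode == "literal") {
    adjacencyMatrix(graph)
  } else {
    normalizedAdjacency(graph)
  }
  S <- if (config$useNgnn) {
    kHopMatrix(graph, enc$kHops)
  } else {
    diag(numNodes(graph))
  }
  emb <- if (config$usePretrained) {
    if (isDrug) {
      provider(seq, config$drugEmbedDim, "drug")
    } else {
      provider(seq, config$protEmbedDim, "protein")
    }
  } else {
    NULL
  }
  list(X = X, P = P, S = S, emb = emb, n = numNodes(graph))
}

# Forward pass over one prepared (drug, prot) pair. Returns prob and,
# when keepCache, everything the backward pass needs. dropMask is the
# inverted-dropout mask for the MLP hidden layer (NULL outside
# training).
dtiForwardPrepared <- function(drug, prot, params, config,
                               dropMask = NULL, keepCache = FALSE) {
  .checkAftLen(drug$n, config$maxDrugLen, "drug graph")
  .checkAftLen(prot$n, config$maxProtLen, "protein graph")
  enc <- config$encoder
  ecD <- encodeForward(drug$X, drug$P, drug$S, params$drug, enc)
  ecP <- encodeForward(prot$X, prot$P, prot$S, params$prot, enc)
  Hd <- ecD$Hp
  Hp <- ecP$Hp
  if (config$useCrossAft) {
    fwD <- .aftBranchForward(
      Hd, Hp, params$aft$WQd, params$aft$WKp, params$aft$WVp, params$aft$wd
    )
    fwP <- .aftBranchForward(
      Hp, Hd, params$aft$WQp, params$aft$WKd, params$aft$WVd, params$aft$wp
    )
    Yd <- fwD$Y
    Yp <- fwP$Y
  } else {
    fwD <- fwP <- NULL
    Yd <- Hd
    Yp <- Hp
  }
  fus <- params$fusion
  pooledD <- if (config$pooling == "sum") colSums(Yd) else colMeans(Yd)
  pooledP <- if (config$pooling == "sum") colSums(Yp) else colMeans(Yp)
  if (config$usePretrained) {
    preMapD <- as.numeric(matrix(drug$emb, 1) %*% fus$Wmapd) + fus$bmapd
    preMapP <- as.numeric(matrix(prot$emb, 1) %*% fus$Wmapp) + fus$bmapp
    finD <- c(pooledD, reluFn(preMapD))
    finP <- c(pooledP, reluFn(preMapP))
  } else {
    preMapD <- preMapP <- NULL
    finD <- pooledD
    finP <- pooledP
  }
  preFcD <- as.numeric(matrix(finD, 1) %*% fus$Wfcd) + fus$bfcd
  preFcP <- as.numeric(matrix(finP, 1) %*% fus$Wfcp) + fus$bfcp
  Fd <- reluFn(preFcD)
  Fp <- reluFn(preFcP)
  z <- c(Fd, Fp)
  preH <- as.numeric(matrix(z, 1) %*% fus$mlp$W1) + fus$mlp$b1
  h <- reluFn(preH)
  hDrop <- if (!is.null(dropMask)) h * dropMask else h
  logit <- sum(hDrop * fus$mlp$W2) + fus$mlp$b2
  prob <- as.numeric(sigmoidFn(logit))
  out <- list(prob = prob, logit = logit)
  if (keepCache) {
    out$cache <- list(
      drug = drug, prot = prot, ecD = ecD, ecP = ecP, fwD = fwD,
      fwP = fwP, Yd = Yd, Yp = Yp, pooledD = pooledD, pooledP = pooledP,
      preMapD = preMapD, preMapP = preMapP, finD = finD, finP = finP,
      preFcD = preFcD, preFcP = preFcP, z = z, preH = preH,
      hDrop = hDrop, dropMask = dropMask
    )
  }
  out
}

# Backward pass matching dtiForwardPrepared; dLogit is dLoss/dlogit
# (prob - label for binary cross-entropy). Returns gradients mirroring
# the parameter structure.
dtiBackwardPrepared <- function(cache, params, config, dLogit) {
  enc <- config$encoder
  fus <- params$fusion
  fd <- config$fusionDim
  grads <- list()
  gmlp <- list(
    W2 = cache$hDrop * dLogit,
    b2 = dLogit
  )
  dhDrop <- fus$mlp$W2 * dLogit
  dh <- if (!is.null(cache$dropMask)) dhDrop * cache$dropMask else dhDrop
  dPreH <- dh * (cache$preH > 0)
  gmlp$W1 <- outer(cache$z, dPreH)
  gmlp$b1 <- dPreH
  dz <- as.numeric(fus$mlp$W1 %*% dPreH)
  dFd <- dz[seq_len(fd)]
  dFp <- dz[fd + seq_len(fd)]
  gfus <- list(mlp = gmlp)
  backBranch <- function(dF, preFc, fin, Wfc, preMap, emb, Wmap) {
    dPreFc <- dF * (preFc > 0)
    gWfc <- outer(fin, dPreFc)
    gbfc <- dPreFc
    dfin <- as.numeric(Wfc %*% dPreFc)
    d <- enc$hiddenDim
    if (config$usePretrained) {
      dPooled <- dfin[seq_len(d)]
      dMap <- dfin[d + seq_len(fd)] * (preMap > 0)
      gWmap <- outer(emb, dMap)
      gbmap <- dMap
      list(gWfc = gWfc, gbfc = gbfc, dPooled = dPooled, gWmap = gWmap,
           gbmap = gbmap)
    } else {
      list(gWfc = gWfc, gbfc = gbfc, dPooled = dfin)
    }
  }
  bd <- backBranch(dFd, cache$preFcD, cache$finD, fus$Wfcd,
                   cache$preMapD, cache$drug$emb, fus$Wmapd)
  bp <- backBranch(dFp, cache$preFcP, cache$finP, fus$Wfcp,
                   cache$preMapP, cache$prot$emb, fus$Wmapp)
  gfus$Wfcd <- bd$gWfc; gfus$bfcd <- bd$gbfc
  gfus$Wfcp <- bp$gWfc; gfus$bfcp <- bp$gbfc
  if (config$usePretrained) {
    gfus$Wmapd <- bd$gWmap; gfus$bmapd <- bd$gbmap
    gfus$Wmapp <- bp$gWmap; gfus$bmapp <- bp$gbmap
  }
  grads$fusion <- gfus
  nD <- cache$drug$n
  nP <- cache$prot$n
  dYd <- if (config$pooling == "sum") {
    matrix(bd$dPooled, nD, length(bd$dPooled), byrow = TRUE)
  } else {
    matrix(bd$dPooled / nD, nD, length(bd$dPooled), byrow = TRUE)
  }
  dYp <- if (config$pooling == "sum") {
    matrix(bp$dPooled, nP, length(bp$dPooled), byrow = TRUE)
  } else {
    matrix(bp$dPooled / nP, nP, length(bp$dPooled), byrow = TRUE)
  }
  if (config$useCrossAft) {
    aft <- params$aft
    abD <- .aftBranchBackward(cache$fwD, aft$WQd, aft$WKp, aft$WVp, dYd)
    abP <- .aftBranchBackward(cache$fwP, aft$WQp, aft$WKd, aft$WVd, dYp)
    gwd <- matrix(0, nrow(aft$wd), ncol(aft$wd))
    gwd[seq_len(nD), seq_len(nP)] <- abD$gW
    gwp <- matrix(0, nrow(aft$wp), ncol(aft$wp))
    gwp[seq_len(nP), seq_len(nD)] <- abP$gW
    grads$aft <- list(
      WQd = abD$gWQ, WKp = abD$gWK, WVp = abD$gWV, wd = gwd,
      WQp = abP$gWQ, WKd = abP$gWK, WVd = abP$gWV, wp = gwp
    )
    dHd <- abD$dHq + abP$dHk
    dHp <- abP$dHq + abD$dHk
  } else {
    dHd <- dYd
    dHp <- dYp
  }
  grads$drug <- encodeBackward(cache$ecD, params$drug, enc, dHd)
  grads$prot <- encodeBackward(cache$ecP, params$prot, enc, dHp)
  grads
}

#' Run the full pipeline on one drug-protein pair
#'
#' Featurized graphs in, interaction probability out; optionally also
#' the implicit attention tensors for interpretation. The ablation
#' toggles live in `config`: with `useCrossAft` off the interaction
#' module is skipped (Y = H); with `usePretrained` off fusion uses the
#' pooled graph features only; with `useNgnn` off the k-hop pooling is
#' bypassed (plain GCN encoder).
#'
#' @param drugGraph,protGraph Featurized [MolecularGraph-class]
#'   objects.
#' @param drugSeq,protSeq The raw sequences handed to the embedding
#'   provider.
#' @param params Parameters from [initModelParams()] (or a trained
#'   checkpoint).
#' @param config The matching [modelConfig()].
#' @param provider Embedding provider, default [stubEmbed()].
#' @param withAttention Also return the implicit attention tensors.
#' @return List with `prob`, `logit`, and optionally `attention`.
#' @export
dtiForward <- function(drugGraph, protGraph, drugSeq, protSeq, params,
                       config, provider = stubEmbed,
                       withAttention = FALSE) {
  drug <- prepareGraphInput(drugGraph, drugSeq, config, provider)
  prot <- prepareGraphInput(protGraph, protSeq, config, provider)
  out <- dtiForwardPrepared(drug, prot, params, config)
  if (withAttention) {
    if (!config$useCrossAft) {
      stop("attention tensors require useCrossAft = TRUE", call. = FALSE)
    }
    enc <- config$encoder
    Hd <- encodeForward(drug$X, drug$P, drug$S, params$drug, enc)$Hp
    Hp <- encodeForward(prot$X, prot$P, prot$S, params$prot, enc)$Hp
    out$attention <- attentionTensors(Hd, Hp, params$aft)
  }
  out
}

# Recursive elementwise walk over parallel parameter structures;
# matches list elements by name where names exist (gradient structures
# may order fields differently from the parameters).
mapParams <- function(f, ...) {
  dots <- list(...)
  x <- dots[[1]]
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    keys <- if (is.null(names(x))) seq_along(x) else names(x)
    for (i in seq_along(keys)) {
      out[[i]] <- do.call(
        mapParams, c(list(f), lapply(dots, `[[`, keys[[i]]))
      )
    }
    out
  } else {
    do.call(f, dots)
  }
}

sumParamNorm <- function(params) {
  tot <- 0
  mapParams(function(x) {
    tot <<- tot + sum(x^2)
    x
  }, params)
  sqrt(tot)
}
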