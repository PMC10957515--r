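# Cross attention-free transformer (cross-AFT) interaction module.
# One branch computes, per query position n and feature dimension i,
#   Y[n,i] = sigmoid(Q[n,i]) * sum_n' exp(K[n',i] + w[n,n']) V[n',i]
#                              / sum_n' exp(K[n',i] + w[n,n'])
# followed by a residual (+ H_query). Queries come from one molecule,
# keys/values from the other; w is a learned pairwise position bias.

#' Initialize cross-AFT parameters
#'
#' Creates the per-branch projection matrices and the two independent
#' pairwise bias tables (drug-as-query sized maxDrugLen x maxProtLen,
#' protein-as-query the transpose shape). Inputs longer than the
#' configured maxima are rejected at use time, never truncated.
#'
#' @param d Embedding width.
#' @param maxDrugLen,maxProtLen Maximum node counts the bias tables
#'   cover (defaults 128 and 1024).
#' @param seed Integer seed.
#' @return Parameter list with elements `WQd`, `WKp`, `WVp`, `wd`
#'   (drug-as-query branch) and `WQp`, `WKd`, `WVd`, `wp`.
#' @export
initAftParams <- function(d, maxDrugLen = 128L, maxProtLen = 1024L,
                          seed = 1L) {
  withLocalSeed(seed, {
    list(
      WQd = glorotMatrix(d, d), WKp = glorotMatrix(d, d),
      WVp = glorotMatrix(d, d),
      wd = matrix(0, maxDrugLen, maxProtLen),
      WQp = glorotMatrix(d, d), WKd = glorotMatrix(d, d),
      WVd = glorotMatrix(d, d),
      wp = matrix(0, maxProtLen, maxDrugLen),
      maxDrugLen = as.integer(maxDrugLen),
      maxProtLen = as.integer(maxProtLen)
    )
  })
}

.checkAftLen <- function(n, maxN, what) {
  if (n > maxN) {
    stop(
      what, " has ", n, " nodes, exceeding the configured pairwise-bias ",
      "maximum of ", maxN, call. = FALSE
    )
  }
}

# Core one-branch computation. Returns Y (with residual), the gated
# pre-residual output G, and caches for the backward pass. Weight
# normalization uses per-(n, i) max subtraction, mathematically
# identical to the printed form.
.aftBranchForward <- function(Hq, Hk, WQ, WK, WV, wTab) {
  Nq <- nrow(Hq); Nk <- nrow(Hk); d <- ncol(Hq)
  Q <- Hq %*% WQ
  K <- Hk %*% WK
  V <- Hk %*% WV
  sigQ <- sigmoidFn(Q)
  G <- matrix(0, Nq, d)
  Aarr <- array(0, dim = c(Nq, Nk, d))
  for (n in seq_len(Nq)) {
    logits <- K + wTab[n, seq_len(Nk)]          # Nk x d, recycled by row
    m <- apply(logits, 2, max)
    E <- exp(sweep(logits, 2, m, "-"))
    den <- colSums(E)
    Anorm <- sweep(E, 2, den, "/")
    Aarr[n, , ] <- Anorm
    G[n, ] <- colSums(Anorm * V)
  }
  Y <- sigQ * G + Hq
  list(Y = Y, G = G, A = Aarr, Q = Q, K = K, V = V, sigQ = sigQ,
       Hq = Hq, Hk = Hk)
}

#' One cross-AFT branch
#'
#' Queries from `Hq`, keys and values from `Hk`, with the pairwise bias
#' table `wTab`; output includes the residual `+ Hq`.
#'
#' @param Hq Nq x d query-side embeddings.
#' @param Hk Nk x d key/value-side embeddings.
#' @param WQ,WK,WV d x d projection matrices.
#' @param wTab Pairwise bias table, at least Nq x Nk.
#' @return Nq x d output matrix.
#' @export
crossAftBranch <- function(Hq, Hk, WQ, WK, WV, wTab) {
  stopifnot(ncol(Hq) == ncol(Hk))
  .checkAftLen(nrow(Hq), nrow(wTab), "query input")
  .checkAftLen(nrow(Hk), ncol(wTab), "key input")
  .aftBranchForward(Hq, Hk, WQ, WK, WV, wTab)$Y
}

#' Both cross-AFT branches of a drug-protein pair
#'
#' The drug branch queries protein keys/values; the protein branch
#' queries drug keys/values; each keeps its own residual.
#'
#' @param Hdrug,Hprot Node embeddings of the two molecules.
#' @param params Parameters from [initAftParams()].
#' @return List with `Ydrug` and `Yprot`.
#' @export
crossAftPair <- function(Hdrug, Hprot, params) {
  .checkAftLen(nrow(Hdrug), params$maxDrugLen, "drug graph")
  .checkAftLen(nrow(Hprot), params$maxProtLen, "protein graph")
  list(
    Ydrug = crossAftBranch(
      Hdrug, Hprot, params$WQd, params$WKp, params$WVp, params$wd
    ),
    Yprot = crossAftBranch(
      Hprot, Hdrug, params$WQp, params$WKd, params$WVd, params$wp
    )
  )
}

#' Implicit attention of one cross-AFT branch
#'
#' Materializes the Nq x Nk x d tensor a with
#' a\[n, n', i\] = sigmoid(Q\[n,i\]) * exp(K\[n',i\] + w\[n,n'\]) /
#' sum_n'' exp(K\[n'',i\] + w\[n,n''\]), so that
#' sum_n' a\[n,n',i\] V\[n',i\] reproduces the pre-residual branch
#' output. All entries are nonnegative and, for fixed (n, i), sum over
#' n' to sigmoid(Q\[n,i\]).
#'
#' @inheritParams crossAftBranch
#' @return List with the attention array `a` (Nq x Nk x d) and `V`.
#' @export
implicitAttention <- function(Hq, Hk, WQ, WK, WV, wTab) {
  stopifnot(ncol(Hq) == ncol(Hk))
  .checkAftLen(nrow(Hq), nrow(wTab), "query input")
  .checkAftLen(nrow(Hk), ncol(wTab), "key input")
  fw <- .aftBranchForward(Hq, Hk, WQ, WK, WV, wTab)
  a <- fw$A
  dims <- dim(a)
  for (n in seq_len(dims[1])) {
    sl <- a[n, , , drop = FALSE]
    dim(sl) <- dims[2:3]
    a[n, , ] <- sweep(sl, 2, fw$sigQ[n, ], "*")
  }
  list(a = a, V = fw$V)
}

#' Implicit attention tensors for a drug-protein pair
#'
#' @param Hdrug,Hprot Node embeddings.
#' @param params Parameters from [initAftParams()].
#' @return List with `drugAsQuery` (Ndrug x Nprot x d tensor over
#'   protein key positions) and `protAsQuery` (Nprot x Ndrug x d tensor
#'   over drug key positions), each as returned by
#'   [implicitAttention()].
#' @export
attentionTensors <- function(Hdrug, Hprot, params) {
  list(
    drugAsQuery = implicitAttention(
      Hdrug, Hprot, params$WQd, params$WKp, params$WVp, params$wd
    ),
    protAsQuery = implicitAttention(
      Hprot, Hdrug, params$WQp, params$WKd, params$WVd, params$wp
    )
  )
}

# Backward pass of one branch. dY is the gradient w.r.t. the branch
# output (residual included). Returns gradients for the projections,
# the used block of the bias table, and the two inputs.
.aftBranchBackward <- function(fw, WQ, WK, WV, dY) {
  Nq <- nrow(fw$Q); Nk <- nrow(fw$V); d <- ncol(fw$Q)
  dHq <- dY                       # residual path
  dG <- dY * fw$sigQ
  dQ <- dY * fw$G * fw$sigQ * (1 - fw$sigQ)
  dV <- matrix(0, Nk, d)
  dK <- matrix(0, Nk, d)
  dwBlock <- matrix(0, Nq, Nk)
  for (np in seq_len(Nk)) {
    Anp <- fw$A[, np, , drop = FALSE]
    dim(Anp) <- c(Nq, d)
    M <- dG * Anp
    dV[np, ] <- colSums(M)
    term <- sweep(-fw$G, 2, fw$V[np, ], "+")  # V[np,i] - G[n,i]
    dlog <- M * term
    dK[np, ] <- colSums(dlog)
    dwBlock[, np] <- rowSums(dlog)
  }
  list(
    gWQ = t(fw$Hq) %*% dQ,
    gWK = t(fw$Hk) %*% dK,
    gWV = t(fw$Hk) %*% dV,
    gW = dwBlock,
    dHq = dHq + dQ %*% t(WQ),
    dHk = dK %*% t(WK) + dV %*% t(WV)
  )
}
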