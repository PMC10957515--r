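# Fusion of interaction-module outputs with pretrained sequence
# embeddings, and the MLP prediction head.

#' Deterministic stub embedding provider
#'
#' Stand-in for pretrained sequence encoders (a SMILES language model
#' on the drug side, a protein language model on the protein side)
#' used so the pipeline runs without downloaded weights: a
#' pseudo-random unit-norm vector keyed by a stable hash of
#' (namespace, sequence). The same input always yields bitwise the
#' same vector; real encoders can be plugged in as any function with
#' the same signature.
#'
#' @param seq Non-empty input string (SMILES or protein sequence).
#' @param dim Output length (512 for the drug provider, 768 for the
#'   protein provider).
#' @param seedNamespace Namespace string keying the hash (e.g.
#'   `"drug"`, `"protein"`).
#' @return Numeric unit-norm vector of length `dim`.
#' @export
#' @examples
#' all.equal(stubEmbed("CCO", 512, "drug"), stubEmbed("CCO", 512, "drug"))
stubEmbed <- function(seq, dim, seedNamespace) {
  stopifnot(is.character(seq), nzchar(seq), dim >= 1)
  seed <- as.integer(stableStringHash(paste0(seedNamespace, "\r", seq)))
  v <- withLocalSeed(seed, stats::rnorm(dim))
  v / sqrt(sum(v^2))
}

#' Fuse one branch with its pretrained embedding
#'
#' Pools the interaction output `Y` over the node axis (mean by
#' default), concatenates the 128-D-mapped provider vector, and
#' applies the branch fully-connected map into the 128-D fusion space
#' with a ReLU.
#'
#' @param Y N x d interaction-module output.
#' @param P Provider vector (or NULL when pretrained features are
#'   ablated).
#' @param Wmap,bmap Provider FC map to 128-D (NULL when ablated).
#' @param Wfc,bfc Branch FC: (d + 128) x 128 (or d x 128 when
#'   ablated) and its bias.
#' @param pooling `"mean"` or `"sum"` over the node axis.
#' @return Length-128 numeric vector.
#' @export
fuseBranch <- function(Y, P, Wmap, bmap, Wfc, bfc, pooling = "mean") {
  pooled <- if (pooling == "sum") colSums(Y) else colMeans(Y)
  fin <- if (!is.null(P)) {
    p128 <- reluFn(as.numeric(matrix(P, 1) %*% Wmap) + bmap)
    c(pooled, p128)
  } else {
    pooled
  }
  if (length(fin) != nrow(Wfc)) {
    stop(
      "fusion input length ", length(fin), " does not match FC rows ",
      nrow(Wfc),
      call. = FALSE
    )
  }
  reluFn(as.numeric(matrix(fin, 1) %*% Wfc) + bfc)
}

#' Predict the interaction probability from fused branch features
#'
#' Concatenates the two 128-D branch representations and applies the
#' MLP head (one ReLU hidden layer, default 256 -> 64 -> 1) followed
#' by a sigmoid.
#'
#' @param Fdrug,Fprot Length-128 fused branch vectors.
#' @param mlp List with `W1`, `b1`, `W2`, `b2`.
#' @return Probability in (0, 1).
#' @export
predictInteraction <- function(Fdrug, Fprot, mlp) {
  z <- c(Fdrug, Fprot)
  h <- reluFn(as.numeric(matrix(z, 1) %*% mlp$W1) + mlp$b1)
  logit <- sum(h * mlp$W2) + mlp$b2
  as.numeric(sigmoidFn(logit))
}
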