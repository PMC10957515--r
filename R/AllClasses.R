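#' MolecularGraph: featurized graph of a drug or a protein
#'
#' Shared container for drug molecules (atoms as nodes, bonds as edges)
#' and protein targets (residues as nodes, contacts as edges). Node
#' features are a dense numeric matrix with one row per node; edges are
#' stored once per undirected pair with the convention `i < j`, zero
#' self-loops.
#'
#' @slot nodeFeatures Numeric matrix, N x F (F = 78 for drugs, 54 for
#'   proteins).
#' @slot edges Integer matrix with two columns (1-based node indices,
#'   `i < j` per row); zero rows for an edgeless graph.
#' @slot nodeLabels Character vector of atom symbols or one-letter
#'   residue codes, length N.
#' @slot kind Either `"drug"` or `"protein"`.
#'
#' @aliases MolecularGraph
#' @exportClass MolecularGraph
setClass("MolecularGraph",
  representation(
    nodeFeatures = "matrix",
    edges = "matrix",
    nodeLabels = "character",
    kind = "character"
  )
)

setValidity("MolecularGraph", function(object) {
  n <- nrow(object@nodeFeatures)
  e <- object@edges
  msgs <- character()
  if (!object@kind %in% c("drug", "protein")) {
    msgs <- c(msgs, "kind must be 'drug' or 'protein'")
  }
  if (length(object@nodeLabels) != n) {
    msgs <- c(msgs, "nodeLabels length must equal node count")
  }
  if (ncol(e) != 2 && nrow(e) > 0) {
    msgs <- c(msgs, "edges must have two columns")
  }
  if (nrow(e) > 0) {
    if (any(e < 1) || any(e > n)) {
      msgs <- c(msgs, "edge indices out of range")
    }
    if (any(e[, 1] == e[, 2])) {
      msgs <- c(msgs, "self-loops are not allowed")
    }
    if (any(e[, 1] > e[, 2])) {
      msgs <- c(msgs, "edges must be stored with i < j")
    }
    if (anyDuplicated(paste(e[, 1], e[, 2]))) {
      msgs <- c(msgs, "duplicate edges")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a MolecularGraph
#'
#' @param nodeFeatures N x F numeric feature matrix.
#' @param edges Two-column matrix of undirected edges (1-based); pairs
#'   are normalized to `i < j` and deduplicated.
#' @param nodeLabels Character node labels.
#' @param kind `"drug"` or `"protein"`.
#' @return A [MolecularGraph-class] object.
#' @export
molecularGraph <- function(nodeFeatures, edges, nodeLabels, kind) {
  nodeFeatures <- as.matrix(nodeFeatures)
  if (is.null(edges) || length(edges) == 0 || nrow(as.matrix(edges)) == 0) {
    edges <- matrix(integer(), 0, 2)
  } else {
    edges <- matrix(as.integer(as.matrix(edges)), ncol = 2)
    edges <- t(apply(edges, 1, sort))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  methods::new("MolecularGraph",
    nodeFeatures = nodeFeatures, edges = edges,
    nodeLabels = as.character(nodeLabels), kind = kind
  )
}

#' ContactMap: binary residue-residue adjacency
#'
#' Symmetric 0/1 matrix derived by thresholding a Calpha distance map;
#' entry (i, j) is 1 when the two residues' Calpha atoms are closer than
#' the threshold (strict `<`). The diagonal is kept at 0 (self-contacts
#' are excluded from graph edges).
#'
#' @slot matrix K x K binary symmetric matrix.
#' @slot thresholdAngstrom Distance cutoff in Angstrom.
#' @aliases ContactMap
#' @exportClass ContactMap
setClass("ContactMap",
  representation(matrix = "matrix", thresholdAngstrom = "numeric")
)

setValidity("ContactMap", function(object) {
  m <- object@matrix
  msgs <- character()
  if (nrow(m) != ncol(m)) msgs <- c(msgs, "matrix must be square")
  if (!all(m %in% c(0, 1))) msgs <- c(msgs, "matrix must be binary")
  if (!isSymmetric(unname(m))) msgs <- c(msgs, "matrix must be symmetric")
  if (length(msgs)) msgs else TRUE
})

#' PPM: position probability matrix with pseudocount
#'
#' Residue occurrence probabilities per alignment column, computed from
#' a frequency matrix F as M[r, k] = (F[r, k] + p) / (A * N + p), where
#' p is the pseudocount, N the number of aligned sequences and A the
#' alphabet-size constant of the formula (default 4; see
#' [computePPM()]).
#'
#' @slot matrix R x K probability matrix (R = 21 residue classes).
#' @slot frequency R x K nonnegative integer count matrix.
#' @slot pseudocount Pseudocount p.
#' @slot nSequences Number of aligned sequences N.
#' @slot alphabetSize The constant A in the denominator A*N + p.
#' @aliases PPM
#' @exportClass PPM
setClass("PPM",
  representation(
    matrix = "matrix", frequency = "matrix",
    pseudocount = "numeric", nSequences = "integer",
    alphabetSize = "numeric"
  )
)

setValidity("PPM", function(object) {
  msgs <- character()
  if (any(dim(object@matrix) != dim(object@frequency))) {
    msgs <- c(msgs, "matrix and frequency dimensions differ")
  }
  if (any(object@matrix < 0) || any(object@matrix > 1)) {
    msgs <- c(msgs, "probabilities must lie in [0, 1]")
  }
  if (object@pseudocount < 0) msgs <- c(msgs, "pseudocount must be >= 0")
  if (length(msgs)) msgs else TRUE
})

# ---- generics ----------------------------------------------------------

#' @rdname MolecularGraph-class
#' @param x,object A MolecularGraph.
#' @export
setGeneric("nodeFeatures", function(x) standardGeneric("nodeFeatures"))
#' @rdname MolecularGraph-class
#' @export
setGeneric("edgeList", function(x) standardGeneric("edgeList"))
#' @rdname MolecularGraph-class
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname MolecularGraph-class
#' @export
setGeneric("graphKind", function(x) standardGeneric("graphKind"))
#' @rdname MolecularGraph-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))
#' @rdname ContactMap-class
#' @param x,object A ContactMap.
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))
#' @rdname ContactMap-class
#' @export
setGeneric("contactThreshold", function(x) standardGeneric("contactThreshold"))
#' @rdname PPM-class
#' @param x,object A PPM.
#' @export
setGeneric("ppmMatrix", function(x) standardGeneric("ppmMatrix"))

#' @rdname MolecularGraph-class
#' @export
setMethod("nodeFeatures", "MolecularGraph", function(x) x@nodeFeatures)
#' @rdname MolecularGraph-class
#' @export
setMethod("edgeList", "MolecularGraph", function(x) x@edges)
#' @rdname MolecularGraph-class
#' @export
setMethod("nodeLabels", "MolecularGraph", function(x) x@nodeLabels)
#' @rdname MolecularGraph-class
#' @export
setMethod("graphKind", "MolecularGraph", function(x) x@kind)
#' @rdname MolecularGraph-class
#' @export
setMethod("numNodes", "MolecularGraph", function(x) nrow(x@nodeFeatures))
#' @rdname ContactMap-class
#' @export
setMethod("contactMatrix", "ContactMap", function(x) x@matrix)
#' @rdname ContactMap-class
#' @export
setMethod("contactThreshold", "ContactMap", function(x) x@thresholdAngstrom)
#' @rdname PPM-class
#' @export
setMethod("ppmMatrix", "PPM", function(x) x@matrix)

setMethod("show", "MolecularGraph", function(object) {
  cat(sprintf(
    "MolecularGraph (%s): %d nodes, %d undirected edges, %d features/node\n",
    object@kind, nrow(object@nodeFeatures), nrow(object@edges),
    ncol(object@nodeFeatures)
  ))
  lbl <- paste(utils::head(object@nodeLabels, 12), collapse = " ")
  if (length(object@nodeLabels) > 12) lbl <- paste(lbl, "...")
  cat("  labels:", lbl, "\n")
})

setMethod("show", "ContactMap", function(object) {
  k <- nrow(object@matrix)
  nc <- sum(object@matrix[upper.tri(object@matrix)])
  cat(sprintf(
    "ContactMap: %d residues, %d contacts (< %.1f Angstrom)\n",
    k, nc, object@thresholdAngstrom
  ))
})

setMethod("show", "PPM", function(object) {
  cat(sprintf(
    "PPM: %d x %d (pseudocount %.3g, N = %d, denominator %gN + p)\n",
    nrow(object@matrix), ncol(object@matrix), object@pseudocount,
    object@nSequences, object@alphabetSize
  ))
})
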