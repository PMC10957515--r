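# Graph utilities shared by the encoder.

#' Dense adjacency matrix of a MolecularGraph
#'
#' @param graph A [MolecularGraph-class].
#' @return N x N symmetric 0/1 matrix, zero diagonal.
#' @export
adjacencyMatrix <- function(graph) {
  n <- numNodes(graph)
  A <- matrix(0, n, n)
  e <- edgeList(graph)
  if (nrow(e) > 0) {
    A[e] <- 1
    A[e[, c(2, 1), drop = FALSE]] <- 1
  }
  A
}

.asIgraph <- function(graph) {
  igraph::graph_from_edgelist(
    rbind(edgeList(graph), cbind(seq_len(numNodes(graph)),
                                 seq_len(numNodes(graph)))),
    directed = FALSE
  ) |> igraph::simplify()
}

#' Nodes within k hops of a node
#'
#' The set of nodes at shortest-path distance <= k from `node`,
#' including the node itself.
#'
#' @param graph A [MolecularGraph-class].
#' @param node 1-based node index.
#' @param k Nonnegative hop count.
#' @return Sorted integer vector of node indices.
#' @export
#' @examples
#' g <- smilesToGraph("c1ccccc1")
#' kHopSubgraph(g, 1, 1)  # the node and its two ring neighbors
kHopSubgraph <- function(graph, node, k) {
  n <- numNodes(graph)
  if (node < 1 || node > n) {
    stop("node index ", node, " out of range [1, ", n, "]", call. = FALSE)
  }
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  if (k == 0) return(as.integer(node))
  ig <- .asIgraph(graph)
  sort(as.integer(igraph::ego(ig, order = k, nodes = node)[[1]]))
}

#' k-hop membership matrix for subgraph pooling
#'
#' Binary N x N matrix S with S\[u, v\] = 1 iff v is within k hops of
#' u; `S %*% H` performs the subgraph-pooling sum for every node at
#' once.
#'
#' @inheritParams kHopSubgraph
#' @return N x N binary matrix.
#' @export
kHopMatrix <- function(graph, k) {
  n <- numNodes(graph)
  S <- matrix(0, n, n)
  if (k == 0) {
    diag(S) <- 1
    return(S)
  }
  ig <- .asIgraph(graph)
  sets <- igraph::ego(ig, order = k, nodes = seq_len(n))
  for (u in seq_len(n)) S[u, as.integer(sets[[u]])] <- 1
  S
}

# Symmetric-normalized adjacency with self-loops:
# D^{-1/2} (A + I) D^{-1/2}, the standard GCN propagation matrix.
normalizedAdjacency <- function(graph) {
  A <- adjacencyMatrix(graph) + diag(numNodes(graph))
  dinv <- 1 / sqrt(rowSums(A))
  A * outer(dinv, dinv)
}
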