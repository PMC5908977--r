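# Community detection in a single weighted bipartite network.

# Symmetric modularity score matrix A_sym - d d^T / (2m) over the joint node
# set (regulators first, then targets).
modularityScoreMatrix <- function(net) {
  W <- as.matrix(adjacencyMatrix(net))
  nr <- nrow(W)
  nt <- ncol(W)
  n <- nr + nt
  A <- matrix(0, n, n)
  A[seq_len(nr), nr + seq_len(nt)] <- W
  A[nr + seq_len(nt), seq_len(nr)] <- t(W)
  d <- c(rowSums(W), colSums(W))
  m2 <- sum(d)  # 2m under the symmetric convention
  A - outer(d, d) / m2
}

#' Bipartite weighted modularity of a partition
#'
#' Computes Q = (1/2m) * sum_ij (A_ij - d_i d_j / 2m) delta(C_i, C_j) on the
#' symmetrized bipartite adjacency: each regulator-target edge appears once
#' in each triangle of the symmetric matrix, so 2m is twice the sum of the
#' edge weights.
#'
#' @param net a \linkS4class{BipartiteNetwork}.
#' @param p a \linkS4class{Partition} covering every node of \code{net}.
#' @return Q, a single number.
#' @examples
#' toy <- twoGroupToy()
#' comm <- detectCommunities(toy$baseline)
#' modularityScore(toy$baseline, comm)
#' @export
modularityScore <- function(net, p) {
  nodes <- c(regulatorNodes(net), targetNodes(net))
  mem <- membership(p)
  missing <- setdiff(nodes, names(mem))
  if (length(missing) > 0) {
    stop(sprintf("partition does not cover node(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  W <- adjacencyMatrix(net)
  m <- sum(W)
  if (m == 0) stop("modularity undefined for a network with zero total weight")
  gR <- mem[regulatorNodes(net)]
  gT <- mem[targetNodes(net)]
  q <- max(c(gR, gT))
  MR <- matrix(0, nrow(W), q)
  MR[cbind(seq_len(nrow(W)), gR)] <- 1
  MT <- matrix(0, ncol(W), q)
  MT[cbind(seq_len(ncol(W)), gT)] <- 1
  Wblk <- crossprod(MR, as.matrix(W) %*% MT)  # q x q block weights
  within <- diag(Wblk)
  dC <- drop(crossprod(MR, rowSums(W))) + drop(crossprod(MT, colSums(W)))
  m2 <- 2 * m
  sum(2 * within / m2 - (dC / m2)^2)
}

#' Detect communities by weighted bipartite modularity maximization
#'
#' Runs a deterministic generalized Louvain procedure on the symmetrized
#' bipartite adjacency with the degree-product null: starting from
#' singletons, greedy single-node moves in a fixed node order (accepting the
#' largest-gain move, ties to the first candidate encountered), followed by
#' aggregation of communities into metanodes, repeated until no move gains
#' more than \code{tol}. With a fixed node order the result is fully
#' deterministic; additional restarts use seeded shuffles of the order and
#' keep the highest-modularity partition.
#'
#' @param net a \linkS4class{BipartiteNetwork} with at least one
#'   positive-weight edge.
#' @param nodeOrder optional character vector of node ids (namespaced
#'   regulators, then targets in any order) giving the visiting order;
#'   default is regulators then targets, each in network order.
#' @param nRestarts number of optimization runs (>= 1); the first uses
#'   \code{nodeOrder}, later ones seeded shuffles of it.
#' @param seed integer seed controlling the restart shuffles.
#' @param tol minimum modularity gain to accept a move.
#' @return A canonicalized \linkS4class{Partition}.
#' @examples
#' toy <- twoGroupToy()
#' detectCommunities(toy$baseline)
#' @export
detectCommunities <- function(net, nodeOrder = NULL, nRestarts = 1L,
                              seed = 1L, tol = 1e-12) {
  nodes <- c(regulatorNodes(net), targetNodes(net))
  if (nrow(edgeTable(net)) == 0 || totalWeight(net) <= 0) {
    stop("community detection needs at least one positive-weight edge")
  }
  ord <- resolveNodeOrder(nodes, nodeOrder)
  S <- modularityScoreMatrix(net)
  lab <- louvainRestarts(S, ord, nRestarts = nRestarts, seed = seed, tol = tol)
  newPartition(nodes, canonicalizeLabels(lab),
               classesFor(nodes, regulatorNodes(net)))
}

# Map an optional user-supplied node order (character ids) to integer
# positions over `nodes`; default is the natural order.
resolveNodeOrder <- function(nodes, nodeOrder) {
  if (is.null(nodeOrder)) return(seq_along(nodes))
  ord <- match(nodeOrder, nodes)
  if (anyNA(ord) || length(ord) != length(nodes) || anyDuplicated(ord)) {
    stop("nodeOrder must be a permutation of the network's node ids")
  }
  ord
}

#' Seedable shuffle of the default node order
#'
#' Convenience helper for robustness experiments: returns the node ids of a
#' network in a seeded random order, suitable for the \code{nodeOrder}
#' argument of [detectCommunities()] and [findDifferentialModules()].
#'
#' @param net a \linkS4class{BipartiteNetwork}.
#' @param seed integer seed.
#' @return Character vector of namespaced node ids.
#' @export
shuffledNodeOrder <- function(net, seed = 1L) {
  nodes <- c(regulatorNodes(net), targetNodes(net))
  withSeed(seed, sample(nodes))
}
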