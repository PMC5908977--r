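# Benchmark comparator methods: edge subtraction and community comparison.

# Rebuild a network from a regulator x target weight matrix with namespaced
# dimnames, keeping only nonzero entries.
networkFromMatrix <- function(W, regs, tgts) {
  idx <- which(as.matrix(W) != 0, arr.ind = TRUE)
  e <- data.frame(
    regulator = regs[idx[, 1]],
    target = tgts[idx[, 2]],
    weight = as.matrix(W)[idx],
    stringsAsFactors = FALSE
  )
  e <- e[order(idx[, 1], idx[, 2]), , drop = FALSE]
  rownames(e) <- NULL
  new("BipartiteNetwork", regulators = regs, targets = tgts, edges = e)
}

#' Edge subtraction of two networks
#'
#' Computes per-pair weight differences dw_ij = w^P_ij - w^B_ij (an absent
#' edge counts as weight 0) and keeps only the strictly positive differences
#' as the weights of a new network. This is the classical way to look for
#' gained regulatory interactions; note that purely *lost* interactions
#' produce no positive difference and are invisible to it.
#'
#' @param perturbed,baseline \linkS4class{BipartiteNetwork} objects (aligned
#'   internally).
#' @return A \linkS4class{BipartiteNetwork} over the union node universe
#'   containing the positive differences; possibly edgeless.
#' @examples
#' toy <- twoGroupToy()
#' edgeSubtract(toy$perturbed, toy$baseline)  # empty: only decreases
#' edgeSubtract(toy$baseline, toy$perturbed)  # the reversed comparison
#' @export
edgeSubtract <- function(perturbed, baseline) {
  al <- alignNodeUniverse(perturbed, baseline)
  Delta <- adjacencyMatrix(al$x) - adjacencyMatrix(al$y)
  Delta@x[Delta@x <= 0] <- 0
  networkFromMatrix(Matrix::drop0(Delta),
                    regulatorNodes(al$x), targetNodes(al$x))
}

#' Community comparison of two networks
#'
#' Detects community structure separately in the baseline and perturbed
#' networks (positive edges only), then maps the two structures onto each
#' other with the least-squares linear transformation R solving B = A R,
#' where A and B are the n x q and n x q' membership indicator matrices. R
#' is computed through the SVD pseudoinverse of A (singular values below
#' 1e-10 of the largest are zeroed). Each node is scored by
#' S_i = sum_k (A R)_ik B_ik; low scores mark nodes whose community context
#' changed between conditions. When the two detected partitions coincide,
#' R is a permutation and every score is 1 — such a pair of networks shows
#' no detectable change under this method.
#'
#' @param baseline,perturbed \linkS4class{BipartiteNetwork} objects.
#' @param threshold positive-weight cutoff applied to both networks.
#' @param nRestarts,seed passed to [detectCommunities()].
#' @return A \linkS4class{MembershipMapping}.
#' @export
communityComparison <- function(baseline, perturbed, threshold = 0,
                                nRestarts = 1L, seed = 1L) {
  al <- alignNodeUniverse(thresholdPositive(baseline, threshold),
                          thresholdPositive(perturbed, threshold))
  pB <- detectCommunities(al$x, nRestarts = nRestarts, seed = seed)
  pP <- detectCommunities(al$y, nRestarts = nRestarts, seed = seed)
  nodes <- c(regulatorNodes(al$x), targetNodes(al$x))
  indicator <- function(p) {
    g <- membership(p)[nodes]
    M <- matrix(0, length(nodes), max(g))
    M[cbind(seq_along(nodes), g)] <- 1
    rownames(M) <- nodes
    M
  }
  A <- indicator(pB)
  B <- indicator(pP)
  R <- svdPseudoinverse(A) %*% B
  scores <- rowSums((A %*% R) * B)
  new("MembershipMapping",
    A = A, B = B, R = R,
    scores = stats::setNames(scores, nodes),
    baselinePartition = pB, perturbedPartition = pP
  )
}
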