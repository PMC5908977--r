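# Rank-based evaluation of planted-module recovery, partition agreement,
# and the method-comparison sweep.

#' One-sided rank test for planted-gene recovery
#'
#' Tests whether the planted (true-positive) genes score higher than the
#' background of remaining genes. \code{"wilcoxon"} is a rank-sum test with
#' mid-rank ties and the tie-corrected normal approximation (no continuity
#' correction, so a fully tied input gives exactly p = 0.5);
#' \code{"ks"} is the one-sided two-sample Kolmogorov-Smirnov test.
#'
#' @param scores named numeric vector of scores for the evaluated genes
#'   (by convention, target genes only).
#' @param truth character vector of planted gene names; must be non-empty
#'   and a strict subset of \code{names(scores)}.
#' @param test \code{"wilcoxon"} or \code{"ks"}.
#' @return One-sided p-value (planted genes rank higher), in (0, 1].
#' @export
rankTest <- function(scores, truth, test = c("wilcoxon", "ks")) {
  test <- match.arg(test)
  if (length(truth) == 0) stop("truth set is empty")
  if (!all(truth %in% names(scores))) {
    stop("truth contains genes without scores")
  }
  bg <- setdiff(names(scores), truth)
  if (length(bg) == 0) stop("truth must be a strict subset of the scored genes")
  x <- scores[truth]
  y <- scores[bg]
  if (test == "wilcoxon") {
    wilcoxonGreater(x, y)
  } else {
    # alternative = "less": CDF of x below that of y, i.e. x stochastically
    # greater
    suppressWarnings(stats::ks.test(x, y, alternative = "less")$p.value)
  }
}

# Rank-sum test, one-sided (x greater), mid-ranks, tie-corrected normal
# approximation without continuity correction.
wilcoxonGreater <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  N <- n1 + n2
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(0.5)
  stats::pnorm((U - n1 * n2 / 2) / sqrt(sigma2), lower.tail = FALSE)
}

#' Chance-adjusted agreement between two partitions
#'
#' Adjusted Rand index between two partitions of the same node universe,
#' plus an exact-match indicator (equality up to relabeling).
#'
#' @param found,truth \linkS4class{Partition} objects over identical node
#'   sets.
#' @return A list with elements \code{index} (adjusted Rand index, in
#'   [-1, 1]) and \code{exact} (logical).
#' @export
partitionAgreement <- function(found, truth) {
  f <- membership(found)
  t <- membership(truth)
  if (!setequal(names(f), names(t))) {
    stop("partitions are defined on different node universes")
  }
  t <- t[names(f)]
  tab <- table(f, t)
  exact <- nrow(tab) == ncol(tab) &&
    all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
  list(index = mclust::adjustedRandIndex(f, t), exact = exact)
}

#' Per-gene scores under each differential-network method
#'
#' Computes, for every target gene of the aligned pair, its contribution to
#' the final score of the chosen method — the quantity by which genes are
#' ranked in the recovery evaluation:
#' \describe{
#'   \item{differential_modularity}{the node score S_i of
#'     [nodeScores()].}
#'   \item{edge_subtraction}{the per-node within-module strength
#'     (1/m) sum_j dw_ij delta(C_i, C_j) of the subtracted network under its
#'     own detected communities — the direct analog of the differential
#'     score with dw in place of D; genes absent from the subtracted network
#'     score 0, as does everything when the subtraction is empty.}
#'   \item{community_comparison}{minus the conservation score S_i^(R) of
#'     [communityComparison()], so that higher means more changed.}
#' }
#'
#' @param method one of the three method names above.
#' @param baseline,perturbed \linkS4class{BipartiteNetwork} objects.
#' @param ... passed to the underlying method ([differentialModules()] or
#'   [communityComparison()]).
#' @return Named numeric vector of scores over target genes.
#' @export
methodGeneScores <- function(method = c("differential_modularity",
                                        "edge_subtraction",
                                        "community_comparison"),
                             baseline, perturbed, ...) {
  method <- match.arg(method)
  if (method == "differential_modularity") {
    res <- differentialModules(baseline, perturbed, ...)
    sc <- scoreTable(res)
    sc <- sc[sc$node_class == "target", , drop = FALSE]
    return(stats::setNames(sc$score, sc$node))
  }
  if (method == "edge_subtraction") {
    al <- alignNodeUniverse(thresholdPositive(perturbed),
                            thresholdPositive(baseline))
    delta <- edgeSubtract(al$x, al$y)
    tgts <- targetNodes(delta)
    if (nrow(edgeTable(delta)) == 0) {
      return(stats::setNames(rep(0, length(tgts)), tgts))
    }
    p <- detectCommunities(delta)
    W <- as.matrix(adjacencyMatrix(delta))
    mem <- membership(p)
    gR <- mem[rownames(W)]
    gT <- mem[colnames(W)]
    Win <- W * outer(gR, gT, "==")
    contrib <- colSums(Win) / totalWeight(delta)
    return(contrib[tgts])
  }
  cc <- communityComparison(baseline, perturbed, ...)
  s <- conservationScores(cc)
  s <- s[names(s) %in% union(targetNodes(baseline), targetNodes(perturbed))]
  -s
}

#' Planted-module recovery sweep across methods and module sizes
#'
#' Runs the full simulation protocol: a block-structured baseline is drawn
#' once; for each replicate a perturbed network is built by (optionally)
#' resampling the baseline edges within community blocks and planting a
#' fully connected module of \code{size} nodes (size/6 TFs and five times as
#' many genes); each method then scores all target genes and the planted
#' genes are compared against the background with a one-sided rank test.
#'
#' @param sizes planted module sizes in nodes; must be multiples of 6.
#' @param nReps replicates per size.
#' @param methods subset of the method names of [methodGeneScores()].
#' @param resample logical: resample baseline edges within blocks (noise) in
#'   each replicate's perturbed network.
#' @param seed integer seed; every replicate derives its own sub-seed.
#' @param spec baseline [blockBaselineSpec()].
#' @param test rank test to report, \code{"wilcoxon"} (default) or
#'   \code{"ks"}.
#' @return data.frame with columns method, size, n_tfs, rep, p, neglog10p.
#' @seealso [summarizeBenchmark()]
#' @export
benchmarkSweep <- function(sizes = c(18L, 30L, 54L, 90L), nReps = 20L,
                           methods = c("differential_modularity",
                                       "edge_subtraction",
                                       "community_comparison"),
                           resample = TRUE, seed = 1L,
                           spec = blockBaselineSpec(),
                           test = "wilcoxon") {
  stopifnot(nReps >= 1, all(sizes %% 6 == 0))
  methods <- match.arg(methods, several.ok = TRUE)
  base <- simulateBlockBaseline(spec, seed)
  rows <- list()
  k <- 0L
  for (size in sizes) {
    nTFs <- size %/% 6L
    for (rep in seq_len(nReps)) {
      k <- k + 1L
      repSeed <- seed * 1009L + k * 31L
      pert0 <- if (resample) {
        resampleWithinBlocks(base$network, base$partition, repSeed)
      } else {
        base$network
      }
      pl <- plantModule(pert0, nTFs, seed = repSeed + 7L)
      for (method in methods) {
        sc <- methodGeneScores(method, base$network, pl$network)
        p <- rankTest(sc, pl$truth$targets, test = test)
        rows[[length(rows) + 1L]] <- data.frame(
          method = method, size = size, n_tfs = nTFs, rep = rep,
          p = p, neglog10p = -log10(p), stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a benchmark sweep
#'
#' Mean and standard deviation of -log10 p per (method, size) cell.
#'
#' @param sweep a data.frame from [benchmarkSweep()].
#' @return data.frame with columns method, size, mean_neglog10p,
#'   sd_neglog10p, n.
#' @export
summarizeBenchmark <- function(sweep) {
  agg <- aggregate(neglog10p ~ method + size, data = sweep,
                   FUN = function(v) c(mean = mean(v), sd = stats::sd(v),
                                       n = length(v)))
  out <- data.frame(
    method = agg$method,
    size = agg$size,
    mean_neglog10p = agg$neglog10p[, "mean"],
    sd_neglog10p = agg$neglog10p[, "sd"],
    n = as.integer(agg$neglog10p[, "n"]),
    stringsAsFactors = FALSE
  )
  out[order(out$size, out$method), ]
}
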