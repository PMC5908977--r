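# Shared fixture builders and the exhaustive-partition oracle.

# Random weighted bipartite network with nR regulators and nT targets.
randomBipartiteNetwork <- function(seed, nR = NULL, nT = NULL,
                                   density = 0.6, wmin = 0.1, wmax = 2) {
  set.seed(seed)
  if (is.null(nR)) nR <- sample(2:4, 1)
  if (is.null(nT)) nT <- sample(2:6, 1)
  grid <- expand.grid(r = sprintf("t%d", seq_len(nR)),
                      t = sprintf("g%d", seq_len(nT)),
                      stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < density
  if (sum(keep) < 2) keep[1:2] <- TRUE
  bipartiteNetwork(data.frame(
    regulator = grid$r[keep], target = grid$t[keep],
    weight = round(stats::runif(sum(keep), wmin, wmax), 3)
  ))
}

# Pair of small random networks over overlapping node sets, total <= 10 nodes.
randomBipartitePair <- function(seed) {
  set.seed(seed)
  nR <- sample(2:4, 1)
  nT <- sample(2:6, 1)
  while (nR + nT > 10) nT <- nT - 1
  list(
    base = randomBipartiteNetwork(seed * 2 + 1, nR, nT),
    pert = randomBipartiteNetwork(seed * 2 + 2, nR, nT)
  )
}

# Small random block-structured pair for null-algebra properties.
randomBlockPair <- function(seed) {
  set.seed(seed)
  nb <- sample(2:3, 1)
  spec <- blockBaselineSpec(
    nRegulators = sample(3:6, nb, replace = TRUE),
    nTargets = sample(8:15, nb, replace = TRUE),
    withinDensity = stats::runif(1, 0.4, 0.9),
    betweenDensity = stats::runif(1, 0.05, 0.3)
  )
  base <- simulateBlockBaseline(spec, seed = seed)
  pert <- simulateBlockBaseline(spec, seed = seed + 1000L)$network
  list(base = base$network, truth = base$partition, pert = pert)
}

# Exhaustive maximum of sum_ij S_ij * delta(g_i, g_j) over ALL partitions
# (restricted-growth-string recursion with incremental objective); the
# independent oracle for the Louvain-family optimizer.
maxPartitionObjective <- function(S) {
  n <- nrow(S)
  best <- -Inf
  g <- integer(n)
  recurse <- function(i, q, obj) {
    if (i > n) {
      if (obj > best) best <<- obj
      return(invisible())
    }
    for (c in seq_len(q + 1L)) {
      inc <- if (c <= q) 2 * sum(S[which(g[seq_len(i - 1L)] == c), i]) else 0
      g[i] <<- c
      recurse(i + 1L, max(q, c), obj + inc)
    }
    g[i] <<- 0L
  }
  recurse(1L, 0L, 0)
  best + sum(diag(S))
}

expect_partition_equal <- function(found, truth) {
  ag <- partitionAgreement(found, truth)
  expect_true(ag$exact)
  expect_equal(ag$index, 1)
}
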