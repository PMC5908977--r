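test_that("null expectations on the two-group toy match direct block sums", {
  toy <- twoGroupToy()
  comm <- detectCommunities(toy$baseline)
  ds <- differentialNull(toy$baseline, comm, totalWeight(toy$perturbed))
  expect_equal(ds@scaleFactor, 2 / 3, tolerance = 1e-12)
  N <- as.matrix(nullMatrix(ds))
  expect_equal(N["tf_A01_reg", "g_A01"], 2 / 3, tolerance = 1e-12)
  expect_equal(N["tf_A01_reg", "g_B01"], 8 / 15, tolerance = 1e-12)
  expect_equal(N["tf_B05_reg", "g_B17"], 2 / 3, tolerance = 1e-12)
})

test_that("nodes unconnected in the baseline have zero null expectation", {
  base <- bipartiteNetwork(
    data.frame(regulator = c("t1", "t2"), target = c("g1", "g2"),
               weight = c(1, 1)),
    regulators = "t3", targets = "g3"
  )
  comm <- detectCommunities(base)
  ds <- differentialNull(base, comm, 5)
  N <- as.matrix(nullMatrix(ds))
  expect_equal(unname(N["t3_reg", ]), rep(0, 3))
  expect_equal(unname(N[, "g3"]), rep(0, 3))
})

test_that("null conserves rescaled block weights on random block networks", {
  for (seed in 1:20) {
    pr <- randomBlockPair(seed)
    al <- alignNodeUniverse(pr$base, pr$pert)
    comm <- detectCommunities(al$x)
    ds <- differentialMatrix(al$x, al$y, comm)
    W <- as.matrix(adjacencyMatrix(al$x)) * ds@scaleFactor
    N <- as.matrix(nullMatrix(ds))
    mem <- membership(comm)
    gR <- mem[rownames(N)]
    gT <- mem[colnames(N)]
    for (cx in unique(gR)) {
      for (cy in unique(gT)) {
        blockW <- sum(W[gR == cx, gT == cy, drop = FALSE])
        blockN <- sum(N[gR == cx, gT == cy, drop = FALSE])
        expect_equal(blockN, blockW, tolerance = 1e-9)
      }
    }
  }
})

test_that("identical networks give zero total differential modularity", {
  for (seed in 1:10) {
    net <- thresholdPositive(randomBipartiteNetwork(seed + 50, nR = 4, nT = 9))
    comm <- detectCommunities(net)
    ds <- differentialMatrix(net, net, comm)
    expect_equal(ds@scaleFactor, 1, tolerance = 1e-12)
    expect_lt(abs(totalDifferentialModularity(ds, comm)), 1e-9)
  }
})

test_that("differential matrix entries on the toy match A_P - N", {
  toy <- twoGroupToy()
  comm <- detectCommunities(toy$baseline)
  al <- alignNodeUniverse(toy$baseline, toy$perturbed)
  ds <- differentialMatrix(al$x, al$y, comm)
  D <- as.matrix(differentialMatrixOf(ds))
  expect_equal(D["tf_A01_reg", "g_A01"], 1 / 3, tolerance = 1e-12)
  expect_equal(D["tf_A01_reg", "g_B01"], -1 / 3, tolerance = 1e-12)
  expect_equal(as.matrix(perturbedMatrix(ds) - nullMatrix(ds)), D,
               tolerance = 1e-15)
  expect_error(differentialMatrix(toy$baseline,
                                  thresholdPositive(toy$perturbed, 0.5), comm),
               NA)
})

test_that("module optimization recovers the toy groups and simple cases", {
  toy <- twoGroupToy()
  res <- differentialModules(toy$baseline, toy$perturbed)
  expect_partition_equal(modules(res), toy$truth)

  # a single positive entry: its endpoints share a module, nothing else merges
  base <- bipartiteNetwork(expand.grid(
    regulator = c("t1", "t2"), target = c("g1", "g2"),
    stringsAsFactors = FALSE) |> transform(weight = 1))
  comm <- detectCommunities(base)
  pert <- bipartiteNetwork(data.frame(
    regulator = c("t1", "t1", "t2", "t2"),
    target = c("g1", "g2", "g1", "g2"),
    weight = c(3, 1, 1, 1)
  ))
  ds <- differentialMatrix(base, pert, comm)
  mods <- findDifferentialModules(ds)
  mem <- membership(mods)
  expect_equal(mem[["t1_reg"]], mem[["g1"]])
  D <- as.matrix(differentialMatrixOf(ds))
  expect_true(D["t1_reg", "g1"] > 0)
})

test_that("an identically zero differential matrix yields singletons", {
  base <- bipartiteNetwork(data.frame(
    regulator = "t1", target = "g1", weight = 1
  ))
  comm <- detectCommunities(base)
  ds <- differentialMatrix(base, base, comm)
  expect_warning(mods <- findDifferentialModules(ds), "singleton")
  expect_equal(nCommunities(mods), 2)
})

test_that("optimizer reaches the exhaustive differential maximum on tiny networks", {
  for (seed in 1:40) {
    pr <- randomBipartitePair(seed)
    al <- alignNodeUniverse(pr$base, pr$pert)
    comm <- detectCommunities(al$x)
    ds <- differentialMatrix(al$x, al$y, comm)
    mods <- findDifferentialModules(ds, nRestarts = 10)
    obj <- totalDifferentialModularity(ds, mods)
    oracle <- maxPartitionObjective(diffmod:::symmetrizedD(ds)) /
      (2 * perturbedTotal(ds))
    expect_lte(oracle - obj, 1e-9)
  }
})

test_that("strengthening a block strictly increases its within-module D sum", {
  toy <- twoGroupToy()
  comm <- detectCommunities(toy$baseline)
  al <- alignNodeUniverse(toy$baseline, toy$perturbed)
  blockSum <- function(pert) {
    ds <- differentialMatrix(al$x, pert, comm)
    D <- as.matrix(differentialMatrixOf(ds))
    aRegs <- grep("^tf_A", rownames(D), value = TRUE)
    aTgts <- grep("^g_A", colnames(D), value = TRUE)
    sum(D[aRegs, aTgts])
  }
  e <- edgeTable(al$y)
  boost <- e
  within <- grepl("^tf_A", boost$regulator) & grepl("^g_A", boost$target)
  boost$weight[within] <- boost$weight[within] * 2
  boosted <- new("BipartiteNetwork", regulators = regulatorNodes(al$y),
                 targets = targetNodes(al$y), edges = boost)
  expect_gt(blockSum(boosted), blockSum(al$y))
})

test_that("node scores follow the stated bookkeeping", {
  toy <- twoGroupToy()
  res <- differentialModules(toy$baseline, toy$perturbed)
  sc <- scoreTable(res)
  expect_equal(sc$score[sc$node == "g_A01"], 1 / 288, tolerance = 1e-12)
  # sum of S_i equals twice the total differential modularity
  expect_equal(sum(sc$score), 2 * res@objective, tolerance = 1e-12)
  # normalized scores sum to 1 per module and node class
  agg <- aggregate(normalized_score ~ module_id + node_class, sc, sum)
  expect_equal(agg$normalized_score, rep(1, nrow(agg)), tolerance = 1e-9)
})

test_that("degenerate modules score zero", {
  base <- bipartiteNetwork(expand.grid(
    regulator = c("t1", "t2"), target = c("g1", "g2"),
    stringsAsFactors = FALSE) |> transform(weight = 1))
  comm <- detectCommunities(base)
  ds <- differentialMatrix(base, base, comm)
  nodes <- c(regulatorNodes(base), targetNodes(base))
  singles <- new("Partition",
    membership = stats::setNames(seq_along(nodes), nodes),
    nodeClass = ifelse(nodes %in% regulatorNodes(base), "regulator", "target"))
  sc <- nodeScores(ds, singles)
  expect_equal(sc$score, rep(0, 4))           # singleton modules
  expect_equal(sc$normalized_score, rep(0, 4)) # zero-total modules
})

test_that("core gene lists are ranked, truncated and tie-stable", {
  toy <- twoGroupToy()
  res <- differentialModules(toy$baseline, toy$perturbed)
  core <- coreGeneLists(res)
  expect_length(core, 2)
  expect_equal(lengths(core), c(module_1 = 40L, module_2 = 40L))
  # all scores tie within a module: stable node order expected
  expect_equal(core$module_1, sprintf("g_A%02d", 1:40))

  sc <- scoreTable(res)
  expect_equal(unname(lengths(coreGenes(sc, k = 7))), c(7L, 7L))
  top1 <- coreGenes(sc, k = 1)
  g <- sc[sc$node_class == "target" & sc$module_id == 1, ]
  expect_equal(top1$module_1, g$node[which.max(g$score)])
})

test_that("the full pipeline is deterministic", {
  toy <- twoGroupToy()
  r1 <- differentialModules(toy$baseline, toy$perturbed)
  r2 <- differentialModules(toy$baseline, toy$perturbed)
  expect_identical(membership(modules(r1)), membership(modules(r2)))
  expect_identical(scoreTable(r1), scoreTable(r2))
  expect_identical(r1@objective, r2@objective)
})

test_that("negative perturbed edges can be kept or dropped", {
  base <- bipartiteNetwork(expand.grid(
    regulator = c("t1", "t2"), target = c("g1", "g2"),
    stringsAsFactors = FALSE) |> transform(weight = 1))
  pert <- bipartiteNetwork(data.frame(
    regulator = c("t1", "t1", "t2"),
    target = c("g1", "g2", "g1"),
    weight = c(2, -1, 1)
  ))
  dropRes <- differentialModules(base, pert)
  keepRes <- differentialModules(base, pert, negativePerturbed = "keep")
  expect_equal(perturbedTotal(differentialScore(dropRes)), 3)
  expect_equal(perturbedTotal(differentialScore(keepRes)), 2)
  APk <- as.matrix(perturbedMatrix(differentialScore(keepRes)))
  expect_equal(APk["t1_reg", "g2"], -1)
})
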