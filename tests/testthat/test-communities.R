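twoBicliques <- function(w = 1) {
  bipartiteNetwork(rbind(
    expand.grid(regulator = c("a1", "a2"), target = c("x1", "x2"),
                stringsAsFactors = FALSE),
    expand.grid(regulator = c("b1", "b2"), target = c("y1", "y2"),
                stringsAsFactors = FALSE)
  ) |> transform(weight = w))
}

test_that("modularity matches its closed forms", {
  net <- twoBicliques()
  nodes <- c(regulatorNodes(net), targetNodes(net))
  classes <- ifelse(nodes %in% regulatorNodes(net), "regulator", "target")

  one <- new("Partition",
             membership = stats::setNames(rep(1L, length(nodes)), nodes),
             nodeClass = classes)
  expect_equal(modularityScore(net, one), 0)

  cliques <- new("Partition",
    membership = stats::setNames(
      ifelse(grepl("^(a|x)", nodes), 1L, 2L), nodes),
    nodeClass = classes)
  expect_equal(modularityScore(net, cliques), 0.5)

  dropped <- new("Partition",
                 membership = stats::setNames(rep(1L, length(nodes) - 1),
                                              nodes[-1]),
                 nodeClass = classes[-1])
  expect_error(modularityScore(net, dropped), "cover")
})

test_that("modularity agrees with igraph on random networks and partitions", {
  skip_if_not_installed("igraph")
  for (seed in 1:10) {
    net <- randomBipartiteNetwork(seed, nR = 4, nT = 7)
    e <- edgeTable(net)
    g <- igraph::graph_from_data_frame(
      e, directed = FALSE,
      vertices = data.frame(name = c(regulatorNodes(net), targetNodes(net)))
    )
    set.seed(seed)
    nodes <- c(regulatorNodes(net), targetNodes(net))
    labels <- sample(1:3, length(nodes), replace = TRUE)
    p <- new("Partition",
             membership = stats::setNames(as.integer(labels), nodes),
             nodeClass = ifelse(nodes %in% regulatorNodes(net),
                                "regulator", "target"))
    expect_equal(
      modularityScore(net, p),
      igraph::modularity(g, labels, weights = igraph::E(g)$weight),
      tolerance = 1e-12
    )
  }
})

test_that("community detection recovers planted structure", {
  toy <- twoGroupToy()
  comm <- detectCommunities(toy$baseline)
  expect_partition_equal(comm, toy$truth)

  net <- twoBicliques()
  p <- detectCommunities(net)
  expect_equal(nCommunities(p), 2)
  expect_equal(unname(communitySizes(p)), c(4, 4))
  mem <- membership(p)
  expect_length(unique(mem[c("a1_reg", "a2_reg", "x1", "x2")]), 1)

  single <- bipartiteNetwork(data.frame(
    regulator = "t", target = "g", weight = 1
  ))
  ps <- detectCommunities(single)
  expect_equal(nCommunities(ps), 1)

  empty <- thresholdPositive(bipartiteNetwork(data.frame(
    regulator = "t", target = "g", weight = -2
  )))
  expect_error(detectCommunities(empty), "positive-weight")
})

test_that("detected modularity dominates trivial partitions", {
  for (seed in 1:10) {
    net <- randomBipartiteNetwork(seed + 100, nR = 4, nT = 8)
    p <- detectCommunities(net)
    Q <- modularityScore(net, p)
    nodes <- c(regulatorNodes(net), targetNodes(net))
    classes <- ifelse(nodes %in% regulatorNodes(net), "regulator", "target")
    singletons <- new("Partition",
      membership = stats::setNames(seq_along(nodes), nodes),
      nodeClass = classes)
    allOne <- new("Partition",
      membership = stats::setNames(rep(1L, length(nodes)), nodes),
      nodeClass = classes)
    expect_gte(Q, modularityScore(net, singletons) - 1e-12)
    expect_gte(Q, modularityScore(net, allOne) - 1e-12)
  }
})

test_that("detection reaches the exhaustive modularity maximum on tiny networks", {
  for (seed in 1:40) {
    net <- randomBipartiteNetwork(seed + 200)
    p <- detectCommunities(net, nRestarts = 10)
    Q <- modularityScore(net, p)
    S <- diffmod:::modularityScoreMatrix(net)
    Qmax <- maxPartitionObjective(S) / (2 * totalWeight(net))
    expect_lte(Qmax - Q, 1e-9)
  }
})

test_that("detection at least matches igraph's Louvain on random networks", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    net <- randomBipartiteNetwork(seed + 300, nR = 6, nT = 15)
    Q <- modularityScore(net, detectCommunities(net, nRestarts = 5))
    e <- edgeTable(net)
    g <- igraph::graph_from_data_frame(
      e, directed = FALSE,
      vertices = data.frame(name = c(regulatorNodes(net), targetNodes(net)))
    )
    cl <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    expect_gte(Q, max(cl$modularity) - 1e-9)
  }
})

test_that("detection is deterministic for a fixed node order and seed", {
  net <- randomBipartiteNetwork(42, nR = 5, nT = 12)
  p1 <- detectCommunities(net, nRestarts = 3)
  p2 <- detectCommunities(net, nRestarts = 3)
  expect_identical(membership(p1), membership(p2))

  ord <- shuffledNodeOrder(net, seed = 9)
  q1 <- detectCommunities(net, nodeOrder = ord)
  q2 <- detectCommunities(net, nodeOrder = ord)
  expect_identical(membership(q1), membership(q2))
  expect_error(detectCommunities(net, nodeOrder = ord[-1]), "permutation")
})

test_that("canonical labels are ordered by size then first member", {
  toy <- twoGroupToy()
  p <- detectCommunities(toy$baseline)
  expect_equal(sort(unique(membership(p))), seq_len(nCommunities(p)))
  # equal-sized groups: community 1 must contain the first node (a group-A TF)
  expect_equal(unname(membership(p)["tf_A01_reg"]), 1L)
  expect_equal(unname(communitySizes(p)), sort(communitySizes(p),
                                               decreasing = TRUE))
})
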