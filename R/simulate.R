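# Synthetic network generators: block-structured baselines, planted-module
# perturbations, block-preserving edge resampling, and the exactly specified
# two- and three-group decreased-edge-weight toys.

#' Specification of a block-structured bipartite baseline
#'
#' Describes a stochastic-block bipartite graph: per-community regulator and
#' target counts, and Bernoulli edge densities within and between
#' communities (all edges unweighted, i.e. weight 1). The default emulates
#' a thresholded regulatory network with five communities at one tenth the
#' scale of a typical genome-wide network (401 nodes, community sizes 134,
#' 83, 78, 102 and 4, roughly one regulator per four targets), with dense
#' within-community and sparse between-community connectivity.
#'
#' @param nRegulators,nTargets integer vectors (one entry per community).
#' @param withinDensity,betweenDensity edge probabilities inside a community
#'   and between two communities, in [0, 1].
#' @return A list with class \code{"blockSpec"}.
#' @export
blockBaselineSpec <- function(nRegulators = c(27L, 17L, 16L, 20L, 1L),
                              nTargets = c(107L, 66L, 62L, 82L, 3L),
                              withinDensity = 0.25,
                              betweenDensity = 0.02) {
  stopifnot(length(nRegulators) == length(nTargets),
            all(nRegulators >= 0), all(nTargets >= 0))
  if (withinDensity < 0 || withinDensity > 1 ||
      betweenDensity < 0 || betweenDensity > 1) {
    stop("densities must lie in [0, 1]")
  }
  structure(
    list(nRegulators = as.integer(nRegulators),
         nTargets = as.integer(nTargets),
         withinDensity = withinDensity,
         betweenDensity = betweenDensity),
    class = "blockSpec"
  )
}

#' Simulate a block-structured bipartite baseline network
#'
#' Draws an unweighted (weight 1) bipartite network with planted community
#' structure: each regulator-target pair receives an edge independently with
#' the within-community or between-community density of the spec. The
#' generator is a pure function of (spec, seed).
#'
#' @param spec a [blockBaselineSpec()].
#' @param seed integer seed.
#' @return A list with elements \code{network}
#'   (\linkS4class{BipartiteNetwork}) and \code{partition} (the true block
#'   \linkS4class{Partition}).
#' @export
simulateBlockBaseline <- function(spec = blockBaselineSpec(), seed = 1L) {
  stopifnot(inherits(spec, "blockSpec"))
  nb <- length(spec$nRegulators)
  regNames <- sprintf("tf%03d", seq_len(sum(spec$nRegulators)))
  tgtNames <- sprintf("g%03d", seq_len(sum(spec$nTargets)))
  regBlock <- rep(seq_len(nb), spec$nRegulators)
  tgtBlock <- rep(seq_len(nb), spec$nTargets)
  edges <- withSeed(seed, {
    out <- vector("list", nb * nb)
    k <- 0L
    for (i in seq_len(nb)) {
      for (j in seq_len(nb)) {
        rs <- regNames[regBlock == i]
        ts <- tgtNames[tgtBlock == j]
        if (length(rs) == 0 || length(ts) == 0) next
        d <- if (i == j) spec$withinDensity else spec$betweenDensity
        pick <- stats::runif(length(rs) * length(ts)) < d
        if (!any(pick)) next
        grid <- expand.grid(regulator = rs, target = ts,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        k <- k + 1L
        out[[k]] <- grid[pick, , drop = FALSE]
      }
    }
    do.call(rbind, out[seq_len(k)])
  })
  edges$weight <- 1
  net <- bipartiteNetwork(edges, regulators = regNames, targets = tgtNames)
  nodes <- c(regulatorNodes(net), targetNodes(net))
  labels <- c(regBlock, tgtBlock)
  truth <- newPartition(nodes, canonicalizeLabels(labels),
                        classesFor(nodes, regulatorNodes(net)))
  list(network = net, partition = truth)
}

#' Plant a fully connected module into a network
#'
#' Uniformly samples \code{nTFs} regulators and \code{nGenes} targets
#' (default five times as many genes as TFs) and adds every absent edge
#' between them at weight 1, creating a new densely connected module on top
#' of the existing structure.
#'
#' @param net the baseline \linkS4class{BipartiteNetwork}.
#' @param nTFs number of regulators in the planted module.
#' @param seed integer seed.
#' @param nGenes number of targets in the planted module.
#' @return A list with elements \code{network} (the perturbed network) and
#'   \code{truth} (list with \code{regulators} and \code{targets}: the
#'   namespaced planted node sets).
#' @export
plantModule <- function(net, nTFs, seed = 1L, nGenes = 5L * nTFs) {
  regs <- regulatorNodes(net)
  tgts <- targetNodes(net)
  if (nTFs > length(regs) || nGenes > length(tgts)) {
    stop("network has too few regulators or targets for the requested module")
  }
  sel <- withSeed(seed, list(
    regulators = sample(regs, nTFs),
    targets = sample(tgts, nGenes)
  ))
  W <- as.matrix(adjacencyMatrix(net))
  block <- W[sel$regulators, sel$targets, drop = FALSE]
  block[block == 0] <- 1
  W[sel$regulators, sel$targets] <- block
  list(
    network = networkFromMatrix(W, regs, tgts),
    truth = sel
  )
}

#' Resample edges while preserving block counts
#'
#' Noise model for simulation studies: for every ordered community pair
#' (C_i, C_j), the number of edges between regulators of C_i and targets of
#' C_j is counted, and the same number of edges is placed uniformly at
#' random (without replacement) among that block's possible pairs, at weight
#' 1. Per-block edge counts are conserved exactly, so the community-level
#' structure is retained while individual edges are scrambled. Intended for
#' unweighted (0/1) networks.
#'
#' @param net a \linkS4class{BipartiteNetwork}.
#' @param p a \linkS4class{Partition} covering \code{net}.
#' @param seed integer seed.
#' @return A resampled \linkS4class{BipartiteNetwork} over the same nodes.
#' @export
resampleWithinBlocks <- function(net, p, seed = 1L) {
  regs <- regulatorNodes(net)
  tgts <- targetNodes(net)
  mem <- membership(p)
  missing <- setdiff(c(regs, tgts), names(mem))
  if (length(missing) > 0) {
    stop(sprintf("partition does not cover node(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  W <- adjacencyMatrix(net)
  gR <- mem[regs]
  gT <- mem[tgts]
  out <- withSeed(seed, {
    Wnew <- matrix(0, length(regs), length(tgts))
    for (ci in sort(unique(gR))) {
      for (cj in sort(unique(gT))) {
        rows <- which(gR == ci)
        cols <- which(gT == cj)
        count <- Matrix::nnzero(W[rows, cols, drop = FALSE])
        if (count == 0) next
        cells <- sample.int(length(rows) * length(cols), count)
        blk <- matrix(0, length(rows), length(cols))
        blk[cells] <- 1
        Wnew[rows, cols] <- blk
      }
    }
    Wnew
  })
  networkFromMatrix(out, regs, tgts)
}

# Fully connected bipartite toy builder: weight of (tf in gi, gene in gj)
# given by weightFun(gi, gj).
toyNetwork <- function(groupTFs, groupGenes, weightFun) {
  groups <- names(groupTFs)
  regs <- unlist(lapply(groups, function(g) {
    sprintf("tf_%s%02d", g, seq_len(groupTFs[[g]]))
  }))
  tgts <- unlist(lapply(groups, function(g) {
    sprintf("g_%s%02d", g, seq_len(groupGenes[[g]]))
  }))
  regGroup <- rep(groups, unlist(groupTFs))
  tgtGroup <- rep(groups, unlist(groupGenes))
  grid <- expand.grid(r = seq_along(regs), t = seq_along(tgts),
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$r, grid$t), ]
  edges <- data.frame(
    regulator = regs[grid$r],
    target = tgts[grid$t],
    weight = mapply(weightFun, regGroup[grid$r], tgtGroup[grid$t]),
    stringsAsFactors = FALSE
  )
  net <- bipartiteNetwork(edges)
  nodes <- c(regulatorNodes(net), targetNodes(net))
  labels <- match(c(regGroup, tgtGroup), groups)
  truth <- newPartition(nodes, canonicalizeLabels(labels),
                        classesFor(nodes, regulatorNodes(net)))
  list(network = net, truth = truth)
}

#' Two-group decreased-edge-weight toy networks
#'
#' Builds the fully connected 100-node bipartite pair with two node groups A
#' and B, each containing 10 TFs and 40 genes. Edges within each group have
#' weight 1.0; edges between groups A and B have weight 0.8 in the baseline
#' network and 0.2 in the perturbed network (every TF-gene pair carries a
#' weight, so the two conditions differ only on the A-B cross edges). The
#' expected differential modules for this transition are exactly groups A
#' and B.
#'
#' @return A list with elements \code{baseline}, \code{perturbed}
#'   (\linkS4class{BipartiteNetwork}) and \code{truth} (the group
#'   \linkS4class{Partition}).
#' @examples
#' toy <- twoGroupToy()
#' totalWeight(toy$baseline)   # 1440
#' totalWeight(toy$perturbed)  # 960
#' @export
twoGroupToy <- function() {
  tfs <- c(A = 10L, B = 10L)
  genes <- c(A = 40L, B = 40L)
  wgt <- function(cross) {
    function(gi, gj) if (gi == gj) 1.0 else cross
  }
  base <- toyNetwork(tfs, genes, wgt(0.8))
  pert <- toyNetwork(tfs, genes, wgt(0.2))
  list(baseline = base$network, perturbed = pert$network, truth = base$truth)
}

#' Three-group decreased-edge-weight toy networks
#'
#' Builds the fully connected 125-node bipartite pair with three node groups
#' A, B and C of 50, 25 and 50 nodes (10, 5 and 10 of them TFs). Weights:
#' 1.0 within each group; 0.2 between B and C in both conditions; 0.8 (A-B,
#' baseline) vs 0.2 (A-B, perturbed); and the default 0.1 for the remaining
#' (A-C) pairs in both conditions. Only the A-B block differs between the
#' two networks.
#'
#' @return A list with elements \code{baseline}, \code{perturbed} and
#'   \code{truth} as in [twoGroupToy()].
#' @export
threeGroupToy <- function() {
  tfs <- c(A = 10L, B = 5L, C = 10L)
  genes <- c(A = 40L, B = 20L, C = 40L)
  wgt <- function(ab) {
    function(gi, gj) {
      pair <- paste(sort(c(gi, gj)), collapse = "")
      switch(pair,
        AA = 1.0, BB = 1.0, CC = 1.0,
        AB = ab,
        BC = 0.2,
        AC = 0.1
      )
    }
  }
  base <- toyNetwork(tfs, genes, wgt(0.8))
  pert <- toyNetwork(tfs, genes, wgt(0.2))
  list(baseline = base$network, perturbed = pert$network, truth = base$truth)
}
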