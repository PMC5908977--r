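# Differential modularity: null model, score matrix, optimization, node
# scores and core genes.

#' Community-conditioned null expectation
#'
#' Computes the null expectation N_ij for every (regulator i, target j) pair
#' from the baseline network and its community structure. The baseline edge
#' weights are first globally rescaled by m_P / m so their total matches the
#' perturbed total m_P; then
#' \deqn{N_{ij} = \frac{(\sum_{b \in C_j} \tilde w_{ib})
#'   (\sum_{a \in C_i} \tilde w_{aj})}{\sum_{a \in C_i, b \in C_j}
#'   \tilde w_{ab}},}
#' where C_i is the baseline community of node i. When numerator and
#' denominator are both zero — no baseline weight at all between the two
#' communities, e.g. a node unconnected in the baseline — N_ij is defined to
#' be zero. Summed over any baseline community pair, N reproduces the
#' rescaled baseline block weight exactly (configuration-model conservation
#' at block level).
#'
#' @param baseline a positive-thresholded \linkS4class{BipartiteNetwork}
#'   with m > 0.
#' @param p baseline \linkS4class{Partition} covering all its nodes.
#' @param mP total perturbed edge weight (> 0).
#' @return A \linkS4class{DifferentialScore} with slots \code{N},
#'   \code{scaleFactor}, \code{mP} and \code{baselinePartition} populated
#'   (\code{AP} and \code{D} are left all-zero; see
#'   [differentialMatrix()]).
#' @export
differentialNull <- function(baseline, p, mP) {
  stopifnot(mP > 0)
  m <- totalWeight(baseline)
  if (m <= 0) stop("baseline network has zero total weight")
  nodes <- c(regulatorNodes(baseline), targetNodes(baseline))
  mem <- membership(p)
  missing <- setdiff(nodes, names(mem))
  if (length(missing) > 0) {
    stop(sprintf("baseline partition does not cover node(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  W <- as.matrix(adjacencyMatrix(baseline)) * (mP / m)
  gR <- mem[regulatorNodes(baseline)]
  gT <- mem[targetNodes(baseline)]
  q <- max(c(gR, gT))
  MR <- matrix(0, nrow(W), q)
  MR[cbind(seq_len(nrow(W)), gR)] <- 1
  MT <- matrix(0, ncol(W), q)
  MT[cbind(seq_len(ncol(W)), gT)] <- 1
  rowToBlock <- W %*% MT          # sum_{b in C} w~_ib
  colToBlock <- crossprod(W, MR)  # sum_{a in C} w~_aj
  Wblk <- crossprod(MR, W %*% MT) # block totals
  den <- Wblk[gR, gT, drop = FALSE]
  N <- rowToBlock[, gT, drop = FALSE] * t(colToBlock[, gR, drop = FALSE]) / den
  N[den == 0] <- 0
  Nsp <- Matrix::drop0(asDgc(N))
  dimnames(Nsp) <- list(regulatorNodes(baseline), targetNodes(baseline))
  zero <- Matrix::sparseMatrix(
    i = integer(0), j = integer(0), x = numeric(0), dims = dim(Nsp),
    dimnames = dimnames(Nsp)
  )
  new("DifferentialScore",
    AP = zero, N = Nsp, D = zero, mP = as.numeric(mP),
    scaleFactor = mP / m, baselinePartition = p
  )
}

#' Differential modularity matrix
#'
#' Computes D = A_P - N, where A_P is the perturbed adjacency and N the
#' community-conditioned null of [differentialNull()]. Both networks must be
#' expressed over the same (aligned) node universe; use
#' [alignNodeUniverse()] first. D is stored sparsely on the union of the
#' supports of A_P and N.
#'
#' @param baseline,perturbed aligned, positive-thresholded
#'   \linkS4class{BipartiteNetwork} objects.
#' @param p baseline \linkS4class{Partition}.
#' @return A fully populated \linkS4class{DifferentialScore}.
#' @export
differentialMatrix <- function(baseline, perturbed, p) {
  if (!identical(regulatorNodes(baseline), regulatorNodes(perturbed)) ||
      !identical(targetNodes(baseline), targetNodes(perturbed))) {
    stop("networks must be aligned on a common node universe; ",
         "see alignNodeUniverse()")
  }
  mP <- totalWeight(perturbed)
  if (mP <= 0) stop("perturbed network has zero total weight")
  ds <- differentialNull(baseline, p, mP)
  AP <- asDgc(adjacencyMatrix(perturbed))
  methods::initialize(ds, AP = AP, D = asDgc(Matrix::drop0(AP - ds@N)))
}

# Dense symmetric differential score matrix over the joint node set.
symmetrizedD <- function(ds) {
  D <- as.matrix(ds@D)
  nr <- nrow(D)
  nt <- ncol(D)
  S <- matrix(0, nr + nt, nr + nt)
  S[seq_len(nr), nr + seq_len(nt)] <- D
  S[nr + seq_len(nt), seq_len(nr)] <- t(D)
  rownames(S) <- colnames(S) <- c(rownames(D), colnames(D))
  S
}

#' Optimize the differential modularity
#'
#' Assigns nodes to differential modules by maximizing
#' (1/m_P) sum_ij D_ij delta(M_i, M_j) with the generalized Louvain
#' procedure on the symmetrized D matrix. Negative entries are used as-is;
#' nodes are visited in the fixed given order every time and equal-gain ties
#' resolve to the first candidate, so the output is deterministic.
#'
#' @param ds a \linkS4class{DifferentialScore} from
#'   [differentialMatrix()].
#' @param nodeOrder optional character node order (see
#'   [detectCommunities()]).
#' @param nRestarts optimization runs; later runs use seeded shuffles of the
#'   order and the highest-objective partition is kept.
#' @param seed integer seed for restart shuffles.
#' @param tol minimum objective gain to accept a move.
#' @return A canonicalized \linkS4class{Partition} of differential modules.
#' @export
findDifferentialModules <- function(ds, nodeOrder = NULL, nRestarts = 1L,
                                    seed = 1L, tol = 1e-12) {
  S <- symmetrizedD(ds)
  nodes <- rownames(S)
  classes <- classesFor(nodes, rownames(ds@D))
  if (all(S == 0)) {
    warning("differential matrix is identically zero; every node is a singleton")
    return(newPartition(nodes, seq_along(nodes), classes))
  }
  ord <- resolveNodeOrder(nodes, nodeOrder)
  lab <- louvainRestarts(S, ord, nRestarts = nRestarts, seed = seed, tol = tol)
  newPartition(nodes, canonicalizeLabels(lab), classes)
}

#' Score nodes by their contribution to the differential modularity
#'
#' For each node, S_i = (1/m_P) sum_j D_ij delta(M_i, M_j), where the sum
#' runs over nodes of the opposite class in the same module (for a target
#' gene, the regulators of its module, and vice versa). The normalized score
#' divides the module-restricted sum by the module's total differential
#' weight, so that genes in small modules are not penalized; within a module
#' the normalized scores of each node class sum to 1 whenever the module
#' total is nonzero, and are defined as 0 for a module with exactly zero
#' total. Under this bookkeeping the sum of S_i over all nodes equals twice
#' the total within-module differential modularity (each regulator-target
#' pair contributes to both endpoints).
#'
#' @param ds a \linkS4class{DifferentialScore}.
#' @param modules a \linkS4class{Partition} covering all nodes of
#'   \code{ds}.
#' @return data.frame with columns node (original name), node_class,
#'   module_id, score, normalized_score.
#' @export
nodeScores <- function(ds, modules) {
  D <- as.matrix(ds@D)
  regs <- rownames(D)
  tgts <- colnames(D)
  mem <- membership(modules)
  missing <- setdiff(c(regs, tgts), names(mem))
  if (length(missing) > 0) {
    stop(sprintf("module partition does not cover node(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  gR <- mem[regs]
  gT <- mem[tgts]
  mask <- outer(gR, gT, "==")
  Din <- D * mask
  sReg <- rowSums(Din) / ds@mP
  sTgt <- colSums(Din) / ds@mP
  q <- max(mem)
  modTotal <- vapply(seq_len(q), function(c) {
    sum(Din[gR == c, gT == c, drop = FALSE])
  }, numeric(1))
  normFor <- function(s, g) {
    tot <- modTotal[g]
    ifelse(tot == 0, 0, s * ds@mP / tot)
  }
  data.frame(
    node = c(stripRegulator(regs), tgts),
    node_class = c(rep("regulator", length(regs)), rep("target", length(tgts))),
    module_id = as.integer(c(gR, gT)),
    score = c(sReg, sTgt),
    normalized_score = c(normFor(sReg, gR), normFor(sTgt, gT)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Top core genes of each differential module
#'
#' Ranks the target genes of every module by their differential modularity
#' contribution S_i (descending; ties broken by stable node order) and
#' truncates at \code{k}. These ranked lists are the hand-off point for
#' downstream pathway-enrichment analyses.
#'
#' @param scores a node score data.frame from [nodeScores()].
#' @param k number of genes to keep per module (default 50; 100 is a common
#'   sensitivity check).
#' @return Named list, one character vector of gene names per module id.
#' @export
coreGenes <- function(scores, k = 50L) {
  stopifnot(k >= 1)
  genes <- scores[scores$node_class == "target", , drop = FALSE]
  out <- lapply(split(genes, genes$module_id), function(df) {
    df <- df[order(-df$score), , drop = FALSE]  # stable: ties keep node order
    utils::head(df$node, k)
  })
  names(out) <- paste0("module_", names(out))
  out
}

#' Full differential module analysis of two networks
#'
#' Runs the complete pipeline: (1) threshold both networks to positive
#' weights and align their node universes; (2) detect communities in the
#' baseline network; (3) compute the differential modularity matrix of the
#' perturbed network against the community-conditioned null and optimize it;
#' (4) score every node and extract per-module core genes. All intermediate
#' artifacts are kept in the returned object.
#'
#' @param baseline,perturbed \linkS4class{BipartiteNetwork} objects (need
#'   not be aligned).
#' @param threshold weight cutoff for [thresholdPositive()] (default 0).
#' @param negativePerturbed how to treat non-positive perturbed edges:
#'   \code{"drop"} (default; mirrors the baseline convention) or
#'   \code{"keep"} (negative weights enter A_P as-is and contribute
#'   negatively).
#' @param nodeOrder optional node order for the module optimization.
#' @param nRestartsBaseline,nRestartsModules restart counts for the two
#'   Louvain stages.
#' @param seed integer seed for restart shuffles.
#' @param coreSize core gene list size per module.
#' @param tol Louvain gain tolerance.
#' @return A \linkS4class{DifferentialModularityResult}.
#' @examples
#' toy <- twoGroupToy()
#' res <- differentialModules(toy$baseline, toy$perturbed)
#' res
#' communitySizes(modules(res))
#' @export
differentialModules <- function(baseline, perturbed, threshold = 0,
                                negativePerturbed = c("drop", "keep"),
                                nodeOrder = NULL, nRestartsBaseline = 1L,
                                nRestartsModules = 1L, seed = 1L,
                                coreSize = 50L, tol = 1e-12) {
  negativePerturbed <- match.arg(negativePerturbed)
  base <- thresholdPositive(baseline, threshold)
  pert <- if (negativePerturbed == "drop") {
    thresholdPositive(perturbed, threshold)
  } else {
    perturbed
  }
  if (nrow(edgeTable(base)) == 0) stop("baseline is empty after thresholding")
  if (nrow(edgeTable(pert)) == 0) stop("perturbed is empty after thresholding")
  al <- alignNodeUniverse(base, pert)
  comm <- detectCommunities(al$x, nRestarts = nRestartsBaseline, seed = seed,
                            tol = tol)
  ds <- differentialMatrix(al$x, al$y, comm)
  mods <- findDifferentialModules(ds, nodeOrder = nodeOrder,
                                  nRestarts = nRestartsModules, seed = seed,
                                  tol = tol)
  sc <- nodeScores(ds, mods)
  new("DifferentialModularityResult",
    baselineCommunities = comm,
    differential = ds,
    modules = mods,
    scores = sc,
    coreGenes = coreGenes(sc, coreSize),
    objective = totalDifferentialModularity(ds, mods)
  )
}

#' Total differential modularity of a module assignment
#'
#' (1/m_P) * sum of D over within-module regulator-target pairs, each
#' unordered pair counted once. With perturbed = baseline and modules equal
#' to the baseline communities this is exactly 0 (block-level conservation
#' of the null).
#'
#' @param ds a \linkS4class{DifferentialScore}.
#' @param modules a \linkS4class{Partition}.
#' @return A single number.
#' @export
totalDifferentialModularity <- function(ds, modules) {
  D <- as.matrix(ds@D)
  mem <- membership(modules)
  gR <- mem[rownames(D)]
  gT <- mem[colnames(D)]
  sum(D * outer(gR, gT, "==")) / ds@mP
}
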