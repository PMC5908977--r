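#' @import methods
#' @importFrom Matrix sparseMatrix drop0 t rowSums colSums
NULL

#' Weighted bipartite regulatory network
#'
#' Represents a weighted bipartite graph between a set of regulator nodes
#' (e.g. transcription-factor proteins) and a set of target nodes (genes).
#' The two namespaces are kept disjoint even when the same gene symbol occurs
#' on both sides: regulator identifiers carry an internal \code{"_reg"}
#' suffix, applied on construction, and stripped again on output.
#'
#' @slot regulators character vector of namespaced regulator identifiers, in
#'   order of first appearance.
#' @slot targets character vector of target identifiers, in order of first
#'   appearance.
#' @slot edges data.frame with columns \code{regulator} (namespaced),
#'   \code{target} and \code{weight}; at most one row per node pair.
#'
#' @seealso [bipartiteNetwork()], [readBipartiteNetwork()],
#'   [thresholdPositive()], [scaleToTotal()]
#' @exportClass BipartiteNetwork
setClass("BipartiteNetwork",
  representation(
    regulators = "character",
    targets = "character",
    edges = "data.frame"
  )
)

setValidity("BipartiteNetwork", function(object) {
  e <- object@edges
  msgs <- character()
  if (!identical(colnames(e), c("regulator", "target", "weight"))) {
    msgs <- c(msgs, "edges must have columns regulator, target, weight")
  } else {
    if (!all(e$regulator %in% object@regulators)) {
      msgs <- c(msgs, "edge regulator not in regulator set")
    }
    if (!all(e$target %in% object@targets)) {
      msgs <- c(msgs, "edge target not in target set")
    }
    if (anyDuplicated(paste(e$regulator, e$target, sep = "\r"))) {
      msgs <- c(msgs, "duplicate (regulator, target) edge")
    }
    if (nrow(e) > 0 && !is.numeric(e$weight)) {
      msgs <- c(msgs, "weights must be numeric")
    }
  }
  if (anyDuplicated(object@regulators)) msgs <- c(msgs, "duplicate regulator ids")
  if (anyDuplicated(object@targets)) msgs <- c(msgs, "duplicate target ids")
  if (length(intersect(object@regulators, object@targets)) > 0) {
    msgs <- c(msgs, "regulator and target namespaces must be disjoint")
  }
  if (length(msgs)) msgs else TRUE
})

#' Node partition of a network
#'
#' Assignment of every node of a network to exactly one community (or, for
#' the differential analysis, one differential module). Labels are
#' canonicalized to 1..q by decreasing community size, ties broken by the
#' community containing the earliest node in the node order.
#'
#' @slot membership named integer vector; names are (namespaced) node
#'   identifiers, values are community labels in 1..q.
#' @slot nodeClass character vector parallel to \code{membership} with values
#'   \code{"regulator"} or \code{"target"}.
#'
#' @seealso [detectCommunities()], [findDifferentialModules()],
#'   [partitionAgreement()]
#' @exportClass Partition
setClass("Partition",
  representation(
    membership = "integer",
    nodeClass = "character"
  )
)

setValidity("Partition", function(object) {
  msgs <- character()
  if (is.null(names(object@membership))) {
    msgs <- c(msgs, "membership must be a named integer vector")
  }
  if (anyDuplicated(names(object@membership))) {
    msgs <- c(msgs, "duplicate node names in membership")
  }
  if (length(object@nodeClass) != length(object@membership)) {
    msgs <- c(msgs, "nodeClass must be parallel to membership")
  }
  if (!all(object@nodeClass %in% c("regulator", "target"))) {
    msgs <- c(msgs, "nodeClass values must be 'regulator' or 'target'")
  }
  if (length(object@membership) > 0) {
    if (anyNA(object@membership) || any(object@membership < 1L)) {
      msgs <- c(msgs, "labels must be positive integers")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Differential modularity matrices
#'
#' Holds the ingredients of the differential comparison of a perturbed
#' network against a baseline network: the perturbed adjacency A_P, the
#' community-conditioned null expectation N, and their difference
#' D = A_P - N, all as sparse regulator x target matrices over the aligned
#' node universe, together with the total perturbed weight m_P, the global
#' rescaling factor m_P / m applied to the baseline, and the baseline
#' partition that conditions the null.
#'
#' @slot AP sparse \code{dgCMatrix}, perturbed weights.
#' @slot N sparse \code{dgCMatrix}, null expectations.
#' @slot D sparse \code{dgCMatrix}, \code{AP - N}.
#' @slot mP numeric(1), total perturbed edge weight.
#' @slot scaleFactor numeric(1), \code{mP / m} for the baseline total m.
#' @slot baselinePartition [Partition-class] of the baseline network.
#'
#' @seealso [differentialNull()], [differentialMatrix()],
#'   [findDifferentialModules()], [nodeScores()]
#' @exportClass DifferentialScore
setClass("DifferentialScore",
  representation(
    AP = "dgCMatrix",
    N = "dgCMatrix",
    D = "dgCMatrix",
    mP = "numeric",
    scaleFactor = "numeric",
    baselinePartition = "Partition"
  )
)

setValidity("DifferentialScore", function(object) {
  msgs <- character()
  if (!identical(dim(object@AP), dim(object@N)) ||
      !identical(dim(object@AP), dim(object@D))) {
    msgs <- c(msgs, "AP, N and D must share dimensions")
  }
  if (length(object@mP) != 1 || object@mP <= 0) {
    msgs <- c(msgs, "mP must be a single positive number")
  }
  if (length(msgs)) msgs else TRUE
})

#' Linear community membership mapping
#'
#' Machinery of the community-comparison benchmark: indicator matrices A
#' (baseline) and B (perturbed) of the separately detected community
#' structures, the least-squares mapping R solving B = A R (computed through
#' the SVD pseudoinverse of A), and the per-node conservation score
#' S_i = sum_k (A R)_ik B_ik. Low scores mark nodes whose community context
#' changed.
#'
#' @slot A numeric matrix, n x q baseline membership indicators.
#' @slot B numeric matrix, n x q' perturbed membership indicators.
#' @slot R numeric matrix, q x q' mapping.
#' @slot scores named numeric vector of per-node conservation scores.
#' @slot baselinePartition [Partition-class] detected on the baseline.
#' @slot perturbedPartition [Partition-class] detected on the perturbed
#'   network.
#'
#' @seealso [communityComparison()]
#' @exportClass MembershipMapping
setClass("MembershipMapping",
  representation(
    A = "matrix",
    B = "matrix",
    R = "matrix",
    scores = "numeric",
    baselinePartition = "Partition",
    perturbedPartition = "Partition"
  )
)

setValidity("MembershipMapping", function(object) {
  msgs <- character()
  if (nrow(object@A) != nrow(object@B)) {
    msgs <- c(msgs, "A and B must have the same number of rows")
  }
  if (!identical(dim(object@R), c(ncol(object@A), ncol(object@B)))) {
    msgs <- c(msgs, "R must be ncol(A) x ncol(B)")
  }
  bad <- function(M) any(abs(rowSums(M) - 1) > 1e-8)
  if (nrow(object@A) > 0 && (bad(object@A) || bad(object@B))) {
    msgs <- c(msgs, "each row of A and B must contain exactly one 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Result of a differential module analysis
#'
#' Bundles every artifact of the pipeline: the baseline community structure,
#' the differential modularity matrices, the optimized differential modules,
#' the per-node score table and the per-module core gene lists.
#'
#' @slot baselineCommunities [Partition-class] found on the thresholded,
#'   aligned baseline network.
#' @slot differential [DifferentialScore-class].
#' @slot modules [Partition-class] of differential modules.
#' @slot scores data.frame with columns node, node_class, module_id, score,
#'   normalized_score (see [nodeScores()]).
#' @slot coreGenes named list (one entry per module) of ranked core target
#'   genes.
#' @slot objective numeric(1): (1/m_P) sum of D over within-module
#'   regulator-target pairs, each unordered pair counted once.
#'
#' @seealso [differentialModules()]
#' @exportClass DifferentialModularityResult
setClass("DifferentialModularityResult",
  representation(
    baselineCommunities = "Partition",
    differential = "DifferentialScore",
    modules = "Partition",
    scores = "data.frame",
    coreGenes = "list",
    objective = "numeric"
  )
)
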