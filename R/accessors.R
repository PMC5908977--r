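# Generics, accessors and show methods for the core classes.

#' @rdname BipartiteNetwork-class
#' @param object,net a \linkS4class{BipartiteNetwork}
#' @export
setGeneric("regulatorNodes", function(object) standardGeneric("regulatorNodes"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("targetNodes", function(object) standardGeneric("targetNodes"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("edgeTable", function(object) standardGeneric("edgeTable"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("totalWeight", function(object) standardGeneric("totalWeight"))

#' @rdname BipartiteNetwork-class
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))

#' @describeIn BipartiteNetwork-class namespaced regulator identifiers.
#' @export
setMethod("regulatorNodes", "BipartiteNetwork", function(object) object@regulators)

#' @describeIn BipartiteNetwork-class target identifiers.
#' @export
setMethod("targetNodes", "BipartiteNetwork", function(object) object@targets)

#' @describeIn BipartiteNetwork-class the edge list as a data.frame
#'   (namespaced regulator ids).
#' @export
setMethod("edgeTable", "BipartiteNetwork", function(object) object@edges)

#' @describeIn BipartiteNetwork-class total edge weight m (sum of all
#'   retained edge weights).
#' @export
setMethod("totalWeight", "BipartiteNetwork", function(object) {
  if (nrow(object@edges) == 0) 0 else sum(object@edges$weight)
})

#' @describeIn BipartiteNetwork-class sparse regulator x target weight
#'   matrix (\code{dgCMatrix}) with namespaced dimnames.
#' @export
setMethod("adjacencyMatrix", "BipartiteNetwork", function(object) {
  e <- object@edges
  Matrix::sparseMatrix(
    i = match(e$regulator, object@regulators),
    j = match(e$target, object@targets),
    x = as.numeric(e$weight),
    dims = c(length(object@regulators), length(object@targets)),
    dimnames = list(object@regulators, object@targets)
  )
})

setMethod("show", "BipartiteNetwork", function(object) {
  cat(sprintf(
    "BipartiteNetwork: %d regulators, %d targets, %d edges, total weight m = %.6g\n",
    length(object@regulators), length(object@targets),
    nrow(object@edges), totalWeight(object)
  ))
})

#' @rdname Partition-class
#' @param object a \linkS4class{Partition}
#' @export
setGeneric("membership", function(object) standardGeneric("membership"))

#' @rdname Partition-class
#' @export
setGeneric("nCommunities", function(object) standardGeneric("nCommunities"))

#' @rdname Partition-class
#' @export
setGeneric("communitySizes", function(object) standardGeneric("communitySizes"))

#' @rdname Partition-class
#' @export
setGeneric("nodeClasses", function(object) standardGeneric("nodeClasses"))

#' @describeIn Partition-class named integer vector of community labels.
#' @export
setMethod("membership", "Partition", function(object) object@membership)

#' @describeIn Partition-class number of communities q.
#' @export
setMethod("nCommunities", "Partition", function(object) {
  if (length(object@membership) == 0) 0L else max(object@membership)
})

#' @describeIn Partition-class table of community sizes, indexed by label.
#' @export
setMethod("communitySizes", "Partition", function(object) {
  tabulate(object@membership, nbins = nCommunities(object))
})

#' @describeIn Partition-class per-node class ("regulator" or "target"),
#'   named by node.
#' @export
setMethod("nodeClasses", "Partition", function(object) {
  stats::setNames(object@nodeClass, names(object@membership))
})

setMethod("show", "Partition", function(object) {
  sz <- communitySizes(object)
  cat(sprintf(
    "Partition: %d nodes in %d communities (sizes: %s)\n",
    length(object@membership), nCommunities(object),
    paste(sz, collapse = ", ")
  ))
})

#' @rdname DifferentialScore-class
#' @param object a \linkS4class{DifferentialScore}
#' @export
setGeneric("differentialMatrixOf", function(object) standardGeneric("differentialMatrixOf"))

#' @rdname DifferentialScore-class
#' @export
setGeneric("nullMatrix", function(object) standardGeneric("nullMatrix"))

#' @rdname DifferentialScore-class
#' @export
setGeneric("perturbedMatrix", function(object) standardGeneric("perturbedMatrix"))

#' @rdname DifferentialScore-class
#' @export
setGeneric("perturbedTotal", function(object) standardGeneric("perturbedTotal"))

#' @describeIn DifferentialScore-class the sparse difference matrix D.
#' @export
setMethod("differentialMatrixOf", "DifferentialScore", function(object) object@D)

#' @describeIn DifferentialScore-class the sparse null expectation N.
#' @export
setMethod("nullMatrix", "DifferentialScore", function(object) object@N)

#' @describeIn DifferentialScore-class the sparse perturbed adjacency A_P.
#' @export
setMethod("perturbedMatrix", "DifferentialScore", function(object) object@AP)

#' @describeIn DifferentialScore-class total perturbed edge weight m_P.
#' @export
setMethod("perturbedTotal", "DifferentialScore", function(object) object@mP)

setMethod("show", "DifferentialScore", function(object) {
  cat(sprintf(
    "DifferentialScore: %d x %d (regulators x targets), m_P = %.6g, scale = %.6g\n",
    nrow(object@D), ncol(object@D), object@mP, object@scaleFactor
  ))
  cat(sprintf(
    "  nonzero entries: A_P %d, N %d, D %d; baseline communities: %d\n",
    Matrix::nnzero(object@AP), Matrix::nnzero(object@N),
    Matrix::nnzero(object@D), nCommunities(object@baselinePartition)
  ))
})

#' @rdname MembershipMapping-class
#' @param object a \linkS4class{MembershipMapping}
#' @export
setGeneric("mappingMatrix", function(object) standardGeneric("mappingMatrix"))

#' @rdname MembershipMapping-class
#' @export
setGeneric("conservationScores", function(object) standardGeneric("conservationScores"))

#' @describeIn MembershipMapping-class the q x q' linear mapping matrix R.
#' @export
setMethod("mappingMatrix", "MembershipMapping", function(object) object@R)

#' @describeIn MembershipMapping-class named numeric vector of per-node
#'   conservation scores; low values flag changed community context.
#' @export
setMethod("conservationScores", "MembershipMapping", function(object) object@scores)

setMethod("show", "MembershipMapping", function(object) {
  cat(sprintf(
    "MembershipMapping: %d nodes, %d baseline -> %d perturbed communities\n",
    nrow(object@A), ncol(object@A), ncol(object@B)
  ))
  cat(sprintf(
    "  conservation scores: min %.4g, median %.4g, max %.4g\n",
    min(object@scores), stats::median(object@scores), max(object@scores)
  ))
})

#' @rdname DifferentialModularityResult-class
#' @param object a \linkS4class{DifferentialModularityResult}
#' @export
setGeneric("modules", function(object) standardGeneric("modules"))

#' @rdname DifferentialModularityResult-class
#' @export
setGeneric("scoreTable", function(object) standardGeneric("scoreTable"))

#' @rdname DifferentialModularityResult-class
#' @export
setGeneric("coreGeneLists", function(object) standardGeneric("coreGeneLists"))

#' @rdname DifferentialModularityResult-class
#' @export
setGeneric("baselineCommunities", function(object) standardGeneric("baselineCommunities"))

#' @rdname DifferentialModularityResult-class
#' @export
setGeneric("differentialScore", function(object) standardGeneric("differentialScore"))

#' @describeIn DifferentialModularityResult-class the differential module
#'   [Partition-class].
#' @export
setMethod("modules", "DifferentialModularityResult", function(object) object@modules)

#' @describeIn DifferentialModularityResult-class per-node score data.frame.
#' @export
setMethod("scoreTable", "DifferentialModularityResult", function(object) object@scores)

#' @describeIn DifferentialModularityResult-class named list of ranked core
#'   target genes per module.
#' @export
setMethod("coreGeneLists", "DifferentialModularityResult", function(object) object@coreGenes)

#' @describeIn DifferentialModularityResult-class the baseline
#'   [Partition-class].
#' @export
setMethod("baselineCommunities", "DifferentialModularityResult",
          function(object) object@baselineCommunities)

#' @describeIn DifferentialModularityResult-class the
#'   [DifferentialScore-class] with A_P, N and D.
#' @export
setMethod("differentialScore", "DifferentialModularityResult",
          function(object) object@differential)

setMethod("show", "DifferentialModularityResult", function(object) {
  cat("Differential module analysis\n")
  cat(sprintf(
    "  baseline communities: %d; differential modules: %d\n",
    nCommunities(object@baselineCommunities), nCommunities(object@modules)
  ))
  cat(sprintf(
    "  module sizes: %s\n",
    paste(communitySizes(object@modules), collapse = ", ")
  ))
  cat(sprintf("  differential modularity: %.6g\n", object@objective))
})
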