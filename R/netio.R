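# Reading, writing, thresholding and normalizing bipartite networks.

#' Construct a bipartite network from an edge table
#'
#' Builds a \linkS4class{BipartiteNetwork} from a three-column edge table of
#' (regulator, target, weight) rows given in original (un-namespaced) names.
#' Regulator identifiers receive an internal \code{"_reg"} suffix so that a
#' gene appearing both as a transcription factor and as a target is kept as
#' two distinct nodes. Node order is the order of first appearance, with any
#' extra (isolated) nodes appended.
#'
#' @param edges data.frame (or coercible) with columns regulator, target,
#'   weight.
#' @param regulators,targets optional character vectors of additional node
#'   names (original names) to include as isolated nodes, and/or to fix the
#'   node order; nodes present in \code{edges} but not listed are appended.
#' @return A \linkS4class{BipartiteNetwork}.
#' @examples
#' net <- bipartiteNetwork(data.frame(
#'   regulator = c("t1", "t1", "t2"),
#'   target = c("g1", "g2", "g1"),
#'   weight = c(1, 0.5, -0.2)
#' ))
#' totalWeight(net)
#' @export
bipartiteNetwork <- function(edges, regulators = NULL, targets = NULL) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 3) stop("edge table must have three columns")
  edges <- edges[, 1:3]
  colnames(edges) <- c("regulator", "target", "weight")
  edges$regulator <- namespaceRegulator(as.character(edges$regulator))
  edges$target <- as.character(edges$target)
  edges$weight <- as.numeric(edges$weight)
  dup <- duplicated(paste(edges$regulator, edges$target, sep = "\r"))
  if (any(dup)) {
    stop(sprintf(
      "duplicate edge(s): %s",
      paste(stripRegulator(edges$regulator[dup]), edges$target[dup],
            sep = "->", collapse = ", ")
    ))
  }
  regs <- unique(c(namespaceRegulator(as.character(regulators)), edges$regulator))
  tgts <- unique(c(as.character(targets), edges$target))
  rownames(edges) <- NULL
  new("BipartiteNetwork", regulators = regs, targets = tgts, edges = edges)
}

#' Read a bipartite network from an edge-list file
#'
#' Parses a three-column (regulator, target, weight) edge list. The default
#' dialect is tab-separated with no header; a header row is auto-detected
#' when the third field of the first row is non-numeric. Malformed rows and
#' duplicate edges are errors.
#'
#' @param path path to the edge-list file.
#' @param sep field separator (default tab).
#' @return A \linkS4class{BipartiteNetwork}.
#' @seealso [writeBipartiteNetwork()]
#' @export
readBipartiteNetwork <- function(path, sep = "\t") {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(bipartiteNetwork(data.frame(
      regulator = character(), target = character(), weight = numeric()
    )))
  }
  fields <- strsplit(lines, sep, fixed = TRUE)
  start <- 1L
  f1 <- fields[[1]]
  if (length(f1) == 3 && is.na(suppressWarnings(as.numeric(f1[3])))) {
    start <- 2L  # header row
  }
  if (start > length(lines)) {
    return(bipartiteNetwork(data.frame(
      regulator = character(), target = character(), weight = numeric()
    )))
  }
  rows <- fields[start:length(fields)]
  nf <- lengths(rows)
  if (any(nf != 3)) {
    stop(sprintf("malformed row at line %d: expected 3 fields, got %d",
                 which(nf != 3)[1] + start - 1L, nf[nf != 3][1]))
  }
  m <- matrix(unlist(rows), ncol = 3, byrow = TRUE)
  w <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(w)) {
    stop(sprintf("malformed row at line %d: non-numeric weight '%s'",
                 which(is.na(w))[1] + start - 1L, m[is.na(w), 3][1]))
  }
  bipartiteNetwork(data.frame(
    regulator = m[, 1], target = m[, 2], weight = w,
    stringsAsFactors = FALSE
  ))
}

#' Write a bipartite network to an edge-list file
#'
#' Writes the tab-separated three-column dialect read by
#' [readBipartiteNetwork()], reporting original (un-namespaced) regulator
#' names. Weights are printed with full double precision so that a
#' read/write round trip reproduces the network exactly.
#'
#' @param net a \linkS4class{BipartiteNetwork}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writeBipartiteNetwork <- function(net, path) {
  e <- edgeTable(net)
  lines <- sprintf("%s\t%s\t%s", stripRegulator(e$regulator), e$target,
                   sprintf("%.17g", e$weight))
  writeLines(lines, path)
  invisible(path)
}

#' Keep only edges above a weight cutoff
#'
#' Retains edges with weight strictly greater than \code{cutoff} (default 0,
#' i.e. positive-weight edges only — a zero-weight edge carries no modularity
#' signal). Node sets are unchanged, so nodes can become isolated.
#'
#' @param net a \linkS4class{BipartiteNetwork}.
#' @param cutoff non-negative weight cutoff; strict inequality.
#' @return A \linkS4class{BipartiteNetwork} with the retained edges.
#' @export
thresholdPositive <- function(net, cutoff = 0) {
  stopifnot(cutoff >= 0)
  e <- edgeTable(net)
  e <- e[e$weight > cutoff, , drop = FALSE]
  rownames(e) <- NULL
  new("BipartiteNetwork",
    regulators = regulatorNodes(net), targets = targetNodes(net), edges = e
  )
}

#' Rescale all edge weights to a target total
#'
#' Multiplies every edge weight by \code{targetTotal / m} so the rescaled
#' network has total weight \code{targetTotal}. Used to put the baseline
#' network on the same global scale as the perturbed network before
#' computing null expectations.
#'
#' @param net a \linkS4class{BipartiteNetwork} with positive total weight.
#' @param targetTotal positive target total weight.
#' @return The rescaled \linkS4class{BipartiteNetwork}.
#' @export
scaleToTotal <- function(net, targetTotal) {
  stopifnot(targetTotal > 0)
  m <- totalWeight(net)
  if (m == 0) stop("cannot rescale a network with zero total weight")
  e <- edgeTable(net)
  e$weight <- e$weight * (targetTotal / m)
  new("BipartiteNetwork",
    regulators = regulatorNodes(net), targets = targetNodes(net), edges = e
  )
}

#' Align two networks on the union of their node sets
#'
#' Returns both networks re-expressed over the union of the regulator and of
#' the target namespaces (first network's order first, then nodes only in
#' the second). Nodes missing from one network become isolated (degree 0)
#' there — e.g. genes that are unconnected in the baseline condition.
#'
#' @param x,y \linkS4class{BipartiteNetwork} objects.
#' @return A list with elements \code{x} and \code{y}.
#' @export
alignNodeUniverse <- function(x, y) {
  regs <- union(regulatorNodes(x), regulatorNodes(y))
  tgts <- union(targetNodes(x), targetNodes(y))
  rebuild <- function(n) {
    new("BipartiteNetwork", regulators = regs, targets = tgts,
        edges = edgeTable(n))
  }
  list(x = rebuild(x), y = rebuild(y))
}

#' Write a partition as a TSV table
#'
#' Columns: node (original name), node_class, community_id.
#'
#' @param p a \linkS4class{Partition}.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
writePartition <- function(p, path) {
  nodes <- names(membership(p))
  df <- data.frame(
    node = ifelse(p@nodeClass == "regulator", stripRegulator(nodes), nodes),
    node_class = p@nodeClass,
    community_id = as.integer(membership(p)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition written by [writePartition()]
#'
#' @param path path to the TSV file.
#' @return A \linkS4class{Partition}.
#' @export
readPartition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  nodes <- ifelse(df$node_class == "regulator",
                  namespaceRegulator(df$node), df$node)
  newPartition(nodes, df$community_id, df$node_class)
}
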