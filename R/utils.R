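# Internal helpers: namespacing, seeded RNG scope, canonical labels, pinv.

REG_SUFFIX <- "_reg"

namespaceRegulator <- function(x) {
  if (length(x) == 0) return(character(0))  # paste0 would recycle to "_reg"
  paste0(x, REG_SUFFIX)
}

stripRegulator <- function(x) sub(paste0(REG_SUFFIX, "$"), "", x)

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Canonicalize integer labels: 1..q by decreasing community size, ties broken
# by the community whose earliest member (in the given node order) comes
# first. `labels` is a vector ordered like the node universe.
canonicalizeLabels <- function(labels) {
  stopifnot(length(labels) > 0)
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  firstMember <- vapply(seq_along(sizes), function(c) {
    which(labels == c)[1]
  }, integer(1))
  rank <- order(-sizes, firstMember)
  newLabel <- integer(length(sizes))
  newLabel[rank] <- seq_along(sizes)
  newLabel[labels]
}

# Coerce to a general double CsparseMatrix (dgCMatrix), regardless of any
# special shape (triangular, symmetric, pattern) Matrix may have inferred.
asDgc <- function(x) {
  methods::as(methods::as(methods::as(
    x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
}

# Moore-Penrose pseudoinverse via SVD; singular values below
# tol * max(singular value) are zeroed.
svdPseudoinverse <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d >= tol * max(s$d)
  dinv <- ifelse(keep, 1 / s$d, 0)
  s$v %*% (dinv * t(s$u))
}

# Partition constructor used internally once labels are canonical.
newPartition <- function(nodes, labels, classes) {
  new("Partition",
    membership = stats::setNames(as.integer(labels), nodes),
    nodeClass = as.character(classes)
  )
}

# Node classes from namespaced ids relative to a network pair context.
classesFor <- function(nodes, regulators) {
  ifelse(nodes %in% regulators, "regulator", "target")
}

logMsg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}
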