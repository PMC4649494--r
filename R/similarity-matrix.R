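#' Construct a labeled similarity matrix
#'
#' A thin wrapper around a base matrix that records which similarity source
#' it carries and enforces the invariants shared by all of them: square,
#' finite, symmetric within tolerance (then symmetrized exactly). Roles:
#' \describe{
#'   \item{SS}{disease semantic similarity}
#'   \item{ES}{lncRNA expression similarity (Spearman-based)}
#'   \item{FS}{lncRNA functional similarity (consumed precomputed)}
#'   \item{KD, KL}{Gaussian interaction-profile kernels (disease / lncRNA)}
#'   \item{DS, LS}{integrated disease / lncRNA similarity}
#' }
#'
#' @param values square numeric matrix.
#' @param ids identifiers for rows/columns; defaults to \code{rownames(values)}.
#' @param role one of \code{"SS","ES","FS","KD","KL","DS","LS"}.
#' @param covered optional logical vector (length \code{nrow}) flagging which
#'   entities the source actually covers (drives the \code{we}/\code{wf}
#'   indicators during integration).
#' @param tol symmetry tolerance (default \code{1e-10}).
#' @return the matrix with dimnames set and attributes \code{role} and
#'   \code{covered}, classed \code{similarity_matrix}.
#' @export
similarity_matrix <- function(values, ids = rownames(values), role,
                              covered = NULL, tol = 1e-10) {
  role <- match.arg(role, c("SS", "ES", "FS", "KD", "KL", "DS", "LS"))
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("similarity matrix must be square")
  if (nrow(values) > 0) {
    if (is.null(ids)) stop("similarity matrix needs identifiers")
    if (anyNA(values) || any(!is.finite(values)))
      stop(sprintf("non-finite entries in %s matrix", role))
    if (max(abs(values - t(values))) > tol)
      stop(sprintf("%s matrix asymmetric beyond tolerance %g", role, tol))
    values <- (values + t(values)) / 2
    lo <- if (role == "ES") -1 else 0
    if (any(values < lo - tol) || any(values > 1 + tol))
      stop(sprintf("%s entries outside [%g, 1]", role, lo))
  }
  dimnames(values) <- list(ids, ids)
  attr(values, "role") <- role
  attr(values, "covered") <- covered
  class(values) <- c("similarity_matrix", class(values))
  values
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("similarity_matrix [%s], %d x %d\n",
              attr(x, "role"), nrow(x), ncol(x)))
  print(unclass_sim(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))),
                       drop = FALSE])
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Role tag of a similarity matrix
#' @param x a \code{\link{similarity_matrix}}.
#' @return the role string.
#' @export
sim_role <- function(x) attr(x, "role")

#' Coverage indicator of a similarity matrix
#' @param x a \code{\link{similarity_matrix}}.
#' @return logical coverage vector, or NULL if the source covers everything.
#' @export
sim_covered <- function(x) attr(x, "covered")

# strip class/attrs for plain-matrix arithmetic
unclass_sim <- function(x) {
  attr(x, "role") <- NULL
  attr(x, "covered") <- NULL
  class(x) <- "matrix"
  x
}

#' Write a labeled matrix as TSV (row and column id headers)
#' @param m matrix with dimnames.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.matrix(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read a labeled matrix from TSV written by \code{\link{write_matrix_tsv}}
#' @param path input path.
#' @return a base matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  as.matrix(df)
}
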