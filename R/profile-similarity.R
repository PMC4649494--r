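#' Load a lincRNA expression profile matrix
#'
#' Expects a TSV whose first column holds lincRNA identifiers and whose
#' remaining columns hold expression levels across tissues or cell types
#' (platform units are arbitrary; only ranks matter downstream). Rows with
#' missing values are dropped with a message.
#'
#' @param path TSV file path.
#' @return object of class \code{expression_profile_set}: list with
#'   \code{lincrna_ids}, \code{tissue_ids} and the numeric \code{values}
#'   matrix (lincRNA x tissue).
#' @export
load_expression_profiles <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  ids <- trimws(as.character(df[[1]]))
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  keep <- stats::complete.cases(values)
  if (any(!keep)) {
    message(sprintf("dropping %d expression rows with missing values",
                    sum(!keep)))
    values <- values[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  expression_profile_set(ids, colnames(values), values)
}

#' Construct an expression profile set
#' @param lincrna_ids lincRNA identifiers (rows).
#' @param tissue_ids tissue/cell-type identifiers (columns).
#' @param values numeric matrix, lincRNA x tissue.
#' @return object of class \code{expression_profile_set}.
#' @export
expression_profile_set <- function(lincrna_ids, tissue_ids, values) {
  lincrna_ids <- as.character(lincrna_ids)
  tissue_ids <- as.character(tissue_ids)
  values <- as.matrix(values)
  if (ncol(values) < 2L)
    stop("need at least 2 tissues to compute rank correlations")
  if (anyDuplicated(lincrna_ids)) stop("duplicate lincRNA identifiers")
  if (nrow(values) != length(lincrna_ids) ||
      ncol(values) != length(tissue_ids))
    stop("expression matrix dimensions do not match identifier lists")
  dimnames(values) <- list(lincrna_ids, tissue_ids)
  structure(list(lincrna_ids = lincrna_ids, tissue_ids = tissue_ids,
                 values = values),
            class = "expression_profile_set")
}

#' LncRNA expression similarity (Spearman)
#'
#' The expression similarity between two lncRNAs is the Spearman rank
#' correlation of their tissue expression profiles when both are lincRNAs
#' with available profiles, and 0 otherwise. Ties take the average-rank
#' (midrank) convention. A constant profile has undefined rank correlation;
#' its off-diagonal entries are set to 0 with a message. Because the KATZ
#' walk interpretation needs nonnegative edge capacities, negative
#' correlations are by default clamped to 0 (\code{"absolute"} and
#' \code{"keep"} are available for sensitivity analysis).
#'
#' @param profiles an \code{\link{expression_profile_set}}.
#' @param lncrna_ids lncRNA identifier vector of the association network;
#'   the result is indexed by these ids.
#' @param negative policy for negative correlations:
#'   \code{"clamp"} (default), \code{"absolute"} or \code{"keep"}.
#' @return a \code{\link{similarity_matrix}} with role \code{"ES"} whose
#'   \code{covered} attribute flags the profiled lincRNAs (this is the
#'   \code{we} indicator source for integration).
#' @export
expression_similarity <- function(profiles, lncrna_ids,
                                  negative = c("clamp", "absolute", "keep")) {
  negative <- match.arg(negative)
  lncrna_ids <- as.character(lncrna_ids)
  n <- length(lncrna_ids)
  profiled <- lncrna_ids %in% profiles$lincrna_ids
  ES <- matrix(0, n, n, dimnames = list(lncrna_ids, lncrna_ids))
  if (any(profiled)) {
    sub <- profiles$values[match(lncrna_ids[profiled], profiles$lincrna_ids),
                           , drop = FALSE]
    constant <- apply(sub, 1, function(r) length(unique(r)) == 1L)
    cc <- suppressWarnings(stats::cor(t(sub), method = "spearman"))
    if (anyNA(cc)) {
      message(sprintf(
        "%d constant expression profile(s): undefined correlations set to 0",
        sum(constant)))
      cc[is.na(cc)] <- 0
    }
    cc <- switch(negative,
                 clamp = pmax(cc, 0),
                 absolute = abs(cc),
                 keep = cc)
    ES[profiled, profiled] <- cc
    diag(ES)[profiled] <- 1
  }
  similarity_matrix(ES, role = "ES",
                    covered = stats::setNames(profiled, lncrna_ids))
}

#' Load a precomputed lncRNA functional similarity matrix
#'
#' Functional similarity is consumed as an input (the package does not
#' recompute it). The labeled square table is aligned to the network's
#' lncRNA list; lncRNAs absent from the file get zero rows/columns and a
#' zero coverage flag (the \code{wf} indicator source). Asymmetries beyond
#' \code{1e-8} are symmetrized by averaging, and entries are clamped to
#' [0, 1]; both repairs are reported with a warning.
#'
#' @param path labeled square TSV (row and column identifiers).
#' @param lncrna_ids lncRNA identifier vector of the association network.
#' @return a \code{\link{similarity_matrix}} with role \code{"FS"} and a
#'   \code{covered} attribute.
#' @export
load_functional_similarity <- function(path, lncrna_ids) {
  functional_similarity_from_matrix(read_matrix_tsv(path), lncrna_ids)
}

#' Align an in-memory functional similarity matrix to a network
#'
#' Same alignment, symmetrization and clamping as
#' \code{\link{load_functional_similarity}}, starting from a labeled
#' square matrix already in memory.
#'
#' @param m labeled square numeric matrix.
#' @param lncrna_ids lncRNA identifier vector of the association network.
#' @return a \code{\link{similarity_matrix}} with role \code{"FS"}.
#' @export
functional_similarity_from_matrix <- function(m, lncrna_ids) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("functional similarity file is not a labeled square matrix")
  asym <- if (nrow(m) > 0) max(abs(m - t(m))) else 0
  if (asym > 1e-8) {
    warning(sprintf(
      "functional similarity asymmetric (max deviation %.3g); symmetrized by averaging",
      asym))
  }
  m <- (m + t(m)) / 2
  if (any(m < 0) || any(m > 1)) {
    warning(sprintf("%d functional similarity entries clamped to [0, 1]",
                    sum(m < 0 | m > 1)))
    m <- pmin(pmax(m, 0), 1)
  }
  lncrna_ids <- as.character(lncrna_ids)
  n <- length(lncrna_ids)
  covered <- lncrna_ids %in% rownames(m)
  FS <- matrix(0, n, n, dimnames = list(lncrna_ids, lncrna_ids))
  if (any(covered)) {
    idx <- match(lncrna_ids[covered], rownames(m))
    FS[covered, covered] <- m[idx, idx]
  }
  similarity_matrix(FS, role = "FS",
                    covered = stats::setNames(covered, lncrna_ids))
}

#' Gaussian interaction-profile kernel bandwidth
#'
#' The kernel bandwidth gamma is the raw bandwidth parameter gamma'
#' normalized by the average squared norm of the interaction profiles on
#' the requested side: \code{gamma = gamma' / mean(||IP(k)||^2)}. For
#' binary profiles the squared norm of an entity's profile is simply its
#' number of known associations, so the normalizer is the average number of
#' associations per disease (or per lncRNA).
#'
#' @param net an \code{\link{association_network}} (or a bare 0/1 matrix).
#' @param side \code{"disease"} or \code{"lncrna"}.
#' @param gamma_prime raw bandwidth, > 0 (default 1).
#' @return object of class \code{kernel_bandwidth}: list with \code{side},
#'   \code{gamma_prime} and \code{gamma}.
#' @export
kernel_bandwidth <- function(net, side = c("disease", "lncrna"),
                             gamma_prime = 1) {
  side <- match.arg(side)
  A <- if (inherits(net, "association_network")) net$adjacency else
    as.matrix(net)
  if (gamma_prime <= 0) stop("gamma_prime must be positive")
  norms2 <- if (side == "disease") colSums(A^2) else rowSums(A^2)
  meansq <- mean(norms2)
  if (meansq == 0)
    stop("configuration error: no known associations; kernel bandwidth undefined")
  structure(list(side = side, gamma_prime = gamma_prime,
                 gamma = gamma_prime / meansq),
            class = "kernel_bandwidth")
}

#' Gaussian interaction-profile kernel similarity matrix
#'
#' Similar diseases tend to show similar interaction and non-interaction
#' patterns with the lncRNAs (and symmetrically for lncRNAs), so the kernel
#' \code{K(a, b) = exp(-gamma * ||IP(a) - IP(b)||^2)} over binary
#' interaction profiles is a similarity on each side of the network.
#' Entities with an all-zero profile (no known associations, e.g. a
#' held-out entity during cross-validation) carry no interaction evidence;
#' under the default \code{zero_profile = "isolate"} policy their kernel
#' row/column is set to 0 off-diagonal and 1 on the diagonal so integration
#' can fall back to the remaining similarity sources.
#'
#' @param net an \code{\link{association_network}} (or bare 0/1 matrix).
#' @param side \code{"disease"} or \code{"lncrna"}.
#' @param gamma_prime raw bandwidth, > 0.
#' @param zero_profile \code{"isolate"} (default) or \code{"kernel"} (keep
#'   the raw kernel value, which is 1 between two all-zero profiles).
#' @return a \code{\link{similarity_matrix}} with role \code{"KD"}
#'   (disease side) or \code{"KL"} (lncRNA side); diagonal exactly 1.
#' @export
gaussian_kernel_matrix <- function(net, side = c("disease", "lncrna"),
                                   gamma_prime = 1,
                                   zero_profile = c("isolate", "kernel")) {
  side <- match.arg(side)
  zero_profile <- match.arg(zero_profile)
  A <- if (inherits(net, "association_network")) net$adjacency else
    as.matrix(net)
  bw <- kernel_bandwidth(A, side = side, gamma_prime = gamma_prime)
  P <- if (side == "disease") t(A) else A
  G <- tcrossprod(P)
  sq <- diag(G)
  D2 <- pmax(outer(sq, sq, "+") - 2 * G, 0)
  K <- exp(-bw$gamma * D2)
  diag(K) <- 1
  if (zero_profile == "isolate") {
    z <- sq == 0
    K[z, ] <- 0
    K[, z] <- 0
    diag(K) <- 1
  }
  similarity_matrix(K, role = if (side == "disease") "KD" else "KL")
}
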