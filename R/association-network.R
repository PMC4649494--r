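#' Construct a lncRNA-disease association network
#'
#' The association network is the central object of the package: a labeled
#' binary bipartite adjacency matrix \code{A} of dimension \code{nl x nd},
#' where \code{A[i, j] = 1} records an experimentally supported association
#' between lncRNA \code{i} and disease \code{j}.
#'
#' @param lncrna_ids character vector of unique lncRNA identifiers (rows).
#' @param disease_ids character vector of unique disease identifiers (columns).
#' @param adjacency numeric/integer matrix of 0s and 1s, \code{nl x nd}.
#'
#' @return An object of class \code{association_network}: a list with
#'   elements \code{lncrna_ids}, \code{disease_ids} and \code{adjacency}
#'   (a dimnamed 0/1 matrix).
#' @export
#' @examples
#' association_network(c("H19", "MEG3"), c("gastric cancer"),
#'                     matrix(c(1, 0), nrow = 2))
association_network <- function(lncrna_ids, disease_ids, adjacency) {
  lncrna_ids <- as.character(lncrna_ids)
  disease_ids <- as.character(disease_ids)
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "double"
  if (length(lncrna_ids) < 1L || length(disease_ids) < 1L)
    stop("need at least one lncRNA and one disease")
  if (anyDuplicated(lncrna_ids)) stop("duplicate lncRNA identifiers")
  if (anyDuplicated(disease_ids)) stop("duplicate disease identifiers")
  if (nrow(adjacency) != length(lncrna_ids) ||
      ncol(adjacency) != length(disease_ids))
    stop("adjacency dimensions do not match identifier lists")
  if (anyNA(adjacency) || !all(adjacency %in% c(0, 1)))
    stop("adjacency must contain only 0 and 1")
  dimnames(adjacency) <- list(lncrna_ids, disease_ids)
  structure(
    list(lncrna_ids = lncrna_ids, disease_ids = disease_ids,
         adjacency = adjacency),
    class = "association_network"
  )
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf(
    "association_network: %d lncRNAs x %d diseases, %d known associations\n",
    length(x$lncrna_ids), length(x$disease_ids), sum(x$adjacency)))
  invisible(x)
}

#' Load lncRNA-disease association pairs from a TSV file
#'
#' Reads a two-or-more-column tab-separated table of
#' \code{(lncrna_id, disease_id, [evidence...])} rows, collapses duplicate
#' pairs recorded with different evidences to a single association, and
#' returns the binary adjacency matrix over the distinct identifiers.
#' Identifiers are trimmed of surrounding whitespace and, by default, matched
#' case-sensitively (database symbols are case-meaningful). Both identifier
#' lists are sorted lexicographically (C locale) so the matrix layout does
#' not depend on input row order.
#'
#' @param path path to the TSV file. A header line is auto-detected when its
#'   first two fields look like column names (e.g. \code{lncrna_id}).
#' @param header \code{"auto"} (default), \code{TRUE} or \code{FALSE}.
#' @param case_sensitive if \code{FALSE}, identifiers differing only by case
#'   are merged (the first spelling seen is kept).
#' @return an \code{\link{association_network}}.
#' @export
load_associations <- function(path, header = "auto", case_sensitive = TRUE) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("input error: association file is empty")

  fields <- strsplit(lines, "\t", fixed = TRUE)
  header_names <- c("lncrna", "lncrna_id", "lncrnaid", "disease", "disease_id")
  has_header <- if (identical(header, "auto")) {
    f1 <- tolower(trimws(fields[[1]][1:2]))
    any(f1 %in% header_names)
  } else isTRUE(header)
  if (has_header) {
    fields <- fields[-1L]
    if (length(fields) == 0L)
      stop("input error: association file has a header but no data rows")
  }

  offset <- as.integer(has_header)
  pairs <- vapply(seq_along(fields), function(k) {
    f <- fields[[k]]
    if (length(f) < 2L || !nzchar(trimws(f[1])) || !nzchar(trimws(f[2])))
      stop(sprintf("parse error at line %d: expected at least two fields",
                   k + offset))
    c(trimws(f[1]), trimws(f[2]))
  }, character(2))
  lnc <- pairs[1, ]
  dis <- pairs[2, ]

  if (!case_sensitive) {
    lnc <- canonical_case(lnc)
    dis <- canonical_case(dis)
  }

  lncrna_ids <- sort(unique(lnc), method = "radix")
  disease_ids <- sort(unique(dis), method = "radix")
  A <- matrix(0, length(lncrna_ids), length(disease_ids),
              dimnames = list(lncrna_ids, disease_ids))
  A[cbind(match(lnc, lncrna_ids), match(dis, disease_ids))] <- 1
  association_network(lncrna_ids, disease_ids, A)
}

# map each id to the first-seen spelling of its lowercase equivalence class
canonical_case <- function(x) {
  key <- tolower(x)
  first <- x[!duplicated(key)]
  names(first) <- key[!duplicated(key)]
  unname(first[key])
}

#' Write an association network back to the pair-list TSV format
#'
#' @param net an \code{\link{association_network}}.
#' @param path output file path.
#' @param header write a \code{lncrna_id\\tdisease_id} header line.
#' @return \code{path}, invisibly.
#' @export
write_associations <- function(net, path, header = TRUE) {
  ones <- which(net$adjacency == 1, arr.ind = TRUE)
  df <- data.frame(lncrna_id = net$lncrna_ids[ones[, 1]],
                   disease_id = net$disease_ids[ones[, 2]])
  df <- df[order(df$lncrna_id, df$disease_id, method = "radix"), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Interaction profile of a lncRNA or disease
#'
#' The interaction profile \code{IP(.)} of an entity is the binary vector
#' encoding the presence or absence of its known associations: the row of
#' \code{A} for a lncRNA, the column for a disease.
#'
#' @param net an \code{\link{association_network}}.
#' @param entity_id identifier of the entity.
#' @param side \code{"lncrna"} or \code{"disease"}.
#' @return an object of class \code{interaction_profile}: a list with
#'   \code{entity_id}, \code{side} and the named binary \code{values} vector.
#' @export
interaction_profile <- function(net, entity_id,
                                side = c("lncrna", "disease")) {
  side <- match.arg(side)
  values <- if (side == "lncrna") {
    i <- match(entity_id, net$lncrna_ids)
    if (is.na(i)) stop(sprintf("unknown lncRNA id: '%s'", entity_id))
    net$adjacency[i, ]
  } else {
    j <- match(entity_id, net$disease_ids)
    if (is.na(j)) stop(sprintf("unknown disease id: '%s'", entity_id))
    net$adjacency[, j]
  }
  structure(list(entity_id = entity_id, side = side, values = values),
            class = "interaction_profile")
}

#' Mean association counts of a network
#'
#' Returns the average number of known associated lncRNAs per disease and
#' the average number of known associated diseases per lncRNA (for the
#' curated gold-standard dimensions, 293 pairs over 118 lncRNAs and 167
#' diseases, these are about 1.75 and 2.48).
#'
#' @param net an \code{\link{association_network}}.
#' @return list with \code{mean_lncrnas_per_disease} and
#'   \code{mean_diseases_per_lncrna}.
#' @export
association_stats <- function(net) {
  n_ones <- sum(net$adjacency)
  list(mean_lncrnas_per_disease = n_ones / length(net$disease_ids),
       mean_diseases_per_lncrna = n_ones / length(net$lncrna_ids))
}

# zero out the given association cells; used by the cross-validation
# protocols to hide test pairs from the scorer
mask_associations <- function(net, rows, cols) {
  A <- net$adjacency
  A[cbind(rows, cols)] <- 0
  association_network(net$lncrna_ids, net$disease_ids, A)
}
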