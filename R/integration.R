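#' Integrated disease similarity
#'
#' Combines disease semantic similarity \code{SS} (available only on the
#' subset \code{IS} of diseases with ontology annotation) with the Gaussian
#' interaction-profile kernel \code{KD} (available everywhere). For a pair
#' with both diseases in \code{IS} the sources are averaged (equal weights
#' by default); otherwise the kernel alone is used:
#' \deqn{DS(i,j) = (w_s SS + w_k KD) / (w_s + w_k) \; if\; i,j \in IS,
#'       \; else\; KD(i,j).}
#'
#' @param SS semantic \code{\link{similarity_matrix}} over \code{IS}.
#' @param KD kernel \code{\link{similarity_matrix}} over all diseases.
#' @param IS disease ids with semantic similarity; defaults to the row
#'   names of \code{SS}.
#' @param weights length-2 numeric \code{c(semantic, kernel)} weights.
#' @return a \code{\link{similarity_matrix}} with role \code{"DS"} indexed
#'   like \code{KD}.
#' @export
integrate_disease_similarity <- function(SS, KD, IS = rownames(SS),
                                         weights = c(semantic = 1,
                                                     kernel = 1)) {
  ids <- rownames(KD)
  DS <- unclass_sim(KD)
  if (length(IS) > 0) {
    IS <- as.character(IS)
    if (!all(IS %in% ids))
      stop("structural error: IS diseases missing from the kernel matrix")
    if (is.null(SS) || !all(IS %in% rownames(SS)))
      stop("structural error: SS does not cover IS")
    idx <- match(IS, ids)
    sidx <- match(IS, rownames(SS))
    w <- weights / sum(weights)
    DS[idx, idx] <- w[1] * unclass_sim(SS)[sidx, sidx] +
      w[2] * DS[idx, idx]
  }
  similarity_matrix(DS, ids = ids, role = "DS")
}

#' Integrated lncRNA similarity
#'
#' Combines expression similarity \code{ES} (defined when both lncRNAs are
#' profiled lincRNAs, indicator \code{we}), precomputed functional
#' similarity \code{FS} (defined when both lncRNAs are covered by the
#' functional-similarity source, indicator \code{wf}) and the Gaussian
#' kernel \code{KL} (always defined) by an indicator-weighted average:
#' \deqn{LS(i,j) = \frac{we\,ES + wf\,FS + KL}{we + wf + 1}.}
#'
#' @param ES expression \code{\link{similarity_matrix}} (role ES) or NULL.
#' @param FS functional \code{\link{similarity_matrix}} (role FS) or NULL.
#' @param KL kernel \code{\link{similarity_matrix}} over all lncRNAs.
#' @param we,wf optional binary indicator matrices; by default derived from
#'   the \code{covered} attributes of \code{ES} / \code{FS} as the outer
#'   AND of entity coverage.
#' @param weights length-3 numeric \code{c(expression, functional, kernel)}
#'   relative weights for sensitivity analysis (default all equal).
#' @return a \code{\link{similarity_matrix}} with role \code{"LS"}.
#' @export
integrate_lncrna_similarity <- function(ES = NULL, FS = NULL, KL,
                                        we = NULL, wf = NULL,
                                        weights = c(expression = 1,
                                                    functional = 1,
                                                    kernel = 1)) {
  ids <- rownames(KL)
  n <- length(ids)
  zero <- matrix(0, n, n, dimnames = list(ids, ids))
  we <- indicator_or_default(we, ES, n, ids)
  wf <- indicator_or_default(wf, FS, n, ids)
  ESm <- if (is.null(ES)) zero else align_square(unclass_sim(ES), ids)
  FSm <- if (is.null(FS)) zero else align_square(unclass_sim(FS), ids)
  num <- weights[1] * we * ESm + weights[2] * wf * FSm +
    weights[3] * unclass_sim(KL)
  den <- weights[1] * we + weights[2] * wf + weights[3]
  similarity_matrix(num / den, ids = ids, role = "LS")
}

# binary pair indicator from a source's entity coverage
indicator_or_default <- function(w, src, n, ids) {
  if (!is.null(w)) {
    w <- align_square(as.matrix(w), ids)
    if (!all(w %in% c(0, 1))) stop("indicator matrices must be binary")
    return(w)
  }
  if (is.null(src)) return(matrix(0, n, n, dimnames = list(ids, ids)))
  cov <- sim_covered(src)
  if (is.null(cov)) cov <- stats::setNames(rep(TRUE, n), ids)
  cov <- as.numeric(cov[ids])
  outer(cov, cov) * 1
}

align_square <- function(m, ids) {
  if (nrow(m) != length(ids) || ncol(m) != length(ids))
    stop("structural error: similarity matrix dimension mismatch")
  if (!is.null(rownames(m)) && !identical(rownames(m), ids))
    stop("structural error: similarity matrix id order mismatch")
  dimnames(m) <- list(ids, ids)
  m
}
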