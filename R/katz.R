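#' Assemble the heterogeneous block matrix
#'
#' The KATZ walk count runs on the heterogeneous network joining the lncRNA
#' similarity network, the disease similarity network and the known
#' association network:
#' \deqn{A^* = \begin{pmatrix} LS & A \\ A^T & DS \end{pmatrix}}
#' of dimension \code{(nl + nd) x (nl + nd)}. Rows/columns 1..nl are
#' lncRNAs, the rest diseases.
#'
#' @param LS integrated lncRNA \code{\link{similarity_matrix}} (nl x nl).
#' @param DS integrated disease \code{\link{similarity_matrix}} (nd x nd).
#' @param net the \code{\link{association_network}} providing \code{A}.
#' @return the block matrix with attributes \code{nl}, \code{nd},
#'   \code{lncrna_ids}, \code{disease_ids}, classed
#'   \code{heterogeneous_matrix}.
#' @export
build_heterogeneous_matrix <- function(LS, DS, net) {
  A <- net$adjacency
  nl <- nrow(A)
  nd <- ncol(A)
  if (nrow(LS) != nl || !identical(rownames(LS), net$lncrna_ids))
    stop("structural error: LS ids do not match the network's lncRNA order")
  if (nrow(DS) != nd || !identical(rownames(DS), net$disease_ids))
    stop("structural error: DS ids do not match the network's disease order")
  H <- rbind(cbind(unclass_sim(LS), A),
             cbind(t(A), unclass_sim(DS)))
  dimnames(H) <- NULL
  structure(H, nl = nl, nd = nd,
            lncrna_ids = net$lncrna_ids, disease_ids = net$disease_ids,
            class = c("heterogeneous_matrix", "matrix"))
}

het_block <- function(S, H) {
  nl <- attr(H, "nl")
  nd <- attr(H, "nd")
  out <- S[seq_len(nl), nl + seq_len(nd), drop = FALSE]
  dimnames(out) <- list(attr(H, "lncrna_ids"), attr(H, "disease_ids"))
  out
}

#' KATZ association scores by truncated walk counting
#'
#' Counts walks between every lncRNA node and every disease node in the
#' heterogeneous network, damping the contribution of longer walks
#' geometrically: \code{S = sum over l = 1..k of beta^l (A*)^l}, of which
#' the lncRNA x disease block is returned. Shorter walks contribute more
#' because \code{beta^l} decreases in the walk length \code{l} for
#' \code{beta < 1}.
#'
#' @param H a \code{\link{build_heterogeneous_matrix}} result.
#' @param beta damping factor, > 0 (default 0.01).
#' @param k truncation order (maximum walk length), >= 1 (default 4).
#' @param full return the full (nl+nd) square series sum instead of the
#'   lncRNA x disease block.
#' @return score matrix (nl x nd, nonnegative for nonnegative inputs), or
#'   the full square series if \code{full = TRUE}.
#' @export
katz_scores_truncated <- function(H, beta = 0.01, k = 4, full = FALSE) {
  stopifnot(beta > 0, k >= 1)
  M <- unclass(H)
  attributes(M) <- attributes(M)["dim"]
  if (anyNA(M) || any(!is.finite(M))) stop("non-finite heterogeneous matrix")
  P <- M
  S <- beta * M
  if (k >= 2) for (l in 2:k) {
    P <- P %*% M
    S <- S + beta^l * P
  }
  if (full) S else het_block(S, H)
}

#' KATZ association scores in closed form
#'
#' For \code{beta} below the reciprocal spectral radius of \code{A*} the
#' damped walk series converges and sums to
#' \code{(I - beta A*)^{-1} - I}; the lncRNA x disease block of that matrix
#' is the score matrix. Refuses to run when \code{beta * rho(A*) >= 1},
#' reporting the spectral radius and the largest admissible \code{beta}.
#'
#' @inheritParams katz_scores_truncated
#' @return score matrix (nl x nd), or the full square matrix if
#'   \code{full = TRUE}.
#' @export
katz_scores_closed_form <- function(H, beta = 0.01, full = FALSE) {
  stopifnot(beta > 0)
  M <- unclass(H)
  attributes(M) <- attributes(M)["dim"]
  rho <- spectral_radius(M)
  if (beta * rho >= 1)
    stop(sprintf(
      "spectral condition violated: rho(A*) = %.6g, beta = %g; closed form needs beta < %.6g",
      rho, beta, 1 / rho))
  n <- nrow(M)
  S <- solve(diag(n) - beta * M) - diag(n)
  if (full) S else het_block(S, H)
}

spectral_radius <- function(M) {
  max(abs(eigen(M, symmetric = isSymmetric(M, tol = 1e-10),
                only.values = TRUE)$values))
}

#' KATZ association scores (dispatching on evaluation mode)
#'
#' Runs the closed form when the spectral condition holds and falls back to
#' the truncated series at order \code{k} (with a warning) otherwise;
#' \code{order = "truncated"} forces the series.
#'
#' @inheritParams katz_scores_truncated
#' @param order \code{"closed_form"} (default) or \code{"truncated"}.
#' @return nl x nd score matrix.
#' @export
katz_scores <- function(H, beta = 0.01, order = c("closed_form", "truncated"),
                        k = 4) {
  order <- match.arg(order)
  if (order == "truncated") return(katz_scores_truncated(H, beta, k))
  tryCatch(
    katz_scores_closed_form(H, beta),
    error = function(e) {
      warning(sprintf(
        "closed form unavailable (%s); falling back to truncated series at k = %d",
        conditionMessage(e), k))
      katz_scores_truncated(H, beta, k)
    }
  )
}

#' Rank candidate lncRNAs for one disease
#'
#' Candidates are the lncRNAs without a known association with the disease;
#' they are ordered by descending score, ties receiving the average
#' (midrank) rank.
#'
#' @param S nl x nd score matrix (dimnamed as the network).
#' @param net the \code{\link{association_network}}.
#' @param disease_id disease to rank candidates for.
#' @return data frame with columns \code{lncrna_id}, \code{score},
#'   \code{rank}, ordered by rank.
#' @export
rank_candidates <- function(S, net, disease_id) {
  j <- match(disease_id, net$disease_ids)
  if (is.na(j)) stop(sprintf("unknown disease id: '%s'", disease_id))
  cand <- net$adjacency[, j] == 0
  sc <- S[cand, j]
  r <- rank(-sc, ties.method = "average")
  out <- data.frame(lncrna_id = net$lncrna_ids[cand], score = unname(sc),
                    rank = unname(r))
  out[order(out$rank, out$lncrna_id, method = "radix"), , drop = FALSE]
}

#' Build a KATZ scoring function over fixed similarity inputs
#'
#' Returns a closure \code{function(net)} that maps an association network
#' (typically a masked copy during cross-validation) to the nl x nd KATZ
#' score matrix. The adjacency-derived Gaussian kernels are, under the
#' default \code{kernel_policy = "recompute"}, rebuilt from the network the
#' closure receives, so held-out associations leak into neither the kernels
#' nor the walk counts; \code{"freeze"} computes them once from
#' \code{reference_net} for comparison with protocols that do not re-derive
#' kernels per fold.
#'
#' @param ss semantic \code{\link{similarity_matrix}} over the annotated
#'   disease subset \code{IS}, or NULL.
#' @param es expression \code{\link{similarity_matrix}}, or NULL.
#' @param fs functional \code{\link{similarity_matrix}}, or NULL.
#' @param beta,order,k see \code{\link{katz_scores}}.
#' @param gamma_prime_disease,gamma_prime_lncrna kernel bandwidth
#'   parameters.
#' @param kernel_policy \code{"recompute"} (default) or \code{"freeze"}.
#' @param reference_net network used when \code{kernel_policy = "freeze"}.
#' @param disease_weights,lncrna_weights integration weights, see
#'   \code{\link{integrate_disease_similarity}} and
#'   \code{\link{integrate_lncrna_similarity}}.
#' @return a function \code{net -> score matrix}.
#' @export
katz_scorer <- function(ss = NULL, es = NULL, fs = NULL,
                        beta = 0.01, order = "closed_form", k = 4,
                        gamma_prime_disease = 1, gamma_prime_lncrna = 1,
                        kernel_policy = c("recompute", "freeze"),
                        reference_net = NULL,
                        disease_weights = c(semantic = 1, kernel = 1),
                        lncrna_weights = c(expression = 1, functional = 1,
                                           kernel = 1)) {
  kernel_policy <- match.arg(kernel_policy)
  frozen <- NULL
  if (kernel_policy == "freeze") {
    if (is.null(reference_net))
      stop("kernel_policy = 'freeze' needs a reference_net")
    frozen <- list(
      KD = gaussian_kernel_matrix(reference_net, "disease",
                                  gamma_prime_disease),
      KL = gaussian_kernel_matrix(reference_net, "lncrna",
                                  gamma_prime_lncrna))
  }
  function(net) {
    KD <- if (is.null(frozen))
      gaussian_kernel_matrix(net, "disease", gamma_prime_disease)
    else frozen$KD
    KL <- if (is.null(frozen))
      gaussian_kernel_matrix(net, "lncrna", gamma_prime_lncrna)
    else frozen$KL
    IS <- if (is.null(ss)) character(0) else
      intersect(rownames(ss), net$disease_ids)
    DS <- integrate_disease_similarity(ss, KD, IS = IS,
                                       weights = disease_weights)
    LS <- integrate_lncrna_similarity(es, fs, KL, weights = lncrna_weights)
    H <- build_heterogeneous_matrix(LS, DS, net)
    katz_scores(H, beta = beta, order = order, k = k)
  }
}

#' One-shot KATZ prediction over a network and its similarity inputs
#'
#' Convenience wrapper equal to \code{katz_scorer(...)(net)}.
#'
#' @param net an \code{\link{association_network}}.
#' @param ... passed to \code{\link{katz_scorer}}.
#' @return nl x nd score matrix.
#' @export
katzlda_scores <- function(net, ...) {
  katz_scorer(...)(net)
}
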