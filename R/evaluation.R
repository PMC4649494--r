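#' Rank-based ROC curve and AUC for pooled cross-validation test samples
#'
#' Each test sample is a held-out known association ranked against its
#' candidate set (numerically smaller rank = better prediction). At a rank
#' cutoff, sensitivity (TPR) is the fraction of test samples ranked at or
#' above the cutoff and 1 - specificity (FPR) the fraction of candidates
#' above it. Pooling across test samples with possibly different candidate
#' counts happens on the normalized-rank (percentile) scale
#' \code{p = (rank - 1) / candidates}; the trapezoidal area then equals the
#' mean per-sample Mann-Whitney statistic (fraction of candidates ranked
#' below the positive, ties counted half).
#'
#' @param test_ranks midranks of the test samples among their candidates,
#'   each in [1, candidate_count + 1].
#' @param candidate_counts candidate-set size per test sample (recycled if
#'   scalar).
#' @return list with \code{roc_points} (data frame \code{fpr}, \code{tpr},
#'   starting (0,0) and ending (1,1)) and \code{auc}.
#' @export
roc_auc <- function(test_ranks, candidate_counts) {
  if (length(test_ranks) == 0) stop("no test samples: ROC undefined")
  m <- rep_len(candidate_counts, length(test_ranks))
  if (any(m < 1)) stop("candidate counts must be >= 1")
  if (any(test_ranks < 1 - 1e-9 | test_ranks > m + 1 + 1e-9))
    stop("test rank outside [1, candidate_count + 1]")
  p <- (test_ranks - 1) / m  # fraction of candidates ranked above, ties half
  auc <- mean(1 - p)
  taus <- sort(unique(c(0, p, 1)))
  tpr_at <- vapply(taus, function(t) mean(p <= t), numeric(1))
  tpr_before <- vapply(taus, function(t) mean(p < t), numeric(1))
  fpr <- c(rbind(taus, taus))
  tpr <- c(rbind(tpr_before, tpr_at))
  pts <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  pts <- pts[!duplicated(pts), , drop = FALSE]
  rownames(pts) <- NULL
  list(roc_points = pts, auc = auc)
}

cv_result <- function(protocol, records, rep_aucs = NULL) {
  ra <- roc_auc(records$rank, records$n_candidates)
  structure(
    list(protocol = protocol, records = records,
         roc_points = ra$roc_points, auc = ra$auc,
         rep_aucs = rep_aucs,
         auc_mean = if (is.null(rep_aucs)) ra$auc else mean(rep_aucs),
         auc_sd = if (is.null(rep_aucs)) NA_real_ else stats::sd(rep_aucs)),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result [%s]: %d test samples, AUC = %.4f\n",
              x$protocol, nrow(x$records), x$auc))
  if (!is.null(x$rep_aucs))
    cat(sprintf("  %d repetitions: mean AUC = %.4f, sd = %.4f\n",
                length(x$rep_aucs), x$auc_mean, x$auc_sd))
  invisible(x)
}

# midrank of a score among a candidate score vector
midrank <- function(score, candidates) {
  1 + sum(candidates > score) + 0.5 * sum(candidates == score)
}

#' Global leave-one-out cross-validation
#'
#' Each known association is left out in turn: it is removed from the
#' adjacency matrix handed to the scorer (which under the default scorer
#' policy also re-derives the Gaussian kernels from the masked network),
#' and the held-out pair is ranked against all lncRNA-disease pairs without
#' known relevance evidence. A test entity left with no remaining
#' associations is still scored: its kernel row falls back to the
#' new-entity policy, never silently skipped.
#'
#' @param net an \code{\link{association_network}} with >= 2 known
#'   associations.
#' @param scorer a function \code{net -> score matrix}, e.g. from
#'   \code{\link{katz_scorer}}.
#' @return a \code{cv_result} with per-test records and pooled ROC/AUC.
#' @export
global_loocv <- function(net, scorer) {
  ones <- which(net$adjacency == 1, arr.ind = TRUE)
  if (nrow(ones) < 2) stop("need at least 2 known associations for LOOCV")
  zeros <- net$adjacency == 0
  m <- sum(zeros)
  recs <- lapply(seq_len(nrow(ones)), function(t) {
    i <- ones[t, 1]; j <- ones[t, 2]
    S <- scorer(mask_associations(net, i, j))
    data.frame(lncrna_id = net$lncrna_ids[i],
               disease_id = net$disease_ids[j],
               score = S[i, j],
               rank = midrank(S[i, j], S[zeros]),
               n_candidates = m)
  })
  cv_result("global_loocv", do.call(rbind, recs))
}

#' Local leave-one-out cross-validation
#'
#' As \code{\link{global_loocv}}, but attention is paid only to the disease
#' of the test sample: the held-out pair is ranked against the lncRNAs
#' without known associations with that disease, so the candidate count for
#' a test pair (l, d) is \code{nl - degree(d)}. Diseases associated with
#' every lncRNA have no candidates and are dropped with a warning.
#'
#' @inheritParams global_loocv
#' @return a \code{cv_result}.
#' @export
local_loocv <- function(net, scorer) {
  ones <- which(net$adjacency == 1, arr.ind = TRUE)
  if (nrow(ones) < 2) stop("need at least 2 known associations for LOOCV")
  recs <- lapply(seq_len(nrow(ones)), function(t) {
    i <- ones[t, 1]; j <- ones[t, 2]
    cand <- net$adjacency[, j] == 0
    if (!any(cand)) return(NULL)
    S <- scorer(mask_associations(net, i, j))
    data.frame(lncrna_id = net$lncrna_ids[i],
               disease_id = net$disease_ids[j],
               score = S[i, j],
               rank = midrank(S[i, j], S[cand, j]),
               n_candidates = sum(cand))
  })
  dropped <- sum(vapply(recs, is.null, logical(1)))
  if (dropped > 0)
    warning(sprintf(
      "%d test pair(s) dropped: their disease has no candidate lncRNAs",
      dropped))
  cv_result("local_loocv", do.call(rbind, recs))
}

#' Repeated k-fold cross-validation
#'
#' Known associations are randomly divided into \code{folds} parts; each
#' part is masked in turn and its held-out pairs are ranked against all
#' pairs without known association evidence (global candidate set). Ranks
#' are pooled over the folds of one division into a per-repetition AUC; the
#' mean and standard deviation over \code{repetitions} random divisions are
#' reported. With \code{folds} equal to the number of associations and one
#' repetition this reduces exactly to global LOOCV.
#'
#' @inheritParams global_loocv
#' @param folds number of folds (default 5).
#' @param repetitions number of random divisions (default 100).
#' @param seed integer seed for the divisions; if NULL, a seed is drawn
#'   from the session RNG with a warning and recorded in the result.
#' @return a \code{cv_result} with per-repetition AUCs (\code{rep_aucs}),
#'   \code{auc_mean}, \code{auc_sd}; \code{records} holds all test records
#'   with a \code{repetition} column.
#' @export
kfold_cv <- function(net, scorer, folds = 5, repetitions = 100, seed = NULL) {
  ones <- which(net$adjacency == 1, arr.ind = TRUE)
  n_assoc <- nrow(ones)
  if (n_assoc < folds) stop("fewer associations than folds")
  if (is.null(seed)) {
    seed <- sample.int(2147483646L, 1)
    warning(sprintf("no seed supplied; drew seed %d for reproducibility",
                    seed))
  }
  set.seed(seed)
  zeros <- net$adjacency == 0
  m <- sum(zeros)
  all_recs <- vector("list", repetitions)
  rep_aucs <- numeric(repetitions)
  for (r in seq_len(repetitions)) {
    fold_of <- sample(rep_len(seq_len(folds), n_assoc))
    recs <- lapply(seq_len(folds), function(f) {
      test <- which(fold_of == f)
      netm <- mask_associations(net, ones[test, 1], ones[test, 2])
      S <- scorer(netm)
      cand <- S[zeros]
      do.call(rbind, lapply(test, function(t) {
        i <- ones[t, 1]; j <- ones[t, 2]
        data.frame(lncrna_id = net$lncrna_ids[i],
                   disease_id = net$disease_ids[j],
                   score = S[i, j],
                   rank = midrank(S[i, j], cand),
                   n_candidates = m)
      }))
    })
    recs <- do.call(rbind, recs)
    recs$repetition <- r
    all_recs[[r]] <- recs
    rep_aucs[r] <- roc_auc(recs$rank, recs$n_candidates)$auc
  }
  out <- cv_result("kfold", do.call(rbind, all_recs), rep_aucs = rep_aucs)
  out$folds <- folds
  out$seed <- seed
  out
}

#' Arithmetic mean of a set of prediction ranks
#'
#' Used to summarize how a method ranks independently confirmed
#' associations (smaller is better).
#'
#' @param ranks nonempty vector of positive rank values.
#' @return the mean rank.
#' @export
average_rank <- function(ranks) {
  if (length(ranks) == 0) stop("empty rank list")
  if (any(!is.finite(ranks)) || any(ranks <= 0))
    stop("ranks must be positive and finite")
  mean(ranks)
}
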