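test_that("rank-based ROC/AUC matches brute-force threshold sweeps", {
  # a single test pair ranked 1 of 10 candidates is perfect
  r <- roc_auc(1, 10)
  expect_equal(r$auc, 1)
  expect_equal(r$roc_points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
               c(fpr = 1, tpr = 1))

  # ranked 6 of 10: sweep all 11 rank cutoffs by hand; the positive beats
  # 5 of 10 candidates
  sweep_auc <- local({
    ranks_cand <- c(1:5, 7:11)  # combined positions of the candidates
    tpr <- vapply(0:11, function(t) as.numeric(6 <= t), numeric(1))
    fpr <- vapply(0:11, function(t) mean(ranks_cand <= t), numeric(1))
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  })
  expect_equal(roc_auc(6, 10)$auc, sweep_auc)
  expect_equal(roc_auc(6, 10)$auc, 0.5)

  # reversing every rank maps AUC to 1 - AUC
  set.seed(31)
  m <- sample(5:20, 12, replace = TRUE)
  ranks <- vapply(m, function(mm) sample(mm + 1, 1), numeric(1))
  a <- roc_auc(ranks, m)$auc
  expect_equal(roc_auc(m + 2 - ranks, m)$auc, 1 - a, tolerance = 1e-12)

  expect_error(roc_auc(numeric(0), numeric(0)), "no test samples")
  expect_error(roc_auc(12, 10), "outside")
})

test_that("ROC points are monotone and integrate to the pairwise statistic", {
  set.seed(77)
  for (i in 1:5) {
    n <- 15
    m <- sample(4:12, n, replace = TRUE)
    pos <- runif(n)
    cands <- lapply(m, function(mm) round(runif(mm), 1))
    ranks <- mapply(function(s, cand)
      1 + sum(cand > s) + 0.5 * sum(cand == s), pos, cands)
    r <- roc_auc(ranks, m)
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
    # trapezoid over the returned polyline equals the reported auc
    trap <- with(r$roc_points,
                 sum(diff(fpr) * (utils::head(tpr, -1) +
                                  utils::tail(tpr, -1)) / 2))
    expect_equal(trap, r$auc, tolerance = 1e-10)
    # and the pairwise-comparison oracle agrees
    expect_equal(r$auc, auc_pairwise_oracle(pos, cands), tolerance = 1e-10)
  }
})

perfect_scorer <- function(truth) function(net) truth
random_scorer <- function(net) {
  matrix(runif(length(net$adjacency)), nrow(net$adjacency),
         dimnames = dimnames(net$adjacency))
}

test_that("global LOOCV is perfect for an oracle predictor and null for noise", {
  net <- random_network(fixture_spec(nl = 20, nd = 15, density = 0.15,
                                     seed = 3))
  cv <- global_loocv(net, perfect_scorer(net$adjacency))
  expect_equal(cv$auc, 1)
  expect_equal(cv$records$rank, rep(1, nrow(cv$records)))

  # label-independent scores: AUC within 3 standard errors of 0.5
  big <- random_network(fixture_spec(nl = 60, nd = 40, density = 0.1,
                                     seed = 4))
  expect_gte(sum(big$adjacency), 200)
  set.seed(11)
  cvr <- global_loocv(big, random_scorer)
  p <- (cvr$records$rank - 1) / cvr$records$n_candidates
  se <- stats::sd(1 - p) / sqrt(length(p))
  expect_lt(abs(cvr$auc - 0.5), 3 * se)
})

test_that("LOOCV ranks match exhaustive enumeration on a toy network", {
  # 3 x 2 network, identity similarity blocks, truncated KATZ at k = 2:
  # recompute every fold by the walk oracle and re-derive the ranks
  A <- rbind(c(1, 0), c(1, 1), c(0, 0))
  net <- make_net(A)
  sc <- function(netm) {
    nl <- 3
    LS <- similarity_matrix(diag(3), ids = netm$lncrna_ids, role = "LS")
    DS <- similarity_matrix(diag(2), ids = netm$disease_ids, role = "DS")
    katz_scores_truncated(build_heterogeneous_matrix(LS, DS, netm),
                          beta = 0.1, k = 2)
  }
  cv <- global_loocv(net, sc)
  ones <- which(A == 1, arr.ind = TRUE)
  for (t in seq_len(nrow(ones))) {
    i <- ones[t, 1]; j <- ones[t, 2]
    Am <- A; Am[i, j] <- 0
    M <- rbind(cbind(diag(3), Am), cbind(t(Am), diag(2)))
    So <- matrix(0, 3, 2)
    for (u in 1:3) for (v in 1:2)
      So[u, v] <- katz_entry_oracle(M, u, 3 + v, 0.1, 2)
    cand <- So[A == 0]
    expected_rank <- 1 + sum(cand > So[i, j]) + 0.5 * sum(cand == So[i, j])
    rec <- cv$records[cv$records$lncrna_id == net$lncrna_ids[i] &
                      cv$records$disease_id == net$disease_ids[j], ]
    expect_equal(rec$rank, expected_rank)
    expect_equal(rec$n_candidates, sum(A == 0))
  }
})

test_that("local LOOCV restricts candidates to the test disease", {
  net <- random_network(fixture_spec(nl = 15, nd = 10, density = 0.2,
                                     seed = 6))
  cv <- local_loocv(net, perfect_scorer(net$adjacency))
  expect_equal(cv$auc, 1)
  deg <- colSums(net$adjacency)
  for (r in seq_len(nrow(cv$records))) {
    d <- cv$records$disease_id[r]
    expect_equal(cv$records$n_candidates[r],
                 nrow(net$adjacency) - deg[[d]])
  }
  # constant scores tie every candidate: local AUC is exactly 0.5
  const <- function(netm) matrix(1, 15, 10,
                                 dimnames = dimnames(netm$adjacency))
  expect_equal(local_loocv(net, const)$auc, 0.5)
})

test_that("k-fold CV is seeded, deterministic, and degenerates to LOOCV", {
  net <- random_network(fixture_spec(nl = 15, nd = 10, density = 0.2,
                                     seed = 7))
  sc <- katz_scorer(beta = 0.01)
  a <- kfold_cv(net, sc, folds = 5, repetitions = 3, seed = 10)
  b <- kfold_cv(net, sc, folds = 5, repetitions = 3, seed = 10)
  expect_identical(a$rep_aucs, b$rep_aucs)
  expect_identical(a$records, b$records)
  c2 <- kfold_cv(net, sc, folds = 5, repetitions = 3, seed = 11)
  expect_false(identical(a$rep_aucs, c2$rep_aucs))

  n <- sum(net$adjacency)
  deg <- kfold_cv(net, sc, folds = n, repetitions = 1, seed = 1)
  expect_equal(deg$auc, global_loocv(net, sc)$auc, tolerance = 1e-12)

  perf <- kfold_cv(net, perfect_scorer(net$adjacency), folds = 5,
                   repetitions = 3, seed = 2)
  expect_equal(perf$auc_mean, 1)
  expect_equal(perf$auc_sd, 0)

  expect_warning(kfold_cv(net, sc, folds = 5, repetitions = 1), "seed")
  expect_error(kfold_cv(make_net(rbind(c(1, 0), c(0, 1))), sc, folds = 5,
                        repetitions = 1, seed = 1), "fewer associations")
})

test_that("every protocol hands the scorer a masked network", {
  net <- random_network(fixture_spec(nl = 10, nd = 8, density = 0.2,
                                     seed = 12))
  seen <- new.env()
  seen$ok <- TRUE
  spy <- function(netm) {
    # the held-out pairs must be invisible: strictly fewer ones than the truth
    if (sum(netm$adjacency) >= sum(net$adjacency)) seen$ok <- FALSE
    matrix(runif(80), 10, 8, dimnames = dimnames(netm$adjacency))
  }
  set.seed(5)
  global_loocv(net, spy)
  local_loocv(net, spy)
  kfold_cv(net, spy, folds = 5, repetitions = 2, seed = 3)
  expect_true(seen$ok)
})

test_that("average rank is the arithmetic mean with input validation", {
  expect_equal(average_rank(1), 1)
  expect_equal(average_rank(c(2, 4)), 3)
  expect_error(average_rank(numeric(0)), "empty")
  expect_error(average_rank(c(1, -2)), "positive")
})
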