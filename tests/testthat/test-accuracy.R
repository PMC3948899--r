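test_that("classification reproduces aggregate confusion counts and conserves patients", {
  fx <- study_fixture()
  pr <- confusion_to_records(fx$confusion$r1$DTS)
  cc <- classify(pr$records, pr$truth)
  expect_equal(unclass(cc), list(tp = 116L, tn = 308L, fp = 13L, fn = 28L))
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, 465)
})

test_that("an indeterminate score counts against the reader by default", {
  pr <- records_from_scores(rep(3, 20), rep(c(TRUE, FALSE), 10))
  cc <- classify(pr$records, pr$truth)
  expect_equal(unclass(cc), list(tp = 0L, tn = 0L, fp = 10L, fn = 10L))
  cc_f <- classify(pr$records, pr$truth, score3 = "favour")
  expect_equal(unclass(cc_f), list(tp = 10L, tn = 10L, fp = 0L, fn = 0L))
  cc_e <- classify(pr$records, pr$truth, score3 = "exclude")
  expect_equal(cc_e$tp + cc_e$tn + cc_e$fp + cc_e$fn, 0)
})

test_that("classification agrees with a per-record oracle on random cohorts", {
  set.seed(42)
  for (rep_i in 1:20) {
    scores <- sample(1:5, 50, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), 50, replace = TRUE)
    pr <- records_from_scores(scores, pos)
    cc <- classify(pr$records, pr$truth)
    oracle <- classify_record_oracle(scores, pos)
    expect_equal(unlist(unclass(cc)), oracle,
                 ignore_attr = TRUE)
  }
})

test_that("classification demands a complete truth table and a single reading arm", {
  pr <- records_from_scores(c(4, 1), c(TRUE, FALSE))
  expect_error(classify(pr$records, pr$truth[1, , drop = FALSE]),
               "no truth label")
  mixed <- pr$records
  mixed$modality <- c("CXR", "DTS")
  expect_error(classify(mixed, pr$truth), "single reader")
})

test_that("performance metrics are exact ratios, undefined on empty classes", {
  m <- confusion_metrics(confusion_counts(tp = 116, tn = 308, fp = 13, fn = 28))
  expect_equal(m$estimates[["sensitivity"]], 116 / 144)
  expect_equal(m$estimates[["specificity"]], 308 / 321)
  expect_equal(m$estimates[["accuracy"]], 424 / 465)
  expect_equal(m$estimates[["ppv"]], 116 / 129)
  expect_equal(m$estimates[["npv"]], 308 / 336)

  m2 <- confusion_metrics(confusion_counts(tp = 34, tn = 33, fp = 288, fn = 110))
  expect_equal(m2$estimates[["sensitivity"]], 34 / 144)
  expect_equal(round_half_up(100 * m2$estimates[["sensitivity"]]), 24)

  und <- confusion_metrics(confusion_counts(tp = 0, tn = 5, fp = 2, fn = 0))
  expect_true(is.na(und$estimates[["sensitivity"]]))
  expect_false(is.na(und$estimates[["specificity"]]))
})

test_that("metrics are invariant to record order and patient relabelling", {
  set.seed(7)
  scores <- sample(1:5, 60, replace = TRUE)
  pos <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(.4, .6))
  pr <- records_from_scores(scores, pos)
  cc <- classify(pr$records, pr$truth)
  perm <- sample(60)
  pr2 <- pr
  pr2$records <- pr2$records[perm, ]
  pr2$records$patient_id <- paste0("x", pr2$records$patient_id)
  pr2$truth$patient_id <- paste0("x", pr2$truth$patient_id)
  expect_equal(classify(pr2$records, pr2$truth), cc)
})

test_that("ordinal AUC handles perfect separation and symmetry", {
  perfect <- rbind(positive = c(0, 0, 0, 0, 10), negative = c(12, 0, 0, 0, 0))
  expect_equal(auc_ordinal(perfect)$auc, 1)
  same <- rbind(positive = c(2, 3, 4, 3, 2), negative = c(4, 6, 8, 6, 4))
  expect_equal(auc_ordinal(same)$auc, 0.5)
  expect_error(auc_ordinal(rbind(positive = rep(0, 5), negative = 1:5)),
               "non-empty")
})

test_that("ordinal AUC equals the exhaustive pairwise oracle on random tables", {
  set.seed(101)
  for (i in 1:200) {
    tab <- random_score_table()
    expect_equal(auc_ordinal(tab)$auc, auc_pairwise_oracle(tab),
                 tolerance = 1e-12)
  }
})

test_that("ordinal AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  for (i in 1:5) {
    scores <- sample(1:5, 120, replace = TRUE)
    pos <- sample(c(TRUE, FALSE), 120, replace = TRUE)
    ref <- suppressMessages(pROC::auc(pROC::roc(pos, scores, direction = "<",
                                                quiet = TRUE)))
    expect_equal(auc_ordinal(scores, pos)$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("correlated-AUC comparison degenerates and reduces correctly", {
  expect_equal(hm_auc_z(0.8, 0.8, 0.03, 0.05, 0.4), 0)
  s <- sample(1:5, 40, replace = TRUE)
  p <- rep(c(TRUE, FALSE), 20)
  res <- auc_compare_correlated(s, s, p, r = 0.5)
  expect_equal(res$z, 0)
  expect_equal(res$p.value, 1)
  # r = 0 is the independent-samples z
  z0 <- hm_auc_z(0.9, 0.7, 0.04, 0.05, 0)
  expect_equal(z0, (0.9 - 0.7) / sqrt(0.04^2 + 0.05^2))
  expect_error(hm_auc_z(0.9, 0.7, 0.04, 0.04, 1.0000001), "degenerate")
})

test_that("correlated-AUC p shrinks with n at a fixed effect and matches the AUC ordering", {
  set.seed(21)
  base_n <- 60
  pos <- rep(c(TRUE, FALSE), c(base_n, base_n))
  s_dts <- ifelse(pos, sample(3:5, 2 * base_n, TRUE), sample(1:3, 2 * base_n, TRUE))
  s_cxr <- sample(1:5, 2 * base_n, TRUE)
  ps <- vapply(c(1, 4, 16), function(k) {
    res <- auc_compare_correlated(rep(s_dts, k), rep(s_cxr, k), rep(pos, k))
    expect_gt(res$z * (res$auc1$auc - res$auc2$auc), 0)
    res$p.value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("McNemar handles degenerate, closed-form and exact-oracle cases", {
  res0 <- mcnemar_paired(b = 0, c = 0)
  expect_equal(res0$p.value, 1)
  expect_true(res0$degenerate)

  res <- mcnemar_paired(b = 10, c = 0)
  expect_equal(res$statistic, (abs(10 - 0) - 1)^2 / 10) # 8.1
  expect_equal(res$statistic, 8.1)

  # decision agreement with the exact binomial on 35 discordant pairs
  chi <- mcnemar_paired(b = 25, c = 10)
  exact_p <- binom.test(25, 35, 0.5)$p.value
  expect_equal(chi$method, "continuity-corrected chi-square")
  expect_equal(chi$p.value < 0.05, exact_p < 0.05)

  # vector interface
  c1 <- c(TRUE, TRUE, FALSE, TRUE)
  c2 <- c(TRUE, FALSE, FALSE, FALSE)
  res_v <- mcnemar_paired(c1, c2)
  expect_equal(res_v$b, 2)
  expect_equal(res_v$c, 0)
})

test_that("Yates-corrected chi-square matches the textbook formula", {
  eq <- accuracy_chisq(50, 30, 50, 30)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)

  res <- accuracy_chisq(424, 41, 69, 396)
  m <- matrix(c(424, 41, 69, 396), nrow = 2, byrow = TRUE)
  n <- sum(m)
  e <- outer(rowSums(m), colSums(m)) / n
  oracle <- sum((abs(m - e) - 0.5)^2 / e)
  expect_equal(res$statistic, oracle, tolerance = 1e-9)

  res2 <- accuracy_chisq(2 * 424, 2 * 41, 2 * 69, 2 * 396)
  expect_gt(res2$statistic, res$statistic)

  expect_error(accuracy_chisq(0, 0, 5, 5), "expected cell")
})

test_that("weighted kappa is exact on identity and at the grading cut-offs", {
  x <- rep(1:5, 4)
  k <- kappa_weighted(x, x)
  expect_equal(k$kappa, 1)
  expect_equal(k$band, "very good")
  expect_equal(agreement_band(c(0.19, 0.20, 0.40, 0.59, 0.60, 0.80, 1.0)),
               c("poor", "fair", "moderate", "moderate", "good",
                 "very good", "very good"))
})

test_that("weighted kappa equals the direct-formula oracle on random tables", {
  set.seed(33)
  for (w in c("linear", "quadratic")) {
    for (i in 1:50) {
      x <- sample(1:5, 80, replace = TRUE)
      y <- sample(1:5, 80, replace = TRUE)
      expect_lt(abs(kappa_weighted(x, y, weights = w)$kappa -
                      kappa_direct_oracle(x, y, weights = w)), 1e-12)
    }
  }
})

test_that("kappa of independent readers is zero in expectation and flags no variation", {
  set.seed(77)
  n_rep <- 200
  ks <- vapply(seq_len(n_rep), function(i) {
    x <- sample(1:5, 200, replace = TRUE)
    y <- sample(1:5, 200, replace = TRUE)
    kappa_weighted(x, y)$kappa
  }, numeric(1))
  mc_se <- sd(ks) / sqrt(n_rep)
  expect_lt(abs(mean(ks)), 3 * mc_se)

  flat <- kappa_weighted(rep(3, 10), sample(1:5, 10, replace = TRUE))
  expect_true(is.na(flat$kappa))
  expect_true(flat$degenerate)
})

test_that("paired time comparison is degenerate on ties and directional on shifts", {
  t <- c(60, 70, 80, NA, 90)
  res <- compare_times(t, t)
  expect_equal(res$p.value, 1)
  expect_true(res$degenerate)
  expect_equal(res$n_pairs, 4)

  set.seed(9)
  cxr <- rlnorm(30, log(60), 0.3)
  dts <- cxr + runif(30, 5, 40) # strictly longer per patient
  expect_lt(compare_times(dts, cxr)$p.value, 0.05)
})

test_that("small-sample signed-rank p equals exhaustive enumeration", {
  d <- c(3, -1, 7, 12, -5, 9) # distinct magnitudes, no zeros
  res <- compare_times(d, rep(0, 6))
  expect_equal(res$p.value, wilcoxon_exact_oracle(d), tolerance = 1e-12)
})

test_that("consensus merging lets the more suspicious score win only across triage bands", {
  expect_equal(consensus_scores(c(1, 2, 4, 5), c(2, 5, 1, 4)),
               c(1L, 5L, 4L, 5L))
})
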