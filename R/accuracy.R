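# Reader-performance statistics for ordinal confidence-score reading studies:
# score-based confusion classification, sensitivity/specificity family,
# nonparametric ROC area with Hanley-McNeil errors, paired tests, and
# weighted kappa agreement.

#' Confusion counts under the score-based classification rule
#'
#' @param tp,tn,fp,fn nonnegative integer tallies.
#' @return object of class `confusion_counts`.
#' @seealso [classify()], [confusion_metrics()]
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  x <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(x < 0) || any(x != round(x))) {
    stop("confusion counts must be nonnegative integers")
  }
  structure(as.list(setNames(as.integer(x), names(x))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts: TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$tp, x$tn, x$fp, x$fn, x$tp + x$tn + x$fp + x$fn))
  invisible(x)
}

#' Classify scored readings against binary truth
#'
#' Applies the confidence-score decision rule for one reader and one
#' modality. Under the default `"penalise"` policy an indeterminate score of
#' 3 counts against the reader: positives scored 1-3 are false negatives and
#' negatives scored 3-5 are false positives, so only scores 4-5 on a positive
#' are true positives and only scores 1-2 on a negative are true negatives.
#' `"exclude"` drops score-3 readings; `"favour"` credits them to the reader
#' (TP on positives, TN on negatives).
#'
#' @param records reading records (see [read_readings()]) from a single
#'   reader and single modality.
#' @param truth a truth table with `patient_id` and either `positive` or
#'   `category` (mapped through [map_truth()]).
#' @param score3 policy for indeterminate scores: `"penalise"` (default),
#'   `"exclude"`, or `"favour"`.
#' @return [confusion_counts()]; under `"penalise"` and `"favour"` the four
#'   cells sum to the number of records.
#' @export
classify <- function(records, truth, score3 = c("penalise", "exclude", "favour")) {
  score3 <- match.arg(score3)
  if (length(unique(records$modality)) > 1 || length(unique(records$reader_id)) > 1) {
    stop("records must come from a single reader and a single modality")
  }
  if (!"positive" %in% names(truth)) truth <- map_truth(truth)
  idx <- match(records$patient_id, truth$patient_id)
  if (anyNA(idx)) {
    stop("no truth label for patient(s): ",
         paste(unique(records$patient_id[is.na(idx)]), collapse = ", "))
  }
  p <- truth$positive[idx]
  s <- records$score
  if (score3 == "exclude") {
    keep <- s != 3
    p <- p[keep]
    s <- s[keep]
  }
  # an indeterminate score 3 is wrong for both classes under "penalise" and
  # right for both under "favour", so correctness is judged per truth class
  correct <- ifelse(p,
                    if (score3 == "favour") s >= 3 else s >= 4,
                    if (score3 == "favour") s <= 3 else s <= 2)
  confusion_counts(tp = sum(p & correct), tn = sum(!p & correct),
                   fp = sum(!p & !correct), fn = sum(p & !correct))
}

#' Diagnostic performance metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy
#' (TP+TN)/(TP+TN+FP+FN), PPV TP/(TP+FP) and NPV TN/(TN+FN), kept as exact
#' ratios; a metric with a zero denominator is `NA` (undefined), never 0.
#'
#' @param x a [confusion_counts()] object.
#' @return object of class `accuracy_report` with elements `estimates` (named
#'   proportions) and `fractions` (named list of `c(numerator, denominator)`).
#' @export
confusion_metrics <- function(x) {
  stopifnot(inherits(x, "confusion_counts"))
  frac <- function(num, den) c(num = num, den = den)
  n <- x$tp + x$tn + x$fp + x$fn
  fractions <- list(
    sensitivity = frac(x$tp, x$tp + x$fn),
    specificity = frac(x$tn, x$tn + x$fp),
    accuracy    = frac(x$tp + x$tn, n),
    ppv         = frac(x$tp, x$tp + x$fp),
    npv         = frac(x$tn, x$tn + x$fn)
  )
  estimates <- vapply(fractions, function(f) {
    if (f[["den"]] == 0) NA_real_ else f[["num"]] / f[["den"]]
  }, numeric(1))
  structure(list(estimates = estimates, fractions = fractions,
                 counts = x), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  for (m in names(x$estimates)) {
    f <- x$fractions[[m]]
    if (is.na(x$estimates[[m]])) {
      cat(sprintf("%-12s undefined (0 denominator)\n", m))
    } else {
      cat(sprintf("%-12s %d%% (%d/%d)\n", m,
                  round_half_up(100 * x$estimates[[m]]), f[["num"]], f[["den"]]))
    }
  }
  invisible(x)
}

#' Tabulate ordinal scores by truth state
#'
#' @param scores integer scores 1-5.
#' @param positive logical truth per score.
#' @return 2 x 5 integer matrix with rows `positive`, `negative` and columns
#'   scores 1-5.
#' @export
score_distribution <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), all(scores %in% 1:5))
  m <- rbind(positive = tabulate(scores[positive], nbins = 5),
             negative = tabulate(scores[!positive], nbins = 5))
  colnames(m) <- 1:5
  m
}

#' Nonparametric ROC area for ordinal scores
#'
#' The area under the empirical ROC curve equals the Mann-Whitney
#' probability that a randomly chosen positive scores higher than a randomly
#' chosen negative, with ties credited 1/2. The standard error is the
#' Hanley-McNeil formula with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param x either a 2 x k score-distribution matrix (rows positive,
#'   negative; see [score_distribution()]) or an integer score vector.
#' @param positive logical truth vector when `x` is a score vector.
#' @param ci interval type: `"normal"` (Hanley-McNeil SE, symmetric) or
#'   `"logit"` (normal on the log-odds scale, respects (0,1)).
#' @param conf_level confidence level, default 0.95.
#' @return object of class `auc_estimate`: `auc`, `se`, `ci` (length 2),
#'   `n_pos`, `n_neg`.
#' @references Hanley JA, McNeil BJ. The meaning and use of the area under a
#'   receiver operating characteristic (ROC) curve. Radiology 1982;143:29-36.
#' @export
auc_ordinal <- function(x, positive = NULL, ci = c("normal", "logit"),
                        conf_level = 0.95) {
  ci <- match.arg(ci)
  if (!is.matrix(x)) {
    stopifnot(!is.null(positive), length(x) == length(positive))
    x <- score_distribution(x, positive)
  }
  pos <- x[1, ]
  neg <- x[2, ]
  n_pos <- sum(pos)
  n_neg <- sum(neg)
  if (n_pos == 0 || n_neg == 0) {
    stop("both truth classes must be non-empty to compute an ROC area")
  }
  k <- length(pos)
  comp <- outer(seq_len(k), seq_len(k), function(i, j) (i > j) + 0.5 * (i == j))
  auc <- as.numeric(pos %*% comp %*% neg) / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
                (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (ci == "normal" || auc %in% c(0, 1) || se == 0) {
    lo <- max(0, auc - z * se)
    hi <- min(1, auc + z * se)
  } else {
    lg <- log(auc / (1 - auc))
    se_lg <- se / (auc * (1 - auc))
    lo <- stats::plogis(lg - z * se_lg)
    hi <- stats::plogis(lg + z * se_lg)
  }
  structure(list(auc = auc, se = se, ci = c(lower = lo, upper = hi),
                 conf_level = conf_level, n_pos = n_pos, n_neg = n_neg),
            class = "auc_estimate")
}

#' @export
print.auc_estimate <- function(x, ...) {
  cat(sprintf("AUC %.3f (%d%% CI %.3f-%.3f), SE %.4f, %d positives / %d negatives\n",
              x$auc, round(100 * x$conf_level), x$ci[1], x$ci[2], x$se,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Compare two correlated ROC areas (paired design)
#'
#' Hanley-McNeil z test for two ROC areas measured on the same cases:
#' `z = (A1 - A2) / sqrt(se1^2 + se2^2 - 2 r se1 se2)` with a two-sided
#' normal p value. The correlation `r` between the two area estimates is
#' approximated by the average of the within-class rank correlations of the
#' paired scores (in place of the published lookup table, to which this
#' average is the standard entry).
#'
#' @param scores1,scores2 paired ordinal scores on the same patients.
#' @param positive logical truth vector.
#' @param cor_method rank correlation passed to [stats::cor()], default
#'   `"spearman"`.
#' @param r optionally override the estimated correlation with a value from
#'   the published table.
#' @return list with `auc1`, `auc2`, `r`, `z`, `p.value`.
#' @references Hanley JA, McNeil BJ. A method of comparing the areas under
#'   receiver operating characteristic curves derived from the same cases.
#'   Radiology 1983;148:839-843.
#' @export
auc_compare_correlated <- function(scores1, scores2, positive,
                                   cor_method = "spearman", r = NULL) {
  stopifnot(length(scores1) == length(scores2),
            length(scores1) == length(positive))
  a1 <- auc_ordinal(scores1, positive)
  a2 <- auc_ordinal(scores2, positive)
  if (is.null(r)) {
    r_class <- vapply(list(positive, !positive), function(cl) {
      suppressWarnings(stats::cor(scores1[cl], scores2[cl],
                                  method = cor_method))
    }, numeric(1))
    r_class[is.na(r_class)] <- 0 # a constant reader contributes no correlation
    r <- mean(r_class)
  }
  z <- hm_auc_z(a1$auc, a2$auc, a1$se, a2$se, r)
  list(auc1 = a1, auc2 = a2, r = r, z = z,
       p.value = 2 * stats::pnorm(-abs(z)))
}

#' @rdname auc_compare_correlated
#' @param auc1,auc2 the two area estimates.
#' @param se1,se2 their standard errors.
#' @export
hm_auc_z <- function(auc1, auc2, se1, se2, r) {
  if (auc1 == auc2) return(0) # degenerate variance is irrelevant at zero diff
  v <- se1^2 + se2^2 - 2 * r * se1 * se2
  if (v <= 0) {
    stop("nonpositive variance of the AUC difference: degenerate pairing")
  }
  (auc1 - auc2) / sqrt(v)
}

#' McNemar test for paired diagnostic outcomes
#'
#' Continuity-corrected chi-square on the discordant pairs,
#' `(|b - c| - 1)^2 / (b + c)` on 1 df, with an exact two-sided binomial p
#' value when the discordant count is below `exact_threshold`. With no
#' discordant pairs the test is degenerate and p = 1 (flagged).
#'
#' @param correct1,correct2 paired logical outcome vectors (e.g. per-patient
#'   correctness under two modalities); alternatively supply the discordant
#'   counts `b` and `c` directly.
#' @param b,c discordant counts: `b` pairs correct under 1 only, `c` correct
#'   under 2 only.
#' @param exact_threshold switch to the exact binomial p value when
#'   `b + c` is strictly below this, default 25.
#' @return list with `statistic`, `p.value`, `b`, `c`, `method`, `degenerate`.
#' @export
mcnemar_paired <- function(correct1 = NULL, correct2 = NULL, b = NULL,
                           c = NULL, exact_threshold = 25) {
  if (is.null(b) || is.null(c)) {
    stopifnot(length(correct1) == length(correct2))
    b <- sum(correct1 & !correct2)
    c <- sum(!correct1 & correct2)
  }
  nd <- b + c
  if (nd == 0) {
    return(list(statistic = NA_real_, p.value = 1, b = b, c = c,
                method = "degenerate (no discordant pairs)",
                degenerate = TRUE))
  }
  statistic <- (abs(b - c) - 1)^2 / nd
  if (nd < exact_threshold) {
    p <- stats::binom.test(b, nd, p = 0.5)$p.value
    method <- "exact binomial"
  } else {
    p <- stats::pchisq(statistic, df = 1, lower.tail = FALSE)
    method <- "continuity-corrected chi-square"
  }
  list(statistic = statistic, p.value = p, b = b, c = c, method = method,
       degenerate = FALSE)
}

#' Yates-corrected chi-square for accuracy comparison
#'
#' Compares correct/incorrect counts between two modalities with the
#' chi-square test with Yates continuity correction on the 2 x 2 table.
#'
#' @param correct1,incorrect1 counts under the first modality.
#' @param correct2,incorrect2 counts under the second.
#' @return list with `statistic`, `p.value`, `table`.
#' @export
accuracy_chisq <- function(correct1, incorrect1, correct2, incorrect2) {
  m <- matrix(c(correct1, incorrect1, correct2, incorrect2), nrow = 2,
              byrow = TRUE,
              dimnames = list(modality = c("1", "2"),
                              outcome = c("correct", "incorrect")))
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0)) stop("expected cell count of zero")
  res <- stats::chisq.test(m, correct = TRUE)
  list(statistic = unname(res$statistic), p.value = res$p.value, table = m)
}

#' Weighted kappa for paired ordinal ratings
#'
#' Cohen's weighted kappa on the fixed 1-5 score scale with linear
#' (`1 - |i-j|/(k-1)`, default) or quadratic agreement weights. The kappa is
#' graded per the conventional bands: poor < 0.20, fair 0.20-0.39, moderate
#' 0.40-0.59, good 0.60-0.79, very good 0.80-1 (left-closed intervals).
#'
#' @param x,y paired ratings from the two readers.
#' @param weights `"linear"` or `"quadratic"`.
#' @param levels the ordinal scale, default `1:5`.
#' @return list with `kappa`, `band`, `weights`, `po`, `pe`, `n`;
#'   `kappa` is `NA` (flagged `degenerate`) when either rater shows no
#'   variation.
#' @export
kappa_weighted <- function(x, y, weights = c("linear", "quadratic"),
                           levels = 1:5) {
  weights <- match.arg(weights)
  stopifnot(length(x) == length(y))
  if (length(x) < 2) stop("at least two paired ratings are required")
  stopifnot(all(x %in% levels), all(y %in% levels))
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    return(list(kappa = NA_real_, band = NA_character_, weights = weights,
                po = NA_real_, pe = NA_real_, n = length(x),
                degenerate = TRUE))
  }
  k <- length(levels)
  tab <- table(factor(x, levels = levels), factor(y, levels = levels))
  p <- tab / sum(tab)
  d <- abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1)
  w <- if (weights == "linear") 1 - d else 1 - d^2
  po <- sum(w * p)
  pe <- sum(w * outer(rowSums(p), colSums(p)))
  kappa <- (po - pe) / (1 - pe)
  list(kappa = kappa, band = agreement_band(kappa), weights = weights,
       po = po, pe = pe, n = length(x), degenerate = FALSE)
}

#' @rdname kappa_weighted
#' @param kappa a kappa value.
#' @export
agreement_band <- function(kappa) {
  as.character(cut(kappa, breaks = c(-Inf, 0.2, 0.4, 0.6, 0.8, Inf),
                   labels = c("poor", "fair", "moderate", "good", "very good"),
                   right = FALSE))
}

#' Compare paired interpretation times
#'
#' Wilcoxon signed-rank test on paired per-patient interpretation times,
#' two-sided. Pairs with a missing time on either side are dropped
#' (pairwise deletion); zero differences are dropped per the signed-rank
#' convention, and when every difference is zero the comparison is
#' degenerate with p = 1.
#'
#' @param t1,t2 paired time vectors in seconds, `NA` allowed.
#' @return list with `statistic` (V), `p.value`, `n_pairs` (non-missing),
#'   `n_zero` (dropped zero differences), `degenerate`.
#' @export
compare_times <- function(t1, t2) {
  stopifnot(length(t1) == length(t2))
  ok <- !is.na(t1) & !is.na(t2)
  d <- t1[ok] - t2[ok]
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0) {
    return(list(statistic = NA_real_, p.value = 1, n_pairs = sum(ok),
                n_zero = n_zero, degenerate = TRUE))
  }
  res <- suppressWarnings(stats::wilcox.test(d, mu = 0))
  list(statistic = unname(res$statistic), p.value = res$p.value,
       n_pairs = sum(ok), n_zero = n_zero, degenerate = FALSE)
}

#' Merge two readers' scores into a consensus score
#'
#' Deterministic stand-in for consensus adjudication: where the two readers'
#' triage decisions differ (one score in 1-2, the other in 3-5) the higher,
#' more suspicious score wins — unresolved suspicion is not dismissed; where
#' the decisions agree, reader 1's score is kept (the choice within a triage
#' band does not alter routing).
#'
#' @param s1,s2 paired scores 1-5.
#' @return integer consensus scores.
#' @export
consensus_scores <- function(s1, s2) {
  stopifnot(length(s1) == length(s2), all(s1 %in% 1:5), all(s2 %in% 1:5))
  differ <- (s1 >= 3) != (s2 >= 3)
  as.integer(ifelse(differ, pmax(s1, s2), s1))
}
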