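# Independent oracles, written deliberately as naive enumerations so they
# share no code path with the implementation they check.

cents_of <- function(x) as.integer(round(x * 100))

# AUC by exhaustive comparison of every (positive, negative) score pair
auc_pairwise_oracle <- function(tab) {
  p <- rep(1:5, tab[1, ])
  q <- rep(1:5, tab[2, ])
  total <- 0
  for (a in p) {
    for (b in q) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(p) * length(q))
}

# weighted kappa from explicit observed/expected weighted agreement sums
kappa_direct_oracle <- function(x, y, weights = "linear", levels = 1:5) {
  k <- length(levels)
  n <- length(x)
  wfun <- function(i, j) {
    d <- abs(i - j) / (k - 1)
    if (weights == "linear") 1 - d else 1 - d^2
  }
  po <- 0
  pe <- 0
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pij <- sum(x == levels[i] & y == levels[j]) / n
      po <- po + wfun(i, j) * pij
      pe <- pe + wfun(i, j) *
        (sum(x == levels[i]) / n) * (sum(y == levels[j]) / n)
    }
  }
  (po - pe) / (1 - pe)
}

# per-record confusion classification, default score-3 policy
classify_record_oracle <- function(scores, positive) {
  cc <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_along(scores)) {
    s <- scores[i]
    if (positive[i]) {
      if (s == 4 || s == 5) cc["tp"] <- cc["tp"] + 1 else cc["fn"] <- cc["fn"] + 1
    } else {
      if (s == 1 || s == 2) cc["tn"] <- cc["tn"] + 1 else cc["fp"] <- cc["fp"] + 1
    }
  }
  cc
}

# exact two-sided signed-rank p by enumerating all sign assignments
wilcoxon_exact_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- drop(signs %*% r)
  min(1, 2 * min(mean(vs >= v_obs), mean(vs <= v_obs)))
}

# random 2x5 score table with both classes non-empty
random_score_table <- function(max_count = 30) {
  repeat {
    tab <- matrix(sample(0:max_count, 10, replace = TRUE), nrow = 2,
                  dimnames = list(c("positive", "negative"), 1:5))
    if (sum(tab[1, ]) > 0 && sum(tab[2, ]) > 0) return(tab)
  }
}

# reading records + truth for ad-hoc score vectors
records_from_scores <- function(scores, positive, modality = "DTS",
                                reader_id = "r1") {
  ids <- sprintf("p%04d", seq_along(scores))
  list(records = data.frame(patient_id = ids, modality = modality,
                            reader_id = reader_id, score = as.integer(scores),
                            interpretation_time_s = NA_real_,
                            stringsAsFactors = FALSE),
       truth = data.frame(patient_id = ids, positive = positive,
                          stringsAsFactors = FALSE))
}

# coverage of the generator's true operating point by exact binomial CIs
recovery_coverage <- function(n_rep, n = 465, sens = 0.80, spec = 0.95,
                              seeds = seq_len(n_rep)) {
  cover_sens <- logical(n_rep)
  cover_spec <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    ch <- generate_cohort(cohort_spec(n = n, seed = seeds[i]))
    recs <- ch$readings[ch$readings$modality == "DTS" &
                          ch$readings$reader_id == "r1", ]
    cc <- classify(recs, ch$truth)
    ci_s <- stats::binom.test(cc$tp, cc$tp + cc$fn)$conf.int
    ci_p <- stats::binom.test(cc$tn, cc$tn + cc$fp)$conf.int
    cover_sens[i] <- sens >= ci_s[1] && sens <= ci_s[2]
    cover_spec[i] <- spec >= ci_p[1] && spec <= ci_p[2]
  }
  c(sensitivity = mean(cover_sens), specificity = mean(cover_spec))
}
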