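# Seeded synthetic cohorts with the statistical structure of a two-reader
# CXR/DTS reading study: categorical truth mix, modality- and
# truth-conditional ordinal score distributions, a copy-probability reader
# dependence, lognormal interpretation times, and a subdiagnostic-DTS rate.

default_category_mix <- function() {
  c(pulmonary_opacity = 60, primary_lung_neoplasm = 5, ground_glass = 47,
    noncalcified_solid_nodule = 32, pulmonary_scar = 26,
    calcified_solid_nodule = 23, pleural_plaque = 36, pseudolesion = 236) / 465
}

# Categorical score distributions P(score | modality, truth), calibrated to
# the aggregate operating points of the reading study the package emulates:
# DTS sensitivity 0.80 / specificity 0.95, CXR sensitivity 0.24 /
# specificity 0.10 (most CXR negatives land on the indeterminate score 3).
default_score_model <- function() {
  list(
    CXR = list(positive = c(0.01, 0.03, 0.72, 0.16, 0.08),
               negative = c(0.01, 0.09, 0.85, 0.04, 0.01)),
    DTS = list(positive = c(0.04, 0.08, 0.08, 0.35, 0.45),
               negative = c(0.75, 0.20, 0.02, 0.02, 0.01))
  )
}

default_time_model <- function() {
  list(CXR = c(mean = 66, sd = 23), DTS = c(mean = 103, sd = 66))
}

# per-category marker-lesion size distributions (cm); pseudolesions carry none
category_size_model <- function() {
  list(mean = c(pulmonary_opacity = 2.5, primary_lung_neoplasm = 2.5,
                ground_glass = 2.5, noncalcified_solid_nodule = 1.1,
                pulmonary_scar = 1.1, calcified_solid_nodule = 1.1,
                pleural_plaque = 2.4, pseudolesion = NA),
       sd = c(pulmonary_opacity = 0.3, primary_lung_neoplasm = 0.7,
              ground_glass = 0.4, noncalcified_solid_nodule = 0.3,
              pulmonary_scar = 0.3, calcified_solid_nodule = 0.3,
              pleural_plaque = 0.6, pseudolesion = NA))
}

#' Specify a synthetic reading-study cohort
#'
#' Defaults reproduce the design of the study the package models: 465
#' patients, prevalence 144/465 of CT-deserving pulmonary lesions, category
#' mix proportional to the reference-standard taxonomy counts, score models
#' calibrated to DTS sensitivity 0.80 / specificity 0.95 and CXR 0.24 /
#' 0.10, lognormal interpretation times of 66 +/- 23 s (CXR) and
#' 103 +/- 66 s (DTS), and a subdiagnostic-DTS rate of 7/465.
#'
#' @param n number of diagnostic patients.
#' @param prevalence proportion of truth-positive patients in (0, 1); the
#'   category mix is renormalised within the positive and negative groups to
#'   match it.
#' @param category_mix named probabilities over [lesion_categories()].
#' @param score_model list `list(CXR = list(positive=, negative=), DTS =
#'   ...)` of length-5 score probability vectors.
#' @param reader_agreement probability in `[0, 1]` that reader 2 copies
#'   reader 1's score; otherwise reader 2 redraws independently from the
#'   same score distribution. Maps monotonically to kappa (1 forces perfect
#'   agreement, 0 gives statistically independent readers).
#' @param time_model list of `c(mean=, sd=)` per modality (seconds); times
#'   are drawn lognormal with moment-matched parameters, truncated at 1 s.
#' @param subdiagnostic_rate expected proportion of additional patients
#'   whose DTS is subdiagnostic (no usable score).
#' @param seed integer seed making the cohort reproducible.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 465, prevalence = 144 / 465, category_mix = NULL,
                        score_model = NULL, reader_agreement = 0.85,
                        time_model = NULL, subdiagnostic_rate = 7 / 465,
                        seed = 1L) {
  stopifnot(n >= 1, prevalence > 0, prevalence < 1,
            reader_agreement >= 0, reader_agreement <= 1,
            subdiagnostic_rate >= 0, subdiagnostic_rate < 1)
  mix <- category_mix %||% default_category_mix()
  if (!setequal(names(mix), lesion_categories()) ||
      abs(sum(mix) - 1) > 1e-8 || any(mix < 0)) {
    stop("category_mix must be probabilities over the eight lesion categories")
  }
  # renormalise within truth groups so the mix is consistent with prevalence
  pos <- positive_categories()
  neg <- negative_categories()
  if (sum(mix[pos]) == 0 || sum(mix[neg]) == 0) {
    stop("category_mix must give weight to both truth classes")
  }
  mix[pos] <- mix[pos] / sum(mix[pos]) * prevalence
  mix[neg] <- mix[neg] / sum(mix[neg]) * (1 - prevalence)
  sm <- score_model %||% default_score_model()
  for (mod in MODALITIES) {
    for (cl in c("positive", "negative")) {
      p <- sm[[mod]][[cl]]
      if (length(p) != 5 || any(p < 0) || abs(sum(p) - 1) > 1e-8) {
        stop("score_model[[", mod, "]]$", cl,
             " must be 5 probabilities summing to 1")
      }
    }
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 category_mix = mix, score_model = sm,
                 reader_agreement = reader_agreement,
                 time_model = time_model %||% default_time_model(),
                 subdiagnostic_rate = subdiagnostic_rate,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# lognormal parameters matched to a target mean and SD
lognormal_params <- function(mean, sd) {
  sdlog2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a synthetic cohort
#'
#' Draws truth labels, paired two-reader ordinal scores for CXR and DTS,
#' interpretation times, DTS consensus scores (via [consensus_scores()]),
#' and a count of additional subdiagnostic-DTS patients. Identical spec and
#' seed give an identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `cohort`: `truth` (patient_id, category, size_cm,
#'   positive), `readings` (one row per patient x modality x reader, with
#'   interpretation times), `consensus` (patient_id, score, subdiagnostic;
#'   includes the subdiagnostic patients with `NA` scores), and
#'   `n_subdiagnostic`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  mix <- spec$category_mix
  cats <- sample(names(mix), n, replace = TRUE, prob = mix)
  positive <- map_truth(cats)
  szm <- category_size_model()
  size_cm <- rep(NA_real_, n)
  has_size <- !is.na(szm$mean[cats])
  size_cm[has_size] <- pmax(0.1, stats::rnorm(sum(has_size),
                                              szm$mean[cats][has_size],
                                              szm$sd[cats][has_size]))
  ids <- sprintf("p%05d", seq_len(n))
  truth <- data.frame(patient_id = ids, category = cats, size_cm = size_cm,
                      positive = positive, stringsAsFactors = FALSE)

  draw_scores <- function(mod) {
    s <- integer(n)
    for (cl in c("positive", "negative")) {
      sel <- if (cl == "positive") positive else !positive
      if (any(sel)) {
        s[sel] <- sample(1:5, sum(sel), replace = TRUE,
                         prob = spec$score_model[[mod]][[cl]])
      }
    }
    s
  }
  draw_times <- function(mod) {
    p <- lognormal_params(spec$time_model[[mod]][["mean"]],
                          spec$time_model[[mod]][["sd"]])
    pmax(1, stats::rlnorm(n, p[["meanlog"]], p[["sdlog"]]))
  }

  readings <- list()
  scores <- list()
  for (mod in MODALITIES) {
    s1 <- draw_scores(mod)
    copy <- stats::runif(n) < spec$reader_agreement
    s2 <- ifelse(copy, s1, draw_scores(mod))
    scores[[mod]] <- list(r1 = s1, r2 = as.integer(s2))
    for (r in c("r1", "r2")) {
      readings[[paste(mod, r)]] <- data.frame(
        patient_id = ids, modality = mod, reader_id = r,
        score = scores[[mod]][[r]],
        interpretation_time_s = round(draw_times(mod), 1),
        stringsAsFactors = FALSE)
    }
  }
  readings <- do.call(rbind, c(readings, list(make.row.names = FALSE)))

  cons <- consensus_scores(scores$DTS$r1, scores$DTS$r2)
  n_sub <- stats::rbinom(1, n, spec$subdiagnostic_rate)
  consensus <- data.frame(
    patient_id = c(ids, if (n_sub > 0) sprintf("s%05d", seq_len(n_sub))),
    score = c(cons, rep(NA_integer_, n_sub)),
    subdiagnostic = c(rep(FALSE, n), rep(TRUE, n_sub)),
    stringsAsFactors = FALSE)

  structure(list(spec = spec, truth = truth, readings = readings,
                 consensus = consensus, n_subdiagnostic = n_sub),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(paste0("synthetic cohort: %d patients (%d positive), ",
                     "%d reading records, %d subdiagnostic DTS, seed %d\n"),
              nrow(x$truth), sum(x$truth$positive), nrow(x$readings),
              x$n_subdiagnostic, x$spec$seed))
  invisible(x)
}
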