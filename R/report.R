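# Orchestration: run accuracy -> triage -> costing on a cohort plus a cost
# configuration and bundle the results with a run manifest.

#' Run the full accuracy, triage and costing pipeline
#'
#' Computes, for each reader and modality, the confusion counts, performance
#' metrics and ROC area; compares the two modalities per reader
#' (correlated-AUC z, McNemar on sensitivity/specificity, Yates chi-square
#' on accuracy, paired interpretation-time test); computes inter-reader
#' weighted kappa per modality; triages the cohort on consensus DTS scores;
#' and prices the before/after utilisation scenarios of the configuration,
#' with differential savings and break-even.
#'
#' @param cohort a `cohort` from [generate_cohort()], or a list with
#'   elements `truth`, `readings`, `consensus` assembled from files read via
#'   [read_readings()] and [read_truth()].
#' @param config a `cost_config`, default [study_cost_config()].
#' @param score3 indeterminate-score policy passed to [classify()].
#' @param count_followup_cxr passed to [tally_utilisation()].
#' @return a list of class `triage_report` with elements `accuracy`,
#'   `comparisons`, `agreement`, `decisions`, `ct_fraction`, `utilisation`,
#'   `costs`, `breakeven`, `manifest`.
#' @export
run_full <- function(cohort, config = study_cost_config(),
                     score3 = "penalise", count_followup_cxr = FALSE) {
  stopifnot(is.list(cohort),
            all(c("truth", "readings", "consensus") %in% names(cohort)))
  truth <- if ("positive" %in% names(cohort$truth)) cohort$truth else
    map_truth(cohort$truth)
  rd <- cohort$readings
  readers <- sort(unique(rd$reader_id))

  get <- function(mod, r) rd[rd$modality == mod & rd$reader_id == r, ]
  ord <- function(df) df[order(df$patient_id), ]

  accuracy <- list()
  comparisons <- list()
  for (r in readers) {
    per_mod <- list()
    for (mod in intersect(MODALITIES, unique(rd$modality))) {
      recs <- get(mod, r)
      cc <- classify(recs, truth, score3 = score3)
      pos <- truth$positive[match(recs$patient_id, truth$patient_id)]
      per_mod[[mod]] <- list(
        confusion = cc,
        metrics = confusion_metrics(cc),
        auc = auc_ordinal(recs$score, pos)
      )
    }
    accuracy[[r]] <- per_mod
    if (all(MODALITIES %in% names(per_mod))) {
      cxr <- ord(get("CXR", r))
      dts <- ord(get("DTS", r))
      stopifnot(identical(cxr$patient_id, dts$patient_id))
      pos <- truth$positive[match(cxr$patient_id, truth$patient_id)]
      correct <- function(s) ifelse(pos, s >= 4, s <= 2)
      comparisons[[r]] <- list(
        auc = auc_compare_correlated(dts$score, cxr$score, pos),
        mcnemar_sensitivity = mcnemar_paired(correct(dts$score)[pos],
                                             correct(cxr$score)[pos]),
        mcnemar_specificity = mcnemar_paired(correct(dts$score)[!pos],
                                             correct(cxr$score)[!pos]),
        accuracy_chisq = accuracy_chisq(
          sum(correct(dts$score)), sum(!correct(dts$score)),
          sum(correct(cxr$score)), sum(!correct(cxr$score))),
        times = compare_times(dts$interpretation_time_s,
                              cxr$interpretation_time_s)
      )
    }
  }

  agreement <- list()
  if (length(readers) >= 2) {
    for (mod in intersect(MODALITIES, unique(rd$modality))) {
      a <- ord(get(mod, readers[1]))
      b <- ord(get(mod, readers[2]))
      if (identical(a$patient_id, b$patient_id) && nrow(a) >= 2) {
        agreement[[mod]] <- kappa_weighted(a$score, b$score)
      }
    }
  }

  decisions <- triage(cohort$consensus)
  tally <- tally_utilisation(decisions, count_followup_cxr = count_followup_cxr)

  costs <- NULL
  breakeven <- NULL
  if (!is.null(config$unit_costs) && !is.null(config$utilisation)) {
    uc <- config$unit_costs
    costs <- list()
    for (variant in c("unenhanced", "contrast_enhanced")) {
      ct_key <- if (variant == "unenhanced") "ct_unenhanced" else "ct_contrast"
      if (is.null(uc[[ct_key]])) next
      table_uc <- list(cxr = uc$cxr, dts = uc$dts, ct = uc[[ct_key]])
      before <- scenario("before", config$utilisation$before, table_uc, variant)
      after <- scenario("after", config$utilisation$after, table_uc, variant)
      costs[[variant]] <- list(
        annual_cost_before = scenario_cost(before),
        annual_cost_after = scenario_cost(after),
        annual_saving = differential_saving(before, after))
    }
  }
  if (!is.null(config$breakeven)) {
    b <- config$breakeven
    breakeven <- list(
      examinations = break_even(b$fixed_cost, b$reimbursement,
                                b$variable_unit_cost %||% 0),
      inputs = b)
  }

  manifest <- list(
    package = "triagecost",
    version = as.character(utils::packageVersion("triagecost")),
    seed = if (inherits(cohort, "cohort")) cohort$spec$seed else NA_integer_,
    n_patients = nrow(truth),
    n_readings = nrow(rd),
    score3 = score3,
    timestamp = format(Sys.time(), tz = "UTC")
  )

  structure(list(accuracy = accuracy, comparisons = comparisons,
                 agreement = agreement, decisions = decisions,
                 ct_fraction = ct_fraction(decisions),
                 utilisation = tally, costs = costs, breakeven = breakeven,
                 manifest = manifest),
            class = "triage_report")
}

#' Write a pipeline report to JSON
#'
#' Serialises a [run_full()] report (minus the patient-level decision table,
#' written alongside as CSV when `decisions_csv` is given) to pretty JSON.
#' Reports from identical inputs are byte-identical apart from the manifest
#' timestamp.
#'
#' @param report a `triage_report`.
#' @param path output JSON path.
#' @param decisions_csv optional path for the triage-decision table.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, decisions_csv = NULL) {
  stopifnot(inherits(report, "triage_report"))
  out <- report
  out$decisions <- NULL
  class(out) <- NULL
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  if (!is.null(decisions_csv)) {
    utils::write.csv(report$decisions, decisions_csv, row.names = FALSE,
                     na = "")
  }
  invisible(path)
}
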