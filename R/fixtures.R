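# Published aggregate inputs of the two-reader CXR/DTS reading study used as
# the package's worked example: reference-standard category counts, per
# reader/modality confusion counts, annual utilisation, cost tables, and
# break-even inputs. These are inputs to the pipeline (printed tables), not
# outputs; everything downstream of them is recomputed.

#' Aggregate fixtures of the reference reading study
#'
#' In-memory aggregates from a single-centre 465-patient study of DTS after
#' equivocal CXR: the lesion-category counts of the reference standard, each
#' reader's confusion counts per modality, the annual utilisation before
#' (CT-only work-up, 271 CTs) and after (91 CXR, 130 + 7 subdiagnostic DTS,
#' 39 CT) DTS implementation, the component unit costs per modality, asset
#' price/depreciation/maintenance with practical capacity hours and mean
#' occupation times, the break-even inputs, the consensus triage tallies
#' (127 of 465 to CT), and the interpretation-time summaries.
#'
#' @return a named list of fixtures: `truth_counts`, `confusion`,
#'   `utilisation_before`, `utilisation_after`, `unit_costs`, `assets`,
#'   `capacity_hours`, `occupation_min`, `breakeven`, `ct_triage`, `times`.
#' @export
study_fixture <- function() {
  list(
    truth_counts = c(pulmonary_opacity = 60, primary_lung_neoplasm = 5,
                     ground_glass = 47, noncalcified_solid_nodule = 32,
                     pulmonary_scar = 26, calcified_solid_nodule = 23,
                     pleural_plaque = 36, pseudolesion = 236),
    confusion = list(
      r1 = list(CXR = confusion_counts(tp = 34, tn = 33, fp = 288, fn = 110),
                DTS = confusion_counts(tp = 116, tn = 308, fp = 13, fn = 28)),
      r2 = list(CXR = confusion_counts(tp = 25, tn = 43, fp = 278, fn = 119),
                DTS = confusion_counts(tp = 122, tn = 308, fp = 13, fn = 22))
    ),
    utilisation_before = utilisation(ct = 271),
    utilisation_after = utilisation(cxr = 91, dts = 130,
                                    dts_subdiagnostic = 7, ct = 39),
    unit_costs = list(
      cxr = unit_cost(medical = 11.65, radiographer = 3.05,
                      depreciation = 0.45),
      dts = unit_cost(medical = 23.04, radiographer = 7.92,
                      depreciation = 10.59),
      ct_unenhanced = unit_cost(medical = 31.95, radiographer = 7.07,
                                nursing = 6.98, depreciation = 19.35),
      ct_contrast = unit_cost(contrast = 25.83, medical = 46.24,
                              radiographer = 11.19, nursing = 11.05,
                              depreciation = 19.35)
    ),
    assets = list(
      dts = list(price = 30000, useful_life_years = 10,
                 annual_maintenance = 10000, capacity_hours_per_year = 2600,
                 printed_annual_depreciation = 3750),
      ct = list(price = 1242000, useful_life_years = 10,
                annual_maintenance = 105996, capacity_hours_per_year = 3030,
                printed_annual_depreciation = 155250)
    ),
    capacity_hours = list(cxr = 2600, dts = 2600, ct = 3030),
    occupation_min = list(cxr = 6, dts = 13, ct_unenhanced = 15,
                          ct_contrast = 19),
    breakeven = list(fixed_cost = 30000, reimbursement = 62.7,
                     variable_unit_cost = 0),
    ct_triage = c(ct = 127, followup = 338),
    times = list(CXR = c(mean = 66, sd = 23), DTS = c(mean = 103, sd = 66))
  )
}

#' Cost configuration built from the study fixtures
#'
#' The "authoritative mode" configuration: unit-cost components, utilisation
#' and break-even inputs carried directly from the printed cost tables.
#'
#' @return a `cost_config` list as from [read_cost_config()].
#' @export
study_cost_config <- function() {
  fx <- study_fixture()
  structure(list(unit_costs = fx$unit_costs,
                 utilisation = list(before = fx$utilisation_before,
                                    after = fx$utilisation_after),
                 assets = fx$assets,
                 capacity_hours = fx$capacity_hours,
                 occupation_min = fx$occupation_min,
                 breakeven = fx$breakeven),
            class = "cost_config")
}

#' Reconstruct patient-level records consistent with confusion counts
#'
#' Expands aggregate confusion counts into a minimal patient-level reading
#' and truth table that the classification rule maps back onto the same
#' counts: true positives are scored 4, false negatives 2, true negatives 1
#' and false positives 4. Within a confusion cell the exact score does not
#' affect any count-based metric, so this synthetic expansion reproduces
#' sensitivity, specificity, accuracy and the predictive values exactly.
#'
#' @param cc a [confusion_counts()] object.
#' @param modality modality label for the records, default `"DTS"`.
#' @param reader_id reader label, default `"r1"`.
#' @return list with `records` and `truth` data frames suitable for
#'   [classify()].
#' @export
confusion_to_records <- function(cc, modality = "DTS", reader_id = "r1") {
  stopifnot(inherits(cc, "confusion_counts"))
  score <- c(rep(4L, cc$tp), rep(2L, cc$fn), rep(1L, cc$tn), rep(4L, cc$fp))
  positive <- c(rep(TRUE, cc$tp + cc$fn), rep(FALSE, cc$tn + cc$fp))
  ids <- sprintf("p%05d", seq_along(score))
  list(records = data.frame(patient_id = ids, modality = modality,
                            reader_id = reader_id, score = score,
                            interpretation_time_s = NA_real_,
                            stringsAsFactors = FALSE),
       truth = data.frame(patient_id = ids, positive = positive,
                          stringsAsFactors = FALSE))
}
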