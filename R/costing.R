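# Activity-based costing: per-examination full costs assembled from
# components, annual scenario costs, differential savings, and
# contribution-margin break-even. All sums run on integer cents so chained
# arithmetic (e.g. 271 examinations at 65.35) is exact.

#' Straight-line annual depreciation of an asset
#'
#' @param price historical cost of the equipment (currency).
#' @param useful_life_years depreciation period in whole years; ten years is
#'   the conventional life for radiological equipment, covering both
#'   technological obsolescence and clinical effectiveness.
#' @return annual depreciation, `price / useful_life_years`.
#' @export
annual_depreciation <- function(price, useful_life_years) {
  stopifnot(is.numeric(price), price >= 0)
  if (!is.numeric(useful_life_years) || useful_life_years <= 0) {
    stop("useful_life_years must be positive")
  }
  price / useful_life_years
}

#' Allocate an annual capacity cost to one examination
#'
#' Capacity costs (personnel, depreciation, maintenance) are related to
#' individual examinations through the mean occupation time: an examination
#' occupying `occupation_min` minutes of a unit with `capacity_hours` hours
#' of practical capacity per year carries
#' `annual_cost / (capacity_hours * 60) * occupation_min`.
#'
#' @param annual_cost annual cost of the capacity resource (currency/year).
#' @param capacity_hours practical capacity in hours per year (e.g. 2600 for
#'   a radiography unit, 3030 for CT).
#' @param occupation_min mean examination occupation time in minutes.
#' @return cost allocated to one examination.
#' @export
allocate_capacity_cost <- function(annual_cost, capacity_hours, occupation_min) {
  stopifnot(is.numeric(annual_cost), annual_cost >= 0,
            is.numeric(occupation_min), occupation_min >= 0)
  if (!is.numeric(capacity_hours) || capacity_hours <= 0) {
    stop("capacity_hours must be positive")
  }
  annual_cost / (capacity_hours * 60) * occupation_min
}

#' Per-examination full cost from components
#'
#' The unit full cost of an imaging examination is the exact cent-level sum
#' of contrast agent, medical personnel, radiographer, nursing and allocated
#' asset-depreciation components.
#'
#' @param contrast,medical,radiographer,nursing,depreciation nonnegative
#'   component costs (currency).
#' @return object of class `unit_cost` with the five components and `total`.
#' @examples
#' unit_cost(medical = 11.65, radiographer = 3.05, depreciation = 0.45)$total
#' @export
unit_cost <- function(contrast = 0, medical = 0, radiographer = 0,
                      nursing = 0, depreciation = 0) {
  comp <- c(contrast = contrast, medical = medical,
            radiographer = radiographer, nursing = nursing,
            depreciation = depreciation)
  if (any(comp < 0)) stop("unit-cost components must be nonnegative")
  comp_cents <- setNames(cents(comp), names(comp))
  structure(c(as.list(setNames(euros(comp_cents), names(comp))),
              list(total = euros(sum(comp_cents)))),
            class = "unit_cost")
}

#' @export
print.unit_cost <- function(x, ...) {
  cat(sprintf(paste0("unit full cost %.2f (contrast %.2f, medical %.2f, ",
                     "radiographer %.2f, nursing %.2f, depreciation %.2f)\n"),
              x$total, x$contrast, x$medical, x$radiographer, x$nursing,
              x$depreciation))
  invisible(x)
}

#' Annual cost scenario
#'
#' Couples a [utilisation()] with a unit-cost table. `unit_costs` must name
#' `cxr`, `dts` and/or `ct` for every utilised modality; subdiagnostic DTS
#' examinations are costed at the DTS unit cost.
#'
#' @param label scenario name.
#' @param utilisation a [utilisation()] object.
#' @param unit_costs named list of [unit_cost()] objects (`cxr`, `dts`, `ct`).
#' @param ct_variant `"unenhanced"` or `"contrast_enhanced"`, recorded so
#'   that only like scenarios are differenced.
#' @return object of class `scenario`.
#' @export
scenario <- function(label, utilisation, unit_costs,
                     ct_variant = c("unenhanced", "contrast_enhanced")) {
  ct_variant <- match.arg(ct_variant)
  stopifnot(inherits(utilisation, "utilisation"), is.list(unit_costs))
  used <- c(cxr = utilisation$cxr > 0,
            dts = utilisation$dts + utilisation$dts_subdiagnostic > 0,
            ct = utilisation$ct > 0)
  absent <- setdiff(names(used)[used], names(unit_costs))
  if (length(absent) > 0) {
    stop("no unit cost for utilised modality: ", paste(absent, collapse = ", "))
  }
  structure(list(label = label, utilisation = utilisation,
                 unit_costs = unit_costs, ct_variant = ct_variant),
            class = "scenario")
}

scenario_cost_cents <- function(s) {
  u <- s$utilisation
  total_cents <- function(m) if (is.null(s$unit_costs[[m]])) 0L else cents(s$unit_costs[[m]]$total)
  u$cxr * total_cents("cxr") +
    (u$dts + u$dts_subdiagnostic) * total_cents("dts") +
    u$ct * total_cents("ct")
}

#' Total annual cost of a scenario
#'
#' Sum over modalities of examination count times unit full cost, exact in
#' cents.
#'
#' @param s a [scenario()].
#' @return annual cost (currency).
#' @export
scenario_cost <- function(s) {
  stopifnot(inherits(s, "scenario"))
  euros(scenario_cost_cents(s))
}

#' Differential annual saving between two scenarios
#'
#' `scenario_cost(before) - scenario_cost(after)`; negative when the new
#' pathway costs more. Scenarios must share the CT variant.
#'
#' @param before,after [scenario()] objects for the same period length.
#' @return annual saving (currency), exact in cents.
#' @export
differential_saving <- function(before, after) {
  stopifnot(inherits(before, "scenario"), inherits(after, "scenario"))
  if (before$ct_variant != after$ct_variant) {
    stop("scenarios use different CT variants: ", before$ct_variant, " vs ",
         after$ct_variant)
  }
  euros(scenario_cost_cents(before) - scenario_cost_cents(after))
}

#' Break-even examination count for a capacity investment
#'
#' The break-even point is fixed (capacity) cost divided by the unit
#' contribution margin (reimbursement rate minus variable unit cost),
#' rounded up to a whole examination: the smallest integer `n` with
#' `n * margin >= fixed_cost`. With a zero variable cost this is
#' `fixed_cost / reimbursement_rate`, rounded up.
#'
#' @param fixed_cost the capacity cost to recover (currency).
#' @param reimbursement_rate reimbursement per examination (currency).
#' @param variable_unit_cost variable cost per examination, default 0.
#' @return integer number of examinations.
#' @examples
#' break_even(30000, 62.7) # 478.47 -> 479
#' @export
break_even <- function(fixed_cost, reimbursement_rate, variable_unit_cost = 0) {
  stopifnot(is.numeric(fixed_cost), fixed_cost >= 0)
  margin <- cents(reimbursement_rate) - cents(variable_unit_cost)
  if (margin <= 0) {
    stop("contribution margin is not positive: the investment never breaks even")
  }
  fixed <- cents(fixed_cost)
  if (fixed == 0) return(0L)
  as.integer((fixed + margin - 1L) %/% margin)
}
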