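# Score-driven triage: consensus DTS scores 1-2 send the patient to
# radiographic follow-up, 3-5 to CT within a week; utilisation tallies feed
# the costing module.

#' Route patients by consensus confidence score
#'
#' Scores 1-2 (definite/probable benign or pseudolesion) route to CXR
#' follow-up at about six months; scores 3-5 (indeterminate through definite
#' pulmonary lesion) route to CT within one week. Patients with a
#' subdiagnostic DTS examination (no usable score) are routed per
#' `subdiagnostic_route`; the default sends them to CT because unresolved
#' suspicion cannot be dismissed.
#'
#' @param consensus data frame with `patient_id`, `score` and optionally a
#'   logical `subdiagnostic` column (scores may be `NA` only on
#'   subdiagnostic rows).
#' @param subdiagnostic_route route for subdiagnostic patients,
#'   `"ct_within_1_week"` (default) or `"cxr_followup"`.
#' @return data frame of triage decisions: `patient_id`, `route`,
#'   `deciding_score`, `subdiagnostic`.
#' @export
triage <- function(consensus,
                   subdiagnostic_route = c("ct_within_1_week", "cxr_followup")) {
  subdiagnostic_route <- match.arg(subdiagnostic_route)
  stopifnot(is.data.frame(consensus),
            all(c("patient_id", "score") %in% names(consensus)))
  sub <- consensus$subdiagnostic %||% rep(FALSE, nrow(consensus))
  sub[is.na(sub)] <- FALSE
  s <- consensus$score
  if (any(is.na(s) & !sub)) {
    stop("missing consensus score for non-subdiagnostic patient(s): ",
         paste(consensus$patient_id[is.na(s) & !sub], collapse = ", "))
  }
  if (any(!is.na(s) & !(s %in% 1:5))) stop("scores must be in 1-5")
  route <- ifelse(sub, subdiagnostic_route,
                  ifelse(s <= 2, "cxr_followup", "ct_within_1_week"))
  data.frame(patient_id = consensus$patient_id, route = route,
             deciding_score = ifelse(sub, NA_integer_, as.integer(s)),
             subdiagnostic = sub, stringsAsFactors = FALSE)
}

#' Proportion of triaged patients routed to CT
#'
#' @param decisions a triage-decision data frame from [triage()].
#' @return exact proportion in `[0, 1]`; multiply by 100 and round for the
#'   conventional integer-percent report.
#' @export
ct_fraction <- function(decisions) {
  if (nrow(decisions) == 0) stop("no triage decisions")
  mean(decisions$route == "ct_within_1_week")
}

#' Annual modality utilisation
#'
#' @param cxr,dts,dts_subdiagnostic,ct nonnegative examination counts per
#'   period. Subdiagnostic DTS examinations carry the DTS cost but no
#'   diagnostic yield and are tallied separately.
#' @return object of class `utilisation`.
#' @export
utilisation <- function(cxr = 0, dts = 0, dts_subdiagnostic = 0, ct = 0) {
  x <- c(cxr = cxr, dts = dts, dts_subdiagnostic = dts_subdiagnostic, ct = ct)
  if (any(x < 0) || any(x != round(x))) {
    stop("utilisation counts must be nonnegative integers")
  }
  structure(as.list(setNames(as.integer(x), names(x))),
            class = "utilisation")
}

#' @export
print.utilisation <- function(x, ...) {
  cat(sprintf("utilisation: %d CXR, %d DTS (+%d subdiagnostic), %d CT\n",
              x$cxr, x$dts, x$dts_subdiagnostic, x$ct))
  invisible(x)
}

#' Tally examination utilisation implied by triage decisions
#'
#' Every triaged patient received one DTS examination (subdiagnostic ones
#' tallied separately); CT-routed patients add one CT each. The follow-up
#' CXR of the benign route is an examination in a later period and is only
#' counted when `count_followup_cxr = TRUE`.
#'
#' @param decisions a triage-decision data frame from [triage()].
#' @param count_followup_cxr count one follow-up CXR per `cxr_followup`
#'   route, default `FALSE`.
#' @return a [utilisation()] object.
#' @export
tally_utilisation <- function(decisions, count_followup_cxr = FALSE) {
  ct <- sum(decisions$route == "ct_within_1_week")
  followup <- sum(decisions$route == "cxr_followup")
  utilisation(cxr = if (count_followup_cxr) followup else 0,
              dts = sum(!decisions$subdiagnostic),
              dts_subdiagnostic = sum(decisions$subdiagnostic),
              ct = ct)
}
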