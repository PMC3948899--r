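# Readers/writers for the three plain-text inputs: per-reading score tables,
# per-patient truth tables, and the cost configuration.

MODALITIES <- c("CXR", "DTS")

#' Read a table of per-patient reading records
#'
#' Each row is one reader's ordinal confidence score (1-5) for one patient on
#' one modality, with an optional interpretation time in seconds. Scores 1-2
#' mean definite/probable benign or pseudolesion, 3 indeterminate, 4-5
#' probable/definite pulmonary lesion.
#'
#' @param path path to a delimited text file with header columns
#'   `patient_id,modality,reader_id,score` and optionally
#'   `interpretation_time_s`.
#' @param delim field delimiter, default comma.
#' @return a data frame with the five columns above (missing times are `NA`),
#'   row order preserved.
#' @details Validation errors name the offending rows: scores outside
#'   `{1,...,5}`, modalities outside `{CXR, DTS}`, negative times, and
#'   duplicated `(patient_id, modality, reader_id)` keys are all rejected.
#' @seealso [write_readings()], [read_truth()]
#' @export
read_readings <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character",
                                       reader_id = "character"))
  required <- c("patient_id", "modality", "reader_id", "score")
  absent <- setdiff(required, names(df))
  if (length(absent) > 0) {
    stop("readings file lacks column(s): ", paste(absent, collapse = ", "))
  }
  if (!"interpretation_time_s" %in% names(df)) {
    df$interpretation_time_s <- NA_real_
  }
  df <- df[c(required, "interpretation_time_s")]
  df$interpretation_time_s <- as.numeric(df$interpretation_time_s)
  validate_readings(df)
}

validate_readings <- function(df) {
  bad <- which(!(df$score %in% 1:5))
  if (length(bad) > 0) {
    stop("score outside 1-5 at row(s): ", paste(bad, collapse = ", "))
  }
  df$score <- as.integer(df$score)
  bad <- which(!(df$modality %in% MODALITIES))
  if (length(bad) > 0) {
    stop("unknown modality at row(s): ", paste(bad, collapse = ", "))
  }
  bad <- which(!is.na(df$interpretation_time_s) & df$interpretation_time_s < 0)
  if (length(bad) > 0) {
    stop("negative interpretation time at row(s): ", paste(bad, collapse = ", "))
  }
  key <- paste(df$patient_id, df$modality, df$reader_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (patient_id, modality, reader_id) at row(s): ",
         paste(dup, collapse = ", "))
  }
  rownames(df) <- NULL
  df
}

#' @rdname read_readings
#' @param df a reading-record data frame.
#' @export
write_readings <- function(df, path) {
  df <- validate_readings(df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-patient truth table
#'
#' @param path path to a delimited file with header columns
#'   `patient_id,category` and optionally `size_cm`.
#' @param delim field delimiter, default comma.
#' @return data frame with columns `patient_id`, `category`, `size_cm` and the
#'   derived logical `positive` column (see [map_truth()]); exactly one row
#'   per patient.
#' @export
read_truth <- function(path, delim = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, sep = delim, stringsAsFactors = FALSE,
                        colClasses = c(patient_id = "character"))
  absent <- setdiff(c("patient_id", "category"), names(df))
  if (length(absent) > 0) {
    stop("truth file lacks column(s): ", paste(absent, collapse = ", "))
  }
  if (!"size_cm" %in% names(df)) df$size_cm <- NA_real_
  df$size_cm <- as.numeric(df$size_cm)
  if (any(!is.na(df$size_cm) & df$size_cm <= 0)) {
    stop("size_cm must be positive where given")
  }
  dup <- which(duplicated(df$patient_id))
  if (length(dup) > 0) {
    stop("duplicate patient_id at row(s): ", paste(dup, collapse = ", "))
  }
  map_truth(df[c("patient_id", "category", "size_cm")])
}

#' Read a cost configuration file
#'
#' Parses a YAML (or JSON) cost configuration with keys
#' `unit_costs.{cxr,dts,ct_unenhanced,ct_contrast}` (component costs per
#' examination), `utilisation.{before,after}` (annual examination counts),
#' `breakeven` (`fixed_cost`, `reimbursement`, `variable_unit_cost`), and
#' optionally `assets`, `capacity_hours`, `occupation_min`,
#' `personnel_rates`, `reimbursement`. Numeric fields written with a decimal
#' comma ("41,55") are normalised to R numbers.
#'
#' @param path path to the configuration file.
#' @return a list of class `cost_config`: `unit_costs` holds [unit_cost()]
#'   objects, `utilisation` holds [utilisation()] objects, other sections are
#'   numeric lists.
#' @export
read_cost_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  as_cost_config(raw)
}

as_cost_config <- function(raw) {
  raw <- rapply(raw, parse_number_eu, classes = "character", how = "replace")
  cfg <- list()
  if (!is.null(raw$unit_costs)) {
    cfg$unit_costs <- lapply(raw$unit_costs, function(u) {
      unit_cost(contrast = u$contrast %||% 0,
                medical = u$medical %||% 0,
                radiographer = u$radiographer %||% 0,
                nursing = u$nursing %||% 0,
                depreciation = u$depreciation %||% 0)
    })
  }
  if (!is.null(raw$utilisation)) {
    cfg$utilisation <- lapply(raw$utilisation, function(u) {
      utilisation(cxr = u$cxr %||% 0, dts = u$dts %||% 0,
                  dts_subdiagnostic = u$dts_subdiagnostic %||% 0,
                  ct = u$ct %||% 0)
    })
  }
  if (!is.null(raw$assets)) {
    for (a in raw$assets) {
      if (!is.null(a$useful_life_years) && a$useful_life_years <= 0) {
        stop("useful_life_years must be positive")
      }
      if (!is.null(a$capacity_hours_per_year) && a$capacity_hours_per_year <= 0) {
        stop("capacity_hours_per_year must be positive")
      }
      neg <- vapply(a[c("price", "annual_maintenance")], function(v) {
        !is.null(v) && v < 0
      }, logical(1))
      if (any(neg)) stop("asset costs must be nonnegative")
    }
    cfg$assets <- raw$assets
  }
  for (k in c("breakeven", "capacity_hours", "occupation_min",
              "personnel_rates", "reimbursement", "variable_costs")) {
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  }
  if (!is.null(cfg$breakeven)) {
    b <- cfg$breakeven
    if (any(unlist(b) < 0)) stop("breakeven costs must be nonnegative")
  }
  structure(cfg, class = "cost_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
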