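# Currency is held as integer cents wherever sums must be exact; euro values
# cross this boundary only through cents()/euros().

cents <- function(x) {
  stopifnot(is.numeric(x), all(is.finite(x)))
  as.integer(round(x * 100))
}

euros <- function(c) as.numeric(c) / 100

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used at report boundaries, where base R's
#' `round()` rounds half to even. `round_half_up(0.5)` is 1, `round(0.5)` is 0.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @examples
#' round_half_up(c(2.5, 3.345), c(0, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# Parse numbers written with a decimal comma ("41,55") alongside plain R
# numbers. A comma followed by one or two digits is a decimal separator; a
# comma followed by exactly three digits is a thousands separator ("30,000").
# Dots are thousands separators only when a decimal comma is present.
parse_number_eu <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  s <- trimws(as.character(x))
  out <- vapply(s, function(v) {
    if (grepl(",", v, fixed = TRUE)) {
      if (grepl(",[0-9]{1,2}$", v)) {
        v <- gsub(".", "", v, fixed = TRUE)
        v <- gsub(",(?=[0-9]{3}(,|$))", "", v, perl = TRUE) # interior groups
        v <- sub(",", ".", v, fixed = TRUE)
      } else {
        v <- gsub(",", "", v, fixed = TRUE)
      }
    }
    suppressWarnings(as.numeric(v))
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(out) && !anyNA(s)) {
    stop("cannot parse as number: ", paste(s[is.na(out)], collapse = ", "))
  }
  out
}
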