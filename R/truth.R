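#' Lesion categories of the reference-standard taxonomy
#'
#' The eight radiographic patterns used to label each patient's marker lesion.
#' The first four are non-calcified pulmonary lesions that warrant CT
#' characterisation ("positive"); the remaining four are overt benign,
#' extra-pulmonary, or pseudolesion patterns that do not ("negative").
#'
#' @return character vector of the eight category names, positives first.
#' @seealso [map_truth()]
#' @export
lesion_categories <- function() {
  c(positive_categories(), negative_categories())
}

#' @rdname lesion_categories
#' @export
positive_categories <- function() {
  c("pulmonary_opacity", "primary_lung_neoplasm", "ground_glass",
    "noncalcified_solid_nodule")
}

#' @rdname lesion_categories
#' @export
negative_categories <- function() {
  c("pulmonary_scar", "calcified_solid_nodule", "pleural_plaque",
    "pseudolesion")
}

#' Map lesion categories to the binary CT-deserving truth state
#'
#' A patient is "positive" when the marker lesion is a non-calcified pulmonary
#' lesion deserving CT characterisation (pulmonary opacity, primary lung
#' neoplasm, ground-glass opacity/nodule, or non-calcified solid nodule);
#' calcified lesions, scars, pleural plaques and pseudolesions are negative.
#' The mapping is total and deterministic over the category enum.
#'
#' @param x a character vector of categories, or a truth data frame with
#'   columns `patient_id` and `category` (as returned by [read_truth()]).
#' @return for a character vector, a logical vector; for a data frame, the
#'   same data frame with a logical `positive` column appended.
#' @examples
#' map_truth(c("pseudolesion", "ground_glass"))
#' @export
map_truth <- function(x) {
  if (is.data.frame(x)) {
    x$positive <- map_truth(x$category)
    return(x)
  }
  x <- as.character(x)
  unknown <- setdiff(unique(x), lesion_categories())
  if (length(unknown) > 0) {
    stop("unknown lesion category: ", paste(unknown, collapse = ", "))
  }
  x %in% positive_categories()
}
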