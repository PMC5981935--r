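#' Outcome categories of an eConsult submission
#'
#' The closed set of seven outcome categories used throughout the cost
#' model, in fixed reporting order: two administrative outcomes (change of
#' details/other, fit note), two GP outcomes with no patient recall (no
#' further action, prescription), and three patient-recall outcomes (other
#' appointment such as bloods or nurse, GP phone back, GP face-to-face
#' appointment).
#'
#' @return Character vector of the seven category identifiers.
#' @export
#' @examples
#' econsult_categories()
econsult_categories <- function() {
  c("admin_other_details", "admin_fit_note", "gp_no_action",
    "gp_prescription", "other_appointment", "gp_phone_back",
    "gp_appointment")
}

#' Human-readable labels for the outcome categories
#'
#' @return Named character vector mapping category identifiers to display
#'   labels, in reporting order.
#' @export
category_labels <- function() {
  c(admin_other_details = "Admin: change of details & other",
    admin_fit_note      = "Admin: fit note",
    gp_no_action        = "GP: no action (e.g. follow-up)",
    gp_prescription     = "GP: prescription",
    other_appointment   = "Other appointment (e.g. bloods)",
    gp_phone_back       = "GP phone back",
    gp_appointment      = "GP appointment")
}

#' Construct a category mix
#'
#' A category mix is a probability distribution over the seven outcome
#' categories: the model's weighting vector.  Probabilities must be
#' non-negative and sum to 1 within `1e-9`.
#'
#' @param probs named numeric vector with one probability per category in
#'   [econsult_categories()] (any order; reordered internally).
#' @return A named numeric vector of class `"category_mix"` in canonical
#'   category order.
#' @export
#' @examples
#' category_mix(c(admin_other_details = 0.5, admin_fit_note = 0.5,
#'                gp_no_action = 0, gp_prescription = 0,
#'                other_appointment = 0, gp_phone_back = 0,
#'                gp_appointment = 0))
category_mix <- function(probs) {
  cats <- econsult_categories()
  check_that(is.numeric(probs) && !is.null(names(probs)),
             "'probs' must be a named numeric vector")
  check_that(setequal(names(probs), cats) && length(probs) == length(cats),
             paste("'probs' must have exactly one entry per category:",
                   paste(cats, collapse = ", ")))
  probs <- probs[cats]
  check_that(all(is.finite(probs)) && all(probs >= 0),
             "mix probabilities must be finite and non-negative")
  check_that(abs(sum(probs) - 1) <= 1e-9,
             sprintf("mix probabilities must sum to 1 (got %.12f)",
                     sum(probs)))
  structure(probs, class = "category_mix")
}

#' Default category mix observed in the pilot
#'
#' The estimated share of submissions falling in each outcome category:
#' 12/15/10/20/13/15/15 percent across the seven categories.
#'
#' @return A `"category_mix"` object.
#' @export
default_category_mix <- function() {
  category_mix(c(admin_other_details = 0.12,
                 admin_fit_note      = 0.15,
                 gp_no_action        = 0.10,
                 gp_prescription     = 0.20,
                 other_appointment   = 0.13,
                 gp_phone_back       = 0.15,
                 gp_appointment      = 0.15))
}

#' Point-mass category mix
#'
#' Convenience constructor for a degenerate mix placing all probability on
#' one category.
#'
#' @param category one of [econsult_categories()].
#' @return A `"category_mix"` object.
#' @export
point_mass_mix <- function(category) {
  cats <- econsult_categories()
  check_that(is.character(category) && length(category) == 1 &&
               category %in% cats, "unknown category")
  probs <- stats::setNames(as.numeric(cats == category), cats)
  category_mix(probs)
}
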