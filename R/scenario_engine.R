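#' Categories counted as replacing a conventional appointment
#'
#' The default saved-category set: fit note, GP no action, GP
#' prescription, other appointment (e.g. bloods) and GP phone back — every
#' category except the pure administrative change-of-details outcome and
#' the outcome that itself generates a face-to-face GP appointment.  Phone
#' back is included because the face-to-face appointment is avoided; the
#' GP's phone time is already charged on the cost side as follow-up
#' consultation time.
#'
#' @return Character vector of category identifiers.
#' @export
default_saved_categories <- function() {
  c("admin_fit_note", "gp_no_action", "gp_prescription",
    "other_appointment", "gp_phone_back")
}

#' Fraction of eConsults that replace a conventional appointment
#'
#' Sums the category-mix probabilities over the saved-category set.  Under
#' the pilot's base mix this is 73% of submissions.
#'
#' @param mix a [category_mix()].
#' @param saved subset of [econsult_categories()] counted as replacing a
#'   conventional appointment.
#' @return Fraction in [0, 1].
#' @export
#' @examples
#' appointments_saved(default_category_mix())  # 0.73
appointments_saved <- function(mix, saved = default_saved_categories()) {
  if (!inherits(mix, "category_mix")) mix <- category_mix(mix)
  check_that(is.character(saved) && all(saved %in% econsult_categories()),
             "'saved' must be a subset of econsult_categories()")
  sum(as.numeric(mix)[econsult_categories() %in% saved])
}

#' Adjust the saved fraction for induced demand
#'
#' Some submissions come from patients who would not otherwise have
#' contacted the practice (8% in the English pilot); these save no
#' appointment.  The minimum saved fraction is
#' `s_raw * (1 - induced_fraction)`, e.g. 73% x 92% = 67%.
#'
#' @param s_raw raw saved fraction in [0, 1].
#' @param induced_fraction fraction of submissions that are induced
#'   demand, in [0, 1] (default 0.08).
#' @return Adjusted fraction in [0, 1] (full precision; round at
#'   presentation with [round_half_away()]).
#' @export
#' @examples
#' round_half_away(100 * adjust_for_induced_demand(0.73), 0)  # 67
adjust_for_induced_demand <- function(s_raw, induced_fraction = 0.08) {
  check_fraction(s_raw, "s_raw")
  check_fraction(induced_fraction, "induced_fraction")
  s_raw * (1 - induced_fraction)
}

#' Load scenario category mixes
#'
#' Scenario mixes are data, not code: the packaged file
#' (`inst/extdata/scenarios.csv`) carries the base mix and the four
#' directed-marketing scenarios, each with the admin and patient-recall
#' shares declared in the published scenario table headers.  Users can
#' supply their own file with the same columns to add scenarios.
#'
#' @param path CSV with columns `scenario`, one column per category in
#'   [econsult_categories()], `declared_admin_share`,
#'   `declared_recall_share`.
#' @return Data frame, one row per scenario; each mix validated to sum
#'   to 1.
#' @export
load_scenarios <- function(path = system.file("extdata", "scenarios.csv",
                                              package = "econsultcost")) {
  check_that(file.exists(path), sprintf("scenario file not found: %s", path))
  sc <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("scenario", econsult_categories())
  check_that(all(needed %in% names(sc)),
             paste("scenario file must have columns:",
                   paste(needed, collapse = ", ")))
  for (i in seq_len(nrow(sc))) {
    category_mix(unlist(sc[i, econsult_categories()]))  # validates
  }
  sc
}

#' Declared header shares recomputed from a mix
#'
#' Internal consistency check for scenario files: the admin share is the
#' sum of the two administrative categories, the patient-recall share the
#' sum of the three categories whose outcome brings the patient back
#' (other appointment, phone back, GP appointment).
#'
#' @param mix a [category_mix()].
#' @return Named list with `admin_share` and `recall_share`.
#' @export
scenario_declared_shares <- function(mix) {
  if (!inherits(mix, "category_mix")) mix <- category_mix(mix)
  m <- as.numeric(mix)
  names(m) <- econsult_categories()
  list(admin_share = unname(m["admin_other_details"] + m["admin_fit_note"]),
       recall_share = unname(m["other_appointment"] + m["gp_phone_back"] +
                               m["gp_appointment"]))
}

#' Evaluate directed-marketing scenarios
#'
#' For each scenario mix: the expected admin/GP minutes (scenario mix
#' weighted over the per-category resources), the raw and
#' induced-demand-adjusted saved fractions, the per-eConsult saving at
#' each, and the break-even submission rates at each supplied annual
#' charge.  The published scenario analysis quotes the charge both as
#' GBP 0.63 (body text) and GBP 1 (figure caption), so `charges` accepts
#' several values and neither is asserted as canonical.
#'
#' @param scenarios a [load_scenarios()] data frame.
#' @param timings an [activity_timings()] object.
#' @param costs a [cost_parameters()] object.
#' @param detailed_fraction note-use mixing fraction.
#' @param induced_fraction induced-demand fraction (default 0.08).
#' @param saved saved-category set.
#' @param charges annual charges (GBP/patient/year) at which break-even
#'   rates are reported; defaults to the charge in `costs`.
#' @return Data frame, one row per scenario x charge: `scenario`,
#'   `charge`, `admin_min`, `gp_min`, `saved_fraction`,
#'   `min_saved_fraction`, `saved_pct`, `min_saved_pct` (whole percent,
#'   half-away), `saving_gbp`, `min_saving_gbp` (full precision),
#'   `breakeven_rate`, `min_breakeven_rate`.
#' @export
#' @examples
#' evaluate_scenarios()
evaluate_scenarios <- function(scenarios = load_scenarios(),
                               timings = activity_timings(),
                               costs = cost_parameters(),
                               detailed_fraction = 0.5,
                               induced_fraction = 0.08,
                               saved = default_saved_categories(),
                               charges = costs$annual_charge_per_patient) {
  per_type <- derive_per_type_resources(timings, detailed_fraction)
  rows <- list()
  for (i in seq_len(nrow(scenarios))) {
    mix <- category_mix(unlist(scenarios[i, econsult_categories()]))
    expd <- expected_resource(per_type, mix)
    s_raw <- appointments_saved(mix, saved)
    s_min <- adjust_for_induced_demand(s_raw, induced_fraction)
    sv_raw <- savings_per_econsult(expd, costs, s_raw)
    sv_min <- savings_per_econsult(expd, costs, s_min)
    for (charge in charges) {
      cs <- costs
      cs$annual_charge_per_patient <- charge
      rows[[length(rows) + 1]] <- data.frame(
        scenario = scenarios$scenario[i],
        charge = charge,
        admin_min = expd$admin_minutes,
        gp_min = expd$gp_minutes,
        saved_fraction = s_raw,
        min_saved_fraction = s_min,
        saved_pct = round_half_away(100 * s_raw, 0),
        min_saved_pct = round_half_away(100 * s_min, 0),
        saving_gbp = sv_raw$total_saving,
        min_saving_gbp = sv_min$total_saving,
        breakeven_rate = breakeven_rate(sv_raw, cs)$rate,
        min_breakeven_rate = breakeven_rate(sv_min, cs)$rate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
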