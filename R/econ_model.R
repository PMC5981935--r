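#' Staff cost and service charge parameters
#'
#' Unit costs and the conventional-appointment comparator used to turn
#' expected staff minutes into money.  Defaults are the evaluation's
#' values: GP time at GBP 95.08 per hour, administrator time at GBP 17.82
#' per hour, a saved conventional contact costed as one 3-minute booking
#' call plus one 10-minute face-to-face appointment, and an annual service
#' charge of GBP 0.63 per registered patient.
#'
#' @param gp_cost_per_hour GP staff cost, GBP/hour.
#' @param admin_cost_per_hour administrative staff cost, GBP/hour.
#' @param conventional_booking_minutes admin minutes to book a conventional
#'   appointment.
#' @param conventional_gp_minutes GP minutes of the conventional
#'   face-to-face appointment an eConsult can replace.
#' @param annual_charge_per_patient service licence charge,
#'   GBP/patient/year.
#' @return A named list of class `"cost_parameters"`.
#' @export
cost_parameters <- function(gp_cost_per_hour = 95.08,
                            admin_cost_per_hour = 17.82,
                            conventional_booking_minutes = 3,
                            conventional_gp_minutes = 10,
                            annual_charge_per_patient = 0.63) {
  x <- list(gp_cost_per_hour = gp_cost_per_hour,
            admin_cost_per_hour = admin_cost_per_hour,
            conventional_booking_minutes = conventional_booking_minutes,
            conventional_gp_minutes = conventional_gp_minutes,
            annual_charge_per_patient = annual_charge_per_patient)
  for (nm in names(x)) check_nonneg_scalar(x[[nm]], nm)
  structure(x, class = "cost_parameters")
}

#' Cost saving per eConsult at a given appointment-replacement fraction
#'
#' For a fraction `s` of submissions that replace a conventional booked
#' face-to-face appointment, the saving per eConsult is the avoided
#' conventional staff time minus the eConsult processing time, valued at
#' the hourly rates:
#' \deqn{admin = (s \cdot m_{book} - E[admin])\,r_{admin}/60, \quad
#'       gp = (s \cdot m_{f2f} - E[gp])\,r_{gp}/60.}
#' The admin component is typically negative (an eConsult takes more admin
#' time than a booking call); the GP component positive; the sign of the
#' total depends on `s`.
#'
#' @param expected an [expected_resource()] at full precision.
#' @param costs a [cost_parameters()] object.
#' @param s fraction in [0, 1] of eConsults replacing a conventional GP
#'   appointment.
#' @return A list of class `"savings_breakdown"` with elements `s`,
#'   `admin_saving`, `gp_saving`, `total_saving` (GBP per eConsult, full
#'   precision; `total = admin + gp` exactly).
#' @export
#' @examples
#' savings_per_econsult(s = 0.73)
savings_per_econsult <- function(expected = expected_resource(),
                                 costs = cost_parameters(),
                                 s) {
  check_that(inherits(expected, "expected_resource"),
             "'expected' must come from expected_resource()")
  check_that(inherits(costs, "cost_parameters"),
             "'costs' must come from cost_parameters()")
  check_that(is.numeric(s) && length(s) == 1 && is.finite(s) &&
               s >= 0 && s <= 1,
             "'s' must be a single fraction in [0, 1]")
  admin <- (s * costs$conventional_booking_minutes -
              expected$admin_minutes) * costs$admin_cost_per_hour / 60
  gp <- (s * costs$conventional_gp_minutes -
           expected$gp_minutes) * costs$gp_cost_per_hour / 60
  structure(list(s = s,
                 admin_saving = admin,
                 gp_saving = gp,
                 total_saving = admin + gp),
            class = "savings_breakdown")
}

#' @export
print.savings_breakdown <- function(x, ...) {
  cat(sprintf(
    "Saving per eConsult at s = %.0f%%: admin %.1f, GP %.1f, total %.1f (GBP)\n",
    100 * x$s, round_half_away(x$admin_saving, 1),
    round_half_away(x$gp_saving, 1), round_half_away(x$total_saving, 1)))
  invisible(x)
}

#' Break-even submission rate against the annual charge
#'
#' The annual number of eConsults per registered patient at which the net
#' staff-cost saving covers the per-patient licence charge:
#' `charge / total_saving` when the total saving is positive.  When the
#' saving is zero or negative no submission volume can break even and the
#' result is flagged undefined (`rate = NA`).
#'
#' @param savings a [savings_per_econsult()] breakdown.
#' @param costs a [cost_parameters()] object (supplies the annual charge).
#' @return A list of class `"breakeven_result"` with elements `rate`
#'   (submissions/patient/year, `NA` when undefined), `defined` (logical)
#'   and `s` (the replacement fraction the saving was computed at).
#' @export
#' @examples
#' breakeven_rate(savings_per_econsult(s = 0.73))  # about 0.54
breakeven_rate <- function(savings, costs = cost_parameters()) {
  check_that(inherits(savings, "savings_breakdown"),
             "'savings' must come from savings_per_econsult()")
  check_that(inherits(costs, "cost_parameters"),
             "'costs' must come from cost_parameters()")
  if (savings$total_saving > 0) {
    structure(list(rate = costs$annual_charge_per_patient /
                     savings$total_saving,
                   defined = TRUE, s = savings$s),
              class = "breakeven_result")
  } else {
    structure(list(rate = NA_real_, defined = FALSE, s = savings$s),
              class = "breakeven_result")
  }
}

#' @export
print.breakeven_result <- function(x, ...) {
  if (x$defined) {
    cat(sprintf(
      "Break-even: %.3f eConsults per patient per year (at s = %.0f%%)\n",
      x$rate, 100 * x$s))
  } else {
    cat(sprintf("No breakeven at s = %.0f%% (non-positive saving)\n",
                100 * x$s))
  }
  invisible(x)
}

#' Savings table over a grid of replacement fractions
#'
#' One [savings_per_econsult()] row per value of `s`.  The default grid,
#' 74% down to 60% in steps of 2 percentage points, reproduces the
#' published cost-savings table at one decimal place.
#'
#' @param expected an [expected_resource()].
#' @param costs a [cost_parameters()] object.
#' @param s_values non-empty numeric vector of fractions in [0, 1].
#' @return Data frame with columns `s`, `admin_saving`, `gp_saving`,
#'   `total_saving` (full precision) and `breakeven_rate` (NA where the
#'   saving is non-positive).  Use [format_savings_table()] for the 1 dp
#'   presentation view.
#' @export
#' @examples
#' format_savings_table(savings_table())
savings_table <- function(expected = expected_resource(),
                          costs = cost_parameters(),
                          s_values = seq(0.74, 0.60, by = -0.02)) {
  check_that(is.numeric(s_values) && length(s_values) >= 1,
             "'s_values' must be a non-empty numeric vector")
  rows <- lapply(s_values, function(s) {
    sv <- savings_per_econsult(expected, costs, s)
    be <- breakeven_rate(sv, costs)
    data.frame(s = s, admin_saving = sv$admin_saving,
               gp_saving = sv$gp_saving, total_saving = sv$total_saving,
               breakeven_rate = be$rate)
  })
  do.call(rbind, rows)
}

#' Round a savings table for presentation
#'
#' @param tab a [savings_table()].
#' @return The same table with money columns rounded half-away to 1 dp and
#'   `s` shown as a whole percentage.
#' @export
format_savings_table <- function(tab) {
  data.frame(gp_appointments_saved_pct = round_half_away(100 * tab$s, 0),
             admin_saving_gbp = round_half_away(tab$admin_saving, 1),
             gp_saving_gbp = round_half_away(tab$gp_saving, 1),
             total_saving_gbp = round_half_away(tab$total_saving, 1))
}

#' Sensitivity of the total saving to administrative timings
#'
#' Rescales administrative task timings by `(1 + perturbation)` and
#' recomputes the full chain (per-category resources, expected time,
#' saving at `s`).  Two variants are reported, because the conventional
#' booking call is itself an administrative task: `"econsult_admin_only"`
#' scales only the eConsult-side admin tasks (receive, both close-offs),
#' while `"all_admin"` also scales the conventional booking time.  The
#' change in total saving is small relative to the GP component in either
#' variant, since admin time is costed at roughly one fifth of the GP
#' rate.
#'
#' @param timings an [activity_timings()] object.
#' @param perturbation relative change in admin timings, in (-1, 1);
#'   e.g. `0.2` for 20% longer.
#' @param mix a [category_mix()].
#' @param detailed_fraction note-use mixing fraction, as in
#'   [derive_per_type_resources()].
#' @param costs a [cost_parameters()] object.
#' @param s appointment-replacement fraction the saving is evaluated at.
#' @return Data frame with one row per variant: `variant`, `perturbation`,
#'   `admin_saving`, `gp_saving`, `total_saving`, `delta_total` (change
#'   from the unperturbed saving).
#' @export
sensitivity_sweep <- function(timings = activity_timings(),
                              perturbation,
                              mix = default_category_mix(),
                              detailed_fraction = 0.5,
                              costs = cost_parameters(),
                              s = 0.73) {
  check_that(is.numeric(perturbation) && length(perturbation) == 1 &&
               is.finite(perturbation) &&
               perturbation > -1 && perturbation < 1,
             "'perturbation' must be a single number in (-1, 1)")
  base <- savings_per_econsult(
    expected_resource(derive_per_type_resources(timings, detailed_fraction),
                      mix),
    costs, s)

  scale_econsult_admin <- function(tm, f) {
    tm$receive_econsult <- tm$receive_econsult * f
    tm$close_off_with_contact <- tm$close_off_with_contact * f
    tm$close_off_no_contact <- tm$close_off_no_contact * f
    tm
  }
  f <- 1 + perturbation

  variants <- list(
    econsult_admin_only = list(
      timings = scale_econsult_admin(timings, f), costs = costs),
    all_admin = list(
      timings = scale_econsult_admin(timings, f),
      costs = {
        cs <- costs
        cs$conventional_booking_minutes <-
          cs$conventional_booking_minutes * f
        cs
      }))

  rows <- lapply(names(variants), function(v) {
    tm <- variants[[v]]$timings
    cs <- variants[[v]]$costs
    sv <- savings_per_econsult(
      expected_resource(derive_per_type_resources(tm, detailed_fraction),
                        mix),
      cs, s)
    data.frame(variant = v, perturbation = perturbation,
               admin_saving = sv$admin_saving, gp_saving = sv$gp_saving,
               total_saving = sv$total_saving,
               delta_total = sv$total_saving - base$total_saving,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
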