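#' Activity timings for eConsult-related tasks
#'
#' Task-level time estimates in minutes for the administrative and GP
#' activities that make up the processing of an eConsult and of a
#' conventional appointment.  Defaults are the pilot's interview-derived
#' estimates: booking a normal GP appointment 3 min; receiving an eConsult
#' 3 min; closing off with patient contact 3 min, without contact 1.5 min;
#' a face-to-face appointment 10 min; a telephone consultation 5 min;
#' processing an eConsult with minimal use of the patient's notes 2.5 min,
#' with detailed use 5 min; generating a sick (fit) note 4 min; generating
#' a prescription adds 1 min to the note check; other follow-up (another
#' appointment, bloods, nurse) adds 0.5 min; a change of details takes
#' 0.5 min.
#'
#' @param book_appointment minutes to book a normal GP appointment.
#' @param receive_econsult minutes of administrative time to receive an
#'   eConsult.
#' @param close_off_with_contact minutes to close off a submission when the
#'   patient must be contacted.
#' @param close_off_no_contact minutes to close off without patient contact.
#' @param face_to_face_appointment minutes of a face-to-face GP appointment.
#' @param telephone_consultation minutes of a GP telephone consultation.
#' @param process_minimal_notes minutes for a GP to process an eConsult with
#'   minimal use of the patient's notes.
#' @param process_detailed_notes minutes with detailed use of the notes.
#' @param sick_note minutes to generate a sick (fit) note.
#' @param prescription_increment extra minutes, on top of the note check, to
#'   generate a prescription.
#' @param other_followup_increment extra minutes to generate another
#'   appointment, bloods, nurse referral etc.
#' @param change_of_details minutes to process a change of details.
#' @return A named list of class `"activity_timings"`; all values in
#'   minutes, all non-negative.
#' @export
#' @examples
#' activity_timings()                    # pilot defaults
#' activity_timings(process_detailed_notes = 6)
activity_timings <- function(book_appointment = 3,
                             receive_econsult = 3,
                             close_off_with_contact = 3,
                             close_off_no_contact = 1.5,
                             face_to_face_appointment = 10,
                             telephone_consultation = 5,
                             process_minimal_notes = 2.5,
                             process_detailed_notes = 5,
                             sick_note = 4,
                             prescription_increment = 1,
                             other_followup_increment = 0.5,
                             change_of_details = 0.5) {
  x <- list(book_appointment = book_appointment,
            receive_econsult = receive_econsult,
            close_off_with_contact = close_off_with_contact,
            close_off_no_contact = close_off_no_contact,
            face_to_face_appointment = face_to_face_appointment,
            telephone_consultation = telephone_consultation,
            process_minimal_notes = process_minimal_notes,
            process_detailed_notes = process_detailed_notes,
            sick_note = sick_note,
            prescription_increment = prescription_increment,
            other_followup_increment = other_followup_increment,
            change_of_details = change_of_details)
  for (nm in names(x)) check_nonneg_scalar(x[[nm]], nm)
  structure(x, class = "activity_timings")
}

# categories whose close-off requires contacting the patient (6.0 admin min
# with default timings); the remaining two close off without contact
# (4.5 admin min).  This assignment is the only one that reproduces the
# published per-category admin column from the task components; see the
# methods vignette.
contact_closeoff_categories <- function() {
  c("admin_fit_note", "gp_prescription", "other_appointment",
    "gp_phone_back", "gp_appointment")
}

#' Derive per-category resource use from activity timings
#'
#' Composes, for each of the seven outcome categories, the expected
#' administrative and GP minutes per eConsult from the task-level timings.
#'
#' Admin minutes are `receive_econsult` plus the close-off time
#' (with-contact for categories requiring the patient to be contacted:
#' fit note, prescription, other appointment, phone back, GP appointment;
#' no-contact otherwise).  The GP "note check" is the mixture
#' `detailed_fraction * process_detailed_notes +
#' (1 - detailed_fraction) * process_minimal_notes` (1.25 + 2.5 = 3.75 min
#' at the defaults).  Per category the GP time is then: change of details
#' alone for the admin/details category; the sick-note time for fit notes;
#' the note check alone for no-action; note check plus the prescription or
#' other-follow-up increment; and for the two recall categories the note
#' check plus a telephone (phone back) or face-to-face (GP appointment)
#' consultation as follow-up.
#'
#' @param timings an [activity_timings()] object.
#' @param detailed_fraction fraction of eConsults requiring detailed use of
#'   the patient's notes (default 0.5, the pilot's assumption).
#' @return A data frame of class `"per_type_resource"` with columns
#'   `category`, `admin_minutes`, `gp_base_minutes`, `gp_followup_minutes`
#'   and `gp_minutes` (= base + follow-up), one row per category in
#'   reporting order.
#' @export
#' @examples
#' derive_per_type_resources()  # reproduces the published per-type table
derive_per_type_resources <- function(timings = activity_timings(),
                                      detailed_fraction = 0.5) {
  check_that(inherits(timings, "activity_timings"),
             "'timings' must be an activity_timings object")
  check_fraction(detailed_fraction, "detailed_fraction")

  note_check <- detailed_fraction * timings$process_detailed_notes +
    (1 - detailed_fraction) * timings$process_minimal_notes

  cats <- econsult_categories()
  contact <- cats %in% contact_closeoff_categories()
  admin <- timings$receive_econsult +
    ifelse(contact, timings$close_off_with_contact,
           timings$close_off_no_contact)

  gp_base <- c(admin_other_details = timings$change_of_details,
               admin_fit_note      = timings$sick_note,
               gp_no_action        = note_check,
               gp_prescription     = note_check + timings$prescription_increment,
               other_appointment   = note_check + timings$other_followup_increment,
               gp_phone_back       = note_check,
               gp_appointment      = note_check)
  gp_followup <- c(admin_other_details = 0,
                   admin_fit_note      = 0,
                   gp_no_action        = 0,
                   gp_prescription     = 0,
                   other_appointment   = 0,
                   gp_phone_back       = timings$telephone_consultation,
                   gp_appointment      = timings$face_to_face_appointment)

  out <- data.frame(category = cats,
                    admin_minutes = unname(admin),
                    gp_base_minutes = unname(gp_base[cats]),
                    gp_followup_minutes = unname(gp_followup[cats]),
                    stringsAsFactors = FALSE)
  out$gp_minutes <- out$gp_base_minutes + out$gp_followup_minutes
  class(out) <- c("per_type_resource", "data.frame")
  out
}

#' Probability-weighted expected resource per eConsult
#'
#' Weights the per-category admin and GP minutes by the category mix:
#' the expected time a submitted eConsult consumes.  With the default
#' timings and mix the full-precision values are 5.67 admin min and
#' 5.9125 GP min per eConsult (5.7 and 5.9 at one decimal place).
#' Full precision is retained; rounding happens only at presentation.
#'
#' @param per_type a [derive_per_type_resources()] table.
#' @param mix a [category_mix()].
#' @return A list of class `"expected_resource"` with elements
#'   `admin_minutes` and `gp_minutes` (full precision, per eConsult).
#' @export
#' @examples
#' expected_resource()
expected_resource <- function(per_type = derive_per_type_resources(),
                              mix = default_category_mix()) {
  check_that(inherits(per_type, "per_type_resource"),
             "'per_type' must come from derive_per_type_resources()")
  if (!inherits(mix, "category_mix")) mix <- category_mix(mix)
  stopifnot(identical(per_type$category, econsult_categories()))
  p <- as.numeric(mix)
  structure(list(admin_minutes = sum(p * per_type$admin_minutes),
                 gp_minutes    = sum(p * per_type$gp_minutes)),
            class = "expected_resource")
}

#' @export
print.expected_resource <- function(x, ...) {
  cat(sprintf("Expected time per eConsult: admin %.1f min, GP %.1f min\n",
              round_half_away(x$admin_minutes, 1),
              round_half_away(x$gp_minutes, 1)))
  cat(sprintf("  (full precision: admin %.4f, GP %.4f)\n",
              x$admin_minutes, x$gp_minutes))
  invisible(x)
}

#' Per-category resource table with shares
#'
#' Presentation table combining the category mix with per-category times,
#' suitable for CSV export.
#'
#' @param per_type a [derive_per_type_resources()] table.
#' @param mix a [category_mix()].
#' @return Data frame with columns `category`, `share`, `admin_min`,
#'   `gp_min` plus a final `total_expected` row holding the mix-weighted
#'   expected times (1 dp).
#' @export
per_type_table <- function(per_type = derive_per_type_resources(),
                           mix = default_category_mix()) {
  if (!inherits(mix, "category_mix")) mix <- category_mix(mix)
  exp_res <- expected_resource(per_type, mix)
  rbind(
    data.frame(category = per_type$category,
               share = as.numeric(mix),
               admin_min = per_type$admin_minutes,
               gp_min = per_type$gp_minutes,
               stringsAsFactors = FALSE),
    data.frame(category = "total_expected",
               share = 1,
               admin_min = round_half_away(exp_res$admin_minutes, 1),
               gp_min = round_half_away(exp_res$gp_minutes, 1),
               stringsAsFactors = FALSE))
}

#' Read model parameters from a YAML file
#'
#' Parses a key-value parameter document with sections `timings`, `notes`
#' (`detailed_fraction`), `mix` and `costs`, mirroring the constructor
#' argument names.  The packaged default file
#' (`system.file("extdata", "default_parameters.yaml", package =
#' "econsultcost")`) reproduces the published timing and cost tables.
#'
#' @param path path to a YAML parameter file.
#' @return List with elements `timings` ([activity_timings()]),
#'   `detailed_fraction`, `mix` ([category_mix()]) and `costs`
#'   ([cost_parameters()]).  Missing sections fall back to the defaults.
#' @export
read_parameters <- function(path = system.file("extdata",
                                               "default_parameters.yaml",
                                               package = "econsultcost")) {
  check_that(file.exists(path), sprintf("parameter file not found: %s", path))
  raw <- yaml::read_yaml(path)
  timings <- if (is.null(raw$timings)) activity_timings() else
    do.call(activity_timings, raw$timings)
  detailed <- if (is.null(raw$notes$detailed_fraction)) 0.5 else
    raw$notes$detailed_fraction
  mix <- if (is.null(raw$mix)) default_category_mix() else
    category_mix(unlist(raw$mix))
  costs <- if (is.null(raw$costs)) cost_parameters() else
    do.call(cost_parameters, raw$costs)
  list(timings = timings, detailed_fraction = detailed,
       mix = mix, costs = costs)
}
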