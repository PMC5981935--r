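# Independent enumeration oracle for the mix-weighted expected time:
# explicit per-category accumulation, no vector algebra.
oracle_expected <- function(per_type, mix) {
  admin <- 0
  gp <- 0
  for (cat in econsult_categories()) {
    p <- unclass(mix)[[cat]]
    row <- per_type[per_type$category == cat, ]
    admin <- admin + p * row$admin_minutes
    gp <- gp + p * (row$gp_base_minutes + row$gp_followup_minutes)
  }
  list(admin_minutes = admin, gp_minutes = gp)
}

# random normalised category mix
random_mix <- function() {
  w <- stats::rexp(7)
  category_mix(stats::setNames(w / sum(w), econsult_categories()))
}

# minimal event-log builder for analytics tests
make_events <- function(practice_id = "P01",
                        n_visits = 0, n_submissions = 0,
                        sex = "unknown", age_band = "unknown",
                        category = "", date = as.Date("2017-05-01")) {
  rows <- list()
  if (n_visits > 0) {
    rows$visits <- data.frame(
      practice_id = practice_id, date = date, kind = "site_visit",
      category = "", sex = "unknown", age_band = "unknown",
      stringsAsFactors = FALSE)[rep(1, n_visits), ]
  }
  if (n_submissions > 0) {
    rows$subs <- data.frame(
      practice_id = practice_id, date = date, kind = "submission",
      category = category, sex = sex, age_band = age_band,
      stringsAsFactors = FALSE)[rep(1, n_submissions), ]
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(practice_id = character(), date = as.Date(character()),
                      kind = character(), category = character(),
                      sex = character(), age_band = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

# roster row builder
make_roster <- function(practice_id, adult_list_size = 10000,
                        simd_q1q2 = 0.3, simd_q4q5 = 0.3) {
  data.frame(practice_id = practice_id,
             list_size = round(adult_list_size / 0.84),
             adult_list_size = adult_list_size,
             share_18_44 = 0.43, share_18_64 = 0.64, share_65_plus = 0.20,
             female_share = 0.504,
             simd_q1q2_share = simd_q1q2, simd_q4q5_share = simd_q4q5,
             stringsAsFactors = FALSE)
}
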