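#' Read an event log CSV
#'
#' Event logs record one row per website event: columns `practice_id`,
#' `date` (ISO 8601), `kind` (one of `site_visit`, `unique_visit`,
#' `urgent_divert`, `submission`), `category` (a broad submission class or
#' outcome category; empty for non-submission rows), `sex` (`female`,
#' `male`, `unknown`) and `age_band` (`18-24`, `25-34`, `35-44`, `45-54`,
#' `55-64`, `65+`, `unknown`).  Demographics may be unknown; kind is
#' mandatory.
#'
#' @param path path to a UTF-8, comma-separated file with a header.
#' @return Data frame of events with `date` parsed as `Date`.
#' @export
read_event_log <- function(path) {
  check_that(file.exists(path), sprintf("event log not found: %s", path))
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  needed <- c("practice_id", "date", "kind", "category", "sex", "age_band")
  check_that(all(needed %in% names(ev)),
             paste("event log must have columns:",
                   paste(needed, collapse = ", ")))
  ev$date <- as.Date(ev$date)
  check_that(!anyNA(ev$date), "event log contains unparseable dates")
  kinds <- c("site_visit", "unique_visit", "urgent_divert", "submission")
  check_that(all(ev$kind %in% kinds),
             paste("event kind must be one of:", paste(kinds, collapse = ", ")))
  ev
}

#' Read a practice roster CSV
#'
#' Roster summaries give, per practice: `practice_id`, `list_size`,
#' `adult_list_size` (patients aged 18+), the age-structure fractions of
#' the total roll `share_18_44`, `share_18_64`, `share_65_plus`,
#' `female_share`, and the deprivation-profile fractions
#' `simd_q1q2_share` (most deprived quintiles) and `simd_q4q5_share`
#' (least deprived).
#'
#' @param path path to a CSV file.
#' @return Data frame of practice profiles.
#' @export
read_rosters <- function(path) {
  check_that(file.exists(path), sprintf("roster file not found: %s", path))
  ro <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("practice_id", "list_size", "adult_list_size", "share_18_44",
              "share_18_64", "share_65_plus", "female_share",
              "simd_q1q2_share", "simd_q4q5_share")
  check_that(all(needed %in% names(ro)),
             paste("roster file must have columns:",
                   paste(needed, collapse = ", ")))
  shares <- c("share_18_44", "share_18_64", "share_65_plus", "female_share",
              "simd_q1q2_share", "simd_q4q5_share")
  for (sh in shares) {
    check_that(all(ro[[sh]] >= 0 & ro[[sh]] <= 1),
               sprintf("roster column '%s' must lie in [0, 1]", sh))
  }
  check_that(all(ro$share_18_64 + ro$share_65_plus <= 1 + 1e-9),
             "age shares 18-64 and 65+ must not exceed the total roll")
  ro
}

#' Conversion rate from site visit to submission
#'
#' Submissions divided by site visits in scope.  The pooled pilot figure
#' was around 30%, with individual practices ranging up to the mid-40s.
#'
#' @param events an event-log data frame ([read_event_log()]).
#' @param practice_id optional practice to restrict to; `NULL` pools all.
#' @return Fraction in [0, 1], or `NA` (with a warning) when there are no
#'   site visits in scope.
#' @export
conversion_rate <- function(events, practice_id = NULL) {
  if (!is.null(practice_id)) {
    events <- events[events$practice_id %in% practice_id, , drop = FALSE]
  }
  visits <- sum(events$kind == "site_visit")
  subs <- sum(events$kind == "submission")
  if (visits == 0) {
    warning("no site visits in scope; conversion rate undefined")
    return(NA_real_)
  }
  subs / visits
}

#' Annualised submission rate per 1000 adult patients
#'
#' Scales the submissions observed in a window of `window_months` months
#' to a full year and normalises by the adult (18+) list size:
#' `submissions * (12 / window_months) * 1000 / adult_list_size`.
#'
#' @param events event-log data frame, already restricted to the practice
#'   if a per-practice rate is wanted.
#' @param adult_list_size number of registered patients aged 18+.
#' @param window_months length of the observation window in months (> 0).
#' @return Rate per 1000 adults per year.
#' @export
annualised_rate <- function(events, adult_list_size, window_months) {
  check_that(is.numeric(window_months) && length(window_months) == 1 &&
               window_months > 0, "'window_months' must be > 0")
  check_that(is.numeric(adult_list_size) && length(adult_list_size) == 1 &&
               adult_list_size > 0, "'adult_list_size' must be > 0")
  subs <- sum(events$kind == "submission")
  subs * (12 / window_months) * 1000 / adult_list_size
}

#' Per-practice annualised submission rates
#'
#' @param events event-log data frame.
#' @param rosters roster data frame ([read_rosters()]).
#' @param window_months observation window in months.
#' @return Data frame with `practice_id`, `site_visits`, `submissions`,
#'   `conversion_rate`, `rate_per_1000_adults` (annualised) and
#'   `rate_per_patient` (annualised submissions per adult).
#' @export
practice_rates <- function(events, rosters, window_months) {
  rows <- lapply(seq_len(nrow(rosters)), function(i) {
    pid <- rosters$practice_id[i]
    ev <- events[events$practice_id == pid, , drop = FALSE]
    visits <- sum(ev$kind == "site_visit")
    subs <- sum(ev$kind == "submission")
    rate <- annualised_rate(ev, rosters$adult_list_size[i], window_months)
    data.frame(practice_id = pid, site_visits = visits, submissions = subs,
               conversion_rate = if (visits > 0) subs / visits else NA_real_,
               rate_per_1000_adults = rate,
               rate_per_patient = rate / 1000,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Demographic and category shares of submissions
#'
#' Shares are computed over submissions with known demographics; unknowns
#' are counted and reported separately, never silently folded into
#' denominators.
#'
#' @param events event-log data frame.
#' @return List with `n_submissions`; `female_share`, `n_sex_known`,
#'   `n_sex_unknown`; `age_band_shares` (named vector over known bands),
#'   `share_18_44`, `n_age_known`, `n_age_unknown`; `category_shares`
#'   (named vector over known categories, summing to 1).  Shares are `NA`
#'   when no known values exist.
#' @export
demographic_shares <- function(events) {
  subs <- events[events$kind == "submission", , drop = FALSE]
  n <- nrow(subs)

  sex_known <- subs$sex[subs$sex %in% c("female", "male")]
  female_share <- if (length(sex_known) > 0) {
    mean(sex_known == "female")
  } else NA_real_

  age_known <- subs$age_band[!(subs$age_band %in% c("unknown", "", NA))]
  age_shares <- if (length(age_known) > 0) {
    tab <- table(age_known)
    stats::setNames(as.numeric(tab) / length(age_known), names(tab))
  } else NULL
  share_18_44 <- if (length(age_known) > 0) {
    mean(age_known %in% c("18-24", "25-34", "35-44"))
  } else NA_real_

  cat_known <- subs$category[!(subs$category %in% c("unknown", "", NA))]
  cat_shares <- if (length(cat_known) > 0) {
    tab <- table(cat_known)
    stats::setNames(as.numeric(tab) / length(cat_known), names(tab))
  } else NULL

  list(n_submissions = n,
       female_share = female_share,
       n_sex_known = length(sex_known),
       n_sex_unknown = n - length(sex_known),
       age_band_shares = age_shares,
       share_18_44 = share_18_44,
       n_age_known = length(age_known),
       n_age_unknown = n - length(age_known),
       category_shares = cat_shares)
}

#' Association between submission rates and deprivation profile
#'
#' Spearman rank correlation of per-practice annualised submission rates
#' against the practice shares of patients in SIMD quintiles 1-2 (most
#' deprived) and 4-5 (least deprived), with a seeded permutation p-value.
#' The pilot reported no discernible relationship by visual inspection;
#' this function replaces the visual claim with a statistic.
#'
#' @param rates a [practice_rates()] data frame (or any data frame with
#'   `practice_id` and `rate_per_1000_adults`).
#' @param rosters roster data frame with the SIMD share columns.
#' @param n_perm number of permutations (>= 999 recommended).
#' @param seed RNG seed for the permutations.
#' @return Data frame with one row per deprivation measure: `measure`,
#'   `rho`, `p_value` (two-sided permutation), `n`, `degenerate` (TRUE
#'   when either variable has zero variance, in which case `rho` is 0 by
#'   convention and `p_value` is `NA`).
#' @export
deprivation_association <- function(rates, rosters, n_perm = 999,
                                    seed = 1) {
  merged <- merge(rates, rosters, by = "practice_id")
  check_that(nrow(merged) >= 3,
             paste("deprivation association needs at least 3 practices;",
                   sprintf("got %d after matching rates to rosters",
                           nrow(merged))))
  check_that(n_perm >= 1, "'n_perm' must be positive")
  set.seed(seed)
  out <- lapply(c("simd_q1q2_share", "simd_q4q5_share"), function(measure) {
    x <- merged$rate_per_1000_adults
    y <- merged[[measure]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(measure = measure, rho = 0, p_value = NA_real_,
                        n = nrow(merged), degenerate = TRUE,
                        stringsAsFactors = FALSE))
    }
    rho <- stats::cor(x, y, method = "spearman")
    perm <- replicate(n_perm,
                      abs(stats::cor(sample(x), y, method = "spearman")))
    p <- (1 + sum(perm >= abs(rho) - 1e-12)) / (1 + n_perm)
    data.frame(measure = measure, rho = rho, p_value = p,
               n = nrow(merged), degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# internal: Wilson 95% score interval via prop.test (no continuity
# correction)
wilson_interval <- function(x, n) {
  ci <- stats::prop.test(x, n, correct = FALSE)$conf.int
  c(lower = ci[1], upper = ci[2])
}

#' Survey proportion summaries with Wilson intervals
#'
#' Point estimates and Wilson 95% score intervals for the patient-survey
#' proportions (satisfaction, willingness to recommend) and, when the
#' submission count is supplied, the survey response rate.
#'
#' @param satisfied number of respondents reporting satisfaction.
#' @param responses number of survey responses (denominator, > 0).
#' @param recommend optional number of respondents likely to recommend.
#' @param submissions optional total submissions, for the response rate.
#' @return Data frame with columns `measure`, `numerator`, `denominator`,
#'   `proportion`, `lower`, `upper`.
#' @export
#' @examples
#' survey_summary(266, 291, recommend = 266, submissions = 4477)
survey_summary <- function(satisfied, responses, recommend = NULL,
                           submissions = NULL) {
  check_that(is.numeric(responses) && length(responses) == 1 &&
               responses > 0, "'responses' must be a positive count")
  check_that(satisfied >= 0 && satisfied <= responses,
             "'satisfied' must lie in [0, responses]")
  row <- function(measure, x, n) {
    ci <- wilson_interval(x, n)
    data.frame(measure = measure, numerator = x, denominator = n,
               proportion = x / n, lower = ci["lower"], upper = ci["upper"],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- row("satisfaction", satisfied, responses)
  if (!is.null(recommend)) {
    check_that(recommend >= 0 && recommend <= responses,
               "'recommend' must lie in [0, responses]")
    out <- rbind(out, row("recommend", recommend, responses))
  }
  if (!is.null(submissions)) {
    check_that(submissions >= responses,
               "'submissions' must be at least 'responses'")
    out <- rbind(out, row("response_rate", responses, submissions))
  }
  out
}

#' Pooled usage metrics from an event log
#'
#' Convenience wrapper combining [conversion_rate()], [practice_rates()]
#' and [demographic_shares()] into one metrics object.
#'
#' @param events event-log data frame.
#' @param rosters roster data frame.
#' @param window_months observation window in months.
#' @return List with `pooled_conversion_rate`, `per_practice`
#'   (a [practice_rates()] table), `pooled_rate_per_1000_adults`,
#'   `pooled_rate_per_patient` and the [demographic_shares()] fields.
#' @export
usage_metrics <- function(events, rosters, window_months) {
  pr <- practice_rates(events, rosters, window_months)
  total_adults <- sum(rosters$adult_list_size)
  subs <- sum(pr$submissions)
  pooled_rate <- subs * (12 / window_months) * 1000 / total_adults
  c(list(pooled_conversion_rate = conversion_rate(events),
         per_practice = pr,
         pooled_rate_per_1000_adults = pooled_rate,
         pooled_rate_per_patient = pooled_rate / 1000),
    demographic_shares(events))
}
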