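#' Configuration for the synthetic pilot generator
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure of the pilot's web-triage logs: Poisson daily site visits
#' proportional to the adult list size, independent Bernoulli conversion
#' of visits to submissions, a categorical broad-class mix, female- and
#' young-adult-skewed usage, and a voluntary patient survey.  Defaults
#' encode the pilot's conditions: 11 practices observed over the 5-month
#' window 17 April - 17 August 2017; conversion probability 0.30 (pooled
#' "around 30%"); broad-class mix 32% specific condition / 27%
#' administrative help / 24% general advice (new) / 17% general advice
#' (existing); female usage odds 2.0, which against rosters of about
#' 50.4% female yields about 67% female submissions; an 18-44 usage
#' multiplier of 1.708, which against adult rosters about 51% 18-44
#' yields about 64% of submissions from that group; no deprivation
#' effect on rates; survey response probability 6.5% with satisfaction
#' 91.4% and recommendation 91.5%.  The daily visit rate of 0.67 per
#' 1000 adults, with conversion 0.30, adults about 84% of the roll and
#' the month-based annualisation the analytics apply (12/5 over the
#' 17 April - 17 August window), reproduces the pilot's pooled submission
#' rate of about 0.05 per registered patient per year.
#'
#' @param seed integer RNG seed; identical (seed, config) pairs produce
#'   identical output.
#' @param n_practices number of practices (>= 1).
#' @param list_size_range range (min, max) of practice list sizes.
#' @param window_start,window_end observation window (ISO dates).
#' @param daily_visit_rate_per_1000 Poisson mean of daily site visits per
#'   1000 adult patients.
#' @param conversion_probability probability a site visit becomes a
#'   submission.
#' @param urgent_divert_probability probability a visit is diverted to the
#'   urgent/emergency page.
#' @param unique_visit_probability probability a visit is the first from
#'   its user in 24 h (the log emits this flag directly).
#' @param broad_class_mix named probabilities over the four broad
#'   submission classes `specific_condition`, `administrative_help`,
#'   `general_advice_new`, `general_advice_existing`.
#' @param female_usage_odds multiplier on the roster female/male odds for
#'   submission propensity.
#' @param age_usage_multipliers named multipliers per age band applied to
#'   the roster's adult age composition.
#' @param simd_effect linear effect of the practice's most-deprived share
#'   (centred at 0.3) on its visit rate; 0 means rates are independent of
#'   deprivation.
#' @param trend_range visit-rate multipliers at the start and end of the
#'   window; rates ramp linearly between them (normalised to mean 1) to
#'   emulate the pilot's growth in usage over the window.
#' @param practice_rate_sd standard deviation of the log-normal
#'   practice-level rate multiplier (between-practice usage spread).
#' @param survey_response_probability probability a submission yields a
#'   survey response.
#' @param satisfaction_probability probability a respondent is satisfied.
#' @param recommend_probability probability a respondent would recommend
#'   the service.
#' @param young_outlier_share_65_plus share aged 65+ forced on the
#'   young-skewed outlier practice (a student-population practice).
#' @param old_outlier_share_65_plus share aged 65+ forced on the
#'   old-skewed (rural) outlier practice.
#' @return A validated list of class `"generator_config"`.
#' @export
generator_config <- function(seed = 1,
                             n_practices = 11,
                             list_size_range = c(6000, 20000),
                             window_start = "2017-04-17",
                             window_end = "2017-08-17",
                             daily_visit_rate_per_1000 = 0.67,
                             conversion_probability = 0.30,
                             urgent_divert_probability = 0.05,
                             unique_visit_probability = 0.80,
                             broad_class_mix = c(
                               specific_condition = 0.32,
                               administrative_help = 0.27,
                               general_advice_new = 0.24,
                               general_advice_existing = 0.17),
                             female_usage_odds = 2.0,
                             age_usage_multipliers = c(
                               "18-24" = 1.708, "25-34" = 1.708,
                               "35-44" = 1.708, "45-54" = 1,
                               "55-64" = 1, "65+" = 1),
                             simd_effect = 0,
                             trend_range = c(0.5, 1.5),
                             practice_rate_sd = 0.5,
                             survey_response_probability = 0.065,
                             satisfaction_probability = 0.914,
                             recommend_probability = 0.915,
                             young_outlier_share_65_plus = 0.023,
                             old_outlier_share_65_plus = 0.281) {
  check_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
             "'seed' must be a single number")
  check_that(n_practices >= 1, "'n_practices' must be >= 1")
  check_that(length(list_size_range) == 2 &&
               list_size_range[1] <= list_size_range[2] &&
               list_size_range[1] > 0,
             "'list_size_range' must be a positive (min, max) pair")
  ws <- as.Date(window_start); we <- as.Date(window_end)
  check_that(!is.na(ws) && !is.na(we) && ws <= we,
             "window must be a non-empty ISO-date range")
  check_nonneg_scalar(daily_visit_rate_per_1000, "daily_visit_rate_per_1000")
  check_fraction(conversion_probability, "conversion_probability")
  check_fraction(urgent_divert_probability, "urgent_divert_probability")
  check_fraction(unique_visit_probability, "unique_visit_probability")
  classes <- c("specific_condition", "administrative_help",
               "general_advice_new", "general_advice_existing")
  check_that(setequal(names(broad_class_mix), classes) &&
               all(broad_class_mix >= 0) &&
               abs(sum(broad_class_mix) - 1) <= 1e-9,
             "'broad_class_mix' must be a distribution over the 4 classes")
  bands <- c("18-24", "25-34", "35-44", "45-54", "55-64", "65+")
  check_that(setequal(names(age_usage_multipliers), bands) &&
               all(age_usage_multipliers >= 0),
             "'age_usage_multipliers' must name the 6 adult age bands")
  check_nonneg_scalar(female_usage_odds, "female_usage_odds")
  check_that(length(trend_range) == 2 && all(trend_range > 0),
             "'trend_range' must be two positive multipliers")
  check_nonneg_scalar(practice_rate_sd, "practice_rate_sd")
  check_fraction(survey_response_probability, "survey_response_probability")
  check_fraction(satisfaction_probability, "satisfaction_probability")
  check_fraction(recommend_probability, "recommend_probability")
  check_fraction(young_outlier_share_65_plus, "young_outlier_share_65_plus")
  check_fraction(old_outlier_share_65_plus, "old_outlier_share_65_plus")

  structure(list(seed = as.integer(seed), n_practices = n_practices,
                 list_size_range = list_size_range,
                 window_start = ws, window_end = we,
                 daily_visit_rate_per_1000 = daily_visit_rate_per_1000,
                 conversion_probability = conversion_probability,
                 urgent_divert_probability = urgent_divert_probability,
                 unique_visit_probability = unique_visit_probability,
                 broad_class_mix = broad_class_mix[classes],
                 female_usage_odds = female_usage_odds,
                 age_usage_multipliers = age_usage_multipliers[bands],
                 simd_effect = simd_effect,
                 trend_range = trend_range,
                 practice_rate_sd = practice_rate_sd,
                 survey_response_probability = survey_response_probability,
                 satisfaction_probability = satisfaction_probability,
                 recommend_probability = recommend_probability,
                 young_outlier_share_65_plus = young_outlier_share_65_plus,
                 old_outlier_share_65_plus = old_outlier_share_65_plus),
            class = "generator_config")
}

# internal: clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Generate synthetic practice rosters
#'
#' Draws `n_practices` practice profiles with heterogeneous age, gender
#' and deprivation composition around the pilot's averages (64% of the
#' roll aged 18-64, 20% aged 65+, about 51% of adults aged 18-44, about
#' 50.4% female).  When at least three practices are requested, the
#' last-but-one practice is a young-skewed outlier (student population,
#' 65+ share forced to `young_outlier_share_65_plus`) and the last an
#' old-skewed rural outlier (65+ share `old_outlier_share_65_plus`), and
#' the first two practices carry a high most-deprived share, emulating
#' the pilot's spread.  A `rate_multiplier` column records each
#' practice's log-normal usage-level multiplier, consumed by
#' [generate_log()].
#'
#' @param config a [generator_config()].
#' @return Data frame of practice profiles (see [read_rosters()] for the
#'   core columns) plus `rate_multiplier`.
#' @export
generate_rosters <- function(config) {
  check_that(inherits(config, "generator_config"),
             "'config' must come from generator_config()")
  set.seed(config$seed)
  n <- config$n_practices
  ids <- sprintf("P%02d", seq_len(n))
  list_size <- round(stats::runif(n, config$list_size_range[1],
                                  config$list_size_range[2]))

  share_65 <- clamp(stats::rnorm(n, 0.20, 0.03), 0.05, 0.35)
  share_18_64 <- clamp(stats::rnorm(n, 0.64, 0.02), 0.55, 0.75)
  # adult share aged 18-44 (pilot average ~51%)
  q_18_44 <- clamp(stats::rnorm(n, 0.51, 0.015), 0.40, 0.62)
  female <- clamp(stats::rnorm(n, 0.504, 0.012), 0.45, 0.56)
  simd_q1q2 <- stats::runif(n, 0.10, 0.45)
  if (n >= 2) simd_q1q2[1:2] <- stats::runif(2, 0.55, 0.70)
  simd_q4q5 <- stats::runif(n, 0.05, pmin(0.50, 1 - simd_q1q2 - 0.05))

  if (n >= 3) {
    young <- n - 1
    share_65[young] <- config$young_outlier_share_65_plus
    share_18_64[young] <- clamp(0.90 - share_65[young], 0.55, 0.95)
    q_18_44[young] <- 0.78
    female[young] <- 0.541
    old <- n
    share_65[old] <- config$old_outlier_share_65_plus
    share_18_64[old] <- 0.56
    q_18_44[old] <- 0.30
    female[old] <- 0.481
  }

  share_18_44 <- q_18_44 * (share_18_64 + share_65)
  rate_multiplier <- stats::rlnorm(n, meanlog = -config$practice_rate_sd^2 / 2,
                                   sdlog = config$practice_rate_sd)

  data.frame(practice_id = ids,
             list_size = list_size,
             adult_list_size = round(list_size * (share_18_64 + share_65)),
             share_18_44 = share_18_44,
             share_18_64 = share_18_64,
             share_65_plus = share_65,
             female_share = female,
             simd_q1q2_share = simd_q1q2,
             simd_q4q5_share = simd_q4q5,
             rate_multiplier = rate_multiplier,
             stringsAsFactors = FALSE)
}

# internal: adult age-band composition of a roster row
adult_band_shares <- function(roster_row) {
  adult_frac <- roster_row$share_18_64 + roster_row$share_65_plus
  q1844 <- roster_row$share_18_44 / adult_frac
  q4564 <- (roster_row$share_18_64 - roster_row$share_18_44) / adult_frac
  q65 <- roster_row$share_65_plus / adult_frac
  c("18-24" = 0.25 * q1844, "25-34" = 0.40 * q1844, "35-44" = 0.35 * q1844,
    "45-54" = 0.5 * q4564, "55-64" = 0.5 * q4564, "65+" = q65)
}

#' Generate a synthetic event log
#'
#' Daily site visits per practice are Poisson with mean
#' `daily_visit_rate_per_1000 * adult_list_size / 1000`, scaled by the
#' practice's `rate_multiplier`, a linear within-window trend (normalised
#' to mean 1) and, when `simd_effect` is non-zero, by
#' `1 + simd_effect * (simd_q1q2_share - 0.3)`.  Each visit independently
#' becomes a submission with `conversion_probability`, carries a 24-h
#' unique flag with `unique_visit_probability`, and is diverted to the
#' urgent page with `urgent_divert_probability`.  Submissions draw a
#' broad class from `broad_class_mix`, a sex from the roster composition
#' tilted by `female_usage_odds`, and an age band from the adult roster
#' composition tilted by `age_usage_multipliers`.
#'
#' @param config a [generator_config()].
#' @param rosters a [generate_rosters()] data frame (a `rate_multiplier`
#'   column defaults to 1 if absent).
#' @return Event data frame with columns `practice_id`, `date`, `kind`,
#'   `category`, `sex`, `age_band` (see [read_event_log()]).
#' @export
generate_log <- function(config, rosters) {
  check_that(inherits(config, "generator_config"),
             "'config' must come from generator_config()")
  check_that(nrow(rosters) >= 1, "'rosters' must have at least one practice")
  days <- seq(config$window_start, config$window_end, by = "day")
  check_that(length(days) >= 1, "empty observation window")
  if (is.null(rosters$rate_multiplier)) rosters$rate_multiplier <- 1

  set.seed(config$seed + 1000L)
  trend <- seq(config$trend_range[1], config$trend_range[2],
               length.out = length(days))
  trend <- trend / mean(trend)
  bands <- names(config$age_usage_multipliers)

  out <- vector("list", nrow(rosters))
  for (i in seq_len(nrow(rosters))) {
    row <- rosters[i, ]
    lambda <- config$daily_visit_rate_per_1000 * row$adult_list_size / 1000 *
      row$rate_multiplier *
      max(0, 1 + config$simd_effect * (row$simd_q1q2_share - 0.3)) * trend
    n_day <- stats::rpois(length(days), lambda)
    v <- sum(n_day)
    if (v == 0) next
    vdate <- rep(days, n_day)

    is_unique <- stats::runif(v) < config$unique_visit_probability
    is_divert <- stats::runif(v) < config$urgent_divert_probability
    is_sub <- stats::runif(v) < config$conversion_probability
    ns <- sum(is_sub)

    blank <- function(n) rep("", n)
    ev <- data.frame(
      practice_id = rep(row$practice_id, v),
      date = vdate, kind = rep("site_visit", v),
      category = blank(v), sex = rep("unknown", v),
      age_band = rep("unknown", v), stringsAsFactors = FALSE)
    extra <- list(ev)
    if (any(is_unique)) {
      e <- ev[is_unique, ]; e$kind <- "unique_visit"; extra <- c(extra, list(e))
    }
    if (any(is_divert)) {
      e <- ev[is_divert, ]; e$kind <- "urgent_divert"; extra <- c(extra, list(e))
    }
    if (ns > 0) {
      p_f <- row$female_share / (1 - row$female_share) *
        config$female_usage_odds
      p_f <- p_f / (1 + p_f)
      band_p <- adult_band_shares(row) * config$age_usage_multipliers
      band_p <- band_p / sum(band_p)
      subs <- ev[is_sub, ]
      subs$kind <- "submission"
      subs$category <- sample(names(config$broad_class_mix), ns,
                              replace = TRUE, prob = config$broad_class_mix)
      subs$sex <- ifelse(stats::runif(ns) < p_f, "female", "male")
      subs$age_band <- sample(bands, ns, replace = TRUE, prob = band_p)
      extra <- c(extra, list(subs))
    }
    out[[i]] <- do.call(rbind, extra)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(practice_id = character(), date = as.Date(character()),
                      kind = character(), category = character(),
                      sex = character(), age_band = character(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$practice_id, out$date, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate synthetic survey response counts
#'
#' Each submission in the log yields a survey response with
#' `survey_response_probability`; responders are satisfied with
#' `satisfaction_probability` and would recommend the service with
#' `recommend_probability`.
#'
#' @param events an event log with at least one `submission` row.
#' @param config a [generator_config()].
#' @return List with counts `submissions`, `responses`, `satisfied`,
#'   `recommend`.
#' @export
generate_survey <- function(events, config) {
  check_that(inherits(config, "generator_config"),
             "'config' must come from generator_config()")
  n <- sum(events$kind == "submission")
  check_that(n >= 1, "event log contains no submissions")
  set.seed(config$seed + 2000L)
  responses <- stats::rbinom(1, n, config$survey_response_probability)
  satisfied <- stats::rbinom(1, responses, config$satisfaction_probability)
  recommend <- stats::rbinom(1, responses, config$recommend_probability)
  list(submissions = n, responses = responses,
       satisfied = satisfied, recommend = recommend)
}

#' Write a synthetic pilot dataset to CSV
#'
#' Runs [generate_rosters()], [generate_log()] and [generate_survey()]
#' and writes `rosters.csv`, `events.csv` and `survey.csv` under
#' `out_dir`.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the three objects and the file paths.
#' @export
write_synthetic_dataset <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rosters <- generate_rosters(config)
  events <- generate_log(config, rosters)
  survey <- generate_survey(events, config)
  paths <- file.path(out_dir, c("rosters.csv", "events.csv", "survey.csv"))
  utils::write.csv(rosters, paths[1], row.names = FALSE)
  utils::write.csv(events, paths[2], row.names = FALSE)
  utils::write.csv(as.data.frame(survey), paths[3], row.names = FALSE)
  invisible(list(rosters = rosters, events = events, survey = survey,
                 paths = paths))
}
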