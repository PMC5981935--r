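test_that("conversion rate is submissions over site visits", {
  ev <- make_events(n_visits = 100, n_submissions = 30)
  expect_equal(conversion_rate(ev), 0.30)
  expect_equal(conversion_rate(make_events(n_visits = 50)), 0)
  expect_warning(r <- conversion_rate(make_events(n_submissions = 5)),
                 "undefined")
  expect_true(is.na(r))
  # practice scoping
  ev2 <- rbind(make_events("P01", n_visits = 100, n_submissions = 30),
               make_events("P02", n_visits = 100, n_submissions = 50))
  expect_equal(conversion_rate(ev2, "P02"), 0.50)
  expect_equal(conversion_rate(ev2), 0.40)
})

test_that("annualised submission rate follows the window arithmetic", {
  ev <- make_events(n_submissions = 1000)
  expect_equal(annualised_rate(ev, 24000, 5), 100)  # 0.1 per patient/yr
  expect_equal(annualised_rate(ev, 24000, 12), 1000 * 1000 / 24000)
  # linearity: doubling window with doubled counts leaves the rate fixed
  ev2 <- make_events(n_submissions = 2000)
  expect_equal(annualised_rate(ev2, 24000, 10), annualised_rate(ev, 24000, 5))
  expect_error(annualised_rate(ev, 24000, 0), "window_months")
  expect_error(annualised_rate(ev, 0, 5), "adult_list_size")
})

test_that("demographic shares use known values, reporting unknowns apart", {
  ev <- rbind(make_events(n_submissions = 670, sex = "female"),
              make_events(n_submissions = 330, sex = "male"),
              make_events(n_submissions = 40, sex = "unknown"))
  d <- demographic_shares(ev)
  expect_equal(d$n_submissions, 1040)
  expect_equal(d$female_share, 0.67)  # unknowns not in the denominator
  expect_equal(d$n_sex_known, 1000)
  expect_equal(d$n_sex_unknown, 40)
  # all-unknown: share undefined, unknown count is the total
  d2 <- demographic_shares(make_events(n_submissions = 25))
  expect_true(is.na(d2$female_share))
  expect_equal(d2$n_sex_unknown, 25)
})

test_that("age-band and category shares sum to one over known values", {
  ev <- rbind(make_events(n_submissions = 64, age_band = "25-34",
                          category = "specific_condition"),
              make_events(n_submissions = 36, age_band = "55-64",
                          category = "administrative_help"))
  d <- demographic_shares(ev)
  expect_equal(d$share_18_44, 0.64)
  expect_equal(sum(d$age_band_shares), 1)
  expect_equal(sum(d$category_shares), 1)
  expect_equal(unname(d$category_shares["specific_condition"]), 0.64)
})

test_that("survey proportions reproduce the pilot's printed figures", {
  s <- survey_summary(266, 291, recommend = 266, submissions = 4477)
  sat <- s[s$measure == "satisfaction", ]
  expect_equal(round_half_away(100 * sat$proportion, 1), 91.4)
  expect_true(sat$lower >= 0 && sat$upper <= 1)
  expect_true(sat$lower < sat$proportion && sat$proportion < sat$upper)
  rr <- s[s$measure == "response_rate", ]
  expect_equal(round_half_away(100 * rr$proportion, 1), 6.5)
  # Wilson interval at a zero numerator is one-sided above zero
  z <- survey_summary(0, 50)
  expect_equal(z$proportion, 0)
  expect_equal(z$lower, 0)
  expect_gt(z$upper, 0)
  expect_error(survey_summary(5, 0), "positive count")
})

test_that("deprivation association handles degenerate and monotone cases", {
  rosters <- do.call(rbind, lapply(1:5, function(i) {
    make_roster(sprintf("P%02d", i), simd_q1q2 = i / 10,
                simd_q4q5 = (6 - i) / 10)
  }))
  # constant rates: correlation 0 by convention, flagged degenerate
  flat <- data.frame(practice_id = rosters$practice_id,
                     rate_per_1000_adults = rep(50, 5))
  d <- deprivation_association(flat, rosters)
  expect_true(all(d$degenerate))
  expect_equal(d$rho, c(0, 0))
  expect_true(all(is.na(d$p_value)))
  # rates perfectly rank-ordered with deprivation
  mono <- data.frame(practice_id = rosters$practice_id,
                     rate_per_1000_adults = c(10, 20, 30, 40, 50))
  d2 <- deprivation_association(mono, rosters, n_perm = 999, seed = 1)
  expect_equal(d2$rho[d2$measure == "simd_q1q2_share"], 1)
  expect_equal(d2$rho[d2$measure == "simd_q4q5_share"], -1)
  expect_lt(d2$p_value[1], 0.05)
  # refuses with fewer than three practices
  expect_error(deprivation_association(mono[1:2, ], rosters[1:2, ]),
               "at least 3 practices")
})

test_that("analytics are pure functions of the log on disk", {
  cfg <- generator_config(seed = 11, n_practices = 4,
                          list_size_range = c(3000, 6000))
  ro <- generate_rosters(cfg)
  ev <- generate_log(cfg, ro)
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(ev, tmp, row.names = FALSE)
  ev1 <- read_event_log(tmp)
  ev2 <- read_event_log(tmp)
  m1 <- usage_metrics(ev1, ro, 5)
  m2 <- usage_metrics(ev2, ro, 5)
  expect_identical(m1, m2)
  expect_equal(m1$pooled_conversion_rate, conversion_rate(ev))
  unlink(tmp)
})

test_that("malformed event logs are rejected with named problems", {
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(practice_id = "P01", date = "2017-05-01"),
                   tmp, row.names = FALSE)
  expect_error(read_event_log(tmp), "must have columns")
  utils::write.csv(data.frame(practice_id = "P01", date = "2017-05-01",
                              kind = "teleport", category = "", sex = "",
                              age_band = ""), tmp, row.names = FALSE)
  expect_error(read_event_log(tmp), "kind must be one of")
  unlink(tmp)
  expect_error(read_event_log("no/such/file.csv"), "not found")
})
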