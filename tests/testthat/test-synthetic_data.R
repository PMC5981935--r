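test_that("identical seed and config give byte-identical output", {
  cfg <- generator_config(seed = 5, n_practices = 6,
                          list_size_range = c(4000, 8000))
  ro1 <- generate_rosters(cfg)
  ro2 <- generate_rosters(cfg)
  expect_identical(ro1, ro2)
  ev1 <- generate_log(cfg, ro1)
  ev2 <- generate_log(cfg, ro2)
  expect_identical(ev1, ev2)
  sv1 <- generate_survey(ev1, cfg)
  expect_identical(sv1, generate_survey(ev2, cfg))
  # a different seed changes the data
  cfg2 <- generator_config(seed = 6, n_practices = 6,
                           list_size_range = c(4000, 8000))
  expect_false(identical(ro1, generate_rosters(cfg2)))
  expect_false(identical(ev1, generate_log(cfg2, generate_rosters(cfg2))))
})

test_that("generated rosters are valid practice profiles", {
  cfg <- generator_config(seed = 1)
  ro <- generate_rosters(cfg)
  expect_equal(nrow(ro), 11)
  expect_equal(anyDuplicated(ro$practice_id), 0)
  shares <- c("share_18_44", "share_18_64", "share_65_plus", "female_share",
              "simd_q1q2_share", "simd_q4q5_share")
  for (sh in shares) expect_true(all(ro[[sh]] >= 0 & ro[[sh]] <= 1))
  expect_true(all(ro$share_18_64 + ro$share_65_plus <= 1))
  expect_true(all(ro$share_18_44 <= ro$share_18_64))
  expect_true(all(ro$adult_list_size <= ro$list_size))
  expect_true(all(ro$simd_q1q2_share + ro$simd_q4q5_share <= 1))
  # the configured outlier shares are carried exactly
  expect_true(0.023 %in% ro$share_65_plus)
  expect_true(0.281 %in% ro$share_65_plus)
  forced <- generator_config(seed = 1, old_outlier_share_65_plus = 0.30)
  expect_true(0.30 %in% generate_rosters(forced)$share_65_plus)
  # round trip through the roster reader validates
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(ro, tmp, row.names = FALSE)
  expect_silent(read_rosters(tmp))
  unlink(tmp)
})

test_that("zero conversion yields visits but no submissions", {
  cfg <- generator_config(seed = 2, n_practices = 3,
                          list_size_range = c(4000, 8000),
                          conversion_probability = 0)
  ev <- generate_log(cfg, generate_rosters(cfg))
  expect_gt(sum(ev$kind == "site_visit"), 0)
  expect_equal(sum(ev$kind == "submission"), 0)
  expect_error(generate_survey(ev, cfg), "no submissions")
})

test_that("pooled conversion is recovered within exact binomial bounds", {
  cfg <- generator_config(seed = 9, list_size_range = c(18000, 30000))
  ev <- generate_log(cfg, generate_rosters(cfg))
  visits <- sum(ev$kind == "site_visit")
  subs <- sum(ev$kind == "submission")
  expect_gte(visits, 10000)
  ci <- stats::binom.test(subs, visits)$conf.int
  expect_gte(0.30, ci[1])
  expect_lte(0.30, ci[2])
})

test_that("a high-conversion practice profile is recovered too", {
  cfg <- generator_config(seed = 12, n_practices = 3,
                          list_size_range = c(8000, 12000),
                          conversion_probability = 0.46)
  ev <- generate_log(cfg, generate_rosters(cfg))
  visits <- sum(ev$kind == "site_visit")
  expect_gte(visits, 2000)
  ci <- stats::binom.test(sum(ev$kind == "submission"), visits)$conf.int
  expect_true(ci[1] <= 0.46 && 0.46 <= ci[2])
})

test_that("the growth ramp concentrates visits late in the window", {
  cfg <- generator_config(seed = 8, n_practices = 4,
                          list_size_range = c(8000, 12000))
  ev <- generate_log(cfg, generate_rosters(cfg))
  visits <- ev[ev$kind == "site_visit", ]
  mid <- cfg$window_start + as.integer(cfg$window_end - cfg$window_start) / 2
  early <- sum(visits$date <= mid)
  late <- sum(visits$date > mid)
  expect_gt(late, 1.5 * early)  # trend 0.5 -> 1.5 implies roughly 5:3
  # a flat trend shows no such imbalance
  flat <- generator_config(seed = 8, n_practices = 4,
                           list_size_range = c(8000, 12000),
                           trend_range = c(1, 1))
  vf <- generate_log(flat, generate_rosters(flat))
  vf <- vf[vf$kind == "site_visit", ]
  expect_lt(abs(sum(vf$date > mid) / nrow(vf) - 0.5), 0.05)
})

test_that("visit volume scales with the configured daily rate", {
  base <- generator_config(seed = 4, n_practices = 4,
                           list_size_range = c(5000, 9000))
  dbl <- generator_config(seed = 4, n_practices = 4,
                          list_size_range = c(5000, 9000),
                          daily_visit_rate_per_1000 = 2 *
                            base$daily_visit_rate_per_1000)
  v1 <- sum(generate_log(base, generate_rosters(base))$kind == "site_visit")
  v2 <- sum(generate_log(dbl, generate_rosters(dbl))$kind == "site_visit")
  expect_gt(v2 / v1, 1.8)
  expect_lt(v2 / v1, 2.2)
})

test_that("annualised submission rates are recovered across 20 seeds", {
  # recovered pooled rate (month-annualised) should match the generator's
  # implied expectation: rate/1000 * conv * n_days * 12/window_months
  ratios <- vapply(1:20, function(seed) {
    cfg <- generator_config(seed = seed, n_practices = 5,
                            list_size_range = c(8000, 12000))
    ro <- generate_rosters(cfg)
    ev <- generate_log(cfg, ro)
    n_days <- as.integer(cfg$window_end - cfg$window_start) + 1
    expected_rate <- cfg$daily_visit_rate_per_1000 *
      cfg$conversion_probability * n_days * (12 / 5) *
      sum(ro$adult_list_size * ro$rate_multiplier) / sum(ro$adult_list_size)
    um <- usage_metrics(ev, ro, window_months = 5)
    um$pooled_rate_per_1000_adults / expected_rate
  }, numeric(1))
  expect_equal(mean(ratios), 1, tolerance = 0.02)
  expect_true(all(abs(ratios - 1) < 0.1))
})

test_that("survey counts track the response and satisfaction rates", {
  cfg <- generator_config(seed = 10, list_size_range = c(18000, 30000))
  ev <- generate_log(cfg, generate_rosters(cfg))
  sv <- generate_survey(ev, cfg)
  expect_equal(sv$submissions, sum(ev$kind == "submission"))
  ci <- stats::binom.test(sv$responses, sv$submissions)$conf.int
  expect_gte(0.065, ci[1])
  expect_lte(0.065, ci[2])
  ci_sat <- stats::binom.test(sv$satisfied, sv$responses)$conf.int
  expect_gte(0.914, ci_sat[1])
  expect_lte(0.914, ci_sat[2])
  # degenerate boundaries
  all_cfg <- generator_config(seed = 10, n_practices = 2,
                              list_size_range = c(3000, 5000),
                              survey_response_probability = 1,
                              satisfaction_probability = 1)
  ev2 <- generate_log(all_cfg, generate_rosters(all_cfg))
  sv2 <- generate_survey(ev2, all_cfg)
  expect_equal(sv2$responses, sv2$submissions)
  expect_equal(sv2$satisfied, sv2$responses)
  none_cfg <- generator_config(seed = 10, n_practices = 2,
                               list_size_range = c(3000, 5000),
                               survey_response_probability = 0)
  sv3 <- generate_survey(ev2, none_cfg)
  expect_equal(sv3$responses, 0)
})

test_that("written synthetic datasets read back through the analytics", {
  cfg <- generator_config(seed = 3, n_practices = 4,
                          list_size_range = c(4000, 8000))
  out <- file.path(tempdir(), "synth-test")
  res <- write_synthetic_dataset(cfg, out)
  ev <- read_event_log(file.path(out, "events.csv"))
  ro <- read_rosters(file.path(out, "rosters.csv"))
  expect_equal(nrow(ev), nrow(res$events))
  expect_equal(conversion_rate(ev), conversion_rate(res$events))
  expect_equal(ro$practice_id, res$rosters$practice_id)
  unlink(out, recursive = TRUE)
})
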