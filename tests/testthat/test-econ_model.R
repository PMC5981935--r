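# frozen published money table: s (percent), admin, GP, total savings in
# GBP per eConsult at 1 dp
published_savings <- data.frame(
  s_pct = c(74, 72, 70, 68, 66, 64, 62, 60),
  admin = c(-1.0, -1.0, -1.1, -1.1, -1.1, -1.1, -1.1, -1.1),
  gp    = c( 2.4,  2.0,  1.7,  1.4,  1.1,  0.8,  0.5,  0.1),
  total = c( 1.3,  1.0,  0.7,  0.3,  0.0, -0.3, -0.7, -1.0))

test_that("savings over the default grid reproduce the published table", {
  tab <- format_savings_table(savings_table())
  expect_equal(tab$gp_appointments_saved_pct, published_savings$s_pct)
  expect_equal(tab$admin_saving_gbp, published_savings$admin)
  expect_equal(tab$gp_saving_gbp, published_savings$gp)
  expect_equal(tab$total_saving_gbp, published_savings$total)
})

test_that("zero replacement is pure added processing cost", {
  sv <- savings_per_econsult(s = 0)
  expect_equal(sv$admin_saving, -5.67 * 17.82 / 60, tolerance = 1e-12)
  expect_equal(sv$gp_saving, -5.9125 * 95.08 / 60, tolerance = 1e-12)
  expect_lt(sv$total_saving, 0)
})

test_that("total equals admin plus GP and all components increase in s", {
  grid <- seq(0, 1, by = 0.01)
  tab <- savings_table(s_values = grid)
  expect_equal(tab$total_saving, tab$admin_saving + tab$gp_saving,
               tolerance = 0)  # exact at full precision
  expect_true(all(diff(tab$admin_saving) > 0))
  expect_true(all(diff(tab$gp_saving) > 0))
  expect_true(all(diff(tab$total_saving) > 0))
  # breakeven strictly decreases wherever defined
  be <- tab$breakeven_rate[!is.na(tab$breakeven_rate)]
  expect_true(all(diff(be) < 0))
})

test_that("total saving crosses zero exactly once, between 66% and 68%", {
  f <- function(s) savings_per_econsult(s = s)$total_saving
  grid <- seq(0, 1, by = 0.005)
  signs <- sign(vapply(grid, f, numeric(1)))
  expect_equal(sum(diff(signs) != 0), 1)  # one sign change on [0, 1]
  expect_lt(f(0.66), 0)
  expect_gt(f(0.68), 0)
  root <- stats::uniroot(f, c(0.66, 0.68), tol = 1e-12)$root
  expect_gt(root, 0.66)
  expect_lt(root, 0.68)
})

test_that("total saving is affine in s with the closed-form slope", {
  slope <- (3 * 17.82 + 10 * 95.08) / 60
  grid <- seq(0, 1, length.out = 100)
  tot <- savings_table(s_values = grid)$total_saving
  expect_equal(diff(tot) / diff(grid), rep(slope, 99), tolerance = 1e-9)
})

test_that("breakeven rate is consistent with the annual charge", {
  costs <- cost_parameters()
  for (s in seq(0.68, 1, by = 0.04)) {
    sv <- savings_per_econsult(costs = costs, s = s)
    be <- breakeven_rate(sv, costs)
    expect_true(be$defined)
    expect_equal(be$rate * sv$total_saving, costs$annual_charge_per_patient,
                 tolerance = 1e-9)
  }
  # headline case: about 0.54 submissions per patient per year
  be73 <- breakeven_rate(savings_per_econsult(s = 0.73))
  expect_gt(be73$rate, 0.5)
  expect_equal(round_half_away(be73$rate, 2), 0.54)
  # free service breaks even at zero submissions
  free <- cost_parameters(annual_charge_per_patient = 0)
  expect_equal(breakeven_rate(savings_per_econsult(costs = free, s = 0.73),
                              free)$rate, 0)
  # non-positive saving: no breakeven, flagged rather than infinite
  be60 <- breakeven_rate(savings_per_econsult(s = 0.60))
  expect_false(be60$defined)
  expect_true(is.na(be60$rate))
})

test_that("admin-timing sensitivity matches a direct recomputation oracle", {
  base <- savings_per_econsult(s = 0.73)
  sw <- sensitivity_sweep(perturbation = 0.2, s = 0.73)
  # scaling eConsult-side admin only: expected admin minutes scale by 1.2,
  # so the saving drops by 0.2 * E[admin] * rate / 60
  d1 <- sw$delta_total[sw$variant == "econsult_admin_only"]
  expect_equal(d1, -0.2 * 5.67 * 17.82 / 60, tolerance = 1e-12)
  # scaling all admin tasks also scales the avoided booking call
  d2 <- sw$delta_total[sw$variant == "all_admin"]
  expect_equal(d2, d1 + 0.2 * 0.73 * 3 * 17.82 / 60, tolerance = 1e-12)
  # the admin perturbation is small relative to the GP component
  expect_true(all(abs(sw$delta_total) < abs(base$gp_saving) / 5))
  # zero perturbation is the identity in both variants
  sw0 <- sensitivity_sweep(perturbation = 0, s = 0.73)
  expect_equal(sw0$total_saving, rep(base$total_saving, 2), tolerance = 1e-12)
  expect_equal(sw0$delta_total, c(0, 0), tolerance = 1e-12)
})

test_that("savings scale linearly in the hourly rates", {
  sv <- savings_per_econsult(s = 0.73)
  doubled <- cost_parameters(gp_cost_per_hour = 2 * 95.08)
  sv2 <- savings_per_econsult(costs = doubled, s = 0.73)
  expect_equal(sv2$gp_saving, 2 * sv$gp_saving, tolerance = 1e-12)
  expect_equal(sv2$admin_saving, sv$admin_saving, tolerance = 1e-12)
})

test_that("domain errors are raised for invalid fractions", {
  expect_error(savings_per_econsult(s = 1.2), "\\[0, 1\\]")
  expect_error(savings_per_econsult(s = -0.1), "\\[0, 1\\]")
  expect_error(sensitivity_sweep(perturbation = -1), "\\(-1, 1\\)")
  expect_error(savings_table(s_values = numeric(0)), "non-empty")
})
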