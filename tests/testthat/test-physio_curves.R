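test_that("GFR quadratic evaluates, peaks and guards as expected", {
  g <- gfr_quadratic()
  expect_equal(eval_gfr(g, 0), 99.04)
  expect_equal(eval_gfr(g, 27.08),
               -0.077 * 27.08^2 + 4.17 * 27.08 + 99.04)
  expect_equal(eval_gfr(g, 27.08), 155.5, tolerance = 1e-3)
  expect_equal(eval_gfr(gfr_quadratic(0, 0, 100), 13.7), 100)

  pk <- gfr_peak(g)
  expect_equal(pk$peak_week, -4.17 / (2 * -0.077))
  expect_equal(gfr_peak(gfr_quadratic(-1, 10, 25))$peak_week, 5)
  expect_error(gfr_peak(gfr_quadratic(0.01, 1, 50)), "interior maximum")

  # peak dominates a dense grid
  grid <- seq(0, 42, by = 0.1)
  expect_true(all(eval_gfr(g, pk$peak_week) >= eval_gfr(g, grid)))

  expect_error(eval_gfr(g, 60), "range")
  expect_error(eval_gfr(gfr_quadratic(-1, 0, 5), 40), "degenerate")
})

test_that("plasma-volume sigmoid evaluates per the printed form", {
  pv <- plasma_volume_sigmoid()
  expect_equal(eval_plasma_volume(pv, 9.2), 796.2 / (0.62 + 4.4) + 2378)
  # sign-independence at the centering week
  pv_neg <- plasma_volume_sigmoid(sign = -1)
  expect_equal(eval_plasma_volume(pv_neg, 9.2), eval_plasma_volume(pv, 9.2))
  # num = 0 collapses to the offset
  expect_equal(eval_plasma_volume(plasma_volume_sigmoid(num = 0), 20), 2378)
  # printed (positive) sign: late-gestation limit approaches the offset
  expect_equal(eval_plasma_volume(pv, 42), 2378, tolerance = 1e-2)
  expect_error(plasma_volume_sigmoid(d0 = -1), "positive")
})

test_that("fractional plasma mass: ratio, line and physiological guard", {
  expect_equal(compute_fpm(0.5, 2.0), 0.25)
  expect_equal(compute_fpm(1.7, 1.7), 1.0)
  expect_error(compute_fpm(0.3, 0), "baseline")

  l <- fpm_line()
  expect_equal(eval_fpm(l, 0), 0.32)
  expect_equal(eval_fpm(l, 20), 0.20)
  expect_equal(eval_fpm(fpm_line(0, 0.3), 35), 0.3)
  expect_error(eval_fpm(fpm_line(-0.02, 0.32), 40), "non-physiological")
  expect_error(eval_fpm(fpm_line(0.1, 0.9), 20), "non-physiological")
})

test_that("r_squared matches its definition", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2), c(1, 3)), "variance")
})

test_that("quadratic GFR fit recovers generating coefficients", {
  g <- gfr_quadratic()
  coh <- generate_cohort(cohort_spec("gfr", noise_sd = 0, seed = 1))
  fit <- fit_gfr_quadratic(coh)
  expect_equal(fit$curve$a2, g$a2, tolerance = 1e-8)
  expect_equal(fit$curve$a1, g$a1, tolerance = 1e-8)
  expect_equal(fit$curve$a0, g$a0, tolerance = 1e-8)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  # constant data give the constant curve
  const <- longitudinal_series(data.frame(
    subject_id = "s1", group = "normal", week = c(0, 10, 20, 30),
    variable = "gfr", value = 120, sd = NA_real_))
  cfit <- fit_gfr_quadratic(const)
  expect_equal(cfit$curve$a2, 0, tolerance = 1e-12)
  expect_equal(cfit$curve$a1, 0, tolerance = 1e-12)
  expect_equal(cfit$curve$a0, 120)

  two <- longitudinal_series(data.frame(
    subject_id = "s1", group = "normal", week = c(0, 16),
    variable = "gfr", value = c(99, 150), sd = NA_real_))
  expect_error(fit_gfr_quadratic(two), "underdetermined")

  # at cohort noise the fit stays within sampling error of truth
  noisy <- fit_gfr_quadratic(generate_cohort(cohort_spec("gfr", seed = 11)))
  expect_lt(noisy$r2, 1)
  wk <- c(0, 16, 26, 36)
  expect_true(all(abs(eval_gfr(noisy$curve, wk) - eval_gfr(g, wk)) <
                    3 * 21.2 / sqrt(25)))
})

test_that("sigmoid plasma-volume fit recovers the generating curve", {
  truth <- plasma_volume_sigmoid(sign = -1)
  coh <- generate_cohort(cohort_spec("plasma_volume", noise_sd = 0, seed = 1))
  fit <- fit_plasma_volume_sigmoid(coh, init = truth)
  for (nm in c("num", "d0", "d1", "rate", "t_mid", "offset")) {
    expect_equal(fit$curve[[nm]], truth[[nm]], tolerance = 1e-4)
  }
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  few <- longitudinal_series(data.frame(
    subject_id = "s1", group = "normal", week = c(0, 10, 20, 30, 38),
    variable = "plasma_volume", value = c(2600, 2900, 3100, 3150, 3160),
    sd = NA_real_))
  expect_error(fit_plasma_volume_sigmoid(few), "underdetermined")

  # at cohort noise (SD 52.3 mL) the fitted curve stays within 1 SD of truth
  sp <- cohort_spec("plasma_volume", seed = 7)
  nf <- fit_plasma_volume_sigmoid(generate_cohort(sp),
                                  init = plasma_volume_sigmoid(sign = -1))
  devs <- abs(eval_plasma_volume(nf$curve, sp$weeks) -
                eval_plasma_volume(sp$truth, sp$weeks))
  expect_true(all(devs < 52.3))
})

test_that("fractional-plasma-mass line fit excludes week 0 and recovers truth", {
  coh <- generate_cohort(cohort_spec("body_composition", noise_sd = 0,
                                     seed = 3))
  fit <- fit_fpm_line(coh)
  expect_equal(fit$line$slope, -0.006, tolerance = 1e-10)
  expect_equal(fit$line$intercept, 0.32, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)

  # two points: exact interpolating line
  two <- longitudinal_series(data.frame(
    subject_id = "s1", group = "normal", week = c(10, 20, 10, 20),
    variable = rep(c("plasma_mass_gain", "total_mass_gain"), each = 2),
    value = c(1, 1.5, 4, 10), sd = NA_real_))
  f2 <- fit_fpm_line(two)
  expect_equal(f2$line$slope, -0.01)   # fractions 0.25 @ wk10, 0.15 @ wk20
  expect_equal(f2$line$intercept, 0.35)
  expect_equal(f2$r2, 1)

  # adding a week-0 record that would be degenerate leaves the fit unchanged
  # (week 0 rows are excluded before the ratio is formed)
  with0 <- longitudinal_series(rbind(
    two$records,
    data.frame(subject_id = "s1", group = "normal", week = 0,
               variable = c("plasma_mass_gain", "total_mass_gain"),
               value = c(0, 0), sd = NA_real_)))
  f0 <- fit_fpm_line(with0)
  expect_equal(f0$line, f2$line)

  one <- longitudinal_series(data.frame(
    subject_id = "s1", group = "normal", week = c(10, 10),
    variable = c("plasma_mass_gain", "total_mass_gain"),
    value = c(1, 4), sd = NA_real_))
  expect_error(fit_fpm_line(one), "underdetermined")
})
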