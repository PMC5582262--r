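test_that("sse matches hand arithmetic and rejects empty observations", {
  weeks <- c(10, 20, 30)
  p <- kinetic_params()
  tr <- trajectory(weeks, p)
  truth <- data.frame(week = weeks, mean = tr$concentration)
  expect_equal(sse(tr, truth), 0)
  one <- data.frame(week = 20, mean = tr$concentration[2] + 2)
  expect_equal(sse(tr, one), 4)
  three <- data.frame(week = weeks,
                      mean = tr$concentration - c(1, -2, 3))
  expect_equal(sse(tr, three), 14)
  expect_error(sse(tr, truth[0, ]), "empty")
  expect_error(sse(tr, data.frame(week = 15, mean = 10)), "grid")
})

test_that("variant defaults encode the six model variants", {
  na <- variant_defaults("normal_adjusted")
  expect_length(na$free, 0)
  expect_equal(na$fixed$k_i, 5)
  expect_equal(na$fixed$a, 0.9984)
  expect_equal(na$fixed$b, 0)
  expect_equal(na$tol, 1e-5)

  expect_setequal(variant_defaults("normal_bestfit")$free, c("k_i", "a"))
  expect_setequal(variant_defaults("normal_bestfit_rtime")$free,
                  c("k_i", "a", "b"))

  da <- variant_defaults("diabetic_adjusted")
  expect_equal(da$fixed$glucose, 8.9)
  expect_equal(da$reabs_model, "stickle")

  db <- variant_defaults("diabetic_bestfit")
  expect_setequal(db$free, c("k_i", "glucose"))
  expect_equal(db$reabs_model, "stickle")

  dr <- variant_defaults("diabetic_bestfit_rtime")
  expect_equal(dr$fixed$k_i, 5)
  expect_equal(dr$fixed$c, 0.0026)
  expect_setequal(dr$free, c("a", "b", "glucose"))

  expect_error(variant_defaults("bogus"))
})

test_that("an all-fixed spec is evaluated, not optimised", {
  obs <- obs_means(kinetic_params())
  fit <- calibrate(obs, variant_defaults("normal_adjusted"))
  expect_true(fit$converged)
  expect_equal(fit$n_eval, 1L)
  expect_equal(fit$estimates$k_i, 5)
  # the data were generated at exactly these defaults, so sse is zero
  expect_equal(fit$sse, 0, tolerance = 1e-20)
})

test_that("jointly free c and glucose are refused as unidentifiable", {
  spec <- fit_spec("diabetic_bestfit_rtime", free = c("c", "glucose"),
                   fixed = list(k_i = 5, a = 0.997, b = 0),
                   init = list(k_i = 5, a = 0.997, b = 0, c = 0.0026,
                               glucose = 8.9))
  expect_error(calibrate(obs_means(truth_diabetic_rtime()), spec),
               "identifiable")
})

test_that("calibration drives sse to the floor and recovers identified
           parameter combinations", {
  truth <- truth_normal_rtime()
  obs <- obs_means(truth)
  fit <- calibrate(obs, variant_defaults("normal_bestfit_rtime"))
  expect_true(fit$converged)
  expect_lt(fit$sse, 1e-10)
  # the trajectory determines k_i/(1-a) and b/(1-a); both are recovered
  est <- fit$estimates
  expect_equal(est$k_i / (1 - est$a), 5.16 / (1 - 0.99825),
               tolerance = 1e-6)
  expect_equal(est$b / (1 - est$a), 5.78e-5 / (1 - 0.99825),
               tolerance = 1e-5)
  # a itself is pinned tightly because it is close to 1
  expect_equal(est$a, 0.99825, tolerance = 1e-2)

  # a single identifiable free parameter is recovered outright
  spec1 <- fit_spec("normal_bestfit", free = "k_i",
                    fixed = list(a = 0.99825, b = 5.78e-5, c = 0.0026,
                                 glucose = 5),
                    init = list(k_i = 2, a = 0.99825, b = 5.78e-5,
                                c = 0.0026, glucose = 5))
  f1 <- calibrate(obs, spec1)
  expect_equal(f1$estimates$k_i, 5.16, tolerance = 1e-6)
})

test_that("an initialization at the optimum is kept (flat-ridge tie-break)", {
  truth <- truth_normal_rtime()
  obs <- obs_means(truth)
  spec <- fit_spec("normal_bestfit_rtime", free = c("k_i", "a", "b"),
                   fixed = list(c = 0.0026, glucose = 5),
                   init = list(k_i = 5.16, a = 0.99825, b = 5.78e-5,
                               c = 0.0026, glucose = 5))
  fit <- calibrate(obs, spec)
  expect_equal(fit$estimates$k_i, 5.16)
  expect_equal(fit$estimates$a, 0.99825)
  expect_equal(fit$estimates$b, 5.78e-5)
  expect_equal(fit$sse, 0, tolerance = 1e-18)
})

test_that("diabetic gestational variant recovers b and the identified
           clearance offset", {
  truth <- truth_diabetic_rtime(c = 0.00029)
  obs <- obs_means(truth)
  spec <- fit_spec("diabetic_bestfit_rtime", free = c("a", "b", "glucose"),
                   fixed = list(k_i = 5, c = 0.00029),
                   init = list(k_i = 5, a = 0.9984, b = 1e-4, c = 0.00029,
                               glucose = 8.9))
  fit <- calibrate(obs, spec)
  expect_lt(fit$sse, 1e-10)
  est <- fit$estimates
  # k_i fixed pins the scale: b and (1-a)+c*[G] are both identified
  expect_equal(est$b, 5.78e-5, tolerance = 1e-4)
  g_term <- function(a, g) (1 - a) + 0.00029 * g * (g > 7.4)
  expect_equal(g_term(est$a, est$glucose), g_term(0.997, 9.5),
               tolerance = 1e-6)
})

test_that("calibration is invariant to row order and to added freedom", {
  set.seed(42)
  weeks <- seq(6, 38, by = 2)
  truth <- truth_normal_rtime()
  noisy <- data.frame(week = weeks,
                      mean = steady_state_closed_form(weeks, truth) +
                        rnorm(length(weeks), 0, 0.5))
  spec <- variant_defaults("normal_bestfit")
  f_fwd <- calibrate(noisy, spec)
  f_rev <- calibrate(noisy[rev(seq_len(nrow(noisy))), ], spec)
  expect_equal(f_fwd$estimates, f_rev$estimates)
  expect_equal(f_fwd$sse, f_rev$sse)

  # sse never increases relative to the starting point
  init_traj <- trajectory(weeks, kinetic_params(k_i = 5, reabs =
    reabsorption_params(a = 0.9984, b = 0)))
  expect_lte(f_fwd$sse, sum((init_traj$concentration - noisy$mean)^2))

  # freeing a superset cannot do worse on the same data
  f_super <- calibrate(noisy, variant_defaults("normal_bestfit_rtime"))
  expect_lte(f_super$sse, f_fwd$sse + 1e-8)
})

test_that("estimates respect their bounds", {
  truth <- truth_normal_rtime()
  obs <- obs_means(truth)
  fit <- calibrate(obs, variant_defaults("normal_bestfit_rtime"))
  for (nm in fit$spec$free) {
    bd <- fit$spec$bounds[[nm]]
    expect_gte(fit$estimates[[nm]], bd[1])
    expect_lte(fit$estimates[[nm]], bd[2])
  }
})
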