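test_that("ensemble CIs drop the prescribed tail counts", {
  expect_equal(unname(ci_from_ensemble(1:1000, 83.4)), c(84, 917))   # 83 per end
  expect_equal(unname(ci_from_ensemble(1:1000, 95)), c(26, 975))     # 25 per end
  expect_equal(unname(ci_from_ensemble(1:100, 90)), c(6, 95))
  expect_error(ci_from_ensemble(1:100, 0), "level")
  expect_error(ci_from_ensemble(1:100, 100), "level")

  # width is non-decreasing in the level
  set.seed(4)
  x <- stats::rnorm(500)
  widths <- vapply(c(50, 70, 83.4, 90, 95, 99), function(l) {
    diff(ci_from_ensemble(x, l))
  }, 1)
  expect_true(all(diff(widths) >= 0))
})

test_that("the CI-equivalence level is 83.4% at equal variance and tends to 95%", {
  expect_equal(round(adjusted_level(1), 1), 83.4)
  expect_equal(round(adjusted_level(1e8), 1), 95.0)
  expect_equal(adjusted_level(2), adjusted_level(0.5))  # symmetry in rho <-> 1/rho
  expect_true(all(diff(adjusted_level(c(1, 2, 5, 20, 100))) > 0))
  expect_error(adjusted_level(0), "positive")
})

test_that("profile walk recovers the closed-form quadratic interval", {
  # SSR(theta) = ((theta - 2) / 0.5)^2: 95% bound where SSR = qchisq(.95, 1)
  refit <- function(v, warm) list(ssr = ((v - 2) / 0.5)^2, warm = NULL)
  thr <- stats::qchisq(0.95, 1)
  up <- profile_walk(refit, 2, 0, thr, step = 0.15, direction = 1)
  dn <- profile_walk(refit, 2, 0, thr, step = 0.15, direction = -1)
  expect_equal(up$bound, 2 + 0.5 * 1.96, tolerance = 5e-3)
  expect_equal(dn$bound, 2 - 0.5 * 1.96, tolerance = 5e-3)

  # structurally flat profile: unbounded interval, not an error
  flat <- profile_walk(function(v, warm) list(ssr = 0, warm = NULL),
                       2, 0, thr, step = 0.5, direction = 1, max_steps = 10)
  expect_equal(flat$bound, Inf)
})

test_that("continuation on a fitted model brackets the truth and finds improvements", {
  d <- washout_data(v = 1, P = 2, noise = 0.008, seed = 17)
  pr <- fit_problem(toy_washout_model(), d, error_model(0.8, 0.8),
                    flux_measurements = washout_fmeas())
  fit <- fit_fluxes(pr, n_starts = 3, seed = 17)
  ci <- continuation_ci(fit, "net.vin")
  expect_true(is.finite(ci$interval["lower"]) && is.finite(ci$interval["upper"]))
  expect_gt(1, ci$interval["lower"])
  expect_lt(1, ci$interval["upper"])

  # a deliberately bad incumbent is replaced during continuation
  bad <- fit
  bad$theta <- to_internal(c(1.35, 2.6), pr$pars)
  bad$ssr <- sum(fit_residuals(pr, bad$theta)^2)
  ci2 <- continuation_ci(bad, "net.vin")
  expect_gte(ci2$restarts, 1)
  expect_lte(ci2$fit$ssr, fit$ssr + 1e-3)
})

test_that("Monte Carlo refits concentrate at the best fit when noise vanishes", {
  d <- washout_data(v = 1, P = 2, noise = 0.01, seed = 19)
  pr <- fit_problem(toy_washout_model(), d, error_model(1.2, 1.2),
                    flux_measurements = washout_fmeas())
  fit <- fit_fluxes(pr, n_starts = 2, seed = 19)
  mc <- monte_carlo(fit, n = 5, seed = 19, noise_scale = 0)
  expect_equal(nrow(mc$samples), 5)
  for (j in seq_len(ncol(mc$samples))) {
    expect_lt(max(abs(mc$samples[, j] - fit$params[j])), 1e-4)
  }
})

test_that("Monte Carlo spread matches the linearized (delta-method) standard error", {
  d <- washout_data(v = 1, P = 2, noise = 0.012, seed = 23)
  em <- error_model(1.2, 1.2)
  pr <- fit_problem(toy_washout_model(), d, em,
                    flux_measurements = washout_fmeas())
  fit <- fit_fluxes(pr, n_starts = 3, seed = 23)
  mc <- monte_carlo(fit, n = 60, seed = 23)

  # independent linearization at the best fit: J on the internal scale
  th <- fit$theta
  r0 <- fit_residuals(pr, th)
  J <- vapply(seq_along(th), function(j) {
    h <- 1e-6 * (1 + abs(th[j]))
    thp <- th; thp[j] <- th[j] + h
    (fit_residuals(pr, thp) - r0) / h
  }, numeric(length(r0)))
  cov_int <- solve(crossprod(J))
  # transform to the natural scale of net.vin (log parameterization)
  j <- match("net.vin", pr$pars$parameter)
  sd_lin <- sqrt(cov_int[j, j]) * fit$params[j]
  sd_mc <- stats::sd(mc$samples[, "net.vin"])
  expect_lt(abs(sd_mc - sd_lin) / sd_lin, 0.25)

  # 1000-round call shape: rows = rounds (run a tiny slice to keep it fast)
  expect_equal(nrow(mc$samples) + nrow(mc$failures), 60)
})

test_that("continuation and Monte Carlo intervals agree on the washout problem", {
  d <- washout_data(v = 1, P = 2, noise = 0.012, seed = 29)
  pr <- fit_problem(toy_washout_model(), d, error_model(1.2, 1.2),
                    flux_measurements = washout_fmeas())
  fit <- fit_fluxes(pr, n_starts = 3, seed = 29)
  mc <- monte_carlo(fit, n = 100, seed = 29)
  cont <- continuation_ci(fit, "net.vin")
  ci_mc <- ci_from_ensemble(mc$samples[, "net.vin"], 95)
  hw_cont <- diff(cont$interval) / 2
  hw_mc <- diff(ci_mc) / 2
  expect_lt(abs(hw_cont - hw_mc) / hw_mc, 0.35)
})

test_that("condition comparison flags separations and respects symmetry", {
  set.seed(31)
  A <- cbind(a = stats::rnorm(1000), b = stats::rnorm(1000))
  B_same <- cbind(a = stats::rnorm(1000), b = stats::rnorm(1000))
  B_far <- cbind(a = stats::rnorm(1000, 10), b = stats::rnorm(1000))
  none <- compare_conditions(A, A)
  expect_false(any(none$significant))
  far <- compare_conditions(A, B_far)
  expect_true(far$significant[far$parameter == "a"])
  expect_false(far$significant[far$parameter == "b"])
  # symmetric in argument order
  swapped <- compare_conditions(B_far, A)
  expect_equal(swapped$significant, far$significant)
  expect_equal(swapped$level, far$level)
  # equal-variance null pairs compare at (or only slightly above) 83.4%
  lv <- compare_conditions(A, B_same)$level
  expect_true(all(lv >= 83.4 & lv < 95))
  expect_error(compare_conditions(A, B_far, parameters = "zz"), "absent")
})
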