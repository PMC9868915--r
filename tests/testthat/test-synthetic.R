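test_that("generated experiments are reproducible and noise-free tables equal the simulator", {
  des <- experiment_design(seed = 5, replicates = 2)
  d1 <- generate_experiment(des)
  d2 <- generate_experiment(des)
  expect_equal(d1, d2, ignore_attr = TRUE)

  d0 <- generate_experiment(des, noise = FALSE)
  sim <- simulate_mids(des$model, des$truth, des$times, mixing = des$mixing,
                       substrate = instmfa:::design_substrate(des), grid_n = 150)
  one <- d0[d0$replicate == 1 & d0$metabolite == "G6P", ]
  ref <- sim[sim$observable == "G6P", ]
  expect_equal(one$value, ref$fraction)
  # bounded raw-measurement mode keeps every noisy MID normalized
  dc <- generate_experiment(des, clamp = TRUE)
  sums <- dc |>
    dplyr::group_by(metabolite, time_min, replicate) |>
    dplyr::summarise(s = sum(value), .groups = "drop")
  expect_lt(max(abs(sums$s - 1)), 1e-12)
  expect_true(all(dc$value >= 0))
  # corrected-MID default: untruncated noise leaves the mean unbiased at
  # near-zero channels (small negatives allowed)
  expect_true(any(d1$value < 0))
  # invalid designs are rejected
  expect_error(experiment_design(times = c(1, 2)), "start at 0")
  expect_error(experiment_design(error_model = error_model(60, 60)), "50 mol%")

  # tidy TSV export round-trips
  tsv <- tempfile(fileext = ".tsv")
  write_timecourse_tsv(sim, tsv)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(sim))
  expect_equal(back$fraction, sim$fraction, tolerance = 1e-12)
})

test_that("average enrichment never exceeds the substrate enrichment ceiling", {
  des <- experiment_design(seed = 5)
  d0 <- generate_experiment(des, noise = FALSE)
  enr <- enrichment_table(d0)
  expect_lt(max(enr$enrichment), 0.6)
  # and the malate observable respects its extra unlabelled dilution
  mal <- enr[enr$metabolite == "MAL", ]
  expect_lt(max(mal$enrichment), 0.6 * (1 - 0.3))
})

test_that("a zero delay reproduces the step and the SSR penalty grows with delay", {
  model <- mfa_example_model("desk")
  net <- emu_network(model)
  truth <- desk_truth()
  tt <- c(0, 0.5, 1, 2, 4, 8, 15, 30, 60)
  step <- simulate_mids(net, truth, tt, mixing = desk_mixing())
  d0 <- simulate_mids(net, truth, tt, mixing = desk_mixing(),
                      substrate = delayed_substrate(model, 0))
  expect_equal(d0$fraction, step$fraction, tolerance = 1e-9)

  em <- error_model(1.2, 1.9)
  sig <- scale_error(100 * step$fraction, em) / 100
  ssr_at_delay <- function(d) {
    pert <- simulate_mids(net, truth, tt, mixing = desk_mixing(),
                          substrate = delayed_substrate(model, d))
    weighted_ssr(step$fraction, pert$fraction, sig)
  }
  ssrs <- vapply(c(0, 1, 2, 5, 10), ssr_at_delay, 1)
  expect_equal(ssrs[1], 0)
  expect_true(all(diff(ssrs) > 0))
  expect_error(delayed_substrate(model, -1), ">= 0")
})

test_that("a delay far beyond the slowest turnover is rejected by the fit", {
  model <- mfa_example_model("desk")
  des <- experiment_design(seed = 61, arrival = "delayed", delay = 60)
  dat <- generate_experiment(des)
  pr <- fit_problem(model, dat, des$error_model, grid_n = 40)
  truth_init <- c(desk_truth()$net[model$free], 0.3,
                  desk_truth()$pools[pr$pars$id[pr$pars$kind == "pool"]], 0.3)
  fit <- fit_fluxes(pr, n_starts = 1, seed = 61, init = unname(truth_init),
                    maxiter = 60)
  expect_gt(fit$ssr, fit$window$upper)
  expect_false(fit$accepted)
})

test_that("population aggregation is the expectation over arrival delays", {
  model <- mfa_example_model("desk")
  truth <- desk_truth()
  tt <- c(0, 1, 4, 15, 60)
  # point mass at zero = step
  ag0 <- aggregate_population(model, truth, tt, delays = 0,
                              mixing = desk_mixing())
  step <- simulate_mids(model, truth, tt, mixing = desk_mixing())
  expect_equal(ag0$fraction, step$fraction, tolerance = 1e-9)
  # two-point 50/50 mixture is the average of the two pure simulations
  net <- emu_network(model)
  tau <- 5
  agg <- aggregate_population(net, truth, tt, delays = c(0, tau),
                              mixing = desk_mixing())
  lag <- simulate_mids(net, truth, tt, mixing = desk_mixing(),
                       substrate = delayed_substrate(model, tau))
  expect_equal(agg$fraction, 0.5 * (step$fraction + lag$fraction),
               tolerance = 1e-9)
  expect_error(aggregate_population(model, truth, tt, delays = c(-1, 2)), ">= 0")
})

test_that("exponential arrival depresses early labelling but not the long-time state", {
  model <- mfa_example_model("desk")
  truth <- desk_truth()
  tt <- c(0, 0.5, 1, 2, 4, 270)
  qa <- exponential_arrival(mean_delay = 2, k = 6)
  agg <- aggregate_population(model, truth, tt, delays = qa$delays,
                              weights = qa$weights, mixing = desk_mixing())
  step <- simulate_mids(model, truth, tt, mixing = desk_mixing())
  enr <- function(d, t) {
    x <- d[d$observable == "G6P" & d$time_min == t, ]
    fractional_enrichment(x$fraction[order(x$isotopologue)])
  }
  for (t in c(0.5, 1, 2, 4)) expect_lt(enr(agg, t), enr(step, t))
  expect_equal(enr(agg, 270), enr(step, 270), tolerance = 1e-3)
})

test_that("a time-limited unlabelled influx produces a transient enrichment dip", {
  tr <- scenario_transient_dilution()
  e <- tr$enrichment
  # rises, dips during the influx window, then recovers: non-monotone trace
  peak_before <- max(e[tr$time_min <= 4])
  dip <- min(e[tr$time_min > 4 & tr$time_min <= 20])
  later <- max(e[tr$time_min > 20])
  expect_lt(dip, peak_before)
  expect_gt(later, dip)
  expect_false(all(diff(e) >= 0))
})
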