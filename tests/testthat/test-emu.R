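test_that("EMU back-tracing finds the minimal cascade and convolution nodes", {
  m <- mfa_example_model("chain2")
  net <- emu_network(m)
  expect_setequal(net$info$key, c("B|1,2", "A|1,2", "S|1,2"))
  expect_true(all(vapply(net$levels, function(l) length(l$inputs) <= 1, TRUE)))

  mc <- mfa_example_model("condense")
  netc <- emu_network(mc)
  conv <- unlist(lapply(netc$levels, function(l) {
    vapply(l$inputs, function(i) length(i$components), 1L)
  }))
  expect_true(any(conv == 2))  # A{1} (x) B{1} convolution node

  # anaplerotic carboxylation makes malate a convolution of PEP and CO2
  netd <- emu_network(mfa_example_model("desk"))
  mal_lev <- netd$levels[["4"]]
  comps <- lapply(mal_lev$inputs, `[[`, "components")
  expect_true(any(vapply(comps, function(cc) setequal(cc, c("PEP|1,2,3", "CO2|1")), TRUE)))

  # unreachable target is an error
  expect_error(emu_network(parse_mfa_model(c(
    "pool A 1", "pool B 1", "pool OUT 1 sink",
    "measure A : A",
    "r: B (a) -> OUT (a)"))), "unreachable")
})

test_that("integrator matches the one-compartment washout closed form", {
  f <- 0.6; v <- 1; P <- 2
  solu <- emu_simulate(emu_network(toy_washout_model()), toy_washout_state(v, P),
                       default_times)
  x <- solu$values[["A|1,2"]][, 3]  # fully labelled fraction
  expect_lt(max(abs(x - f * (1 - exp(-v * default_times / P)))), 1e-6)

  # t = 0: unlabelled initial condition for every observable
  sim0 <- simulate_mids(mfa_example_model("desk"), desk_truth(), c(0, 1),
                        mixing = desk_mixing())
  at0 <- dplyr::filter(sim0, time_min == 0)
  expect_equal(at0$fraction[at0$isotopologue == 0], rep(1, 5))
  expect_equal(sum(abs(at0$fraction[at0$isotopologue > 0])), 0)
})

test_that("long-time limit reaches uniform substrate enrichment", {
  m <- mfa_example_model("chain2")
  st <- unit_state(m)
  solu <- emu_simulate(emu_network(m), st, c(0, 5000))
  b <- solu$values[["B|1,2"]][2, ]
  expect_lt(max(abs(b - c(0.4, 0, 0.6))), 1e-6)
  expect_equal(fractional_enrichment(b), 0.6, tolerance = 1e-6)
})

test_that("steady-state solve matches mixing arithmetic and the Cauchy product", {
  # linear chain passes the substrate MID through unchanged
  m <- mfa_example_model("chain2")
  ss <- emu_steady_state(emu_network(m), unit_state(m))
  expect_equal(ss[["B|1,2"]], c(0.4, 0, 0.6), tolerance = 1e-10)

  # 50/50 converging branches from labelled and unlabelled sources
  mb <- mfa_example_model("branch")
  ssb <- emu_steady_state(emu_network(mb), unit_state(mb))
  expect_equal(ssb[["A|1,2"]], c(0.5, 0, 0.5), tolerance = 1e-10)

  # condensation of two half-labelled 1-carbon units
  mcn <- mfa_example_model("condense")
  ssc <- emu_steady_state(emu_network(mcn), unit_state(mcn))
  expect_equal(ssc[["C|1,2"]], c(0.25, 0.5, 0.25), tolerance = 1e-10)
  expect_equal(convolve_mid(c(0.5, 0.5), c(0.5, 0.5)), c(0.25, 0.5, 0.25))
})

test_that("MID normalization and monotone-chain enrichment hold along trajectories", {
  sim <- simulate_mids(mfa_example_model("desk"), desk_truth(), default_times,
                       mixing = desk_mixing())
  sums <- sim |>
    dplyr::group_by(observable, time_min) |>
    dplyr::summarise(s = sum(fraction), .groups = "drop")
  expect_lt(max(abs(sums$s - 1)), 1e-9)

  m <- mfa_example_model("chain2")
  solu <- emu_simulate(emu_network(m), unit_state(m), default_times)
  for (k in c("A|1,2", "B|1,2")) {
    enr <- apply(solu$values[[k]], 1, fractional_enrichment)
    expect_true(all(diff(enr) > -1e-9))
  }
})

test_that("rescaling pools and fluxes dilates time without moving the steady state", {
  m <- mfa_example_model("desk")
  net <- emu_network(m)
  st1 <- desk_truth()
  st2 <- st1  # uniform rescaling of every rate and pool (still balanced)
  st2$net <- st1$net / 2
  st2$exchange <- st1$exchange / 2
  st2$pools <- st1$pools * 2
  tt <- c(0, 1, 2, 5, 10, 30, 60)
  s1 <- emu_simulate(net, st1, tt)
  s2 <- emu_simulate(net, st2, 4 * tt)
  for (k in names(s1$values)) {
    expect_lt(max(abs(s1$values[[k]] - s2$values[[k]])), 1e-5)
  }
  ss1 <- emu_steady_state(net, st1)
  ss2 <- emu_steady_state(net, st2)
  for (k in names(ss1)) expect_equal(ss1[[k]], ss2[[k]], tolerance = 1e-9)
})

test_that("EMU and brute-force isotopomer paths agree on toy networks", {
  tt <- c(0, 0.5, 2, 8, 30, 120)
  for (nm in c("chain2", "condense", "branch")) {
    m <- mfa_example_model(nm)
    st <- unit_state(m)
    sv <- emu_simulate(emu_network(m), st, tt, method = "lsoda",
                       rtol = 1e-11, atol = 1e-13)
    bf <- simulate_isotopomers(m, st, tt, observables = FALSE,
                               rtol = 1e-11, atol = 1e-13)
    for (p in unique(bf$observable)) {
      n <- pool_carbons(m)[[p]]
      k <- paste0(p, "|", paste(seq_len(n), collapse = ","))
      if (is.null(sv$values[[k]])) next
      bmat <- matrix(bf$fraction[bf$observable == p], ncol = n + 1)
      expect_lt(max(abs(bmat - sv$values[[k]])), 1e-8)
    }
  }
})

test_that("symmetric intermediates scramble positional label", {
  m <- mfa_example_model("symmetric")
  st <- unit_state(m, pools = 1)
  raw <- simulate_isotopomers(m, st, c(1, 5, 20), observables = "raw")
  # positionally asymmetric source (10 only), yet SY's two M1 isotopomers match
  expect_lt(max(abs(raw$dist$SY[, "10"] - raw$dist$SY[, "01"])), 1e-9)
  expect_gt(max(raw$dist$SY[, "10"]), 0.1)
})

test_that("expm backend converges to the lsoda reference", {
  m <- mfa_example_model("desk")
  net <- emu_network(m)
  st <- desk_truth()
  tt <- c(0, 1, 4, 15, 60, 270)
  ref <- emu_simulate(net, st, tt, method = "lsoda", rtol = 1e-11, atol = 1e-13)
  coarse <- emu_simulate(net, st, tt, grid_n = 60)
  fine <- emu_simulate(net, st, tt, grid_n = 240)
  err <- function(s) max(mapply(function(a, b) max(abs(a - b)),
                                s$values[names(ref$values)], ref$values))
  expect_lt(err(coarse), 5e-4)
  expect_lt(err(fine), 5e-5)
  expect_lt(err(fine), err(coarse))  # second-order grid refinement
})

test_that("simulation rejects missing or non-positive pool sizes", {
  m <- mfa_example_model("chain2")
  st <- unit_state(m)
  st$pools <- st$pools["A"]
  expect_error(emu_simulate(emu_network(m), st, c(0, 1)), "missing pool size")
  st2 <- unit_state(m)
  st2$pools["B"] <- 0
  expect_error(emu_simulate(emu_network(m), st2, c(0, 1)), "positive")
})
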