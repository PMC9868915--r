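test_that("natural-abundance correction inverts the binomial convolution", {
  expect_equal(correct_natural_abundance(c(0.7, 0.2, 0.1), p13 = 0), c(0.7, 0.2, 0.1))

  # unlabelled 3-carbon fragment: observed M1 = 3 * p * (1-p)^2
  p <- 0.0107
  obs <- apply_natural_abundance(c(1, 0, 0, 0), p13 = p)
  expect_equal(obs[2], 3 * p * (1 - p)^2, tolerance = 1e-12)
  expect_equal(correct_natural_abundance(obs, p13 = p), c(1, 0, 0, 0),
               tolerance = 1e-10)

  # round-trip property on random MIDs
  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    x <- stats::runif(n + 1); x <- x / sum(x)
    back <- correct_natural_abundance(apply_natural_abundance(x, n), n)
    expect_lt(max(abs(back - x)), 1e-10)
  }

  expect_error(correct_natural_abundance(c(1, 0), p13 = 0.2), "0.05")
})

test_that("overlap deconvolution inverts exact mixtures and flags degeneracy", {
  # alpha = 0: contaminant cannot be subtracted at all
  r0 <- deconvolute_mid(c(0, 1), c(1, 0))
  expect_lt(r0$alpha, 1e-5)
  expect_equal(r0$component, c(0, 1))

  # exact 50/50 mixture is inverted to its true components
  r <- deconvolute_mid(0.5 * c(1, 0) + 0.5 * c(0, 1), c(1, 0))
  expect_equal(r$alpha, 0.5, tolerance = 1e-5)
  expect_equal(r$component, c(0, 1), tolerance = 1e-5)

  # contaminant identical to the observation: unidentifiable
  expect_warning(rd <- deconvolute_mid(c(0.5, 0.5), c(0.5, 0.5)), "degenerate")
  expect_true(rd$degenerate)
})

test_that("fractional enrichment is the label probability and is dilution-linear", {
  expect_equal(fractional_enrichment(c(1, 0, 0)), 0)
  expect_equal(fractional_enrichment(c(0, 0, 1)), 1)
  expect_equal(fractional_enrichment(c(0.25, 0.5, 0.25)), 0.5)

  set.seed(1)
  for (i in 1:20) {
    x <- stats::runif(5); x <- x / sum(x)
    lam <- stats::runif(1)
    mix <- lam * x + (1 - lam) * c(1, 0, 0, 0, 0)
    expect_equal(fractional_enrichment(mix), lam * fractional_enrichment(x),
                 tolerance = 1e-12)
  }
})

test_that("substrate normalization divides and warns above unity", {
  expect_equal(normalize_to_substrate(0.30, 0.60), 0.5)
  expect_equal(normalize_to_substrate(0.60, 0.60), 1)
  expect_warning(v <- normalize_to_substrate(0.66, 0.60), "1.05")
  expect_equal(v, 1.1)
  expect_error(normalize_to_substrate(0.3, 0), "scalar in")
})

test_that("MID tables round-trip through CSV with mol% auto-detection", {
  d <- tibble::tibble(
    metabolite = rep("G6P", 8), n_carbons = 1L,
    time_min = rep(c(0, 1, 2, 4), each = 2),
    replicate = 1L, isotopologue = rep(0:1, 4),
    value = c(100, 0, 90, 10, 80, 20, 70, 30))  # mol% scale
  path <- tempfile(fileext = ".csv")
  write_mid_table(d, path)
  back <- read_mid_table(path)
  expect_equal(sum(back$value[back$time_min == 1]), 1)
  expect_equal(back$value[back$time_min == 4 & back$isotopologue == 1], 0.3)

  bad <- d; bad$time_min <- 0
  write_mid_table(bad, path)
  expect_error(read_mid_table(path), "isotopologue rows|strictly increasing")
  expect_error(read_mid_table({
    p2 <- tempfile(fileext = ".csv")
    utils::write.csv(d[, -1], p2, row.names = FALSE); p2
  }), "misses column")
})

test_that("table-level correction and enrichment wrappers preserve shape", {
  d <- tibble::tibble(
    metabolite = "X", n_carbons = 2L, time_min = rep(c(0, 5), each = 3),
    replicate = 1L, isotopologue = rep(0:2, 2),
    value = c(apply_natural_abundance(c(1, 0, 0)),
              apply_natural_abundance(c(0.4, 0, 0.6))))
  cor <- correct_mid_table(d)
  expect_equal(cor$value[cor$time_min == 0], c(1, 0, 0), tolerance = 1e-9)
  expect_equal(cor$value[cor$time_min == 5], c(0.4, 0, 0.6), tolerance = 1e-9)
  enr <- enrichment_table(cor, substrate_fraction = 0.6)
  expect_equal(enr$enrichment[enr$time_min == 5], 1, tolerance = 1e-9)
})
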