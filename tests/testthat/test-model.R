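test_that("parser builds valid models and reports conservation violations", {
  m <- parse_mfa_model(c(
    "pool A 2", "pool B 1", "pool C 1", "pool S 2 source", "pool OUT 1 sink",
    "substrate S enrichment=0.5",
    "measure B : B",
    "in: S (ab) -> A (ab)",
    "split: A (ab) -> B (b) + C (a)",
    "ob: B (a) -> OUT (a)",
    "oc: C (a) -> OUT (a)"))
  expect_s3_class(m, "mfa_model")
  expect_equal(length(m$reactions), 4)

  # reversible carboxylation with a 3+1 -> 4 atom map
  m2 <- parse_mfa_model(c(
    "pool PEP.c 3", "pool CO2 1", "pool MAL 4", "pool S 3 source", "pool OUT 4 sink",
    "substrate S enrichment=0.5", "measure MAL : MAL",
    "in: S (abc) -> PEP.c (abc)",
    "ana1: PEP.c (abc) + CO2 (d) <-> MAL (abcd)",
    "rel: MAL (abcd) -> PEP.c (abc) + CO2 (d)",
    "out: MAL (abcd) -> OUT (abcd)"))
  r <- m2$reactions[[2]]
  expect_true(r$reversible)
  expect_equal(r$products[[1]]$map, c("a", "b", "c", "d"))

  expect_error(parse_mfa_model(c(
    "pool A 2", "pool B 3", "measure B : B",
    "bad: A (ab) -> B (abc)")), "conserve carbon")
  expect_error(parse_mfa_model(c(
    "pool A 2", "bad: A (abc) -> A (abc)")), "3 letters")
  expect_error(parse_mfa_model(c(
    "pool A 1", "r: A (a) -> A (a)", "r: A (a) -> A (a)")), "duplicate reaction")
  expect_error(parse_mfa_model(c(
    "pool A 1", "r: A (a) -> Z (a)")), "unknown pool")
  expect_error(parse_mfa_model(c("pool A 1", "gibberish here")), "line 2")
})

test_that("stoichiometry null space counts free fluxes", {
  expect_equal(n_free_fluxes(chain_model()), 1)

  m <- diamond_model()
  expect_equal(n_free_fluxes(m), 2)
  # independent oracle: Gaussian elimination on the hand-written matrix
  S <- rbind(A = c(1, -1, -1, 0, 0, 0),
             B = c(0, 1, 0, -1, 0, 0),
             C = c(0, 0, 1, 0, -1, 0),
             D = c(0, 0, 0, 1, 1, -1))
  gauss_rank <- function(M, tol = 1e-10) {
    r <- 0
    for (j in seq_len(ncol(M))) {
      piv <- which(abs(M[, j]) > tol)
      piv <- piv[piv > r]
      if (!length(piv)) next
      r <- r + 1
      M[c(r, piv[1]), ] <- M[c(piv[1], r), ]
      for (i in seq_len(nrow(M))[-r]) M[i, ] <- M[i, ] - M[i, j] / M[r, j] * M[r, ]
    }
    r
  }
  expect_equal(ncol(S) - gauss_rank(S), 2)
  expect_equal(unname(stoichiometry_matrix(m)[c("A", "B", "C", "D"), ]), unname(S))
})

test_that("flux_state balances pools and enforces sign constraints", {
  st <- desk_truth("control")
  S <- stoichiometry_matrix(mfa_example_model("desk"))
  expect_lt(max(abs(S %*% st$net)), 1e-9)
  expect_equal(unname(st$net[["upt"]]), 1)
  expect_equal(unname(st$net[["pk"]]), 2 * (1 + 0.162) - 0.838)

  m <- mfa_example_model("desk")
  expect_error(flux_state(m, free = c(dil = 0.1, ana = 5, out_mal = 0.2),
                          pools = desk_truth()$pools),
               "negative net flux")
  expect_error(flux_state(m, free = c(dil = 0.1, ana = 0.5, out_mal = 0.2),
                          exchange = c(gly2 = -1)), "nonnegative")
  expect_error(flux_state(m, free = c(dil = 0.1, wrong = 1, out_mal = 0.2)),
               "named exactly")
})

test_that("models serialize and reparse identically", {
  for (nm in c("desk", "chain2", "condense", "symmetric", "arabidopsis")) {
    m <- mfa_example_model(nm)
    m2 <- parse_mfa_model(write_mfa_model(m))
    expect_equal(m2$pools, m$pools)
    expect_equal(m2$fixed, m$fixed)
    expect_equal(m2$free, m$free)
    expect_equal(length(m2$reactions), length(m$reactions))
    for (i in seq_along(m$reactions)) {
      expect_equal(m2$reactions[[i]][c("id", "reversible", "pseudo", "reactants", "products")],
                   m$reactions[[i]][c("id", "reversible", "pseudo", "reactants", "products")])
    }
    expect_equal(length(m2$measurements), length(m$measurements))
  }
})

test_that("observable composition mixes pools and unlabelled dilution", {
  expect_equal(compose_observable(list(c(1, 0)), weights = 1), c(1, 0))
  expect_equal(compose_observable(list(c(1, 0), c(0, 1)), weights = c(0.5, 0.5)),
               c(0.5, 0.5))
  expect_equal(compose_observable(list(c(0, 1)), weights = 0.8, unlabelled = 0.2),
               c(0.2, 0.8))
  expect_error(compose_observable(list(c(1, 0), c(1, 0, 0)), weights = c(0.5, 0.5)),
               "carbon count")
  expect_error(compose_observable(list(c(1, 0)), weights = 0.5), "sum to 1")
})

test_that("free-parameter enumeration and design bookkeeping are consistent", {
  m <- mfa_example_model("desk")
  net <- emu_network(m)
  fp <- free_parameter_vector(m, fit_pools = c("G6P", "TP", "PEP", "PYR", "MAL", "CO2"))
  expect_equal(sum(fp$kind == "net"), 3)
  expect_equal(sum(fp$kind == "exchange"), 1)
  expect_equal(sum(fp$kind == "pool"), 6)
  expect_equal(sum(fp$kind == "mixing"), 1)
  expect_equal(attr(fp, "n_total"), 11)
  expect_equal(attr(free_parameter_vector(m, fit_pools = "G6P",
                                          n_normalisations = 10), "n_total"), 16)

  acc <- parameter_accounting(isotopologue_measurements = 936,
                              flux_measurements = 1, normalisations = 0,
                              free_fluxes = 4, pool_sizes = 6)
  expect_equal(acc$n, 937)
  expect_equal(acc$p, 10)
  expect_equal(acc$df, 927)
})

test_that("the transcribed arabidopsis network is stoichiometrically sound", {
  m <- mfa_example_model("arabidopsis")
  # every declared free flux is needed: nullity equals the declared count + 0
  expect_equal(n_free_fluxes(m), length(m$free) + length(m$fixed))
  # a Table-2-like flux assignment balances with nonnegative irreversible fluxes
  st <- arabidopsis_reference_state()
  S <- stoichiometry_matrix(m)
  expect_lt(max(abs(S %*% st$net)), 1e-9)
  expect_equal(unname(st$net[["upt"]]), 1)
})
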