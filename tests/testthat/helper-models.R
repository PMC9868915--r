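# Small networks built in code for oracle and fitting tests.

toy_washout_model <- function() {
  parse_mfa_model(c(
    "pool S 2 source",
    "pool A 2",
    "pool OUT 2 sink",
    "substrate S enrichment=0.6",
    "free vin",
    "measure A : A",
    "vin: S (ab) -> A (ab)",
    "vout: A (ab) -> OUT (ab)"))
}

toy_washout_state <- function(v = 1, P = 2) {
  flux_state(toy_washout_model(), free = c(vin = v), pools = c(A = P))
}

diamond_model <- function() {
  parse_mfa_model(c(
    "pool S 1 source", "pool A 1", "pool B 1", "pool C 1", "pool D 1",
    "pool OUT 1 sink",
    "substrate S enrichment=0.5",
    "measure D : D",
    "r1: S (a) -> A (a)",
    "r2: A (a) -> B (a)",
    "r3: A (a) -> C (a)",
    "r4: B (a) -> D (a)",
    "r5: C (a) -> D (a)",
    "r6: D (a) -> OUT (a)"))
}

chain_model <- function() {
  parse_mfa_model(c(
    "pool S 1 source", "pool A 1", "pool B 1", "pool OUT 1 sink",
    "substrate S enrichment=0.5",
    "measure B : B",
    "r1: S (a) -> A (a)",
    "r2: A (a) -> B (a)",
    "r3: B (a) -> OUT (a)"))
}

# balanced unit state for toy models whose fluxes are all determined
unit_state <- function(model, pools = 1.5) {
  bal <- model$pools$name[model$pools$role == "balanced"]
  flux_state(model, pools = stats::setNames(rep(pools, length(bal)), bal))
}

default_times <- c(0, 0.5, 1, 2, 4, 8, 10, 15, 20, 30, 60, 120, 270)

# noise-free washout dataset at given truth, one replicate
washout_data <- function(v = 1, P = 2, times = default_times, noise = 0,
                         seed = 1) {
  model <- toy_washout_model()
  sim <- simulate_mids(model, toy_washout_state(v, P), times)
  d <- tibble::tibble(observable = sim$observable, time_min = sim$time_min,
                      replicate = 1L, isotopologue = sim$isotopologue,
                      value = sim$fraction)
  if (noise > 0) {
    set.seed(seed)
    d$value <- pmax(d$value + stats::rnorm(nrow(d), 0, noise), 0)
  }
  d
}

# the washout flux is only identified jointly with the pool size unless an
# output flux measurement pins the scale, as the real designs do
washout_fmeas <- function(v = 1, sd = 0.05) {
  tibble::tibble(reaction = "vin", value = v, sd = sd)
}
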