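.default_error_model <- function() error_model(1.20, 1.90)

#' Design of an in-silico labelling experiment
#'
#' Captures the study conditions a synthetic experiment emulates: bolus
#' addition of uniformly 13C-labelled glucose at ~60% enrichment at t = 0,
#' 13 sampling times over 270 minutes, 3 replicate cultures, and
#' mol%-dependent Gaussian measurement noise. The default model is the
#' compact desk network with its control-condition ground truth.
#'
#' @param model an `mfa_model`.
#' @param truth ground-truth [flux_state()] (balanced, with pool sizes).
#' @param mixing ground-truth values of free mixing parameters.
#' @param enrichment labelled fraction of the substrate (default 0.60);
#'   overrides the model's declared substrate enrichment.
#' @param times sampling grid in minutes (default the 13-point grid
#'   0, 0.5, 1, 2, 4, 8, 10, 15, 20, 30, 60, 120, 270).
#' @param replicates number of replicate cultures (default 3).
#' @param error_model measurement [error_model()] (default 1.20-1.90 mol%,
#'   the control-condition calibration).
#' @param seed master seed; per-replicate, per-metabolite noise streams are
#'   derived from it.
#' @param arrival substrate arrival mode: instantaneous `"step"`, lagged
#'   `"delayed"`, or `"distributed"` over a cell population.
#' @param delay arrival delay in minutes (`"delayed"` mode), or `tau` for
#'   first-order saturation when `first_order = TRUE`.
#' @param first_order use first-order saturation instead of a pure lag.
#' @param arrival_delays,arrival_weights discrete arrival-time distribution
#'   (`"distributed"` mode).
#' @return object of class `experiment_design`.
#' @export
experiment_design <- function(model = mfa_example_model("desk"),
                              truth = desk_truth("control"),
                              mixing = desk_mixing(),
                              enrichment = 0.60,
                              times = c(0, 0.5, 1, 2, 4, 8, 10, 15, 20, 30, 60, 120, 270),
                              replicates = 3,
                              error_model = .default_error_model(),
                              seed = 1,
                              arrival = c("step", "delayed", "distributed"),
                              delay = 0, first_order = FALSE,
                              arrival_delays = NULL, arrival_weights = NULL) {
  arrival <- match.arg(arrival)
  times <- sort(unique(times))
  if (times[1] != 0) stop("time grid must start at 0", call. = FALSE)
  if (any(diff(times) <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  if (scale_error(100, error_model) > 50) {
    stop("noise sd exceeding 50 mol% rejected", call. = FALSE)
  }
  sub_pool <- model$substrates[[1]]$pool
  structure(list(model = model, truth = truth, mixing = mixing,
                 enrichment = enrichment, times = times, replicates = replicates,
                 error_model = error_model, seed = seed, arrival = arrival,
                 delay = delay, first_order = first_order,
                 arrival_delays = arrival_delays, arrival_weights = arrival_weights,
                 substrate_pool = sub_pool),
            class = "experiment_design")
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("<experiment_design> %d times (0-%g min), %d replicates, substrate %.0f%% labelled, arrival %s\n",
              length(x$times), max(x$times), x$replicates, 100 * x$enrichment, x$arrival))
  invisible(x)
}

#' Time-dependent substrate arrival
#'
#' Turns a step substrate into a lagged or first-order saturating one: the
#' labelled fraction of the substrate pool is 0 before `delay` (pure lag)
#' or rises as `1 - exp(-t / tau)` (first-order), emulating delayed
#' diffusion of the labelled substrate to cells.
#'
#' @param model an `mfa_model` (its first declared substrate is modified).
#' @param delay lag in minutes (pure-delay mode) or time constant `tau`
#'   (first-order mode).
#' @param first_order use first-order saturation.
#' @param enrichment labelled fraction after arrival; default from the
#'   model's substrate declaration.
#' @return a [source_patterns()] list with time-dependent weights.
#' @export
delayed_substrate <- function(model, delay, first_order = FALSE,
                              enrichment = NULL) {
  if (delay < 0) stop("delay must be >= 0", call. = FALSE)
  src <- source_patterns(model)
  pool <- model$substrates[[1]]$pool
  n <- pool_carbons(model)[[pool]]
  f <- if (is.null(enrichment)) model$substrates[[1]]$enrichment else enrichment
  if (is.null(f)) stop("substrate enrichment not declared; pass `enrichment`", call. = FALSE)
  make_w <- if (first_order && delay > 0) {
    function(t) {
      s <- f * (1 - exp(-pmax(t, 0) / delay))
      rbind(s, 1 - s)
    }
  } else {
    function(t) {
      s <- f * as.numeric(t >= delay)
      rbind(s, 1 - s)
    }
  }
  src[[pool]] <- list(patterns = rbind(rep(1, n), rep(0, n)), weights = make_w)
  src
}

#' Observable time-courses of a cell population with distributed substrate arrival
#'
#' Simulates the label time-courses of an aggregate of cells whose
#' individual substrate-arrival delays follow a discrete distribution
#' (e.g. a quadrature of an exponential): the observed MID is the
#' expectation over per-delay simulations. A point mass at zero
#' reproduces the step simulation.
#'
#' @param model an `mfa_model`.
#' @param state a [flux_state()].
#' @param times output times.
#' @param delays,weights arrival-time distribution (weights normalized;
#'   all delays must be >= 0).
#' @param mixing,... passed to [simulate_mids()].
#' @return tidy MID tibble ([simulate_mids()] layout).
#' @export
aggregate_population <- function(model, state, times, delays, weights = NULL,
                                 mixing = NULL, ...) {
  if (any(delays < 0)) stop("arrival delays must be >= 0", call. = FALSE)
  if (is.null(weights)) weights <- rep(1 / length(delays), length(delays))
  weights <- weights / sum(weights)
  net <- if (inherits(model, "emu_network")) model else emu_network(model)
  sims <- lapply(seq_along(delays), function(i) {
    sub <- delayed_substrate(net$model, delays[i])
    simulate_mids(net, state, times, mixing = mixing, substrate = sub, ...)
  })
  out <- sims[[1]]
  out$fraction <- Reduce(`+`, Map(function(s, w) w * s$fraction, sims, as.list(weights)))
  out
}

#' Exponential arrival-time quadrature
#'
#' Midpoint quadrature of an exponential delay distribution for
#' [aggregate_population()].
#'
#' @param mean_delay mean of the exponential (minutes).
#' @param k number of quadrature nodes.
#' @return list with `delays` and `weights`.
#' @export
exponential_arrival <- function(mean_delay, k = 8) {
  q <- (seq_len(k) - 0.5) / k
  list(delays = stats::qexp(q, rate = 1 / mean_delay), weights = rep(1 / k, k))
}

# substrate source list of a design (arrival mode applied)
design_substrate <- function(design) {
  model <- design$model
  src <- source_patterns(model)
  pool <- design$substrate_pool
  n <- pool_carbons(model)[[pool]]
  f <- design$enrichment
  if (design$arrival == "step") {
    src[[pool]] <- list(patterns = rbind(rep(1, n), rep(0, n)),
                        weights = c(f, 1 - f))
    return(src)
  }
  delayed_substrate(model, design$delay, design$first_order, enrichment = f)
}

#' Generate a synthetic labelling experiment
#'
#' Simulates the design's ground-truth MID time-courses, composes the
#' declared observables (compartment mixing and unlabelled dilution), and
#' adds independent Gaussian noise with sd given by the error model at the
#' simulated abundance; noisy MIDs are clamped to `[0, 1]` and
#' renormalized (a small truncation bias at near-0/near-1 fractions is
#' inherent to this scheme). Replicates and metabolites draw from seeds
#' derived from the master seed, so partial regeneration is reproducible.
#'
#' @param design an [experiment_design()].
#' @param noise add measurement noise (set `FALSE` for noise-free tables).
#' @param clamp clamp noisy values to `[0, 1]` and renormalize each MID.
#'   The default is `FALSE`: the pipeline fits natural-abundance-corrected
#'   MIDs, and corrected measurements legitimately carry small negative
#'   values in near-zero channels, so untruncated Gaussian noise is the
#'   faithful emulation (and keeps the weighted SSR chi-squared
#'   distributed). `TRUE` emulates bounded raw-signal tables; the
#'   truncation then biases every near-zero channel upward by about
#'   sigma/sqrt(2*pi), which is visible as an SSR deficit and a shift in
#'   fluxes that feed intermediate mass channels.
#' @return tidy MID tibble (`metabolite`, `n_carbons`, `time_min`,
#'   `replicate`, `isotopologue`, `value`) with the ground truth attached
#'   as attribute `"truth"`.
#' @export
generate_experiment <- function(design, noise = TRUE, clamp = FALSE) {
  model <- design$model
  if (design$arrival == "distributed") {
    sim <- aggregate_population(model, design$truth, design$times,
                                delays = design$arrival_delays,
                                weights = design$arrival_weights,
                                mixing = design$mixing, grid_n = 150)
  } else {
    sim <- simulate_mids(model, design$truth, design$times,
                         mixing = design$mixing,
                         substrate = design_substrate(design), grid_n = 150)
  }
  nc <- pool_carbons(model)
  meas <- model$measurements
  obs_nc <- stats::setNames(
    vapply(meas, function(m) nc[[m$pools[1]]], 1L),
    vapply(meas, `[[`, "", "observable"))
  mets <- sort(unique(sim$observable))
  out <- list()
  for (r in seq_len(design$replicates)) {
    for (mi in seq_along(mets)) {
      mdat <- sim[sim$observable == mets[mi], ]
      wide <- matrix(mdat$fraction, nrow = length(design$times))
      if (noise) {
        # collision-free stream per (seed, replicate, metabolite): distinct
        # master seeds must never share a stream
        set.seed((design$seed %% 2000000L) * 1000L + r * 100L + mi)
        sd_frac <- scale_error(100 * wide, design$error_model) / 100
        wide <- wide + stats::rnorm(length(wide), 0, as.vector(sd_frac))
        if (clamp) {
          wide <- pmin(pmax(wide, 0), 1)
          wide <- wide / rowSums(wide)
        }
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        metabolite = mets[mi],
        n_carbons = obs_nc[[mets[mi]]],
        time_min = rep(design$times, ncol(wide)),
        replicate = r,
        isotopologue = rep(0:(ncol(wide) - 1L), each = length(design$times)),
        value = as.vector(wide))
    }
  }
  res <- dplyr::bind_rows(out)
  attr(res, "truth") <- list(state = design$truth, mixing = design$mixing,
                             free = design$truth$net[design$model$free],
                             design = design)
  res
}

#' Piecewise-constant-flux simulation
#'
#' Simulates a sequence of balanced flux states over consecutive time
#' segments, chaining the labelling state across the breakpoints. Used for
#' scenarios where a flux (e.g. an unlabelled-carbon influx) switches on
#' for a limited period.
#'
#' @param net an [emu_network()] (or `mfa_model`).
#' @param states list of [flux_state()]s, one per segment.
#' @param breaks interior breakpoints (length `length(states) - 1`).
#' @param times output times.
#' @param mixing,... passed through to composition / [emu_simulate()].
#' @return tidy MID tibble as from [simulate_mids()].
#' @export
simulate_piecewise <- function(net, states, breaks, times, mixing = NULL, ...) {
  if (inherits(net, "mfa_model")) net <- emu_network(net)
  stopifnot(length(breaks) == length(states) - 1L)
  bounds <- c(0, breaks, max(times))
  x0 <- NULL
  vals <- NULL
  out_times <- c()
  for (k in seq_along(states)) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    loc <- sort(unique(c(times[times > lo & times <= hi] - lo, hi - lo)))
    loc <- unique(c(0, loc))
    solu <- emu_simulate(net, states[[k]], loc, x0 = x0, ...)
    x0 <- lapply(solu$values, function(M) M[nrow(M), ])
    keep <- which((solu$times + lo) %in% times & (solu$times + lo) > lo |
                    (k == 1 & solu$times == 0))
    if (length(keep)) {
      sel <- lapply(solu$values, function(M) M[keep, , drop = FALSE])
      vals <- if (is.null(vals)) sel else
        Map(function(a, b) rbind(a, b), vals, sel)
      out_times <- c(out_times, solu$times[keep] + lo)
    }
  }
  nc <- pool_carbons(net$model)
  mix <- resolve_mixing(net$measurements, mixing)
  rows <- lapply(mix, function(m) {
    n <- nc[[m$pools[1]]]
    M <- Reduce(`+`, lapply(seq_along(m$pools), function(i) {
      m$weights[i] * vals[[emu_key(m$pools[i], seq_len(n))]]
    }))
    M[, 1] <- M[, 1] + m$unlabelled
    tibble::tibble(observable = m$observable,
                   time_min = rep(out_times, n + 1L),
                   isotopologue = rep(0:n, each = length(out_times)),
                   fraction = as.vector(M))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mid_timecourse", class(out))
  out
}

#' Transient unlabelled-influx scenario
#'
#' Reproduces the characteristic transient dip in hexose-phosphate
#' enrichment seen when pre-existing unlabelled carbohydrate stores are
#' mobilized for a limited period: the desk network's unlabelled glucose
#' influx is raised during a time window and the hexose-phosphate
#' fractional enrichment traced.
#'
#' @param window start and end (minutes) of the elevated influx.
#' @param dil_high unlabelled influx during the window (relative flux;
#'   baseline 0.162).
#' @param times output grid.
#' @return tibble: `time_min`, `enrichment` of the hexose-phosphate
#'   observable.
#' @export
scenario_transient_dilution <- function(window = c(4, 15), dil_high = 1.2,
                                        times = c(0, 0.5, 1, 2, 3, 4, 5, 6, 8, 10,
                                                  12, 15, 20, 30, 45, 60, 120, 270)) {
  model <- mfa_example_model("desk")
  base <- desk_truth("control")
  st_hi <- flux_state(model,
                      free = c(dil = dil_high, ana = 0.838, out_mal = 0.2),
                      exchange = c(gly2 = 0.3), pools = base$pools)
  sim <- simulate_piecewise(model, list(base, st_hi, base), breaks = window,
                            times = times, mixing = desk_mixing())
  sim |>
    dplyr::filter(.data$observable == "G6P") |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(enrichment = fractional_enrichment(
      .data$fraction[order(.data$isotopologue)]), .groups = "drop")
}
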