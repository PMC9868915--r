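#' Percentile confidence interval from a Monte Carlo ensemble
#'
#' Ranks the parameter estimates in ascending order, discards
#' `floor((1 - level/100)/2 * n)` values from each end, and returns the
#' range of the remainder: for 1000 samples, the top and bottom 8.3% are
#' discarded for an 83.4% interval and the top and bottom 2.5% for a 95%
#' interval.
#'
#' @param x numeric vector of one parameter's Monte Carlo estimates
#'   (intended for ensembles of >= 100 refits).
#' @param level confidence level in percent, in (0, 100).
#' @return named numeric `c(lower, upper)`.
#' @export
ci_from_ensemble <- function(x, level) {
  if (level <= 0 || level >= 100) stop("level must be in (0, 100)", call. = FALSE)
  x <- sort(x)
  n <- length(x)
  k <- floor(round((1 - level / 100) / 2 * n, 9))  # guard fp error in the tail count
  kept <- x[(k + 1):(n - k)]
  c(lower = kept[1], upper = kept[length(kept)])
}

#' Per-group confidence level for CI-overlap testing at P = 0.05
#'
#' Non-overlap of two per-group confidence intervals corresponds to a
#' two-group test at P = 0.05 when each interval is drawn at the level
#' `[1 - 2 * pnorm(-1.96 * sqrt(1 + rho^2) / (1 + rho))] * 100` percent,
#' where `rho` is the ratio of the two groups' standard deviations. At
#' `rho = 1` (equal variances) this is 83.4%; as the variances diverge it
#' approaches 95%. The 1.96 constant is kept literal, matching the normal
#' 0.975 quantile of the published rule.
#'
#' @param rho ratio of standard deviations (> 0); the level is symmetric
#'   under `rho <-> 1/rho`.
#' @return confidence level in percent.
#' @examples
#' adjusted_level(1)    # 83.4
#' adjusted_level(1e6)  # ~95.0
#' @export
adjusted_level <- function(rho) {
  if (any(rho <= 0)) stop("rho must be positive", call. = FALSE)
  (1 - 2 * stats::pnorm(-1.96 * sqrt(1 + rho^2) / (1 + rho))) * 100
}

# ---- profile-likelihood continuation ---------------------------------------

# Generic one-sided profile walk. refit(value, warm) must return
# list(ssr = profiled SSR, warm = warm-start payload, improved = optional
# better-than-incumbent flag payload). Returns the crossing of
# ssr_min + threshold, +/-Inf when the profile stays flat, and any
# improvement discovered.
profile_walk <- function(refit, value_hat, ssr_min, threshold, step,
                         direction = 1, max_steps = 40, warm = NULL) {
  target <- ssr_min + threshold
  v_prev <- value_hat; s_prev <- ssr_min
  improved <- NULL
  h <- step
  for (k in seq_len(max_steps)) {
    v <- v_prev + direction * h
    r <- refit(v, warm)
    warm <- r$warm
    if (r$ssr < ssr_min - 1e-6) {
      improved <- list(value = v, refit = r)
      break
    }
    if (r$ssr >= target) {
      # bracketed: refine the crossing by bisection
      lo <- v_prev; s_lo <- s_prev; hi <- v; s_hi <- r$ssr
      for (b in 1:8) {
        mid <- (lo + hi) / 2
        rm <- refit(mid, warm)
        warm <- rm$warm
        if (rm$ssr < ssr_min - 1e-6) {
          improved <- list(value = mid, refit = rm)
          return(list(bound = NA_real_, improved = improved))
        }
        if (rm$ssr >= target) { hi <- mid; s_hi <- rm$ssr } else { lo <- mid; s_lo <- rm$ssr }
      }
      frac <- if (s_hi > s_lo) (target - s_lo) / (s_hi - s_lo) else 0.5
      return(list(bound = lo + (hi - lo) * frac, improved = improved))
    }
    v_prev <- v; s_prev <- r$ssr
    h <- h * 1.6  # expand: identifiable profiles cross quickly
  }
  if (!is.null(improved)) return(list(bound = NA_real_, improved = improved))
  list(bound = direction * Inf, improved = NULL)
}

#' Profile-likelihood (continuation) confidence interval
#'
#' Steps one parameter away from its optimum in both directions,
#' re-optimizing all remaining parameters at each step, and reports where
#' the profiled SSR crosses `SSR_min + qchisq(1 - alpha, 1)`. A flat
#' profile yields an unbounded (one- or two-sided infinite) interval
#' rather than an error. If a better global solution is discovered during
#' the walk, the incumbent fit is replaced and the continuation restarted
#' (improvement retention).
#'
#' @param fit an `mfa_fit`.
#' @param parameter parameter name (a row of `fit$problem$pars`).
#' @param alpha significance level (default 0.05 for a 95% interval).
#' @param step initial step on the internal (transformed) scale.
#' @param max_steps maximum walk length per direction.
#' @param max_restarts improvement-retention restarts allowed.
#' @return list: `interval` (natural scale), `fit` (possibly improved
#'   incumbent), `restarts`.
#' @export
continuation_ci <- function(fit, parameter, alpha = 0.05, step = 0.15,
                            max_steps = 40, max_restarts = 3) {
  problem <- fit$problem
  j <- match(parameter, problem$pars$parameter)
  if (is.na(j)) stop(sprintf("unknown parameter '%s'", parameter), call. = FALSE)
  threshold <- stats::qchisq(1 - alpha, 1)
  restarts <- 0
  repeat {
    theta_hat <- fit$theta
    refit <- function(vj, warm) {
      th0 <- if (is.null(warm)) theta_hat[-j] else warm
      fn <- function(th_rest) {
        th <- numeric(length(theta_hat))
        th[-j] <- th_rest; th[j] <- vj
        fit_residuals(problem, th)
      }
      res <- tryCatch(suppressWarnings(minpack.lm::nls.lm(th0, fn = fn,
        control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-9))),
        error = function(e) NULL)
      if (is.null(res)) return(list(ssr = Inf, warm = th0))
      list(ssr = res$deviance, warm = res$par)
    }
    up <- profile_walk(refit, theta_hat[j], fit$ssr, threshold, step, 1, max_steps)
    dn <- profile_walk(refit, theta_hat[j], fit$ssr, threshold, step, -1, max_steps)
    imp <- if (!is.null(up$improved)) up$improved else dn$improved
    if (!is.null(imp) && restarts < max_restarts) {
      restarts <- restarts + 1
      theta_new <- fit$theta
      theta_new[j] <- imp$value
      theta_new[-j] <- imp$refit$warm
      res <- minpack.lm::nls.lm(theta_new, fn = function(th) fit_residuals(problem, th),
        control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-9))
      fit$theta <- res$par
      fit$ssr <- res$deviance
      nat <- clamp_natural(to_natural(res$par, problem$pars), problem$pars)
      fit$params <- stats::setNames(nat, problem$pars$parameter)
      sp <- state_from_params(problem, nat)
      fit$state <- sp$state; fit$mixing <- sp$mixing
      next
    }
    tr <- problem$pars$transform[j]
    back <- function(v) {
      if (!is.finite(v)) return(ifelse(tr == "identity", v, ifelse(v > 0,
        switch(tr, log = Inf, logit = 1), switch(tr, log = 0, logit = 0))))
      switch(tr, log = exp(v), logit = stats::plogis(v), v)
    }
    lo <- back(dn$bound); hi <- back(up$bound)
    return(list(interval = c(lower = lo, upper = hi), fit = fit, restarts = restarts))
  }
}

# ---- Monte Carlo ------------------------------------------------------------

# Warm-start Levenberg-Marquardt refit tuned for the Monte Carlo inner
# loop: forward-difference Jacobian per iteration, Marquardt-scaled
# damping, step acceptance by SSR decrease. Starting at the incumbent
# optimum of a slightly perturbed problem, 2-4 iterations suffice.
lm_warm_refit <- function(problem, th, maxiter = 8, ftol = 1e-7) {
  r <- fit_residuals(problem, th)
  ssr <- sum(r^2)
  lambda <- 0
  for (it in seq_len(maxiter)) {
    J <- vapply(seq_along(th), function(j) {
      h <- 1e-6 * (1 + abs(th[j]))
      tp <- th; tp[j] <- th[j] + h
      (fit_residuals(problem, tp) - r) / h
    }, numeric(length(r)))
    A <- crossprod(J)
    g <- crossprod(J, r)
    dA <- pmax(diag(A), 1e-8)
    improved <- FALSE
    for (trial in 1:6) {
      M <- A + lambda * diag(dA, nrow(A))
      delta <- tryCatch(solve(M, -g), error = function(e) NULL)
      if (is.null(delta)) {
        lambda <- max(lambda * 10, 1e-4)
        next
      }
      th1 <- th + as.vector(delta)
      r1 <- fit_residuals(problem, th1)
      ssr1 <- sum(r1^2)
      if (is.finite(ssr1) && ssr1 < ssr) {
        rel <- (ssr - ssr1) / max(ssr1, 1e-300)
        th <- th1; r <- r1; ssr <- ssr1
        lambda <- lambda / 3
        improved <- TRUE
        if (rel < ftol) return(list(par = th, ssr = ssr, converged = TRUE))
        break
      }
      lambda <- max(lambda * 10, 1e-4)
    }
    if (!improved) break
  }
  list(par = th, ssr = ssr, converged = TRUE)
}

#' Monte Carlo parameter uncertainty by synthetic-data refitting
#'
#' Generates `n` synthetic datasets by perturbing the best-fit simulated
#' measurements with Gaussian noise at the per-measurement error-model
#' sigmas (and the flux measurements at their own errors), refits each
#' dataset from the best-fit starting values, and collects the refitted
#' parameter vectors. The perturbation is plain Gaussian, matching the
#' corrected-MID data the model is fitted to (small negatives are
#' legitimate there); `clamp = TRUE` truncates and renormalizes each
#' synthetic MID instead, for data generated in the bounded
#' raw-measurement mode. Failed refits are recorded separately, never
#' silently dropped; a failure rate above `max_fail` aborts.
#'
#' @param fit an accepted `mfa_fit`.
#' @param n number of Monte Carlo rounds (the published analyses used
#'   1000).
#' @param seed integer seed; rounds use derived seeds `seed + round`.
#' @param max_fail tolerated failure fraction before aborting.
#' @param maxiter per-refit Levenberg-Marquardt iteration cap.
#' @param ftol per-refit relative SSR convergence tolerance.
#' @param noise_scale multiplier on the error-model sigmas (0 gives
#'   noise-free rounds, in which every refit reproduces the best fit).
#' @param clamp truncate synthetic MIDs to `[0, 1]` and renormalize
#'   (matches [generate_experiment()]'s `clamp = TRUE` mode).
#' @param condition label carried into comparisons.
#' @return object of class `mfa_ensemble`: `samples` (n_ok x free
#'   parameters, natural scale), `net` (n_ok x all net fluxes),
#'   `failures` (tibble), `condition`, `seed`.
#' @export
monte_carlo <- function(fit, n = 1000, seed = 1, max_fail = 0.1,
                        maxiter = 60, ftol = 1e-8, noise_scale = 1, clamp = FALSE,
                        condition = "condition") {
  problem <- fit$problem
  base <- fitted_mids(fit)$fitted
  sig <- noise_scale * scale_error(100 * base, problem$error_model) / 100
  grp <- interaction(problem$data$observable, problem$data$time_min,
                     problem$data$replicate, drop = TRUE)
  fm <- problem$flux_measurements
  rows <- vector("list", n)
  fails <- list()
  for (i in seq_len(n)) {
    set.seed(seed + i)
    noisy <- base + stats::rnorm(length(base), 0, sig)
    if (clamp) {
      noisy <- pmax(pmin(noisy, 1), 0)
      tot <- tapply(noisy, grp, sum)[grp]
      noisy <- noisy / as.numeric(tot)
    }
    pr2 <- problem
    pr2$data$value <- noisy
    pr2$sigmas <- scale_error(100 * pmax(noisy, 0), problem$error_model) / 100
    if (!is.null(fm)) {
      pr2$flux_measurements$value <- fm$value +
        stats::rnorm(nrow(fm), 0, noise_scale * fm$sd)
    }
    res <- tryCatch(lm_warm_refit(pr2, fit$theta, maxiter = maxiter, ftol = ftol),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$ssr)) {
      fails[[length(fails) + 1L]] <- tibble::tibble(round = i, reason = "refit error")
      next
    }
    nat <- clamp_natural(to_natural(res$par, problem$pars), problem$pars)
    sp <- state_from_params(problem, nat)
    if (is.null(sp$state)) {
      fails[[length(fails) + 1L]] <- tibble::tibble(round = i, reason = "infeasible")
      next
    }
    rows[[i]] <- list(params = nat, net = sp$state$net, ssr = res$ssr, round = i)
  }
  ok <- !vapply(rows, is.null, TRUE)
  failures <- dplyr::bind_rows(fails)
  if (nrow(failures) / n > max_fail) {
    stop(sprintf("Monte Carlo refit failure rate %.1f%% exceeds %.0f%%",
                 100 * nrow(failures) / n, 100 * max_fail), call. = FALSE)
  }
  rows <- rows[ok]
  samples <- do.call(rbind, lapply(rows, `[[`, "params"))
  colnames(samples) <- problem$pars$parameter
  netm <- do.call(rbind, lapply(rows, `[[`, "net"))
  colnames(netm) <- paste0("net.", names(rows[[1]]$net))
  structure(list(samples = samples, net = netm,
                 ssr = vapply(rows, `[[`, 1, "ssr"),
                 round = vapply(rows, `[[`, 1, "round"),
                 failures = failures, condition = condition,
                 seed = seed, fit = fit),
            class = "mfa_ensemble")
}

#' @export
print.mfa_ensemble <- function(x, ...) {
  cat(sprintf("<mfa_ensemble> '%s': %d refits (%d failures), %d free parameters, seed %d\n",
              x$condition, nrow(x$samples), nrow(x$failures), ncol(x$samples), x$seed))
  invisible(x)
}

#' @rdname tidy.mfa_fit
#' @method tidy mfa_ensemble
#' @export
tidy.mfa_ensemble <- function(x, ...) {
  tibble::as_tibble(x$samples) |>
    dplyr::mutate(round = x$round, condition = x$condition) |>
    tidyr::pivot_longer(-c("round", "condition"),
                        names_to = "parameter", values_to = "value")
}

#' @rdname tidy.mfa_fit
#' @method glance mfa_ensemble
#' @export
glance.mfa_ensemble <- function(x, ...) {
  tibble::tibble(condition = x$condition, n = nrow(x$samples),
                 failures = nrow(x$failures), seed = x$seed)
}

#' Significance of between-condition parameter differences
#'
#' For each parameter, compares the two ensembles' confidence intervals:
#' at the 83.4% level when a two-sided variance-ratio test finds the
#' ensemble variances compatible (non-overlap then corresponds to
#' P = 0.05), or at [adjusted_level()] of the sd ratio otherwise. A
#' difference is significant when the two intervals do not overlap.
#'
#' @param a,b `mfa_ensemble` objects (or plain matrices with matching
#'   column names).
#' @param what compare all net fluxes (`"net"`) or the free parameter
#'   vector (`"params"`).
#' @param parameters optional subset of parameter names.
#' @param var_alpha level of the equal-variance gate.
#' @return tibble: parameter, means, CI bounds, rho, level, significant;
#'   symmetric in the argument order.
#' @export
compare_conditions <- function(a, b, what = c("net", "params"),
                               parameters = NULL, var_alpha = 0.05) {
  what <- match.arg(what)
  A <- if (inherits(a, "mfa_ensemble")) a[[what]] else as.matrix(a)
  B <- if (inherits(b, "mfa_ensemble")) b[[what]] else as.matrix(b)
  common <- intersect(colnames(A), colnames(B))
  if (is.null(parameters)) parameters <- common
  miss <- setdiff(parameters, common)
  if (length(miss)) stop(sprintf("parameter '%s' absent from both ensembles", miss[1]),
                         call. = FALSE)
  rows <- lapply(parameters, function(pname) {
    xa <- A[, pname]; xb <- B[, pname]
    sa <- stats::sd(xa); sb <- stats::sd(xb)
    if (sa == 0 && sb == 0) {
      rho <- 1; equal <- TRUE
    } else if (sa == 0 || sb == 0) {
      rho <- Inf; equal <- FALSE
    } else {
      Fst <- sa^2 / sb^2
      pv <- 2 * min(stats::pf(Fst, length(xa) - 1, length(xb) - 1),
                    1 - stats::pf(Fst, length(xa) - 1, length(xb) - 1))
      equal <- pv >= var_alpha
      rho <- sa / sb
    }
    level <- if (equal) 83.4 else adjusted_level(min(rho, 1e6))
    cia <- ci_from_ensemble(xa, level)
    cib <- ci_from_ensemble(xb, level)
    sig <- cia["upper"] < cib["lower"] || cib["upper"] < cia["lower"]
    tibble::tibble(parameter = pname,
                   estimate_a = mean(xa), lower_a = cia[["lower"]], upper_a = cia[["upper"]],
                   estimate_b = mean(xb), lower_b = cib[["lower"]], upper_b = cib[["upper"]],
                   rho = rho, level = level, significant = sig)
  })
  dplyr::bind_rows(rows)
}
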