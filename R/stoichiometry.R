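#' Stoichiometry matrix over balanced pools
#'
#' Rows are balanced metabolite pools, columns are reactions; entries are
#' net stoichiometric coefficients (products positive). The null-space
#' dimension of this matrix is the number of free net fluxes.
#'
#' @param model an `mfa_model`.
#' @return numeric matrix with dimnames (pools x reactions).
#' @export
stoichiometry_matrix <- function(model) {
  bal <- model$pools$name[model$pools$role == "balanced"]
  ids <- reaction_ids(model)
  S <- matrix(0, nrow = length(bal), ncol = length(ids),
              dimnames = list(bal, ids))
  for (r in model$reactions) {
    for (tm in r$reactants) {
      if (tm$pool %in% bal) S[tm$pool, r$id] <- S[tm$pool, r$id] - 1
    }
    for (tm in r$products) {
      if (tm$pool %in% bal) S[tm$pool, r$id] <- S[tm$pool, r$id] + 1
    }
  }
  S
}

#' Number of free net fluxes (null-space dimension)
#' @param model an `mfa_model`.
#' @return integer nullity of the stoichiometry matrix.
#' @export
n_free_fluxes <- function(model) {
  S <- stoichiometry_matrix(model)
  ncol(S) - qr(S)$rank
}

#' Export the stoichiometry matrix as TSV
#' @param model an `mfa_model`.
#' @param path output file.
#' @export
export_stoichiometry <- function(model, path) {
  S <- stoichiometry_matrix(model)
  utils::write.table(data.frame(pool = rownames(S), S, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a balanced flux state
#'
#' Given values for the model's declared free net fluxes, solves the
#' steady-state balance `S v = 0` for the remaining (dependent) net fluxes,
#' holding fixed fluxes (e.g. glucose uptake = 1) at their declared values.
#' Exchange fluxes (reversible reactions only) and pool sizes are carried
#' alongside the net fluxes; they do not enter the balance.
#'
#' @param model an `mfa_model` with `free`/`fixed` flux declarations.
#' @param free named numeric vector of free net flux values (names must
#'   equal `model$free`).
#' @param exchange named nonnegative vector of exchange fluxes for
#'   reversible reactions (missing entries default to 0).
#' @param pools named positive vector of pool sizes.
#' @param tol tolerance for the balance residual check.
#' @return an object of class `flux_state` with elements `net`, `exchange`,
#'   `pools`.
#' @export
flux_state <- function(model, free = NULL, exchange = NULL, pools = NULL,
                       tol = 1e-9) {
  S <- stoichiometry_matrix(model)
  ids <- colnames(S)
  fixed <- model$fixed
  if (is.null(free)) free <- stats::setNames(numeric(0), character(0))
  if (!setequal(names(free), model$free)) {
    stop(sprintf("free flux values must be named exactly {%s}",
                 paste(model$free, collapse = ", ")), call. = FALSE)
  }
  known <- c(fixed, free[model$free])
  dep <- setdiff(ids, names(known))
  v <- stats::setNames(numeric(length(ids)), ids)
  v[names(known)] <- known
  if (length(dep)) {
    A <- S[, dep, drop = FALSE]
    b <- if (length(known)) -S[, names(known), drop = FALSE] %*% known else
      numeric(nrow(S))
    qrA <- qr(A)
    if (qrA$rank < length(dep)) {
      stop(sprintf("dependent fluxes are not uniquely determined (rank %d < %d); declare more free fluxes",
                   qrA$rank, length(dep)), call. = FALSE)
    }
    sol <- qr.coef(qrA, b)
    v[dep] <- sol
  }
  resid <- max(abs(S %*% v))
  if (is.na(resid) || resid > tol) {
    stop(sprintf("flux state does not balance (max residual %.3g); the fixed/free values are inconsistent with the stoichiometry",
                 resid), call. = FALSE)
  }
  rev_ids <- reversible_ids(model)
  ex <- stats::setNames(rep(0, length(rev_ids)), rev_ids)
  if (!is.null(exchange)) {
    bad <- setdiff(names(exchange), rev_ids)
    if (length(bad)) stop(sprintf("exchange flux for non-reversible reaction '%s'", bad[1]),
                          call. = FALSE)
    if (any(exchange < 0)) stop("exchange fluxes must be nonnegative", call. = FALSE)
    ex[names(exchange)] <- exchange
  }
  irrev <- setdiff(ids, rev_ids)
  neg <- irrev[v[irrev] < -tol]
  if (length(neg)) {
    stop(sprintf("irreversible reaction '%s' has negative net flux %.4g", neg[1], v[neg[1]]),
         call. = FALSE)
  }
  ps <- stats::setNames(numeric(0), character(0))
  if (!is.null(pools)) {
    bad <- setdiff(names(pools), model$pools$name)
    if (length(bad)) stop(sprintf("unknown pool '%s' in pool sizes", bad[1]), call. = FALSE)
    if (any(pools <= 0)) stop("pool sizes must be positive", call. = FALSE)
    ps <- pools
  }
  structure(list(net = v, exchange = ex, pools = ps), class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state>\n  net:", paste(sprintf("%s=%.4g", names(x$net), x$net), collapse = " "), "\n")
  if (length(x$exchange)) cat("  exchange:",
    paste(sprintf("%s=%.4g", names(x$exchange), x$exchange), collapse = " "), "\n")
  if (length(x$pools)) cat("  pools:",
    paste(sprintf("%s=%.4g", names(x$pools), x$pools), collapse = " "), "\n")
  invisible(x)
}

# Precompute the structures of the balance solve so that repeated
# free -> full flux mapping (the inner loop of fitting) skips the
# stoichiometry and QR construction.
balance_cache <- function(model) {
  S <- stoichiometry_matrix(model)
  ids <- colnames(S)
  known <- c(names(model$fixed), model$free)
  dep <- setdiff(ids, known)
  qrA <- qr(S[, dep, drop = FALSE])
  if (qrA$rank < length(dep)) {
    stop("dependent fluxes are not uniquely determined; declare more free fluxes",
         call. = FALSE)
  }
  rev_ids <- reversible_ids(model)
  list(ids = ids, known = known, dep = dep, qrA = qrA,
       Sk = S[, known, drop = FALSE],
       fixed = model$fixed, rev_ids = rev_ids,
       irrev_dep = setdiff(dep, rev_ids))
}

# fast counterpart of flux_state() over a balance_cache; returns NULL on an
# infeasible (negative irreversible) state
flux_state_fast <- function(bc, free, exchange, pools, tol = 1e-9) {
  kv <- c(bc$fixed, free)[bc$known]
  v <- stats::setNames(numeric(length(bc$ids)), bc$ids)
  v[bc$known] <- kv
  if (length(bc$dep)) {
    v[bc$dep] <- qr.coef(bc$qrA, -(bc$Sk %*% kv))
  }
  if (any(v[bc$irrev_dep] < -tol)) return(NULL)
  ex <- stats::setNames(rep(0, length(bc$rev_ids)), bc$rev_ids)
  ex[names(exchange)] <- exchange
  structure(list(net = v, exchange = ex, pools = pools), class = "flux_state")
}

#' Directional flow rates of a flux state
#'
#' Expands net/exchange values into unidirectional rates: for a reversible
#' reaction with net v and exchange e, forward = max(v, 0) + e and
#' backward = max(-v, 0) + e; irreversible reactions have forward = v.
#'
#' @param model an `mfa_model`.
#' @param state a `flux_state`.
#' @return tibble with columns `reaction`, `direction` ("f"/"b"), `rate`.
#' @export
flow_rates <- function(model, state) {
  rows <- list()
  for (r in model$reactions) {
    v <- state$net[[r$id]]
    if (r$reversible) {
      e <- state$exchange[[r$id]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction = r$id, direction = c("f", "b"),
        rate = c(max(v, 0) + e, max(-v, 0) + e))
    } else {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        reaction = r$id, direction = "f", rate = v)
    }
  }
  dplyr::bind_rows(rows)
}

#' Free parameter vector of a fit design
#'
#' Enumerates the ordered free parameters of an estimation problem on a
#' model: free net fluxes, exchange fluxes of reversible reactions, fitted
#' pool sizes, free mixing/dilution fractions of the measurement groups,
#' and (by count only) the per-fragment MS normalisation factors.
#'
#' @param model an `mfa_model`.
#' @param fit_pools character vector of pools whose sizes are fitted.
#' @param n_normalisations number of multiplicative normalisation factors in
#'   the measurement design (counted in the total, not named individually).
#' @return tibble with columns `parameter`, `kind`; the attribute `n_total`
#'   includes the normalisation count.
#' @export
free_parameter_vector <- function(model, fit_pools = character(0),
                                  n_normalisations = 0) {
  rows <- list()
  if (length(model$free)) {
    rows[[1]] <- tibble::tibble(parameter = paste0("net.", model$free), kind = "net")
  }
  rev_ids <- reversible_ids(model)
  if (length(rev_ids)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(parameter = paste0("exch.", rev_ids),
                                                kind = "exchange")
  }
  if (length(fit_pools)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(parameter = paste0("pool.", fit_pools),
                                                kind = "pool")
  }
  for (m in model$measurements) {
    if (identical(m$weights, "free") && length(m$pools) > 1) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = paste0("mix.", m$observable, ".", m$pools[-1]), kind = "mixing")
    }
    if (identical(m$unlabelled, "free")) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        parameter = paste0("unlab.", m$observable), kind = "mixing")
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0 && n_normalisations == 0) {
    stop("design has no free parameters (over-determined constraint set)", call. = FALSE)
  }
  attr(out, "n_total") <- nrow(out) + as.integer(n_normalisations)
  out
}

#' Measurement and parameter bookkeeping for a fit design
#'
#' Combines measurement counts and parameter counts into the degrees of
#' freedom and the chi-squared acceptance window used to judge a fit.
#'
#' @param isotopologue_measurements number of independent isotopologue
#'   measurements fitted.
#' @param flux_measurements number of fixed-output (biomass) flux
#'   measurements.
#' @param normalisations number of MS normalisation factors.
#' @param free_fluxes number of free fluxes (net + exchange).
#' @param pool_sizes number of fitted pool sizes.
#' @param alpha two-sided significance level of the acceptance window.
#' @return one-row tibble: `n`, `p`, `df`, `lower`, `upper`.
#' @export
parameter_accounting <- function(isotopologue_measurements, flux_measurements,
                                 normalisations, free_fluxes, pool_sizes,
                                 alpha = 0.05) {
  n <- isotopologue_measurements + flux_measurements
  p <- normalisations + free_fluxes + pool_sizes
  w <- chi2_window(n - p, alpha = alpha)
  tibble::tibble(n = n, p = p, df = w$df, lower = w$lower, upper = w$upper)
}

#' Compose an observable MID from contributing pools
#'
#' Observed fragments mix subcellular pools upon extraction and may be
#' diluted by a pre-existing unlabelled fraction: the observable MID is the
#' weighted sum of the pool MIDs plus `unlabelled * M0`, with weights and
#' the unlabelled fraction summing to 1.
#'
#' @param pool_mids list (or matrix rows) of MID vectors, all of the same
#'   length.
#' @param weights nonnegative mixing weights, one per pool MID.
#' @param unlabelled unlabelled dilution fraction in `[0, 1)`.
#' @return composed MID vector summing to 1.
#' @examples
#' compose_observable(list(c(0, 1)), weights = 0.8, unlabelled = 0.2)
#' @export
compose_observable <- function(pool_mids, weights = NULL, unlabelled = 0) {
  if (is.matrix(pool_mids)) pool_mids <- asplit(pool_mids, 1)
  lens <- vapply(pool_mids, length, 1L)
  if (length(unique(lens)) != 1) {
    stop("contributing pool MIDs differ in carbon count", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep((1 - unlabelled) / length(pool_mids), length(pool_mids))
  if (length(weights) != length(pool_mids)) {
    stop("one weight per contributing pool MID required", call. = FALSE)
  }
  if (any(weights < 0) || unlabelled < 0) stop("weights must be nonnegative", call. = FALSE)
  s <- sum(weights) + unlabelled
  if (abs(s - 1) > 1e-6) stop("weights plus unlabelled fraction must sum to 1", call. = FALSE)
  out <- Reduce(`+`, Map(`*`, pool_mids, weights))
  out[1] <- out[1] + unlabelled
  out
}
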