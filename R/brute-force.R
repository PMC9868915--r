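#' Brute-force positional isotopomer simulation
#'
#' Independent oracle for the EMU cascade: integrates the full positional
#' isotopomer distribution of every non-source pool (2^n states per
#' n-carbon pool) with `deSolve::lsoda` and marginalizes to MIDs. Joint
#' distributions over multi-reactant flows are products of the reactant
#' marginals (well-mixed pools), the same assumption the EMU formulation
#' makes. Intended for small test networks only; a state-space guard
#' rejects larger problems.
#'
#' @param model an `mfa_model`.
#' @param state a balanced [flux_state()] with pool sizes for all balanced
#'   pools.
#' @param times output times (minutes).
#' @param substrate optional [source_patterns()] override.
#' @param observables compose measurement groups when `TRUE` (default);
#'   `FALSE` returns per-pool MIDs; `"raw"` returns the full positional
#'   isotopomer distributions (for symmetry checks).
#' @param mixing as in [simulate_mids()].
#' @param max_states guard on the total number of isotopomer states.
#' @param rtol,atol integration tolerances.
#' @return tibble in the [simulate_mids()] layout (observable or pool in the
#'   first column).
#' @export
simulate_isotopomers <- function(model, state, times, substrate = NULL,
                                 observables = TRUE, mixing = NULL,
                                 max_states = 5000, rtol = 1e-10, atol = 1e-12) {
  nc <- pool_carbons(model)
  role <- stats::setNames(model$pools$role, model$pools$name)
  sources <- if (is.null(substrate)) source_patterns(model) else substrate
  flows <- expand_flows(model)
  rates <- flow_rate_vector(list(flow_tab = tibble::tibble(
    idx = seq_along(flows),
    reaction = vapply(flows, `[[`, "", "reaction"),
    direction = vapply(flows, `[[`, "", "direction"),
    weight = vapply(flows, `[[`, 1, "weight"))), state)

  # dynamic pools: balanced pools with a declared size. Balanced pools
  # without a size may only feed sinks (accumulating pools are not part of
  # the labelling dynamics of the measured system).
  bal <- model$pools$name[role[model$pools$name] == "balanced"]
  dyn <- intersect(bal, names(state$pools))
  dropped <- setdiff(bal, dyn)
  for (fl in flows) {
    rp <- vapply(fl$reactants, `[[`, "", "pool")
    pp <- vapply(fl$products, `[[`, "", "pool")
    if (any(rp %in% dropped) && any(pp %in% dyn)) {
      stop(sprintf("pool '%s' needs a size: it feeds the measured system",
                   intersect(rp, dropped)[1]), call. = FALSE)
    }
  }
  sizes <- nc[dyn]
  if (sum(2^sizes) > max_states) {
    stop(sprintf("isotopomer state space too large (%d > %d)", sum(2^sizes), max_states),
         call. = FALSE)
  }
  offset <- c(0, cumsum(2^sizes))[seq_along(dyn)]
  names(offset) <- dyn
  nstate <- sum(2^sizes)

  # per-flow precomputation: reactant pools, joint enumeration, product maps
  flow_pre <- lapply(flows, function(fl) {
    rp <- vapply(fl$reactants, `[[`, "", "pool")
    rn <- nc[rp]
    njoint <- prod(2^rn)
    # joint index -> per-reactant isotopomer patterns
    labels <- matrix(0L, njoint, sum(rn))
    colnames(labels) <- unlist(lapply(fl$reactants, `[[`, "map"))
    idx <- 0L
    grid <- expand.grid(lapply(rn, function(n) 0:(2^n - 1L)))
    for (ri in seq_along(rp)) {
      bits <- t(vapply(grid[[ri]], function(v) as.integer(intToBits(v)[seq_len(rn[ri])]), integer(rn[ri])))
      cols <- (c(0, cumsum(rn))[ri] + 1):(c(0, cumsum(rn))[ri] + rn[ri])
      labels[, cols] <- bits
    }
    # per-reactant state index within its pool (1-based)
    ridx <- lapply(seq_along(rp), function(ri) grid[[ri]] + 1L)
    # product isotopomer index per joint state
    letter_of <- stats::setNames(seq_len(ncol(labels)), colnames(labels))
    pmaps <- lapply(fl$products, function(tm) {
      cols <- letter_of[tm$map]
      bits <- labels[, cols, drop = FALSE]
      as.integer(bits %*% 2^(seq_along(cols) - 1L)) + 1L
    })
    list(rpools = rp, ridx = ridx, pmaps = pmaps,
         ppools = vapply(fl$products, `[[`, "", "pool"))
  })

  src_dist <- function(pool, t) {
    src <- sources[[pool]]
    w <- drop(source_weights_at(src, t))
    n <- nc[[pool]]
    d <- numeric(2^n)
    for (r in seq_len(nrow(src$patterns))) {
      i <- as.integer(src$patterns[r, ] %*% 2^(seq_len(n) - 1L)) + 1L
      d[i] <- d[i] + w[r]
    }
    d
  }

  psize <- state$pools
  deriv <- function(t, y, parms) {
    dy <- numeric(nstate)
    get_dist <- function(pool) {
      if (role[[pool]] == "source") src_dist(pool, t)
      else y[offset[[pool]] + seq_len(2^nc[[pool]])]
    }
    for (fi in seq_along(flows)) {
      v <- rates[fi]
      if (v <= 0) next
      pre <- flow_pre[[fi]]
      if (any(pre$ppools %in% dyn)) {
        dists <- lapply(pre$rpools, get_dist)
        joint <- dists[[1]][pre$ridx[[1]]]
        if (length(dists) > 1) {
          for (ri in 2:length(dists)) joint <- joint * dists[[ri]][pre$ridx[[ri]]]
        }
        for (pi in seq_along(pre$ppools)) {
          pp <- pre$ppools[pi]
          if (!pp %in% dyn) next
          prod_dist <- rowsum(joint, pre$pmaps[[pi]])
          tgt <- offset[[pp]] + as.integer(rownames(prod_dist))
          dy[tgt] <- dy[tgt] + v * prod_dist
        }
      }
      for (rp in unique(pre$rpools)) {
        if (!rp %in% dyn) next
        mult <- sum(pre$rpools == rp)
        sel <- offset[[rp]] + seq_len(2^nc[[rp]])
        dy[sel] <- dy[sel] - v * mult * y[sel]
      }
    }
    for (p in dyn) {
      sel <- offset[[p]] + seq_len(2^nc[[p]])
      dy[sel] <- dy[sel] / psize[[p]]
    }
    list(dy)
  }

  y0 <- numeric(nstate)
  y0[offset + 1L] <- 1  # unlabelled isotopomer of each pool
  tgrid <- sort(unique(c(0, times)))
  out <- deSolve::lsoda(y0, tgrid, deriv, parms = NULL, rtol = rtol, atol = atol)
  ti <- match(sort(unique(times)), tgrid)

  pool_mid <- function(p) {
    sel <- 1 + offset[[p]] + seq_len(2^nc[[p]])
    dist <- out[ti, sel, drop = FALSE]
    wts <- vapply(0:(2^nc[[p]] - 1L), function(v) sum(as.integer(intToBits(v)[seq_len(nc[[p]])])), 1L)
    M <- matrix(0, length(ti), nc[[p]] + 1L)
    for (k in 0:nc[[p]]) {
      cls <- which(wts == k)
      M[, k + 1L] <- rowSums(dist[, cls, drop = FALSE])
    }
    M
  }

  tv <- sort(unique(times))
  if (identical(observables, "raw")) {
    dist <- lapply(dyn, function(p) {
      sel <- 1 + offset[[p]] + seq_len(2^nc[[p]])
      D <- out[ti, sel, drop = FALSE]
      colnames(D) <- vapply(0:(2^nc[[p]] - 1L), function(v) {
        paste(as.integer(intToBits(v)[seq_len(nc[[p]])]), collapse = "")
      }, "")
      D
    })
    names(dist) <- dyn
    return(list(times = tv, dist = dist))
  }
  if (!observables) {
    rows <- lapply(dyn, function(p) {
      M <- pool_mid(p)
      tibble::tibble(observable = p, time_min = rep(tv, nc[[p]] + 1L),
                     isotopologue = rep(0:nc[[p]], each = length(tv)),
                     fraction = as.vector(M))
    })
    return(dplyr::bind_rows(rows))
  }
  mix <- resolve_mixing(model$measurements, mixing)
  rows <- lapply(mix, function(m) {
    n <- nc[[m$pools[1]]]
    M <- Reduce(`+`, lapply(seq_along(m$pools), function(i) m$weights[i] * pool_mid(m$pools[i])))
    M[, 1] <- M[, 1] + m$unlabelled
    tibble::tibble(observable = m$observable, time_min = rep(tv, n + 1L),
                   isotopologue = rep(0:n, each = length(tv)),
                   fraction = as.vector(M))
  })
  dplyr::bind_rows(rows)
}
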