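#' Source-pool labelling patterns
#'
#' Source pools are described by a set of positional labelling patterns with
#' weights, which is what makes marginalization to arbitrary EMUs (atom
#' subsets) well defined. A substrate declared `enrichment=f` is a mixture
#' of the fully labelled molecule (weight f) and the unlabelled molecule; a
#' substrate declared by an MID spreads each mass class uniformly over its
#' positional isotopomers. Undeclared source pools are unlabelled. Weights
#' may be a function of time (minutes) returning one weight per pattern, to
#' express delayed or gradual substrate arrival.
#'
#' @param model an `mfa_model`.
#' @return named list: pool -> list(patterns = 0/1 matrix, weights = numeric
#'   or function(t) -> matrix n_patterns x length(t)).
#' @export
source_patterns <- function(model) {
  nc <- pool_carbons(model)
  src <- model$pools$name[model$pools$role == "source"]
  out <- list()
  for (p in src) {
    n <- nc[[p]]
    out[[p]] <- list(patterns = matrix(0, 1, n), weights = 1)
  }
  for (s in model$substrates) {
    n <- nc[[s$pool]]
    if (!is.null(s$enrichment)) {
      out[[s$pool]] <- list(
        patterns = rbind(rep(1, n), rep(0, n)),
        weights = c(s$enrichment, 1 - s$enrichment))
    } else if (!is.null(s$patterns)) {
      out[[s$pool]] <- list(patterns = s$patterns, weights = s$weights / sum(s$weights))
    } else {
      mid <- mid_vector(s$mid, n)
      pats <- list(); w <- c()
      for (k in 0:n) {
        if (mid[k + 1] <= 0) next
        cmb <- if (k == 0) matrix(integer(0), 1, 0) else utils::combn(n, k)
        if (k == 0) {
          pats[[length(pats) + 1L]] <- rep(0, n); w <- c(w, mid[1])
        } else {
          for (ci in seq_len(ncol(cmb))) {
            v <- rep(0, n); v[cmb[, ci]] <- 1
            pats[[length(pats) + 1L]] <- v
            w <- c(w, mid[k + 1] / ncol(cmb))
          }
        }
      }
      out[[s$pool]] <- list(patterns = do.call(rbind, pats), weights = w)
    }
  }
  out
}

# weights of a source over a time vector -> n_patterns x length(t) matrix
source_weights_at <- function(src, tvec) {
  if (is.function(src$weights)) {
    w <- src$weights(tvec)
    if (is.null(dim(w))) w <- matrix(w, nrow = nrow(src$patterns))
    w
  } else {
    matrix(src$weights, nrow = length(src$weights), ncol = length(tvec))
  }
}

# MID time-course of a source EMU: length(tvec) x (size+1)
source_emu_mid <- function(src, atoms, tvec) {
  s <- length(atoms)
  cnt <- if (s == 1) src$patterns[, atoms] else rowSums(src$patterns[, atoms, drop = FALSE])
  W <- source_weights_at(src, tvec)           # np x T
  Y <- matrix(0, length(tvec), s + 1L)
  agg <- rowsum(W, group = cnt)               # classes x T
  Y[, as.integer(rownames(agg)) + 1L] <- t(agg)
  Y
}

# assemble numeric A (m x m) and B (m x r) for one level from flow rates
assemble_level <- function(lev, rates) {
  m <- length(lev$keys)
  r <- length(lev$inputs)
  A <- matrix(0, m, m)
  if (!is.null(lev$A) && nrow(lev$A)) {
    flat <- (lev$A$j - 1L) * m + lev$A$i
    ag <- rowsum(rates[lev$A$flow], flat)
    A[as.integer(rownames(ag))] <- ag
  }
  d <- rowsum(rates[lev$cons$flow] * lev$cons$mult, lev$cons$i)
  ii <- as.integer(rownames(d))
  A[(ii - 1L) * m + ii] <- A[(ii - 1L) * m + ii] - d
  B <- matrix(0, m, max(r, 1L))
  if (!is.null(lev$B) && nrow(lev$B)) {
    flat <- (lev$B$input - 1L) * m + lev$B$i
    bg <- rowsum(rates[lev$B$flow], flat)
    B[as.integer(rownames(bg))] <- bg
  }
  list(A = A, B = B)
}

# input trajectories of one level: list over inputs of G x (size+1) matrices
level_inputs <- function(net, lev, sol, sources, grid, src_cache = NULL) {
  lapply(seq_along(lev$inputs), function(ii) {
    inp <- lev$inputs[[ii]]
    if (!is.null(src_cache) && !is.null(src_cache[[ii]])) return(src_cache[[ii]])
    comp_mid <- lapply(inp$components, function(k) {
      e <- net$emus[[k]]
      if (net$info$source[net$info$key == k]) {
        source_emu_mid(sources[[e$pool]], e$atoms, grid)
      } else {
        sol[[k]]
      }
    })
    Y <- comp_mid[[1]]
    if (length(comp_mid) > 1) {
      for (cm in comp_mid[-1]) {
        G <- nrow(Y)
        out <- matrix(0, G, ncol(Y) + ncol(cm) - 1L)
        for (a in seq_len(ncol(Y))) {
          cols <- a:(a + ncol(cm) - 1L)
          out[, cols] <- out[, cols] + Y[, a] * cm
        }
        Y <- out
      }
    }
    Y
  })
}

# I_k(lambda, h) = integral_0^h exp(lambda (h - s)) s^k ds for k = 0..3,
# vectorized over a matrix of lambda*h values. Exact recurrence
# I_k = (k I_{k-1} - h^k) / lambda away from zero; Taylor series
# I_k = h^{k+1} sum_m (lambda h)^m k! / (k+m+1)! near zero.
.exp_int_coef <- lapply(0:3, function(k) factorial(k) / factorial(k + (10:0) + 1))

exp_integrals <- function(LH, Hm) {
  E <- exp(LH)
  Lam <- LH / Hm
  I0 <- (E - 1) / Lam
  I1 <- (I0 - Hm) / Lam
  I2 <- (2 * I1 - Hm^2) / Lam
  I3 <- (3 * I2 - Hm^3) / Lam
  small <- which(abs(LH) < 0.5)
  if (length(small)) {
    ls <- LH[small]; hs <- Hm[small]
    for (k in 0:3) {
      cf <- .exp_int_coef[[k + 1]]
      acc <- 0
      for (m in seq_along(cf)) acc <- acc * ls + cf[m]
      val <- hs^(k + 1) * acc
      if (k == 0) I0[small] <- val
      else if (k == 1) I1[small] <- val
      else if (k == 2) I2[small] <- val
      else I3[small] <- val
    }
  }
  list(E = E, I0 = I0, I1 = I1, I2 = I2, I3 = I3)
}

# exponential-integrator solve of one level on the grid.
# M: m x m; U, Udot: m x (s+1) x G forcing and its time derivative (already
# premultiplied and row-scaled); returns m x (s+1) x G. Inputs are
# represented as cubic Hermite interpolants between grid nodes (values and
# derivatives known exactly at nodes), and the update within each interval
# is exact for that representation (variation of constants in the
# eigenbasis of M).
solve_level_expm <- function(M, U, Udot, grid, X0) {
  m <- nrow(M); sc <- dim(U)[2]; G <- length(grid)
  eg <- eigen(M, symmetric = FALSE)
  V <- eg$vectors; la <- eg$values
  Vi <- tryCatch(solve(V), error = function(e) NULL)
  if (is.null(Vi) || !all(is.finite(Mod(Vi))) ||
      max(Mod(Vi)) * max(Mod(V)) > 1e10) {
    return(NULL)  # defective/ill-conditioned: caller falls back to lsoda
  }
  # forcing (and derivative) in the eigenbasis, (m*sc) x G with m fastest
  UcM <- matrix(0i, m * sc, G)
  DcM <- matrix(0i, m * sc, G)
  for (c in seq_len(sc)) {
    rows <- (c - 1L) * m + seq_len(m)
    UcM[rows, ] <- Vi %*% matrix(U[, c, ], m, G)
    DcM[rows, ] <- Vi %*% matrix(Udot[, c, ], m, G)
  }
  H <- diff(grid)
  LH <- outer(la, H)
  Hm <- matrix(H, m, G - 1L, byrow = TRUE)
  ph <- exp_integrals(LH, Hm)
  # Hermite coefficients and the per-interval forcing integral, fully
  # vectorized across intervals; `tile` expands the per-eigenvalue weights
  # over the mass-index blocks
  U0 <- UcM[, -G, drop = FALSE]; U1 <- UcM[, -1L, drop = FALSE]
  D0 <- DcM[, -G, drop = FALSE]; D1 <- DcM[, -1L, drop = FALSE]
  Hrow <- matrix(H, m * sc, G - 1L, byrow = TRUE)
  Del <- U1 - U0
  C2 <- 3 * Del / Hrow^2 - (2 * D0 + D1) / Hrow
  C3 <- -2 * Del / Hrow^3 + (D0 + D1) / Hrow^2
  tile <- rep(seq_len(m), sc)
  W <- ph$I0[tile, , drop = FALSE] * U0 + ph$I1[tile, , drop = FALSE] * D0 +
    ph$I2[tile, , drop = FALSE] * C2 + ph$I3[tile, , drop = FALSE] * C3
  Et <- ph$E[tile, , drop = FALSE]
  Zall <- matrix(0i, m * sc, G)
  zv <- as.vector(Vi %*% X0)
  Zall[, 1] <- zv
  for (g in seq_len(G - 1L)) {
    zv <- Et[, g] * zv + W[, g]
    Zall[, g + 1L] <- zv
  }
  X <- array(0, dim = c(m, sc, G))
  for (c in seq_len(sc)) {
    X[, c, ] <- Re(V %*% Zall[(c - 1L) * m + seq_len(m), ])
  }
  X
}

solve_level_lsoda <- function(M, U, grid, X0, rtol, atol) {
  m <- nrow(M); sc <- dim(U)[2]
  ufun <- lapply(seq_len(m), function(i) {
    lapply(seq_len(sc), function(c) stats::approxfun(grid, U[i, c, ], rule = 2))
  })
  deriv <- function(t, y, parms) {
    X <- matrix(y, m, sc)
    Ut <- matrix(0, m, sc)
    for (i in seq_len(m)) for (c in seq_len(sc)) Ut[i, c] <- ufun[[i]][[c]](t)
    list(as.vector(M %*% X + Ut))
  }
  out <- deSolve::lsoda(as.vector(X0), grid, deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  X <- array(0, dim = c(m, sc, length(grid)))
  for (g in seq_along(grid)) X[, , g] <- matrix(out[g, -1], m, sc)
  X
}

#' Simulate EMU mass-isotopologue time-courses
#'
#' Integrates the cascaded EMU balance systems `P dX/dt = A(v) X + B(v) Y`
#' level by level in increasing EMU size, starting from the unlabelled
#' state. Two backends are provided: `"expm"` (default) eigendecomposes the
#' per-level system once per flux state and propagates it exactly between
#' nodes of a dense internal time grid, carrying lower-level solutions and
#' substrate inputs on that grid (piecewise-linear between nodes); `"lsoda"`
#' integrates the whole stacked cascade with a stiff-capable solver and
#' evaluates convolution inputs exactly from the current state, which is the
#' high-accuracy reference.
#'
#' @param net an [emu_network()].
#' @param state a balanced [flux_state()] whose `pools` cover every pool in
#'   the cascade (positive sizes).
#' @param times output times in minutes, sorted, first >= 0.
#' @param substrate optional [source_patterns()] list overriding the model's
#'   declared sources (e.g. with time-dependent weights).
#' @param method `"expm"` or `"lsoda"`.
#' @param grid_n number of internal grid nodes for the `"expm"` backend.
#' @param rtol,atol integration tolerances for the `"lsoda"` backend (and
#'   the per-level fallback of `"expm"`).
#' @param x0 optional named list EMU key -> MID vector giving a non-
#'   unlabelled initial state (used for piecewise simulations).
#' @return an `emu_solution`: EMU MIDs at `times` (`$values`), plus the full
#'   internal grid solution.
#' @export
emu_simulate <- function(net, state, times, substrate = NULL,
                         method = c("expm", "lsoda"), grid_n = 150,
                         rtol = 1e-8, atol = 1e-10, x0 = NULL, cache = NULL) {
  method <- method[[1]]
  if (!method %in% c("expm", "lsoda")) stop("method must be 'expm' or 'lsoda'", call. = FALSE)
  times <- sort(unique(as.numeric(times)))
  if (times[1] < 0) stop("times must be >= 0", call. = FALSE)
  sources <- if (is.null(substrate)) source_patterns(net$model) else substrate

  need_pools <- unique(unlist(lapply(net$levels, `[[`, "pools")))
  miss <- setdiff(need_pools, names(state$pools))
  if (length(miss)) stop(sprintf("missing pool size for '%s'", miss[1]), call. = FALSE)
  if (any(state$pools[need_pools] <= 0)) stop("pool sizes must be positive", call. = FALSE)

  rates <- flow_rate_vector(net, state)

  if (method == "expm") {
    if (!is.null(cache)) {
      grid <- cache$grid
    } else {
      Tmax <- max(times, 1e-6)
      tpos <- Tmax * exp(seq(log(1e-4), 0, length.out = grid_n))
      grid <- sort(unique(c(0, tpos, times)))
    }
  } else {
    grid <- sort(unique(c(0, times)))
  }

  sol <- list()
  if (method == "expm") {
    dsol <- list()  # exact time derivatives of the solved EMU MIDs
    rowconv <- function(A, B) {
      out <- matrix(0, nrow(A), ncol(A) + ncol(B) - 1L)
      for (a in seq_len(ncol(A))) {
        cols <- a:(a + ncol(B) - 1L)
        out[, cols] <- out[, cols] + A[, a] * B
      }
      out
    }
    G <- length(grid)
    for (s in as.character(net$sizes)) {
      lev <- net$levels[[s]]
      m <- length(lev$keys); sc <- lev$size + 1L
      AB <- assemble_level(lev, rates)
      P <- state$pools[lev$pools]
      # input trajectories and their derivatives (product rule over the
      # convolution components; source-EMU inputs contribute no derivative
      # except through their own weight functions, which are handled as
      # piecewise-linear)
      src_cache <- cache$src[[s]]
      YD <- lapply(seq_along(lev$inputs), function(ii) {
        inp <- lev$inputs[[ii]]
        if (!is.null(src_cache) && !is.null(src_cache[[ii]])) {
          return(list(Y = src_cache[[ii]],
                      D = matrix(0, G, ncol(src_cache[[ii]]))))
        }
        vals <- list(); ders <- list()
        for (k in inp$components) {
          e <- net$emus[[k]]
          if (net$info$source[net$info$key == k]) {
            v <- source_emu_mid(sources[[e$pool]], e$atoms, grid)
            vals[[k]] <- v; ders[[k]] <- matrix(0, G, ncol(v))
          } else {
            vals[[k]] <- sol[[k]]; ders[[k]] <- dsol[[k]]
          }
        }
        Y <- Reduce(rowconv, vals)
        D <- 0
        for (j in seq_along(vals)) {
          term <- ders[[j]]
          for (l in seq_along(vals)) if (l != j) term <- rowconv(term, vals[[l]])
          D <- D + term
        }
        if (length(vals) == 1L) D <- ders[[1]]
        list(Y = Y, D = D)
      })
      U <- array(0, dim = c(m, sc, G))
      Udot <- array(0, dim = c(m, sc, G))
      if (length(YD)) {
        for (c in seq_len(sc)) {
          Yc <- do.call(rbind, lapply(YD, function(x) x$Y[, c]))  # r x G
          Dc <- do.call(rbind, lapply(YD, function(x) x$D[, c]))
          U[, c, ] <- (AB$B %*% Yc) / P
          Udot[, c, ] <- (AB$B %*% Dc) / P
        }
      }
      M <- AB$A / P
      X0 <- matrix(0, m, sc); X0[, 1] <- 1
      if (!is.null(x0)) {
        for (k in intersect(names(x0), lev$keys)) X0[match(k, lev$keys), ] <- x0[[k]]
      }
      X <- solve_level_expm(M, U, Udot, grid, X0)
      if (is.null(X)) X <- solve_level_lsoda(M, U, grid, X0, rtol, atol)
      for (i in seq_len(m)) {
        sol[[lev$keys[i]]] <- pmax(t(X[i, , ]), 0)
      }
      # exact derivative of the level solution, for the next level's inputs
      for (c in seq_len(sc)) {
        Xd <- M %*% matrix(X[, c, ], m, G) + matrix(U[, c, ], m, G)
        for (i in seq_len(m)) {
          k <- lev$keys[i]
          if (is.null(dsol[[k]])) dsol[[k]] <- matrix(0, G, sc)
          dsol[[k]][, c] <- Xd[i, ]
        }
      }
    }
  } else {
    # stacked lsoda over every solved EMU
    layout <- list(); off <- 0L
    for (s in as.character(net$sizes)) {
      lev <- net$levels[[s]]
      for (i in seq_along(lev$keys)) {
        layout[[lev$keys[i]]] <- list(offset = off, sc = lev$size + 1L)
        off <- off + lev$size + 1L
      }
    }
    pre <- lapply(as.character(net$sizes), function(s) {
      lev <- net$levels[[s]]
      AB <- assemble_level(lev, rates)
      c(lev[c("keys", "size", "inputs")],
        list(Amat = AB$A, Bmat = AB$B, P = state$pools[lev$pools]))
    })
    y0 <- numeric(off)
    for (k in names(layout)) {
      e0 <- c(1, rep(0, layout[[k]]$sc - 1L))
      if (!is.null(x0) && k %in% names(x0)) e0 <- x0[[k]]
      y0[layout[[k]]$offset + seq_len(layout[[k]]$sc)] <- e0
    }
    emu_val <- function(y, k, t) {
      if (net$info$source[net$info$key == k]) {
        e <- net$emus[[k]]
        drop(source_emu_mid(sources[[e$pool]], e$atoms, t))
      } else {
        y[layout[[k]]$offset + seq_len(layout[[k]]$sc)]
      }
    }
    deriv <- function(t, y, parms) {
      dy <- numeric(length(y))
      for (lev in pre) {
        m <- length(lev$keys); sc <- lev$size + 1L
        X <- matrix(0, m, sc)
        for (i in seq_len(m)) {
          X[i, ] <- y[layout[[lev$keys[i]]]$offset + seq_len(sc)]
        }
        R <- lev$Amat %*% X
        if (length(lev$inputs)) {
          Yg <- do.call(rbind, lapply(lev$inputs, function(inp) {
            mids <- lapply(inp$components, function(k) emu_val(y, k, t))
            Reduce(convolve_mid, mids)
          }))
          R <- R + lev$Bmat %*% Yg
        }
        R <- R / lev$P
        for (i in seq_len(m)) {
          dy[layout[[lev$keys[i]]]$offset + seq_len(sc)] <- R[i, ]
        }
      }
      list(dy)
    }
    out <- deSolve::lsoda(y0, grid, deriv, parms = NULL, rtol = rtol, atol = atol)
    for (k in names(layout)) {
      sol[[k]] <- pmax(out[, 1 + layout[[k]]$offset + seq_len(layout[[k]]$sc), drop = FALSE], 0)
    }
  }

  ti <- match(times, grid)
  values <- lapply(sol, function(X) X[ti, , drop = FALSE])
  structure(list(times = times, grid = grid, t_index = ti, sol = sol,
                 values = values, state = state, method = method),
            class = "emu_solution")
}

#' Precompute the constant parts of repeated simulations
#'
#' For repeated simulation of the same network/times/substrate (the inner
#' loop of fitting), the internal time grid and every input trajectory that
#' depends only on the substrate (not on fluxes or lower-level solutions)
#' are constant; this builds them once.
#'
#' @param net an [emu_network()].
#' @param times output times.
#' @param grid_n internal grid density.
#' @param substrate optional [source_patterns()] override (must have
#'   constant weights to be cacheable).
#' @return cache list for [emu_simulate()]'s `cache` argument.
#' @export
build_sim_cache <- function(net, times, grid_n = 60, substrate = NULL) {
  sources <- if (is.null(substrate)) source_patterns(net$model) else substrate
  cacheable <- all(!vapply(sources, function(s) is.function(s$weights), TRUE))
  times <- sort(unique(as.numeric(times)))
  Tmax <- max(times, 1e-6)
  tpos <- Tmax * exp(seq(log(1e-4), 0, length.out = grid_n))
  grid <- sort(unique(c(0, tpos, times)))
  src <- list()
  for (s in as.character(net$sizes)) {
    lev <- net$levels[[s]]
    src[[s]] <- lapply(lev$inputs, function(inp) {
      all_src <- all(vapply(inp$components, function(k) {
        net$info$source[net$info$key == k]
      }, TRUE))
      if (!all_src || !cacheable) return(NULL)
      mids <- lapply(inp$components, function(k) {
        e <- net$emus[[k]]
        source_emu_mid(sources[[e$pool]], e$atoms, grid)
      })
      Y <- mids[[1]]
      if (length(mids) > 1) {
        for (cm in mids[-1]) {
          out <- matrix(0, nrow(Y), ncol(Y) + ncol(cm) - 1L)
          for (a in seq_len(ncol(Y))) {
            cols <- a:(a + ncol(cm) - 1L)
            out[, cols] <- out[, cols] + Y[, a] * cm
          }
          Y <- out
        }
      }
      Y
    })
  }
  list(grid = grid, src = src)
}

#' Isotopic steady state of the EMU cascade
#'
#' Solves `A(v) X = -B(v) Y` per level, the t -> infinity limit of
#' [emu_simulate()] for constant substrate weights.
#'
#' @inheritParams emu_simulate
#' @return named list EMU key -> MID vector.
#' @export
emu_steady_state <- function(net, state, substrate = NULL) {
  sources <- if (is.null(substrate)) source_patterns(net$model) else substrate
  # constant weights required; take the long-time value for functions
  sources <- lapply(sources, function(src) {
    if (is.function(src$weights)) src$weights <- drop(source_weights_at(src, 1e12))
    src
  })
  rates <- flow_rate_vector(net, state)
  need_pools <- unique(unlist(lapply(net$levels, `[[`, "pools")))
  state2 <- state
  if (length(setdiff(need_pools, names(state2$pools)))) {
    state2$pools <- stats::setNames(rep(1, length(need_pools)), need_pools)
  }
  sol <- list()
  for (s in as.character(net$sizes)) {
    lev <- net$levels[[s]]
    AB <- assemble_level(lev, rates)
    Ys <- level_inputs(net, lev, lapply(sol, function(v) matrix(v, 1)), sources, 0)
    rhs <- matrix(0, length(lev$keys), lev$size + 1L)
    if (length(Ys)) {
      Yg <- do.call(rbind, lapply(Ys, function(Y) Y[1, ]))
      rhs <- -(AB$B %*% Yg)
    }
    X <- tryCatch(solve(AB$A, rhs), error = function(e) {
      stop(sprintf("singular EMU balance at size %s (zero-throughput cycle?)", s),
           call. = FALSE)
    })
    for (i in seq_along(lev$keys)) sol[[lev$keys[i]]] <- pmax(X[i, ], 0)
  }
  sol
}

#' Compose observable MIDs from an EMU solution or steady state
#' @keywords internal
resolve_mixing <- function(meas, mixing = NULL) {
  lapply(meas, function(m) {
    mx <- if (!is.null(mixing)) mixing[[m$observable]] else NULL
    u <- if (identical(m$unlabelled, "free")) {
      if (is.null(mx$unlabelled)) {
        stop(sprintf("observable '%s': free unlabelled fraction needs a value in `mixing`",
                     m$observable), call. = FALSE)
      }
      mx$unlabelled
    } else m$unlabelled
    w <- if (identical(m$weights, "free")) {
      if (is.null(mx$weights)) {
        stop(sprintf("observable '%s': free weights need values in `mixing`", m$observable),
             call. = FALSE)
      }
      mx$weights
    } else if (identical(m$weights, "equal")) {
      rep((1 - u) / length(m$pools), length(m$pools))
    } else m$weights * (1 - u) / sum(m$weights)
    list(observable = m$observable, pools = m$pools, weights = w, unlabelled = u)
  })
}

#' Simulate observable MID time-courses as a tidy table
#'
#' Runs the EMU cascade for a model and flux state and composes the
#' declared measurement groups (compartment mixing weights + unlabelled
#' dilution) into observable MIDs.
#'
#' @param model an `mfa_model` or a prebuilt [emu_network()].
#' @param state a [flux_state()].
#' @param times output times (minutes).
#' @param mixing named list observable -> list(weights=, unlabelled=) giving
#'   values for mixing parameters declared `free` in the model.
#' @param ... passed to [emu_simulate()] (`method`, `substrate`, tolerances).
#' @return tibble with columns `observable`, `time_min`, `isotopologue`,
#'   `fraction`, of class `mid_timecourse`.
#' @export
simulate_mids <- function(model, state, times, mixing = NULL, ...) {
  net <- if (inherits(model, "emu_network")) model else emu_network(model)
  solu <- emu_simulate(net, state, times, ...)
  nc <- pool_carbons(net$model)
  mix <- resolve_mixing(net$measurements, mixing)
  rows <- lapply(mix, function(m) {
    n <- nc[[m$pools[1]]]
    mids <- lapply(seq_along(m$pools), function(i) {
      m$weights[i] * solu$values[[emu_key(m$pools[i], seq_len(n))]]
    })
    M <- Reduce(`+`, mids)
    M[, 1] <- M[, 1] + m$unlabelled
    tibble::tibble(
      observable = m$observable,
      time_min = rep(solu$times, n + 1L),
      isotopologue = rep(0:n, each = length(solu$times)),
      fraction = as.vector(M))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mid_timecourse", class(out))
  out
}
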