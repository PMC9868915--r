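#' @keywords internal
emu_key <- function(pool, atoms) paste0(pool, "|", paste(sort(atoms), collapse = ","))

#' Expand reactions into unidirectional flows
#'
#' Reversible reactions become a forward and a backward flow (rates
#' max(net,0)+exchange and max(-net,0)+exchange). Reactions producing a
#' symmetric metabolite are split into two half-weight variants with the
#' symmetric product's atom map reversed, which randomizes the orientation
#' of the symmetric molecule (succinate/fumarate scrambling).
#'
#' @keywords internal
expand_flows <- function(model) {
  sym <- model$pools$name[model$pools$symmetric]
  flows <- list()
  add_dir <- function(r, dir) {
    base <- list(reaction = r$id, direction = dir, weight = 1,
                 reactants = if (dir == "f") r$reactants else r$products,
                 products  = if (dir == "f") r$products  else r$reactants)
    variants <- list(base)
    for (pi in seq_along(base$products)) {
      if (base$products[[pi]]$pool %in% sym) {
        variants <- unlist(lapply(variants, function(v) {
          v2 <- v
          v2$products[[pi]]$map <- rev(v2$products[[pi]]$map)
          v$weight <- v$weight / 2; v2$weight <- v2$weight / 2
          list(v, v2)
        }), recursive = FALSE)
      }
    }
    variants
  }
  for (r in model$reactions) {
    flows <- c(flows, add_dir(r, "f"))
    if (r$reversible) flows <- c(flows, add_dir(r, "b"))
  }
  flows
}

#' Decompose a network into the EMU cascade of a set of observables
#'
#' Back-traces elementary metabolite units (EMUs) from the full-molecule
#' fragments of the measured pools through the atom-transition flows,
#' creating convolution nodes where a product EMU draws carbons from more
#' than one reactant molecule. The result groups EMUs by size and stores,
#' per size level, the index structure of the linear balance system
#' `P dX/dt = A(v) X + B(v) Y` so that the numeric matrices can be
#' assembled cheaply for any flux state.
#'
#' @param model an `mfa_model`.
#' @param targets character vector of observable names (default: all
#'   declared measurement groups).
#' @return an object of class `emu_network`.
#' @export
emu_network <- function(model, targets = NULL) {
  meas <- model$measurements
  if (is.null(targets)) targets <- vapply(meas, `[[`, "", "observable")
  meas <- meas[vapply(meas, function(m) m$observable %in% targets, TRUE)]
  if (!length(meas)) stop("no measurement groups selected as targets", call. = FALSE)

  nc <- pool_carbons(model)
  role <- stats::setNames(model$pools$role, model$pools$name)
  flows <- expand_flows(model)

  # ---- back-trace EMUs -----------------------------------------------------
  emus <- list()   # key -> list(pool, atoms, size, prod = list of routes)
  queue <- list()
  push <- function(pool, atoms) {
    k <- emu_key(pool, atoms)
    if (is.null(emus[[k]])) {
      emus[[k]] <<- list(pool = pool, atoms = sort(atoms), size = length(atoms),
                         prod = list())
      queue[[length(queue) + 1L]] <<- k
    }
    k
  }
  for (m in meas) for (p in m$pools) push(p, seq_len(nc[[p]]))

  qi <- 0L
  while (qi < length(queue)) {
    qi <- qi + 1L
    k <- queue[[qi]]
    e <- emus[[k]]
    if (role[[e$pool]] == "source") next  # terminal: substrate-defined
    routes <- list()
    for (fi in seq_along(flows)) {
      fl <- flows[[fi]]
      for (term in fl$products) {
        if (term$pool != e$pool) next
        letters <- term$map[e$atoms]
        comps <- list()
        for (rt in fl$reactants) {
          pos <- which(rt$map %in% letters)
          if (length(pos)) {
            comps[[length(comps) + 1L]] <- list(pool = rt$pool, atoms = sort(pos))
          }
        }
        stopifnot(sum(vapply(comps, function(cc) length(cc$atoms), 1L)) == e$size)
        keys <- vapply(comps, function(cc) push(cc$pool, cc$atoms), "")
        routes[[length(routes) + 1L]] <- list(flow = fi, components = keys)
      }
    }
    if (!length(routes)) {
      stop(sprintf("EMU %s has no producing flow: target unreachable from any substrate", k),
           call. = FALSE)
    }
    emus[[k]]$prod <- routes
    # re-read e not needed; emus updated
  }

  # ---- group solved EMUs by size and build index structures ---------------
  keys <- names(emus)
  info <- tibble::tibble(
    key = keys,
    pool = vapply(emus, `[[`, "", "pool"),
    size = vapply(emus, `[[`, 1L, "size"),
    source = vapply(emus, function(e) role[[e$pool]] == "source", TRUE))
  solved <- info[!info$source, , drop = FALSE]
  sizes <- sort(unique(solved$size))

  # flow rate expression: per flow, (reaction, direction, weight)
  flow_tab <- tibble::tibble(
    idx = seq_along(flows),
    reaction = vapply(flows, `[[`, "", "reaction"),
    direction = vapply(flows, `[[`, "", "direction"),
    weight = vapply(flows, `[[`, 1, "weight"))

  # consumption multiplicity per (pool, flow)
  cons <- list()
  for (fi in seq_along(flows)) {
    for (rt in flows[[fi]]$reactants) {
      kk <- rt$pool
      cons[[length(cons) + 1L]] <- tibble::tibble(pool = kk, flow = fi)
    }
  }
  cons <- dplyr::count(dplyr::bind_rows(cons), .data$pool, .data$flow, name = "mult")

  levels <- list()
  for (s in sizes) {
    lev_keys <- solved$key[solved$size == s]
    idx_of <- stats::setNames(seq_along(lev_keys), lev_keys)
    A_terms <- list(); B_terms <- list(); inputs <- list()
    get_input <- function(desc_key, desc) {
      if (!desc_key %in% names(inputs)) inputs[[desc_key]] <<- desc
      match(desc_key, names(inputs))
    }
    for (k in lev_keys) {
      i <- idx_of[[k]]
      for (rt in emus[[k]]$prod) {
        comps <- rt$components
        if (length(comps) == 1L && !info$source[info$key == comps] &&
            emus[[comps]]$size == s) {
          A_terms[[length(A_terms) + 1L]] <- tibble::tibble(
            i = i, j = idx_of[[comps]], flow = rt$flow)
        } else {
          desc_key <- paste(comps, collapse = " x ")
          ii <- get_input(desc_key, list(components = comps))
          B_terms[[length(B_terms) + 1L]] <- tibble::tibble(
            i = i, input = ii, flow = rt$flow)
        }
      }
    }
    lev_pools <- vapply(lev_keys, function(k) emus[[k]]$pool, "")
    cons_lev <- dplyr::inner_join(
      tibble::tibble(i = seq_along(lev_keys), pool = lev_pools), cons, by = "pool",
      relationship = "many-to-many")
    levels[[as.character(s)]] <- list(
      size = s, keys = lev_keys, pools = lev_pools,
      A = dplyr::bind_rows(A_terms), B = dplyr::bind_rows(B_terms),
      cons = cons_lev, inputs = inputs)
  }

  structure(list(model = model, flows = flows, flow_tab = flow_tab,
                 emus = emus, info = info, sizes = sizes, levels = levels,
                 targets = targets, measurements = meas),
            class = "emu_network")
}

#' @export
print.emu_network <- function(x, ...) {
  cat(sprintf("<emu_network> %d EMUs (%d solved) over sizes {%s}; %d flows; targets: %s\n",
              nrow(x$info), sum(!x$info$source),
              paste(x$sizes, collapse = ","), length(x$flows),
              paste(x$targets, collapse = ", ")))
  invisible(x)
}

#' Numeric flow rates for a flux state
#' @keywords internal
flow_rate_vector <- function(net, state) {
  ft <- net$flow_tab
  rates <- numeric(nrow(ft))
  v <- state$net; ex <- state$exchange
  for (r in seq_len(nrow(ft))) {
    id <- ft$reaction[r]
    vn <- v[[id]]
    e <- if (id %in% names(ex)) ex[[id]] else 0
    rates[r] <- ft$weight[r] * if (ft$direction[r] == "f") max(vn, 0) + e else max(-vn, 0) + e
  }
  rates
}
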