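#' Parse a plain-text atom-transition model
#'
#' Reads the package's model-definition dialect: one declaration per line,
#' `#` comments allowed. Recognised forms:
#'
#' \preformatted{
#' pool NAME CARBONS [source|sink] [symmetric]
#' substrate NAME enrichment=F            # F fully (U-13C) labelled, 1-F unlabelled
#' substrate NAME mid=a0,a1,...,an        # mass classes spread uniformly over positions
#' fixed ID = VALUE
#' free ID [ID ...]
#' measure OBS : POOL[,POOL...] [weights=w1,w2|free] [unlabelled=U|free]
#' ID: A (ab) + B (c) -> C (abc)          # or <-> for reversible
#' }
#'
#' Atom maps use lowercase letters, one letter per carbon; the multiset of
#' letters must match between the two sides of a reaction (carbon
#' conservation, CO2 explicit) and every letter appears exactly once per
#' side. Pools declared `source` or `sink` are exempt from steady-state
#' balancing; `symmetric` pools (e.g. succinate, fumarate) have the two
#' orientation-equivalent atom maps averaged with weight 0.5 whenever they
#' are produced, the conventional treatment of rotationally symmetric
#' intermediates. Compartments are encoded in pool names by suffix
#' (".c", ".p", ".m", ".v") but carry no special semantics beyond naming.
#'
#' Reactions may carry options after a `|`: `pseudo` marks a non-biochemical
#' mixing/dilution flux, `class=NAME` tags the pathway group.
#'
#' @param text character scalar (whole document) or vector of lines.
#' @return an object of class `mfa_model`.
#' @seealso [write_mfa_model()], [stoichiometry_matrix()], [flux_state()]
#' @export
parse_mfa_model <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(text)
  }
  perr <- function(i, msg) {
    stop(sprintf("model line %d: %s [%s]", i, msg, trimws(lines[i])), call. = FALSE)
  }

  pools <- list(); reactions <- list(); substrates <- list()
  measurements <- list(); fixed <- c(); free <- character(0)

  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next

    if (grepl("^pool\\s", ln)) {
      tk <- strsplit(ln, "\\s+")[[1]][-1]
      if (length(tk) < 2) perr(i, "pool needs a name and a carbon count")
      nc <- suppressWarnings(as.integer(tk[2]))
      if (is.na(nc) || nc < 1) perr(i, "carbon count must be a positive integer")
      flags <- tk[-(1:2)]
      bad <- setdiff(flags, c("source", "sink", "symmetric"))
      if (length(bad)) perr(i, paste("unknown pool flag:", bad[1]))
      role <- if ("source" %in% flags) "source" else if ("sink" %in% flags) "sink" else "balanced"
      if (tk[1] %in% vapply(pools, `[[`, "", "name")) perr(i, "duplicate pool")
      pools[[length(pools) + 1L]] <- list(
        name = tk[1], carbons = nc, role = role,
        symmetric = "symmetric" %in% flags)

    } else if (grepl("^substrate\\s", ln)) {
      tk <- strsplit(ln, "\\s+")[[1]][-1]
      if (length(tk) < 2) perr(i, "substrate needs a pool and an enrichment= or mid= spec")
      spec <- paste(tk[-1], collapse = " ")
      s <- list(pool = tk[1])
      if (grepl("^enrichment=", spec)) {
        f <- suppressWarnings(as.numeric(sub("^enrichment=", "", spec)))
        if (is.na(f) || f < 0 || f > 1) perr(i, "enrichment must be in [0, 1]")
        s$enrichment <- f
      } else if (grepl("^mid=", spec)) {
        v <- suppressWarnings(as.numeric(strsplit(sub("^mid=", "", spec), ",")[[1]]))
        if (anyNA(v)) perr(i, "bad mid= vector")
        s$mid <- v
      } else if (grepl("^pattern=", spec)) {
        entries <- strsplit(sub("^pattern=", "", spec), ",")[[1]]
        pw <- lapply(entries, function(e) {
          pp <- strsplit(e, ":", fixed = TRUE)[[1]]
          if (length(pp) != 2 || !grepl("^[01]+$", pp[1])) perr(i, "bad pattern= entry")
          list(pattern = as.integer(strsplit(pp[1], "")[[1]]),
               weight = suppressWarnings(as.numeric(pp[2])))
        })
        if (anyNA(vapply(pw, `[[`, 1, "weight"))) perr(i, "bad pattern= weight")
        s$patterns <- do.call(rbind, lapply(pw, `[[`, "pattern"))
        s$weights <- vapply(pw, `[[`, 1, "weight")
      } else perr(i, "substrate spec must be enrichment=F, mid=a0,a1,... or pattern=BITS:w,...")
      substrates[[length(substrates) + 1L]] <- s

    } else if (grepl("^fixed\\s", ln)) {
      m <- regmatches(ln, regexec("^fixed\\s+(\\S+)\\s*=\\s*(\\S+)$", ln))[[1]]
      if (length(m) != 3) perr(i, "expected 'fixed ID = VALUE'")
      v <- suppressWarnings(as.numeric(m[3]))
      if (is.na(v)) perr(i, "fixed value is not numeric")
      fixed[m[2]] <- v

    } else if (grepl("^free\\s", ln)) {
      free <- c(free, strsplit(ln, "\\s+")[[1]][-1])

    } else if (grepl("^measure\\s", ln)) {
      m <- regmatches(ln, regexec("^measure\\s+(\\S+)\\s*:\\s*(.*)$", ln))[[1]]
      if (length(m) != 3) perr(i, "expected 'measure OBS : POOLS [options]'")
      rest <- strsplit(trimws(m[3]), "\\s+")[[1]]
      pls <- trimws(strsplit(rest[1], ",")[[1]])
      opt <- rest[-1]
      wspec <- "equal"; uspec <- 0
      for (o in opt) {
        if (grepl("^weights=", o)) {
          w <- sub("^weights=", "", o)
          wspec <- if (w == "free") "free" else {
            v <- suppressWarnings(as.numeric(strsplit(w, ",")[[1]]))
            if (anyNA(v) || length(v) != length(pls)) perr(i, "bad weights=")
            v
          }
        } else if (grepl("^unlabelled=", o)) {
          u <- sub("^unlabelled=", "", o)
          uspec <- if (u == "free") "free" else {
            v <- suppressWarnings(as.numeric(u))
            if (is.na(v) || v < 0 || v >= 1) perr(i, "unlabelled= must be in [0, 1)")
            v
          }
        } else perr(i, paste("unknown measure option:", o))
      }
      measurements[[length(measurements) + 1L]] <- list(
        observable = m[2], pools = pls, weights = wspec, unlabelled = uspec)

    } else if (grepl("^\\S+\\s*:", ln)) {
      m <- regmatches(ln, regexec("^(\\S+?)\\s*:\\s*(.*)$", ln))[[1]]
      id <- m[1 + 1]; body <- m[3]
      opts <- ""
      if (grepl("\\|", body)) {
        parts <- strsplit(body, "\\|", fixed = FALSE)[[1]]
        body <- trimws(parts[1]); opts <- trimws(paste(parts[-1], collapse = " "))
      }
      rev <- grepl("<->", body, fixed = TRUE)
      sides <- strsplit(body, if (rev) "<->" else "->", fixed = TRUE)[[1]]
      if (length(sides) != 2) perr(i, "expected 'LHS -> RHS' or 'LHS <-> RHS'")
      parse_side <- function(side) {
        terms <- strsplit(side, "+", fixed = TRUE)[[1]]
        lapply(terms, function(tm) {
          mm <- regmatches(tm, regexec("^\\s*(\\S+)\\s*\\(([a-z]+)\\)\\s*$", tm))[[1]]
          if (length(mm) != 3) perr(i, sprintf("bad term '%s' (need 'POOL (map)')", trimws(tm)))
          list(pool = mm[2], map = strsplit(mm[3], "")[[1]])
        })
      }
      optv <- strsplit(opts, "\\s+")[[1]]
      optv <- optv[optv != ""]
      pseudo <- "pseudo" %in% optv
      class <- NA_character_
      for (o in optv) {
        if (grepl("^class=", o)) class <- sub("^class=", "", o)
        else if (o != "pseudo") perr(i, paste("unknown reaction option:", o))
      }
      if (id %in% vapply(reactions, `[[`, "", "id")) perr(i, paste("duplicate reaction id", id))
      reactions[[length(reactions) + 1L]] <- list(
        id = id, reversible = rev, pseudo = pseudo, class = class,
        reactants = parse_side(sides[1]), products = parse_side(sides[2]),
        line = i)
    } else {
      perr(i, "unrecognised declaration")
    }
  }

  model <- structure(list(
    pools = dplyr::bind_rows(lapply(pools, tibble::as_tibble)),
    reactions = reactions,
    substrates = substrates,
    measurements = measurements,
    fixed = fixed,
    free = free
  ), class = "mfa_model")
  validate_mfa_model(model)
  model
}

validate_mfa_model <- function(model) {
  p <- model$pools
  if (nrow(p) == 0) stop("model declares no pools", call. = FALSE)
  nc <- stats::setNames(p$carbons, p$name)
  for (r in model$reactions) {
    at <- function(side) unlist(lapply(side, `[[`, "map"))
    for (term in c(r$reactants, r$products)) {
      if (!term$pool %in% p$name) {
        stop(sprintf("reaction '%s' (line %d): unknown pool '%s'", r$id, r$line, term$pool),
             call. = FALSE)
      }
      if (length(term$map) != nc[[term$pool]]) {
        stop(sprintf("reaction '%s' (line %d): atom map '%s' has %d letters but pool '%s' has %d carbons",
                     r$id, r$line, paste(term$map, collapse = ""), length(term$map),
                     term$pool, nc[[term$pool]]), call. = FALSE)
      }
    }
    lhs <- at(r$reactants); rhs <- at(r$products)
    if (anyDuplicated(lhs) || anyDuplicated(rhs)) {
      stop(sprintf("reaction '%s' (line %d): atom-map letter reused within one side",
                   r$id, r$line), call. = FALSE)
    }
    if (!identical(sort(lhs), sort(rhs))) {
      stop(sprintf("reaction '%s' (line %d): atom maps do not conserve carbon (LHS '%s' vs RHS '%s')",
                   r$id, r$line, paste(sort(lhs), collapse = ""),
                   paste(sort(rhs), collapse = "")), call. = FALSE)
    }
  }
  for (s in model$substrates) {
    if (!s$pool %in% p$name) stop(sprintf("substrate pool '%s' not declared", s$pool), call. = FALSE)
    if (p$role[p$name == s$pool] != "source") {
      stop(sprintf("substrate pool '%s' must be declared 'source'", s$pool), call. = FALSE)
    }
    if (!is.null(s$mid) && length(s$mid) != nc[[s$pool]] + 1) {
      stop(sprintf("substrate '%s': mid length must be %d", s$pool, nc[[s$pool]] + 1), call. = FALSE)
    }
    if (!is.null(s$patterns) && ncol(s$patterns) != nc[[s$pool]]) {
      stop(sprintf("substrate '%s': patterns must have %d positions", s$pool, nc[[s$pool]]),
           call. = FALSE)
    }
  }
  rids <- vapply(model$reactions, `[[`, "", "id")
  for (f in names(model$fixed)) {
    if (!f %in% rids) stop(sprintf("fixed flux '%s' is not a reaction id", f), call. = FALSE)
  }
  for (f in model$free) {
    if (!f %in% rids) stop(sprintf("free flux '%s' is not a reaction id", f), call. = FALSE)
  }
  for (m in model$measurements) {
    miss <- setdiff(m$pools, p$name)
    if (length(miss)) stop(sprintf("measurement '%s': unknown pool '%s'", m$observable, miss[1]),
                           call. = FALSE)
    ncs <- unique(nc[m$pools])
    if (length(ncs) != 1) stop(sprintf("measurement '%s': contributing pools differ in carbon count",
                                       m$observable), call. = FALSE)
  }
  invisible(model)
}

#' @export
print.mfa_model <- function(x, ...) {
  nrev <- sum(vapply(x$reactions, `[[`, TRUE, "reversible"))
  cat(sprintf("<mfa_model> %d pools (%d balanced), %d reactions (%d reversible), %d measurement group(s)\n",
              nrow(x$pools), sum(x$pools$role == "balanced"),
              length(x$reactions), nrev, length(x$measurements)))
  if (length(x$free)) cat("  free fluxes:", paste(x$free, collapse = ", "), "\n")
  if (length(x$fixed)) cat("  fixed fluxes:",
                           paste(sprintf("%s=%g", names(x$fixed), x$fixed), collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a model back to its text form
#'
#' `write_mfa_model()` produces a document that [parse_mfa_model()] reparses
#' to an identical model (round-trip property).
#'
#' @param model an `mfa_model`.
#' @param path optional file path; when `NULL` the text is returned.
#' @return character vector of lines, invisibly when writing to a file.
#' @export
write_mfa_model <- function(model, path = NULL) {
  p <- model$pools
  out <- c("# pools", sprintf("pool %s %d%s%s", p$name, p$carbons,
    ifelse(p$role == "balanced", "", paste0(" ", p$role)),
    ifelse(p$symmetric, " symmetric", "")))
  if (length(model$substrates)) {
    out <- c(out, "# substrates")
    for (s in model$substrates) {
      out <- c(out, if (!is.null(s$enrichment)) {
        sprintf("substrate %s enrichment=%.10g", s$pool, s$enrichment)
      } else if (!is.null(s$patterns)) {
        sprintf("substrate %s pattern=%s", s$pool, paste(
          sprintf("%s:%s", apply(s$patterns, 1, paste, collapse = ""),
                  format(s$weights, digits = 12)), collapse = ","))
      } else {
        sprintf("substrate %s mid=%s", s$pool, paste(format(s$mid, digits = 12), collapse = ","))
      })
    }
  }
  if (length(model$fixed) || length(model$free)) out <- c(out, "# fluxes")
  for (f in names(model$fixed)) out <- c(out, sprintf("fixed %s = %.10g", f, model$fixed[[f]]))
  if (length(model$free)) out <- c(out, paste("free", paste(model$free, collapse = " ")))
  if (length(model$measurements)) {
    out <- c(out, "# measurements")
    for (m in model$measurements) {
      wtxt <- if (identical(m$weights, "equal")) "" else if (identical(m$weights, "free")) {
        " weights=free"
      } else paste0(" weights=", paste(format(m$weights, digits = 12), collapse = ","))
      utxt <- if (identical(m$unlabelled, "free")) " unlabelled=free" else if (
        is.numeric(m$unlabelled) && m$unlabelled != 0) {
        paste0(" unlabelled=", format(m$unlabelled, digits = 12))
      } else ""
      out <- c(out, sprintf("measure %s : %s%s%s", m$observable,
                            paste(m$pools, collapse = ","), wtxt, utxt))
    }
  }
  out <- c(out, "# reactions")
  side_txt <- function(side) {
    paste(vapply(side, function(tm) sprintf("%s (%s)", tm$pool, paste(tm$map, collapse = "")), ""),
          collapse = " + ")
  }
  for (r in model$reactions) {
    opts <- c(if (r$pseudo) "pseudo", if (!is.na(r$class)) paste0("class=", r$class))
    out <- c(out, sprintf("%s: %s %s %s%s", r$id, side_txt(r$reactants),
                          if (r$reversible) "<->" else "->", side_txt(r$products),
                          if (length(opts)) paste0(" | ", paste(opts, collapse = " ")) else ""))
  }
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Read a model definition from a file
#' @param path path to a model text file.
#' @return an `mfa_model`.
#' @export
read_mfa_model <- function(path) parse_mfa_model(readLines(path))

reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

reversible_ids <- function(model) {
  ids <- reaction_ids(model)
  ids[vapply(model$reactions, `[[`, TRUE, "reversible")]
}

pool_carbons <- function(model) stats::setNames(model$pools$carbons, model$pools$name)
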