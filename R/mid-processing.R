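#' Natural-abundance correction matrix for carbon
#'
#' `C[i, j]` is the probability that a molecule with `j` tracer-derived
#' labels is observed at mass `i` because some of its `n - j` remaining
#' carbons are naturally 13C: `C[i,j] = choose(n-j, i-j) p^(i-j)
#' (1-p)^(n-j-(i-j))` for `i >= j`.
#'
#' @param n_carbons carbon count of the fragment.
#' @param p13 natural 13C abundance (default 0.0107).
#' @return (n+1) x (n+1) lower-triangular matrix.
#' @export
natural_abundance_matrix <- function(n_carbons, p13 = 0.0107) {
  n <- n_carbons
  C <- matrix(0, n + 1, n + 1)
  for (j in 0:n) {
    k <- 0:(n - j)
    C[j + 1 + k, j + 1] <- stats::dbinom(k, n - j, p13)
  }
  C
}

#' Correct an observed MID for natural 13C abundance
#'
#' Solves the nonnegative least-squares system `C x = raw` for the
#' tracer-only MID `x`, where `C` is [natural_abundance_matrix()]. This is
#' the least-squares carbon-correction core of resolution-aware correction
#' tools; heavy isotopes of other elements are not modelled.
#'
#' @param raw observed MID (fractions or mol%).
#' @param n_carbons carbon count; default inferred from `length(raw) - 1`.
#' @param p13 natural 13C abundance, in `[0, 0.05]`.
#' @param tol negative-mass tolerance: if the nonnegative solution misfits
#'   the observed vector by more than `tol` (infinity norm) a warning flags
#'   a measurement anomaly.
#' @return corrected MID, renormalized to sum 1.
#' @export
correct_natural_abundance <- function(raw, n_carbons = length(raw) - 1L,
                                      p13 = 0.0107, tol = 1e-6) {
  if (p13 < 0 || p13 > 0.05) stop("p13 must be in [0, 0.05]", call. = FALSE)
  raw <- mid_vector(raw, n_carbons)
  if (p13 == 0) return(raw)
  C <- natural_abundance_matrix(n_carbons, p13)
  x <- pracma::lsqnonneg(C, raw)$x
  resid <- max(abs(C %*% x - raw))
  if (resid > tol) {
    warning(sprintf("natural-abundance correction misfit %.3g: negative mass beyond tolerance (measurement anomaly)",
                    resid), call. = FALSE)
  }
  x / sum(x)
}

#' Forward-convolve a tracer MID with natural abundance
#'
#' Inverse of [correct_natural_abundance()]: predicts the observed MID of a
#' fragment whose tracer-only MID is `mid`.
#'
#' @inheritParams correct_natural_abundance
#' @param mid tracer-only MID.
#' @return observed MID.
#' @export
apply_natural_abundance <- function(mid, n_carbons = length(mid) - 1L, p13 = 0.0107) {
  drop(natural_abundance_matrix(n_carbons, p13) %*% mid_vector(mid, n_carbons))
}

# squared distance of obs to alpha*contaminant + (1-alpha)*simplex point
.deconv_inner <- function(alpha, observed, contaminant) {
  if (alpha >= 1) return(list(obj = sum((observed - contaminant)^2),
                              x = unlabelled_mid(length(observed) - 1L)))
  y <- (observed - alpha * contaminant) / (1 - alpha)
  x <- project_simplex(y)
  list(obj = sum((observed - alpha * contaminant - (1 - alpha) * x)^2), x = x)
}

# Euclidean projection onto the probability simplex
project_simplex <- function(y) {
  u <- sort(y, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(y + theta, 0)
}

#' Deconvolute an overlapping species from an observed MID
#'
#' Models the observed vector as a mixture `alpha * contaminant +
#' (1 - alpha) * component` and recovers the component MID and mixing
#' fraction by least squares under simplex constraints (component >= 0,
#' sums to 1, `alpha` in `[0, 1]`), as used to strip the UDP signal from
#' UDP-glucose.
#'
#' @param observed observed MID.
#' @param contaminant MID of the overlapping species mapped onto the same
#'   carbon backbone.
#' @details Because the observed vector is itself a valid MID, `alpha = 0`
#'   with `component = observed` always attains a zero residual; the
#'   mixture is only identified up to the largest contaminant fraction the
#'   simplex constraint allows. The returned `alpha` is therefore the
#'   maximal value whose residual still matches the best attainable one
#'   (maximal contaminant subtraction), the convention under which an exact
#'   mixture is inverted to its true components.
#' @return list with `component` (MID), `alpha` (mixing fraction of the
#'   contaminant) and `degenerate` (TRUE when the component signal is
#'   unidentifiable: alpha is approximately 1, e.g. contaminant equals the
#'   observed vector).
#' @export
deconvolute_mid <- function(observed, contaminant) {
  observed <- mid_vector(observed)
  contaminant <- mid_vector(contaminant)
  if (length(observed) != length(contaminant)) {
    stop("observed and contaminant MIDs must have the same length", call. = FALSE)
  }
  obj <- function(a) .deconv_inner(a, observed, contaminant)$obj
  opt <- stats::optimize(obj, c(0, 1), tol = 1e-12)
  minobj <- min(opt$objective, obj(0), obj(1))
  thr <- minobj + 1e-12
  if (obj(1) <= thr) {
    alpha <- 1
  } else {
    lo <- if (opt$objective <= thr) opt$minimum else 0
    hi <- 1
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (obj(mid) <= thr) lo <- mid else hi <- mid
    }
    alpha <- lo
  }
  inner <- .deconv_inner(alpha, observed, contaminant)
  degenerate <- alpha > 0.99
  if (degenerate) {
    warning("deconvolution is degenerate: no identifiable component signal", call. = FALSE)
  }
  list(component = inner$x, alpha = alpha, degenerate = degenerate)
}

#' Read and write MID measurement tables
#'
#' CSV dialect: columns `metabolite`, `n_carbons`, `time_min`, `replicate`,
#' `isotopologue`, `value` and optionally `sd`. Values may be mol% (0-100)
#' or fractions; each (metabolite, time, replicate) MID is renormalized to
#' fractions on ingest. The reader validates that the time grid is
#' strictly increasing within each replicate series.
#'
#' @param path file path.
#' @return tibble in the package's tidy MID layout.
#' @export
read_mid_table <- function(path) {
  df <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  need <- c("metabolite", "n_carbons", "time_min", "replicate", "isotopologue", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(sprintf("MID table misses column '%s'", miss[1]), call. = FALSE)
  out <- df |>
    dplyr::group_by(.data$metabolite, .data$time_min, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      nc <- unique(d$n_carbons)
      if (length(nc) != 1 || nrow(d) != nc + 1) {
        stop(sprintf("metabolite '%s' t=%g rep %s: expected %s isotopologue rows",
                     key$metabolite, key$time_min, key$replicate,
                     if (length(nc) == 1) nc + 1 else "consistent"), call. = FALSE)
      }
      d <- d[order(d$isotopologue), ]
      d$value <- mid_vector(d$value, nc[1])
      d
    }) |>
    dplyr::ungroup()
  grid_ok <- out |>
    dplyr::distinct(.data$metabolite, .data$replicate, .data$time_min) |>
    dplyr::group_by(.data$metabolite, .data$replicate) |>
    dplyr::summarise(ok = all(diff(sort(.data$time_min)) > 0) &&
                       !anyDuplicated(.data$time_min), .groups = "drop")
  if (!all(grid_ok$ok)) stop("time grid is not strictly increasing within a replicate",
                             call. = FALSE)
  out
}

#' @rdname read_mid_table
#' @param data tidy MID tibble.
#' @export
write_mid_table <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Natural-abundance correct a tidy MID table
#'
#' Applies [correct_natural_abundance()] to every (metabolite, time,
#' replicate) MID of a table in the [read_mid_table()] layout.
#'
#' @param data tidy MID tibble.
#' @param p13 natural 13C abundance.
#' @return tibble of the same shape with corrected `value`.
#' @export
correct_mid_table <- function(data, p13 = 0.0107) {
  data |>
    dplyr::group_by(.data$metabolite, .data$time_min, .data$replicate) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$isotopologue), ]
      d$value <- correct_natural_abundance(d$value, unique(d$n_carbons)[1], p13 = p13)
      d
    }) |>
    dplyr::ungroup()
}

#' Average fractional enrichment time-courses from a tidy MID table
#'
#' Computes [fractional_enrichment()] per (metabolite, time, replicate) and
#' optionally normalizes to the substrate enrichment, the quantity plotted
#' in labelling time-course figures.
#'
#' @param data tidy MID tibble ([read_mid_table()] layout).
#' @param substrate_fraction optional labelled substrate fraction for
#'   [normalize_to_substrate()].
#' @return tibble: metabolite, time_min, replicate, enrichment.
#' @export
enrichment_table <- function(data, substrate_fraction = NULL) {
  out <- data |>
    dplyr::group_by(.data$metabolite, .data$time_min, .data$replicate) |>
    dplyr::summarise(
      enrichment = fractional_enrichment(.data$value[order(.data$isotopologue)]),
      .groups = "drop")
  if (!is.null(substrate_fraction)) {
    out$enrichment <- normalize_to_substrate(out$enrichment, substrate_fraction)
  }
  out
}
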