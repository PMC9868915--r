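#' Mass isotopologue distribution (MID) vectors
#'
#' An MID for an n-carbon fragment is a numeric vector of length `n + 1`
#' giving the fractional abundances of isotopologues carrying 0..n heavy
#' carbons (M0..Mn). `mid_vector()` validates and normalizes such a vector;
#' inputs on the mol% (0-100) scale are detected by their sum and rescaled.
#'
#' @param x numeric vector of isotopologue abundances, fractions or mol%.
#' @param n_carbons expected carbon count; checked against `length(x) - 1`
#'   when supplied.
#' @param tol tolerance on the normalization check after rescaling.
#' @return numeric vector summing to 1 with small negatives clamped to 0.
#' @examples
#' mid_vector(c(97.9, 2.1, 0))    # mol% input
#' mid_vector(c(0.4, 0, 0.6))
#' @export
mid_vector <- function(x, n_carbons = NULL, tol = 1e-6) {
  if (!is.numeric(x) || length(x) < 2) {
    stop("an MID must be a numeric vector of length >= 2", call. = FALSE)
  }
  if (!is.null(n_carbons) && length(x) != n_carbons + 1) {
    stop(sprintf("MID length %d does not match n_carbons = %d (expected %d entries)",
                 length(x), n_carbons, n_carbons + 1), call. = FALSE)
  }
  s <- sum(x)
  if (s > 1.5) x <- x / 100  # mol% scale
  if (any(x < -1e-8)) {
    stop("MID has negative entries beyond tolerance", call. = FALSE)
  }
  x <- pmax(x, 0)
  s <- sum(x)
  if (abs(s) < tol) stop("MID sums to zero", call. = FALSE)
  x / s
}

#' @rdname mid_vector
#' @param n carbon count of the unlabelled fragment.
#' @export
unlabelled_mid <- function(n) c(1, rep(0, n))

#' Convolve two MIDs (Cauchy product)
#'
#' The MID of a molecule assembled from two independent fragments is the
#' convolution of the fragment MIDs.
#'
#' @param a,b MID vectors.
#' @return MID of length `length(a) + length(b) - 1`.
#' @examples
#' convolve_mid(c(0.5, 0.5), c(0.5, 0.5))  # [0.25, 0.5, 0.25]
#' @export
convolve_mid <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' Fractional atom enrichment of an MID
#'
#' The probability that a randomly chosen carbon atom of the fragment is
#' labelled: sum(a_i * i) / n for isotopologue fractions a_i.
#'
#' @param mid MID vector (fractions).
#' @return scalar in `[0, 1]`.
#' @examples
#' fractional_enrichment(c(0.25, 0.5, 0.25))  # 0.5
#' @export
fractional_enrichment <- function(mid) {
  n <- length(mid) - 1L
  if (n < 1) stop("MID must have at least two entries", call. = FALSE)
  sum(mid * (0:n)) / n
}

#' Normalize an enrichment to the substrate enrichment
#'
#' Divides a fractional enrichment by the labelled fraction of the supplied
#' substrate, so a value of 1 means the metabolite has reached the substrate
#' labelling. Values above 1.05 trigger a warning (over-unity beyond noise).
#'
#' @param enrichment fractional enrichment(s).
#' @param substrate_fraction labelled fraction of the substrate, in (0, 1].
#' @return normalized enrichment.
#' @export
normalize_to_substrate <- function(enrichment, substrate_fraction) {
  if (length(substrate_fraction) != 1 || substrate_fraction <= 0 ||
      substrate_fraction > 1) {
    stop("substrate_fraction must be a scalar in (0, 1]", call. = FALSE)
  }
  out <- enrichment / substrate_fraction
  if (any(out > 1.05)) {
    warning("normalized enrichment exceeds 1.05: check substrate enrichment or correction",
            call. = FALSE)
  }
  out
}
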