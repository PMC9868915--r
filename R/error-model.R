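#' Piecewise-linear measurement error model on the mol% scale
#'
#' Isotopologue measurement errors are set to `sigma_min` for low-abundance
#' isotopologues (<= `x_low` mol%), scale linearly between `x_low` and
#' `x_high`, and saturate at `sigma_max` for abundances >= `x_high` mol%.
#' The ramp avoids putting overly large errors on small isotopologue
#' signals while acknowledging that large signals carry larger absolute
#' uncertainty.
#'
#' @param sigma_min,sigma_max error bounds in mol%.
#' @param x_low,x_high abundance breakpoints in mol% (defaults 0.5 and 25).
#' @return object of class `error_model`.
#' @examples
#' em <- error_model(1.20, 1.90)
#' scale_error(c(0.3, 12.75, 40), em)  # 1.20, 1.55, 1.90
#' @export
error_model <- function(sigma_min, sigma_max, x_low = 0.5, x_high = 25) {
  if (sigma_min <= 0 || sigma_max < sigma_min) {
    stop("need 0 < sigma_min <= sigma_max", call. = FALSE)
  }
  if (x_low >= x_high) stop("need x_low < x_high", call. = FALSE)
  structure(list(sigma_min = sigma_min, sigma_max = sigma_max,
                 x_low = x_low, x_high = x_high), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf("<error_model> %.3g - %.3g mol%% (ramp %.3g - %.3g mol%%)\n",
              x$sigma_min, x$sigma_max, x$x_low, x$x_high))
  invisible(x)
}

#' @rdname error_model
#' @param x isotopologue abundance(s) in mol% (>= 0).
#' @param em an `error_model`.
#' @return sigma in mol%, vectorized over `x`.
#' @export
scale_error <- function(x, em) {
  if (any(x < 0)) stop("abundance must be >= 0", call. = FALSE)
  f <- pmin(pmax((x - em$x_low) / (em$x_high - em$x_low), 0), 1)
  em$sigma_min + f * (em$sigma_max - em$sigma_min)
}

#' Chi-squared acceptance window for a fit
#'
#' A variance-weighted least-squares fit is statistically acceptable when
#' its SSR falls between the `alpha/2` and `1 - alpha/2` quantiles of the
#' chi-squared distribution with `n - p` degrees of freedom.
#'
#' @param df degrees of freedom (`n` measurements minus `p` parameters).
#' @param alpha two-sided significance level (default 0.05).
#' @return one-row tibble: `df`, `lower`, `upper`.
#' @examples
#' chi2_window(3601)  # lower 3436.6, upper 3769.2
#' @export
chi2_window <- function(df, alpha = 0.05) {
  if (df <= 0) stop("degrees of freedom must be positive", call. = FALSE)
  tibble::tibble(df = df,
                 lower = stats::qchisq(alpha / 2, df),
                 upper = stats::qchisq(1 - alpha / 2, df))
}

#' Variance-weighted sum of squared residuals
#'
#' @param simulated,measured numeric vectors of matched simulated and
#'   measured values (fractions).
#' @param sigmas per-measurement standard deviations (same scale); zero
#'   sigmas are rejected.
#' @param normalisations optional grouping vector; when given, a
#'   multiplicative factor per group is solved in closed form (it is linear
#'   in the factor) and applied to the simulated values before residuals
#'   are formed, mirroring per-fragment MS normalisation.
#' @return scalar SSR; the applied factors are attached as attribute
#'   `"factors"` when normalisations are used.
#' @export
weighted_ssr <- function(simulated, measured, sigmas, normalisations = NULL) {
  if (any(sigmas <= 0)) stop("sigma = 0 is not allowed", call. = FALSE)
  if (length(simulated) != length(measured) || length(measured) != length(sigmas)) {
    stop("simulated, measured and sigmas must have equal length", call. = FALSE)
  }
  if (!is.null(normalisations)) {
    g <- as.factor(normalisations)
    num <- tapply(simulated * measured / sigmas^2, g, sum)
    den <- tapply(simulated^2 / sigmas^2, g, sum)
    fac <- ifelse(den > 0, num / den, 1)
    simulated <- simulated * as.numeric(fac[g])
    out <- sum(((simulated - measured) / sigmas)^2)
    attr(out, "factors") <- as.numeric(fac)
    return(out)
  }
  sum(((simulated - measured) / sigmas)^2)
}
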