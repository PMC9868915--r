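#' Plot simulated MID time-courses
#'
#' One panel per observable, one line per isotopologue.
#'
#' @param object a `mid_timecourse` tibble from [simulate_mids()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mid_timecourse
#' @export
autoplot.mid_timecourse <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_min, .data$fraction,
                                       colour = factor(.data$isotopologue))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~observable) +
    ggplot2::labs(x = "time (min)", y = "isotopologue fraction",
                  colour = "M+i") +
    ggplot2::theme_minimal()
}

#' Plot measured versus fitted MIDs
#'
#' @param object an `mfa_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mfa_fit
#' @export
autoplot.mfa_fit <- function(object, ...) {
  d <- fitted_mids(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value,
                                     colour = factor(.data$isotopologue)),
                        size = 0.6, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted,
                                    colour = factor(.data$isotopologue),
                                    group = interaction(.data$isotopologue,
                                                        .data$replicate))) +
    ggplot2::facet_wrap(~observable) +
    ggplot2::labs(x = "time (min)", y = "fraction", colour = "M+i") +
    ggplot2::theme_minimal()
}

#' Plot a Monte Carlo ensemble
#'
#' Histograms of the refitted parameter values.
#'
#' @param object an `mfa_ensemble`.
#' @param parameters optional subset.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mfa_ensemble
#' @export
autoplot.mfa_ensemble <- function(object, parameters = NULL, ...) {
  d <- tidy(object)
  if (!is.null(parameters)) d <- dplyr::filter(d, .data$parameter %in% parameters)
  ggplot2::ggplot(d, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 40) +
    ggplot2::facet_wrap(~parameter, scales = "free_x") +
    ggplot2::theme_minimal()
}

#' Score plot of a PCA of flux ensembles
#'
#' @param object a `flux_pca`.
#' @param class optional factor colouring the samples.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot flux_pca
#' @export
autoplot.flux_pca <- function(object, class = NULL, ...) {
  d <- tibble::tibble(PC1 = object$scores[, 1],
                      PC2 = if (ncol(object$scores) > 1) object$scores[, 2] else 0)
  if (!is.null(class)) d$class <- class
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = if (length(object$explained) > 1)
        sprintf("PC2 (%.1f%%)", 100 * object$explained[2]) else "PC2") +
    ggplot2::theme_minimal()
  if (is.null(class)) p + ggplot2::geom_point(alpha = 0.5)
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$class), alpha = 0.5)
}

#' Score plot of a PLS-DA of flux ensembles
#'
#' @param object a `flux_plsda`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot flux_plsda
#' @export
autoplot.flux_plsda <- function(object, ...) {
  d <- tibble::tibble(comp1 = object$scores[, 1],
                      comp2 = if (ncol(object$scores) > 1) object$scores[, 2] else 0,
                      class = object$class)
  ggplot2::ggplot(d, ggplot2::aes(.data$comp1, .data$comp2, colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::labs(x = "component 1", y = "component 2") +
    ggplot2::theme_minimal()
}
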