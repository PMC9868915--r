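#' instmfa: isotopically non-stationary metabolic flux analysis
#'
#' Estimates intracellular fluxes and metabolite pool sizes from transient
#' 13C labelling time-courses in compartmented metabolic networks:
#' plain-text atom-transition models, EMU decomposition and simulation,
#' measurement processing (natural-abundance correction, deconvolution,
#' fractional enrichment), multistart Levenberg-Marquardt estimation with
#' chi-squared acceptance, Monte Carlo and profile-likelihood uncertainty,
#' CI-overlap significance rules, PCA/PLS-DA over flux ensembles, and a
#' synthetic-experiment generator.
#'
#' @keywords internal
#' @importFrom rlang .data
#' @importFrom generics tidy glance
"_PACKAGE"

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

utils::globalVariables(".")
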