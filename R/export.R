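#' Write simulated MID time-courses as tidy TSV
#'
#' @param sim tibble from [simulate_mids()].
#' @param path output file.
#' @export
write_timecourse_tsv <- function(sim, path) {
  utils::write.table(sim, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# human-readable reaction equation from the model structure
reaction_equation <- function(model, id) {
  r <- model$reactions[[match(id, reaction_ids(model))]]
  side <- function(s) paste(vapply(s, `[[`, "", "pool"), collapse = " + ")
  sprintf("%s %s %s", side(r$reactants),
          if (r$reversible) "<->" else "->", side(r$products))
}

#' Export a fitted flux table
#'
#' One row per reaction with its equation and fitted net flux; when a
#' Monte Carlo ensemble is supplied, 95% confidence bounds are added.
#'
#' @param fit an `mfa_fit`.
#' @param ensemble optional `mfa_ensemble` for confidence bounds.
#' @param path optional TSV output path.
#' @param level confidence level for the bounds.
#' @return tibble: `flux`, `equation`, `value`, `lower`, `upper`.
#' @export
flux_table <- function(fit, ensemble = NULL, path = NULL, level = 95) {
  model <- fit$problem$model
  ids <- reaction_ids(model)
  out <- tibble::tibble(
    flux = ids,
    equation = vapply(ids, function(id) reaction_equation(model, id), ""),
    value = unname(fit$state$net[ids]),
    lower = NA_real_, upper = NA_real_)
  if (!is.null(ensemble)) {
    for (i in seq_along(ids)) {
      col <- paste0("net.", ids[i])
      if (col %in% colnames(ensemble$net)) {
        ci <- ci_from_ensemble(ensemble$net[, col], level)
        out$lower[i] <- ci[["lower"]]
        out$upper[i] <- ci[["upper"]]
      }
    }
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}
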