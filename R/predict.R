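#' Predict scaled mutation rates per context and methylation state
#'
#' Evaluates the fitted linear predictor for every sequence context at
#' methylation state `x = 0` (unmethylated) and `x = 1` (fully methylated)
#' and returns `muT = -eta`: the sample-scaled mutation rate
#' `alpha_c T` (at `x = 0`) or `(alpha_c + beta_c) T` (at `x = 1`).
#' Standard errors come from the fit covariance (`muT` is linear in the
#' coefficients) and the 95% interval is the normal approximation
#' `muT +/- 1.96 se`. Extrapolation to methylation levels outside `{0, 1}`
#' is deliberately not supported.
#'
#' @param fit a `cpg_fit`.
#' @param state methylation states to evaluate; subset of `c(0, 1)`.
#'   Ignored (single unmethylated-style prediction, `state = NA`) for
#'   context-only models.
#' @return A tibble of class `cpg_rates` with columns `context`, `state`,
#'   `muT`, `se`, `ci_low`, `ci_high`.
#' @examples
#' sites <- simulate_site_table(synthetic_truth(seed = 1, n_per_context = 2000))
#' predict_scaled_rates(fit_cpg_glm(sites, "4mer"))
#' @export
predict_scaled_rates <- function(fit, state = c(0, 1)) {
  spec <- fit$spec
  if (!all(state %in% c(0, 1))) {
    abort("predict_scaled_rates: state must be a subset of c(0, 1)")
  }
  contexts <- enumerate_contexts(spec$k)
  if (spec$with_methylation) {
    grid <- tidyr::expand_grid(context = contexts, state = as.numeric(state))
  } else {
    grid <- tibble(context = contexts, state = NA_real_)
  }
  newdata <- tibble(chrom = "pred", cpg_start = seq_len(nrow(grid)),
                    strand = "+", context = grid$context)
  newdata[[paste0("context", spec$k)]] <- grid$context
  if (spec$with_methylation) newdata$m <- grid$state
  Xp <- build_design_matrix(newdata, spec)$X
  theta <- fit$coefficients
  eta <- as.numeric(Xp %*% theta)
  XV <- as.matrix(Xp %*% fit$vcov)
  se <- sqrt(rowSums(XV * as.matrix(Xp)))
  out <- tibble(
    context = grid$context,
    state = grid$state,
    muT = -eta,
    se = se,
    ci_low = -eta - 1.96 * se,
    ci_high = -eta + 1.96 * se
  )
  class(out) <- c("cpg_rates", class(out))
  out
}

#' Serialize a fit as JSON
#'
#' Writes the model name, coefficient table, likelihood summaries and
#' convergence block to a JSON file.
#'
#' @param fit a `cpg_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    model = fit$spec$name,
    coefficients = tidy(fit)[, c("term", "estimate", "std.error")],
    logLik = fit$logLik,
    deviance = fit$deviance,
    null_deviance = fit$null_deviance,
    AIC = fit$aic,
    BIC = fit$bic,
    variance_explained = (fit$null_deviance - fit$deviance) / fit$null_deviance,
    convergence = list(
      iterations = fit$iterations,
      converged = fit$converged,
      boundary = fit$boundary
    ),
    n = fit$n,
    n_poly = fit$n_poly
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
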