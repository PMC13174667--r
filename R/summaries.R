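#' Concordance between two sets of scaled-rate estimates
#'
#' Pearson correlation of point estimates across shared contexts, computed
#' separately per methylation state when `by_state = TRUE` — the comparison
#' used between nested context models, between fits on different datasets
#' or species, and between strata.
#'
#' @param estimates_a,estimates_b `cpg_rates` tibbles (or any tibble with
#'   `context`, `state`, `muT`).
#' @param by_state compute one correlation per methylation state
#'   (default `TRUE`).
#' @return A tibble with columns `state` (NA when `by_state = FALSE`), `r`,
#'   `n_contexts`; the paired estimates are attached as attribute
#'   `"pairs"`.
#' @export
concordance <- function(estimates_a, estimates_b, by_state = TRUE) {
  keys <- if (by_state) c("context", "state") else "context"
  paired <- inner_join(
    select(as_tibble(estimates_a), dplyr::all_of(c(keys, "muT"))),
    select(as_tibble(estimates_b), dplyr::all_of(c(keys, "muT"))),
    by = keys, suffix = c("_a", "_b"), na_matches = "na"
  )
  if (!by_state) paired$state <- NA_real_
  counts <- count(paired, .data$state)
  if (any(counts$n < 3L)) {
    abort("concordance: fewer than 3 shared contexts in at least one state")
  }
  out <- paired |>
    group_by(.data$state) |>
    summarise(
      r = stats::cor(.data$muT_a, .data$muT_b, method = "pearson"),
      n_contexts = n(),
      .groups = "drop"
    )
  attr(out, "pairs") <- paired
  out
}

#' Test mutational asymmetry within CpG dinucleotides
#'
#' The two adjacent C:G base pairs of one CpG dinucleotide correspond to a
#' context and its reverse complement, so differing rates between
#' reverse-complement context pairs indicate within-CpG mutational
#' asymmetry. For each non-palindromic pair (a, b = revcomp(a), with a the
#' lexicographically smaller member) and each methylation state the test
#' statistic is `z = (muT_a - muT_b) / sqrt(se_a^2 + se_b^2)` (independent
#' error propagation; the two members are estimated from disjoint site
#' sets), with a two-sided normal p-value. Palindromic contexts are
#' excluded. Bonferroni adjustment over the whole family
#' (pairs x states) is reported alongside the raw p-values.
#'
#' @param rates a `cpg_rates` tibble from [predict_scaled_rates()].
#' @param k context width of the pairing (default 4).
#' @param adjust `"bonferroni"` (default) or `"none"`.
#' @return A tibble with columns `context_a`, `context_b`, `state`,
#'   `muT_a`, `muT_b`, `delta`, `se_delta`, `z`, `p.value`, `p.adjusted`.
#' @export
test_asymmetry <- function(rates, k = 4L, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  pairing <- pair_reverse_complements(enumerate_contexts(k))
  res <- pairing$pairs |>
    rename(context_a = "a", context_b = "b") |>
    inner_join(
      select(as_tibble(rates), "context", "state", "muT", "se") |>
        rename(context_a = "context", muT_a = "muT", se_a = "se"),
      by = "context_a", na_matches = "na"
    ) |>
    inner_join(
      select(as_tibble(rates), "context", "state", "muT", "se") |>
        rename(context_b = "context", muT_b = "muT", se_b = "se"),
      by = c("context_b", "state"), na_matches = "na"
    )
  n_expected <- nrow(pairing$pairs) *
    length(unique(stats::na.omit(as_tibble(rates)$state)))
  if (nrow(res) < max(n_expected, 1L)) {
    warn(sprintf("test_asymmetry: %d pair-state combination(s) missing an estimate; skipped",
                 n_expected - nrow(res)))
  }
  res <- res |>
    mutate(
      delta = .data$muT_a - .data$muT_b,
      se_delta = sqrt(.data$se_a^2 + .data$se_b^2),
      z = .data$delta / .data$se_delta,
      p.value = 2 * pnorm(-abs(.data$z)),
      p.adjusted = if (adjust == "bonferroni") {
        pmin(1, .data$p.value * dplyr::n())
      } else {
        .data$p.value
      }
    ) |>
    select("context_a", "context_b", "state", "muT_a", "muT_b",
           "delta", "se_delta", "z", "p.value", "p.adjusted") |>
    arrange(.data$state, .data$context_a)
  class(res) <- c("cpg_asymmetry", class(res))
  res
}

# Wilson 95% score interval for a binomial proportion
wilson_ci <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  cbind(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Polymorphism rate by methylation bin
#'
#' Partitions sites into `n_bins` equal-width methylation bins (the last bin
#' closed, `[1 - 1/n_bins, 1]`) and reports the observed polymorphism rate
#' per bin with a Wilson 95% confidence interval. This is the raw,
#' model-free view in which recurrent-mutation saturation appears as a
#' flattening of the rate at high methylation.
#'
#' @param sites a site table with `m` and `y`.
#' @param n_bins number of bins (default 20).
#' @return A tibble of class `cpg_bins` with `bin`, `m_low`, `m_high`,
#'   `n`, `n_poly`, `rate`, `ci_low`, `ci_high`. Empty bins have `n = 0`
#'   and `NA` rate.
#' @export
binned_rates <- function(sites, n_bins = 20L) {
  n_bins <- as.integer(n_bins)
  stopifnot(n_bins >= 1L, all(sites$m >= 0 & sites$m <= 1))
  idx <- pmin(as.integer(floor(sites$m * n_bins)), n_bins - 1L) + 1L
  counts <- tibble(bin = idx, y = sites$y) |>
    group_by(.data$bin) |>
    summarise(n = n(), n_poly = sum(.data$y), .groups = "drop")
  out <- tibble(bin = seq_len(n_bins)) |>
    left_join(counts, by = "bin") |>
    mutate(
      n = dplyr::coalesce(.data$n, 0L),
      n_poly = dplyr::coalesce(.data$n_poly, 0L),
      m_low = (.data$bin - 1L) / n_bins,
      m_high = .data$bin / n_bins,
      rate = ifelse(.data$n > 0L, .data$n_poly / .data$n, NA_real_)
    )
  ci <- wilson_ci(out$n_poly, pmax(out$n, 1L))
  out$ci_low <- ifelse(out$n > 0L, ci[, "low"], NA_real_)
  out$ci_high <- ifelse(out$n > 0L, ci[, "high"], NA_real_)
  out <- select(out, "bin", "m_low", "m_high", "n", "n_poly",
                "rate", "ci_low", "ci_high")
  class(out) <- c("cpg_bins", class(out))
  out
}

#' Refit a model within strata of a per-site covariate
#'
#' Generic stratified refit (e.g. recombination-rate bins used to gauge the
#' impact of GC-biased gene conversion): the model is fitted separately in
#' each stratum and each stratum's scaled-rate estimates are compared with
#' the pooled fit by Pearson concordance.
#'
#' @param sites a site table.
#' @param strata a vector of stratum labels, one per site (or the name of a
#'   column of `sites`).
#' @param model model name or `cpg_model_spec`.
#' @param state methylation states at which to predict.
#' @return A tibble with one row per stratum: `stratum`, `n`, `converged`,
#'   a list-column `rates` of `cpg_rates`, and one concordance-vs-pooled
#'   column per state (`r_state0`, `r_state1`, or `r_all` for context-only
#'   models). The pooled rates are attached as attribute `"pooled"`; fits
#'   as attribute `"fits"`.
#' @export
stratified_refit <- function(sites, strata, model = "4mer", state = c(0, 1)) {
  if (is.character(strata) && length(strata) == 1L && strata %in% names(sites)) {
    strata <- sites[[strata]]
  }
  stopifnot(length(strata) == nrow(sites))
  pooled_fit <- fit_cpg_glm(sites, model)
  pooled <- predict_scaled_rates(pooled_fit, state = state)
  labels <- sort(unique(strata))
  fits <- list()
  rows <- purrr::map(labels, function(lab) {
    sub <- sites[strata == lab, , drop = FALSE]
    fit <- tryCatch(fit_cpg_glm(sub, model), error = function(e) NULL)
    if (is.null(fit)) {
      return(tibble(stratum = as.character(lab), n = nrow(sub),
                    converged = FALSE, rates = list(NULL)))
    }
    fits[[as.character(lab)]] <<- fit
    rates <- predict_scaled_rates(fit, state = state)
    row <- tibble(stratum = as.character(lab), n = nrow(sub),
                  converged = fit$converged, rates = list(rates))
    conc <- concordance(rates, pooled, by_state = TRUE)
    for (i in seq_len(nrow(conc))) {
      col <- if (is.na(conc$state[i])) "r_all" else sprintf("r_state%d", conc$state[i])
      row[[col]] <- conc$r[i]
    }
    row
  })
  out <- bind_rows(rows)
  attr(out, "pooled") <- pooled
  attr(out, "fits") <- fits
  out
}
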