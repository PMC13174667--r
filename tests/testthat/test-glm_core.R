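test_that("link functions follow the closed forms and are mutually inverse", {
  expect_equal(mu_inverse_link(0), 0)
  expect_equal(mu_inverse_link(-1), 1 - exp(-1), tolerance = 1e-12)
  expect_error(mu_link(1), "strictly")
  expect_error(mu_link(0), "strictly")
  eta <- -c(10, 5, 1, 1e-2, 1e-5, 1e-8)
  expect_lt(max(abs(mu_link(mu_inverse_link(eta)) - eta)), 1e-12)
  # round trip through p loses precision as p -> 1 (1 - p underflows in the
  # double representation of p), so the deep-saturation regime is looser
  expect_equal(mu_link(mu_inverse_link(-20)), -20, tolerance = 1e-7)
  # analytic derivative matches a central difference
  h <- 1e-6
  num <- (mu_inverse_link(-1 + h) - mu_inverse_link(-1 - h)) / (2 * h)
  expect_equal(mu_d_inverse_link(-1), num, tolerance = 1e-8)
})

test_that("design matrices carry the documented coefficient counts", {
  s4 <- sim_sites(k = 4L, n = 200L, seed = 61L)
  s6 <- sim_sites(k = 6L, n = 20L, seed = 62L)
  counts <- c("up1_down1" = 14L, "4mer" = 32L, "context_only_4mer" = 16L,
              "context_only_up1_down1" = 7L)
  for (mn in names(counts)) {
    expect_identical(ncol(build_design_matrix(s4, mn)$X), counts[[mn]])
    expect_identical(model_spec(mn)$n_params, counts[[mn]])
  }
  counts6 <- c("6mer" = 512L, "up21_down12" = 62L, "additive_positions" = 26L)
  for (mn in names(counts6)) {
    expect_identical(ncol(build_design_matrix(s6, mn)$X), counts6[[mn]])
    expect_identical(model_spec(mn)$n_params, counts6[[mn]])
  }
})

test_that("prediction errors on states outside {0,1} and unseeable levels error at build", {
  fit <- fit_cpg_glm(sim_sites(n = 500L, seed = 63L), "4mer")
  expect_error(predict_scaled_rates(fit, state = 0.5), "subset")
  bad <- tibble::tibble(context4 = "AAAA", m = 0.5, y = 0L)
  expect_error(fit_cpg_glm(bad, "4mer"))
})

test_that("intercept-only MLE equals the closed form -log(1 - k/n)", {
  # single-context data so the intercept is the only identifiable column;
  # fit via the context-only model restricted to one context
  n <- 1000L
  k <- 100L
  sites <- tibble::tibble(
    chrom = "t", cpg_start = seq_len(n), strand = "+",
    context4 = "ACGA", m = 0.5, y = rep(c(1L, 0L), c(k, n - k))
  )
  fit <- suppressWarnings(fit_cpg_glm(sites, "context_only_4mer"))
  est <- predict_scaled_rates(fit)
  got <- est$muT[est$context == "ACGA"]
  expect_equal(got, -log(1 - k / n), tolerance = 1e-6)

  # independent oracle: dense 1-D grid search of the Bernoulli likelihood
  grid <- seq(0.01, 0.3, by = 1e-5)
  ll <- k * log(1 - exp(-grid)) + (n - k) * (-grid)
  expect_equal(got, grid[which.max(ll)], tolerance = 1e-4)
})

test_that("4mer fit with m in {0,1} reproduces stratified closed forms", {
  tab <- sim_sites(n = 4000L, seed = 64L)
  set.seed(65)
  tab$m <- as.numeric(runif(nrow(tab)) < 0.5)
  fit <- fit_cpg_glm(tab, "4mer")
  est <- predict_scaled_rates(fit)
  closed <- tab |>
    dplyr::group_by(context4, m) |>
    dplyr::summarise(muT_cf = -log(1 - mean(y)), .groups = "drop")
  mg <- dplyr::inner_join(est, closed, by = c(context = "context4", state = "m"))
  expect_equal(nrow(mg), 32L)
  expect_equal(mg$muT, mg$muT_cf, tolerance = 1e-6)
})

test_that("Newton MLE matches stats::glm with the same custom link", {
  tab <- sim_sites(n = 3000L, seed = 66L)
  mine <- fit_cpg_glm(tab, "up1_down1")
  df <- dplyr::mutate(tab,
                      U1 = factor(substr(context4, 1, 1), c("A", "C", "G", "T")),
                      D1 = factor(substr(context4, 4, 4), c("A", "C", "G", "T")))
  ref <- glm_reference_fit(df, y ~ U1 + D1 + m + U1:m + D1:m,
                           start = c(log1p(-mean(df$y)), rep(0, 13)))
  expect_setequal(names(coef(ref)), names(mine$coefficients))
  # both routes stop on likelihood-change rules, so agreement is bounded by
  # the flatter of the two stopping regions, not machine precision
  expect_lt(max(abs(mine$coefficients[names(coef(ref))] - coef(ref))), 1e-5)
  expect_equal(mine$logLik, as.numeric(stats::logLik(ref)), tolerance = 1e-8)
  expect_equal(mine$deviance, stats::deviance(ref), tolerance = 1e-6)
})

test_that("Newton MLE matches a dense grid-search oracle on a 2-parameter model", {
  set.seed(71)
  n <- 20000L
  m <- as.numeric(runif(n) < 0.6) * runif(n)
  eta <- -(0.05 + 0.3 * m)
  y <- rbinom(n, 1, -expm1(eta))
  sites <- tibble::tibble(chrom = "t", cpg_start = seq_len(n), strand = "+",
                          context4 = "ACGA", m = m, y = y)
  fit <- suppressWarnings(fit_cpg_glm(sites, "context_only_4mer"))
  # augment with the methylation slope via the 4mer model on one context:
  # identifiable columns are (Intercept) and m
  fitm <- suppressWarnings(fit_cpg_glm(sites, "4mer"))
  a_hat <- -fitm$coefficients[["(Intercept)"]]
  b_hat <- -fitm$coefficients[["m"]]

  llfun <- function(a, b) {
    e <- -(a + b * m)
    sum(y * log(-expm1(e)) + (1 - y) * e)
  }
  # coarse-to-fine full 2-D grid refinement, independent of the fitter
  a0 <- 0.25; b0 <- 0.25; span <- 0.25
  for (round in 1:6) {
    agrid <- seq(max(a0 - span, 1e-6), a0 + span, length.out = 41)
    bgrid <- seq(b0 - span, b0 + span, length.out = 41)
    vals <- outer(agrid, bgrid, Vectorize(llfun))
    best <- arrayInd(which.max(vals), dim(vals))
    a0 <- agrid[best[1]]; b0 <- bgrid[best[2]]
    span <- span / 8
  }
  expect_lt(abs(a_hat - a0), 1e-4)
  expect_lt(abs(b_hat - b0), 1e-4)
})

test_that("standard errors shrink like 1/sqrt(n)", {
  t_small <- synthetic_truth(alphaT = 0.02, betaT = 0.4, n_per_context = 500L, seed = 81L)
  t_big <- synthetic_truth(alphaT = 0.02, betaT = 0.4, n_per_context = 50000L, seed = 82L)
  se_small <- predict_scaled_rates(fit_cpg_glm(simulate_site_table(t_small), "4mer"))$se
  se_big <- predict_scaled_rates(fit_cpg_glm(simulate_site_table(t_big), "4mer"))$se
  ratio <- mean(se_small / se_big)
  expect_gt(ratio, 8)
  expect_lt(ratio, 12)
})

test_that("null simulation: zero methylation effect gives |muT(1)-muT(0)| < 3 se", {
  truth <- synthetic_truth(alphaT = NULL, betaT = 0, n_per_context = 5000L, seed = 83L)
  fit <- fit_cpg_glm(simulate_site_table(truth), "4mer")
  est <- predict_scaled_rates(fit)
  wide <- tidyr::pivot_wider(est, id_cols = "context", names_from = "state",
                             values_from = c("muT", "se"))
  z <- abs(wide$muT_1 - wide$muT_0) / sqrt(wide$se_1^2 + wide$se_0^2)
  # 16 null contexts; allow a single borderline excursion
  expect_lte(sum(z > 3), 1L)
})

test_that("model scores: arithmetic identities and nesting of variance explained", {
  fit <- fit_cpg_glm(sim_sites(n = 2000L, seed = 84L), "4mer")
  g <- glance(fit)
  expect_equal(g$AIC, 2 * g$df - 2 * g$logLik)
  expect_equal(g$BIC, g$df * log(g$n) - 2 * g$logLik)
  expect_equal(model_scores(fit)$variance_explained,
               (g$null.deviance - g$deviance) / g$null.deviance)
  expect_gte(g$variance_explained, 0)
  expect_lte(g$variance_explained, 1)

  fit_sub <- fit_cpg_glm(sim_sites(n = 2000L, seed = 84L), "up1_down1")
  expect_gte(model_scores(fit)$variance_explained,
             model_scores(fit_sub)$variance_explained)
})

test_that("deviance is monotone along both nesting chains", {
  tab6 <- sim_sites(k = 6L, n = 600L, seed = 85L)
  d <- vapply(c("up1_down1", "4mer", "6mer", "additive_positions", "up21_down12"),
              function(mn) fit_cpg_glm(tab6, mn)$deviance, numeric(1))
  expect_gte(d[["up1_down1"]], d[["4mer"]])
  expect_gte(d[["4mer"]], d[["6mer"]])
  expect_gte(d[["additive_positions"]], d[["up21_down12"]])
  expect_gte(d[["up21_down12"]], d[["6mer"]])
})

test_that("fitted probabilities stay inside (0,1) with negative predictors", {
  fit <- fit_cpg_glm(sim_sites(n = 1000L, seed = 86L), "4mer")
  expect_true(all(fit$eta < 0))
  p_hat <- mu_inverse_link(fit$eta)
  expect_true(all(p_hat > 0 & p_hat < 1))
  expect_false(fit$boundary)
})

test_that("small-rate limit: p agrees with muT to first order", {
  muT <- c(1e-5, 1e-4, 1e-3)
  p <- mu_inverse_link(-muT)
  expect_true(all(abs(p - muT) / muT <= muT))
})

test_that("duplicated contexts under two labels give identical estimates", {
  tab <- sim_sites(n = 3000L, seed = 87L)
  tab_dup <- tab
  # relabel half of ACGA sites as ACGC and make ACGC data identical to ACGA
  base <- tab[tab$context4 == "ACGA", ]
  clone <- dplyr::mutate(base, context4 = "ACGC")
  two <- dplyr::bind_rows(
    base, clone,
    tab[!tab$context4 %in% c("ACGA", "ACGC"), ]
  )
  fit <- fit_cpg_glm(two, "4mer")
  est <- predict_scaled_rates(fit)
  a <- est[est$context == "ACGA", c("state", "muT")]
  b <- est[est$context == "ACGC", c("state", "muT")]
  expect_equal(a$muT, b$muT, tolerance = 1e-8)
})
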