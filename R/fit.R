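# ---- link functions -------------------------------------------------------

#' The polymorphism link: eta = log(1 - p)
#'
#' Under recurrent mutation with total coalescent tree length `T`, a site
#' with per-generation mutation rate `mu` is polymorphic with probability
#' `p = 1 - exp(-mu T)`, so the linear predictor `eta = log(1 - p)` equals
#' `-mu T`: coefficients on the eta scale are (negated) sample-scaled
#' mutation rates. All three functions use `log1p`/`expm1` so they are
#' accurate for the tiny rates typical of single sites.
#'
#' @param p polymorphism probability in (0, 1).
#' @param eta linear predictor, `eta < 0` for valid probabilities.
#' @return `mu_link`: eta; `mu_inverse_link`: p; `mu_d_inverse_link`:
#'   d p / d eta (equal to `-exp(eta)`).
#' @examples
#' mu_inverse_link(-1) # 1 - exp(-1)
#' @export
mu_link <- function(p) {
  if (any(p <= 0 | p >= 1)) abort("mu_link: p must lie strictly in (0, 1)")
  log1p(-p)
}

#' @rdname mu_link
#' @export
mu_inverse_link <- function(eta) -expm1(eta)

#' @rdname mu_link
#' @export
mu_d_inverse_link <- function(eta) -exp(eta)

# log(p) = log(1 - e^eta) computed stably for eta < 0
log_p_from_eta <- function(eta) {
  ifelse(eta > -log(2), log(-expm1(eta)), log1p(-exp(eta)))
}

# eta kept inside the open region: p in [1e-12, 1 - 1e-12]
ETA_MIN <- log(1e-12)        # p ~ 1 - 1e-12
ETA_MAX <- log1p(-1e-12)     # p ~ 1e-12
ETA_CAP <- -1e-9             # line-search boundary: iterates stay below this

# ---- Newton-Raphson MLE ---------------------------------------------------

# Solve info %*% step = score, escalating a relative ridge when the
# information is (near-)singular, e.g. a context level with no polymorphic
# site. Returns NULL only if every attempt fails.
solve_newton_step <- function(info, score) {
  for (ridge in c(0, 1e-8, 1e-4, 1e-1)) {
    info_r <- if (ridge == 0) info else {
      info + Matrix::Diagonal(ncol(info), ridge * (1 + Matrix::diag(info)))
    }
    step <- tryCatch(as.numeric(Matrix::solve(info_r, score)),
                     error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step))) {
      attr(step, "ridged") <- ridge > 0
      return(step)
    }
  }
  NULL
}

# Bernoulli log-likelihood, gradient and information weights under the
# log(1-p) link. For eta = X theta:
#   l            = sum_i y_i log(1 - e^eta_i) + (1 - y_i) eta_i
#   dl/deta_i    = (1 - y_i) - y_i e^eta_i / (1 - e^eta_i)
#   -d2l/deta_i2 = y_i e^eta_i / (1 - e^eta_i)^2          (observed)
#   E[-d2l/deta_i2] = e^eta_i / (1 - e^eta_i)             (expected/Fisher)
# Monomorphic sites contribute linearly to l, so all observed curvature
# comes from polymorphic sites; iteration therefore uses the Fisher weights
# (every site contributes, conditioning is benign) while the reported
# covariance is the inverse observed information at the optimum.
loglik_parts <- function(X, y, theta) {
  eta_raw <- as.numeric(X %*% theta)
  clipped <- eta_raw < ETA_MIN | eta_raw > ETA_MAX
  eta <- pmin(pmax(eta_raw, ETA_MIN), ETA_MAX)
  q <- exp(eta)          # 1 - p
  p <- -expm1(eta)
  list(
    eta = eta,
    ll = sum(y * log_p_from_eta(eta) + (1 - y) * eta),
    g = (1 - y) - y * q / p,
    w_fisher = pmin(q / p, 1e10),
    w_obs = pmin(y * q / p^2, 1e12),
    clipped = any(clipped)
  )
}

#' Fit a context model by exact maximum likelihood
#'
#' Maximizes the Bernoulli likelihood of the site-level polymorphism
#' indicators under the `eta = log(1 - p)` link by Newton scoring with
#' analytic gradient and Fisher information, with step-halving (up to 30
#' halvings per iteration). Iteration starts from the intercept-only closed
#' form (`eta0 = log(1 - mean(y))`, all context effects zero) and stops when
#' the relative change in log-likelihood drops below `tol` or after
#' `max_iter` iterations. The valid region `eta < 0` is open: each step is
#' damped so every site's linear predictor stays strictly interior, and
#' probabilities are additionally clipped to `[1e-12, 1 - 1e-12]`; a fit
#' whose final predictor sits against the boundary is flagged, not silently
#' accepted. The reported covariance is the inverse observed information at
#' the optimum.
#'
#' @param sites a site table (tibble with the model's context column, `m`
#'   where applicable, and the binary outcome `y`), or a `cpg_design` from
#'   [build_design_matrix()].
#' @param model a model name (see [model_spec()]) or a `cpg_model_spec`.
#'   Ignored when `sites` is already a design.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum Newton iterations.
#' @return An object of class `cpg_fit`: coefficients, covariance (inverse
#'   observed information), log-likelihood, null and residual deviance, AIC,
#'   BIC, iteration count, `converged` and `boundary` flags, and the design
#'   metadata needed for prediction. Supports [tidy()], [glance()] and
#'   [predict_scaled_rates()].
#' @examples
#' sites <- simulate_site_table(synthetic_truth(seed = 1, n_per_context = 2000))
#' fit <- fit_cpg_glm(sites, "4mer")
#' glance(fit)
#' @export
fit_cpg_glm <- function(sites, model = "4mer", tol = 1e-10, max_iter = 100L) {
  design <- if (inherits(sites, "cpg_design")) sites else build_design_matrix(sites, model)
  X <- design$X
  y <- design$y
  if (is.null(y)) abort("fit_cpg_glm: site table has no outcome column y")
  if (!all(y %in% c(0L, 1L))) abort("fit_cpg_glm: y must be binary")
  n <- nrow(X)
  p_cols <- ncol(X)
  if (n <= p_cols) abort("fit_cpg_glm: need more sites than coefficients")

  ybar <- mean(y)
  theta <- numeric(p_cols)
  names(theta) <- colnames(X)
  theta[1] <- log1p(-min(max(ybar, 1e-8), 1 - 1e-8))

  cur <- loglik_parts(X, y, theta)
  converged <- FALSE
  iter <- 0L
  singular <- FALSE
  for (iter in seq_len(max_iter)) {
    info <- Matrix::crossprod(X, X * cur$w_fisher)
    score <- as.numeric(Matrix::crossprod(X, cur$g))
    step <- solve_newton_step(info, score)
    if (is.null(step)) {
      singular <- TRUE
      break
    }
    if (attr(step, "ridged")) singular <- TRUE
    # the valid region is eta < 0: damp the step to stay strictly interior,
    # so gradients and weights remain finite at every iterate
    eta_step <- as.numeric(X %*% step)
    pos <- eta_step > 0
    lam_bound <- if (any(pos)) {
      min((ETA_CAP - cur$eta[pos]) / eta_step[pos])
    } else {
      Inf
    }
    lambda <- min(1, 0.95 * max(lam_bound, 0))
    if (lambda == 0) break
    improved <- FALSE
    for (h in seq_len(31L)) {
      cand <- theta + lambda * step
      nxt <- loglik_parts(X, y, cand)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll) {
        theta <- cand
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    rel <- abs(nxt$ll - cur$ll) / (abs(cur$ll) + 1e-10)
    cur <- nxt
    if (rel < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged && !singular) {
    warn(sprintf("fit_cpg_glm: model '%s' did not converge in %d iterations",
                 design$spec$name, iter))
  }

  info_obs <- Matrix::crossprod(X, X * cur$w_obs)
  vcov <- tryCatch(as.matrix(Matrix::solve(info_obs)), error = function(e) {
    matrix(NA_real_, p_cols, p_cols)
  })
  dimnames(vcov) <- list(colnames(X), colnames(X))

  # saturated Bernoulli log-likelihood is 0, so D_resid = -2 l_hat
  ll <- cur$ll
  ll_null <- if (ybar %in% c(0, 1)) 0 else n * (ybar * log(ybar) + (1 - ybar) * log1p(-ybar))

  structure(
    list(
      spec = design$spec,
      coefficients = theta,
      vcov = vcov,
      logLik = ll,
      null_deviance = -2 * ll_null,
      deviance = -2 * ll,
      aic = 2 * p_cols - 2 * ll,
      bic = p_cols * log(n) - 2 * ll,
      n = n,
      n_poly = sum(y),
      p = p_cols,
      iterations = iter,
      converged = converged,
      boundary = cur$clipped || any(cur$eta > -1e-8),
      singular_info = singular,
      eta = cur$eta
    ),
    class = "cpg_fit"
  )
}

#' @export
print.cpg_fit <- function(x, ...) {
  cat(sprintf(
    "<cpg_fit> model %s: %d sites (%d polymorphic), %d coefficients\n",
    x$spec$name, x$n, x$n_poly, x$p
  ))
  cat(sprintf(
    "  logLik %.2f | deviance %.2f (null %.2f) | AIC %.2f | BIC %.2f\n",
    x$logLik, x$deviance, x$null_deviance, x$aic, x$bic
  ))
  cat(sprintf(
    "  %s in %d iteration(s)%s\n",
    if (x$converged) "converged" else "NOT converged", x$iterations,
    if (x$boundary) " [probability clipped at boundary]" else ""
  ))
  invisible(x)
}

#' Tidy a fitted context model
#'
#' @param x a `cpg_fit`.
#' @param ... unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @method tidy cpg_fit
#' @export
tidy.cpg_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(x$coefficients / se),
    p.value = 2 * pnorm(-abs(unname(x$coefficients / se)))
  )
}

#' One-row summary of a fitted context model
#'
#' @param x a `cpg_fit`.
#' @param ... unused.
#' @return A tibble with `model`, `n`, `n_poly`, `df`, `logLik`, `deviance`,
#'   `null.deviance`, `AIC`, `BIC`, `variance_explained`, `iterations`,
#'   `converged`, `boundary`.
#' @method glance cpg_fit
#' @export
glance.cpg_fit <- function(x, ...) {
  tibble(
    model = x$spec$name,
    n = x$n,
    n_poly = x$n_poly,
    df = x$p,
    logLik = x$logLik,
    deviance = x$deviance,
    null.deviance = x$null_deviance,
    AIC = x$aic,
    BIC = x$bic,
    variance_explained = (x$null_deviance - x$deviance) / x$null_deviance,
    iterations = x$iterations,
    converged = x$converged,
    boundary = x$boundary
  )
}

#' Model comparison scores
#'
#' AIC, BIC and the proportion of (deviance) variance explained,
#' `(D_null - D_resid) / D_null`, where the null model is the intercept-only
#' fit on the same sites under the same link.
#'
#' @param fit a `cpg_fit`.
#' @return A one-row tibble with `model`, `AIC`, `BIC`,
#'   `variance_explained`.
#' @export
model_scores <- function(fit) {
  tibble(
    model = fit$spec$name,
    AIC = fit$aic,
    BIC = fit$bic,
    variance_explained = (fit$null_deviance - fit$deviance) / fit$null_deviance
  )
}
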