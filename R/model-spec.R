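#' Context-model registry
#'
#' Each model describes the polymorphism probability of one strand-resolved
#' CpG cytosine through the linear predictor `eta = -muT`, with
#' `muT = (alpha_c + beta_c m) T` structured by sequence context:
#'
#' * `"4mer"` — `4mer * m`: every 4-mer context has its own baseline and
#'   methylation slope (32 coefficients).
#' * `"up1_down1"` — `U1 + D1 + m + U1:m + D1:m`: the immediate upstream and
#'   downstream bases act independently on baseline and slope
#'   (14 coefficients).
#' * `"6mer"` — `6mer * m` (512 coefficients).
#' * `"up21_down12"` — `U21 + D12 + m + U21:m + D12:m`: upstream and
#'   downstream dimers act independently, with interactions allowed within
#'   each dimer (62 coefficients).
#' * `"additive_positions"` — `U2 + U1 + D1 + D2 + m + (each):m`: all four
#'   flanking positions independent (26 coefficients).
#' * `"context_only_4mer"`, `"context_only_up1_down1"` — the corresponding
#'   context structure with every methylation term removed, for species with
#'   negligible germline methylation (16 and 7 coefficients).
#'
#' `U1`/`U2` are the bases one/two positions upstream of the focal C,
#' `D1`/`D2` one/two positions downstream of the focal G, `U21`/`D12` the
#' upstream/downstream dimers; all read on the focal cytosine's strand.
#'
#' @param name model name, one of the registry names above.
#' @return An object of class `cpg_model_spec`: a list with `name`,
#'   `formula` (RHS), `k` (context width used), `with_methylation`,
#'   `n_params` (coefficient count when all context levels are present).
#' @examples
#' model_spec("up1_down1")$n_params # 14
#' @export
model_spec <- function(name = c("4mer", "up1_down1", "6mer", "up21_down12",
                                "additive_positions", "context_only_4mer",
                                "context_only_up1_down1")) {
  name <- match.arg(name)
  reg <- list(
    "4mer" = list(rhs = "context4 * m", k = 4L, meth = TRUE, p = 32L),
    "up1_down1" = list(rhs = "U1 + D1 + m + U1:m + D1:m", k = 4L, meth = TRUE, p = 14L),
    "6mer" = list(rhs = "context6 * m", k = 6L, meth = TRUE, p = 512L),
    "up21_down12" = list(rhs = "U21 + D12 + m + U21:m + D12:m", k = 6L, meth = TRUE, p = 62L),
    "additive_positions" = list(
      rhs = "U2 + U1 + D1 + D2 + m + U2:m + U1:m + D1:m + D2:m",
      k = 6L, meth = TRUE, p = 26L
    ),
    "context_only_4mer" = list(rhs = "context4", k = 4L, meth = FALSE, p = 16L),
    "context_only_up1_down1" = list(rhs = "U1 + D1", k = 4L, meth = FALSE, p = 7L)
  )
  r <- reg[[name]]
  structure(
    list(name = name, formula = r$rhs, k = r$k,
         with_methylation = r$meth, n_params = r$p),
    class = "cpg_model_spec"
  )
}

#' @export
print.cpg_model_spec <- function(x, ...) {
  cat(sprintf("<cpg_model_spec> %s: ~ %s  (%d coefficients, %d-mer context%s)\n",
              x$name, x$formula, x$n_params, x$k,
              if (x$with_methylation) "" else ", no methylation terms"))
  invisible(x)
}

#' Names of all registered context models
#'
#' @return Character vector of model names accepted by [model_spec()].
#' @export
model_names <- function() {
  c("4mer", "up1_down1", "6mer", "up21_down12", "additive_positions",
    "context_only_4mer", "context_only_up1_down1")
}

# Derive the flank factor columns (U1, D1, U2, D2, U21, D12) a spec needs
# from the site table's context strings. Factors carry the full level set so
# the design is identical across data subsets.
add_flank_factors <- function(sites, spec) {
  ctx_col <- paste0("context", spec$k)
  if (!ctx_col %in% names(sites)) {
    abort(sprintf("model '%s' needs column %s", spec$name, ctx_col))
  }
  if (anyNA(sites[[ctx_col]])) {
    abort(sprintf("model '%s': %d sites have missing %s; drop them first",
                  spec$name, sum(is.na(sites[[ctx_col]])), ctx_col))
  }
  ctx <- sites[[ctx_col]]
  bases <- c("A", "C", "G", "T")
  dimers <- sort(do.call(paste0, expand.grid(bases, bases)[2:1]))
  vars <- all.vars(as.formula(paste("~", spec$formula)))
  if ("context4" %in% vars) {
    sites$context4 <- factor(sites$context4, levels = enumerate_contexts(4L))
  }
  if ("context6" %in% vars) {
    sites$context6 <- factor(sites$context6, levels = enumerate_contexts(6L))
  }
  n_flank <- (spec$k - 2L) %/% 2L
  if ("U1" %in% vars) sites$U1 <- factor(substr(ctx, n_flank, n_flank), bases)
  if ("D1" %in% vars) sites$D1 <- factor(substr(ctx, n_flank + 3L, n_flank + 3L), bases)
  if ("U2" %in% vars) sites$U2 <- factor(substr(ctx, 1L, 1L), bases)
  if ("D2" %in% vars) sites$D2 <- factor(substr(ctx, 6L, 6L), bases)
  if ("U21" %in% vars) sites$U21 <- factor(substr(ctx, 1L, 2L), dimers)
  if ("D12" %in% vars) sites$D12 <- factor(substr(ctx, 5L, 6L), dimers)
  if ("m" %in% vars && !"m" %in% names(sites)) {
    abort(sprintf("model '%s' needs a methylation column m", spec$name))
  }
  sites
}

#' Build the design matrix for a context model
#'
#' Treatment coding with an intercept; the reference level of every factor
#' is the lexicographically first level, so column identity is reproducible.
#' The matrix is sparse (context indicators are mostly zero).
#'
#' @param sites a site table with the context column the model needs (and
#'   `m`, `y` where applicable).
#' @param spec a `cpg_model_spec` (or a model name).
#' @return A list of class `cpg_design`: `X` (sparse n x p design),
#'   `y` (integer outcome, when present in `sites`), `m`, `spec`.
#' @examples
#' ncol(build_design_matrix(simulate_site_table(synthetic_truth(seed = 1)), "4mer")$X)
#' @export
build_design_matrix <- function(sites, spec) {
  if (is.character(spec)) spec <- model_spec(spec)
  sites <- add_flank_factors(sites, spec)
  f <- as.formula(paste("~", spec$formula))
  old <- options(contrasts = c("contr.treatment", "contr.poly"))
  on.exit(options(old), add = TRUE)
  X <- Matrix::sparse.model.matrix(f, data = sites)
  structure(
    list(
      X = X,
      y = if ("y" %in% names(sites)) as.integer(sites$y) else NULL,
      m = if ("m" %in% names(sites)) sites$m else NULL,
      spec = spec
    ),
    class = "cpg_design"
  )
}
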