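#' Load and validate a run configuration
#'
#' The pipeline is driven by a flat YAML key-value file; every stage writes
#' the resolved configuration and a manifest next to its outputs so a run
#' can be reproduced exactly.
#'
#' Recognized keys (all optional unless a stage needs them): `fasta`,
#' `include_bed`, `exclude_bed`, `vcf`, `methylation`, `out_dir`, `models`
#' (list of model names), `k` (list of context widths), `min_coverage`,
#' `singleton_policy`, `n_bins`, `seed`.
#'
#' @param path path to a YAML config, or a named list of overrides.
#' @param overrides named list merged over the file contents (CLI flags win
#'   over the config file).
#' @return A validated config list of class `cpg_config`.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- list(
    models = c("4mer", "up1_down1"),
    k = c(4L, 6L),
    min_coverage = 5L,
    singleton_policy = "keep",
    n_bins = 20L,
    seed = 1L,
    out_dir = "cpgrates_out"
  )
  if (!is.null(path)) {
    if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
    cfg <- modifyList(cfg, yaml::read_yaml(path))
  }
  cfg <- modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])
  bad <- setdiff(cfg$models, model_names())
  if (length(bad) > 0L) {
    abort(sprintf("unknown model name(s): %s", paste(bad, collapse = ", ")))
  }
  for (key in c("fasta", "include_bed", "exclude_bed", "vcf", "methylation")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      abort(sprintf("config: %s file not found: %s", key, cfg[[key]]))
    }
  }
  structure(cfg, class = c("cpg_config", "list"))
}

write_manifest <- function(out_dir, stage, inputs, counts, cfg) {
  manifest <- list(
    stage = stage,
    package_version = as.character(utils::packageVersion("cpgrates")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    inputs = inputs,
    counts = as.list(counts)
  )
  jsonlite::write_json(manifest, file.path(out_dir, paste0(stage, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

require_stage_output <- function(cfg, name, producer) {
  p <- stage_path(cfg, name)
  if (!file.exists(p)) {
    abort(sprintf("missing %s — run the '%s' stage first", p, producer))
  }
  p
}

#' Pipeline stage: extract CpG sites
#'
#' Reads the genome FASTA and region BEDs, computes the analyzable region
#' set (include minus exclude), scans for CpGs and writes the strand-
#' resolved site table (`sites.tsv`).
#'
#' @param cfg a `cpg_config`.
#' @return The site tibble, invisibly.
#' @export
pipeline_extract <- function(cfg) {
  if (is.null(cfg$fasta)) abort("pipeline_extract: config needs 'fasta'")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- read_genome_fasta(cfg$fasta)
  included <- if (!is.null(cfg$include_bed)) read_bed(cfg$include_bed) else genome_regions(genome)
  if (!is.null(cfg$exclude_bed)) {
    included <- subtract_regions(included, read_bed(cfg$exclude_bed))
  }
  sites <- find_cpg_sites(genome, included, k = as.integer(unlist(cfg$k)))
  write_site_tsv(sites, stage_path(cfg, "sites.tsv"))
  write_manifest(cfg$out_dir, "extract",
                 inputs = cfg[c("fasta", "include_bed", "exclude_bed")],
                 counts = c(n_sites = nrow(sites)), cfg)
  invisible(sites)
}

#' Pipeline stage: annotate sites with methylation and polymorphism
#'
#' Joins the extracted cytosines with pooled methylation and MAF-polarized
#' variants into the model-ready table (`site_table.tsv`).
#'
#' @param cfg a `cpg_config`.
#' @return The annotated site tibble, invisibly.
#' @export
pipeline_annotate <- function(cfg) {
  if (is.null(cfg$vcf) || is.null(cfg$methylation)) {
    abort("pipeline_annotate: config needs 'vcf' and 'methylation'")
  }
  sites <- read_site_tsv(require_stage_output(cfg, "sites.tsv", "extract"))
  meth <- read_methylation_tsv(cfg$methylation)
  pooled <- pool_methylation(meth, min_coverage = cfg$min_coverage, by_strand = FALSE)
  variants <- read_vcf_snvs(cfg$vcf, singleton_policy = cfg$singleton_policy)
  polarized <- polarize_maf(variants)
  tab <- assemble_site_table(sites, pooled, polarized,
                             model_k = min(as.integer(unlist(cfg$k))))
  write_site_tsv(tab, stage_path(cfg, "site_table.tsv"))
  write_manifest(cfg$out_dir, "annotate",
                 inputs = cfg[c("vcf", "methylation")],
                 counts = attr(tab, "drop_counts"), cfg)
  invisible(tab)
}

#' Pipeline stage: fit the configured context models
#'
#' @param cfg a `cpg_config`.
#' @return Named list of `cpg_fit` objects, invisibly.
#' @export
pipeline_fit <- function(cfg) {
  tab <- read_site_tsv(require_stage_output(cfg, "site_table.tsv", "annotate"))
  fits <- purrr::map(setNames(cfg$models, cfg$models), function(mn) {
    fit <- fit_cpg_glm(tab, mn)
    write_fit_json(fit, stage_path(cfg, sprintf("fit_%s.json", mn)))
    fit
  })
  write_manifest(cfg$out_dir, "fit",
                 inputs = list(site_table = stage_path(cfg, "site_table.tsv")),
                 counts = c(n_sites = nrow(tab),
                            setNames(vapply(fits, function(f) f$p, numeric(1)),
                                     paste0("n_coef_", names(fits)))),
                 cfg)
  invisible(fits)
}

#' Pipeline stage: predict scaled rates for every fitted model
#'
#' @param cfg a `cpg_config`.
#' @return Named list of `cpg_rates` tibbles, invisibly.
#' @export
pipeline_predict <- function(cfg) {
  tab <- read_site_tsv(require_stage_output(cfg, "site_table.tsv", "annotate"))
  rates <- purrr::map(setNames(cfg$models, cfg$models), function(mn) {
    r <- predict_scaled_rates(fit_cpg_glm(tab, mn))
    write_site_tsv(r, stage_path(cfg, sprintf("rates_%s.tsv", mn)))
    r
  })
  write_manifest(cfg$out_dir, "predict",
                 inputs = list(site_table = stage_path(cfg, "site_table.tsv")),
                 counts = c(n_models = length(rates)), cfg)
  invisible(rates)
}

#' Pipeline stage: compare the configured models
#'
#' Writes AIC/BIC/variance-explained for every configured model plus the
#' pairwise concordance of their rate estimates.
#'
#' @param cfg a `cpg_config`.
#' @return A list with `scores` and `concordance` tibbles, invisibly.
#' @export
pipeline_compare <- function(cfg) {
  tab <- read_site_tsv(require_stage_output(cfg, "site_table.tsv", "annotate"))
  fits <- purrr::map(setNames(cfg$models, cfg$models), ~ fit_cpg_glm(tab, .x))
  scores <- purrr::map_dfr(fits, model_scores)
  rates <- purrr::map(fits, predict_scaled_rates)
  pairs <- utils::combn(names(fits), 2L, simplify = FALSE)
  conc <- purrr::map_dfr(pairs, function(pr) {
    concordance(rates[[pr[1]]], rates[[pr[2]]]) |>
      mutate(model_a = pr[1], model_b = pr[2], .before = 1)
  })
  readr::write_tsv(scores, stage_path(cfg, "model_scores.tsv"), progress = FALSE)
  readr::write_tsv(conc, stage_path(cfg, "model_concordance.tsv"), progress = FALSE)
  write_manifest(cfg$out_dir, "compare",
                 inputs = list(site_table = stage_path(cfg, "site_table.tsv")),
                 counts = c(n_models = length(fits)), cfg)
  invisible(list(scores = scores, concordance = conc))
}

#' Pipeline stage: reverse-complement asymmetry tests
#'
#' @param cfg a `cpg_config`; uses the first configured 4-mer-context model.
#' @return The asymmetry tibble, invisibly.
#' @export
pipeline_asymmetry <- function(cfg) {
  tab <- read_site_tsv(require_stage_output(cfg, "site_table.tsv", "annotate"))
  mn <- cfg$models[vapply(cfg$models, function(x) model_spec(x)$k == 4L, logical(1))][1]
  if (is.na(mn)) abort("pipeline_asymmetry: no 4-mer-context model configured")
  asym <- test_asymmetry(predict_scaled_rates(fit_cpg_glm(tab, mn)))
  readr::write_tsv(asym, stage_path(cfg, "asymmetry.tsv"), progress = FALSE)
  write_manifest(cfg$out_dir, "asymmetry",
                 inputs = list(site_table = stage_path(cfg, "site_table.tsv")),
                 counts = c(n_pairs = nrow(asym)), cfg)
  invisible(asym)
}

#' Pipeline stage: methylation-binned polymorphism rates
#'
#' @param cfg a `cpg_config`.
#' @return The bin tibble, invisibly.
#' @export
pipeline_bins <- function(cfg) {
  tab <- read_site_tsv(require_stage_output(cfg, "site_table.tsv", "annotate"))
  bins <- binned_rates(tab, n_bins = cfg$n_bins)
  readr::write_tsv(bins, stage_path(cfg, "methylation_bins.tsv"), progress = FALSE)
  write_manifest(cfg$out_dir, "bins",
                 inputs = list(site_table = stage_path(cfg, "site_table.tsv")),
                 counts = c(n_bins = nrow(bins), n_sites = nrow(tab)), cfg)
  invisible(bins)
}

#' Pipeline stage: simulate a site table from configured truth
#'
#' Writes a simulated `site_table.tsv` (so fit/predict/compare stages run on
#' it unchanged) plus the generating truth as JSON.
#'
#' @param cfg a `cpg_config`; honours `seed`, optional `n_per_context` and
#'   `sim_k`.
#' @return The simulated site tibble, invisibly.
#' @export
pipeline_simulate <- function(cfg) {
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- synthetic_truth(
    k = if (!is.null(cfg$sim_k)) as.integer(cfg$sim_k) else 4L,
    n_per_context = if (!is.null(cfg$n_per_context)) as.integer(cfg$n_per_context) else 20000L,
    seed = cfg$seed
  )
  tab <- simulate_site_table(truth)
  write_site_tsv(tab, stage_path(cfg, "site_table.tsv"))
  jsonlite::write_json(
    list(k = truth$k, n_per_context = truth$n_per_context, seed = truth$seed,
         contexts = truth$contexts,
         mixture = list(weight = truth$mix_weight, beta_low = truth$beta_low,
                        beta_high = truth$beta_high)),
    stage_path(cfg, "truth.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_manifest(cfg$out_dir, "simulate", inputs = list(),
                 counts = c(n_sites = nrow(tab)), cfg)
  invisible(tab)
}

#' Command-line entry point
#'
#' Dispatches `cpgrates <subcommand> [--config FILE] [--key value ...]` to
#' the corresponding pipeline stage. Installed as the executable script
#' `exec/cpgrates`; exposed as a function so the dispatcher is testable
#' in-process.
#'
#' @param args character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Integer exit status, invisibly (0 on success, 1 on error).
#' @export
cpg_pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages <- list(
    extract = pipeline_extract, annotate = pipeline_annotate,
    fit = pipeline_fit, predict = pipeline_predict,
    compare = pipeline_compare, asymmetry = pipeline_asymmetry,
    bins = pipeline_bins, simulate = pipeline_simulate
  )
  usage <- paste0(
    "usage: cpgrates <", paste(names(stages), collapse = "|"),
    "> [--config FILE] [--key value ...]\n"
  )
  if (length(args) == 0L || !args[1] %in% names(stages)) {
    cat(usage)
    return(invisible(1L))
  }
  flags <- args[-1]
  overrides <- list()
  config_path <- NULL
  i <- 1L
  while (i <= length(flags)) {
    key <- sub("^--", "", flags[i])
    if (!startsWith(flags[i], "--") || i == length(flags)) {
      cat(usage)
      return(invisible(1L))
    }
    val <- flags[i + 1L]
    if (key == "config") {
      config_path <- val
    } else {
      if (key %in% c("models", "k")) val <- strsplit(val, ",", fixed = TRUE)[[1]]
      if (key %in% c("min_coverage", "n_bins", "seed", "n_per_context", "sim_k")) {
        val <- as.integer(val)
      }
      if (identical(key, "k")) val <- as.integer(val)
      overrides[[key]] <- val
    }
    i <- i + 2L
  }
  status <- tryCatch({
    cfg <- read_run_config(config_path, overrides)
    stages[[args[1]]](cfg)
    0L
  }, error = function(e) {
    message("cpgrates ", args[1], ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
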