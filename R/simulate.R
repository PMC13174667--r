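#' Define a synthetic truth for site-table simulation
#'
#' Describes the generative model the regression is built to invert: each
#' context `c` has a true baseline scaled rate `alphaT_c` and methylation
#' effect `betaT_c`, a site's methylation level is drawn from a two-mode
#' Beta mixture on \[0, 1\] (the bimodal landscape of germline CpG
#' methylation), and its polymorphism indicator is Bernoulli with
#' `p = 1 - exp(-(alphaT_c + betaT_c m))`. The defaults place `alphaT` in
#' \[0.01, 0.05\] and `betaT` in \[0.2, 0.6\], so `p` spans roughly
#' 0.01-0.4 — the regime where the exponential recurrent-mutation
#' correction is material.
#'
#' @param k context width (4 or 6).
#' @param alphaT per-context baseline scaled rates; a single value, a vector
#'   of length `4^(k-2)`, or `NULL` to draw uniformly from `alphaT_range`.
#' @param betaT per-context methylation effects, likewise.
#' @param alphaT_range,betaT_range ranges used when drawing unspecified
#'   truths.
#' @param n_per_context sites per context (default 20000).
#' @param mix_weight weight of the low-methylation mode (default 0.45).
#' @param beta_low,beta_high shape parameters `c(a, b)` of the low and high
#'   Beta modes (defaults `c(0.6, 8)` and `c(8, 0.6)`).
#' @param seed integer seed; fully determines the simulated table.
#' @return An object of class `cpg_truth`: tibble `contexts` (context,
#'   alphaT, betaT) plus the mixture parameters, `n_per_context`, `k`,
#'   `seed`.
#' @export
synthetic_truth <- function(k = 4L,
                            alphaT = NULL,
                            betaT = NULL,
                            alphaT_range = c(0.01, 0.05),
                            betaT_range = c(0.2, 0.6),
                            n_per_context = 20000L,
                            mix_weight = 0.45,
                            beta_low = c(0.6, 8),
                            beta_high = c(8, 0.6),
                            seed = 1L) {
  contexts <- enumerate_contexts(k)
  nc <- length(contexts)
  if (any(beta_low <= 0) || any(beta_high <= 0)) {
    abort("synthetic_truth: Beta mixture shape parameters must be positive")
  }
  if (mix_weight < 0 || mix_weight > 1) abort("synthetic_truth: mix_weight must lie in [0, 1]")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  draw <- function(x, range) {
    if (is.null(x)) return(runif(nc, range[1], range[2]))
    if (length(x) == 1L) return(rep(x, nc))
    stopifnot(length(x) == nc)
    x
  }
  a <- draw(alphaT, alphaT_range)
  b <- draw(betaT, betaT_range)
  if (any(a < 0) || any(a + b < 0)) {
    abort("synthetic_truth: need alphaT >= 0 and alphaT + betaT >= 0 for valid rates")
  }
  structure(
    list(
      contexts = tibble(context = contexts, alphaT = a, betaT = b),
      k = as.integer(k),
      n_per_context = as.integer(n_per_context),
      mix_weight = mix_weight,
      beta_low = beta_low,
      beta_high = beta_high,
      seed = as.integer(seed)
    ),
    class = "cpg_truth"
  )
}

#' @export
print.cpg_truth <- function(x, ...) {
  cat(sprintf("<cpg_truth> %d-mer, %d contexts x %d sites, seed %d\n",
              x$k, nrow(x$contexts), x$n_per_context, x$seed))
  cat(sprintf("  alphaT in [%.4f, %.4f], betaT in [%.4f, %.4f]\n",
              min(x$contexts$alphaT), max(x$contexts$alphaT),
              min(x$contexts$betaT), max(x$contexts$betaT)))
  invisible(x)
}

#' Simulate a model-level site table from a known truth
#'
#' Draws `n_per_context` sites per context: methylation from the Beta
#' mixture, polymorphism from
#' `y ~ Bernoulli(1 - exp(-(alphaT_c + betaT_c m)))`. The output has the
#' same columns as an assembled site table, so every downstream operation
#' (fitting, prediction, summaries) runs on it unchanged.
#'
#' @param truth a `cpg_truth` from [synthetic_truth()].
#' @return A site-table tibble with `chrom`, `cpg_start`, `strand`,
#'   `context4` (and `context6` when `k = 6`), `m`, `y`.
#' @examples
#' head(simulate_site_table(synthetic_truth(seed = 7, n_per_context = 100)))
#' @export
simulate_site_table <- function(truth) {
  stopifnot(inherits(truth, "cpg_truth"))
  set.seed(truth$seed)
  nc <- nrow(truth$contexts)
  n <- truth$n_per_context
  total <- nc * n
  ctx <- rep(truth$contexts$context, each = n)
  alpha <- rep(truth$contexts$alphaT, each = n)
  beta <- rep(truth$contexts$betaT, each = n)
  low <- runif(total) < truth$mix_weight
  m <- numeric(total)
  m[low] <- rbeta(sum(low), truth$beta_low[1], truth$beta_low[2])
  m[!low] <- rbeta(sum(!low), truth$beta_high[1], truth$beta_high[2])
  muT <- alpha + beta * m
  y <- rbinom(total, 1L, -expm1(-muT))
  out <- tibble(
    chrom = "sim",
    cpg_start = seq_len(total) - 1L,
    strand = "+",
    context4 = if (truth$k == 4L) ctx else substr(ctx, 2L, 5L),
    m = m,
    y = y
  )
  if (truth$k == 6L) out$context6 <- ctx
  out
}

# ---- byte-level fixture bundle -------------------------------------------

random_masked_genome <- function(genome_length, n_chrom = 2L) {
  bases <- c("A", "C", "G", "T")
  purrr::map_chr(seq_len(n_chrom), function(i) {
    s <- sample(bases, genome_length, replace = TRUE,
                prob = c(0.3, 0.22, 0.22, 0.26))
    # hard-mask a couple of short stretches and soft-mask one
    n_mask <- max(1L, genome_length %/% 50L)
    for (j in seq_len(n_mask)) {
      at <- sample.int(genome_length - 3L, 1L)
      s[at:(at + 2L)] <- "N"
    }
    at <- sample.int(genome_length - 4L, 1L)
    s[at:(at + 3L)] <- tolower(s[at:(at + 3L)])
    paste(s, collapse = "")
  })
}

# Independent oracle: enumerate the expected site table by walking the
# sequence base by base with plain character operations. Deliberately
# written as a naive loop, sharing no code with find_cpg_sites() /
# assemble_site_table().
enumerate_expected_sites <- function(genome, regions, meth_pooled, variants,
                                     min_coverage = 5L) {
  rows <- list()
  for (gi in seq_len(nrow(genome))) {
    chrom <- genome$chrom[gi]
    chars <- strsplit(genome$seq[gi], "")[[1]]
    L <- length(chars)
    for (i in seq_len(L - 1L)) {
      if (chars[i] != "C" || chars[i + 1L] != "G") next
      p0 <- i - 1L # 0-based C position
      inside <- FALSE
      for (ri in seq_len(nrow(regions))) {
        if (regions$chrom[ri] == chrom &&
            p0 >= regions$start[ri] && (p0 + 1L) < regions$end[ri]) {
          inside <- TRUE
          break
        }
      }
      if (!inside) next
      ctx <- if (i >= 2L && i + 2L <= L) paste(chars[(i - 1L):(i + 2L)], collapse = "") else NA
      if (!is.na(ctx) && grepl("[^ACGT]", ctx)) ctx <- NA
      if (is.na(ctx)) next
      mrow <- meth_pooled[meth_pooled$chrom == chrom & meth_pooled$pos == p0, ]
      if (nrow(mrow) != 1L || mrow$total_reads < min_coverage) next
      m <- mrow$meth_reads / mrow$total_reads
      for (strand in c("+", "-")) {
        vpos <- if (strand == "+") p0 else p0 + 1L
        want_anc <- if (strand == "+") "C" else "G"
        want_der <- if (strand == "+") "T" else "A"
        y <- 0L
        tie <- FALSE
        vr <- variants[variants$chrom == chrom & variants$pos == vpos, ]
        if (nrow(vr) == 1L) {
          if (2L * vr$ac == vr$an) {
            tie <- TRUE
          } else {
            anc <- if (2L * vr$ac < vr$an) vr$ref else vr$alt
            der <- if (2L * vr$ac < vr$an) vr$alt else vr$ref
            if (anc == want_anc && der == want_der) y <- 1L
          }
        }
        if (tie) next
        cctx <- if (strand == "+") ctx else {
          paste(rev(chartr("ACGT", "TGCA", strsplit(ctx, "")[[1]])), collapse = "")
        }
        rows[[length(rows) + 1L]] <- tibble(
          chrom = chrom, cpg_start = p0, strand = strand,
          context4 = cctx, m = m, y = y
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(chrom = character(), cpg_start = integer(), strand = character(),
                  context4 = character(), m = numeric(), y = integer()))
  }
  arrange(bind_rows(rows), .data$chrom, .data$cpg_start, .data$strand)
}

#' Generate a mutually consistent byte-level fixture bundle
#'
#' Writes a small random genome (with hard- and soft-masked stretches), an
#' inclusion BED, a VCF whose records sit on fixture CpG cytosines, a
#' per-sample methylation TSV, and the expected model-ready site table —
#' the last produced by an independent base-by-base enumeration, not by the
#' pipeline, so the bundle can serve as an end-to-end oracle.
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed; fully determines the bundle.
#' @param genome_length bases per chromosome (two chromosomes; minimum 50).
#' @param n_variants number of VCF records to place on CpG cytosines.
#' @param n_samples bisulfite samples in the methylation table.
#' @param min_coverage pooled-coverage threshold mirrored in the expected
#'   table.
#' @return A list of paths: `fasta`, `bed`, `vcf`, `methylation`,
#'   `expected_sites`, `truth_json`.
#' @export
generate_fixture_bundle <- function(dir,
                                    seed = 1L,
                                    genome_length = 400L,
                                    n_variants = 12L,
                                    n_samples = 3L,
                                    min_coverage = 5L) {
  if (genome_length < 50L) abort("generate_fixture_bundle: genome_length must be >= 50")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))

  genome <- tibble(
    chrom = c("chrA", "chrB"),
    seq = random_masked_genome(genome_length)
  )
  # include most of each chromosome, leaving the edges out so some CpGs are
  # excluded by region membership
  regions <- region_set(genome$chrom, 5L, genome_length - 5L)

  # fixture CpG cytosine positions (forward C of uppercase CG dimers)
  cg <- find_cpg_sites(genome, regions, k = 4L)
  cg_plus <- filter(cg, .data$strand == "+")

  # methylation: every CpG gets per-sample read counts; a few sites are
  # deliberately under-covered so the coverage filter is exercised
  meth <- purrr::map_dfr(seq_len(n_samples), function(si) {
    tot <- pmax(1L, rbinom(nrow(cg_plus), 12L, 0.7))
    lvl <- ifelse(runif(nrow(cg_plus)) < 0.5,
                  rbeta(nrow(cg_plus), 0.6, 8), rbeta(nrow(cg_plus), 8, 0.6))
    tibble(
      chrom = cg_plus$chrom,
      pos = cg_plus$cpg_start,
      strand = "+",
      meth_reads = rbinom(nrow(cg_plus), tot, lvl),
      total_reads = tot,
      sample = sprintf("s%02d", si)
    )
  })
  lowcov <- sample.int(nrow(cg_plus), max(1L, nrow(cg_plus) %/% 10L))
  lowkey <- paste(cg_plus$chrom[lowcov], cg_plus$cpg_start[lowcov])
  meth <- meth |>
    mutate(.low = paste(.data$chrom, .data$pos) %in% lowkey,
           total_reads = ifelse(.data$.low, 1L, .data$total_reads),
           meth_reads = pmin(.data$meth_reads, .data$total_reads)) |>
    select(-".low")

  # variants on CpG cytosines: mostly derived C>T / G>A, plus a non-C>T
  # substitution, a high-frequency (derived-C) record and an exact tie
  n_variants <- min(n_variants, 2L * nrow(cg_plus))
  pick <- cg[sample.int(nrow(cg), n_variants), ]
  an <- 2000L
  empty_variants <- tibble(chrom = character(), pos = integer(),
                           ref = character(), alt = character(),
                           ac = integer(), an = integer())
  variants <- purrr::map_dfr(seq_len(nrow(pick)), function(i) {
    strand <- pick$strand[i]
    pos <- if (strand == "+") pick$cpg_start[i] else pick$cpg_start[i] + 1L
    ref <- if (strand == "+") "C" else "G"
    alt <- if (strand == "+") "T" else "A"
    kind <- sample(c("ct", "ct", "ct", "other", "highfreq", "tie"), 1L)
    if (kind == "other") alt <- if (strand == "+") "A" else "T"
    ac <- switch(kind,
                 ct = sample(2:100, 1L),
                 other = sample(2:100, 1L),
                 highfreq = an - sample(2:100, 1L),
                 tie = an %/% 2L)
    tibble(chrom = pick$chrom[i], pos = pos, ref = ref, alt = alt,
           ac = as.integer(ac), an = an)
  })
  variants <- bind_rows(empty_variants, variants) |>
    distinct(.data$chrom, .data$pos, .keep_all = TRUE) |>
    arrange(.data$chrom, .data$pos)

  paths <- list(
    fasta = file.path(dir, "genome.fa"),
    bed = file.path(dir, "include.bed"),
    vcf = file.path(dir, "variants.vcf"),
    methylation = file.path(dir, "methylation.tsv"),
    expected_sites = file.path(dir, "expected_sites.tsv"),
    truth_json = file.path(dir, "bundle.json")
  )
  write_genome_fasta(genome, paths$fasta)
  write_bed(regions, paths$bed)
  write_minimal_vcf(variants, paths$vcf)
  readr::write_tsv(meth, paths$methylation, progress = FALSE)

  pooled <- pool_methylation(meth, min_coverage = min_coverage, by_strand = FALSE)
  expected <- enumerate_expected_sites(genome, regions, pooled, variants,
                                       min_coverage = min_coverage)
  write_site_tsv(expected, paths$expected_sites)
  jsonlite::write_json(
    list(seed = seed, genome_length = genome_length,
         n_variants = nrow(variants), n_samples = n_samples,
         min_coverage = min_coverage, n_expected_sites = nrow(expected)),
    paths$truth_json, auto_unbox = TRUE, pretty = TRUE
  )
  paths
}

# Minimal VCFv4.2 writer for fixture bundles (pos is internal 0-based).
write_minimal_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total allele number\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAC=%d;AN=%d",
                  variants$chrom, variants$pos + 1L, variants$ref,
                  variants$alt, variants$ac, variants$an)
  writeLines(c(header, body), path)
  invisible(path)
}
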