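#' Pool methylation observations across samples
#'
#' The methylation level of a cytosine is estimated by summing methylated and
#' total bisulfite read counts across samples before dividing, which damps
#' the bias introduced by C/T polymorphism carriers in individual samples.
#' Sites whose pooled coverage is below `min_coverage` get `m = NA` and are
#' dropped at assembly.
#'
#' @param observations tibble with columns `chrom`, `pos`, `strand`,
#'   `meth_reads`, `total_reads`, `sample` (one row per site per sample).
#' @param min_coverage minimum pooled read count for a usable estimate
#'   (default 5).
#' @param by_strand if `TRUE` pool per (chrom, pos, strand); if `FALSE`
#'   (CpG-level tables) pool per (chrom, pos).
#' @return A tibble with the grouping keys plus `meth_reads`, `total_reads`,
#'   `m`.
#' @examples
#' obs <- tibble::tibble(chrom = "chr1", pos = 2L, strand = "+",
#'                       meth_reads = c(5L, 15L), total_reads = c(10L, 20L),
#'                       sample = c("s1", "s2"))
#' pool_methylation(obs) # m = 20/30
#' @export
pool_methylation <- function(observations, min_coverage = 5L, by_strand = TRUE) {
  stopifnot(all(observations$meth_reads <= observations$total_reads),
            all(observations$meth_reads >= 0L))
  keys <- if (by_strand) c("chrom", "pos", "strand") else c("chrom", "pos")
  observations |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(
      meth_reads = sum(.data$meth_reads),
      total_reads = sum(.data$total_reads),
      .groups = "drop"
    ) |>
    mutate(m = ifelse(.data$total_reads >= min_coverage,
                      .data$meth_reads / .data$total_reads, NA_real_))
}

#' Polarize variants by minor allele frequency
#'
#' The major allele is taken as the ancestral state and the minor allele as
#' the derived state. Records with an exact frequency tie (`AC = AN/2`)
#' cannot be polarized and are flagged; sites carrying them are excluded
#' from the model table entirely.
#'
#' @param variants tibble from [read_vcf_snvs()] with `ref`, `alt`, `ac`,
#'   `an`.
#' @return The input with added columns `ancestral`, `derived`,
#'   `substitution` (e.g. `"C>T"`, on the forward strand), and `tie`
#'   (logical). `ancestral`/`derived` are `NA` for ties.
#' @export
polarize_maf <- function(variants) {
  if (any(variants$an == 0L)) abort("polarize_maf: record with AN = 0")
  stopifnot(all(variants$ac >= 0L), all(variants$ac <= variants$an))
  alt_minor <- variants$ac * 2L < variants$an
  tie <- variants$ac * 2L == variants$an
  variants |>
    mutate(
      tie = tie,
      ancestral = dplyr::case_when(tie ~ NA_character_,
                                   alt_minor ~ .data$ref,
                                   TRUE ~ .data$alt),
      derived = dplyr::case_when(tie ~ NA_character_,
                                 alt_minor ~ .data$alt,
                                 TRUE ~ .data$ref),
      substitution = ifelse(tie, NA_character_,
                            paste0(.data$ancestral, ">", .data$derived))
    )
}

#' Assemble the model-ready CpG site table
#'
#' Joins strand-resolved cytosines with pooled methylation and polarized
#' variants into one record per cytosine carrying the methylation level `m`
#' and the binary polymorphism indicator `y`. `y = 1` iff a polarized
#' derived C>T event sits on the focal cytosine: a forward-strand C>T at
#' `cpg_start` for `+` records, a forward-strand G>A at `cpg_start + 1` for
#' `-` records. Other substitutions at the focal position leave `y = 0`
#' (they are not the modelled outcome); set `drop_nonancestral = TRUE` to
#' instead drop cytosines whose MAF-ancestral allele is not the reference
#' cytosine (the ancestral state is then not a CpG). Sites with missing
#' methylation, a missing required context, or an unpolarizable frequency
#' tie at the focal position are dropped, with per-reason counts attached as
#' the `"drop_counts"` attribute.
#'
#' @param cytosines tibble from [find_cpg_sites()].
#' @param methylation pooled methylation tibble from [pool_methylation()].
#'   When it carries a `strand` column the join is strand-resolved (a `-`
#'   cytosine matches `pos = cpg_start + 1`); otherwise the CpG-level value
#'   at `pos = cpg_start` is applied to both strands.
#' @param variants polarized variant tibble from [polarize_maf()]. May be
#'   `NULL`/empty for an all-monomorphic table.
#' @param model_k which context must be valid for a site to be kept: 4, 6,
#'   or both.
#' @param drop_nonancestral drop cytosines whose ancestral allele at the
#'   focal position is the derived (non-C) state. Default `FALSE`.
#' @return A tibble with columns `chrom`, `cpg_start`, `strand`, the context
#'   columns present in `cytosines`, `m`, `y`.
#' @export
assemble_site_table <- function(cytosines, methylation, variants = NULL,
                                model_k = 4L, drop_nonancestral = FALSE) {
  model_k <- as.integer(model_k)
  ctx_cols <- paste0("context", model_k)
  missing_ctx_cols <- setdiff(ctx_cols, names(cytosines))
  if (length(missing_ctx_cols) > 0L) {
    abort(sprintf("assemble_site_table: cytosines lack column(s) %s",
                  paste(missing_ctx_cols, collapse = ", ")))
  }

  n_in <- nrow(cytosines)
  tab <- cytosines

  # methylation join: strand-resolved when the table carries strand
  if ("strand" %in% names(methylation)) {
    tab <- tab |>
      mutate(.mpos = ifelse(.data$strand == "+", .data$cpg_start, .data$cpg_start + 1L)) |>
      left_join(select(methylation, "chrom", "pos", "strand", "m"),
                by = c(chrom = "chrom", .mpos = "pos", strand = "strand")) |>
      select(-".mpos")
  } else {
    tab <- left_join(tab, select(methylation, "chrom", "pos", "m"),
                     by = c(chrom = "chrom", cpg_start = "pos"))
  }

  # focal-position variant join (forward-strand coordinates)
  if (is.null(variants) || nrow(variants) == 0L) {
    variants <- tibble(chrom = character(), pos = integer(), ref = character(),
                       ancestral = character(), derived = character(),
                       tie = logical())
  }
  focal <- tab |>
    mutate(.vpos = ifelse(.data$strand == "+", .data$cpg_start, .data$cpg_start + 1L)) |>
    left_join(
      variants |>
        select("chrom", "pos", "ref", "ancestral", "derived", "tie") |>
        rename(.vref = "ref", .vanc = "ancestral", .vder = "derived", .vtie = "tie"),
      by = c(chrom = "chrom", .vpos = "pos")
    )

  # the modelled outcome: a derived C>T on the focal cytosine's strand,
  # i.e. forward C>T at the C or forward G>A at the G
  focal <- focal |>
    mutate(
      y = as.integer(
        !is.na(.data$.vder) &
          ((.data$strand == "+" & .data$.vanc == "C" & .data$.vder == "T") |
           (.data$strand == "-" & .data$.vanc == "G" & .data$.vder == "A"))
      ),
      .tie_here = !is.na(.data$.vtie) & .data$.vtie,
      .nonanc = !is.na(.data$.vanc) &
        ((.data$strand == "+" & .data$.vanc != "C") |
         (.data$strand == "-" & .data$.vanc != "G"))
    )

  # unmatched variants (positions never extracted as CpG cytosines) -> warning
  focal_pos <- unique(paste(focal$chrom,
                            ifelse(focal$strand == "+", focal$cpg_start,
                                   focal$cpg_start + 1L)))
  n_orphan <- sum(!paste(variants$chrom, variants$pos) %in% focal_pos)
  if (n_orphan > 0L) {
    warn(sprintf("%d variant record(s) fall outside extracted CpG cytosines; ignored",
                 n_orphan))
  }

  drop_missing_m <- sum(is.na(focal$m))
  ctx_ok <- rowSums(is.na(focal[, ctx_cols, drop = FALSE])) == 0L
  drop_missing_ctx <- sum(!ctx_ok & !is.na(focal$m))
  keep <- !is.na(focal$m) & ctx_ok & !focal$.tie_here
  drop_tie <- sum(!is.na(focal$m) & ctx_ok & focal$.tie_here)
  drop_nonanc <- 0L
  if (drop_nonancestral) {
    drop_nonanc <- sum(keep & focal$.nonanc)
    keep <- keep & !focal$.nonanc
  }

  out <- focal[keep, c("chrom", "cpg_start", "strand", ctx_cols,
                       setdiff(names(cytosines),
                               c("chrom", "cpg_start", "strand", ctx_cols)),
                       "m", "y")]
  attr(out, "drop_counts") <- c(
    input = n_in,
    kept = nrow(out),
    missing_m = drop_missing_m,
    missing_context = drop_missing_ctx,
    unpolarizable_tie = drop_tie,
    nonancestral = drop_nonanc,
    orphan_variants = n_orphan
  )
  out
}

#' Exclude sites by position list or region set
#'
#' Generic site-exclusion mechanism (e.g. removing every CpG with a non-zero
#' hydroxymethylation signal before refitting).
#'
#' @param sites a site table.
#' @param exclude either a tibble with `chrom`, `cpg_start` keys or a region
#'   tibble with `chrom`, `start`, `end`.
#' @return The filtered site table; the number of removed rows is attached
#'   as attribute `"n_excluded"`.
#' @export
exclude_sites <- function(sites, exclude) {
  if (nrow(exclude) == 0L) {
    out <- sites
    attr(out, "n_excluded") <- 0L
    return(out)
  }
  if (all(c("start", "end") %in% names(exclude))) {
    hit <- in_regions(exclude, sites$chrom, sites$cpg_start)
  } else {
    stopifnot(all(c("chrom", "cpg_start") %in% names(exclude)))
    hit <- paste(sites$chrom, sites$cpg_start) %in%
      paste(exclude$chrom, exclude$cpg_start)
  }
  out <- sites[!hit, , drop = FALSE]
  attr(out, "n_excluded") <- sum(hit)
  out
}
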