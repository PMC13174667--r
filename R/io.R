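#' Read a genome FASTA
#'
#' Reads a (possibly multi-record) FASTA file preserving base case exactly:
#' hard-masked bases are `N`, and lowercase soft-masked bases are treated as
#' masked everywhere downstream, so only uppercase `A`/`C`/`G`/`T` enter the
#' analysis.
#'
#' @param path path to a FASTA file.
#' @return A tibble with columns `chrom` (record name) and `seq` (bases,
#'   verbatim).
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  if (file.size(path) == 0L) {
    return(tibble(chrom = character(), seq = character()))
  }
  recs <- tryCatch(
    seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE, seqonly = FALSE),
    error = function(e) abort(sprintf("Malformed FASTA %s: %s", path, conditionMessage(e)))
  )
  seqs <- vapply(recs, function(r) as.character(r)[1], character(1))
  if (any(!nzchar(seqs))) {
    abort(sprintf("Malformed FASTA %s: empty sequence for record '%s'",
                  path, names(seqs)[!nzchar(seqs)][1]))
  }
  tibble(chrom = names(seqs), seq = unname(seqs))
}

#' Write a genome tibble as FASTA
#'
#' @param genome tibble with columns `chrom` and `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  seqinr::write.fasta(
    sequences = as.list(genome$seq),
    names = genome$chrom,
    file.out = path,
    as.string = TRUE,
    nbchar = 80
  )
  invisible(path)
}

#' Read a BED file as a region set
#'
#' BED is 0-based half-open; intervals are normalized (sorted, merged) on
#' read. Columns beyond the first three are ignored.
#'
#' @param path path to a BED3+ file.
#' @return A normalized region tibble.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("BED file not found: %s", path))
  raw <- readr::read_tsv(
    path,
    col_names = FALSE,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#",
    progress = FALSE
  )
  if (nrow(raw) == 0L) return(region_set())
  if (ncol(raw) < 3L) abort(sprintf("BED file %s has fewer than 3 columns", path))
  start <- suppressWarnings(as.integer(raw[[2]]))
  end <- suppressWarnings(as.integer(raw[[3]]))
  if (anyNA(start) || anyNA(end)) {
    bad <- which(is.na(start) | is.na(end))[1]
    abort(sprintf("BED file %s: non-numeric coordinates at line %d", path, bad))
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1]
    abort(sprintf("BED file %s: start >= end at line %d", path, bad))
  }
  region_set(raw[[1]], start, end)
}

#' Write a region set as BED3
#'
#' @param regions a region tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(
    normalize_regions(regions),
    path,
    col_names = FALSE,
    progress = FALSE
  )
  invisible(path)
}

#' Read biallelic SNVs from a VCF
#'
#' Parses a VCF (plain or bgzipped), retains single-nucleotide records, and
#' applies the singleton policy. Allele counts come from the INFO `AC`/`AN`
#' fields when present, otherwise they are derived from sample genotypes. A
#' singleton is a record whose minor allele count equals 1 (covering both
#' `AC = 1` and `AC = AN - 1`).
#'
#' @param path path to a VCF file.
#' @param require_biallelic drop records with more than one ALT allele
#'   (default `TRUE`).
#' @param mappability optional region tibble of uniquely mappable positions,
#'   used by the `"drop_unless_in_regionset"` singleton policy (the human
#'   single-read mappability filter).
#' @param singleton_policy one of `"keep"`, `"drop"`,
#'   `"drop_unless_in_regionset"`.
#' @return A tibble with columns `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `ac`, `an`.
#' @export
read_vcf_snvs <- function(path,
                          require_biallelic = TRUE,
                          mappability = NULL,
                          singleton_policy = c("keep", "drop", "drop_unless_in_regionset")) {
  singleton_policy <- match.arg(singleton_policy)
  if (!file.exists(path)) abort(sprintf("VCF file not found: %s", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alt = character(), ac = integer(), an = integer()))
  }

  multi <- grepl(",", fix$ALT, fixed = TRUE)
  ac <- suppressWarnings(as.integer(vcfR::extract.info(v, "AC")))
  an <- suppressWarnings(as.integer(vcfR::extract.info(v, "AN")))
  # multiallelic AC is comma-separated and only matters when such records are
  # retained; AC/AN must resolve for every record that survives filtering
  keep <- (!require_biallelic | !multi) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  need <- keep & (is.na(ac) | is.na(an))
  if (any(need)) {
    gt_counts <- ac_an_from_gt(v)
    if (is.null(gt_counts)) {
      abort(sprintf("VCF %s: records lack INFO AC/AN and no genotypes to derive them", path))
    }
    ac[need] <- gt_counts$ac[need]
    an[need] <- gt_counts$an[need]
    if (anyNA(ac[keep]) || anyNA(an[keep])) {
      abort(sprintf("VCF %s: could not determine AC/AN for all records", path))
    }
  }

  out <- tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS) - 1L, # internal 0-based
    ref = fix$REF,
    alt = fix$ALT,
    ac = ac,
    an = an
  )[keep, , drop = FALSE]

  is_singleton <- pmin(out$ac, out$an - out$ac) == 1L
  if (singleton_policy == "drop") {
    out <- out[!is_singleton, , drop = FALSE]
  } else if (singleton_policy == "drop_unless_in_regionset") {
    if (is.null(mappability)) {
      abort("singleton_policy 'drop_unless_in_regionset' requires a mappability region set")
    }
    ok <- !is_singleton | in_regions(mappability, out$chrom, out$pos)
    out <- out[ok, , drop = FALSE]
  }
  arrange(out, .data$chrom, .data$pos)
}

# AC/AN from GT fields; returns NULL when the VCF carries no genotypes.
ac_an_from_gt <- function(v) {
  if (is.null(v@gt) || nrow(v@gt) == 0L || ncol(v@gt) < 2L) return(NULL)
  gt <- vcfR::extract.gt(v, element = "GT")
  alleles <- apply(gt, 1, function(row) {
    toks <- unlist(strsplit(row[!is.na(row)], "[/|]"))
    toks <- toks[toks != "."]
    c(ac = sum(toks != "0"), an = length(toks))
  })
  list(ac = as.integer(alleles["ac", ]), an = as.integer(alleles["an", ]))
}

#' Read a per-CpG methylation table
#'
#' Expects a TSV with columns `chrom`, `pos` (0-based cytosine position),
#' `strand`, `meth_reads`, `total_reads`, `sample` — one row per cytosine per
#' bisulfite-sequenced sample.
#'
#' @param path path to the TSV.
#' @return A tibble with those columns, types enforced.
#' @export
read_methylation_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("Methylation table not found: %s", path))
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      strand = readr::col_character(),
      meth_reads = readr::col_integer(),
      total_reads = readr::col_integer(),
      sample = readr::col_character()
    ),
    progress = FALSE
  )
  if (any(tab$meth_reads > tab$total_reads)) {
    abort(sprintf("Methylation table %s: meth_reads exceeds total_reads", path))
  }
  tab
}

#' Write a site table (or any tibble) as TSV with header
#'
#' Missing contexts are serialized as `.` to match the site-table dialect.
#'
#' @param x a tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_tsv <- function(x, path) {
  readr::write_tsv(x, path, na = ".", progress = FALSE)
  invisible(path)
}

#' Read a site table written by [write_site_tsv()]
#'
#' @param path path to the TSV.
#' @return A tibble; `.` fields become `NA`.
#' @export
read_site_tsv <- function(path) {
  readr::read_tsv(path, na = ".", show_col_types = FALSE, progress = FALSE)
}
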