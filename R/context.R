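#' Reverse complement of a context string
#'
#' Plain Watson–Crick reverse complement over `{A, C, G, T}`. Vectorized.
#'
#' @param s character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ACGC") # "GCGT"
#' @export
reverse_complement <- function(s) {
  if (length(s) == 0L) return(character())
  if (any(grepl("[^ACGT]", s))) {
    abort("reverse_complement: input contains characters outside {A, C, G, T}")
  }
  comp <- chartr("ACGT", "TGCA", s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""),
         character(1))
}

#' Enumerate all k-mer contexts with a central CpG
#'
#' A context of width `k` is the k-mer centred on the CpG dinucleotide, read
#' on the focal cytosine's strand: `k = 4` carries one flanking base on each
#' side, `k = 6` two. Positions `k/2` and `k/2 + 1` are always `CG`, so there
#' are `4^(k-2)` contexts.
#'
#' @param k context width, 4 or 6.
#' @return Character vector of contexts in lexicographic order.
#' @examples
#' enumerate_contexts(4) # 16 contexts ACGA ... TCGT
#' @export
enumerate_contexts <- function(k) {
  if (!k %in% c(4L, 6L)) abort("enumerate_contexts: k must be 4 or 6")
  bases <- c("A", "C", "G", "T")
  n_flank <- (k - 2L) %/% 2L
  flanks <- do.call(expand.grid, rep(list(bases), 2L * n_flank))
  # expand.grid varies the first factor fastest; reorder for lexicographic k-mers
  up <- do.call(paste0, rev(flanks[seq_len(n_flank)]))
  down <- do.call(paste0, rev(flanks[n_flank + seq_len(n_flank)]))
  sort(paste0(up, "CG", down))
}

#' Pair contexts with their reverse complements
#'
#' Within one CpG dinucleotide the two strand-resolved cytosines see
#' reverse-complement contexts, so pairing each context with its reverse
#' complement identifies the two adjacent C:G base pairs of the same CpG.
#' Palindromic contexts (equal to their own reverse complement) are returned
#' separately.
#'
#' @param contexts character vector of contexts, typically from
#'   [enumerate_contexts()].
#' @return A list with `pairs` (tibble with columns `a`, `b`, where
#'   `a < b` lexicographically and `b = reverse_complement(a)`) and
#'   `palindromes` (character vector).
#' @examples
#' pair_reverse_complements(enumerate_contexts(4))
#' @export
pair_reverse_complements <- function(contexts) {
  rc <- reverse_complement(contexts)
  is_pal <- contexts == rc
  first <- !is_pal & contexts < rc
  list(
    pairs = tibble(a = contexts[first], b = rc[first]),
    palindromes = sort(contexts[is_pal])
  )
}

# Extract the window [start, start + width) from a sequence string; returns NA
# unless the window is fully in bounds and all-uppercase ACGT.
context_window <- function(seq_str, start0, width) {
  n <- nchar(seq_str)
  ok <- start0 >= 0L & (start0 + width) <= n
  out <- rep(NA_character_, length(start0))
  if (any(ok)) {
    w <- substring(seq_str, start0[ok] + 1L, start0[ok] + width)
    w[grepl("[^ACGT]", w)] <- NA_character_
    out[ok] <- w
  }
  out
}

#' Locate CpG sites and their k-mer contexts
#'
#' Scans each genome sequence for occurrences of uppercase `CG` whose two
#' bases both fall inside `included`, and emits two strand-resolved cytosine
#' records per dinucleotide: the forward-strand C (`strand = "+"`) and the
#' cytosine paired with the forward G (`strand = "-"`). Both records are
#' positioned by `cpg_start`, the 0-based position of the forward-strand C,
#' so the two cytosines of one CpG stay joinable. The minus-strand context is
#' the reverse complement of the plus-strand context over the same window.
#' Context windows that leave the sequence or touch a masked base (N or
#' lowercase) are reported as `NA` and excluded by downstream model builders.
#'
#' @param genome genome tibble from [read_genome_fasta()].
#' @param included optional region tibble restricting the scan; default is
#'   the whole genome.
#' @param k context widths to attach, subset of `c(4, 6)`.
#' @return A tibble with columns `chrom`, `cpg_start`, `strand`, and
#'   `context4`/`context6` as requested.
#' @examples
#' g <- tibble::tibble(chrom = "chr1", seq = "TACGCA")
#' find_cpg_sites(g, k = 4)
#' @export
find_cpg_sites <- function(genome, included = NULL, k = c(4L, 6L)) {
  k <- as.integer(k)
  if (!all(k %in% c(4L, 6L))) abort("find_cpg_sites: k must be a subset of c(4, 6)")
  if (is.null(included)) included <- genome_regions(genome)

  per_chrom <- purrr::map(seq_len(nrow(genome)), function(i) {
    chrom <- genome$chrom[i]
    s <- genome$seq[i]
    hits <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) return(NULL)
    cpg_start <- as.integer(hits) - 1L # 0-based position of the C
    keep <- in_regions(included, rep(chrom, length(cpg_start)), cpg_start) &
      in_regions(included, rep(chrom, length(cpg_start)), cpg_start + 1L)
    cpg_start <- cpg_start[keep]
    if (length(cpg_start) == 0L) return(NULL)

    fwd <- tibble(chrom = chrom, cpg_start = cpg_start, strand = "+")
    rev <- tibble(chrom = chrom, cpg_start = cpg_start, strand = "-")
    for (kk in sort(k)) {
      n_flank <- (kk - 2L) %/% 2L
      ctx_plus <- context_window(s, cpg_start - n_flank, kk)
      ctx_minus <- ctx_plus
      nn <- !is.na(ctx_plus)
      ctx_minus[nn] <- reverse_complement(ctx_plus[nn])
      col <- paste0("context", kk)
      fwd[[col]] <- ctx_plus
      rev[[col]] <- ctx_minus
    }
    bind_rows(fwd, rev)
  })

  out <- bind_rows(per_chrom)
  if (nrow(out) == 0L) {
    out <- tibble(chrom = character(), cpg_start = integer(), strand = character())
    for (kk in sort(k)) out[[paste0("context", kk)]] <- character()
    return(out)
  }
  arrange(out, .data$chrom, .data$cpg_start, .data$strand)
}
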