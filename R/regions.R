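#' Region sets
#'
#' A region set is a tibble with columns `chrom`, `start`, `end` holding
#' 0-based half-open intervals, kept sorted and non-overlapping
#' ("normalized"). All interval arithmetic in the package runs on this
#' representation; coordinates are converted once at the file boundary
#' (VCF is 1-based on disk, BED is native 0-based half-open).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @return A normalized region tibble.
#' @examples
#' region_set("chr1", c(0L, 5L), c(10L, 15L))
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  normalize_regions(tibble(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end)
  ))
}

as_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    # IRanges are 1-based closed; half-open [start, end) maps to start+1 .. end
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

granges_to_regions <- function(gr) {
  if (length(gr) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  ) |>
    arrange(.data$chrom, .data$start)
}

#' Normalize a region tibble
#'
#' Sorts intervals and merges overlapping or bookended intervals per
#' chromosome so that membership queries and set arithmetic are well defined.
#'
#' @param regions a tibble with columns `chrom`, `start`, `end`.
#' @return A normalized region tibble.
#' @export
normalize_regions <- function(regions) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (nrow(regions) == 0L) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  if (any(regions$start >= regions$end)) {
    bad <- which(regions$start >= regions$end)[1]
    abort(sprintf(
      "Invalid interval at row %d: start (%d) must be < end (%d)",
      bad, regions$start[bad], regions$end[bad]
    ))
  }
  granges_to_regions(GenomicRanges::reduce(as_granges(regions)))
}

#' Subtract one region set from another
#'
#' Returns the positions present in `universe` but not in `excluded` — the
#' operation used to remove genic and conserved regions from the analyzable
#' genome.
#'
#' @param universe,excluded normalized region tibbles.
#' @return A normalized region tibble.
#' @examples
#' subtract_regions(region_set("chr1", 0, 100), region_set("chr1", 40, 60))
#' @export
subtract_regions <- function(universe, excluded) {
  if (nrow(excluded) == 0L) {
    return(normalize_regions(universe))
  }
  granges_to_regions(GenomicRanges::setdiff(
    as_granges(normalize_regions(universe)),
    as_granges(normalize_regions(excluded))
  ))
}

#' Intersect two region sets
#'
#' Positions present in both inputs, e.g. restricting the hard-masked genome
#' to the portion covered by an ancestral-genome reconstruction.
#'
#' @param a,b region tibbles.
#' @return A normalized region tibble.
#' @export
intersect_regions <- function(a, b) {
  granges_to_regions(GenomicRanges::intersect(
    as_granges(normalize_regions(a)),
    as_granges(normalize_regions(b))
  ))
}

#' Total number of bases covered by a region set
#'
#' @param regions a region tibble.
#' @return Integer total width.
#' @export
region_width <- function(regions) {
  if (nrow(regions) == 0L) return(0L)
  regions <- normalize_regions(regions)
  sum(regions$end - regions$start)
}

#' Test positions for membership in a region set
#'
#' @param regions a normalized region tibble.
#' @param chrom chromosome of each query position.
#' @param pos 0-based position of each query.
#' @return Logical vector, `TRUE` where the position is covered.
#' @export
in_regions <- function(regions, chrom, pos) {
  if (nrow(regions) == 0L) return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  IRanges::overlapsAny(q, as_granges(regions))
}

#' Region set covering whole sequences
#'
#' Convenience constructor: one interval per genome sequence spanning its
#' full length.
#'
#' @param genome a genome tibble from [read_genome_fasta()].
#' @return A normalized region tibble.
#' @export
genome_regions <- function(genome) {
  region_set(genome$chrom, 0L, nchar(genome$seq))
}
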