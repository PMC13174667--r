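# Shared fixture builders; everything is generated in code at test time.

# Small simulated site table, cached per (k, n, seed) within one test run.
local({
  cache <- new.env(parent = emptyenv())
  sim_sites <<- function(k = 4L, n = 2000L, seed = 101L, ...) {
    key <- paste(k, n, seed, ...)
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_site_table(
        synthetic_truth(k = k, n_per_context = n, seed = seed, ...)
      )
    }
    cache[[key]]
  }
})

# A tiny genome whose CpGs are easy to enumerate by hand.
toy_genome <- function() {
  tibble::tibble(
    chrom = c("chr1", "chr2"),
    seq = c("TACGCA", "NNCGNN")
  )
}

# Brute-force per-base membership mask over a chromosome of given length.
region_mask <- function(regions, chrom, len) {
  mask <- rep(FALSE, len)
  rr <- regions[regions$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(rr))) {
    lo <- rr$start[i] + 1L
    hi <- rr$end[i]
    if (hi >= lo) mask[lo:hi] <- TRUE
  }
  mask
}

# Random region set on a toy chromosome (0-based half-open).
random_regions <- function(chrom = "chr1", len = 1000L, n = 8L) {
  start <- sample.int(len - 2L, n, replace = TRUE) - 1L
  width <- sample.int(80L, n, replace = TRUE)
  region_set(rep(chrom, n), start, pmin(start + width, len))
}

# stats::glm with the same custom link: the independent reference route.
glm_reference_fit <- function(data, formula, start) {
  link <- structure(
    list(
      linkfun = function(mu) log1p(-mu),
      linkinv = function(eta) -expm1(pmin(eta, -1e-12)),
      mu.eta = function(eta) -exp(pmin(eta, -1e-12)),
      valideta = function(eta) all(eta < 0),
      name = "log1m"
    ),
    class = "link-glm"
  )
  stats::glm(formula, data = data, family = binomial(link = link), start = start,
             control = stats::glm.control(epsilon = 1e-12, maxit = 200))
}
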