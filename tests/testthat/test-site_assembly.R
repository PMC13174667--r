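test_that("methylation pooling sums counts across samples with a coverage floor", {
  obs <- tibble::tibble(
    chrom = "chr1", pos = 2L, strand = "+",
    meth_reads = c(5L, 15L), total_reads = c(10L, 20L),
    sample = c("s1", "s2")
  )
  expect_equal(pool_methylation(obs)$m, 20 / 30)

  single <- tibble::tibble(chrom = "chr1", pos = 0L, strand = "+",
                           meth_reads = 0L, total_reads = 12L, sample = "s1")
  expect_equal(pool_methylation(single)$m, 0)

  low <- tibble::tibble(chrom = "chr1", pos = 1L, strand = "+",
                        meth_reads = c(3L, 0L), total_reads = c(4L, 1L),
                        sample = c("s1", "s2"))
  expect_true(is.na(pool_methylation(low, min_coverage = 10L)$m))
  expect_equal(pool_methylation(low, min_coverage = 5L)$m, 3 / 5)
})

test_that("MAF polarization sets major allele ancestral and flags exact ties", {
  v <- tibble::tibble(
    chrom = "chr1", pos = c(10L, 20L, 30L),
    ref = c("C", "C", "A"), alt = c("T", "T", "G"),
    ac = c(10L, 1990L, 1000L), an = 2000L
  )
  p <- polarize_maf(v)
  expect_equal(p$ancestral, c("C", "T", NA))
  expect_equal(p$derived, c("T", "C", NA))
  expect_equal(p$substitution, c("C>T", "T>C", NA))
  expect_equal(p$tie, c(FALSE, FALSE, TRUE))
  expect_error(polarize_maf(dplyr::mutate(v, an = 0L)), "AN = 0")
})

test_that("polarization truth table: only derived-T events count as C>T", {
  # brute force over all (ref, alt, minor-side) combinations at a C position
  combos <- expand.grid(ref = c("C", "A"), alt = c("T", "G"),
                        alt_minor = c(TRUE, FALSE), stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  for (i in seq_len(nrow(combos))) {
    cc <- combos[i, ]
    v <- tibble::tibble(chrom = "c", pos = 0L, ref = cc$ref, alt = cc$alt,
                        ac = if (cc$alt_minor) 10L else 1990L, an = 2000L)
    p <- polarize_maf(v)
    manual_is_ct <- (if (cc$alt_minor) cc$ref else cc$alt) == "C" &&
      (if (cc$alt_minor) cc$alt else cc$ref) == "T"
    expect_equal(identical(p$substitution, "C>T"), manual_is_ct)
  }
})

toy_assembly_inputs <- function() {
  genome <- tibble::tibble(chrom = "chr1", seq = "TACGCA")
  cyt <- find_cpg_sites(genome, k = 4)
  meth <- tibble::tibble(chrom = "chr1", pos = 2L, meth_reads = 8L,
                         total_reads = 10L, m = 0.8)
  list(genome = genome, cyt = cyt, meth = meth)
}

test_that("site assembly hand trace: C>T marks the + strand, G>A the - strand", {
  fx <- toy_assembly_inputs()
  v_ct <- polarize_maf(tibble::tibble(chrom = "chr1", pos = 2L, ref = "C",
                                      alt = "T", ac = 10L, an = 100L))
  tab <- assemble_site_table(fx$cyt, fx$meth, v_ct)
  expect_equal(nrow(tab), 2L)
  plus <- tab[tab$strand == "+", ]
  minus <- tab[tab$strand == "-", ]
  expect_equal(plus$context4, "ACGC")
  expect_equal(plus$m, 0.8)
  expect_equal(plus$y, 1L)
  expect_equal(minus$context4, "GCGT")
  expect_equal(minus$y, 0L)

  # forward G>A at the G position flips the minus record instead
  v_ga <- polarize_maf(tibble::tibble(chrom = "chr1", pos = 3L, ref = "G",
                                      alt = "A", ac = 10L, an = 100L))
  tab2 <- assemble_site_table(fx$cyt, fx$meth, v_ga)
  expect_equal(tab2$y[tab2$strand == "-"], 1L)
  expect_equal(tab2$y[tab2$strand == "+"], 0L)

  # no variants: all y = 0, size = number of valid cytosines
  tab0 <- assemble_site_table(fx$cyt, fx$meth, NULL)
  expect_equal(tab0$y, c(0L, 0L))
})

test_that("non-C>T substitutions leave y = 0; drop_nonancestral removes derived-C sites", {
  fx <- toy_assembly_inputs()
  # C>A at the focal C: not the modelled outcome
  v_ca <- polarize_maf(tibble::tibble(chrom = "chr1", pos = 2L, ref = "C",
                                      alt = "A", ac = 10L, an = 100L))
  tab <- assemble_site_table(fx$cyt, fx$meth, v_ca)
  expect_equal(tab$y, c(0L, 0L))

  # high-frequency alt: ancestral is T, the ancestral state is not a CpG
  v_hf <- polarize_maf(tibble::tibble(chrom = "chr1", pos = 2L, ref = "C",
                                      alt = "T", ac = 1990L, an = 2000L))
  kept <- assemble_site_table(fx$cyt, fx$meth, v_hf)
  expect_equal(kept$y[kept$strand == "+"], 0L)
  dropped <- assemble_site_table(fx$cyt, fx$meth, v_hf, drop_nonancestral = TRUE)
  expect_false("+" %in% dropped$strand)
  expect_true("-" %in% dropped$strand)

  # exact tie: the affected strand record is excluded entirely
  v_tie <- polarize_maf(tibble::tibble(chrom = "chr1", pos = 2L, ref = "C",
                                       alt = "T", ac = 1000L, an = 2000L))
  tab_tie <- assemble_site_table(fx$cyt, fx$meth, v_tie)
  expect_false("+" %in% tab_tie$strand)
  expect_equal(attr(tab_tie, "drop_counts")[["unpolarizable_tie"]], 1L)
})

test_that("assembly join totals conserve across drop reasons", {
  set.seed(21)
  chars <- sample(c("A", "C", "G", "T", "N"), 3000L, replace = TRUE,
                  prob = c(0.27, 0.24, 0.24, 0.2, 0.05))
  genome <- tibble::tibble(chrom = "g", seq = paste(chars, collapse = ""))
  cyt <- find_cpg_sites(genome, k = 4)
  plus <- cyt[cyt$strand == "+", ]
  # methylation for ~80% of CpGs
  meth_idx <- sample(nrow(plus), round(0.8 * nrow(plus)))
  meth <- tibble::tibble(chrom = "g", pos = plus$cpg_start[meth_idx],
                         m = runif(length(meth_idx)))
  # a few variants, one of them a tie
  vpos <- sample(plus$cpg_start, 6L)
  v <- polarize_maf(tibble::tibble(
    chrom = "g", pos = vpos, ref = "C", alt = "T",
    ac = c(5L, 10L, 50L, 100L, 500L, 1000L), an = 2000L
  ))
  tab <- assemble_site_table(cyt, meth, v)
  dc <- attr(tab, "drop_counts")
  expect_equal(dc[["input"]],
               dc[["kept"]] + dc[["missing_m"]] + dc[["missing_context"]] +
                 dc[["unpolarizable_tie"]])
  # every y=1 record is backed by exactly one retained C>T variant
  hit <- tab[tab$y == 1L, ]
  expect_true(all(hit$strand == "+"))
  expect_true(all(hit$cpg_start %in% vpos))
  # dropping the variants flips all y to 0
  tab0 <- assemble_site_table(cyt, meth, NULL)
  expect_equal(sum(tab0$y), 0L)
})

test_that("strand flip symmetry: rc genome with swapped alleles gives same records", {
  set.seed(31)
  chars <- sample(c("A", "C", "G", "T"), 400L, replace = TRUE)
  fwd <- paste(chars, collapse = "")
  rev <- reverse_complement(fwd)
  L <- nchar(fwd)

  cyt_f <- find_cpg_sites(tibble::tibble(chrom = "x", seq = fwd), k = 4)
  cyt_r <- find_cpg_sites(tibble::tibble(chrom = "x", seq = rev), k = 4)

  meth_f <- dplyr::transmute(dplyr::distinct(cyt_f, chrom, cpg_start),
                             chrom, pos = cpg_start, m = 0.5)
  meth_r <- dplyr::transmute(dplyr::distinct(cyt_r, chrom, cpg_start),
                             chrom, pos = cpg_start, m = 0.5)

  # one C>T variant on the forward genome at the first CpG C
  p0 <- sort(unique(cyt_f$cpg_start))[1]
  v_f <- polarize_maf(tibble::tibble(chrom = "x", pos = p0, ref = "C", alt = "T",
                                     ac = 10L, an = 2000L))
  # same biological event on the rc genome: G>A at the mirrored position
  v_r <- polarize_maf(tibble::tibble(chrom = "x", pos = L - 1L - p0, ref = "G",
                                     alt = "A", ac = 10L, an = 2000L))
  tab_f <- assemble_site_table(cyt_f, meth_f, v_f)
  tab_r <- assemble_site_table(cyt_r, meth_r, v_r)
  key <- function(t) sort(paste(t$context4, t$m, t$y))
  expect_equal(key(tab_f), key(tab_r))
})

test_that("site exclusion by key and by region removes exactly the matches", {
  sites <- sim_sites(n = 50L, seed = 55L)
  expect_equal(exclude_sites(sites, tibble::tibble(chrom = character(),
                                                   cpg_start = integer())),
               sites, ignore_attr = TRUE)
  all_keys <- dplyr::distinct(sites, chrom, cpg_start)
  expect_equal(nrow(exclude_sites(sites, all_keys)), 0L)
  some <- all_keys[seq(1, nrow(all_keys), by = 3), ]
  out <- exclude_sites(sites, some)
  expect_equal(nrow(sites), nrow(out) + attr(out, "n_excluded"))
  # region-based exclusion agrees with brute-force membership
  reg <- region_set("sim", 100L, 5000L)
  out2 <- exclude_sites(sites, reg)
  manual <- sites$cpg_start >= 100L & sites$cpg_start < 5000L
  expect_equal(attr(out2, "n_excluded"), sum(manual))
})
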