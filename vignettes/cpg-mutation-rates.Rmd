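---
title: "Estimating context-dependent CpG mutation rates from polymorphism data"
author: "cpgrates authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating context-dependent CpG mutation rates from polymorphism data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgrates)
library(dplyr)
```

## The problem

CpG dinucleotides are the most mutable sites in vertebrate genomes: the
5-methylcytosine (5mC) carried by most germline CpGs deaminates to thymine,
and unrepaired T:G mismatches fix as C>T mutations. Mutability also varies
with the bases flanking the CpG, and only part of that variation tracks the
context-specific methylation level. `cpgrates` estimates, from population
polymorphism data, the mutation rate of *unmethylated* and *methylated*
CpGs separately within each k-mer sequence context, so that the baseline
mutability of a context and the mutagenic effect of methylation in that
context can be disentangled.

Two observations shape the model:

1. **Each CpG contains two cytosines**, one per strand. Every CG occurrence
   yields two strand-resolved records, each annotated with the k-mer context
   read on its own strand (the two contexts are reverse complements).
   Comparing a context with its reverse complement therefore compares the
   two adjacent C:G base pairs of the same dinucleotide — the within-CpG
   mutational asymmetry analysis.
2. **Polymorphism probability saturates.** In large cohorts, hypermutable
   sites are hit repeatedly, so the probability that a site is polymorphic
   grows sub-linearly in its mutation rate. With a constant total coalescent
   tree length \(T\) across sites, a site with per-generation rate \(\mu\) is
   polymorphic with probability
   \[ p = 1 - e^{-\mu T}. \]
   Presence/absence of polymorphism identifies the *sample-scaled* rate
   \(\mu T\), not \(\mu\) itself; all estimates are reported on the
   \(\mu T\) scale.

## The model

For cytosine \(i\) with methylation level \(m_i \in [0,1]\) in context
\(c\), the scaled rate is linear in methylation,
\[ \mu_i T = (\alpha_c + \beta_c m_i) T, \]
and the polymorphism indicator is Bernoulli with
\(p_i = 1 - e^{-\mu_i T}\). This is a binomial GLM with the non-standard
link
\[ \eta = \log(1 - p), \qquad
   \text{link}^{-1}(\eta) = 1 - e^{\eta}, \qquad
   \frac{dp}{d\eta} = -e^{\eta}, \]
under which \(\eta_i = -\mu_i T\): linear-predictor contrasts *are*
(negated) scaled mutation rates. Context structure enters through the model
registry (`model_spec()`):

| name | linear predictor | coefficients |
|---|---|---|
| `4mer` | `context4 * m` | 32 |
| `up1_down1` | `U1 + D1 + m + U1:m + D1:m` | 14 |
| `6mer` | `context6 * m` | 512 |
| `up21_down12` | `U21 + D12 + m + U21:m + D12:m` | 62 |
| `additive_positions` | `U2 + U1 + D1 + D2 + m + (each):m` | 26 |
| `context_only_4mer` / `context_only_up1_down1` | no methylation terms | 16 / 7 |

`U1`/`D1` are the immediate flanking bases, `U2`/`D2` the next ones out,
`U21`/`D12` the flanking dimers, all read on the focal cytosine's strand.
The fully interacted k-mer models let every context have its own baseline
and methylation slope; the additive models encode the hypothesis that
upstream and downstream sequence act independently on CpG mutability. The
context-only variants serve species with negligible germline methylation.
Factors use treatment coding against the lexicographically first level, so
column identity is reproducible; predictions are invariant to the coding.

## Fitting

`fit_cpg_glm()` maximizes the exact Bernoulli likelihood by Newton scoring:
analytic score, Fisher (expected) information as the step matrix,
step-halving, and convergence when the relative log-likelihood change falls
below `1e-10` (at most 100 iterations). Two numerical properties of this
link shaped the optimizer:

* The valid region \(\eta < 0\) is **open**, and the log-likelihood of a
  monomorphic site is *linear* in \(\eta\) (its maximum sits at the
  boundary \(\eta \to 0\)). Each Newton step is therefore damped so every
  site's predictor stays strictly interior before step-halving begins; this
  keeps gradients and weights finite at every iterate. Probabilities are
  additionally clipped to \([10^{-12}, 1-10^{-12}]\), and a fit whose final
  predictor rests against the boundary is flagged (`boundary = TRUE`)
  rather than silently accepted.
* Because monomorphic sites carry no observed curvature, the **observed**
  information is ill-conditioned away from the optimum; the **expected**
  information, to which all sites contribute, is benign and yields the
  classical IRLS-type iteration. At the optimum the score is zero under
  either matrix, so the MLE is unchanged. The reported covariance is the
  inverse *observed* information at the optimum.

Interval estimates are Wald: \(\mu T\) is linear in the coefficients, so
`predict_scaled_rates()` returns \(\hat\mu T \pm 1.96\,\mathrm{se}\) per
context at methylation state 0 and 1. Extrapolation to other methylation
values is deliberately unsupported. Model comparison uses AIC
(\(2p - 2\ell\)), BIC (\(p\ln n - 2\ell\)) and the proportion of deviance
explained \((D_\text{null}-D_\text{resid})/D_\text{null}\), with the null
model defined as the intercept-only fit under the same link — the standard
reading of "null deviance".

```{r fit-example}
truth <- synthetic_truth(seed = 2, n_per_context = 5000)
sites <- simulate_site_table(truth)
fit <- fit_cpg_glm(sites, "4mer")
glance(fit)
predict_scaled_rates(fit) |> head(4)
```

## From files to the site table

The pipeline half of the package turns standard formats into the model
table. Coordinates are 0-based half-open everywhere internally; VCF
positions are converted on read, BED is native. Only uppercase `A/C/G/T`
is analyzable: `N` (hard mask) and lowercase (soft mask) are treated as
masked, which handles soft-masked inputs conservatively.

* `read_genome_fasta()` / `read_bed()` / `read_vcf_snvs()` /
  `read_methylation_tsv()` read the inputs; `subtract_regions()` and
  `intersect_regions()` compute the analyzable region set (e.g. genome
  minus genic minus conserved, intersected with ancestral coverage).
* `find_cpg_sites()` emits the two strand-resolved records per CG; context
  windows that leave the sequence or touch a masked base yield missing
  contexts (never clipped k-mers) and are dropped at assembly.
* `pool_methylation()` sums methylated/total read counts across samples
  before dividing — pooling damps the bias from C/T polymorphism carriers —
  with a default minimum pooled coverage of 5 reads. The methylation value
  is CpG-level (applied to both strands) by default, matching how sperm
  WGBS tables are usually reported; strand-resolved joining is supported.
* `polarize_maf()` takes the major allele as ancestral. Exact frequency
  ties (`AC = AN/2`) are unpolarizable and the affected cytosine record is
  excluded. A singleton is a record with minor-allele count 1, computed
  before polarization; policies `keep`, `drop`, and
  `drop_unless_in_regionset` (retain singletons only in high-mappability
  regions) are provided.
* `assemble_site_table()` sets `y = 1` exactly when a polarized derived
  C>T event sits on the focal cytosine's strand (forward C>T at the C,
  forward G>A at the G). Other substitutions at the focal position leave
  `y = 0`: the outcome modelled is "presence of a C>T polymorphism", not
  "any variant". Cytosines whose MAF-ancestral allele is the derived non-C
  state are likewise kept with `y = 0` by default — `drop_nonancestral =
  TRUE` removes them instead, since their ancestral state is not a CpG.
  Multiallelic records are excluded on read. Per-reason drop counts are
  attached to the result.

Stages are also exposed as a configurable pipeline
(`pipeline_extract()` … `pipeline_simulate()`, YAML config, JSON
manifests) and a thin command-line wrapper (`exec/cpgrates`).

## The synthetic-data generator

`synthetic_truth()` + `simulate_site_table()` generate site tables from
known parameters: per-context \(\alpha T\) drawn from \([0.01, 0.05]\) and
\(\beta T\) from \([0.2, 0.6]\) unless given, so \(p\) spans roughly
0.01–0.4 — the regime where the exponential saturation correction is
material. Methylation is drawn from a two-mode Beta mixture (weight 0.45 on
`Beta(0.6, 8)`, 0.55 on `Beta(8, 0.6)`), mimicking the strongly bimodal
germline CpG methylation landscape with mass near 0 and 1 and full support
on \([0,1]\). A single integer seed determines the entire table.
`generate_fixture_bundle()` additionally writes a byte-level
FASTA/BED/VCF/methylation bundle whose expected site table is produced by
an independent base-by-base enumeration, so the whole file pipeline can be
checked for exact equality against an oracle that shares no code with it.

What the generator does *not* emulate: linked genealogies (sites are
independent Bernoulli draws; real \(T\) varies along the genome),
allele-frequency information beyond presence/absence, methylation
measurement error, and spatial clustering of CpGs. Passing recovery and
calibration tests therefore demonstrate correctness of the estimator under
its own assumptions, not robustness to genealogical heterogeneity or
methylation noise in real data.

## Verification strategy and problem sizes

The test suite confronts every layer with an independent oracle:

* interval arithmetic and CpG extraction against per-base brute force on
  random sequences;
* the fitter against closed forms (intercept-only MLE
  \(-\log(1-k/n)\); per-context stratified closed forms when
  \(m \in \{0,1\}\)), against a coarse-to-fine dense grid search of the
  likelihood (agreement to \(10^{-4}\) per coefficient), and against
  `stats::glm` equipped with the same custom link;
* CI calibration by parameter recovery: 200 replicates of 16 contexts
  \(\times\) 20,000 sites, requiring 95% CI coverage of the true
  \(\mu T(x)\) within \([93\%, 97\%]\);
* the asymmetry z-test under a strand-symmetric truth (rejection rate at
  \(\alpha = 0.05\) within \([3\%, 7\%]\) over 540 null tests);
* nesting monotonicity of residual deviance along
  `up1_down1` ⊆ `4mer` ⊆ `6mer` and
  `additive_positions` ⊆ `up21_down12` ⊆ `6mer`;
* byte-for-byte equality of the file pipeline with the fixture bundle's
  independently enumerated table.

These sizes (20,000 sites per context for calibration, 100,000 per context
for cross-model concordance, 1,000 per 6-mer context for the nesting
checks) were chosen as the smallest at which the asymptotic approximations
under test are expected to hold cleanly; they keep the full suite to a few
minutes on a single core.

## Design choices on open points

* **Tie polarization**: sites with `AC = AN/2` are excluded entirely
  rather than assigned either state — misclassification risk outweighs the
  negligible count at large `AN`.
* **Overlapping CGs** (`CGCG`) each contribute their own strand pair;
  every CG occurrence is treated independently.
* **Context validity** is required only for the context column the fitted
  model uses — a site with a masked outer base still enters 4-mer models.
* **Asymmetry error propagation** treats the two paired estimates as
  independent (they derive from disjoint site sets; the joint-fit
  cross-covariance is near zero but not exactly zero — a known
  approximation).
* **Wilson intervals** for methylation-bin rates, which behave well at the
  extreme rates of the lowest bins; the family of asymmetry tests is
  reported both raw and Bonferroni-adjusted over pairs × states.
* **Pearson concordance** is computed on point estimates, unweighted, per
  methylation state.

## Known limitations

\(T\) is assumed constant across sites, so between-dataset comparisons of
absolute \(\mu T\) conflate mutation rate with cohort genealogy; rankings
and within-fit contrasts are the robust quantities. Wald intervals on
\(\eta\) undercover slightly when a context×state cell has few polymorphic
sites (the recovery criterion's band \([93\%, 97\%]\) reflects this).
Site-specific genealogies, GC-biased gene conversion corrections beyond
stratified refitting (`stratified_refit()`), and overdispersion are out of
scope.
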