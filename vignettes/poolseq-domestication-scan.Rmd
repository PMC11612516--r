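---
title: "Pool-Seq domestication scans with poolscan: models, thresholds, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pool-Seq domestication scans with poolscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscan)
```

## The problem

Aquaculture species such as European seabass have been domesticated only
recently, so farmed strains differ from natural-origin populations at many
loci of small effect rather than at a few large-effect genes. Pool-Seq —
sequencing pooled DNA from tens of individuals per population — is an
economical way to estimate allele frequencies in many populations at once,
at the price of never observing individual genotypes. `poolscan` implements
a complete analysis for such designs: it turns per-position pooled read
counts from farmed and natural-origin ("wild") pools into biallelic SNP
frequencies, scans every SNP for farmed-vs-wild differentiation with two
complementary statistics, classifies consensus outliers, annotates them to
nearby genes and CpG islands, and asks whether the candidate genes
concentrate inside a functional-interaction network more than random gene
sets of the same size do.

All stages run on synthetic data with known ground truth, so the pipeline's
operating characteristics can be measured rather than assumed.

## Why a minimum depth of 25

A site's read depth limits how many pool members its reads can possibly
represent. Modeling reads as uniform draws with replacement over the `n`
individuals of a pool, the number of distinct individuals hit by `d` reads
is the classical occupancy statistic with expectation
`n (1 - (1 - 1/n)^d)`. For the reference design (pools of 25), one million
resampling events give a mean of about 16 distinct individuals at depth 25,
and the lower bound of the central 95% interval is 13 — at least half the
pool. That is the justification for the default `min_depth = 25` filter:

```{r depth}
representation_summary(n_pool = 25, depth = 25, n_reps = 1e5, seed = 1)
```

Two readings of "lower 95% confidence limit" are possible (a central
2.5% quantile or a one-sided 5% quantile); both are implemented
(`interval = "central"` is the default) and both give 13 for this design.
We resample individuals, not haplotypes: "13 of 25 samples represented"
only parses at the individual level. Unequal DNA contributions per
individual are not modeled.

## From counts to SNPs

Counts arrive as per-position, per-base read counts per
population-replicate track (`read_pool_counts()`,
`read_bam_readcount()`). Technical replicates are merged by base-wise
summation; the depth filter then requires the merged depth to reach
`min_depth` in *every* population, because the downstream between-group
tests need every pool typed. Alleles with frequency strictly below 1% —
computed from counts summed across all populations — are discarded as
likely sequencing error, and a site is emitted only when exactly two
alleles remain. A per-population variant of the MAF screen
(`maf_scope = "per_population"`, retaining alleles that reach the threshold
in at least one pool) is provided because the dataset-wide convention,
though the common practice, is not the only defensible reading. Ties for
the alternate allele are broken in base order A < C < G < T for
determinism.

## The genome scan

For every SNP, with `p_j` the alternate-allele frequency of pool `j`:

* **Mean cross-group FST.** The classical heterozygosity estimator
  `FST = (hT - hS) / hT` is computed for every farmed x wild pair and
  averaged. No pool-size bias correction is applied; the estimator is
  isolated behind `pairwise_fst()` so an alternative can be swapped in.
* **Fisher exact test.** Read counts are summed within each group and the
  2x2 table (ref, alt) x (farmed, wild) is tested two-sidedly by the
  point-probability rule (summing all tables with hypergeometric
  probability at most the observed one) — the standard convention, and the
  one `stats::fisher.test` uses, against which it is tested. Aggregating
  counts to the group level gives one test per SNP, rather than combining
  per-pair tests.
* **XtX.** Frequencies are standardized per site,
  `z_j = (p_j - pi) / sqrt(pi (1 - pi))` with `pi` the across-pool mean,
  and whitened by the scaled covariance of population allele frequencies,
  `Omega = Z Z' / L + lambda I` (`lambda = 1e-6 trace`), estimated from all
  polymorphic sites. `xtx = z' Omega^{-1} z` is referred to the upper tail
  of a chi-squared distribution with `J` degrees of freedom. This is a
  deterministic moment-based surrogate for the MCMC machinery usually used
  for this statistic: it preserves the definition — squared frequency
  deviations corrected for shared demography — at desk scale.
* **Multiple testing and consensus.** Benjamini-Hochberg is applied
  separately per track genome-wide, mirroring two independently run
  programs. A SNP is *highly suggestive* when both adjusted p-values fall
  below `1e-5`, and *suggestive* when one falls below `1e-5` and the other
  below `1e-3`.

A population PCA of the column-centered frequency matrix
(`population_pca()`) summarizes overall structure.

### Numerical notes and known calibration limits

Because `z` is centered on the across-pool mean, `Z` has rank `J - 1`, and
with `Omega` estimated from the same sites the average XtX is exactly
`J - 1` (up to the ridge), not `J`. The chi-squared-`J` reference is
therefore slightly conservative on average; its far tail remains usable
for ranking, which is all the consensus rule consumes.

The pooled Fisher test inherits a well-known liberality: it models only
read-level sampling, while a pool of `N` individuals adds allele-copy
sampling variance of `p(1-p)/2N` per pool. With pools of 11-25, group
frequency differences are overdispersed by roughly 50% in standard
deviation relative to the hypergeometric model, so isolated Fisher-track
discoveries must be expected even without selection. This is precisely why
the consensus classification demands agreement with the
demography-corrected XtX track: on a 50,000-site no-selection simulation
the Fisher track alone flags hundreds of sites at `q < 1e-3`, while the
consensus classes flag none.

The same denominators limit power: with realistic farmed drift (see below)
a fully shifted locus (`delta = 0.4`) reaches XtX around 45-70 on 20
pools, which ranks cleanly but does not always survive BH at `1e-3` over
tens of thousands of tests. On the default planted-selection world the
consensus rule therefore recovers only a minority of planted loci while
keeping the false-positive fraction at zero — conservative by
construction. Users wanting sensitivity over specificity can relax
`q_sugg`/`q_high` or interpret the single-track rankings directly.

## Candidate annotation

Suggestive and highly-suggestive SNPs are mapped to features of a GFF3
catalog (genes, plus CpG islands as a second feature class — frequent
methylation targets and hence markers of possible epigenetic involvement)
within 100 kbp on both sides. Coordinates follow GFF3: 1-based, closed on
both ends; the window is anchored on the SNP position, applied per SNP
with de-duplication of the union (clustered SNPs are not merged into
peaks). Ortholog translation to a better-annotated model species is a
plain two-column join (`map_orthologs()`): the mapping is data, not
computation. `term_enrichment()` then applies a one-sided Fisher test per
term over any supplied gene-to-term table, with BH across terms.

## Interactome-assisted enrichment

Functional couplings (gene, gene, probability) are filtered at probability
`>= 0.90` (boundary inclusive), and the network is restricted to edges
with at least one candidate endpoint; remaining non-candidate genes are
*intermediate partners*. The degree sweep then tightens the network: at
threshold `k` a partner is retained only if it connects to at least `k`
*distinct candidate* genes. We read "degree connectivity of interacting
partners" as candidate-neighbor count because the sweep's purpose is to
concentrate the network around the candidate set; a total-degree reading
is available (`mode = "total"`). At each `k` the candidate enrichment of
the network genes is assessed with a one-sided hypergeometric test against
the genome-wide gene universe (enrichment, not depletion, is the
hypothesis; the annotation's gene count is the default background). The
sweep is repeated for random candidate sets of the same size (1000
permutations by default), giving a per-`k` null envelope.

No explicit stopping rule exists in this kind of analysis; `poolscan`
selects the smallest `k` whose observed p-value beats the permutation 5th
percentile while the null median has collapsed to non-significance, then
reports the largest connected component (ties broken toward the
lexicographically smallest node). Degree and radiality
(`sum(diam + 1 - d) / (n - 1)` over shortest paths within a component)
are reported per node for topology-based prioritization, and the network
is exported as SIF and GraphML for Cytoscape.

## The synthetic world

`simulate_counts()` generates the stated study design: 12 farmed and 8
wild pools with the reference pool sizes (mostly 25 diploids, a few pools
of 11-12), ancestral frequencies from Beta(0.7, 0.7) truncated to
[0.05, 0.95] (a U-shaped, SFS-like spectrum without unusable fixed sites),
Balding-Nichols drift per pool, and two-stage sampling: 2N allele copies
binomially, then per-replicate Poisson depths
(`mean_depth * replicate_fraction`, two technical replicates) and binomial
alternate reads. The two-stage scheme reproduces the finite-pool variance
that the depth-representation simulation is about; depths are Poisson
rather than negative binomial (overdispersed depth is out of scope), no
linkage or sequencing-error structure is simulated, and read-level
artifacts (mapping bias, duplicates) are absent. A green test on this
world therefore establishes the statistical pipeline's correctness, not
robustness to upstream artifacts.

Defaults chosen once, on design grounds:

* `drift_farmed = 0.10`, `drift_wild = 0.01`: Balding-Nichols `c` is the
  pool's FST to the ancestor; with roughly ten generations since the
  domestication bottleneck and effective sizes near 24 (farmed) versus
  several hundred (wild), `c ~ t / 2Ne` gives this order of magnitude,
  consistent with the modest farmed-wild differentiation seen in
  Mediterranean seabass.
* `selection_shift = 0.4` at selected loci, direction randomized per locus
  (domestication-allele direction is unknown); shifted means are clamped
  to [0.01, 0.99], so loci with extreme ancestral frequencies carry
  effectively smaller shifts. The shift is a free parameter of the
  simulator, not an estimate of the real system.
* `mean_depth = 60`, `replicate_fraction = 0.5`: two technical replicates
  of 30x each, comfortably above the depth filter.

`simulate_annotation()` writes non-overlapping genes plus interspersed
CpG islands (islands may overlap genes, as in real promoters);
`simulate_interactome()` plants a fully connected high-confidence module
inside a background whose couplings all fall below the 0.90 filter, so the
network machinery can be validated against a known answer: the planted
module must be recovered essentially exactly and must beat every
permutation minimum.

## Degenerate inputs and tie-breaks

Monomorphic sites yield FST 0 (by the `hT = 0` convention) and are
excluded from Omega estimation; an empty margin in a Fisher table gives
p = 1 with a warning; an empty SNP table propagates to empty-but-valid
outputs at every stage; `n_perm = 1` and singleton network components are
handled (radiality 0 by convention). All RNG consumption is controlled by
explicit seeds, and a rerun of `run_pipeline()` with the same seed
produces byte-identical stage outputs.

## Limitations

* The XtX surrogate is not the full hierarchical Bayesian treatment: no
  POD calibration, no covariate models; its chi-squared reference is
  slightly conservative (mean `J - 1`, not `J`).
* The Fisher track is anticonservative for pooled data (see above); use
  the consensus classes, not the Fisher track alone.
* FST carries no pool-size bias correction.
* The simulator omits linkage, overdispersed depth, and sequencing error;
  window-based annotation consequently sees a cleaner landscape than real
  data would offer.
* GO-style term enrichment treats the term table as flat; no ontology
  graph propagation.
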