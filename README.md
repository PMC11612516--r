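# poolscan

Genome scans for signatures of domestication from **Pool-Seq** data —
pooled whole-genome sequencing of farmed versus natural-origin ("wild")
populations — with an interactome-assisted enrichment stage for the
resulting candidate genes.

Recently domesticated species (farmed fish in particular) rarely show
large-effect loci; the signal is spread over many small allele-frequency
shifts. `poolscan` is built for that regime: it detects consensus outlier
SNPs with two complementary differentiation statistics, maps them to
nearby genes and CpG islands, and then asks whether the candidates hang
together in a functional-interaction network more than chance allows —
shifting the unit of inference from single loci to gene modules.

## What it computes

Starting from per-position pooled base counts (bam-readcount style), per
population and technical replicate:

1. **SNP calling** — replicate merging, a minimum-depth filter (default
   25, justified by an occupancy simulation: at depth 25 a pool of 25
   diploids has at least 13 members represented with 95% confidence), a 1%
   minor-allele-frequency screen, and biallelic site selection.
2. **Genome scan** — per SNP: mean farmed×wild F<sub>ST</sub>
   ((h<sub>T</sub> − h<sub>S</sub>)/h<sub>T</sub> averaged over group
   pairs); a two-sided Fisher exact test on group-summed counts; and the
   XtX statistic z′Ω⁻¹z, where z are standardized frequency deviations and
   Ω is the scaled covariance of population allele frequencies (a
   deterministic moment estimate), referred to χ²
   with J degrees of freedom. Benjamini–Hochberg per track; SNPs with
   q < 10⁻⁵ in both tracks are *highly suggestive*, q < 10⁻⁵ in one and
   < 10⁻³ in the other *suggestive*.
3. **Candidate annotation** — genes and CpG islands within ±100 kbp of
   each outlier SNP (GFF3 coordinates), optional ortholog translation, and
   Fisher+BH term enrichment over any gene→term table.
4. **Network enrichment** — functional couplings filtered at probability
   ≥ 0.90, direct-interactor subgraph of the candidates, an iterative
   partner-degree sweep with hypergeometric enrichment at each step, a
   1000-permutation null envelope, largest-component extraction, and
   degree/radiality topology indices (SIF/GraphML export for Cytoscape).

A synthetic-data module (`simulate_counts()`, `simulate_annotation()`,
`simulate_interactome()`) generates the whole input stack under a
Balding–Nichols drift model with planted selection and a planted
interactome module, with ground truth for validation.

## Worked example

```r
library(poolscan)

## why depth 25 is enough for pools of 25
representation_summary(25, 25, n_reps = 1e6, seed = 1)
#> pool representation: n_pool=25 depth=25 (1,000,000 reps)
#>   mean distinct individuals: 15.99 (closed form 15.99)
#>   lower 95% limit (central): 13

## a synthetic study: 12 farmed + 8 wild pools, 20,000 sites,
## 100 loci with a 0.4 farmed allele-frequency shift
cfg  <- sim_config(n_sites = 20000, n_selected = 100, seed = 11)
sim  <- simulate_counts(cfg)
snps <- call_biallelic(filter_depth(merge_replicates(sim$counts), 25))
snps
#> snp_table: 19999 biallelic SNPs x 20 pools

scan <- genome_scan(snps, sim$design)
table(scan$class)
#>              none        suggestive highly_suggestive
#>             19991                 8                 0

head(scan[order(scan$fisher_q),
          c("chrom", "pos", "mean_fst", "fisher_q", "xtx", "xtx_q", "class")], 3)
#>       chrom     pos mean_fst fisher_q  xtx    xtx_q      class
#> 7326    LG9 1554022    0.301 5.24e-95 74.6 0.000242 suggestive
#> 10741  LG13 1753703    0.267 2.46e-86 68.9 0.000689 suggestive
#> 780     LG1 1866475    0.249 7.14e-85 68.9 0.000689 suggestive
```

Every consensus outlier here is a truly planted locus (the false-positive
fraction on non-planted loci is 0): the consensus rule is conservative by
design, trading sensitivity for specificity — the Fisher track alone is
anticonservative for pooled data, and the Ω-corrected XtX track absorbs
the farmed pools' drift into its denominator. See the methods vignette
(`vignettes/poolseq-domestication-scan.Rmd`) for the calibration analysis.

The same objects drive annotation and the network stage
(`collate_candidates()`, `degree_sweep()`, `permutation_null()`), or run
everything from files in one call:

```r
run_pipeline(pipeline_config("counts.tsv", "design.tsv", "features.gff3",
                             "interactome.tsv", out_dir = "out", seed = 1))
```

which writes `snps.tsv`, `scan.tsv`, PCA tables, candidate and enrichment
tables, the final network (SIF/GraphML), and a JSON manifest; reruns with
the same seed are byte-identical.

## Acceptance script

`scripts/acceptance.R` recomputes the desk-scale reference quantity from
scratch with the installed package — the Monte-Carlo lower 95% limit of
distinct individuals represented at depth 25 in a pool of 25 (one million
resampling events) — and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
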