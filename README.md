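# meiospec

Identification of meiosis-specific genes from three-tissue bulk RNA-Seq:
isolated male meiocytes profiled against whole-anther and seedling controls.

Whole anthers contain only ~1% meiocytes, so anther-based screens for
meiotic genes are contaminated by tapetum and anther-wall expression. With a
meiocyte library alongside anther and seedling controls, that contamination
becomes a testable signature, and `meiospec` implements the full analysis:

* **Normalization** — reads per million (RPM), `rpm = 1e6 · count / library
  total`, with `log2(rpm + 1)` transformation and binomial pseudo-replicate
  splitting for tissues sequenced as a single library.
* **Differential expression** — per-gene one-way ANOVA across the three
  tissues with pooled pairwise contrasts
  `t = (ȳᵢ − ȳⱼ) / √(MSE·(1/nᵢ + 1/nⱼ))` on `N − k` df, Benjamini–Hochberg
  FDR per contrast at 5%, and a twofold filter on untransformed tissue-mean
  RPM ratios, gated at 5 RPM in at least one sample.
* **Specificity classification** — the two-criterion rule: a gene is a
  meiosis-specific candidate if (1) it is at least twofold higher in
  meiocytes than anthers (or meiocyte-detected with anthers below 1 RPM),
  and/or (2) both meiocytes and anthers are at least twofold above
  seedlings — *excluding* any gene expressed fourfold or more in anthers
  versus meiocytes, which is called an anther-wall candidate instead.
* **Genomic summaries** — Venn partition of the significant sets,
  the chromosome II mitochondrial-genomic-insertion (MGI) block
  (II:3,222,935–3,626,460), and transposable-element expression by
  superfamily and binned chromosomal position.
* **Synthetic data** — a seeded generator planting all of the above
  (expression classes, MGI block, pericentromeric TE placement with an
  analytically checkable truncated-Laplace kernel) so every stage is tested
  against ground truth.

## Worked example

A self-contained run on the default 5,000-gene simulated experiment
(meiocyte ×2, anther ×2, seedling ×1 libraries; the seedling library is
pseudo-split automatically):

```r
library(meiospec)
res <- run_pipeline(pipeline_config(sim = sim_config(), seed = 1))
glance(res)
#> # A tibble: 1 × 7
#>   n_genes n_kept n_significant_union n_candidates n_mgi_genes n_te_differential
#>     <int>  <int>               <int>        <int>       <int>             <int>
#> 1    5000   4299                1794          961         150               174
```

Of 5,000 simulated genes, 4,299 pass the 1-RPM detection filter, 1,794 are
significant in at least one pairwise contrast after FDR and fold filtering,
and 961 land in the candidate meiosis-specific pool. The MGI block summary
counts its 150 genes by meiocyte detection, meiocyte-only status and
preferential/fourfold expression:

```r
res$mgi
#> # A tibble: 1 × 5
#>   n_genes_in_region n_detected_in_meiocyte n_meiocyte_only ...
#> 1               150                    114              53
```

The classifier reproduces published per-gene patterns — an anther-wall
regulator (meiocyte/anther/seedling = 7.8/89.3/0.0 RPM) is excluded by the
fourfold rule even though it beats seedlings, while 3.03/0.71 RPM with no
seedling measurement is meiocyte-specific:

```r
classify_specificity(tibble::tibble(
  gene_id  = c("DYT1", "AGO8"),
  meiocyte = c(7.8, 3.03), anther = c(89.3, 0.71), seedling = c(0.0, NA)))
#>   gene_id category              criterion1 excluded_fourfold m_rpm a_rpm s_rpm
#> 1 DYT1    anther_wall_candidate FALSE      TRUE               7.8  89.3      0
#> 2 AGO8    meiocyte_specific     TRUE       FALSE              3.03  0.71    NA
```

Against the planted truth, the seed-1 run recovers meiocyte-specific and
meiocyte-preferential genes with sensitivity 0.995 and precision 0.960, and
flags 99.5% of planted anther-wall genes as excluded.

Per-stage functions (`rpm_normalize()`, `split_pseudoreplicates()`,
`de_results()`, `significant_sets()`, `classify_specificity()`,
`venn_partition()`, `candidate_pool()`, `mgi_summary()`,
`te_differential_summary()`, `chromosome_bin_distribution()`) expose every
intermediate; `tidy()`/`glance()` methods and `autoplot()`/`plot_*()`
functions cover the result types. See the vignette
(`vignettes/meiocyte-rnaseq.Rmd`) for the model, parameter and design
details.

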