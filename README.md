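# swagmeth

Sparse wrapper model selection (SWAG) for two-group epigenome-wide DNA
methylation studies on Illumina-style arrays.

## The problem

Epigenome-wide association studies (EWAS) with small cohorts — here, a
31-child study contrasting early versus late bedtime groups (15 vs 16
children) — face an extreme *p >> n* problem: hundreds of thousands of CpG
β-values per subject, but far too few subjects to fit any joint model.
`swagmeth` implements the sparse-wrapper approach to this problem: instead
of one model, it builds a *library* of many low-dimensional logistic
classification models and asks which CpGs recur across the strongest ones.

The core procedure, for a binary group label *y* and probe matrix *X*:

1. **Screening (dimension 1).** Fit all *p* single-probe logistic
   regressions of *y* on β_j, score each by AIC = 2k − 2ℓ, and keep the
   best ⌈α·K⌉ of the K rankable fits. The union of their variables is the
   screened set.
2. **Growth (dimensions 2…d_max).** Extend each retained (d−1)-variable
   model by every screened variable it lacks, deduplicate, fit, and again
   keep the best ⌈α·K⌉ by AIC (optionally subsampling at most *m*
   candidates per dimension from a seeded stream).
3. **Post-processing.** Keep models whose every variable earns its place:
   a model survives only if its AIC beats each of its drop-one sub-models
   and the intercept-only model. A Δ-AIC window around the library minimum
   (`select_models()`) is also available.
4. **Variable importance.** For each probe, the share of Akaike weight
   w_m ∝ exp(−ΔAIC_m/2) carried by post-processed models containing it,
   alongside raw selection counts and frequencies.

Perfectly separating fits — routine at n = 31 when a probe is strongly
differential — are flagged and refit with Firth's bias-reduced logistic
regression so they stay rankable at a finite AIC instead of degenerating.

Around the core, the package provides the full pipeline: negative-control
background normalisation, bead-count/detection-p probe filtering and
β = M/(M+U+offset) computation; vectorised per-probe Welch/pooled t-tests
with Δβ direction calls; summary-statistics t-tests (for reproducing
printed cohort tables); CpG island / RefGene manifest annotation with
explicit-denominator context distributions; gene-set cross-comparison with
Benjamini–Yekutieli FDR control; and a seeded synthetic EPIC-like data
generator with planted differential probes, so everything is testable
without any external data.

## Worked example

Simulate a study-sized dataset (31 samples, 1000 probes, 10 planted CpGs
with a group shift of |Δβ| = 0.15), run the whole pipeline, and inspect the
result:

```r
library(swagmeth)

summary <- run_pipeline(list(
  sim  = list(n_probes = 1000, n_planted = 10, delta_beta = 0.15),
  seed = 1, out_dir = "run1"))
print(summary)
```

```
Pipeline run summary
  seed 1; 1000 probes x 31 samples
  QC: 1000/1000 probes retained
  significant probes (p < 0.001): 12 (6 hyper / 6 hypo in early)
  SWAG models per dimension: 51/64/112; min AIC 6.214
  unique genes among significant probes: 11
  planted-probe recall in top-10 importance: 0.80
```

Reading this: QC dropped nothing (the simulated panel had no failing
cells); the per-probe Welch tests call 12 probes significant at p < 0.001
(10 planted plus ~2 expected false positives at this threshold); the SWAG
library holds 227 models (51 singletons, 64 pairs, 112 triples); and 8 of
the 10 top-ranked probes by importance are truly planted. The top of the
importance-joined report (`summary$top_table`, also written to
`run1/top_table.tsv`):

```
     variable akaike_weight  delta_beta      p_value     direction
1  cg00000385         0.372 -0.15972847 7.659695e-11  hypo_in_late
2  cg00000316         0.242  0.18984021 9.751792e-11 hyper_in_late
3  cg00000805         0.144 -0.18284563 6.087444e-09  hypo_in_late
```

Each row ties a probe's model-library importance to its marginal
statistics: cg00000385 sits in post-processed models carrying 37% of the
library's Akaike weight, is 0.16 lower in the late-bedtime group, and its
Welch test agrees (p ≈ 8e-11).

The stages also run standalone, e.g. reproducing a printed cohort-table
row (group means ± standard errors, n = 15 vs 16):

```r
st <- summary_ttest(8.22, 0.39, 15, 8.86, 0.29, 16, dispersion_mode = "sem")
#> t = 1.317, df = 26.3, p = 0.199
```

and a gene-set cross-comparison with Benjamini–Yekutieli correction:

```r
sleep   <- load_gene_set(system.file("extdata", "sleep_genes_demo.txt",   package = "swagmeth"))
obesity <- load_gene_set(system.file("extdata", "obesity_genes_demo.txt", package = "swagmeth"))
intersect_sets(gene_set(c("CDH4", "FTO", "CAT", "TP53"), "study"), sleep, obesity)
#> Gene-set overlap: 3 study genes in 'sleep_genes_demo.txt', 3 in 'obesity_genes_demo.txt', 3 in both
```

A YAML-driven command-line wrapper lives at
`inst/scripts/run_pipeline.R`.

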