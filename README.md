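# tcrisk

Length-stratified TCR repertoire classification and the Lung Cancer Risk
Index (LCRI), in R.

## The problem

Tumor-reactive T cells expand clonally and circulate, so the peripheral
blood TCRβ repertoire carries a detectable cancer signature. `tcrisk`
implements an end-to-end framework that turns per-sample clonotype tables
into a single, interpretable per-sample risk score, for immunologists and
computational biologists working with bulk TCR-seq data:

1. **Repertoire handling** — VDJtools-style and AIRR Rearrangement TSV
   parsing, productivity filtering (`*` stop / `_` frameshift markers),
   seeded downsampling to a standard read depth (100,000), and the usual
   diversity/clonality statistics:
   Shannon $H = -\sum_i f_i \ln f_i$, Simpson $S = 1 - \sum_i f_i^2$, D50,
   high-expansion clone counts (frequency strictly > 0.5%), and V/J
   gene-usage profiles.
2. **Corpus curation** — per-class frequency filters (> 0.03% non-cancer,
   > 0.04% cancer; CDR3 lengths 11–20 aa), cross-sample deduplication,
   shared-sequence exclusion, CD-HIT-style greedy clustering (40% identity,
   LCS-based match count over the shorter length) and ≥ 15%
   dominant-cluster retention, followed by a length-stratified
   test/train/validation split (500 test sequences per length per class at
   full quota, remainder 4:1).
3. **Per-length scorers** — one binary classifier per CDR3 length behind a
   common interface: a fast, deterministic k-mer lasso-logistic reference
   backend, plus a job-spec exporter for fine-tuning a pretrained protein
   language model.
4. **Calibration** — AUC as the Mann-Whitney pair statistic and per-length
   probability cutoffs maximizing Youden's J under the rule
   "positive iff score > threshold".
5. **LCRI** — per sample,
   $\mathrm{LCRI} = \sum_{i\,\in\,\text{flagged}} f_i \in [0, 1]$: the
   summed frequency of clones whose predicted cancer-class probability
   strictly exceeds their length-specific cutoff.
6. **Cohort and longitudinal analyses** — Mann-Whitney group comparisons
   (exact permutation for small groups), cohort cutoffs with
   sensitivity/specificity, age-stratified AUCs, and pre/post trajectory
   subtyping (positive induction / temporal stability / reduction at the
   ±0.01 change boundary, with Δ > 0.15 and post > 0.30 risk flags).
7. **Synthetic cohorts** — a seeded simulator (Zipf clone sizes, planted
   motif signal with group-ordered prevalence, shared public-sequence
   catalogue, longitudinal pairs) so the whole pipeline is testable without
   controlled-access data.

See `vignettes/lcri-methods.Rmd` for the full methods account.

## Worked example

Simulate a cohort at the package's study conditions (20 samples each of
healthy donors, benign pulmonary nodules, and lung cancer; 100,000 reads
per sample; planted motif read-prevalence 0.05 / 0.15 / 0.30) and run the
full pipeline:

```r
library(tcrisk)

cfg    <- pipeline_config(sim = sim_config(), test_quota = 100, seed = 7)
report <- run_pipeline(cfg)
report
#> # pipeline report
#>   seed: 7, samples: 60, models: 10
#>   pooled validation AUC: 0.973
#>   LC vs HD: mean LCRI 0.309 vs 0.061, AUC 1.000, p = 6.8e-08
```

The report holds the per-length threshold table (`report$thresholds`:
cutoff, sensitivity, specificity, AUC per CDR3 length), the per-sample
LCRI table (`report$lcri`), and all pairwise group comparisons. The
headline numbers say: the ten length-specific scorers separate held-out
cancer-associated from non-cancer CDR3s (pooled validation AUC 0.97), and
the resulting risk index cleanly stratifies the cohorts (mean LCRI 0.309
in cancer vs 0.061 in healthy donors — close to the planted 0.30 vs 0.05
motif mass — with p = 6.8e-08, the smallest two-sided value attainable for
20 vs 20 samples).

Longitudinal trajectories:

```r
classify_trajectory(pre  = c(0.15, 0.08, 0.33),
                    post = c(0.23, 0.07, 0.23),
                    patient_id = c("P03", "P07", "P01"))
#> # A tibble: 3 × 7
#>   patient_id   pre  post   delta subtype            strong_elevation high_post
#> 1 P03         0.15  0.23  0.08   positive_induction FALSE            FALSE
#> 2 P07         0.08  0.07 -0.0100 temporal_stability FALSE            FALSE
#> 3 P01         0.33  0.23 -0.1    reduction          FALSE            FALSE
```

Plot helpers: `plot_lcri()`, `plot_roc()`, `plot_trajectories()`, and
`autoplot()` on threshold tables. A thin CLI wrapper ships in
`inst/cli/tcrisk.R` (`simulate`, `run-all`, `score` subcommands).

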