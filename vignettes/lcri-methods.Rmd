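---
title: "Length-stratified CDR3 classification and the Lung Cancer Risk Index: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Length-stratified CDR3 classification and the Lung Cancer Risk Index: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrisk)
```

# The problem

T cells recognize tumor antigens through their T cell receptor (TCR), and the
clonal expansion of tumor-reactive T cells leaves a detectable imprint on the
peripheral blood TCRβ repertoire. `tcrisk` implements a complete framework
that turns per-sample clonotype tables into a single per-sample cancer risk
score: it curates labeled CDR3 amino-acid training pools from cancer and
non-cancer cohorts, trains one binary sequence scorer per CDR3 length,
calibrates per-length probability cutoffs on held-out data, and aggregates
the frequencies of flagged clones into the Lung Cancer Risk Index (LCRI).

This vignette is the package's own account of the models, the tunable
parameters, the numerical choices, and what the synthetic-data experiments
do and do not demonstrate.

# Repertoire model and preprocessing

A *repertoire* is one sample's collection of clonotypes: a unique CDR3
amino-acid sequence (with optional V/D/J calls), a read count, and a
frequency $f_i = c_i / \sum_j c_j$. Frequencies always refer to the sample's
own read total, so they live on the probability simplex.

Preprocessing follows a fixed chain:

1. **Productivity filtering.** A CDR3 containing a stop codon (`*`) or a
   frameshift marker (`_`) is nonproductive and removed; an explicit AIRR
   `productive` call takes precedence over the sequence markers. Whether
   frequencies are renormalized over the survivors is exposed as a flag
   (`renormalize`, default `TRUE`): downstream diversity statistics assume
   a normalized simplex, and renormalization is the choice that keeps them
   well-defined.
2. **Depth standardization.** Each sample is downsampled to a fixed number
   of reads (default 100,000) by a multivariate hypergeometric draw —
   sampling reads *without replacement* from the finite sequenced pool.
   Sampling with replacement would inflate the apparent clonality of small
   samples; without replacement, expected clone frequencies are exactly
   preserved. The draw is seeded and bit-reproducible.

CDR3 length is the length of the reported amino-acid string as-is,
conserved anchor residues included; no trimming is applied.

# Diversity statistics

For clone frequencies $f_1, \dots, f_n$:

- Shannon index $H = -\sum_i f_i \ln f_i$ (natural log, nats);
- Simpson index $S = 1 - \sum_i f_i^2$;
- D50: the smallest fraction of unique clones whose cumulative frequency,
  in decreasing order, reaches one half;
- high-expansion clones (HECs): clones with frequency *strictly above*
  0.5%. All frequency comparisons in the package ("exceeding", the curation
  filters, the flagging rule) are strict; boundary values are excluded, so
  calibration and deployment agree on every edge case.

Gene-segment usage profiles are read-weighted by default (sequence
abundance); a clone-weighted mode is available for sensitivity analysis.
Group comparisons of any per-sample statistic use the two-sided
Mann-Whitney U test.

# Training-pool curation

The corpus construction mimics the clinical workflow at desk scale:

1. **Frequency filtering.** From non-cancer samples, CDR3s with per-sample
   frequency > 0.03%; from cancer samples, > 0.04%; both restricted to
   lengths 11–20 aa (the range covering >99% of repertoires), with
   cross-sample duplicate removal.
2. **Shared-sequence exclusion.** Cancer-pool sequences also observed in
   the non-cancer pool are removed, ensuring tumor specificity of the
   positive class.
3. **Greedy clustering.** A CD-HIT-style greedy incremental clustering at
   40% identity. Sequences are processed in decreasing length order (ties
   lexicographic — a deterministic replacement for input order); the first
   unassigned sequence founds a cluster, and each subsequent sequence joins
   the earliest-founded representative reaching the identity threshold.
   Identity is the maximal number of matched residues in a free-gap global
   alignment (match 1, mismatch 0, gap 0 — equivalently the longest common
   subsequence) divided by the shorter length, the CD-HIT convention. A
   residue-multiset upper bound prunes hopeless alignments; it is exact, so
   the short-word parameter is accepted for parameter parity but cannot
   change assignments.
4. **Dominant-cluster retention.** Clusters holding at least 15% of the
   clustered sequences are kept in full. The denominator of
   "15% representation" is ambiguous in common usage, so it is an explicit
   option: fraction of all clustered sequences (default) or fraction of the
   largest cluster. The comparison is inclusive (≥).

The split stage samples, per length and per class, 500 sequences without
replacement into a test partition (10 lengths × 2 classes × 500 = 10,000
test sequences at full quota), and divides the remainder 4:1 into training
and validation by seeded randomized allocation. A stratum that cannot fund
the quota while leaving a remainder has its quota reduced to half the
stratum size, with a warning; desk-scale runs in this package use a quota
of 100 per stratum for the same reason (the synthetic pools hold hundreds,
not tens of thousands, of sequences per stratum).

# Per-length scorers

Class 1 is the cancer-associated class throughout. Each CDR3 length in
11–20 gets its own binary scorer behind one interface, with two backends:

- **`reference_scorer`** (default): elastic-net logistic regression
  (mixing 0.9, i.e. predominantly lasso with a stabilizing ridge
  component) on k-mer count features (k = 1, 2, 3), fit with `glmnet`
  using class-balanced observation weights — imbalanced, perfectly
  separable strata would otherwise let a pure lasso path diverge. It
  trains in seconds on one CPU, is fully deterministic, and is the backend
  used by
  every test in this package. The regularization path plays the role of the
  training trajectory: the model state maximizing validation *balanced
  accuracy* (mean of sensitivity and specificity) is selected, ties broken
  toward the most regularized (earliest) state. Balanced accuracy rather
  than plain accuracy is deliberate: curated validation strata at tail CDR3
  lengths are strongly class-imbalanced, and plain accuracy would select
  the degenerate always-majority model there (the same imbalance concern
  that motivates ROC-based threshold selection downstream).
  The k-mer representation is this package's own design choice — it is
  documented as such and makes no claim of architectural fidelity to any
  particular deep model; for planted-motif recognition tasks it is
  essentially optimal, which is what the synthetic experiments require.
- **`plm_finetune`**: the hyperparameter set for fine-tuning a pretrained
  protein language model (base model `Rostlab/prot_bert`): per-length
  learning rates (3e-5 for lengths 11–12, 5e-6 for 13/14/16/17, 3e-7 for
  15, 1e-5 for 18/19, 1e-6 for 20), linear scheduler with warmup ratio 0.1,
  batch size 32, 5 epochs, weight decay 0.01, seed 42, gradient
  accumulation 1, best-accuracy epoch selection. Executing this backend
  requires downloading pretrained weights and a GPU toolchain, so the
  package emits a complete, versioned job specification
  (`export_plm_job()`: JSON plus train/validation TSVs) rather than running
  the fine-tune itself.

Tokenization maps residues of the canonical 20-letter alphabet to integer
indices and is strictly validated: ambiguity codes (B, J, O, U, X, Z) and
the nonproductive markers are rejected with the offending position. The
output layer contract is a numerically stable two-class softmax; predicted
probabilities are exactly `softmax(logit, 0)[1]`, and tests assert this
internal consistency.

# Calibration

AUC is computed as the Mann-Whitney pair statistic (concordant pairs plus
half the ties over all positive-negative pairs), evaluated via midranks.
The per-length cutoff maximizes Youden's J = sensitivity + specificity − 1
over the observed score values under the deployment rule
"positive iff score > threshold", ties resolved toward the smallest
threshold. Youden's J is the package's default because "optimal cutoff with
reported sensitivity/specificity" is its standard operationalization, but
the criterion is pluggable (`closest_topleft`, `fixed_specificity`) since
published cutoff tables generally do not disclose the criterion; the
bundled `example_threshold_table()` is an illustrative fixture of realistic
cutoff magnitudes and is never asserted against.

# The LCRI

For one sample, the LCRI is

$$\mathrm{LCRI} = \sum_{i \,:\, \text{flagged}} f_i,$$

the summed frequency of clones whose predicted cancer-class probability
strictly exceeds their length-specific cutoff. Clones outside 11–20 aa are
never flagged. Frequencies are the sample's productive-clone frequencies
over *all* productive reads, not renormalized to the scored length range:
this keeps the index in [0, 1] with the eligible length-11–20 mass as a
natural upper bound, and matches feeding repertoire frequencies directly
into the sum. A renormalized variant (divide by the eligible mass) is
available behind a flag. The LCRI is computed after the standard
preprocessing chain; applying the 100,000-read standardization before
scoring is the package default, and both the depth and the chain are
configurable and logged in pipeline reports.

Longitudinal pairs are classified by Δ = post − pre against a meaningful-
change boundary of 0.01: positive induction (Δ > 0.01), temporal stability
(|Δ| ≤ 0.01, boundary inclusive — a patient moving 0.08 → 0.07 lands
exactly on the boundary and is stable), reduction (Δ < −0.01). Deltas are
compared at full precision; nothing is rounded before the comparison. Two
strict risk flags mark the post-treatment pattern associated with distant
metastasis: Δ > 0.15 (strong elevation) and post > 0.30 (high post value).

Cohort comparisons use the Mann-Whitney U test: exact enumeration of all
group assignments for groups of at most 8 (valid under ties), otherwise the
normal approximation with continuity and tie correction. Age-stratified
AUCs use the bins <41, 41–50, 51–60, >60 by default; single-class bins are
reported as not evaluable rather than failing. Age correlations default to
Pearson's r with a Spearman option, since correlation reports in this
field frequently leave the coefficient type unstated.

# The synthetic-repertoire simulator

The simulator generates the statistical structure the framework assumes,
with all randomness threaded through explicit seeds:

- **Clone sizes.** Background clone frequencies follow a Zipf law
  (exponent 1 by default, per-group configurable), the standard model for
  repertoire clonality; reads are allocated multinomially (100,000 per
  sample by default).
- **Sequences.** CDR3s are uniform over the 20-letter alphabet with
  conserved `C...F` anchors and a discretized-normal length law over
  8–24 aa with mode near 14.5, matching observed CDR3 length profiles.
- **Class signal.** A planted 3-mer motif, carried by a dedicated set of
  400 clones whose total read mass equals the group prevalence
  (HD 0.05 < BPN 0.15 < LC 0.30). The signal is motif content, not a
  distributional shift: this mirrors the premise that specific
  cancer-associated CDR3 sequences accumulate, and keeps the classification
  task well-posed at desk scale. Motif-clone lengths are uniform over
  11–20 so every length stratum is exercised. Because the motif budget is
  spread over the same number of clones in every group, each motif clone in
  a healthy donor sits *below* the curation frequency filters while the
  same clones in cancer samples sit above them — cancer-associated-like
  sequences are present but unexpanded in health, which is exactly the
  regime the frequency-filter step exploits.
- **Public background.** Expanded background clones draw their sequences
  mostly (probability 0.9 for the top 300 ranks) from a shared 1,000-
  sequence public catalogue fixed by the config seed. This gives the
  shared-sequence exclusion step its real-data role — removing the public
  repertoire from the cancer pool — emulating at toy scale the millions of
  sequences shared between real cohorts.
- **Nonproductive clones** carry 5% of reads, exercising the productivity
  filter.
- **Ages** are drawn per group (means 40/52/62, sd 10), emulating the age
  imbalance typical of observational cohorts.
- **Longitudinal pairs** shift the post-sample motif prevalence by a draw
  from the subtype's delta range (default magnitude 0.05–0.20, zero for
  stability) from a 0.25 baseline — a typical cancer-sample prevalence that
  keeps all three subtypes reachable; unreachable targets error.

These defaults were chosen once as the package's study conditions and are
used unchanged by the test suite and the acceptance script.

**What the synthetic experiments show — and don't.** Passing the
end-to-end recovery test demonstrates that the pipeline machinery is
correct: curation isolates the planted positive class, per-length scorers
detect it (validation AUC ≥ 0.85 at prevalences 0.05 vs 0.30 with 20
samples/group), and the LCRI separates the cohorts (Mann-Whitney
p < 0.01). It does *not* demonstrate clinical performance: real
cancer-associated TCRs are not defined by a single shared k-mer, real
repertoires carry batch effects, HLA structure and age confounding that the
simulator deliberately omits, and the reference scorer's k-mer capacity is
matched to the synthetic signal, not to the complexity of real antigen
recognition.

# Numerical choices and degenerate inputs

- Deterministic row order everywhere (descending count, lexicographic
  sequence; length-descending processing order in clustering) so equal
  seeds give byte-equal artifacts.
- Seeded sampling uses `withr` scoping and never disturbs the caller's RNG
  state; derived per-sample seeds stay below 2^31 − 1.
- Simplex checks tolerate 1e−9 relative drift; diversity functions reject
  non-positive frequencies outright and warn when the input visibly fails
  to sum to 1.
- Empty repertoires, single-class training strata, single-class ROC
  inputs, missing per-length models or thresholds, and zero-size cohort
  groups raise typed errors early, with the offending length/label named.
- Downsampling to a depth at or above the current total returns the sample
  unchanged with a warning (not an error), since depth standardization is a
  ceiling, not a requirement.

# Problem sizes

The test suite and acceptance script run the full pipeline at the
simulator's study conditions — 60 samples (20 per group), 2,000 background
plus 400 motif clones per sample, 100,000 reads — three seeds for the
recovery test, plus many small fixtures. The split-construction check uses
pools of ~540 sequences per length per class to fund the full 500-sequence
test quota. These sizes were chosen so that a complete run takes on the
order of a minute per seed on one CPU while every stage still operates in
its intended regime.

# Known limitations

- The reference scorer is a linear k-mer model; it cannot represent
  positional or long-range sequence dependencies the PLM backend targets.
- Greedy clustering is quadratic in the worst case; it is intended for
  desk-scale pools (tens of thousands of sequences), not the millions of a
  full production corpus.
- The simulator's V/D/J calls are uniform draws from a small catalogue and
  carry no recombination realism; gene-usage analyses on synthetic data
  exercise bookkeeping, not biology.
- `plm_finetune` is a job-spec exporter by design; its results cannot be
  validated inside this package.
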