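---
title: "Methods: imbalance-aware scoring of noncoding regulatory variants"
author: "remscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: imbalance-aware scoring of noncoding regulatory variants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remscore)
```

## The problem

Whole-genome sequencing of a patient with a suspected Mendelian disorder
yields millions of variants, of which at most a handful are causal, and most
of the candidates outside coding regions have no interpretable consequence
annotation. A regulatory pathogenicity score must therefore be learned from
a training set in which a few hundred curated pathogenic noncoding SNVs face
roughly fourteen million putatively neutral, human-lineage-derived
"proxy-benign" alterations — a class imbalance on the order of 1 : 30,000.
Two things break at that imbalance: an ordinary classifier collapses into
predicting the majority class, and naive cross-validation leaks information
because genomically proximal variants share annotation values. remscore
implements the training machinery that addresses both, together with the
calibration and distribution tooling around it.

## The ensemble model

Let $m$ be the minority (pathogenic) sample size and $M$ the majority
(proxy-benign) sample size. The ensemble is built as follows:

1. **SMOTE oversampling.** For each minority vector $x$, `oversample_factor`
   ($f$, default 2) synthetic vectors are generated as
   $x + u\,(x_{nn} - x)$, with $u \sim U(0,1)$ and $x_{nn}$ drawn uniformly
   from the $k$ Euclidean nearest minority neighbours of $x$
   (`smote_k`, default 5). The combined minority is $(1+f)\,m$ vectors.
2. **Majority partitioning.** The $M$ majority samples are shuffled and
   split into `n_partitions` ($n$, default 100) disjoint sets whose sizes
   differ by at most one; each is then subsampled to `ratio` ($r$, default
   3) times $m$ without replacement.
3. **Member forests.** On each partition's training set — all minority
   originals, that partition's fresh synthetics, and its subsampled
   majority — one probability random forest (`ranger`, `trees_per_forest`
   default 10) is fitted.
4. **Score.** The score of a variant is the arithmetic mean over the $n$
   member class-1 probabilities, a value in $[0,1]$.

With the defaults and $m = 406$ this yields per-partition training sets of
$1{,}218$ minority plus $1{,}218$ majority rows — each member sees a nearly
balanced problem of a couple of thousand points, while the union of members
still covers the entire majority space.

Two readings of "oversampled by factor 2" exist in the literature: $f$
synthetics per original (combined minority $(1+f)m$) versus a combined
minority of $f\,m$. remscore adopts the first (the hyperSMURF parameter
meaning) and keeps $f$ configurable, so the second is available as
$f' = f - 1$.

### Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `n_partitions` | 100 | majority coverage vs compute; scaled to 20 in the synthetic studies |
| `oversample_factor` | 2 | SMOTE synthetics per original positive |
| `ratio` | 3 | majority rows per partition, in units of $m$; keeps members near 1:1–1:3 |
| `smote_k` | 5 | SMOTE literature default; must be $< m$ |
| `trees_per_forest` | 10 | small members are cheap; the ensemble supplies the variance reduction |
| `seed` | — | master seed; per-partition child streams are hash-derived so changing `n_partitions` leaves earlier partitions untouched |

Forest hyperparameters (`mtry`, `min_node_size`, `max_depth`) default to the
`ranger` conventions and are exposed untouched.

SMOTE interpolates in the unscaled feature space: the procedure it mirrors
defines no standardisation step, and tree ensembles are invariant to
monotone per-feature rescaling anyway, so adding one would change the
synthetic geometry without a compensating benefit.

## Missing-value imputation

Each feature carries one of three constant policies, applied after fitting
on training data only:

* `zero` — epigenetic and regulatory signal tracks, where a missing value
  usually means signal too low to measure;
* `mean` — the average of the defined training values, for features such as
  GC content or conservation where absence is a data gap. (In a
  whole-genome deployment this statistic would be the genome-wide average;
  here it is the training-matrix average — the same estimator on the data
  the artifact has.)
* `one` — P-value-like features, where absence of evidence corresponds to
  a non-significant P value of 1.

The default feature-to-policy map in `remm_feature_metadata()` assigns
sequence/conservation/population features to `mean`, epigenetic and
regulatory features to `zero` and the two P-value features to `one`; it is
a plain data frame and fully user-editable, since any real deployment will
carry its own annotation-specific table. Fitted means are stored in the
model and reused verbatim at scoring time; query data never re-fits.

## Cytoband-aware cross-validation

Pathogenic variants cluster around well-studied loci, and annotation values
are locally correlated along the genome. Ten-fold cross-validation therefore
assigns whole cytogenetic bands, not variants, to folds:

* bands carrying pathogenic variants are placed greedily — descending
  pathogenic count, each band onto the currently lightest fold
  (longest-processing-time bin packing). This is deterministic, and its
  imbalance is provably bounded: the max–min fold spread never exceeds the
  largest single-band count, which the test suite asserts exactly.
* bands without pathogenic variants are assigned uniformly at random from a
  dedicated child seed.

Each fold model is a full ensemble trained on the other nine folds (imputer
re-fitted on the training portion), and every training variant receives
exactly one held-out score. A repeat-runs driver
(`cross_validate_repeated()`) reruns the procedure across a seed list and
reports mean ± sd of the held-out AUPRC, with a `pick` index selecting the
run whose model is carried forward.

## Calibration and classification bands

Curves are evaluated at every unique score plus sentinels 0 and 1, with the
inclusive rule `score >= cutoff` ⇒ positive. AUPRC uses the step-function
(non-interpolated, average-precision) convention — standard for highly
imbalanced data, where trapezoidal interpolation is optimistic — and AUROC
the trapezoid rule; both conventions are recorded in the result object.
Precision at zero predicted positives is reported as 0 with an explicit
flag rather than NaN. F-beta optima are exhaustive over the evaluated
thresholds with ties broken toward the largest threshold (the most specific
cutoff attaining the maximum; the choice only matters on plateaus).

The F1- and F2-optimal cutoffs become the "pathogenic" and "likely
pathogenic" evidence bands (`threshold_bands()`, `classify_score()`); for
the published whole-genome GRCh38 model those cutoffs are 0.963 and 0.914.
Both boundaries are inclusive, and classification is monotone in the score
by construction.

## Prescored tracks

`write_score_track()` emits a sorted `(chrom, pos, score)` TSV,
bgzip-compresses and tabix-indexes it (`Rsamtools`), giving point and range
lookup without model evaluation. Scores are serialised at 3 decimals by
default — inferred from the granularity of published thresholds such as
0.963, and configurable because the true precision of distributed files is
not documented. `make_final_track()` substitutes each training variant's
held-out cross-validation score for its general-model score, so benchmarks
run against the track are not optimistically biased. Chromosome names are
opaque strings end to end; no "chr" prefix harmonisation is attempted,
because silent renaming is how build mismatches hide.

## The synthetic-data generator

`simulate_dataset()` produces the statistical structure the learner must
survive, at desk scale:

* **imbalance** — `n_pos = 200` positives vs `imbalance = 1000` negatives
  each (200,000 negatives; prevalence exactly 1/1001). The real problem is
  ~30× more imbalanced; 1:1,000 is the largest ratio that keeps a
  multi-seed study in the minutes range on one core while remaining deep in
  the regime where a raw classifier fails.
* **band clustering** — positives are confined to 20% of 50 bands,
  negatives are uniform over all bands.
* **band-local correlation** — every (band, feature) pair draws a shared
  $N(0, \text{band\_sd}^2)$ effect (default sd 0.5), so same-band variants
  are more similar than cross-band ones. This is what makes naive CV leak
  and band-aware CV necessary.
* **feature structure** — continuous Gaussian features for
  sequence/conservation/population categories; zero-inflated positive
  signal for regulatory features (a 30% baseline activation probability,
  slightly higher for positives); P-value-like features mapped through
  $1 - \Phi(z)$ so positives shift toward small P values.
* **class signal** — a per-feature mean shift `delta` in noise-SD units.
  The defaults (conservation 1.0, epigenetics 0.8, regulatory 0.5,
  sequence/population 0.3) represent a moderate, realistically uneven
  signal: conservation-type features carry the most information, sequence
  composition the least.
* **missingness** — per-feature Bernoulli masking at the metadata rates,
  including two enhancer-style features at 96–97% missing.

What the generator does **not** emulate: real genomic coordinates, real
annotation distributions and their heavy tails, sequence context,
linkage-like dependence between features beyond the shared band effect, and
label noise in the curated positives. Passing tests on simulated data
therefore demonstrate the correctness and imbalance behaviour of the
machinery, not the attainable performance on real variant sets — the
published whole-genome figure (held-out AUPRC ≈ 0.61) requires the real
~14M-variant feature set and is out of reach of any desk-scale surrogate,
which is why no test asserts it.

## Numerical and degenerate-case choices

* kNN ties in SMOTE break by row index; two identical minority points
  interpolate to themselves (the degenerate geometry is exercised in
  tests).
* `partition_majority` gives the first `N mod n` partitions the extra
  element after shuffling.
* A partition smaller than `ratio × m` is used whole, with a warning
  (small-data degeneracy, not an error).
* Constant score vectors yield a degenerate curve with a warning, not an
  error; zero-variance input to `correlate()` is an error, because a
  silent `NA` propagates.
* A fold left without training positives aborts naming the fold — the
  caller should lower `n_folds`.
* All child seeds derive from the master seed through an integer hash that
  is exact in double arithmetic and stays below $2^{31}$.

## Problem sizes used in the shipped studies

The test suite and the acceptance script run the generator at its default
study conditions (200 positives, 1:1,000, 20 partitions, 10-fold CV) for
the headline comparisons, and at smaller sizes (30–60 positives, 1:40–1:50)
for unit-level properties; the ensemble-vs-single-forest comparison uses a
band-aware 2-fold holdout with the single forest given the same total tree
count (200) as the ensemble, so the contrast isolates the sampling scheme
rather than model capacity. The no-signal null is judged against a
Monte-Carlo interval obtained by rescoring the same labels with random
scores.

## Known limitations

* The training-matrix mean stands in for the genome-wide average when
  fitting `mean`-policy imputation; on a genuinely genome-scale matrix the
  two coincide.
* SMOTE distances are computed on the full minority in memory
  ($O(m^2)$) — fine for hundreds of positives, the intended regime.
* The band-aware CV guards against *within-band* leakage only; pathogenic
  variants sharing structure across bands (e.g. recurrent mechanisms) are
  not held apart, matching the published procedure.
* Scoring a VCF writes gzip output via `vcfR`; records are matched to the
  prescored track by (chrom, pos) only, as a track stores one score per
  position, not per allele.
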