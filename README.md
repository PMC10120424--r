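# remscore

Training and scoring framework for probability-like pathogenicity scores of
noncoding single-nucleotide variants under extreme class imbalance.

## The problem

In genome sequencing of individuals with rare Mendelian disease, a causal
noncoding variant must be found among millions of neutral ones. A score for
this setting has to be trained on a few hundred curated pathogenic SNVs
against ~14 million proxy-benign, human-lineage-derived alterations — a
class imbalance near 1 : 30,000 at which ordinary classifiers collapse and
naive cross-validation leaks through local annotation correlation. remscore
is aimed at method developers and bioinformaticians who need this training
machinery as a reusable, testable toolkit.

## The model

The learner is the hyperSMURF scheme — *hyper-ensemble SMOTE undersampled
random forests*. With minority size $m$ and majority size $M$:

1. SMOTE oversampling of the minority: each positive $x$ spawns $f$
   synthetics $x + u\,(x_{nn} - x)$, $u \sim U(0,1)$, $x_{nn}$ one of its
   $k$ nearest minority neighbours (defaults $f = 2$, $k = 5$);
2. the majority is shuffled into $n$ disjoint partitions (default 100),
   each subsampled to $r \cdot m$ rows (default $r = 3$);
3. one probability random forest per partition (ranger, 10 trees);
4. the score of a variant is the mean of the $n$ member class-1
   probabilities, a value in $[0, 1]$.

Around the learner the package provides cytoband-aware 10-fold
cross-validation (whole cytogenetic bands move between folds, balanced on
pathogenic counts, so held-out variants are never genomically adjacent to
training data), per-feature missing-value policies (0 / training-set mean /
1 for P-value-like features), precision–recall / ROC / F-beta calibration
with the pathogenic ("F1-optimal") and likely-pathogenic ("F2-optimal")
score bands, Gini feature-importance aggregation, bgzip + tabix prescored
score tracks in which training positions carry their held-out CV score, and
a synthetic-data generator reproducing the imbalance, band clustering and
missingness structure of real training sets at desk scale.

## Worked example

```r
library(remscore)

sim <- simulate_dataset(sim_config(n_pos = 60, imbalance = 200,
                                   n_bands = 20, seed = 7))
sim
#> <remm_sim> 60 positives / 12000 negatives in 20 bands (4 carry positives); 26 features

cfg <- hypersmurf_config(n_partitions = 10, seed = 7)
cv <- cross_validate(sim$variants, sim$features, sim$bands, cfg,
                     n_folds = 5, seed = 7)
cv
#> <remm_cv> 5 folds, 12060 variants (60 pathogenic); held-out AUPRC 0.0998, AUROC 0.8706

bands <- calibrate_bands(cv$scores$score, cv$scores$label)
sprintf("F1 %.3f  F2 %.3f", bands$f1_threshold, bands$f2_threshold)
#> [1] "F1 0.634  F2 0.584"
table(classify_score(cv$scores$score[cv$scores$label == 1], bands))
#>    below_evidence likely_pathogenic        pathogenic
#>                40                 5                15
```

The held-out AUPRC of 0.0998 is ~20× the 0.005 prevalence: under 1:200
imbalance with moderate simulated signal, ranking by score concentrates
the 60 positives strongly, while AUROC (0.87) alone would overstate how
usable the ranking is. The calibrated bands then classify 15 of the 60
positives as "pathogenic" and 5 more as "likely pathogenic" at their
held-out scores.

```r
imp <- fit_imputer(sim$features)
general <- fit_hypersmurf(impute_features(sim$features, imp),
                          sim$variants$label, cfg, imputer = imp)
head(gini_importance(general)[order(gini_importance(general)$rank), ], 3)
#>             feature importance rank
#> 7  phyloPvertebrate   21.80328    1
#> 5     phyloPprimate   14.94053    2
#> 17         h3k36me3   13.67892    3

tr <- make_final_track(general, cv, sim$variants, sim$features,
                       path = tempfile(fileext = ".tsv"))
v1 <- sim$variants[sim$variants$label == 1, ][1, ]
track_lookup(tr, v1$chrom, v1$pos)
#>   chrom    pos score
#> 1  chr3 195204 0.223
```

Conservation-type features rank highest — they carry the largest simulated
effect sizes. The looked-up score (0.223) is this training variant's
*held-out* cross-validation score, substituted into the track in place of
the optimistic general-model score.

The same pipeline is available from a shell via the installed `remscore`
script (subcommands `simulate`, `train`, `cv`, `thresholds`, `score`); see
`?remscore_cli`.

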