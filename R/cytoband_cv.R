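#' Assign cytobands to cross-validation folds
#'
#' Pathogenic variants cluster in a small subset of bands, so folds are
#' balanced on pathogenic count rather than on variant count: bands carrying
#' positives are assigned greedily (descending count, each band to the fold
#' currently holding the fewest positives — longest-processing-time bin
#' packing, which keeps the max-min fold spread within the largest single
#' band count), and bands without positives are assigned uniformly at
#' random. Ties in the greedy step go to the lowest fold index, making the
#' deterministic part reproducible independent of the random part.
#'
#' @param bands A `remm_cytobands` data frame or character vector of band
#'   names.
#' @param pathogenic_counts Named integer vector: pathogenic variants per
#'   band (bands not listed count 0).
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for the random placement of positive-free bands.
#' @return An object of class `remm_folds`: `data.frame` (`band`, `fold`)
#'   with attribute `n_folds`.
#' @export
assign_folds <- function(bands, pathogenic_counts, n_folds = 10, seed = 1) {
  band_names <- if (is.data.frame(bands)) bands$band else as.character(bands)
  if (!length(band_names)) stop_("empty band list")
  if (n_folds < 2L) stop_("n_folds must be >= 2")
  counts <- rep(0L, length(band_names))
  names(counts) <- band_names
  known <- intersect(names(pathogenic_counts), band_names)
  counts[known] <- as.integer(pathogenic_counts[known])
  if (sum(counts) < n_folds)
    stop_("fewer pathogenic variants (", sum(counts),
          ") than folds (", n_folds, ")")
  fold <- rep(NA_integer_, length(band_names))
  names(fold) <- band_names
  loaded <- names(counts)[counts > 0L]
  loaded <- loaded[order(-counts[loaded], match(loaded, band_names))]
  load <- rep(0L, n_folds)
  for (b in loaded) {
    f <- which.min(load) # ties -> lowest index
    fold[b] <- f
    load[f] <- load[f] + counts[b]
  }
  empty <- names(counts)[counts == 0L]
  if (length(empty)) {
    set.seed(derive_seed(seed, 1))
    fold[empty] <- sample.int(n_folds, length(empty), replace = TRUE)
  }
  structure(data.frame(band = band_names, fold = unname(fold[band_names])),
            n_folds = as.integer(n_folds), class = c("remm_folds",
                                                     "data.frame"))
}

#' Cytoband-aware cross-validation
#'
#' Runs `n_folds`-fold cross-validation in which whole cytobands — never
#' individual variants — move between folds, so a model is never validated
#' on variants genomically adjacent to (and annotation-correlated with) its
#' training data. Each fold model is an independent [fit_hypersmurf()]
#' ensemble trained on the other folds, with the imputer re-fitted on the
#' training portion only; every variant receives exactly one held-out score.
#'
#' @param variants Labeled `remm_variants` (all labels 0/1).
#' @param features Aligned [remm_features] (may contain missing values;
#'   imputation is fitted per fold).
#' @param bands A `remm_cytobands` map covering all variants.
#' @param config A [hypersmurf_config()] for the fold models.
#' @param n_folds Number of folds (default 10).
#' @param seed Master seed for fold assignment and fold-model training.
#' @return An object of class `remm_cv`: `scores` (`data.frame` with
#'   `chrom`, `pos`, `ref`, `alt`, `label`, `band`, `fold`, `score`),
#'   `fold_assignment`, `models` (one per fold), `pooled` (`auprc`,
#'   `auroc`, `curve` over all held-out scores), and `per_fold` metrics.
#' @export
cross_validate <- function(variants, features, bands,
                           config = hypersmurf_config(), n_folds = 10,
                           seed = 1) {
  stopifnot(inherits(features, "remm_features"))
  if (anyNA(variants$label)) stop_("cross-validation requires labeled variants")
  if (nrow(features$values) != nrow(variants))
    stop_("features and variants are not aligned")
  band_of <- map_to_bands(variants, bands)
  pos_counts <- table(band_of[variants$label == 1L])
  fa <- assign_folds(bands, pos_counts, n_folds, derive_seed(seed, 7))
  fold_of <- fa$fold[match(band_of, fa$band)]
  y <- variants$label
  heldout <- rep(NA_real_, nrow(variants))
  models <- vector("list", n_folds)
  per_fold <- data.frame(fold = seq_len(n_folds), n = NA_integer_,
                         n_pos = NA_integer_, auprc = NA_real_,
                         auroc = NA_real_)
  for (f in seq_len(n_folds)) {
    tr <- which(fold_of != f)
    te <- which(fold_of == f)
    if (!any(y[tr] == 1L))
      stop_("fold ", f, " leaves no pathogenic variants for training; ",
            "reduce n_folds")
    if (!any(y[tr] == 0L))
      stop_("fold ", f, " leaves no benign variants for training")
    imp <- fit_imputer(features[tr])
    cfg <- config
    cfg$seed <- derive_seed(seed, 100L + f)
    m <- fit_hypersmurf(impute_features(features[tr], imp), y[tr], cfg,
                        imputer = imp)
    models[[f]] <- m
    if (length(te)) {
      heldout[te] <- predict(m, impute_features(features[te], imp))
      per_fold$n[f] <- length(te)
      per_fold$n_pos[f] <- sum(y[te] == 1L)
      if (length(unique(y[te])) == 2L) {
        cv <- pr_curve(heldout[te], y[te])
        per_fold$auprc[f] <- cv$auprc
        per_fold$auroc[f] <- cv$auroc
      }
    }
  }
  if (anyNA(heldout)) stop_("internal error: unscored variants remain")
  pooled <- pr_curve(heldout, y)
  scores <- data.frame(chrom = variants$chrom, pos = variants$pos,
                       ref = variants$ref, alt = variants$alt,
                       label = y, band = band_of, fold = fold_of,
                       score = heldout)
  structure(list(scores = scores, fold_assignment = fa, models = models,
                 pooled = list(auprc = pooled$auprc, auroc = pooled$auroc,
                               curve = pooled),
                 per_fold = per_fold, n_folds = n_folds, seed = seed),
            class = "remm_cv")
}

#' @export
print.remm_cv <- function(x, ...) {
  cat(sprintf(paste0("<remm_cv> %d folds, %d variants (%d pathogenic); ",
                     "held-out AUPRC %.4f, AUROC %.4f\n"),
              x$n_folds, nrow(x$scores), sum(x$scores$label == 1L),
              x$pooled$auprc, x$pooled$auroc))
  invisible(x)
}

#' Repeated cross-validation over seeds
#'
#' Training-cycle driver: reruns [cross_validate()] under each seed and
#' summarises the held-out AUPRC as mean and standard deviation, the way
#' multi-seed training campaigns report performance; `pick` selects which
#' run's result is carried forward as "the" model.
#'
#' @inheritParams cross_validate
#' @param seeds Integer vector of master seeds.
#' @param pick Index into `seeds` of the run to retain (default 1).
#' @return List with `runs` (`data.frame` of seed, auprc, auroc),
#'   `mean_auprc`, `sd_auprc`, and `picked` (the retained `remm_cv`).
#' @export
cross_validate_repeated <- function(variants, features, bands,
                                    config = hypersmurf_config(),
                                    n_folds = 10, seeds = 1:5, pick = 1) {
  stopifnot(length(seeds) >= 1L, pick >= 1L, pick <= length(seeds))
  runs <- data.frame(seed = seeds, auprc = NA_real_, auroc = NA_real_)
  picked <- NULL
  for (i in seq_along(seeds)) {
    cv <- cross_validate(variants, features, bands, config, n_folds,
                         seed = seeds[i])
    runs$auprc[i] <- cv$pooled$auprc
    runs$auroc[i] <- cv$pooled$auroc
    if (i == pick) picked <- cv
  }
  list(runs = runs, mean_auprc = mean(runs$auprc),
       sd_auprc = sd(runs$auprc), picked = picked)
}

#' Build the final prescored track with CV-score substitution
#'
#' Every position is scored with the general model (trained on all data),
#' except positions of training-set variants, which carry their held-out
#' cross-validation score instead — so benchmark use of the prescored file
#' is never optimistically biased by training leakage.
#'
#' @param model General `hypersmurf` model trained on all training data.
#' @param cv A `remm_cv` result covering every labeled variant.
#' @param variants Variants to place in the track (labeled rows must appear
#'   in `cv`; unlabeled rows are scored by `model`).
#' @param features [remm_features] aligned to `variants`.
#' @param path Optional output path; when given, the track is written with
#'   [write_score_track()] and a `remm_track` is returned.
#' @param digits Serialisation precision (default 3).
#' @return A `remm_track` (when `path` is given) or the `data.frame` of
#'   (`chrom`, `pos`, `score`) records.
#' @export
make_final_track <- function(model, cv, variants, features, path = NULL,
                             digits = 3) {
  stopifnot(inherits(model, "hypersmurf"), inherits(cv, "remm_cv"))
  score <- predict(model, features)
  key <- paste(variants$chrom, variants$pos)
  cv_key <- paste(cv$scores$chrom, cv$scores$pos)
  is_train <- !is.na(variants$label)
  hit <- match(key, cv_key)
  if (any(is_train & is.na(hit)))
    stop_("training variant without a cross-validation score: ",
          key[which(is_train & is.na(hit))[1]])
  sub <- is_train & !is.na(hit)
  score[sub] <- cv$scores$score[hit[sub]]
  rec <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    score = score)
  if (is.null(path)) return(rec)
  write_score_track(rec, path, digits = digits)
}
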