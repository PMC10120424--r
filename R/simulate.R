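#' Simulation configuration
#'
#' Parameters of the synthetic benchmark generator. The defaults describe a
#' desk-scale version of a whole-genome regulatory training set: 200
#' pathogenic variants against 1,000 proxy-benign variants each (1:1,000
#' imbalance, 200,000 negatives), positives clustered in 20% of 50
#' cytobands, five feature categories with band-level random effects
#' producing band-local annotation correlation, and per-feature missingness
#' taken from the feature metadata (two enhancer-style features >95%
#' missing).
#'
#' @param n_pos Number of pathogenic (minority) variants.
#' @param imbalance Proxy-benign variants per pathogenic variant.
#' @param n_bands Number of cytobands.
#' @param band_length Band length in bp.
#' @param n_chromosomes Chromosomes the bands are laid out on.
#' @param pos_band_fraction Fraction of bands that may carry positives.
#' @param delta Class effect (mean shift of positives, in noise SD units):
#'   a single number for all features, or a named per-feature vector;
#'   `NULL` uses moderate per-category defaults (conservation 1.0,
#'   epigenetics 0.8, regulatory 0.5, sequence and population 0.3).
#' @param band_sd Standard deviation of the per-(band, feature) random
#'   effect inducing band-local correlation (default 0.5).
#' @param missingness Optional named per-feature missingness rates in
#'   `[0, 1)`; defaults to `metadata$missingness`.
#' @param metadata Feature metadata (default [remm_feature_metadata()]).
#' @param seed Integer seed; the full dataset is a deterministic function
#'   of the configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pos = 200, imbalance = 1000, n_bands = 50,
                       band_length = 1e5, n_chromosomes = 5,
                       pos_band_fraction = 0.2, delta = NULL,
                       band_sd = 0.5, missingness = NULL,
                       metadata = remm_feature_metadata(), seed = 1) {
  stopifnot(is_count(n_pos), is_count(imbalance), is_count(n_bands),
            is_count(band_length), is_count(n_chromosomes),
            pos_band_fraction > 0, pos_band_fraction <= 1,
            band_sd >= 0)
  feats <- metadata$feature
  if (is.null(delta)) {
    cat_delta <- c(sequence = 0.3, conservation = 1.0, epigenetics = 0.8,
                   population = 0.3, regulatory = 0.5)
    delta <- unname(cat_delta[metadata$category])
  } else if (length(delta) == 1L && is.null(names(delta))) {
    delta <- rep(delta, length(feats))
  } else {
    d <- rep(0, length(feats))
    names(d) <- feats
    d[names(delta)] <- delta
    delta <- unname(d)
  }
  stopifnot(all(is.finite(delta)), length(delta) == length(feats))
  if (is.null(missingness)) {
    missingness <- metadata$missingness %||% rep(0, length(feats))
  } else if (!is.null(names(missingness))) {
    m <- metadata$missingness %||% rep(0, length(feats))
    names(m) <- feats
    m[names(missingness)] <- missingness
    missingness <- unname(m)
  }
  stopifnot(all(missingness >= 0), all(missingness < 1),
            length(missingness) == length(feats))
  structure(list(n_pos = as.integer(n_pos), imbalance = as.integer(imbalance),
                 n_bands = as.integer(n_bands),
                 band_length = as.integer(band_length),
                 n_chromosomes = as.integer(n_chromosomes),
                 pos_band_fraction = pos_band_fraction,
                 delta = delta, band_sd = band_sd,
                 missingness = missingness, metadata = metadata,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic training dataset
#'
#' Produces a labeled variant table, feature matrix and cytoband map with
#' the statistical structure an imbalance-aware scorer has to cope with:
#'
#' * extreme imbalance — `n_pos` positives vs `n_pos * imbalance` negatives
#'   (prevalence exactly `1 / (1 + imbalance)`);
#' * band-clustered positives — positives only in a designated subset of
#'   bands, negatives everywhere;
#' * band-local correlation — each (band, feature) pair draws a shared
#'   Gaussian random effect, so variants in the same band are more alike
#'   than variants across bands;
#' * category-structured features — continuous Gaussian for sequence /
#'   conservation / population features, zero-inflated positive signal for
#'   regulatory-element features, and P-value-like features in (0, 1) that
#'   shift toward 0 for positives;
#' * per-feature missingness at the configured rates, applied after value
#'   generation.
#'
#' @param config A [sim_config()].
#' @return List of class `remm_sim`: `variants` (labeled `remm_variants`),
#'   `features` ([remm_features] with missing cells), `bands`
#'   (`remm_cytobands`), and `truth` (per-feature `delta`, the band-effect
#'   matrix, the positive-carrying bands and the prevalence).
#' @export
#' @examples
#' sim <- simulate_dataset(sim_config(n_pos = 20, imbalance = 50,
#'                                    n_bands = 8, seed = 42))
#' table(sim$variants$label)
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  md <- config$metadata
  p <- nrow(md)
  n_pos <- config$n_pos
  n_neg <- config$n_pos * config$imbalance
  n <- n_pos + n_neg

  # band layout: consecutive intervals, round-robin over chromosomes
  chrom <- paste0("chr", rep_len(seq_len(config$n_chromosomes),
                                 config$n_bands))
  idx_on_chr <- stats::ave(seq_len(config$n_bands), chrom,
                           FUN = seq_along)
  start <- (idx_on_chr - 1) * config$band_length
  bands <- remm_cytobands(data.frame(
    chrom = chrom, start = start, end = start + config$band_length,
    band = sprintf("band%03d", seq_len(config$n_bands))))

  n_pos_bands <- max(1L, ceiling(config$pos_band_fraction * config$n_bands))
  pos_bands <- sort(sample.int(config$n_bands, n_pos_bands))

  # variant placement: positives only in pos_bands, negatives everywhere;
  # per-band positions drawn without replacement so (chrom, pos) is unique
  band_of_pos <- pos_bands[sample.int(n_pos_bands, n_pos, replace = TRUE)]
  band_of_neg <- sample.int(config$n_bands, n_neg, replace = TRUE)
  band_idx <- c(band_of_pos, band_of_neg)
  label <- c(rep(1L, n_pos), rep(0L, n_neg))
  pos <- integer(n)
  for (b in unique(band_idx)) {
    i <- which(band_idx == b)
    if (length(i) > config$band_length)
      stop_("band_length too small for the variant count per band")
    offs <- sample.int(config$band_length, length(i))
    pos[i] <- as.integer(bands$start[b]) + offs # 1-based within [start,end)
  }
  ref <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r),
                                        1), character(1))
  variants <- data.frame(chrom = bands$chrom[band_idx], pos = pos,
                         ref = ref, alt = unname(alt), label = label,
                         stringsAsFactors = FALSE)
  class(variants) <- c("remm_variants", "data.frame")

  # feature values: baseline + band random effect + class shift + noise
  band_eff <- matrix(rnorm(config$n_bands * p, sd = config$band_sd),
                     config$n_bands, p,
                     dimnames = list(bands$band, md$feature))
  vals <- matrix(NA_real_, n, p, dimnames = list(NULL, md$feature))
  for (j in seq_len(p)) {
    z <- band_eff[band_idx, j] + config$delta[j] * label + rnorm(n)
    vals[, j] <- switch(
      md$category[j],
      regulatory = {
        # sparse signal track: mostly exact zeros, positive bursts elsewhere
        on <- rbinom(n, 1, 0.3 + 0.2 * label) == 1L
        ifelse(on, abs(z) + 0.1, 0)
      },
      {
        if (md$impute[j] == "one") 1 - pnorm(z) # P-value-like, small when shifted
        else z
      })
  }
  mask <- matrix(FALSE, n, p, dimnames = dimnames(vals))
  for (j in seq_len(p)) {
    if (config$missingness[j] > 0)
      mask[, j] <- runif(n) < config$missingness[j]
  }
  vals[mask] <- NA_real_
  features <- remm_features(vals, md, mask)

  structure(list(variants = variants, features = features, bands = bands,
                 truth = list(delta = stats::setNames(config$delta,
                                                      md$feature),
                              band_effects = band_eff,
                              pos_bands = bands$band[pos_bands],
                              prevalence = n_pos / n),
                 config = config),
            class = "remm_sim")
}

#' @export
print.remm_sim <- function(x, ...) {
  cat(sprintf(paste0("<remm_sim> %d positives / %d negatives in %d bands ",
                     "(%d carry positives); %d features\n"),
              x$config$n_pos, x$config$n_pos * x$config$imbalance,
              x$config$n_bands, length(x$truth$pos_bands),
              nrow(x$config$metadata)))
  invisible(x)
}

#' Planted-signal recovery check
#'
#' Validates feature-importance behaviour on a simulation where exactly one
#' feature carries class signal: that feature should attain Gini-importance
#' rank 1 in the fitted ensemble.
#'
#' @param sim A `remm_sim` whose truth has exactly one feature with
#'   `delta > 0`.
#' @param model A `hypersmurf` ensemble fitted on that simulation.
#' @return List with `planted` (the feature), `rank` (its importance rank)
#'   and `recovered` (`rank == 1`).
#' @export
planted_signal_check <- function(sim, model) {
  stopifnot(inherits(sim, "remm_sim"), inherits(model, "hypersmurf"))
  planted <- names(sim$truth$delta)[sim$truth$delta > 0]
  if (length(planted) != 1L)
    stop_("planted-signal check needs exactly one feature with delta > 0")
  imp <- gini_importance(model)
  r <- imp$rank[imp$feature == planted]
  list(planted = planted, rank = r, recovered = r == 1L)
}
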