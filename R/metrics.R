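# Classification rule throughout: score >= cutoff => predicted positive.

#' Confusion counts and rates at a score cutoff
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param labels Binary labels (1 positive / 0 negative); positives must be
#'   present.
#' @param cutoff Classification cutoff; `score >= cutoff` is called positive.
#' @return List with `tp`, `fp`, `tn`, `fn`, `recall` (= TP rate),
#'   `precision`, `fp_rate` and `precision_defined` (FALSE when nothing is
#'   predicted positive, in which case precision is reported as 0).
#' @export
#' @examples
#' # 375 of 406 positives recovered at a 0.5 cutoff -> recall 92%
#' s <- c(rep(1, 375), rep(0, 31))
#' round_half_up(100 * confusion_at(s, rep(1, 406), 0.5)$recall)
confusion_at <- function(scores, labels, cutoff) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)), cutoff >= 0, cutoff <= 1)
  if (!any(labels == 1L)) stop_("no positives in labels; recall undefined")
  pred <- scores >= cutoff
  tp <- sum(pred & labels == 1L)
  fp <- sum(pred & labels == 0L)
  fn <- sum(!pred & labels == 1L)
  tn <- sum(!pred & labels == 0L)
  n_neg <- fp + tn
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       recall = tp / (tp + fn),
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       precision_defined = tp + fp > 0,
       fp_rate = if (n_neg > 0) fp / n_neg else 0)
}

# Shared curve engine: one row per evaluated threshold (all unique scores
# plus sentinels 0 and 1), with counts obtained from sorted cumulative
# tallies rather than a per-threshold pass.
curve_points <- function(scores, labels, betas = c(1, 2)) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  if (length(unique(labels)) < 2L)
    stop_("both classes must be present to compute a curve")
  if (length(unique(scores)) == 1L)
    warning("constant scores; curve is degenerate", call. = FALSE)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  pos_s <- sort(scores[labels == 1L])
  neg_s <- sort(scores[labels == 0L])
  th <- sort(unique(c(0, 1, scores)))
  # counts strictly below each threshold -> counts at-or-above
  tp <- n_pos - findInterval(th, pos_s, left.open = TRUE)
  fp <- n_neg - findInterval(th, neg_s, left.open = TRUE)
  recall <- tp / n_pos
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  out <- data.frame(threshold = th, tp = tp, fp = fp,
                    precision = precision, recall = recall,
                    fp_rate = fp / n_neg)
  for (b in betas) {
    fb <- ifelse(precision + recall > 0,
                 (1 + b^2) * precision * recall /
                   (b^2 * precision + recall), 0)
    out[[sprintf("f%g", b)]] <- fb
  }
  out
}

# Step-function (non-interpolated) area under the PR curve: walking from the
# highest threshold down, each recall increment contributes at the precision
# reached there (the average-precision convention, standard for reporting on
# imbalanced data).
auprc_step <- function(pts) {
  d <- pts[order(-pts$threshold), ]
  sum(diff(c(0, d$recall)) * d$precision)
}

auroc_trapezoid <- function(pts) {
  d <- pts[order(pts$fp_rate, pts$recall), ]
  x <- c(0, d$fp_rate, 1)
  y <- c(0, d$recall, 1)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Precision-recall curve with AUPRC
#'
#' Evaluated at every unique score plus the sentinels 0 and 1. AUPRC uses
#' the step-function (non-interpolated, average-precision) convention;
#' the convention is recorded in the result.
#'
#' @inheritParams confusion_at
#' @return An object of class `remm_curve`: the per-threshold table
#'   (`threshold`, `tp`, `fp`, `precision`, `recall`, `fp_rate`, `f1`,
#'   `f2`) plus `auprc`, `auroc` and `conventions`.
#' @export
pr_curve <- function(scores, labels) {
  pts <- curve_points(scores, labels)
  structure(list(points = pts, auprc = auprc_step(pts),
                 auroc = auroc_trapezoid(pts),
                 conventions = list(auprc = "step", auroc = "trapezoid",
                                    positive = "score >= threshold")),
            class = "remm_curve")
}

#' ROC curve with AUROC
#'
#' Same evaluation grid as [pr_curve()]; AUROC by the trapezoid rule.
#'
#' @inheritParams confusion_at
#' @return A `remm_curve` object (see [pr_curve()]).
#' @export
roc_curve <- function(scores, labels) pr_curve(scores, labels)

#' @export
print.remm_curve <- function(x, ...) {
  cat(sprintf("<remm_curve> %d thresholds; AUPRC %.4f (step), AUROC %.4f\n",
              nrow(x$points), x$auprc, x$auroc))
  invisible(x)
}

#' F-beta score across thresholds
#'
#' `F_beta = (1 + beta^2) P R / (beta^2 P + R)` (0 when both P and R are 0);
#' beta > 1 weights recall more heavily, so the F2-optimal cutoff sits at or
#' below the F1-optimal one.
#'
#' @inheritParams confusion_at
#' @param beta Positive weight; 1 = harmonic mean, 2 = recall-weighted.
#' @return `data.frame` with columns `threshold` and `fbeta`.
#' @export
f_beta_curve <- function(scores, labels, beta) {
  stopifnot(beta > 0)
  pts <- curve_points(scores, labels, betas = beta)
  data.frame(threshold = pts$threshold,
             fbeta = pts[[sprintf("f%g", beta)]])
}

#' Threshold maximising the F-beta score
#'
#' Exhaustive over every evaluated threshold (all unique scores plus 0 and
#' 1); ties are broken toward the largest threshold, i.e. the most specific
#' cutoff achieving the maximum.
#'
#' @param curve A `data.frame` from [f_beta_curve()], or raw scores (then
#'   `labels` and `beta` are required).
#' @param labels,beta Used when `curve` is a score vector.
#' @return The optimal threshold (length-1 numeric).
#' @export
optimal_threshold <- function(curve, labels = NULL, beta = 1) {
  if (is.numeric(curve) && !is.null(labels))
    curve <- f_beta_curve(curve, labels, beta)
  best <- max(curve$fbeta)
  max(curve$threshold[curve$fbeta == best])
}

#' Pathogenic / likely-pathogenic score bands
#'
#' Two calibrated cutoffs partition the score range into evidence bands,
#' analogous to clinical-database assertion categories: scores at or above
#' the F1-optimal threshold are "pathogenic" (weak computational evidence),
#' scores between the F2- and F1-optimal thresholds "likely pathogenic",
#' and everything below "below_evidence". For the published whole-genome
#' GRCh38 model those cutoffs are 0.963 (F1) and 0.914 (F2).
#'
#' @param f1_threshold,f2_threshold Cutoffs in `[0, 1]`; `f2_threshold`
#'   must not exceed `f1_threshold`.
#' @return An object of class `remm_bands`.
#' @export
threshold_bands <- function(f1_threshold, f2_threshold) {
  stopifnot(f1_threshold >= 0, f1_threshold <= 1,
            f2_threshold >= 0, f2_threshold <= 1)
  if (f2_threshold > f1_threshold)
    stop_("f2_threshold (", f2_threshold, ") must be <= f1_threshold (",
          f1_threshold, ")")
  structure(list(f1_threshold = f1_threshold, f2_threshold = f2_threshold),
            class = "remm_bands")
}

#' Calibrate score bands from held-out scores
#'
#' Convenience wrapper: the F1- and F2-optimal thresholds of the supplied
#' (cross-validated) scores become the band boundaries.
#'
#' @inheritParams confusion_at
#' @return A [threshold_bands()] object.
#' @export
calibrate_bands <- function(scores, labels) {
  threshold_bands(optimal_threshold(scores, labels, beta = 1),
                  optimal_threshold(scores, labels, beta = 2))
}

#' Classify scores into evidence bands
#'
#' Monotone in the score: a higher score never yields a weaker category.
#'
#' @param score Numeric score(s) in `[0, 1]`.
#' @param bands A [threshold_bands()] object.
#' @return Factor with levels `below_evidence < likely_pathogenic <
#'   pathogenic`.
#' @export
#' @examples
#' hg38 <- threshold_bands(0.963, 0.914)
#' classify_score(c(0.97, 0.93, 0.5), hg38)
classify_score <- function(score, bands) {
  stopifnot(inherits(bands, "remm_bands"))
  out <- ifelse(score >= bands$f1_threshold, "pathogenic",
                ifelse(score >= bands$f2_threshold, "likely_pathogenic",
                       "below_evidence"))
  factor(out, levels = c("below_evidence", "likely_pathogenic",
                         "pathogenic"), ordered = TRUE)
}

#' Spearman / Pearson correlation
#'
#' Thin wrapper over [stats::cor()] with the input checks scoring work
#' needs: equal length of at least 3, finite values, non-zero variance
#' (zero-variance input makes the coefficient undefined and is an error
#' rather than `NA`). Spearman uses midranks for ties.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param method `"spearman"` or `"pearson"`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3L)
    stop_("x and y must have equal length >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop_("zero-variance input; correlation undefined")
  cor(x, y, method = method)
}
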