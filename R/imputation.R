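#' Fit per-feature imputation statistics
#'
#' Missing annotation values are replaced by a per-feature constant chosen by
#' policy: `"zero"` (signal tracks where absence means signal too low to
#' measure), `"mean"` (the average over the defined training values, standing
#' in for a genome-wide average of annotations such as GC content or
#' conservation, where absence is a data gap rather than absence of signal)
#' and `"one"` (P-value-like features, where no evidence corresponds to
#' P = 1). Only the `"mean"` policy has a fitted statistic; it is computed
#' once on the training matrix and reused verbatim at scoring time, so query
#' data never re-fits.
#'
#' @param x A [remm_features] training matrix.
#' @param policy Optional named character vector or `data.frame`
#'   (`feature`, `impute`) overriding the policies in `x$metadata`.
#' @return An object of class `remm_imputer`: the policy table plus the
#'   fitted means.
#' @export
#' @examples
#' md <- data.frame(feature = "f1", category = "sequence", impute = "mean")
#' x <- remm_features(matrix(c(1, 3, NA), ncol = 1,
#'                           dimnames = list(NULL, "f1")), md)
#' fit_imputer(x)$means   # mean over defined values only: 2
fit_imputer <- function(x, policy = NULL) {
  stopifnot(inherits(x, "remm_features"))
  pol <- x$metadata$impute
  names(pol) <- x$metadata$feature
  if (!is.null(policy)) {
    if (is.data.frame(policy)) {
      p <- policy$impute
      names(p) <- policy$feature
      policy <- p
    }
    unknown <- setdiff(names(policy), names(pol))
    if (length(unknown))
      stop_("policy for unknown feature: ", paste(unknown, collapse = ", "))
    pol[names(policy)] <- policy
  }
  if (!all(pol %in% c("zero", "mean", "one")))
    stop_("policies must be zero, mean or one")
  means <- rep(NA_real_, length(pol))
  names(means) <- names(pol)
  for (f in names(pol)[pol == "mean"]) {
    v <- x$values[, f][!x$mask[, f]]
    if (!length(v))
      stop_("feature '", f, "' has policy mean but no defined values; ",
            "cannot fit an imputation mean")
    means[f] <- mean(v)
  }
  structure(list(policy = pol, means = means, fitted = TRUE),
            class = "remm_imputer")
}

#' Apply a fitted imputer
#'
#' Fills every masked cell with its policy constant (0, the stored training
#' mean, or 1); defined cells are never modified, and applying the imputer
#' twice is a no-op.
#'
#' @param x A [remm_features] object.
#' @param imputer A fitted `remm_imputer` from [fit_imputer()].
#' @return A [remm_features] object with an all-`FALSE` mask.
#' @export
impute_features <- function(x, imputer) {
  stopifnot(inherits(x, "remm_features"), inherits(imputer, "remm_imputer"))
  if (!isTRUE(imputer$fitted)) stop_("imputer is not fitted")
  absent <- setdiff(colnames(x$values), names(imputer$policy))
  if (length(absent))
    stop_("feature absent from imputation policy: ",
          paste(absent, collapse = ", "))
  vals <- x$values
  for (f in colnames(vals)) {
    m <- x$mask[, f]
    if (!any(m)) next
    vals[m, f] <- switch(imputer$policy[[f]],
                         zero = 0,
                         one = 1,
                         mean = imputer$means[[f]])
  }
  if (anyNA(vals)) stop_("imputation left missing cells") # defensive
  remm_features(vals, x$metadata,
                mask = matrix(FALSE, nrow(vals), ncol(vals),
                              dimnames = dimnames(vals)))
}
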