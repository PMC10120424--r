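#' Default annotation feature set
#'
#' The scoring model consumes 26 numeric annotations per variant, grouped into
#' five categories: sequence composition, conservation, epigenetics,
#' population variance and regulatory regions. Each feature carries an
#' imputation policy for missing values:
#'
#' * `"mean"` — replace by the average of the defined training values
#'   (the stand-in for a genome-wide average; used for sequence composition
#'   and conservation scores, where absence does not mean "no signal");
#' * `"zero"` — replace by 0 (epigenetic and regulatory-element signal
#'   tracks, where a missing value typically reflects signal too low to
#'   measure);
#' * `"one"` — replace by 1 (P-value-like features, where absence of
#'   evidence corresponds to a non-significant P value).
#'
#' The `missingness` column is the per-feature missing-data rate used by the
#' synthetic generator; real regulatory-element annotations are sparse, hence
#' the two FANTOM-style enhancer features default to >95% missing.
#'
#' The table is a default, not a contract: supply your own `data.frame` with
#' columns `feature`, `category`, `impute` (and optionally `missingness`) to
#' describe a different annotation set.
#'
#' @return A `data.frame` with columns `feature`, `category`,
#'   `impute` (one of `"zero"`, `"mean"`, `"one"`) and `missingness`.
#' @export
#' @examples
#' head(remm_feature_metadata())
#' table(remm_feature_metadata()$category)
remm_feature_metadata <- function() {
  md <- rbind(
    data.frame(
      feature = c("GCcontent", "CpGcontent", "dinucEntropy", "seqComplexity"),
      category = "sequence", impute = "mean",
      missingness = c(0, 0, 0.01, 0.01)
    ),
    data.frame(
      feature = c("phyloPprimate", "phyloPmammal", "phyloPvertebrate",
                  "phastConsVertebrate", "gerpRS"),
      category = "conservation", impute = "mean",
      missingness = c(0.05, 0.05, 0.05, 0.10, 0.30)
    ),
    data.frame(
      feature = c("gerpRSpval", "fitConsPval"),
      category = "conservation", impute = "one",
      missingness = c(0.30, 0.40)
    ),
    data.frame(
      feature = c("dnaseSignal", "h3k4me1", "h3k4me3", "h3k27ac", "h3k27me3",
                  "h3k36me3", "ctcfSignal"),
      category = "epigenetics", impute = "zero",
      missingness = c(0.10, 0.15, 0.15, 0.15, 0.20, 0.20, 0.25)
    ),
    data.frame(
      feature = c("commonVarDensity", "rareVarDensity", "hetRate", "avgMAF"),
      category = "population", impute = "mean",
      missingness = c(0.02, 0.02, 0.05, 0.05)
    ),
    data.frame(
      feature = c("fantomEnhancer", "fantomCAGE", "encodeTFBS",
                  "regElementCount"),
      category = "regulatory", impute = "zero",
      missingness = c(0.96, 0.97, 0.50, 0.40)
    )
  )
  rownames(md) <- NULL
  md
}

#' Feature matrix container
#'
#' Bundles a variants-by-features numeric matrix with an explicit missingness
#' mask and per-feature metadata (category and imputation policy). Missing
#' cells are `NA` in `values` and `TRUE` in `mask`; every defined cell must be
#' finite.
#'
#' @param values Numeric matrix, one row per variant, with column names.
#' @param metadata Feature metadata `data.frame` (see
#'   [remm_feature_metadata()]); must describe exactly the matrix columns.
#' @param mask Optional logical matrix of the same shape; defaults to
#'   `is.na(values)`.
#' @return An object of class `remm_features` with elements `values`, `mask`
#'   and `metadata`.
#' @export
remm_features <- function(values, metadata, mask = is.na(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_("`values` must be a numeric matrix")
  if (is.null(colnames(values)))
    stop_("`values` must have feature column names")
  if (!all(c("feature", "category", "impute") %in% names(metadata)))
    stop_("`metadata` needs columns feature, category, impute")
  extra <- setdiff(colnames(values), metadata$feature)
  if (length(extra))
    stop_("feature column not described by metadata: ",
          paste(extra, collapse = ", "))
  missing_md <- setdiff(metadata$feature, colnames(values))
  if (length(missing_md))
    stop_("metadata feature absent from matrix: ",
          paste(missing_md, collapse = ", "))
  if (!all(metadata$impute %in% c("zero", "mean", "one")))
    stop_("imputation policy must be one of zero, mean, one")
  if (!identical(dim(mask), dim(values)))
    stop_("`mask` must match the shape of `values`")
  mode(mask) <- "logical"
  dimnames(mask) <- dimnames(values)
  if (any(is.na(values) & !mask))
    stop_("NA cell not flagged in the missingness mask")
  if (any(!is.finite(values[!mask])))
    stop_("non-finite defined cell; every cell must be finite or masked")
  values[mask] <- NA_real_
  md <- metadata[match(colnames(values), metadata$feature), , drop = FALSE]
  rownames(md) <- NULL
  structure(list(values = values, mask = mask, metadata = md),
            class = "remm_features")
}

#' @export
dim.remm_features <- function(x) dim(x$values)

#' @export
print.remm_features <- function(x, ...) {
  cat(sprintf("<remm_features> %d variants x %d features (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(x$mask)))
  cat("categories:", paste(unique(x$metadata$category), collapse = ", "), "\n")
  invisible(x)
}

#' Subset rows of a feature matrix
#'
#' @param x A `remm_features` object.
#' @param i Row index vector.
#' @param ... Ignored.
#' @return A `remm_features` object with the selected rows.
#' @export
`[.remm_features` <- function(x, i, ...) {
  remm_features(x$values[i, , drop = FALSE], x$metadata,
                x$mask[i, , drop = FALSE])
}

#' Read a feature matrix from TSV
#'
#' The file must have a header whose column names match `metadata$feature`
#' exactly (any order); missing cells are encoded by a sentinel token.
#'
#' @param path Path to a tab-separated file with header.
#' @param metadata Feature metadata (see [remm_feature_metadata()]).
#' @param na Sentinel string(s) marking missing cells. Default `"NA"`.
#' @param n_variants Optional expected row count; mismatch is an error.
#' @return A [remm_features] object.
#' @export
read_feature_matrix <- function(path, metadata = remm_feature_metadata(),
                                na = "NA", n_variants = NULL) {
  dt <- data.table::fread(path, sep = "\t", na.strings = na,
                          colClasses = "numeric", showProgress = FALSE)
  unknown <- setdiff(names(dt), metadata$feature)
  if (length(unknown))
    stop_("unknown feature column in ", path, ": ",
          paste(unknown, collapse = ", "))
  absent <- setdiff(metadata$feature, names(dt))
  if (length(absent))
    stop_("feature column missing from ", path, ": ",
          paste(absent, collapse = ", "))
  if (!is.null(n_variants) && nrow(dt) != n_variants)
    stop_(sprintf("row count mismatch: %d rows in %s, %d variants expected",
                  nrow(dt), path, n_variants))
  m <- as.matrix(dt[, metadata$feature, with = FALSE])
  remm_features(m, metadata)
}

#' Write a feature matrix to TSV
#'
#' Inverse of [read_feature_matrix()]: masked cells are written as the
#' sentinel token.
#'
#' @param x A `remm_features` object.
#' @param path Output path.
#' @param na Sentinel string for missing cells.
#' @export
write_feature_matrix <- function(x, path, na = "NA") {
  stopifnot(inherits(x, "remm_features"))
  data.table::fwrite(data.table::as.data.table(x$values), path, sep = "\t",
                     na = na, quote = FALSE)
  invisible(path)
}
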