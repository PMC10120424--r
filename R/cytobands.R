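#' Read a cytoband interval file
#'
#' Cytogenetic bands are the unit of cross-validation fold assignment: all
#' variants in one band travel together, so a model is never validated on
#' variants genomically adjacent to its training data. The file is BED-like:
#' four tab-separated columns `chrom`, `start` (0-based inclusive), `end`
#' (exclusive), `band`, without header (a header line is tolerated). Extra
#' columns (e.g. Giemsa stain of UCSC `cytoBand.txt`) are ignored.
#'
#' @param path Path to the interval file.
#' @return A `data.frame` of class `remm_cytobands` with columns `chrom`,
#'   `start`, `end`, `band`, sorted by (chrom, start); intervals must be
#'   non-overlapping within a chromosome and band names unique.
#' @export
read_cytobands <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          showProgress = FALSE)
  if (ncol(dt) < 4L) stop_("cytoband file needs 4 columns: chrom start end band")
  dt <- dt[, 1:4]
  data.table::setnames(dt, c("chrom", "start", "end", "band"))
  # tolerate a header line
  if (is.na(suppressWarnings(as.numeric(dt$start[1])))) dt <- dt[-1]
  df <- data.frame(chrom = as.character(dt$chrom),
                   start = as.numeric(dt$start),
                   end = as.numeric(dt$end),
                   band = as.character(dt$band),
                   stringsAsFactors = FALSE)
  remm_cytobands(df)
}

#' Construct and validate a cytoband map
#'
#' @param df `data.frame` with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `band`.
#' @return A validated, sorted `remm_cytobands` data frame.
#' @export
remm_cytobands <- function(df) {
  need <- c("chrom", "start", "end", "band")
  if (!all(need %in% names(df))) stop_("cytobands need columns ",
                                       paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop_("empty cytoband list")
  if (any(df$end <= df$start)) stop_("cytoband with end <= start")
  if (anyDuplicated(df$band)) stop_("duplicate band names")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  # non-overlap within chromosome
  by_chr <- split(df, df$chrom)
  for (d in by_chr) {
    if (nrow(d) > 1L && any(d$start[-1] < d$end[-nrow(d)]))
      stop_("overlapping cytobands on ", d$chrom[1])
  }
  rownames(df) <- NULL
  class(df) <- c("remm_cytobands", "data.frame")
  df
}

#' Write a cytoband map as BED-like TSV
#'
#' @param bands A `remm_cytobands` data frame.
#' @param path Output path.
#' @export
write_cytobands <- function(bands, path) {
  data.table::fwrite(as.data.frame(bands)[c("chrom", "start", "end", "band")],
                     path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Map variants to cytobands
#'
#' Variant positions are 1-based; band intervals are 0-based half-open, so a
#' variant at `pos` falls in band `[start, end)` when `start < pos <= end`.
#' Overlap is resolved with `GenomicRanges::findOverlaps()`. Every variant
#' must map to exactly one band — bands are required to tile the variant
#' space for leakage-free cross-validation.
#'
#' @param variants A `remm_variants` data frame.
#' @param bands A `remm_cytobands` data frame.
#' @return Character vector of band names, one per variant.
#' @export
map_to_bands <- function(variants, bands) {
  bgr <- GenomicRanges::GRanges(bands$chrom,
                                IRanges::IRanges(bands$start + 1, bands$end))
  vgr <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(variants$pos, variants$pos))
  suppressWarnings(
    hits <- GenomicRanges::findOverlaps(vgr, bgr))
  n_hit <- tabulate(S4Vectors::queryHits(hits), nbins = length(vgr))
  if (any(n_hit == 0L))
    stop_(sum(n_hit == 0L), " variant(s) map to no cytoband (first: ",
          variants$chrom[which(n_hit == 0L)[1]], ":",
          variants$pos[which(n_hit == 0L)[1]], ")")
  if (any(n_hit > 1L))
    stop_("variant maps to multiple cytobands; bands must not overlap")
  bands$band[S4Vectors::subjectHits(hits)][order(S4Vectors::queryHits(hits))]
}
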