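#' Read labeled or query variants from VCF or TSV
#'
#' Training sets pair pathogenic variants (label 1) with proxy-benign
#' variants (label 0); query sets carry no label. Only single-nucleotide
#' substitutions are retained: records whose REF or ALT spans more than one
#' base, or whose REF equals ALT, are dropped. Mitochondrial records can be
#' excluded, mirroring the usual filtering of curated clinical variant sets.
#' Record order is preserved and chromosome names are kept verbatim (no
#' "chr"-prefix harmonisation — silent renaming hides build mismatches).
#'
#' @param path Path to a VCF (v4.x; only CHROM/POS/REF/ALT are consumed) or a
#'   tab-separated file with header columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `label` (0/1).
#' @param format `"auto"` (by file extension), `"vcf"` or `"tsv"`.
#' @param exclude_mito Drop mitochondrial records? Default `FALSE`.
#' @param mito_names Chromosome names treated as mitochondrial.
#' @return A `data.frame` of class `remm_variants` with columns `chrom`
#'   (character), `pos` (integer, 1-based), `ref`, `alt` (single bases) and
#'   `label` (integer 0/1 or `NA` for query variants).
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tref\talt\tlabel",
#'              "chr1\t100\tA\tG\t1",
#'              "chr1\t200\tAT\tA\t0"), tsv)   # indel line is dropped
#' read_variants(tsv)
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          exclude_mito = FALSE,
                          mito_names = c("MT", "M", "chrM", "chrMT")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.b?gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (!file.exists(path)) stop_("no such file: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    df <- data.frame(chrom = as.character(fix[, "CHROM"]),
                     pos = as.integer(fix[, "POS"]),
                     ref = as.character(fix[, "REF"]),
                     alt = as.character(fix[, "ALT"]),
                     label = NA_integer_,
                     stringsAsFactors = FALSE)
  } else {
    dt <- tryCatch(
      data.table::fread(path, sep = "\t", colClasses = list(
        character = c("chrom", "ref", "alt")), showProgress = FALSE),
      error = function(e) stop_("failed to parse ", path, ": ",
                                conditionMessage(e)))
    need <- c("chrom", "pos", "ref", "alt")
    if (!all(need %in% names(dt)))
      stop_("TSV must have header columns chrom, pos, ref, alt")
    bad_pos <- which(is.na(suppressWarnings(as.integer(dt$pos))))
    if (length(bad_pos))
      stop_("malformed pos at data line ", bad_pos[1], " of ", path)
    df <- data.frame(chrom = dt$chrom, pos = as.integer(dt$pos),
                     ref = dt$ref, alt = dt$alt,
                     label = if ("label" %in% names(dt))
                       as.integer(dt$label) else NA_integer_,
                     stringsAsFactors = FALSE)
  }
  keep <- nchar(df$ref) == 1L & nchar(df$alt) == 1L & df$ref != df$alt
  if (exclude_mito) keep <- keep & !(df$chrom %in% mito_names)
  df <- df[keep, , drop = FALSE]
  if (any(df$pos < 1L)) stop_("positions must be >= 1")
  lab <- df$label
  if (!all(is.na(lab) | lab %in% c(0L, 1L)))
    stop_("label column must be 0/1")
  rownames(df) <- NULL
  class(df) <- c("remm_variants", "data.frame")
  df
}

#' Write a variant table to TSV
#'
#' @param variants A `remm_variants` (or compatible) data frame.
#' @param path Output path.
#' @export
write_variants <- function(variants, path) {
  cols <- intersect(c("chrom", "pos", "ref", "alt", "label"), names(variants))
  data.table::fwrite(as.data.frame(variants)[cols], path, sep = "\t",
                     quote = FALSE, na = "NA")
  invisible(path)
}
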