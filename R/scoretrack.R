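#' Write a prescored score track
#'
#' A score track is the prescored-file form of the model: one row per genomic
#' position with its pathogenicity score in `[0, 1]`, sorted by
#' (chrom, pos), block-gzip compressed and tabix-indexed so single positions
#' and ranges can be looked up without evaluating the model. Scores are
#' serialised at a fixed decimal precision (default 3, matching the
#' granularity of published threshold values such as 0.963).
#'
#' @param records `data.frame` with columns `chrom`, `pos` (1-based),
#'   `score`. Records are sorted on write; duplicate positions are an error.
#' @param path Output path; `.gz`/`.bgz` is appended if absent.
#' @param digits Decimal places used for serialisation (default 3).
#' @return An object of class `remm_track` pointing at the bgzipped file and
#'   its tabix index.
#' @export
#' @examples
#' tr <- write_score_track(
#'   data.frame(chrom = "c1", pos = c(5, 2), score = c(0.5, 0.9)),
#'   tempfile(fileext = ".tsv"))
#' track_lookup(tr, "c1", 1, 10)
write_score_track <- function(records, path, digits = 3) {
  need <- c("chrom", "pos", "score")
  if (!all(need %in% names(records)))
    stop_("records need columns chrom, pos, score")
  if (any(!is.finite(records$score)) ||
      any(records$score < 0) || any(records$score > 1))
    stop_("scores must be finite and within [0, 1]")
  if (any(records$pos < 1)) stop_("positions must be >= 1")
  ord <- order(records$chrom, records$pos, method = "radix")
  records <- records[ord, , drop = FALSE]
  if (anyDuplicated(records[c("chrom", "pos")]))
    stop_("duplicate position in score track; one record per position")
  plain <- sub("\\.(b?gz)$", "", path)
  out <- data.frame(chrom = records$chrom, pos = as.integer(records$pos),
                    score = formatC(records$score, format = "f",
                                    digits = digits))
  data.table::fwrite(out, plain, sep = "\t", col.names = FALSE, quote = FALSE)
  bgz <- Rsamtools::bgzip(plain, dest = paste0(plain, ".gz"), overwrite = TRUE)
  unlink(plain)
  idx <- Rsamtools::indexTabix(bgz, seq = 1, start = 2, end = 2,
                               zeroBased = FALSE)
  structure(list(path = bgz, index = idx, digits = digits),
            class = "remm_track")
}

#' Open an existing score track
#'
#' @param path Path to a bgzipped track written by [write_score_track()];
#'   the `.tbi` index must sit next to it (it is created if absent).
#' @param digits Decimal precision the track was written with.
#' @return A `remm_track` object.
#' @export
open_score_track <- function(path, digits = 3) {
  if (!file.exists(path)) stop_("no such track: ", path)
  idx <- paste0(path, ".tbi")
  if (!file.exists(idx))
    idx <- Rsamtools::indexTabix(path, seq = 1, start = 2, end = 2,
                                 zeroBased = FALSE)
  structure(list(path = path, index = idx, digits = digits),
            class = "remm_track")
}

#' @export
print.remm_track <- function(x, ...) {
  cat("<remm_track>", x$path, sprintf("(%d-decimal scores)\n", x$digits))
  invisible(x)
}

#' Point / range lookup in a score track
#'
#' Returns every record with `start <= pos <= end` on `chrom`. Querying a
#' chromosome absent from the track yields an empty result, not an error.
#'
#' @param track A `remm_track` object.
#' @param chrom Chromosome name (verbatim; no prefix harmonisation).
#' @param start,end 1-based inclusive range bounds (`end` defaults to
#'   `start` for a point query).
#' @return `data.frame` with columns `chrom`, `pos`, `score`.
#' @export
track_lookup <- function(track, chrom, start, end = start) {
  stopifnot(inherits(track, "remm_track"), end >= start)
  tbx <- Rsamtools::TabixFile(track$path, index = track$index)
  empty <- data.frame(chrom = character(), pos = integer(),
                      score = numeric())
  if (!chrom %in% Rsamtools::seqnamesTabix(tbx)) return(empty)
  param <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  lines <- unlist(Rsamtools::scanTabix(tbx, param = param), use.names = FALSE)
  if (!length(lines)) return(empty)
  parts <- data.table::tstrsplit(lines, "\t")
  data.frame(chrom = as.character(parts[[1]]), pos = as.integer(parts[[2]]),
             score = as.numeric(parts[[3]]))
}

#' Read a full score track back into memory
#'
#' @param track A `remm_track` object or a path to a track file.
#' @return `data.frame` with columns `chrom`, `pos`, `score`, in file order.
#' @export
read_score_track <- function(track) {
  path <- if (inherits(track, "remm_track")) track$path else track
  # read.table opens and closes the connection itself
  read.table(gzfile(path), sep = "\t",
             col.names = c("chrom", "pos", "score"),
             colClasses = c("character", "integer", "numeric"))
}

#' Score a VCF against a model or a prescored track
#'
#' Writes a copy of the input VCF with each record's score appended to the
#' INFO field under the key `REMM`. With a `remm_track` source, scores come
#' from indexed lookup; positions absent from the track get a missing value
#' (`.`). With a model source, a feature matrix aligned to the VCF records
#' must be supplied.
#'
#' @param vcf_path Input VCF.
#' @param source A `remm_track`, or a fitted `hypersmurf` model.
#' @param out_path Output VCF path (written gzip-compressed; `.gz` appended
#'   if absent).
#' @param features `remm_features` aligned to the VCF records (model source
#'   only).
#' @param digits Decimal places for the emitted scores.
#' @return Invisibly, the vector of scores (NA where unscored).
#' @export
score_vcf <- function(vcf_path, source, out_path, features = NULL,
                      digits = 3) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  chrom <- as.character(fix[, "CHROM"])
  pos <- as.integer(fix[, "POS"])
  if (inherits(source, "remm_track")) {
    scores <- rep(NA_real_, length(pos))
    for (cr in unique(chrom)) {
      i <- which(chrom == cr)
      hit <- track_lookup(source, cr, min(pos[i]), max(pos[i]))
      scores[i] <- hit$score[match(pos[i], hit$pos)]
    }
  } else if (inherits(source, "hypersmurf")) {
    if (is.null(features))
      stop_("scoring a VCF with a model requires an aligned feature matrix")
    if (nrow(features$values) != length(pos))
      stop_("feature matrix rows must match VCF records")
    scores <- predict(source, features)
  } else stop_("`source` must be a remm_track or a hypersmurf model")
  tag <- ifelse(is.na(scores), ".",
                formatC(scores, format = "f", digits = digits))
  info <- v@fix[, "INFO"]
  info <- ifelse(is.na(info) | info == "." | info == "",
                 paste0("REMM=", tag), paste0(info, ";REMM=", tag))
  v@fix[, "INFO"] <- info
  v@meta <- c(v@meta,
              "##INFO=<ID=REMM,Number=1,Type=Float,Description=\"Regulatory pathogenicity score\">")
  if (!grepl("\\.gz$", out_path)) out_path <- paste0(out_path, ".gz")
  vcfR::write.vcf(v, file = out_path)
  invisible(scores)
}
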