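test_that("VCF reading keeps SNVs, drops indels, honours the mito flag", {
  vcf <- write_tiny_vcf(withr::local_tempfile(fileext = ".vcf"), list(
    list(chrom = "chr1", pos = 100, ref = "A", alt = "G"),
    list(chrom = "chr1", pos = 200, ref = "AT", alt = "A"),   # deletion
    list(chrom = "chr2", pos = 50, ref = "C", alt = "CTT"),   # insertion
    list(chrom = "MT", pos = 10, ref = "G", alt = "T"),
    list(chrom = "chr2", pos = 60, ref = "T", alt = "A")))
  v <- read_variants(vcf, format = "vcf")
  expect_s3_class(v, "remm_variants")
  expect_equal(nrow(v), 3L)
  expect_equal(v$chrom, c("chr1", "MT", "chr2")) # order preserved
  expect_true(all(nchar(v$ref) == 1L & nchar(v$alt) == 1L))
  expect_true(all(is.na(v$label)))

  v2 <- read_variants(vcf, format = "vcf", exclude_mito = TRUE)
  expect_false("MT" %in% v2$chrom)
  expect_equal(nrow(v2), 2L)
})

test_that("TSV variants round-trip and malformed positions are reported", {
  df <- data.frame(chrom = c("chr1", "chr1", "chrX"), pos = c(5L, 9L, 2L),
                   ref = c("A", "C", "G"), alt = c("T", "G", "A"),
                   label = c(1L, 0L, 0L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variants(df, path)
  back <- read_variants(path)
  expect_equal(as.data.frame(back), df)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt", "chr1\toops\tA\tG"), bad)
  expect_error(read_variants(bad), "pos")
})

test_that("feature matrix reader masks exactly the sentinel cells", {
  md <- tiny_metadata()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("f1\tf2\tf3", "1\t2\t3", "4\tNA\t6", "7\t8\t9"), path)
  x <- read_feature_matrix(path, md)
  expect_equal(dim(x), c(3L, 3L))
  expect_equal(sum(x$mask), 1L)
  expect_true(x$mask[2, "f2"])
  expect_true(all(is.finite(x$values[!x$mask])))

  clean <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("f1\tf2\tf3", "1\t2\t3"), clean)
  expect_false(any(read_feature_matrix(clean, md)$mask))

  expect_error(read_feature_matrix(path, md[1:2, ]), "unknown feature")
  expect_error(read_feature_matrix(path, md, n_variants = 5),
               "row count mismatch")
})

test_that("feature matrices round-trip through TSV", {
  set.seed(4)
  vals <- matrix(rnorm(30), 10, 3)
  vals[c(2, 17)] <- NA
  x <- tiny_features(vals)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_feature_matrix(x, path)
  back <- read_feature_matrix(path, x$metadata)
  expect_equal(back$mask, x$mask, ignore_attr = TRUE)
  expect_equal(back$values, x$values, tolerance = 1e-12)
})

test_that("score tracks round-trip bit-exactly at the declared precision", {
  rec <- data.frame(chrom = c("c2", "c1", "c1"), pos = c(7L, 5L, 2L),
                    score = c(0.963, 0.5, 0.9145))
  tr <- write_score_track(rec, withr::local_tempfile(fileext = ".tsv"))
  back <- read_score_track(tr)
  expect_equal(back$chrom, c("c1", "c1", "c2")) # sorted on write
  expect_equal(back$pos, c(2L, 5L, 7L))
  expect_equal(back$score, round(rec$score[c(3, 2, 1)], 3))

  expect_equal(track_lookup(tr, "c1", 5, 5),
               data.frame(chrom = "c1", pos = 5L, score = 0.5))
  expect_equal(nrow(track_lookup(tr, "c1", 100, 200)), 0L)
  expect_equal(nrow(track_lookup(tr, "absent", 1, 10)), 0L)
})

test_that("score track write rejects invalid records", {
  expect_error(write_score_track(
    data.frame(chrom = "c1", pos = c(1L, 1L), score = c(0.1, 0.2)),
    tempfile()), "duplicate")
  expect_error(write_score_track(
    data.frame(chrom = "c1", pos = 1L, score = 1.2), tempfile()),
    "\\[0, 1\\]")
})

test_that("range lookup matches a linear-scan oracle on random tracks", {
  set.seed(99)
  rec <- data.frame(
    chrom = sample(c("c1", "c2", "c3"), 1000, replace = TRUE),
    pos = sample.int(5000, 1000), score = round(runif(1000), 3))
  rec <- rec[!duplicated(rec[c("chrom", "pos")]), ]
  tr <- write_score_track(rec, withr::local_tempfile(fileext = ".tsv"))
  for (i in 1:100) {
    chrom <- sample(c("c1", "c2", "c3", "c4"), 1)
    a <- sample.int(5000, 1)
    b <- min(5000, a + sample.int(500, 1))
    got <- track_lookup(tr, chrom, a, b)
    want <- oracle_lookup(rec, chrom, a, b)
    expect_equal(got$pos, want$pos)
    expect_equal(got$score, want$score)
  }
})

test_that("cytoband files parse, validate and map variants correctly", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tp1\tgneg", "chr1\t100\t250\tp2\tgpos50",
               "chr2\t0\t80\tq1\tgneg"), path)
  b <- read_cytobands(path)
  expect_s3_class(b, "remm_cytobands")
  expect_equal(nrow(b), 3L)

  v <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                  pos = c(100L, 101L, 80L), # boundary: pos 100 is in [0,100)
                  ref = "A", alt = "G", label = c(1L, 0L, 0L))
  expect_equal(map_to_bands(v, b), c("p1", "p2", "q1"))

  v_bad <- data.frame(chrom = "chr2", pos = 81L, ref = "A", alt = "G")
  expect_error(map_to_bands(v_bad, b), "no cytoband")
  expect_error(remm_cytobands(data.frame(chrom = "c", start = c(0, 50),
                                         end = c(60, 100),
                                         band = c("a", "b"))),
               "overlapping")
})

test_that("VCF scoring emits the REMM INFO key from a track", {
  vcf <- write_tiny_vcf(withr::local_tempfile(fileext = ".vcf"), list(
    list(chrom = "c1", pos = 5, ref = "A", alt = "G"),
    list(chrom = "c1", pos = 999, ref = "C", alt = "T")))
  tr <- write_score_track(data.frame(chrom = "c1", pos = 5L, score = 0.42),
                          withr::local_tempfile(fileext = ".tsv"))
  out <- withr::local_tempfile(fileext = ".vcf.gz")
  scores <- score_vcf(vcf, tr, out)
  expect_equal(scores, c(0.42, NA))
  lines <- readLines(gzfile(out))
  body <- grep("^[^#]", lines, value = TRUE)
  expect_match(body[1], "REMM=0.420")
  expect_match(body[2], "REMM=\\.")
  expect_true(any(grepl("ID=REMM", lines)))
})
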