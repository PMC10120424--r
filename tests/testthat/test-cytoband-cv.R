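test_that("greedy fold assignment balances pathogenic counts", {
  bands <- paste0("b", 1:4)
  # symmetric case: [5,5,5,5] into 2 folds -> 10 per fold
  fa <- assign_folds(bands, setNames(c(5, 5, 5, 5), bands), n_folds = 2,
                     seed = 1)
  load <- tapply(c(5, 5, 5, 5)[match(fa$band, bands)], fa$fold, sum)
  expect_equal(unname(as.vector(load)), c(10, 10))

  # greedy: [7,1,1,1] into 2 folds -> {7} vs {1,1,1}
  fa2 <- assign_folds(bands, setNames(c(7, 1, 1, 1), bands), n_folds = 2,
                      seed = 1)
  big_fold <- fa2$fold[fa2$band == "b1"]
  expect_true(all(fa2$fold[fa2$band != "b1"] != big_fold))

  expect_error(assign_folds(character(0), integer(0), 2, 1), "empty band")
  expect_error(assign_folds(bands, setNames(c(1, 0, 0, 0), bands),
                            n_folds = 2), "fewer pathogenic")
})

test_that("fold spread is bounded by the largest single-band count", {
  set.seed(13)
  for (rep in 1:10) {
    n_bands <- sample(10:40, 1)
    bands <- paste0("b", seq_len(n_bands))
    counts <- rpois(n_bands, 3)
    counts[1] <- counts[1] + 10 # ensure enough positives
    fa <- assign_folds(bands, setNames(counts, bands), n_folds = 5,
                       seed = rep)
    load <- vapply(1:5, function(f)
      sum(counts[match(fa$band[fa$fold == f], bands)]), numeric(1))
    expect_lte(max(load) - min(load), max(counts))
    expect_true(all(!is.na(fa$fold)))
  }
})

test_that("cross-validation scores every variant once, leak-free, reproducibly", {
  sim <- small_sim(seed = 14)
  cv <- cross_validate(sim$variants, sim$features, sim$bands,
                       small_config(seed = 14), n_folds = 3, seed = 14)
  expect_s3_class(cv, "remm_cv")
  # bijection: one held-out score per training variant
  expect_equal(nrow(cv$scores), nrow(sim$variants))
  expect_false(anyNA(cv$scores$score))
  # all variants of one band share a fold (the leakage guard)
  expect_true(all(tapply(cv$scores$fold, cv$scores$band,
                         function(f) length(unique(f))) == 1L))
  # the fold of each variant matches the band-level assignment
  fa <- cv$fold_assignment
  expect_equal(cv$scores$fold,
               fa$fold[match(cv$scores$band, fa$band)])
  expect_length(cv$models, 3L)

  cv2 <- cross_validate(sim$variants, sim$features, sim$bands,
                        small_config(seed = 14), n_folds = 3, seed = 14)
  expect_identical(cv$scores$score, cv2$scores$score)
})

test_that("held-out variants are never seen by their scoring model", {
  # direct leakage check: rescoring fold f's variants with the fold-f model
  # reproduces the held-out scores, and that model's stored training sizes
  # exclude fold f entirely
  sim <- small_sim(seed = 15)
  cv <- cross_validate(sim$variants, sim$features, sim$bands,
                       small_config(seed = 15), n_folds = 3, seed = 15)
  f <- 2L
  te <- which(cv$scores$fold == f)
  m <- cv$models[[f]]
  rescored <- predict(m, sim$features[te])
  expect_equal(unname(rescored), cv$scores$score[te], tolerance = 1e-12)
  n_train <- sum(cv$scores$fold != f)
  expect_equal(m$n_minority + m$n_majority, n_train)
})

test_that("a fold holding all positives aborts with a clear error", {
  sim <- small_sim(seed = 16)
  v <- sim$variants
  # relocate every positive into one band's interval
  b <- sim$bands[1, ]
  pos_idx <- which(v$label == 1L)
  v$chrom[pos_idx] <- b$chrom
  v$pos[pos_idx] <- as.integer(b$start + seq_along(pos_idx))
  keep <- !duplicated(v[c("chrom", "pos")])
  v <- v[keep, ]
  feats <- sim$features[which(keep)]
  expect_error(
    cross_validate(v, feats, sim$bands, small_config(), n_folds = 2,
                   seed = 1),
    "no pathogenic variants for training")
})

test_that("the final track substitutes held-out scores at training positions", {
  sim <- small_sim(seed = 18)
  cv <- cross_validate(sim$variants, sim$features, sim$bands,
                       small_config(seed = 18), n_folds = 3, seed = 18)
  imp <- fit_imputer(sim$features)
  general <- fit_hypersmurf(impute_features(sim$features, imp),
                            sim$variants$label, small_config(seed = 18),
                            imputer = imp)
  rec <- make_final_track(general, cv, sim$variants, sim$features)
  expect_equal(nrow(rec), nrow(sim$variants))
  # training positions carry the CV score, not the general-model score
  expect_equal(rec$score,
               cv$scores$score[match(paste(rec$chrom, rec$pos),
                                     paste(cv$scores$chrom,
                                           cv$scores$pos))])
  gen_scores <- predict(general, sim$features)
  expect_gt(sum(abs(rec$score - gen_scores) > 1e-8), 0) # they do differ

  # written form satisfies the track invariants
  tr <- make_final_track(general, cv, sim$variants, sim$features,
                         path = withr::local_tempfile(fileext = ".tsv"))
  back <- read_score_track(tr)
  expect_true(all(back$score >= 0 & back$score <= 1))
  expect_true(all(tapply(back$pos, back$chrom, function(p) !is.unsorted(p))))

  # a training position missing from the CV result is an error
  cv_broken <- cv
  cv_broken$scores <- cv$scores[-1, ]
  expect_error(make_final_track(general, cv_broken, sim$variants,
                                sim$features), "without a cross-validation")
})

test_that("unlabeled positions fall back to the general model", {
  sim <- small_sim(seed = 19)
  cv <- cross_validate(sim$variants, sim$features, sim$bands,
                       small_config(seed = 19), n_folds = 3, seed = 19)
  imp <- fit_imputer(sim$features)
  general <- fit_hypersmurf(impute_features(sim$features, imp),
                            sim$variants$label, small_config(seed = 19),
                            imputer = imp)
  v <- sim$variants
  v$label[1:10] <- NA # pretend these are non-training positions
  v$pos[1:10] <- v$pos[1:10] + 1L # move off the training coordinates
  keep <- !duplicated(v[c("chrom", "pos")])
  v <- v[keep, ]
  feats <- sim$features[which(keep)]
  rec <- make_final_track(general, cv, v, feats)
  gen <- predict(general, feats)
  expect_equal(rec$score[1:10], gen[1:10])
})

test_that("repeated cross-validation summarises AUPRC across seeds", {
  sim <- small_sim(seed = 20)
  rep3 <- cross_validate_repeated(sim$variants, sim$features, sim$bands,
                                  small_config(), n_folds = 3,
                                  seeds = c(1, 2, 3), pick = 2)
  expect_equal(nrow(rep3$runs), 3L)
  expect_true(all(is.finite(rep3$runs$auprc)))
  expect_equal(rep3$mean_auprc, mean(rep3$runs$auprc))
  expect_s3_class(rep3$picked, "remm_cv")
  expect_equal(rep3$picked$seed, 2)
})
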