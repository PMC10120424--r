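# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles are deliberately naive (exhaustive loops) so they cannot
# share a defect with the implementation they check.

# Exhaustive k-nearest-neighbour sets (Euclidean, self excluded).
oracle_knn <- function(m, k) {
  n <- nrow(m)
  lapply(seq_len(n), function(i) {
    d2 <- colSums((t(m) - m[i, ])^2)
    d2[i] <- Inf
    order(d2)[seq_len(k)]
  })
}

# AUROC as the Mann-Whitney pairwise statistic (ties count 0.5).
oracle_auroc <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (n in ns)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(ps) * length(ns))
}

# Range lookup by linear scan.
oracle_lookup <- function(records, chrom, start, end) {
  hit <- records$chrom == chrom & records$pos >= start & records$pos <= end
  out <- records[hit, c("chrom", "pos", "score")]
  out[order(out$pos), , drop = FALSE]
}

# Best F-beta threshold by scanning every unique score plus sentinels,
# computing precision/recall from first principles at each cutoff.
oracle_best_threshold <- function(scores, labels, beta) {
  ths <- sort(unique(c(0, 1, scores)))
  fb <- vapply(ths, function(t) {
    tp <- sum(scores >= t & labels == 1)
    fp <- sum(scores >= t & labels == 0)
    fn <- sum(scores < t & labels == 1)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- tp / (tp + fn)
    if (p + r == 0) 0 else (1 + beta^2) * p * r / (beta^2 * p + r)
  }, numeric(1))
  max(ths[fb == max(fb)])
}

# Small feature matrix with a trivial 3-feature metadata table.
tiny_metadata <- function(policies = c("mean", "zero", "one")) {
  data.frame(feature = paste0("f", seq_along(policies)),
             category = "sequence", impute = policies)
}

tiny_features <- function(values, policies = NULL) {
  if (is.null(policies)) policies <- rep("mean", ncol(values))
  colnames(values) <- paste0("f", seq_len(ncol(values)))
  remm_features(values, tiny_metadata(policies))
}

# Desk-scale simulation small enough for unit tests.
small_sim <- function(seed = 1, ...) {
  simulate_dataset(sim_config(n_pos = 30, imbalance = 40, n_bands = 10,
                              n_chromosomes = 2, seed = seed, ...))
}

small_config <- function(seed = 1, ...) {
  hypersmurf_config(n_partitions = 4, trees_per_forest = 10, smote_k = 3,
                    seed = seed, ...)
}

# Minimal VCF writer for fixtures (plain text, header + records).
write_tiny_vcf <- function(path, rows) {
  lines <- c("##fileformat=VCFv4.2",
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
             vapply(rows, function(r)
               paste(r$chrom, r$pos, ".", r$ref, r$alt, ".", ".", ".",
                     sep = "\t"), character(1)))
  writeLines(lines, path)
  path
}
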