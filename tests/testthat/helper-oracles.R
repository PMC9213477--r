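# Independent brute-force oracles used across the suite. These work on
# plain data.frames in BED coordinates and never call the package's
# interval machinery.

# data.frame view of a peak GRanges in BED coordinates
peaks_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = bed_start(gr), end = bed_end(gr),
             score = if ("score" %in% names(S4Vectors::mcols(gr)))
               S4Vectors::mcols(gr)$score else rep(0, length(gr)),
             name = if ("name" %in% names(S4Vectors::mcols(gr)))
               S4Vectors::mcols(gr)$name else rep(NA_character_, length(gr)),
             stringsAsFactors = FALSE, row.names = NULL)
}

# >= 1 bp overlap of half-open intervals
ovl1 <- function(c1, s1, e1, c2, s2, e2) c1 == c2 & s1 < e2 & s2 < e1

# brute-force greedy consolidation: repeatedly keep the highest-scoring
# remaining peak (ties: earlier chrom/start/end) and delete overlappers
oracle_consolidate <- function(df) {
  kept <- integer(0)
  alive <- seq_len(nrow(df))
  while (length(alive) > 0) {
    sub <- df[alive, ]
    best <- alive[order(-sub$score, sub$chrom, sub$start, sub$end)[1]]
    kept <- c(kept, best)
    alive <- alive[!ovl1(df$chrom[alive], df$start[alive], df$end[alive],
                         df$chrom[best], df$start[best], df$end[best])]
  }
  sort(kept)
}

# quadratic all-pairs any-overlap mask
oracle_overlaps_any <- function(q, s) {
  vapply(seq_len(nrow(q)), function(i) {
    any(ovl1(q$chrom[i], q$start[i], q$end[i], s$chrom, s$start, s$end))
  }, logical(1))
}

# random scored peak data.frame on a small genome
random_peaks_df <- function(n, n_chrom = 2, span = 2000, max_w = 300) {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = paste0("chr", sample.int(n_chrom, n, replace = TRUE)),
             start = start,
             end = start + sample.int(max_w, n, replace = TRUE),
             score = round(stats::runif(n, 0, 100), 3),
             stringsAsFactors = FALSE)
}

df_to_gr <- function(df) {
  peak_set(df$chrom, df$start, df$end, score = df$score,
           name = sprintf("p%03d", seq_len(nrow(df))))
}

# independent re-application of the consensus selection rule to logged
# per-fold importances/coefficients (spec rules (b)-(e))
oracle_consensus <- function(fold_log, top_fraction, lasso_min_folds,
                             consensus_min_methods) {
  feats <- rownames(fold_log$rf)
  p <- length(feats)
  k <- min(p, ceiling(top_fraction * p))
  rf_mean <- apply(fold_log$rf, 1, mean)
  svm_mean <- apply(fold_log$svm, 1, mean)
  rf_top <- feats[order(-rf_mean, seq_len(p))[seq_len(k)]]
  rf_set <- intersect(rf_top, feats[rf_mean > 0])
  svm_set <- feats[order(-abs(svm_mean), seq_len(p))[seq_len(k)]]
  lasso_set <- feats[apply(fold_log$lasso != 0, 1, sum) >= lasso_min_folds]
  votes <- vapply(feats, function(f) {
    (f %in% rf_set) + (f %in% svm_set) + (f %in% lasso_set)
  }, numeric(1))
  feats[votes >= consensus_min_methods]
}

# small simulated world shared by several test files (kept small for speed)
small_sim_world <- function(seed = 101, n_regions = 500) {
  cfg <- sim_config(n_regions = n_regions, samples_per_type = 8,
                    blood_samples_per_celltype = 4, seed = seed)
  sim <- simulate_atac(cfg)
  cpm <- cpm_normalize(sim$counts)
  sheet <- sim$sample_sheet
  blood <- weighted_blood_mean(
    cpm[, sheet$sample_id[sheet$label == "PBMC"], drop = FALSE],
    cpm[, sheet$sample_id[sheet$label == "neutrophil"], drop = FALSE])
  list(cfg = cfg, sim = sim, cpm = cpm, sheet = sheet, blood = blood)
}
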