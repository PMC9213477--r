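make_track <- function(ids, scores) {
  structure(data.frame(region_id = ids, tumor_mean = 1,
                       blood_weighted_mean = 1, relaccs = scores,
                       stringsAsFactors = FALSE),
            class = c("relaccs_track", "data.frame"))
}

test_that("rank_markers assigns peak RelAccS and sorts ascending", {
  peaks <- peak_set(c("chr1", "chr1", "chr2"), c(0, 1000, 0),
                    c(501, 1501, 501), name = c("pk1", "pk2", "pk3"))
  track <- make_track(c("pk1", "pk2", "pk3"), c(0.5, -3.2, -1.0))
  markers <- data.frame(chrom = c("chr1", "chr1", "chr2", "chr3"),
                        start = c(100, 1200, 250, 0),
                        end = c(101, 1201, 251, 1),
                        name = c("m1", "m2", "m3", "m_outside"))
  ranked <- rank_markers(markers, peaks, track)
  expect_equal(ranked$name, c("m2", "m3", "m1"))
  expect_equal(ranked$relaccs, c(-3.2, -1.0, 0.5))
  expect_false("m_outside" %in% ranked$name)
  # ranking is a permutation of the overlap-surviving subset
  expect_setequal(ranked$name, c("m1", "m2", "m3"))
  # overlapping peak universe rejected
  bad <- peak_set(c("chr1", "chr1"), c(0, 400), c(501, 901),
                  name = c("a", "b"))
  expect_error(rank_markers(markers, bad, track), "consolidate")
})

test_that("marker-peak assignment matches an all-pairs oracle", {
  set.seed(17)
  for (i in 1:10) {
    pdf <- random_peaks_df(15)
    peaks <- consolidate_nonoverlapping(df_to_gr(pdf))
    kdf <- peaks_df(peaks)
    track <- make_track(kdf$name, round(rnorm(nrow(kdf)), 3))
    ms <- sample.int(2500, 40)
    markers <- data.frame(chrom = paste0("chr", sample.int(2, 40, TRUE)),
                          start = ms, end = ms + 1,
                          name = sprintf("m%02d", 1:40))
    ranked <- rank_markers(markers, peaks, track)
    hit_o <- oracle_overlaps_any(markers, kdf)
    expect_setequal(ranked$name, markers$name[hit_o])
    expect_false(is.unsorted(ranked$relaccs))
  }
})

test_that("variant quality and germline filters follow the stated rules", {
  v <- data.frame(chrom = "chr1", pos = 1:5, ref = "A", alt = "T",
                  af = c(0.05, 0.05, 0.05, 0.25, 0.05),
                  depth = c(9, 10, 50, 50, 50),
                  mmq = c(60, 50, 49, 60, 60),
                  mbq = c(30, 20, 30, 30, 19))
  q <- filter_variant_quality(v)
  # depth 9 fails; boundary depth 10 / mmq 50 / mbq 20 pass; mmq 49, mbq 19 fail
  expect_equal(q$pos, c(2, 4))
  expect_identical(filter_variant_quality(q), q)  # idempotent
  tumor <- data.frame(chrom = "chr1", pos = c(1, 2), ref = "A", alt = "T",
                      af = c(0.1, 0.4), depth = 100, mmq = 60, mbq = 30)
  cfdna <- data.frame(chrom = "chr1", pos = c(1, 2), ref = "A", alt = "T",
                      af = c(0.1, 0.25), depth = 100, mmq = 60, mbq = 30)
  f <- filter_variants(tumor, cfdna)
  # cfDNA AF 0.25 > 20%: removed from both lists
  expect_equal(f$tumor$pos, 1)
  expect_equal(f$cfdna$pos, 1)
  f2 <- do.call(filter_variants, f)
  expect_identical(f2$tumor, f$tumor)
})

test_that("af concordance groups by RelAccS sign with exact allele matching", {
  peaks <- peak_set(c("chr1", "chr1", "chr1"), c(0, 1000, 2000),
                    c(501, 1501, 2501), name = c("n1", "p1", "z1"))
  track <- make_track(c("n1", "p1", "z1"), c(-1, 1, 0))
  mkv <- function(pos, af, alt = "T") {
    data.frame(chrom = "chr1", pos = pos, ref = "A", alt = alt, af = af,
               depth = 100, mmq = 60, mbq = 30, stringsAsFactors = FALSE)
  }
  tumor <- rbind(mkv(c(10, 20, 30), c(0.1, 0.2, 0.3)),
                 mkv(c(1010, 1020, 1030), c(0.1, 0.2, 0.3)),
                 mkv(2100, 0.5),        # RelAccS == 0: excluded
                 mkv(40, 0.4, alt = "G"))  # allele mismatch vs cfDNA below
  cfdna <- rbind(mkv(c(10, 20, 30), c(0.1, 0.2, 0.3)),
                 mkv(c(1010, 1020, 1030), c(0.3, 0.1, 0.2)),
                 mkv(2100, 0.5),
                 mkv(40, 0.4, alt = "C"))
  out <- af_concordance_by_relaccs(tumor, cfdna, peaks, track)
  expect_equal(out$n_neg, 3)
  expect_equal(out$n_pos, 3)
  expect_equal(out$r_neg, 1)          # identical AFs
  expect_lt(out$r_pos, 1)
  expect_false(any(out$detected$pos == 40))  # alt mismatch not "detected in both"
  # a group with < 3 variants reports NA
  out2 <- af_concordance_by_relaccs(tumor[1:3, ], cfdna[1:3, ], peaks, track)
  expect_equal(out2$r_neg, 1)
  expect_true(is.na(out2$r_pos))
})

test_that("synthetic cohorts reproduce higher concordance at RelAccS < 0", {
  w <- small_sim_world(seed = 404, n_regions = 400)
  sheet <- w$sheet
  track <- compute_relaccs(w$cpm[, sheet$sample_id[sheet$label == "cancerA"],
                                 drop = FALSE], w$blood)
  wins <- 0L
  for (s in 1:20) {
    coh <- simulate_variant_cohort(w$sim$regions, track, w$cfg, seed = s)
    f <- filter_variants(coh$tumor, coh$cfdna)
    cc <- af_concordance_by_relaccs(f$tumor, f$cfdna, w$sim$regions, track)
    wins <- wins + (cc$r_neg > cc$r_pos)
  }
  expect_gte(wins, 18L)
  # zero noise: both correlations are 1
  cfg0 <- w$cfg; cfg0$af_noise_sd_neg <- 0; cfg0$af_noise_sd_pos <- 0
  coh0 <- simulate_variant_cohort(w$sim$regions, track, cfg0, seed = 1)
  cc0 <- af_concordance_by_relaccs(coh0$tumor, coh0$cfdna, w$sim$regions, track)
  expect_equal(cc0$r_neg, 1, tolerance = 1e-12)
  expect_equal(cc0$r_pos, 1, tolerance = 1e-12)
})
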