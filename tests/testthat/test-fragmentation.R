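test_that("region_fragment_stats computes depth and median length", {
  regions <- peak_set(c("chr1", "chr1"), c(0, 1000), c(500, 1500),
                      name = c("r1", "r2"))
  frags <- peak_set(rep("chr1", 5), c(10, 50, 100, 1100, 1200),
                    c(110, 200, 300, 1200, 1400))
  S4Vectors::mcols(frags) <- NULL
  st <- region_fragment_stats(frags, regions)
  expect_equal(st$depth, c(3, 2))
  expect_equal(st$median_length, c(150, 150))  # [100,150,200] and [100,200]
  expect_equal(st$n_fragments, c(3L, 2L))
  # empty region flagged NA
  r3 <- peak_set(c("chr1", "chr2"), c(0, 0), c(500, 500), name = c("r1", "r3"))
  st3 <- region_fragment_stats(frags[1:3], r3)
  expect_true(is.na(st3$median_length[2]))
  expect_equal(st3$depth[2], 0)
  # unsorted input rejected
  expect_error(region_fragment_stats(rev(frags), regions), "sorted")
})

test_that("fragment assignment matches the quadratic oracle (any_overlap and midpoint)", {
  set.seed(10)
  for (i in 1:5) {
    rdf <- data.frame(chrom = "chr1",
                      start = seq(0, by = 600, length.out = 20),
                      end = seq(500, by = 600, length.out = 20))
    fs <- sample.int(12500, 500, replace = TRUE)
    fdf <- data.frame(chrom = "chr1", start = fs,
                      end = fs + sample(80:250, 500, replace = TRUE))
    regions <- peak_set(rdf$chrom, rdf$start, rdf$end,
                        name = sprintf("r%02d", 1:20))
    frags <- peak_set(fdf$chrom, fdf$start, fdf$end)
    S4Vectors::mcols(frags) <- NULL
    fdf <- fdf[order(fdf$start), ]
    st <- region_fragment_stats(frags, regions)
    depth_o <- vapply(seq_len(20), function(r) {
      sum(ovl1(fdf$chrom, fdf$start, fdf$end, rdf$chrom[r], rdf$start[r], rdf$end[r]))
    }, numeric(1))
    expect_equal(st$depth, depth_o)
    stm <- region_fragment_stats(frags, regions, assignment = "midpoint")
    mid <- (fdf$start + fdf$end) %/% 2
    depth_m <- vapply(seq_len(20), function(r) {
      sum(mid >= rdf$start[r] & mid < rdf$end[r])
    }, numeric(1))
    expect_equal(stm$depth, depth_m)
  }
})

test_that("normalize_depth rescales to fragments per million", {
  st <- data.frame(region_id = "r1", depth = 50, median_length = 160,
                   n_fragments = 50L)
  expect_equal(normalize_depth(st, 1e6)$depth, 50)
  expect_equal(normalize_depth(st, 2e6)$depth, 25)
  st0 <- st; st0$depth <- 0
  expect_equal(normalize_depth(st0, 1e6)$depth, 0)
  expect_error(normalize_depth(st, 0), "> 0")
})

test_that("compare_low_high is a Welch t-test with directional means", {
  same <- compare_low_high(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  # hand-computable 3+3 Welch case
  a <- c(1, 2, 3); b <- c(7, 9, 11)
  out <- compare_low_high(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(out$t, t_hand, tolerance = 1e-12)
  expect_equal(out$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
  set.seed(6)
  lo <- rnorm(50, 10, 1); hi <- rnorm(50, 0, 1)
  sh <- compare_low_high(lo, hi)
  expect_lt(sh$p_value, 1e-6)
  expect_gt(sh$mean_low, sh$mean_high)
  expect_error(compare_low_high(1, c(1, 2)), ">= 2")
})

test_that("smooth_series reproduces low-order polynomials and matches per-window fits", {
  y_const <- rep(4.2, 30)
  expect_equal(smooth_series(y_const), y_const)
  y_lin <- 2 + 0.5 * (1:40)
  expect_equal(smooth_series(y_lin), as.numeric(y_lin))
  y_quad <- 1 + 0.3 * (1:40) - 0.02 * (1:40)^2
  expect_equal(smooth_series(y_quad), as.numeric(y_quad), tolerance = 1e-8)
  # interior points equal a direct least-squares quadratic on the window
  set.seed(12)
  y <- rnorm(60)
  sm <- smooth_series(y, window = 15, order = 2)
  for (i in c(8, 20, 41, 53)) {
    win <- (i - 7):(i + 7)
    fit <- lm(y[win] ~ poly(win, 2, raw = TRUE))
    expect_equal(sm[i], unname(predict(fit, data.frame(win = i))),
                 tolerance = 1e-8)
  }
  expect_error(smooth_series(rnorm(10), window = 15), "shorter")
  expect_error(smooth_series(rnorm(30), window = 14), "odd")
})

test_that("accessibility-fragmentation correlation detects monotone structure", {
  set.seed(13)
  acc <- sort(runif(300, 4, 500))
  metric <- 5000 / acc  # exact decreasing function
  out <- accessibility_fragmentation_correlation(acc, metric)
  expect_lt(out$r, -0.99)
  # independent metric: |r| small for most seeds
  rs <- replicate(40, {
    accessibility_fragmentation_correlation(runif(1000, 4, 500),
                                            runif(1000, 4, 500))$r
  })
  expect_gte(mean(abs(rs) < 0.15), 0.9)
  # sign invariant to rescaling of either series
  out2 <- accessibility_fragmentation_correlation(acc, metric * 37)
  expect_equal(sign(out2$r), sign(out$r))
  expect_error(accessibility_fragmentation_correlation(acc[1:10], metric[1:10]),
               "window")
})

test_that("simulated cfDNA reproduces the low > high depth and length pattern", {
  w <- small_sim_world(seed = 303, n_regions = 400)
  fr <- simulate_cfdna(w$sim$regions, w$blood, w$cfg, total_fragments = 8e4,
                       seed = 9)
  st <- normalize_depth(region_fragment_stats(fr$fragments, w$sim$regions),
                        length(fr$fragments))
  lab <- classify_accessibility_quartiles(w$blood)
  cd <- compare_low_high(st$depth[lab == "low"], st$depth[lab == "high"])
  cl <- compare_low_high(st$median_length[lab == "low"],
                         st$median_length[lab == "high"])
  expect_gt(cd$mean_low, cd$mean_high)
  expect_gt(cl$mean_low, cl$mean_high)
  expect_gt(cl$mean_low - cl$mean_high, 20)  # 190 vs 140 bp length model
})
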