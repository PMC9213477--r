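#' Per-region cfDNA fragment statistics
#'
#' Assigns fragments to regions (by any >= 1 bp overlap, the default, or by
#' fragment midpoint) and reports per-region fragment depth and median
#' fragment length (mean of the middle two for even counts). Regions with
#' no assigned fragments get `median_length = NA`.
#'
#' @param fragments `GRanges` of fragment intervals, sorted by coordinate.
#' @param regions `GRanges` region set, sorted by coordinate.
#' @param assignment `"any_overlap"` or `"midpoint"`.
#' @return data.frame with `region_id`, `depth`, `median_length`,
#'   `n_fragments`.
#' @export
region_fragment_stats <- function(fragments, regions,
                                  assignment = c("any_overlap", "midpoint")) {
  assignment <- match.arg(assignment)
  .check_sorted <- function(gr, what) {
    if (length(gr) > 1L) {
      ord <- order(as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr), GenomicRanges::end(gr))
      if (is.unsorted(ord)) stop(what, " must be sorted by (chrom, start, end)")
    }
  }
  .check_sorted(fragments, "fragments")
  .check_sorted(regions, "regions")
  ids <- S4Vectors::mcols(regions)$name
  if (is.null(ids)) ids <- sprintf("%s:%d-%d",
                                   as.character(GenomicRanges::seqnames(regions)),
                                   bed_start(regions), bed_end(regions))
  qry <- if (assignment == "midpoint") {
    # midpoint defined in BED coordinates: (start0 + end0) %/% 2
    mid0 <- (bed_start(fragments) + bed_end(fragments)) %/% 2L
    GenomicRanges::GRanges(GenomicRanges::seqnames(fragments),
                           IRanges::IRanges(mid0 + 1L, mid0 + 1L))
  } else {
    fragments
  }
  hits <- suppressWarnings(GenomicRanges::findOverlaps(qry, regions))
  lens <- GenomicRanges::width(fragments)[S4Vectors::queryHits(hits)]
  by_region <- split(lens, factor(S4Vectors::subjectHits(hits),
                                  levels = seq_along(regions)))
  n <- lengths(by_region)
  med <- vapply(by_region, function(v) {
    if (length(v) == 0L) NA_real_ else stats::median(v)
  }, numeric(1))
  data.frame(region_id = ids, depth = as.numeric(n), median_length = med,
             n_fragments = as.integer(n), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Depth normalization to total library fragments
#'
#' `depth' = depth * 1e6 / total_fragments` (fragments per million),
#' making depth comparable across samples of different sequencing depth.
#'
#' @param stats output of [region_fragment_stats()].
#' @param total_fragments total fragments in the library (> 0).
#' @return `stats` with rescaled `depth`.
#' @export
normalize_depth <- function(stats, total_fragments) {
  if (total_fragments <= 0) stop("total_fragments must be > 0")
  stats$depth <- stats$depth * 1e6 / total_fragments
  stats
}

#' Compare a metric between low- and high-accessibility regions
#'
#' Two-sided unpaired Welch t-test with group means for directional
#' reporting (e.g. depth or median fragment length in lowly vs highly
#' accessible regions).
#'
#' @param values_low,values_high numeric vectors (>= 2 finite values each).
#' @return list with `t`, `p_value`, `mean_low`, `mean_high`.
#' @export
compare_low_high <- function(values_low, values_high) {
  values_low <- values_low[is.finite(values_low)]
  values_high <- values_high[is.finite(values_high)]
  if (length(values_low) < 2L || length(values_high) < 2L) {
    stop("need >= 2 finite values per group")
  }
  if (stats::sd(values_low) == 0 && stats::sd(values_high) == 0 &&
      values_low[1] == values_high[1]) {
    return(list(t = 0, p_value = 1, mean_low = mean(values_low),
                mean_high = mean(values_high)))
  }
  tt <- stats::t.test(values_low, values_high, var.equal = FALSE)
  list(t = unname(tt$statistic), p_value = tt$p.value,
       mean_low = mean(values_low), mean_high = mean(values_high))
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing: each point is replaced by the
#' value at its position of a degree-`order` polynomial fit to the
#' `window` points centred on it. Edge points are fit on the truncated
#' window actually available. Polynomials of degree <= `order` are
#' reproduced exactly.
#'
#' @param y numeric series, ordered.
#' @param window odd window size (default 15).
#' @param order polynomial order (default 2; must be < `window`).
#' @return smoothed numeric vector of the same length.
#' @export
smooth_series <- function(y, window = 15L, order = 2L) {
  n <- length(y)
  window <- as.integer(window); order <- as.integer(order)
  if (window %% 2L == 0L) stop("window must be odd")
  if (order >= window) stop("order must be < window")
  if (n < window) stop("series shorter than the smoothing window")
  h <- window %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - h); hi <- min(n, i + h)
    x <- (lo:hi) - i
    V <- outer(x, 0:order, "^")
    beta <- qr.coef(qr(V), y[lo:hi])
    out[i] <- beta[1]  # polynomial evaluated at x = 0
  }
  out
}

#' Smoothed accessibility-fragmentation correlation
#'
#' Reproduces the accessibility-vs-fragmentation correlation analysis:
#' both series are log2-transformed, regions where either log2 value falls
#' below `log2_outlier_floor` are removed as outliers, regions are ordered
#' by accessibility, both series are Savitzky-Golay smoothed (window 15,
#' order 2 by default) and the Pearson correlation of the smoothed series
#' is returned.
#'
#' @param blood_weighted_mean per-region accessibility (positive scale).
#' @param cfdna_metric per-region cfDNA metric (normalized depth or median
#'   fragment length), aligned with `blood_weighted_mean`.
#' @param log2_outlier_floor outlier floor in log2 units (default 1).
#' @param window,order smoothing parameters.
#' @return list with `r`, `n_used`, `n_removed`, and the smoothed series
#'   (`accessibility`, `metric`) for plotting.
#' @export
accessibility_fragmentation_correlation <- function(blood_weighted_mean,
                                                    cfdna_metric,
                                                    log2_outlier_floor = 1.0,
                                                    window = 15L, order = 2L) {
  if (length(blood_weighted_mean) != length(cfdna_metric)) {
    stop("region universes differ in length")
  }
  la <- suppressWarnings(log2(blood_weighted_mean))
  lm_ <- suppressWarnings(log2(cfdna_metric))
  keep <- is.finite(la) & is.finite(lm_) &
    la >= log2_outlier_floor & lm_ >= log2_outlier_floor
  la <- la[keep]; lm_ <- lm_[keep]
  if (length(la) < window) stop("fewer surviving regions than the smoothing window")
  ord <- order(la)
  sa <- smooth_series(la[ord], window, order)
  sm <- smooth_series(lm_[ord], window, order)
  list(r = stats::cor(sa, sm, method = "pearson"),
       n_used = length(la), n_removed = sum(!keep),
       accessibility = sa, metric = sm)
}
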