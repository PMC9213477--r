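#' Build a reproducible cell-type-specific peak set
#'
#' Per-sample peak scores are score-per-million normalized, all samples of
#' the cell type are pooled, and overlapping peaks are trimmed by the same
#' iterative highest-score-first consolidation used per sample. A
#' consolidated peak is retained only when it is supported — overlapped by
#' at least 1 bp by an original per-sample peak with normalized score
#' strictly greater than `min_score` — in at least `min_samples` distinct
#' samples.
#'
#' @param sample_peaksets list of `GRanges`, one per sample, all with the
#'   same fixed peak width.
#' @param min_samples minimum number of distinct supporting samples
#'   (default 2).
#' @param min_score per-sample normalized score a supporting peak must
#'   exceed (default 5).
#' @param cell_type label stored on the result.
#' @return `GRanges` with metadata column `n_supporting_samples` and
#'   attribute-like metadata `cell_type` (in `S4Vectors::metadata`).
#' @export
build_celltype_peakset <- function(sample_peaksets, min_samples = 2L,
                                   min_score = 5, cell_type = "celltype") {
  stopifnot(is.list(sample_peaksets), length(sample_peaksets) >= 1L)
  normed <- lapply(sample_peaksets, normalize_scores_spm)
  for (i in seq_along(normed)) {
    S4Vectors::mcols(normed[[i]])$sample_index <- i
  }
  pooled <- suppressWarnings(do.call(c, unname(normed)))
  consolidated <- consolidate_nonoverlapping(pooled)
  if (length(consolidated) == 0L) {
    warning("cell-type peak set is empty")
    S4Vectors::metadata(consolidated)$cell_type <- cell_type
    return(consolidated)
  }
  strong <- pooled[S4Vectors::mcols(pooled)$score > min_score]
  hits <- suppressWarnings(GenomicRanges::findOverlaps(consolidated, strong))
  supp <- integer(length(consolidated))
  if (length(hits) > 0L) {
    samp <- S4Vectors::mcols(strong)$sample_index[S4Vectors::subjectHits(hits)]
    by_q <- split(samp, factor(S4Vectors::queryHits(hits),
                               levels = seq_along(consolidated)))
    supp <- unname(vapply(by_q, function(s) length(unique(s)), integer(1)))
  }
  S4Vectors::mcols(consolidated)$n_supporting_samples <- supp
  keep <- consolidated[supp >= min_samples]
  S4Vectors::mcols(keep)$sample_index <- NULL
  if (length(keep) == 0L) warning("no peaks pass the reproducibility filter")
  S4Vectors::metadata(keep)$cell_type <- cell_type
  keep
}

#' Build the consensus blood peak set
#'
#' Scores of each cell-type-specific peak set are renormalized
#' (score-per-million within the set), the sets are pooled, and overlapping
#' peaks are removed with the iterative highest-score-first consolidation,
#' yielding a fixed-width, non-overlapping consensus peak set.
#'
#' @param celltype_sets list of `GRanges` (e.g. PBMC, neutrophil, HUVEC
#'   cell-type peak sets).
#' @return sorted, non-overlapping `GRanges`.
#' @export
build_blood_consensus <- function(celltype_sets) {
  stopifnot(is.list(celltype_sets), length(celltype_sets) >= 1L)
  normed <- lapply(celltype_sets, function(g) {
    S4Vectors::mcols(g) <- S4Vectors::mcols(g)[, intersect(c("score", "name"),
                                                           names(S4Vectors::mcols(g))),
                                               drop = FALSE]
    normalize_scores_spm(g)
  })
  pooled <- suppressWarnings(do.call(c, unname(normed)))
  consolidate_nonoverlapping(pooled)
}

#' Weighted blood accessibility mean
#'
#' For each region, the weighted average of the per-cell-type sample means
#' of normalized ATAC-seq counts; neutrophils are weighted 2 and PBMC 1 by
#' default (the approximate 2:1 neutrophil:PBMC abundance in blood):
#' `(mean(PBMC) + 2 * mean(neutrophil)) / 3`.
#'
#' @param pbmc_counts,neut_counts region x sample matrices of normalized
#'   counts with identical region-id rownames.
#' @param weights named numeric vector `c(pbmc = 1, neut = 2)`.
#' @return named numeric vector of per-region weighted means.
#' @export
weighted_blood_mean <- function(pbmc_counts, neut_counts,
                                weights = c(pbmc = 1, neut = 2)) {
  pbmc_counts <- as.matrix(pbmc_counts)
  neut_counts <- as.matrix(neut_counts)
  if (nrow(pbmc_counts) != nrow(neut_counts) ||
      !identical(rownames(pbmc_counts), rownames(neut_counts))) {
    stop("PBMC and neutrophil matrices must share the same region index")
  }
  stopifnot(all(c("pbmc", "neut") %in% names(weights)))
  wm <- (weights[["pbmc"]] * rowMeans(pbmc_counts) +
           weights[["neut"]] * rowMeans(neut_counts)) /
    (weights[["pbmc"]] + weights[["neut"]])
  stats::setNames(as.numeric(wm), rownames(pbmc_counts))
}

#' Classify regions into accessibility quartile groups
#'
#' Rank-based slicing: the `floor(n/4)` lowest-ranked regions are labelled
#' `low` ("lowly accessible"), the `floor(n/4)` highest-ranked `high`
#' ("highly accessible"), everything else `mid`. Rank ties are broken by
#' position for determinism (stable order).
#'
#' @param weighted_mean numeric vector (n >= 4).
#' @return character vector in `{low, mid, high}` along the input.
#' @export
classify_accessibility_quartiles <- function(weighted_mean) {
  n <- length(weighted_mean)
  if (n < 4L) stop("need at least 4 regions to form quartiles")
  k <- n %/% 4L
  ord <- order(weighted_mean)  # stable: ties broken by original position
  lab <- rep("mid", n)
  lab[ord[seq_len(k)]] <- "low"
  lab[ord[seq.int(n - k + 1L, n)]] <- "high"
  stats::setNames(lab, names(weighted_mean))
}
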