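#' Counts-per-million normalization
#'
#' Scales every sample column so it sums to one million:
#' `counts'[r, s] = counts[r, s] * 1e6 / sum_r counts[r, s]`. Idempotent on
#' already-normalized input; preserves the within-sample rank order of
#' regions.
#'
#' @param counts region x sample numeric matrix (raw or cpm).
#' @return cpm matrix with the same dimnames.
#' @export
cpm_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- colSums(counts)
  bad <- which(tot <= 0)
  if (length(bad) > 0L) {
    nm <- colnames(counts)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zero-sum count column(s): ", paste(nm, collapse = ", "))
  }
  sweep(counts, 2L, tot / 1e6, "/")
}

#' Relative Accessibility Score (RelAccS)
#'
#' Per-region log2 ratio of the mean normalized tumor ATAC-seq count to the
#' weighted blood mean:
#' `relaccs[r] = log2((mean_s tumor_cpm[r, s] + eps) / (blood[r] + eps))`.
#' Positive scores mark regions more accessible in tumor than in blood
#' cells; negative scores the reverse. A small pseudocount keeps the score
#' finite at zero counts; `pseudocount = 0` is allowed for strictly
#' positive data.
#'
#' @param tumor_cpm region x sample cpm matrix for one cancer type, or a
#'   precomputed per-region mean vector.
#' @param blood_weighted_mean per-region weighted blood mean (same region
#'   order; names checked when present on both).
#' @param pseudocount pseudocount epsilon in cpm units (default 0.01).
#' @return a `data.frame` of class `relaccs_track` with columns
#'   `region_id`, `tumor_mean`, `blood_weighted_mean`, `relaccs`, and the
#'   pseudocount stored in attribute `pseudocount`.
#' @export
compute_relaccs <- function(tumor_cpm, blood_weighted_mean, pseudocount = 0.01) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  tumor_mean <- if (is.matrix(tumor_cpm) || is.data.frame(tumor_cpm)) {
    rowMeans(as.matrix(tumor_cpm))
  } else {
    tumor_cpm
  }
  if (length(tumor_mean) != length(blood_weighted_mean)) {
    stop("tumor and blood region universes differ in length")
  }
  tn <- names(tumor_mean); bn <- names(blood_weighted_mean)
  if (!is.null(tn) && !is.null(bn) && !identical(tn, bn)) {
    stop("tumor and blood region ids do not match")
  }
  if (pseudocount == 0 && any(blood_weighted_mean == 0 | tumor_mean == 0)) {
    stop("zero counts with pseudocount = 0; use a positive pseudocount")
  }
  ids <- if (!is.null(tn)) tn else if (!is.null(bn)) bn else
    sprintf("region_%d", seq_along(tumor_mean))
  out <- data.frame(
    region_id = ids,
    tumor_mean = as.numeric(tumor_mean),
    blood_weighted_mean = as.numeric(blood_weighted_mean),
    relaccs = log2((as.numeric(tumor_mean) + pseudocount) /
                     (as.numeric(blood_weighted_mean) + pseudocount)),
    stringsAsFactors = FALSE
  )
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("relaccs_track", "data.frame")
  out
}

#' @rdname compute_relaccs
#' @param x a `relaccs_track`.
#' @param path output TSV path.
#' @export
write_relaccs_track <- function(x, path) {
  .write_tsv(as.data.frame(x)[, c("region_id", "tumor_mean",
                                  "blood_weighted_mean", "relaccs")], path)
}

#' @rdname compute_relaccs
#' @export
read_relaccs_track <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                        colClasses = list(character = "region_id")))
  class(df) <- c("relaccs_track", "data.frame")
  df
}
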