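#' Construct a fixed-width peak set from BED-style coordinates
#'
#' Peaks are held as a [GenomicRanges::GRanges] with metadata columns
#' `score` (non-negative real), `name`, optional `summit_offset` (bp offset
#' of the summit from the peak start) and logical `clipped` (peak truncated
#' at a chromosome edge). File formats use 0-based half-open (BED)
#' coordinates; this constructor converts them to the 1-based closed
#' convention GRanges uses internally.
#'
#' @param chrom character vector of chromosome names.
#' @param start0,end0 integer vectors, 0-based half-open interval bounds.
#' @param score numeric peak scores (default 0).
#' @param name optional peak names; auto-generated `chrom:start-end` ids
#'   (BED coordinates) when `NULL`.
#' @param summit_offset optional integer offset of the summit from `start0`.
#' @param sort sort by (chrom, start, end)? Default `TRUE`.
#' @return A `GRanges` of peaks sorted by (chrom, start, end).
#' @export
peak_set <- function(chrom, start0, end0, score = 0, name = NULL,
                     summit_offset = NULL, sort = TRUE) {
  stopifnot(length(start0) == length(end0))
  chrom <- rep_len(as.character(chrom), length(start0))
  if (length(chrom) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr)$score <- numeric(0)
    S4Vectors::mcols(gr)$name <- character(0)
    return(gr)
  }
  if (any(start0 < 0)) stop("peak start must be >= 0")
  if (any(end0 <= start0)) stop("peak end must be > start")
  score <- rep_len(as.numeric(score), length(chrom))
  if (any(score < 0)) stop("peak scores must be non-negative")
  if (is.null(name)) {
    name <- sprintf("%s:%d-%d", chrom, as.integer(start0), as.integer(end0))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = as.integer(start0) + 1L,
                              end = as.integer(end0)),
    score = score,
    name = as.character(name)
  )
  if (!is.null(summit_offset)) {
    S4Vectors::mcols(gr)$summit_offset <- as.integer(summit_offset)
  }
  if (sort) gr <- sort_peaks(gr)
  gr
}

#' Sort a peak set by (chromosome, start, end)
#'
#' Chromosomes are ordered lexicographically by name, independently of any
#' seqlevel ordering carried by the object, so that sorting is reproducible
#' across inputs assembled from different files.
#'
#' @param peaks a `GRanges`.
#' @return the same `GRanges`, reordered.
#' @export
sort_peaks <- function(peaks) {
  if (length(peaks) == 0L) return(peaks)
  ord <- order(as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  peaks[ord]
}

#' BED-style 0-based start/end accessors
#'
#' @param peaks a `GRanges`.
#' @return integer vector of 0-based starts / half-open ends.
#' @export
bed_start <- function(peaks) GenomicRanges::start(peaks) - 1L

#' @rdname bed_start
#' @export
bed_end <- function(peaks) GenomicRanges::end(peaks)

#' Extend peak summits into fixed-width peaks
#'
#' Each summit at 0-based position `p` becomes the interval
#' `[p - flank, p + flank + 1)` (width `2 * flank + 1`, the summit base
#' included), clipped to `[0, chrom_length)`. Clipped peaks are retained and
#' flagged rather than dropped. Records on chromosomes absent from
#' `chrom_sizes` are rejected with a warning.
#'
#' @param summits data.frame with columns `chrom`, `pos` (0-based summit
#'   position) and `score`.
#' @param flank half-width in bp (default 250, giving 501-bp peaks).
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @return `GRanges` peak set with metadata columns `score`, `name`,
#'   `summit_offset`, `clipped`, sorted by coordinate.
#' @export
extend_summits <- function(summits, flank = 250L, chrom_sizes) {
  stopifnot(is.data.frame(summits),
            all(c("chrom", "pos", "score") %in% names(summits)))
  if (flank <= 0) stop("flank must be > 0")
  known <- summits$chrom %in% names(chrom_sizes)
  if (any(!known)) {
    warning(sprintf("dropping %d summit(s) on unknown chromosome(s): %s",
                    sum(!known),
                    paste(unique(summits$chrom[!known]), collapse = ", ")))
    summits <- summits[known, , drop = FALSE]
  }
  if (nrow(summits) == 0L) return(peak_set(character(0), integer(0), integer(0)))
  pos <- as.integer(summits$pos)
  len <- as.integer(chrom_sizes[summits$chrom])
  if (any(pos < 0 | pos >= len)) stop("summit positions must lie within chromosome bounds")
  start0 <- pmax(pos - as.integer(flank), 0L)
  end0 <- pmin(pos + as.integer(flank) + 1L, len)
  gr <- peak_set(summits$chrom, start0, end0, score = summits$score,
                 summit_offset = pos - start0, sort = FALSE)
  S4Vectors::mcols(gr)$clipped <-
    (pos - as.integer(flank) < 0L) | (pos + as.integer(flank) + 1L > len)
  sort_peaks(gr)
}

#' Remove peaks overlapping a blacklist
#'
#' A peak is removed when it shares at least 1 bp with any blacklist
#' interval; half-open adjacency is not overlap. An empty blacklist returns
#' the input unchanged.
#'
#' @param peaks,blacklist `GRanges`.
#' @return the retained peaks, input order preserved.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (length(blacklist) == 0L || length(peaks) == 0L) return(peaks)
  peaks[!overlaps_any(peaks, blacklist)]
}

#' Score-per-million normalization of peak scores
#'
#' Rescales peak scores so they sum to one million:
#' `score_i' = score_i * 1e6 / sum(score)`. Mirrors dividing each score by
#' (total score / 1e6).
#'
#' @param peaks `GRanges` with a `score` column.
#' @return the peak set with normalized scores.
#' @export
normalize_scores_spm <- function(peaks) {
  if (length(peaks) == 0L) return(peaks)
  s <- S4Vectors::mcols(peaks)$score
  total <- sum(s)
  if (!is.finite(total) || total <= 0) {
    stop("cannot score-per-million normalize: total peak score is zero")
  }
  S4Vectors::mcols(peaks)$score <- s * 1e6 / total
  peaks
}

#' Iterative non-overlapping peak consolidation
#'
#' Greedy retention by descending score: the highest-scoring peak is kept
#' and every peak overlapping it (>= 1 bp) is removed; the process repeats
#' on the remainder until no peaks are left. Equivalently, peaks are visited
#' in decreasing score order and kept iff they overlap no already-kept peak.
#' Ties in score are broken in favor of the earlier (chrom, start, end)
#' peak, so the result is invariant to input ordering.
#'
#' @param peaks scored `GRanges`.
#' @return the retained peaks, sorted by coordinate; pairwise
#'   non-overlapping per chromosome.
#' @export
consolidate_nonoverlapping <- function(peaks) {
  n <- length(peaks)
  if (n <= 1L) return(sort_peaks(peaks))
  sc <- S4Vectors::mcols(peaks)$score
  ord <- order(-sc, as.character(GenomicRanges::seqnames(peaks)),
               GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  hits <- GenomicRanges::findOverlaps(peaks, peaks)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  keep_self <- qh != sh
  partners <- split(sh[keep_self], factor(qh[keep_self], levels = seq_len(n)))
  removed <- logical(n)
  kept <- logical(n)
  for (i in ord) {
    if (removed[i]) next
    kept[i] <- TRUE
    removed[partners[[i]]] <- TRUE
  }
  sort_peaks(peaks[kept])
}

#' Per-query any-overlap mask
#'
#' `mask[i]` is `TRUE` iff query interval `i` shares at least 1 bp with any
#' subject interval (chromosome-aware; half-open adjacency in BED
#' coordinates is not overlap).
#'
#' @param query,subject `GRanges`.
#' @return logical vector along `query`.
#' @export
overlaps_any <- function(query, subject) {
  # objects assembled from different files may have disjoint seqlevels;
  # that is an ordinary "no overlap", not worth a warning
  suppressWarnings(as.logical(IRanges::overlapsAny(query, subject)))
}
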