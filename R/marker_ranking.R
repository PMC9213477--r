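#' Rank marker regions by RelAccS
#'
#' Markers (recurrent mutations or DMRs, BED-style 0-based half-open
#' intervals; a point mutation occupies 1 bp) are intersected with a
#' non-overlapping peak universe; markers outside every peak are dropped,
#' the rest inherit the RelAccS of their overlapping peak, and the list is
#' sorted ascending — the lowest (most negative) RelAccS is the highest
#' priority for cfDNA representation.
#'
#' @param markers data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), optional `name`, `marker_type`.
#' @param peaks non-overlapping `GRanges` peak universe with a `name`
#'   column matching `track$region_id`.
#' @param track `relaccs_track` over the peak universe.
#' @return the surviving markers with `assigned_peak_id` and `relaccs`
#'   columns, sorted by ascending RelAccS (ties by chrom/start).
#' @export
rank_markers <- function(markers, peaks, track) {
  stopifnot(all(c("chrom", "start", "end") %in% names(markers)))
  red <- GenomicRanges::reduce(peaks)
  if (length(red) != length(peaks)) {
    stop("peak universe contains overlapping peaks; consolidate first")
  }
  peak_ids <- S4Vectors::mcols(peaks)$name
  if (is.null(peak_ids)) stop("peaks must carry a name column")
  mgr <- peak_set(markers$chrom, markers$start, markers$end, sort = FALSE)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(mgr, peaks, select = "first"))
  keep <- !is.na(hits)
  out <- markers[keep, , drop = FALSE]
  out$assigned_peak_id <- peak_ids[hits[keep]]
  out$relaccs <- track$relaccs[match(out$assigned_peak_id, track$region_id)]
  ord <- order(out$relaccs, out$chrom, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Variant quality filter
#'
#' Removes variants failing `depth < min_depth`, `mmq < min_mmq` or
#' `mbq < min_mbq` (strict inequalities: boundary values pass). Idempotent.
#'
#' @param variants variant data.frame (`chrom`, `pos`, `ref`, `alt`, `af`,
#'   `depth`, `mmq`, `mbq`).
#' @param min_depth,min_mmq,min_mbq quality thresholds (defaults 10/50/20).
#' @return the surviving rows.
#' @export
filter_variant_quality <- function(variants, min_depth = 10, min_mmq = 50,
                                   min_mbq = 20) {
  keep <- !(variants$depth < min_depth | variants$mmq < min_mmq |
              variants$mbq < min_mbq)
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = "|")

#' Paired tumor / cfDNA variant filtering
#'
#' Applies the quality filter to both lists, then removes putative germline
#' variants — those whose cfDNA allele fraction exceeds `germline_af`
#' (default 20%) — from *both* the cfDNA and the matched tumor list
#' (matching on chrom/pos/ref/alt).
#'
#' @param tumor,cfdna variant data.frames.
#' @param min_depth,min_mmq,min_mbq quality thresholds.
#' @param germline_af cfDNA AF above which a variant is treated as
#'   germline (strict `>`; default 0.20).
#' @return list with filtered `tumor` and `cfdna` data.frames.
#' @export
filter_variants <- function(tumor, cfdna, min_depth = 10, min_mmq = 50,
                            min_mbq = 20, germline_af = 0.20) {
  tumor <- filter_variant_quality(tumor, min_depth, min_mmq, min_mbq)
  cfdna <- filter_variant_quality(cfdna, min_depth, min_mmq, min_mbq)
  germ <- .variant_key(cfdna)[cfdna$af > germline_af]
  tumor <- tumor[!.variant_key(tumor) %in% germ, , drop = FALSE]
  cfdna <- cfdna[!.variant_key(cfdna) %in% germ, , drop = FALSE]
  rownames(tumor) <- NULL; rownames(cfdna) <- NULL
  list(tumor = tumor, cfdna = cfdna)
}

#' Tumor-cfDNA allele-frequency concordance stratified by RelAccS sign
#'
#' Variants detected in both tumor and matched cfDNA (exact
#' chrom/pos/ref/alt match; `pos` is 1-based) are assigned the RelAccS of
#' their overlapping peak and split into a RelAccS > 0 and a RelAccS < 0
#' group (score exactly 0 or no overlapping peak: excluded). Within each
#' group the Pearson correlation between tumor AF and cfDNA AF is
#' computed; groups with fewer than 3 variants report `NA`.
#'
#' @param tumor,cfdna variant data.frames (already filtered).
#' @param peaks non-overlapping peak universe with `name` column.
#' @param track `relaccs_track` over the peak universe.
#' @return list with `r_neg`, `n_neg`, `r_pos`, `n_pos` and the matched
#'   per-variant table `detected`.
#' @export
af_concordance_by_relaccs <- function(tumor, cfdna, peaks, track) {
  kt <- .variant_key(tumor); kc <- .variant_key(cfdna)
  common <- intersect(kt, kc)
  t2 <- tumor[match(common, kt), , drop = FALSE]
  c2 <- cfdna[match(common, kc), , drop = FALSE]
  detected <- data.frame(chrom = t2$chrom, pos = t2$pos, ref = t2$ref,
                         alt = t2$alt, af_tumor = t2$af, af_cfdna = c2$af,
                         stringsAsFactors = FALSE)
  if (nrow(detected) > 0L) {
    vgr <- peak_set(detected$chrom, detected$pos - 1L, detected$pos,
                    sort = FALSE)
    hit <- suppressWarnings(GenomicRanges::findOverlaps(vgr, peaks,
                                                        select = "first"))
    peak_ids <- S4Vectors::mcols(peaks)$name
    detected$relaccs <- track$relaccs[match(peak_ids[hit], track$region_id)]
  } else {
    detected$relaccs <- numeric(0)
  }
  grp_r <- function(mask) {
    if (sum(mask, na.rm = TRUE) < 3L) return(NA_real_)
    stats::cor(detected$af_tumor[which(mask)], detected$af_cfdna[which(mask)],
               method = "pearson")
  }
  neg <- !is.na(detected$relaccs) & detected$relaccs < 0
  pos <- !is.na(detected$relaccs) & detected$relaccs > 0
  list(r_neg = grp_r(neg), n_neg = sum(neg),
       r_pos = grp_r(pos), n_pos = sum(pos),
       detected = detected)
}
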