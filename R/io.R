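#' @importFrom data.table fread fwrite data.table as.data.table :=
NULL

# shared float format for TSV output: 6 significant digits
.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .fmt_num)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA",
                     eol = "\n")
  invisible(path)
}

#' Read / write ENCODE narrowPeak files
#'
#' narrowPeak is 10-column BED6+4: chrom, start, end, name, score, strand,
#' signalValue, pValue (-log10), qValue (-log10), peak (summit offset from
#' start, -1 if absent). `score_column` selects which column feeds the peak
#' `score` used downstream: `5` (integer display score, the default) or
#' `8` (the -log10 p-value column).
#'
#' @param path file path.
#' @param score_column 5 or 8.
#' @return `GRanges` with `score`, `name`, `summit_offset`, `signal`,
#'   `pvalue`, `qvalue` metadata columns, sorted.
#' @export
read_narrowpeak <- function(path, score_column = 5) {
  if (!score_column %in% c(5, 8)) stop("score_column must be 5 or 8")
  cols <- c("chrom", "start", "end", "name", "score", "strand",
            "signal", "pvalue", "qvalue", "peak")
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = cols, colClasses = list(character = c(1, 4, 6)))
  sc <- if (score_column == 5) dt$score else dt$pvalue
  so <- ifelse(dt$peak < 0, NA_integer_, as.integer(dt$peak))
  gr <- peak_set(dt$chrom, dt$start, dt$end, score = sc, name = dt$name,
                 summit_offset = so, sort = FALSE)
  S4Vectors::mcols(gr)$signal <- dt$signal
  S4Vectors::mcols(gr)$pvalue <- dt$pvalue
  S4Vectors::mcols(gr)$qvalue <- dt$qvalue
  sort_peaks(gr)
}

#' @rdname read_narrowpeak
#' @param peaks `GRanges` peak set.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- sort_peaks(peaks)
  mc <- S4Vectors::mcols(peaks)
  get_or <- function(col, default) if (col %in% names(mc)) mc[[col]] else rep(default, length(peaks))
  so <- get_or("summit_offset", NA_integer_)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = bed_start(peaks),
    end = bed_end(peaks),
    name = get_or("name", "."),
    score = .fmt_num(get_or("score", 0)),
    strand = ".",
    signal = .fmt_num(get_or("signal", 0)),
    pvalue = .fmt_num(get_or("pvalue", -1)),
    qvalue = .fmt_num(get_or("qvalue", -1)),
    peak = ifelse(is.na(so), -1L, as.integer(so)),
    stringsAsFactors = FALSE
  )
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read / write BED files
#'
#' BED3 (chrom/start/end) or BED6 (+ name/score/strand). Browser-facing BED
#' scores are clamped to \[0, 1000\]; pass `clamp_score = FALSE` to keep
#' full precision (e.g. for RelAccS-scored BEDs read back by this package).
#'
#' @param path file path.
#' @return `GRanges`, sorted; BED6 carries `name` and `score`.
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3) stop("BED file must have >= 3 columns: ", path)
  if (ncol(dt) >= 5) {
    # scores may be signed (e.g. RelAccS-scored BED): bypass the
    # non-negativity check peak constructors apply to caller scores
    gr <- peak_set(as.character(dt[[1]]), dt[[2]], dt[[3]],
                   name = as.character(dt[[4]]), sort = FALSE)
    S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(dt[[5]]))
    sort_peaks(gr)
  } else if (ncol(dt) == 4) {
    peak_set(as.character(dt[[1]]), dt[[2]], dt[[3]], name = as.character(dt[[4]]))
  } else {
    peak_set(as.character(dt[[1]]), dt[[2]], dt[[3]])
  }
}

#' @rdname read_bed
#' @param regions `GRanges`.
#' @param clamp_score clamp scores into \[0, 1000\] (browser BED spec)?
#' @export
write_bed <- function(regions, path, clamp_score = FALSE) {
  regions <- sort_peaks(regions)
  mc <- S4Vectors::mcols(regions)
  sc <- if ("score" %in% names(mc)) mc$score else rep(0, length(regions))
  if (clamp_score) sc <- pmin(pmax(sc, 0), 1000)
  nm <- if ("name" %in% names(mc)) mc$name else rep(".", length(regions))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(regions)),
    start = bed_start(regions),
    end = bed_end(regions),
    name = nm,
    score = .fmt_num(sc),
    strand = ".",
    stringsAsFactors = FALSE
  )
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read / write region x sample count matrices
#'
#' TSV with a `region_id` first column and one column per sample.
#'
#' @param path file path.
#' @return numeric matrix with region-id rownames and sample-id colnames.
#' @export
read_counts <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  if (names(dt)[1] != "region_id") stop("counts TSV must start with a region_id column")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_counts
#' @param counts numeric matrix, rownames = region ids.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(region_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, path)
}

#' Read / write sample sheets
#'
#' TSV with columns `sample_id`, `label` (cell type or cancer type) and an
#' optional `path` column pointing at per-sample peak files.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  if (!all(c("sample_id", "label") %in% names(df))) {
    stop("sample sheet needs sample_id and label columns")
  }
  df
}

#' @rdname read_sample_sheet
#' @param sheet data.frame with `sample_id`, `label` (and optionally `path`).
#' @export
write_sample_sheet <- function(sheet, path) .write_tsv(sheet, path)

#' Read / write cfDNA fragment BED3
#'
#' Fragment records are plain BED3 intervals; fragment length is
#' `end - start`.
#'
#' @param path file path.
#' @return `GRanges` sorted by coordinate.
#' @export
read_fragments <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  gr <- peak_set(as.character(dt[[1]]), dt[[2]], dt[[3]], sort = TRUE)
  S4Vectors::mcols(gr) <- NULL
  gr
}

#' @rdname read_fragments
#' @param fragments `GRanges`.
#' @export
write_fragments <- function(fragments, path) {
  fragments <- sort_peaks(fragments)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(fragments)),
                   start = bed_start(fragments),
                   end = bed_end(fragments))
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, col.names = FALSE,
                     eol = "\n")
  invisible(path)
}

#' Read / write variant tables
#'
#' TSV with columns `chrom`, `pos` (1-based, variant-format convention),
#' `ref`, `alt`, `af`, `depth`, `mmq`, `mbq`, `sample_role`
#' (`tumor`/`cfdna`). A minimal VCF reader/writer is also provided:
#' single-sample VCF with AF/DP/MMQ/MBQ encoded in INFO.
#'
#' @param path file path.
#' @return data.frame of variant records.
#' @export
read_variants <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                        colClasses = list(character = c("chrom", "ref", "alt"))))
  need <- c("chrom", "pos", "ref", "alt", "af", "depth", "mmq", "mbq")
  if (!all(need %in% names(df))) {
    stop("variant TSV needs columns: ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname read_variants
#' @param variants variant data.frame.
#' @export
write_variants <- function(variants, path) .write_tsv(variants, path)

#' @rdname read_variants
#' @export
read_vcf_minimal <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), af = numeric(0), depth = integer(0),
                      mmq = numeric(0), mbq = numeric(0)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    kv <- strsplit(strsplit(info, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    for (p in kv) if (p[1] == key) return(as.numeric(p[2]))
    NA_real_
  }
  data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    pos = as.integer(vapply(fields, `[`, "", 2L)),
    ref = vapply(fields, `[`, "", 4L),
    alt = vapply(fields, `[`, "", 5L),
    af = vapply(fields, function(f) info_get(f[8], "AF"), 0),
    depth = as.integer(vapply(fields, function(f) info_get(f[8], "DP"), 0)),
    mmq = vapply(fields, function(f) info_get(f[8], "MMQ"), 0),
    mbq = vapply(fields, function(f) info_get(f[8], "MBQ"), 0),
    stringsAsFactors = FALSE
  )
}

#' @rdname read_variants
#' @export
write_vcf_minimal <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele fraction\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=MMQ,Number=1,Type=Float,Description=\"Median mapping quality\">",
           "##INFO=<ID=MBQ,Number=1,Type=Float,Description=\"Median base quality\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  info <- sprintf("AF=%s;DP=%d;MMQ=%s;MBQ=%s",
                  .fmt_num(variants$af), as.integer(variants$depth),
                  .fmt_num(variants$mmq), .fmt_num(variants$mbq))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s",
                  variants$chrom, as.integer(variants$pos),
                  variants$ref, variants$alt, info)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Every CLI run records its inputs, parameters, seed and package version so
#' the run can be reproduced.
#'
#' @param params named list of run parameters.
#' @param path output JSON path.
#' @export
write_run_manifest <- function(params, path) {
  params$package_version <- as.character(utils::packageVersion("relaccs"))
  params$r_version <- paste(R.version$major, R.version$minor, sep = ".")
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
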