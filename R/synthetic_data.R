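# Seeded generators for every input the pipeline consumes. The planted
# structure (which regions are cancer-specifically open/closed, how cfDNA
# depth and fragment length depend on accessibility, how cfDNA allele
# fractions degrade with RelAccS sign) is recorded in truth tables so
# recall/precision of every stage can be computed exactly.

# Evaluate expr under a private seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults describe the stated synthetic world: 2000 fixed-width regions,
#' 3 cancer types of 15 ATAC-seq samples each plus PBMC and neutrophil
#' blood samples, 2% of regions planted cancer-specifically open and 2%
#' closed per type (40 each at the default size), plus pan-cancer shared
#' open/closed classes (open or closed in every tumor type relative to
#' blood; 20% each) that make the candidate pools entering feature
#' selection realistically large. Counts are negative binomial
#' (`Var = mu + dispersion * mu^2`) around an 8-fold planted effect. cfDNA
#' fragments have depth inversely monotone in accessibility (4-fold between
#' extremes) and Gaussian lengths (open 140 bp, closed 190 bp, sd 25,
#' truncated at 50). cfDNA allele-fraction noise is sd 0.03 at RelAccS < 0
#' sites and 0.12 at RelAccS > 0 sites.
#'
#' @param n_regions number of regions (default 2000).
#' @param n_cancer_types number of cancer types (default 3).
#' @param samples_per_type tumor ATAC-seq samples per type (default 15).
#' @param blood_samples_per_celltype PBMC and neutrophil samples (default 6
#'   each).
#' @param fraction_planted_open,fraction_planted_closed per-type planted
#'   fractions (default 0.02 each).
#' @param fraction_shared_open,fraction_shared_closed pan-cancer fractions
#'   (default 0.20 each).
#' @param effect_size fold change of planted regions (default 8).
#' @param dispersion NB overdispersion (default 0.2).
#' @param tumor_fraction cfDNA tumor mixture weight (default 0.1).
#' @param frag_len_open_mean,frag_len_closed_mean,frag_len_sd fragment
#'   length model in bp (defaults 140 / 190 / 25).
#' @param depth_ratio_closed_over_open cfDNA depth ratio between fully
#'   closed and fully open regions (default 4).
#' @param af_noise_sd_neg,af_noise_sd_pos cfDNA AF noise sd by RelAccS sign
#'   (defaults 0.03 / 0.12).
#' @param qual_fail_fraction fraction of variants failing each quality
#'   filter (default 0.05).
#' @param region_width fixed region width in bp (default 501).
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 2000L, n_cancer_types = 3L,
                       samples_per_type = 15L,
                       blood_samples_per_celltype = 6L,
                       fraction_planted_open = 0.02,
                       fraction_planted_closed = 0.02,
                       fraction_shared_open = 0.20,
                       fraction_shared_closed = 0.20,
                       effect_size = 8, dispersion = 0.2,
                       tumor_fraction = 0.1,
                       frag_len_open_mean = 140, frag_len_closed_mean = 190,
                       frag_len_sd = 25,
                       depth_ratio_closed_over_open = 4,
                       af_noise_sd_neg = 0.03, af_noise_sd_pos = 0.12,
                       qual_fail_fraction = 0.05,
                       region_width = 501L, seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              n_cancer_types = as.integer(n_cancer_types),
              samples_per_type = as.integer(samples_per_type),
              blood_samples_per_celltype = as.integer(blood_samples_per_celltype),
              fraction_planted_open = fraction_planted_open,
              fraction_planted_closed = fraction_planted_closed,
              fraction_shared_open = fraction_shared_open,
              fraction_shared_closed = fraction_shared_closed,
              effect_size = effect_size, dispersion = dispersion,
              tumor_fraction = tumor_fraction,
              frag_len_open_mean = frag_len_open_mean,
              frag_len_closed_mean = frag_len_closed_mean,
              frag_len_sd = frag_len_sd,
              depth_ratio_closed_over_open = depth_ratio_closed_over_open,
              af_noise_sd_neg = af_noise_sd_neg,
              af_noise_sd_pos = af_noise_sd_pos,
              qual_fail_fraction = qual_fail_fraction,
              region_width = as.integer(region_width),
              seed = as.integer(seed))
  planted_total <- n_cancer_types * (fraction_planted_open + fraction_planted_closed) +
    fraction_shared_open + fraction_shared_closed
  if (planted_total > 1) stop("planted fractions exceed 1")
  stopifnot(effect_size > 0, dispersion >= 0, tumor_fraction >= 0,
            tumor_fraction <= 1, depth_ratio_closed_over_open > 0,
            frag_len_sd > 0)
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-cancer + blood ATAC-seq experiment
#'
#' Produces the fixed-width region universe, a region x sample raw
#' insertion-count matrix covering all cancer types plus PBMC and
#' neutrophil blood samples, the sample sheet, the true blood-open peak set
#' and a truth table of planted region classes. Planted
#' cancer-specifically open regions have an `effect_size`-fold higher mean
#' in their cancer type than in blood and the other types; planted closed
#' regions the reverse; shared open/closed regions separate every tumor
#' type from blood. Counts are negative binomial with lognormal per-sample
#' library factors. Fully deterministic under `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list with `regions` (`GRanges`), `counts` (region x sample raw
#'   matrix), `sample_sheet` (`sample_id`, `label`, `role`), `blood_peaks`
#'   (`GRanges` of truly blood-accessible regions), `truth` (`region_id`,
#'   `class`, `cancer_type`, `blood_open`), `cancer_types`.
#' @export
simulate_atac <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, {
    n <- config$n_regions
    types <- paste0("cancer", LETTERS[seq_len(config$n_cancer_types)])
    ids <- sprintf("region_%05d", seq_len(n))
    spacing <- 2L * config$region_width + 1000L
    start0 <- (seq_len(n) - 1L) * spacing
    regions <- peak_set(rep("chr1", n), start0, start0 + config$region_width,
                        name = ids)

    base <- stats::rlnorm(n, meanlog = log(30), sdlog = 0.7)
    half <- sqrt(config$effect_size)
    hi <- base * half
    lo <- base / half

    n_po <- round(config$fraction_planted_open * n)
    n_pc <- round(config$fraction_planted_closed * n)
    n_so <- round(config$fraction_shared_open * n)
    n_sc <- round(config$fraction_shared_closed * n)
    shuffled <- sample.int(n)
    take <- function(k) {
      out <- shuffled[seq_len(k)]
      shuffled <<- shuffled[-seq_len(k)]
      out
    }
    cls <- rep("background", n)
    cls_type <- rep(NA_character_, n)
    for (t in types) {
      i <- take(n_po); cls[i] <- "planted_open"; cls_type[i] <- t
      i <- take(n_pc); cls[i] <- "planted_closed"; cls_type[i] <- t
    }
    cls[take(n_so)] <- "shared_open"
    cls[take(n_sc)] <- "shared_closed"

    # per-region expected mean for each cancer type and for blood
    mu <- matrix(base, n, length(types) + 1L,
                 dimnames = list(ids, c(types, "blood")))
    for (j in seq_along(types)) {
      t <- types[j]
      own_open <- cls == "planted_open" & cls_type == t
      oth_open <- cls == "planted_open" & cls_type != t
      own_closed <- cls == "planted_closed" & cls_type == t
      oth_closed <- cls == "planted_closed" & cls_type != t
      mu[own_open, j] <- hi[own_open]
      mu[oth_open, j] <- lo[oth_open]
      mu[own_closed, j] <- lo[own_closed]
      mu[oth_closed, j] <- hi[oth_closed]
      mu[cls == "shared_open", j] <- hi[cls == "shared_open"]
      mu[cls == "shared_closed", j] <- lo[cls == "shared_closed"]
    }
    bcol <- length(types) + 1L
    mu[cls == "planted_open", bcol] <- lo[cls == "planted_open"]
    mu[cls == "planted_closed", bcol] <- hi[cls == "planted_closed"]
    mu[cls == "shared_open", bcol] <- lo[cls == "shared_open"]
    mu[cls == "shared_closed", bcol] <- hi[cls == "shared_closed"]

    draw <- function(mu_vec, libfac) {
      m <- mu_vec * libfac
      if (config$dispersion > 0) {
        stats::rnbinom(length(m), mu = m, size = 1 / config$dispersion)
      } else {
        stats::rpois(length(m), m)
      }
    }
    samples <- list(); sheet <- list()
    for (j in seq_along(types)) {
      for (s in seq_len(config$samples_per_type)) {
        sid <- sprintf("%s_s%02d", types[j], s)
        samples[[sid]] <- draw(mu[, j], stats::rlnorm(1, 0, 0.2))
        sheet[[sid]] <- data.frame(sample_id = sid, label = types[j],
                                   role = "tumor")
      }
    }
    for (ct in c("PBMC", "neutrophil")) {
      for (s in seq_len(config$blood_samples_per_celltype)) {
        sid <- sprintf("%s_s%02d", ct, s)
        samples[[sid]] <- draw(mu[, bcol], stats::rlnorm(1, 0, 0.2))
        sheet[[sid]] <- data.frame(sample_id = sid, label = ct, role = "blood")
      }
    }
    counts <- do.call(cbind, samples)
    rownames(counts) <- ids
    storage.mode(counts) <- "double"
    sample_sheet <- do.call(rbind, unname(sheet))

    blood_open <- mu[, bcol] >= base  # background + blood-high classes
    truth <- data.frame(region_id = ids, class = cls, cancer_type = cls_type,
                        blood_open = blood_open, stringsAsFactors = FALSE,
                        row.names = NULL)
    list(regions = regions, counts = counts, sample_sheet = sample_sheet,
         blood_peaks = regions[blood_open], truth = truth,
         cancer_types = types, expected_mu = mu)
  })
}

#' Simulate multi-sample peak calls with reproducible and private peaks
#'
#' Emulates per-sample ATAC-seq peak summits for the consensus-building
#' workflow: a set of reproducible summit locations shared (with small
#' positional jitter and lognormal score variation) by every sample, plus
#' sample-private summits unique to each sample.
#'
#' @param n_samples number of samples.
#' @param n_shared reproducible summits present in every sample.
#' @param n_private private summits per sample.
#' @param chrom_size chromosome length (single chromosome `chr1`).
#' @param flank summit extension half-width (default 250).
#' @param seed integer seed.
#' @return list with `sample_peaks` (list of `GRanges`), `shared_pos`
#'   (true reproducible summit positions) and `chrom_sizes`.
#' @export
simulate_sample_peaksets <- function(n_samples = 4L, n_shared = 200L,
                                     n_private = 40L, chrom_size = 5e6,
                                     flank = 250L, seed = 1L) {
  .with_seed(seed, {
    chrom_sizes <- c(chr1 = as.integer(chrom_size))
    spacing <- floor(chrom_size / (n_shared + 1))
    if (spacing <= 4 * flank) stop("chromosome too small for n_shared summits")
    shared_pos <- spacing * seq_len(n_shared)
    sample_peaks <- lapply(seq_len(n_samples), function(s) {
      jit <- shared_pos + sample(-50:50, n_shared, replace = TRUE)
      priv <- sample.int(chrom_size - 2L * flank - 1L, n_private) + flank
      df <- data.frame(
        chrom = "chr1",
        pos = c(jit, priv),
        score = c(stats::rlnorm(n_shared, log(50), 0.5),
                  stats::rlnorm(n_private, log(10), 0.5))
      )
      extend_summits(df, flank = flank, chrom_sizes = chrom_sizes)
    })
    list(sample_peaks = sample_peaks, shared_pos = shared_pos,
         chrom_sizes = chrom_sizes)
  })
}

#' Simulate cfDNA fragments over a region set
#'
#' Per-region fragment counts are multinomial with weights inversely
#' monotone in accessibility: with accessibility rank-scaled to
#' `u in [0, 1]`, the weight is `ratio - (ratio - 1) * u`, so fully closed
#' regions attract `depth_ratio_closed_over_open` times the depth of fully
#' open ones. Fragment lengths are Gaussian with mean interpolating from
#' `frag_len_closed_mean` (u = 0) to `frag_len_open_mean` (u = 1), sd
#' `frag_len_sd`, truncated at 50 bp. A healthy sample uses blood
#' accessibility; a cancer sample mixes in tumor accessibility with weight
#' `tumor_fraction`.
#'
#' @param regions `GRanges` region set.
#' @param accessibility per-region blood accessibility (positive scale).
#' @param config a [sim_config()].
#' @param total_fragments library size in fragments (default 2e5).
#' @param tumor_accessibility optional per-region tumor accessibility; when
#'   supplied the sample is a cancer sample mixed at
#'   `config$tumor_fraction`.
#' @param seed seed (defaults to `config$seed`).
#' @return list with `fragments` (`GRanges`, sorted), `total_fragments`,
#'   and the per-region expected depth weights `weight`.
#' @export
simulate_cfdna <- function(regions, accessibility, config = sim_config(),
                           total_fragments = 2e5, tumor_accessibility = NULL,
                           seed = config$seed) {
  n <- length(regions)
  stopifnot(length(accessibility) == n, all(is.finite(accessibility)))
  .with_seed(seed, {
    uscale <- function(a) {
      if (n == 1L) return(0.5)
      (rank(a, ties.method = "average") - 1) / (n - 1)
    }
    u <- uscale(accessibility)
    if (!is.null(tumor_accessibility)) {
      u <- (1 - config$tumor_fraction) * u +
        config$tumor_fraction * uscale(tumor_accessibility)
    }
    ratio <- config$depth_ratio_closed_over_open
    w <- ratio - (ratio - 1) * u
    counts <- as.integer(stats::rmultinom(1, size = total_fragments,
                                          prob = w / sum(w)))
    len_mean <- config$frag_len_closed_mean -
      (config$frag_len_closed_mean - config$frag_len_open_mean) * u
    reg_start <- bed_start(regions)
    reg_width <- GenomicRanges::width(regions)
    chroms <- as.character(GenomicRanges::seqnames(regions))
    idx <- rep.int(seq_len(n), counts)
    lens <- pmax(50L, as.integer(round(stats::rnorm(length(idx),
                                                    mean = len_mean[idx],
                                                    sd = config$frag_len_sd))))
    offs <- floor(stats::runif(length(idx)) * reg_width[idx])
    fs <- reg_start[idx] + offs
    frags <- peak_set(chroms[idx], fs, fs + lens, sort = TRUE)
    S4Vectors::mcols(frags) <- NULL
    list(fragments = frags, total_fragments = total_fragments, weight = w)
  })
}

#' Simulate a paired tumor / cfDNA variant cohort
#'
#' Places variants in peaks of both RelAccS signs, draws tumor allele
#' fractions uniformly in \[0.05, 0.6\], and sets the cfDNA allele fraction
#' to the tumor AF plus Gaussian noise whose sd depends on the RelAccS sign
#' of the harboring peak (`af_noise_sd_neg` / `af_noise_sd_pos`),
#' emulating the better cfDNA representation of tumor-closed/blood-open
#' sites. Quality fields are drawn so that about `qual_fail_fraction` of
#' variants fail each of the depth / MMQ / MBQ filters.
#'
#' @param regions `GRanges` peak universe with `name` column.
#' @param track `relaccs_track` over the universe.
#' @param config a [sim_config()].
#' @param n_per_group variants per RelAccS-sign group (default 100).
#' @param seed seed (defaults to `config$seed`).
#' @return list with `tumor` and `cfdna` variant data.frames and `truth`
#'   (variant key, harboring peak, RelAccS sign, true AFs).
#' @export
simulate_variant_cohort <- function(regions, track, config = sim_config(),
                                    n_per_group = 100L, seed = config$seed) {
  ids <- S4Vectors::mcols(regions)$name
  stopifnot(!is.null(ids), identical(ids, track$region_id))
  .with_seed(seed, {
    neg_pool <- which(track$relaccs < 0)
    pos_pool <- which(track$relaccs > 0)
    if (length(neg_pool) < n_per_group || length(pos_pool) < n_per_group) {
      stop("not enough peaks of each RelAccS sign")
    }
    pick <- c(sample(neg_pool, n_per_group), sample(pos_pool, n_per_group))
    sign_grp <- rep(c("neg", "pos"), each = n_per_group)
    m <- length(pick)
    pos1 <- bed_start(regions)[pick] +
      GenomicRanges::width(regions)[pick] %/% 2L + 1L  # 1-based midpoint
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    af_t <- stats::runif(m, 0.05, 0.6)
    sdv <- ifelse(sign_grp == "neg", config$af_noise_sd_neg,
                  config$af_noise_sd_pos)
    af_c <- pmin(pmax(af_t + stats::rnorm(m, 0, sdv), 0), 1)
    qual <- function() {
      f <- config$qual_fail_fraction
      list(depth = ifelse(stats::runif(m) < f, sample(1:9, m, replace = TRUE),
                          10L + stats::rpois(m, 90)),
           mmq = ifelse(stats::runif(m) < f, stats::runif(m, 20, 49.9),
                        stats::runif(m, 50, 60)),
           mbq = ifelse(stats::runif(m) < f, stats::runif(m, 5, 19.9),
                        stats::runif(m, 20, 40)))
    }
    qt <- qual(); qc <- qual()
    chrom <- as.character(GenomicRanges::seqnames(regions))[pick]
    tumor <- data.frame(chrom = chrom, pos = pos1, ref = ref, alt = alt,
                        af = af_t, depth = as.integer(qt$depth),
                        mmq = qt$mmq, mbq = qt$mbq, sample_role = "tumor",
                        stringsAsFactors = FALSE, row.names = NULL)
    cfdna <- data.frame(chrom = chrom, pos = pos1, ref = ref, alt = alt,
                        af = af_c, depth = as.integer(qc$depth),
                        mmq = qc$mmq, mbq = qc$mbq, sample_role = "cfdna",
                        stringsAsFactors = FALSE, row.names = NULL)
    truth <- data.frame(chrom = chrom, pos = pos1, ref = ref, alt = alt,
                        peak_id = ids[pick], relaccs_sign = sign_grp,
                        af_tumor = af_t, af_cfdna = af_c,
                        stringsAsFactors = FALSE, row.names = NULL)
    list(tumor = tumor, cfdna = cfdna, truth = truth)
  })
}
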