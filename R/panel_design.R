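#' Panel design configuration
#'
#' Bundles the thresholds of the two panel-design workflows. Defaults
#' follow the published pipeline: |RelAccS| threshold 1.5, FDR < 0.01 for
#' differential accessibility, 5-fold cross validation, top 10% of features
#' per classifier, LASSO features non-zero in >= 2 of 5 folds, and a
#' >= 2-of-3 classifier consensus.
#'
#' @param direction `"accessible"` (tumor-open, blood-closed) or
#'   `"inaccessible"` (tumor-closed, blood-open).
#' @param relaccs_threshold magnitude of the RelAccS cut (default 1.5).
#' @param fdr_threshold Benjamini-Hochberg q-value cut (default 0.01).
#' @param n_folds cross-validation folds (default 5).
#' @param top_fraction fraction of features kept per classifier ranking
#'   (default 0.10).
#' @param lasso_min_folds folds in which a LASSO coefficient must be
#'   non-zero (default 2).
#' @param consensus_min_methods classifiers that must agree (default 2).
#' @param da_method `"nb"` (negative-binomial Wald) or `"wilcoxon"`.
#' @param seed integer seed for fold assignment and the random forest.
#' @return list of class `panel_config`.
#' @export
panel_config <- function(direction = c("accessible", "inaccessible"),
                         relaccs_threshold = 1.5, fdr_threshold = 0.01,
                         n_folds = 5L, top_fraction = 0.10,
                         lasso_min_folds = 2L, consensus_min_methods = 2L,
                         da_method = c("nb", "wilcoxon"), seed = 1L) {
  direction <- match.arg(direction)
  da_method <- match.arg(da_method)
  stopifnot(relaccs_threshold >= 0, top_fraction > 0, top_fraction <= 1,
            consensus_min_methods %in% 1:3, n_folds >= 2, lasso_min_folds >= 1)
  structure(list(direction = direction, relaccs_threshold = relaccs_threshold,
                 fdr_threshold = fdr_threshold, n_folds = as.integer(n_folds),
                 top_fraction = top_fraction,
                 lasso_min_folds = as.integer(lasso_min_folds),
                 consensus_min_methods = as.integer(consensus_min_methods),
                 da_method = da_method, seed = as.integer(seed)),
            class = "panel_config")
}

#' RelAccS filter
#'
#' Accessible panels keep regions with `relaccs >= +threshold` (the
#' pipeline drops peaks with RelAccS *less than* the threshold, so the
#' boundary survives); inaccessible panels keep `relaccs < -threshold`
#' (strict).
#'
#' @param track a `relaccs_track`.
#' @param config a `panel_config`.
#' @return character vector of surviving region ids.
#' @export
filter_by_relaccs <- function(track, config) {
  if (any(!is.finite(track$relaccs))) stop("RelAccS scores must be finite")
  thr <- config$relaccs_threshold
  keep <- if (config$direction == "accessible") {
    track$relaccs >= thr
  } else {
    track$relaccs < -thr
  }
  track$region_id[keep]
}

#' Blood-overlap filter
#'
#' Accessible panels must avoid blood-accessible chromatin: regions
#' overlapping (>= 1 bp) the consensus blood peak set are removed.
#' Inaccessible panels target blood-open chromatin: only overlapping
#' regions are retained. The two modes partition the input.
#'
#' @param regions `GRanges` of candidate regions.
#' @param blood `GRanges` consensus blood peak set.
#' @param direction `"accessible"` or `"inaccessible"`.
#' @return the retained subset of `regions`.
#' @export
blood_overlap_filter <- function(regions, blood,
                                 direction = c("accessible", "inaccessible")) {
  direction <- match.arg(direction)
  hit <- overlaps_any(regions, blood)
  if (direction == "accessible") regions[!hit] else regions[hit]
}

#' Differential accessibility between tumor and blood
#'
#' Per-region two-group test on library-size-normalized insertion counts.
#' The default is a negative-binomial Wald test: counts are modelled as
#' NB with per-region method-of-moments dispersion `alpha`
#' (`Var = mu + alpha mu^2`, pooled across the two groups) and sample
#' scaling factors `s_j = libsize_j / 1e6`; the log2 fold change
#' (tumor over blood) is tested against a t reference with
#' Welch-Satterthwaite degrees of freedom. A Wilcoxon rank-sum alternative
#' is available. P-values are Benjamini-Hochberg adjusted.
#'
#' @param tumor,blood region x sample raw count matrices with identical
#'   region-id rownames; >= 2 samples per group.
#' @param fdr_threshold q-value cut defining `significant` (default 0.01).
#' @param method `"nb"` or `"wilcoxon"`.
#' @param pseudocount cpm pseudocount for the fold change (default 0.5).
#' @param lib_sizes_tumor,lib_sizes_blood per-sample library sizes; default
#'   the column sums of the supplied matrices. Pass full-library sizes when
#'   testing a region subset, otherwise normalization is driven by the
#'   subset itself.
#' @return data.frame with `region_id`, `log2fc`, `stat`, `pvalue`,
#'   `qvalue`, `significant`.
#' @export
differential_accessibility <- function(tumor, blood, fdr_threshold = 0.01,
                                       method = c("nb", "wilcoxon"),
                                       pseudocount = 0.5,
                                       lib_sizes_tumor = NULL,
                                       lib_sizes_blood = NULL) {
  method <- match.arg(method)
  tumor <- as.matrix(tumor); blood <- as.matrix(blood)
  if (ncol(tumor) < 2L || ncol(blood) < 2L) {
    stop("need at least 2 samples per group")
  }
  if (!identical(rownames(tumor), rownames(blood))) {
    stop("tumor and blood matrices must share the same region index")
  }
  if (is.null(lib_sizes_tumor)) lib_sizes_tumor <- colSums(tumor)
  if (is.null(lib_sizes_blood)) lib_sizes_blood <- colSums(blood)
  st <- lib_sizes_tumor / 1e6
  sb <- lib_sizes_blood / 1e6
  if (any(c(st, sb) <= 0)) stop("zero-sum sample column")
  zt <- sweep(tumor, 2, st, "/")  # cpm
  zb <- sweep(blood, 2, sb, "/")
  mt <- rowMeans(zt); mb <- rowMeans(zb)
  lfc <- log2((mt + pseudocount) / (mb + pseudocount))
  nt <- ncol(tumor); nb <- ncol(blood)
  if (method == "nb") {
    at <- mean(1 / st); ab <- mean(1 / sb)
    vt_emp <- apply(zt, 1, stats::var)
    vb_emp <- apply(zb, 1, stats::var)
    # pooled MoM dispersion: Var(z) = mu * mean(1/s) + alpha * mu^2
    num <- pmax(vt_emp - mt * at, 0) + pmax(vb_emp - mb * ab, 0)
    den <- mt^2 + mb^2
    alpha <- ifelse(den > 0, num / den, 0)
    Vt <- (mt * at + alpha * mt^2) / nt
    Vb <- (mb * ab + alpha * mb^2) / nb
    # delta method on log2 scale
    Lt <- Vt / ((mt + pseudocount)^2 * log(2)^2)
    Lb <- Vb / ((mb + pseudocount)^2 * log(2)^2)
    se <- sqrt(Lt + Lb)
    stat <- ifelse(se > 0, lfc / se, 0)
    df <- ifelse(Lt + Lb > 0,
                 (Lt + Lb)^2 / (Lt^2 / (nt - 1) + Lb^2 / (nb - 1)),
                 nt + nb - 2)
    pval <- 2 * stats::pt(-abs(stat), df = pmax(df, 1))
    pval[se == 0] <- 1
  } else {
    res <- vapply(seq_len(nrow(zt)), function(i) {
      if (stats::sd(c(zt[i, ], zb[i, ])) == 0) return(c(0, 1))
      w <- suppressWarnings(stats::wilcox.test(zt[i, ], zb[i, ], exact = FALSE))
      c(unname(w$statistic), w$p.value)
    }, numeric(2))
    stat <- res[1, ]; pval <- res[2, ]
  }
  qval <- stats::p.adjust(pval, method = "BH")
  data.frame(region_id = rownames(tumor), log2fc = lfc, stat = stat,
             pvalue = pval, qvalue = qval,
             significant = qval < fdr_threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Apply the published consensus rule to logged per-fold importances /
# coefficients. Shared by select_consensus_features; tests re-derive it
# independently.
.consensus_rule <- function(rf_mat, svm_mat, lasso_mat, feature_names,
                            top_fraction, lasso_min_folds,
                            consensus_min_methods) {
  p <- length(feature_names)
  k_top <- min(p, as.integer(ceiling(top_fraction * p)))
  rf_mean <- rowMeans(rf_mat)
  svm_mean <- rowMeans(svm_mat)
  rf_rank <- order(-rf_mean, seq_len(p))
  rf_set <- feature_names[intersect(rf_rank[seq_len(k_top)], which(rf_mean > 0))]
  svm_rank <- order(-abs(svm_mean), seq_len(p))
  svm_set <- feature_names[svm_rank[seq_len(k_top)]]
  lasso_folds <- rowSums(lasso_mat != 0)
  lasso_set <- feature_names[lasso_folds >= lasso_min_folds]
  votes <- (feature_names %in% rf_set) + (feature_names %in% svm_set) +
    (feature_names %in% lasso_set)
  list(final = feature_names[votes >= consensus_min_methods],
       rf_set = rf_set, svm_set = svm_set, lasso_set = lasso_set,
       rf_mean = stats::setNames(rf_mean, feature_names),
       svm_mean = stats::setNames(svm_mean, feature_names),
       lasso_folds = stats::setNames(lasso_folds, feature_names),
       votes = stats::setNames(votes, feature_names))
}

#' Cross-validated RF / SVM / LASSO consensus feature selection
#'
#' Fits a random forest, a linear SVM and an L1-penalized logistic model in
#' each of `n_folds` stratified cross-validation folds, then selects:
#' the top `ceiling(top_fraction * p)` features by mean RF importance
#' restricted to non-zero mean importance; the top
#' `ceiling(top_fraction * p)` by absolute mean SVM coefficient; and the
#' features with a non-zero LASSO coefficient in at least `lasso_min_folds`
#' folds. The final set contains features present in at least
#' `consensus_min_methods` of the three sets. Deterministic under a fixed
#' `config$seed`.
#'
#' @param X sample x region matrix (typically `log2(cpm + 1)`).
#' @param y binary labels (cancer of interest vs rest).
#' @param config a `panel_config`.
#' @return list with `features` (final consensus set, in column order),
#'   `sets` (the three per-method sets), `provenance` (per-feature mean
#'   importance/coefficient, lasso fold counts, votes), `fold_log`
#'   (per-fold importance/coefficient matrices, for auditing) and `folds`.
#' @export
select_consensus_features <- function(X, y, config) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("f%d", seq_len(ncol(X)))
  yf <- as.factor(y)
  if (nlevels(yf) != 2L) stop("y must be binary")
  p <- ncol(X)
  if (p < 1L) stop("need at least one feature")
  folds <- stratified_folds(yf, config$n_folds, config$seed)
  rf_mat <- matrix(0, p, config$n_folds, dimnames = list(colnames(X), NULL))
  svm_mat <- matrix(0, p, config$n_folds, dimnames = list(colnames(X), NULL))
  lasso_mat <- matrix(0, p, config$n_folds, dimnames = list(colnames(X), NULL))
  for (k in seq_len(config$n_folds)) {
    tr <- folds != k
    Xtr <- X[tr, , drop = FALSE]
    ytr <- yf[tr]
    rf_mat[, k] <- rf_importance(Xtr, ytr, seed = config$seed + 1000L * k)
    svm_mat[, k] <- svm_linear_coef(Xtr, ytr)
    lasso_mat[, k] <- .lasso_fold_coef(Xtr, ytr, seed = config$seed + 2000L * k)
  }
  sel <- .consensus_rule(rf_mat, svm_mat, lasso_mat, colnames(X),
                         config$top_fraction, config$lasso_min_folds,
                         config$consensus_min_methods)
  list(features = sel$final,
       sets = list(rf = sel$rf_set, svm = sel$svm_set, lasso = sel$lasso_set),
       provenance = data.frame(
         region_id = colnames(X),
         rf_importance = unname(sel$rf_mean),
         svm_coef = unname(sel$svm_mean),
         lasso_folds = unname(sel$lasso_folds),
         n_methods = unname(sel$votes),
         selected = colnames(X) %in% sel$final,
         stringsAsFactors = FALSE),
       fold_log = list(rf = rf_mat, svm = svm_mat, lasso = lasso_mat),
       folds = folds)
}

# L1 logistic coefficients for one training fold; lambda chosen by an
# internal deterministic cross-validation on the fold's training data.
.lasso_fold_coef <- function(Xtr, ytr, seed) {
  nf <- max(3L, min(5L, min(table(ytr))))
  foldid <- stratified_folds(ytr, nf, seed)
  # small inner folds are routine at these sample sizes; glmnet's
  # "fewer than 8 observations" advisory is expected, not actionable
  cv <- suppressWarnings(
    glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 1,
                      foldid = foldid, standardize = TRUE))
  as.numeric(glmnet::coef.glmnet(cv, s = "lambda.min"))[-1]
}

#' Cross-validated panel classifier evaluation
#'
#' Stratified k-fold cross validation of a ridge-logistic classifier
#' restricted to the selected panel features; reports per-fold sensitivity
#' (recall of the positive class) and specificity.
#'
#' @param X sample x region matrix.
#' @param y binary labels; the second factor level is the positive class
#'   (logical `y`: `TRUE`).
#' @param features character vector of panel feature ids (subset of
#'   `colnames(X)`).
#' @param n_folds folds (default 5).
#' @param seed fold-assignment seed.
#' @return data.frame with one row per fold (`fold`, `sensitivity`,
#'   `specificity`) plus attribute `mean` holding the across-fold means.
#' @export
evaluate_panel_classifier <- function(X, y, features, n_folds = 5L, seed = 1L) {
  if (length(features) == 0L) stop("empty feature set")
  X <- as.matrix(X)
  if (!all(features %in% colnames(X))) stop("features must be columns of X")
  yf <- as.factor(y)
  pos <- levels(yf)[2L]
  folds <- stratified_folds(yf, n_folds, seed)
  res <- lapply(seq_len(n_folds), function(k) {
    tr <- folds != k
    fit <- ridge_logistic(X[tr, features, drop = FALSE], yf[tr])
    prob <- predict(fit, X[!tr, features, drop = FALSE])
    pred <- ifelse(prob > 0.5, levels(yf)[2L], levels(yf)[1L])
    truth <- yf[!tr]
    data.frame(fold = k,
               sensitivity = mean(pred[truth == pos] == pos),
               specificity = mean(pred[truth != pos] != pos))
  })
  out <- do.call(rbind, res)
  attr(out, "mean") <- c(sensitivity = mean(out$sensitivity),
                         specificity = mean(out$specificity))
  out
}

#' Design a cancer-specifically accessible or inaccessible panel
#'
#' Runs the full workflow for one cancer type: RelAccS filter ->
#' blood-overlap filter -> differential accessibility (tumor vs blood,
#' FDR < threshold) -> cross-validated RF/SVM/LASSO consensus feature
#' selection (cancer of interest vs all other cancers) -> classifier
#' evaluation. Every stage shrinks the region set; per-region provenance is
#' recorded.
#'
#' @param track `relaccs_track` for the cancer of interest over the region
#'   universe.
#' @param regions `GRanges` of the region universe; names/`name` column
#'   must match `track$region_id`.
#' @param blood_peaks consensus blood peak set (`GRanges`).
#' @param tumor_counts raw counts, samples of the cancer of interest.
#' @param blood_counts raw counts, blood samples (PBMC + neutrophils).
#' @param all_cancer_counts raw counts over all cancer samples (feature
#'   matrix source for the classifiers).
#' @param labels per-sample cancer-type labels along
#'   `colnames(all_cancer_counts)`.
#' @param cancer_type the positive-class label.
#' @param config a `panel_config`.
#' @return list of class `relaccs_panel` with `regions` (`GRanges`),
#'   `provenance`, `classifier_metrics`, `stage_log` and `config`.
#' @export
design_panel <- function(track, regions, blood_peaks, tumor_counts,
                         blood_counts, all_cancer_counts, labels,
                         cancer_type, config) {
  region_names <- S4Vectors::mcols(regions)$name
  if (is.null(region_names)) stop("regions must carry a name column")
  if (!all(track$region_id %in% region_names)) {
    stop("track region ids missing from the region universe")
  }
  stage_log <- list(universe = nrow(track))

  ids1 <- filter_by_relaccs(track, config)
  stage_log$relaccs_filter <- length(ids1)

  sel1 <- regions[match(ids1, region_names)]
  sel2 <- blood_overlap_filter(sel1, blood_peaks, config$direction)
  ids2 <- S4Vectors::mcols(sel2)$name
  stage_log$blood_overlap_filter <- length(ids2)

  empty_panel <- function(stage) {
    structure(list(cancer_type = cancer_type, direction = config$direction,
                   regions = regions[0], provenance = NULL,
                   classifier_metrics = NULL,
                   stage_log = c(stage_log, list(empty_after = stage)),
                   config = config),
              class = "relaccs_panel")
  }
  if (length(ids2) == 0L) return(empty_panel("blood_overlap_filter"))

  da <- differential_accessibility(tumor_counts[ids2, , drop = FALSE],
                                   blood_counts[ids2, , drop = FALSE],
                                   fdr_threshold = config$fdr_threshold,
                                   method = config$da_method,
                                   lib_sizes_tumor = colSums(tumor_counts),
                                   lib_sizes_blood = colSums(blood_counts))
  ids3 <- da$region_id[da$significant]
  stage_log$differential_accessibility <- length(ids3)
  if (length(ids3) == 0L) return(empty_panel("differential_accessibility"))

  X <- t(log2(cpm_normalize(all_cancer_counts)[ids3, , drop = FALSE] + 1))
  y <- labels == cancer_type
  sel <- select_consensus_features(X, y, config)
  stage_log$consensus_selection <- length(sel$features)
  if (length(sel$features) == 0L) return(empty_panel("consensus_selection"))

  metrics <- evaluate_panel_classifier(X, y, sel$features,
                                       n_folds = config$n_folds,
                                       seed = config$seed)

  prov <- sel$provenance
  prov$relaccs <- track$relaccs[match(prov$region_id, track$region_id)]
  prov$da_qvalue <- da$qvalue[match(prov$region_id, da$region_id)]
  prov$da_log2fc <- da$log2fc[match(prov$region_id, da$region_id)]

  structure(list(cancer_type = cancer_type, direction = config$direction,
                 regions = sort_peaks(regions[match(sel$features, region_names)]),
                 provenance = prov, classifier_metrics = metrics,
                 stage_log = stage_log, config = config,
                 selection = sel),
            class = "relaccs_panel")
}

#' @export
print.relaccs_panel <- function(x, ...) {
  cat(sprintf("<relaccs_panel> %s / %s: %d region(s)\n",
              x$cancer_type, x$direction, length(x$regions)))
  cat("  stages:", paste(sprintf("%s=%s", names(x$stage_log),
                                 unlist(x$stage_log)), collapse = " -> "), "\n")
  if (!is.null(x$classifier_metrics)) {
    m <- attr(x$classifier_metrics, "mean")
    cat(sprintf("  CV sensitivity %.3f, specificity %.3f\n",
                m["sensitivity"], m["specificity"]))
  }
  invisible(x)
}
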