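---
title: "Methods: chromatin-accessibility-aware panel design for liquid biopsy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-accessibility-aware panel design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Cell-free DNA (cfDNA) in plasma is dominated by fragments from dying blood
cells; tumor-derived fragments (ctDNA) are a small minority. Targeted
sequencing panels concentrate depth on marker regions, but most designs
consider only where mutations or methylation markers recur — not whether
fragments from those regions actually survive into plasma. Chromatin
accessibility governs that survival: nucleases degrade open chromatin, so
regions open in the tumor but closed in blood yield fewer, shorter
fragments, while regions closed in the tumor but open in blood are
over-represented among tumor-derived fragments. This package encodes that
logic as a scoring and panel-design pipeline driven by ATAC-seq data from
tumors and blood cells.

## The model

**Weighted blood mean.** For region $r_i$, with library-size-normalized
(counts-per-million, CPM) ATAC-seq insertion counts, the blood reference
signal is the weighted average of the PBMC and neutrophil sample means,

$$
b_{r_i} \;=\; \frac{\overline{\mathrm{PBMC}}_{r_i} + 2\,\overline{\mathrm{Neut}}_{r_i}}{3},
$$

with the neutrophil:PBMC weights fixed at 2:1 — the approximate abundance
ratio of the two compartments in whole blood. HUVEC (endothelial) peaks
contribute *locations* to the consensus blood peak set (endothelium sheds
small amounts of cfDNA) but no counts to the weighted mean; the weights
are exposed as configuration only.

**Relative Accessibility Score (RelAccS).** For a cancer type with CPM
matrix $T$,

$$
\mathrm{RelAccS}_{r_i} \;=\; \log_2
\frac{\overline{T}_{r_i} + \varepsilon}{\,b_{r_i} + \varepsilon\,}.
$$

Positive scores mark tumor-open/blood-closed chromatin, negative scores
the reverse. The pseudocount $\varepsilon$ (default 0.01 CPM) is a design
choice of this package: the ratio is undefined at zero counts, and 0.01
CPM is far below any real peak signal, so it regularizes without biasing
ranks. $\varepsilon = 0$ is allowed for exact algebraic tests on positive
data.

CPM is deliberately the only normalization: it accounts for library size
but not library composition. A composition-aware score (TMM or
median-of-ratios style) is explicitly future work, not implemented here.

## Building the blood reference

Per sample, MACS2-style peak summits are extended ±250 bp into fixed
501-bp peaks (the summit base is included; the width question — 500 vs
501 bp — is resolved here as $2 \cdot \mathrm{flank} + 1$), clipped but
not dropped at chromosome edges, and blacklist-filtered (any ≥ 1 bp
overlap removes a peak; half-open adjacency is not overlap). Scores are
normalized to score-per-million, and overlapping peaks are removed by the
iterative rule: keep the highest-scoring peak, delete everything it
touches, repeat. Score ties are broken toward the earlier (chrom, start)
peak so the result is order-invariant.

Cell-type peak sets pool all samples of a cell type, consolidate again,
and keep peaks supported — overlapped by an original per-sample peak with
normalized score strictly above 5 — in at least two distinct samples. The
wording "present in at least two samples with scores higher than 5" is
ambiguous between peak presence and score presence; we interpret it as
score-qualified presence, with both thresholds configurable. The
consensus blood peak set renormalizes each cell-type set and consolidates
their union.

Regions are classified into accessibility quartiles by *rank slicing*:
the $\lfloor n/4 \rfloor$ lowest-ranked regions are "lowly accessible",
the $\lfloor n/4 \rfloor$ highest "highly accessible". Rank slicing
rather than interpolated quantile cut-points makes the classification
deterministic under ties.

## Panel design

Two directions share one pipeline (each stage shrinks the candidate set):

1. **RelAccS filter.** Accessible panels keep regions with
   $\mathrm{RelAccS} \ge 1.5$ (the workflow removes scores *less than*
   1.5, so the boundary survives); inaccessible panels keep
   $\mathrm{RelAccS} < -1.5$ (strict).
2. **Blood-overlap filter.** Accessible panels drop regions overlapping
   the consensus blood peak set; inaccessible panels keep only
   overlapping regions. The two modes partition their input.
3. **Differential accessibility.** Tumor vs blood on raw counts. The
   external DESeq2-based step of the original workflow is replaced by an
   internal negative-binomial Wald test: per region, group means on the
   CPM scale with per-sample scaling $s_j = \mathrm{lib}_j/10^6$, pooled
   method-of-moments dispersion $\alpha$ from
   $\mathrm{Var}(z) = \mu\overline{1/s} + \alpha\mu^2$ (floored at 0),
   delta-method standard error of the log2 fold change, and a
   $t$ reference with Welch–Satterthwaite degrees of freedom as a
   finite-sample correction. Benjamini–Hochberg q-values; FDR < 0.01.
   This preserves the count-model character without a cross-package
   dependency; exact DESeq2 equivalence is a non-goal. A Wilcoxon
   rank-sum switch (`da_method = "wilcoxon"`) is provided. Library sizes
   are always taken from the *full* count matrices — normalizing within a
   candidate subset whose members all shift the same way would cancel the
   very signal being tested.
4. **Consensus feature selection.** Five stratified CV folds; in each,
   a random forest, a linear SVM and an L1-penalized logistic model are
   fit on $\log_2(\mathrm{CPM}+1)$ (log stabilization is standard for
   ATAC counts; whether the original classifiers used raw or log counts
   is not stated). Selection: top $\lceil 0.10\,p \rceil$ features by
   mean RF importance restricted to non-zero mean importance; top
   $\lceil 0.10\,p \rceil$ by absolute mean SVM coefficient; LASSO
   features non-zero in ≥ 2 of 5 folds; final set = features in ≥ 2 of
   the 3 sets. The "top 10%" base is all candidate features entering the
   classifiers, then intersected with the RF non-zero restriction.
5. **Evaluation.** Stratified CV sensitivity/specificity of a
   ridge-logistic classifier restricted to the panel (one-vs-rest for the
   cancer of interest).

Because `randomForest`/`e1071` are not dependencies, the forest (bagged
CART, Gini importance, `mtry = floor(sqrt(p))`) and the linear SVM
(L2-regularized squared-hinge primal solved by BFGS on standardized
features) are implemented in the package; LASSO uses glmnet with a
deterministic inner fold assignment. SVM coefficients are ranked on the
standardized scale — the only scale on which $|w_j|$ comparisons across
features are meaningful. The SVM kernel is linear because coefficient
rankings only exist for linear kernels. All fits are deterministic under
the configured seed; per-fold importances and coefficients are logged so
the consensus rule can be re-applied (and is, in the tests) by an
independent implementation.

## cfDNA fragmentation validation

Fragments (not reads — fragmentation is the phenomenon of interest) are
assigned to regions by any ≥ 1 bp overlap by default (`midpoint` is
available; coverage-style counting matches the depth measurements the
design is validated against, and the assignment rule for lengths is
otherwise unstated). Per region: depth (optionally per-million
normalized) and median fragment length (mean-of-middle-two for even
counts). Low vs high accessibility groups are compared with a two-sided
Welch t-test.

The accessibility–fragmentation correlation log2-transforms both series,
removes regions where *either* value is below 1 log2 unit (the outlier
rule's scope is ambiguous in its source; applying it to each series
independently is the symmetric reading, and the floor is configurable),
orders by accessibility, smooths both series with a Savitzky–Golay filter
(window 15, order 2 — the "15 neighbors, second order" smoothing of the
original graphing software), and reports the Pearson correlation. Edge
points are fit on the truncated window actually available, which
preserves polynomials up to the filter order everywhere.

## Marker ranking and AF concordance

Markers (mutations as 1-bp intervals, DMRs as intervals) are intersected
with a *non-overlapping* peak universe (overlapping universes are
rejected — assignment must be unambiguous), inherit the peak's RelAccS,
and are ranked ascending: the most negative score is the most promising
cfDNA target. Variant coordinates are 1-based (variant-format convention)
and converted to 0-based half-open internally.

Variant filters follow the stated rules with strict inequalities:
depth < 10, MMQ < 50, MBQ < 20 fail; a cfDNA allele fraction strictly
above 20% flags a germline variant, which is removed from *both* the
cfDNA and the matched tumor list. "Detected in both" requires an exact
chrom/pos/ref/alt match — position-only matching would count distinct
alleles as concordant. Concordance is the per-group Pearson correlation
of tumor vs cfDNA AF after splitting on RelAccS sign; a score of exactly
0 falls in neither group, and groups with fewer than 3 variants report
`NA`.

## The synthetic world

The generators produce every input the pipeline consumes, with planted
truth tables. Defaults are the stated world and are not tuned per test:

* 2000 fixed-width (501 bp) regions; 3 cancer types × 15 ATAC-seq
  samples; 6 PBMC + 6 neutrophil blood samples.
* Per type, 2% of regions planted cancer-specifically open and 2% closed
  (40 + 40 at the default size) with an 8-fold effect; negative-binomial
  counts with dispersion 0.2 (variance $\mu + 0.2\mu^2$) and lognormal
  (sd 0.2) library factors.
* Additionally 20% of regions are *shared open* (open in every tumor
  type, closed in blood) and 20% *shared closed*. These classes are
  biologically standard — most tumor-vs-blood accessibility differences
  are tissue-general, and closed chromatin in particular is known to be
  less cancer-specific — and they matter structurally: the consensus
  selection keeps ~10% of candidates, so a candidate pool consisting
  only of the 40 planted regions could never return a 40-region panel.
  The shared classes give the RelAccS and differential-accessibility
  filters a realistic pass-through population that the classifiers must
  then reject as non-discriminative.
* cfDNA: per-region depth weights interpolate linearly from 4 (fully
  closed) to 1 (fully open) on the accessibility rank scale; lengths are
  Gaussian, mean 190 bp (closed) to 140 bp (open), sd 25, truncated at
  50 bp; a cancer sample mixes tumor accessibility at tumor fraction 0.1.
* Variants: tumor AF uniform on [0.05, 0.6] (a realistic tumor-tissue
  somatic range; chosen once, before the acceptance suite was run);
  cfDNA AF = tumor AF + Gaussian noise, sd 0.03 at RelAccS < 0 sites and
  0.12 at RelAccS > 0 sites; ~5% of variants fail each quality filter.
  Note the 20% germline rule then removes the high-AF tail — the
  surviving cohorts are ~20 variants per sign group, which is the
  regime the concordance comparison actually operates in.

What the generator does **not** model: sequence content, GC and
mappability bias, di-nucleosome length modes, tumor purity and clonal
heterogeneity, and composition effects that CPM cannot remove. A green
test therefore establishes that the algorithms implement their contracts
and reproduce the *directions* of the published effects under the stated
world — not that the pipeline reproduces any cohort-specific magnitude.

## Numerical and design choices

* Coordinates: 0-based half-open (BED) at every file boundary; 1-based
  GRanges internally. Overlap means ≥ 1 shared bp.
* Consolidation tie-break: equal scores go to the earlier (chrom, start,
  end) peak — determinism over any statistical argument.
* narrowPeak scores come from column 5 by default; column 8
  ($-\log_{10} p$) by the `score_column` switch.
* Degenerate inputs error early and name the offender: all-zero peak
  scores, zero-sum count columns, < 2 samples per DA group, empty
  feature sets, series shorter than the smoothing window.
* All randomness (generators, fold assignment, forest bootstraps) runs
  under private seeds that restore the caller's RNG state; identical
  seeds give byte-identical TSV outputs across the whole CLI chain.
* TSV floats are written with 6 significant digits; browser-facing BED
  scores can be clamped to [0, 1000] while full-precision values stay in
  sidecar TSVs.

## Limitations

The differential-accessibility test is a pragmatic internal NB Wald test,
calibrated in simulation but not an emulation of DiffBind/DESeq2
shrinkage; borderline regions can differ from a DESeq2 analysis. RelAccS
inherits CPM's blindness to library composition. The panel classifiers
are evaluated on ATAC-seq counts, as in the original design — showing a
panel separates cancer types in ATAC space, not that it detects cancer in
plasma. Marker ranking assumes one peak per marker; markers spanning
multiple consolidated peaks take the first overlap in coordinate order.
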