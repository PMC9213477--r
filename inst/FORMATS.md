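# File formats

All coordinates in files are BED convention: 0-based half-open. TSV
floats use 6 significant digits. Writers emit sorted, tab-separated
output; BED-family files have no header.

* **narrowPeak** (10 cols): chrom, start, end, name, score, strand,
  signalValue, pValue (-log10), qValue (-log10), peak (summit offset from
  start; -1 when absent). `score_column` config: 5 (default) or 8.
* **BED3 / BED6**: chrom, start, end [, name, score, strand]. Scores may
  be signed (RelAccS-scored BEDs); browser-facing output can clamp to
  [0, 1000] with full precision kept in sidecar TSVs.
* **counts TSV**: header `region_id` + one column per sample id; raw or
  CPM values.
* **sample sheet TSV**: header `sample_id`, `label` (cell type or cancer
  type), optional `role` (`tumor`/`blood`), optional `path` (per-sample
  peak file for `blood-consensus`).
* **RelAccS track TSV**: `region_id`, `tumor_mean`,
  `blood_weighted_mean`, `relaccs`.
* **fragment BED3**: one cfDNA fragment per row; length = end - start.
* **variant TSV**: `chrom`, `pos` (1-based), `ref`, `alt`, `af`,
  `depth`, `mmq`, `mbq`, `sample_role`. Minimal VCF equivalent stores
  AF/DP/MMQ/MBQ in INFO.
* **panel outputs**: `panel.bed` (selected regions), `provenance.tsv`
  (`region_id`, `rf_importance`, `svm_coef`, `lasso_folds`, `n_methods`,
  `selected`, `relaccs`, `da_qvalue`, `da_log2fc`), `metrics.tsv`
  (per-fold `fold`, `sensitivity`, `specificity`).
* **run_manifest.json**: subcommand, parameters, seed, package and R
  versions — sufficient to reproduce the run.
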