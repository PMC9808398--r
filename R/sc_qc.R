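# Cell-level quality control and the per-sample doublet-rate formula.

#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the UMI total, the number of detected genes
#' (count > 0), and the percentage of counts falling in mitochondrial and
#' hemoglobin genes. Percentages are `100 * flagged / total`, defined as 0
#' for an all-zero cell.
#'
#' @param counts gene x cell count matrix (dense or sparse).
#' @param mito_flags,hemoglobin_flags logical vectors, one entry per gene.
#' @return data frame with columns `cell`, `umi_count`, `n_features`,
#'   `pct_mito`, `pct_hemoglobin`.
#' @export
compute_qc_metrics <- function(counts, mito_flags, hemoglobin_flags) {
  .check_counts(counts)
  ng <- nrow(counts)
  if (length(mito_flags) != ng || length(hemoglobin_flags) != ng)
    stop("flag vectors must have one entry per gene (", ng, ")", call. = FALSE)
  stopifnot(is.logical(mito_flags), is.logical(hemoglobin_flags))

  umi <- Matrix::colSums(counts)
  nfeat <- Matrix::colSums(counts > 0)
  mito <- Matrix::colSums(counts[mito_flags, , drop = FALSE])
  hb <- Matrix::colSums(counts[hemoglobin_flags, , drop = FALSE])
  pct <- function(x) ifelse(umi > 0, 100 * x / umi, 0)

  data.frame(cell = colnames(counts) %||% sprintf("C%05d", seq_len(ncol(counts))),
             umi_count = as.numeric(umi),
             n_features = as.integer(nfeat),
             pct_mito = pct(mito),
             pct_hemoglobin = pct(hb),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quality-control thresholds
#'
#' All comparisons are strict, matching the filtering rules: a cell passes iff
#' `umi_count > min_umi`, `min_features < n_features < max_features`,
#' `pct_mito < max_pct_mito`, and `pct_hemoglobin < max_pct_hemoglobin`.
#' Defaults are UMI > 1000, 500 < features < 6000, mito < 50%, Hb < 1%.
#'
#' @param min_umi,min_features,max_features,max_pct_mito,max_pct_hemoglobin
#'   numeric thresholds; boundary values are removed.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umi = 1000, min_features = 500,
                          max_features = 6000, max_pct_mito = 50,
                          max_pct_hemoglobin = 1) {
  if (min_features >= max_features)
    stop("'min_features' must be below 'max_features'", call. = FALSE)
  structure(list(min_umi = min_umi, min_features = min_features,
                 max_features = max_features, max_pct_mito = max_pct_mito,
                 max_pct_hemoglobin = max_pct_hemoglobin),
            class = "qc_thresholds")
}

#' Cell keep-mask from QC metrics
#'
#' @param metrics output of [compute_qc_metrics()].
#' @param thresholds a [qc_thresholds()].
#' @return logical keep-mask, one entry per cell; a cell is kept iff all four
#'   strict inequalities hold.
#' @export
filter_cells <- function(metrics, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(metrics), inherits(thresholds, "qc_thresholds"))
  with(metrics,
       umi_count > thresholds$min_umi &
       n_features > thresholds$min_features &
       n_features < thresholds$max_features &
       pct_mito < thresholds$max_pct_mito &
       pct_hemoglobin < thresholds$max_pct_hemoglobin)
}

#' Expected doublet rate from the detected-feature count
#'
#' The expected doublet fraction of a sample is `total_feature_number * 8e-6`,
#' a linear calibration of doublet frequency against library complexity. The
#' raw product can exceed 1 above 125,000 features, so the returned value is
#' clipped to `[0, 1]`.
#'
#' @param total_feature_number number of genes detected (count > 0) in the
#'   sample; non-negative.
#' @param rate_per_feature slope of the calibration (default `8e-6`).
#' @return expected doublet proportion in `[0, 1]`.
#' @export
expected_doublet_rate <- function(total_feature_number, rate_per_feature = 8e-6) {
  if (!is.numeric(total_feature_number) || any(!is.finite(total_feature_number)))
    stop("'total_feature_number' must be finite and numeric", call. = FALSE)
  if (any(total_feature_number < 0))
    stop("'total_feature_number' must be non-negative", call. = FALSE)
  pmin(1, pmax(0, total_feature_number * rate_per_feature))
}

#' Remove the expected number of doublets by an external doublet score
#'
#' Doublet detection itself is delegated to external tools; this hook removes
#' the `ceiling(rate * n_cells)` highest-scoring cells given a caller-supplied
#' per-cell doublet score.
#'
#' @param counts gene x cell matrix after QC.
#' @param doublet_score numeric per-cell score, higher = more doublet-like.
#' @param rate expected doublet proportion (e.g. from
#'   [expected_doublet_rate()]).
#' @return logical keep-mask (TRUE = retained singlet).
#' @export
remove_expected_doublets <- function(counts, doublet_score, rate) {
  .check_counts(counts)
  n <- ncol(counts)
  stopifnot(length(doublet_score) == n)
  .check_scalar(rate, "rate", 0, 1)
  n_remove <- min(n, ceiling(rate * n))
  keep <- rep(TRUE, n)
  if (n_remove > 0)
    keep[order(doublet_score, decreasing = TRUE)[seq_len(n_remove)]] <- FALSE
  keep
}
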