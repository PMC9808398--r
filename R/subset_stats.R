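# Per-sample subset composition statistics: the NecroLRS-High Ratio and the
# correlation between that ratio and immune-subtype proportions.

#' Proportion of NecroLRS-High cells in a sample
#'
#' `Ratio_i = n_high / (n_high + n_low)` over the NecroLRS-classified
#' malignant cells of sample i.
#'
#' @param n_high,n_low non-negative cell counts (vectorized).
#' @return proportion(s) in `[0, 1]`.
#' @export
ratio_high <- function(n_high, n_low) {
  stopifnot(is.numeric(n_high), is.numeric(n_low),
            length(n_high) == length(n_low))
  if (any(n_high < 0) || any(n_low < 0))
    stop("cell counts must be non-negative", call. = FALSE)
  tot <- n_high + n_low
  if (any(tot == 0))
    stop("undefined ratio: sample(s) with zero NecroLRS-classified cells",
         call. = FALSE)
  n_high / tot
}

#' Within-compartment cell-subtype proportions, ordered by Ratio
#'
#' For each sample, the proportion of each cell subtype inside one
#' compartment (e.g. myeloid or T), with samples ordered by ascending
#' `Ratio_i`. Samples with an empty compartment are flagged and their
#' proportions set `NA`.
#'
#' @param composition data frame with columns `sample`, `subtype`, `count`
#'   (non-negative integers), restricted to one compartment.
#' @param ratios named numeric `Ratio_i` per sample.
#' @return data frame `sample`, `subtype`, `proportion`, `ratio`,
#'   `flagged`, ordered by `ratio`.
#' @export
compartment_proportions <- function(composition, ratios) {
  stopifnot(is.data.frame(composition),
            all(c("sample", "subtype", "count") %in% names(composition)),
            all(composition$count >= 0), !is.null(names(ratios)))
  missing <- setdiff(unique(composition$sample), names(ratios))
  if (length(missing) > 0)
    stop("no Ratio for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  totals <- tapply(composition$count, composition$sample, sum)
  out <- composition
  out$total <- as.numeric(totals[out$sample])
  out$flagged <- out$total == 0
  out$proportion <- ifelse(out$flagged, NA_real_, out$count / out$total)
  out$ratio <- as.numeric(ratios[out$sample])
  if (any(out$flagged))
    warning("empty compartment in sample(s): ",
            paste(unique(out$sample[out$flagged]), collapse = ", "))
  # stable sort: samples by ascending ratio, subtype rows in input order
  out <- out[order(out$ratio),
             c("sample", "subtype", "proportion", "ratio", "flagged")]
  rownames(out) <- NULL
  out
}

#' Correlation between Ratio and a subtype proportion
#'
#' `method = "auto"` runs a Shapiro-Wilk normality check (alpha 0.05) on
#' both vectors and uses Pearson when neither rejects, Spearman otherwise;
#' the choice is recorded in the result. Samples with `NA` proportion
#' (empty compartments) are dropped with a warning.
#'
#' @param ratios,proportions paired numeric vectors (>= 3 complete pairs).
#' @param method `"auto"`, `"pearson"`, or `"spearman"`.
#' @param shapiro_alpha normality-test level for `"auto"` (default 0.05).
#' @return list: `coefficient`, `pval`, `method_used`, `n`.
#' @export
proportion_correlation <- function(ratios, proportions, method = c("auto",
                                   "pearson", "spearman"),
                                   shapiro_alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(length(ratios) == length(proportions))
  ok <- complete.cases(ratios, proportions)
  if (any(!ok)) {
    warning(sum(!ok), " sample(s) with undefined proportions dropped")
    ratios <- ratios[ok]
    proportions <- proportions[ok]
  }
  if (length(ratios) < 3)
    stop("need at least 3 paired samples", call. = FALSE)
  if (sd(ratios) == 0 || sd(proportions) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  if (method == "auto") {
    normal <- shapiro.test(ratios)$p.value >= shapiro_alpha &&
              shapiro.test(proportions)$p.value >= shapiro_alpha
    method <- if (normal) "pearson" else "spearman"
  }
  ct <- suppressWarnings(cor.test(ratios, proportions, method = method))
  list(coefficient = unname(ct$estimate), pval = ct$p.value,
       method_used = method, n = length(ratios))
}
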