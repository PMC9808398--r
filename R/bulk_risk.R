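# Bulk arm: expression transforms, lncRNA screening, the published
# four-lncRNA NecroLRS linear risk score, Youden-cutoff stratification, and
# survival evaluation (Kaplan-Meier / log-rank / time-dependent ROC).

#' Convert FPKM to TPM
#'
#' Per sample: `TPM_g = FPKM_g / sum_g(FPKM_g) * 1e6`. Idempotent on input
#' already on the TPM scale.
#'
#' @param fpkm sample x gene non-negative matrix.
#' @return matrix of the same shape, each row summing to 1e6.
#' @export
fpkm_to_tpm <- function(fpkm) {
  fpkm <- as.matrix(fpkm)
  if (min(fpkm) < 0) stop("FPKM values must be non-negative", call. = FALSE)
  totals <- rowSums(fpkm)
  if (any(totals == 0))
    stop("sample(s) with all-zero expression: ",
         paste(head(which(totals == 0), 5), collapse = ", "), call. = FALSE)
  sweep(fpkm, 1, totals, "/") * 1e6
}

#' Tumor-vs-normal differential expression
#'
#' Per-gene two-sided Wilcoxon rank-sum test on log2 counts-per-million
#' (`log2(CPM + 1)`), Benjamini-Hochberg adjustment. The log2 fold change is
#' the difference of group means of log2-CPM, tumor minus normal. A constant
#' gene gets `log2fc = 0` and `p = 1`.
#'
#' @param counts sample x gene count (or expression) matrix.
#' @param groups factor or character per sample with exactly two levels;
#'   the second level of `factor(groups)` is treated as "tumor" unless
#'   `tumor_level` names it.
#' @param tumor_level which level is the tumor group (default: second level).
#' @return data frame: `gene`, `log2fc`, `pval`, `padj`.
#' @export
differential_expression <- function(counts, groups, tumor_level = NULL) {
  m <- as.matrix(counts)
  groups <- factor(groups)
  if (nlevels(groups) != 2 || length(groups) != nrow(m))
    stop("'groups' must label every sample with exactly two levels",
         call. = FALSE)
  if (any(table(groups) < 2))
    stop("both groups need at least 2 samples", call. = FALSE)
  tumor_level <- tumor_level %||% levels(groups)[2]
  tumor <- groups == tumor_level

  # library-size normalization to CPM, then log2
  libsize <- rowSums(m)
  if (any(libsize == 0)) stop("sample(s) with zero total counts", call. = FALSE)
  logcpm <- log2(sweep(m, 1, libsize, "/") * 1e6 + 1)

  log2fc <- colMeans(logcpm[tumor, , drop = FALSE]) -
            colMeans(logcpm[!tumor, , drop = FALSE])
  pvals <- apply(logcpm, 2, function(x) {
    if (all(x == x[1])) return(1)
    wilcox.test(x[tumor], x[!tumor], exact = FALSE)$p.value
  })
  data.frame(gene = colnames(m), log2fc = log2fc, pval = pvals,
             padj = p.adjust(pvals, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Select differentially expressed lncRNAs
#'
#' Keeps lncRNAs with `|log2FC|` strictly above `fc_threshold` and adjusted
#' p strictly below `p_threshold`; genes on either boundary are excluded.
#'
#' @param de data frame from [differential_expression()].
#' @param lnc_genes character vector of lncRNA names (the annotation).
#' @param fc_threshold,p_threshold screening thresholds (defaults 1 and
#'   0.05).
#' @return character vector of retained lncRNA names.
#' @export
select_delncs <- function(de, lnc_genes, fc_threshold = 1, p_threshold = 0.05) {
  stopifnot(is.data.frame(de), all(c("gene", "log2fc", "padj") %in% names(de)))
  keep <- de$gene %in% lnc_genes &
    abs(de$log2fc) > fc_threshold &
    !is.na(de$padj) & de$padj < p_threshold
  de$gene[keep]
}

#' Necroptosis-gene correlation screen
#'
#' A lncRNA is retained when some necroptosis gene's expression has
#' `|Pearson r|` strictly above `r_threshold` with p strictly below
#' `p_threshold`. Zero-variance vectors are skipped with a warning.
#'
#' @param lnc_expr sample x lncRNA expression matrix.
#' @param necro_expr sample x necroptosis-gene expression matrix (same
#'   samples).
#' @param r_threshold,p_threshold screening thresholds (defaults 0.4 and
#'   0.001).
#' @return data frame of retained lncRNAs with the best pair per lncRNA:
#'   `lncRNA`, `best_partner`, `r`, `pval`.
#' @export
necroptosis_correlation <- function(lnc_expr, necro_expr,
                                    r_threshold = 0.4, p_threshold = 0.001) {
  lnc_expr <- as.matrix(lnc_expr)
  necro_expr <- as.matrix(necro_expr)
  stopifnot(nrow(lnc_expr) == nrow(necro_expr), nrow(lnc_expr) >= 3)
  lnc_ok <- apply(lnc_expr, 2, sd) > 0
  nec_ok <- apply(necro_expr, 2, sd) > 0
  if (!all(lnc_ok) || !all(nec_ok))
    warning("zero-variance column(s) skipped: ",
            sum(!lnc_ok) + sum(!nec_ok), " of ",
            ncol(lnc_expr) + ncol(necro_expr))
  out <- lapply(colnames(lnc_expr)[lnc_ok], function(l) {
    best <- NULL
    for (g in colnames(necro_expr)[nec_ok]) {
      ct <- cor.test(lnc_expr[, l], necro_expr[, g], method = "pearson")
      if (abs(ct$estimate) > r_threshold && ct$p.value < p_threshold &&
          (is.null(best) || abs(ct$estimate) > abs(best$r)))
        best <- data.frame(lncRNA = l, best_partner = g,
                           r = unname(ct$estimate), pval = ct$p.value,
                           stringsAsFactors = FALSE)
    }
    best
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(lncRNA = character(0), best_partner = character(0),
                      r = numeric(0), pval = numeric(0))
  out
}

#' Univariate Cox screen over genes
#'
#' Fits one proportional-hazards model per gene by partial-likelihood
#' maximization. Zero-variance genes and non-converging fits are flagged and
#' excluded from the fitted table.
#'
#' @param expression sample x gene matrix (any monotone transform of
#'   expression; callers typically pass `log2(TPM + 1)`).
#' @param survival data frame with `time` and `event` aligned to the rows of
#'   `expression`.
#' @return data frame: `gene`, `coef`, `hr`, `pval`, `flagged` (TRUE when
#'   the gene was skipped).
#' @export
cox_screen <- function(expression, survival) {
  m <- as.matrix(expression)
  stopifnot(is.data.frame(survival), all(c("time", "event") %in% names(survival)),
            nrow(survival) == nrow(m))
  if (sum(survival$event) < 2)
    stop("need at least 2 events for Cox screening", call. = FALSE)
  surv_obj <- survival::Surv(survival$time, survival$event)
  rows <- lapply(colnames(m), function(g) {
    x <- m[, g]
    if (sd(x) == 0)
      return(data.frame(gene = g, coef = NA_real_, hr = NA_real_,
                        pval = NA_real_, flagged = TRUE))
    fit <- tryCatch(survival::coxph(surv_obj ~ x), error = function(e) NULL,
                    warning = function(w) NULL)
    if (is.null(fit) || !is.finite(coef(fit)[1]))
      return(data.frame(gene = g, coef = NA_real_, hr = NA_real_,
                        pval = NA_real_, flagged = TRUE))
    s <- summary(fit)
    data.frame(gene = g, coef = unname(coef(fit)[1]),
               hr = unname(s$conf.int[1, "exp(coef)"]),
               pval = unname(s$coefficients[1, "Pr(>|z|)"]),
               flagged = FALSE)
  })
  do.call(rbind, rows)
}

#' The published four-lncRNA NecroLRS risk model
#'
#' Ordered genes FAM83A-AS1, LINC02323, OGFRP1, WWC2-AS2 with Cox
#' coefficients 0.2486147, 0.1862710, 0.3906980, 0.6592927, applied to
#' `log2(TPM + 1)` expression. Alternative coefficient sets (e.g. a user's
#' own fit) can be supplied.
#'
#' @param genes,coefficients override the published model.
#' @return object of class `risk_model` with `genes`, `coefficients`,
#'   `transform = "log2(TPM+1)"`.
#' @export
necrolrs_model <- function(genes = c("FAM83A-AS1", "LINC02323",
                                     "OGFRP1", "WWC2-AS2"),
                           coefficients = c(0.2486147, 0.1862710,
                                            0.3906980, 0.6592927)) {
  stopifnot(is.character(genes), is.numeric(coefficients))
  if (length(genes) != length(coefficients))
    stop("one coefficient per gene required", call. = FALSE)
  structure(list(genes = genes,
                 coefficients = setNames(coefficients, genes),
                 transform = "log2(TPM+1)"),
            class = "risk_model")
}

#' Per-sample NecroLRS risk score
#'
#' `score = sum_g coefficient_g * log2(TPM_g + 1)` over the model genes.
#'
#' @param tpm sample x gene TPM matrix (or named vector for one sample)
#'   containing every model gene.
#' @param model a [necrolrs_model()].
#' @return numeric per-sample score vector.
#' @export
necrolrs_score <- function(tpm, model = necrolrs_model()) {
  stopifnot(inherits(model, "risk_model"))
  if (is.vector(tpm)) tpm <- matrix(tpm, nrow = 1, dimnames = list(NULL, names(tpm)))
  tpm <- as.matrix(tpm)
  missing <- setdiff(model$genes, colnames(tpm))
  if (length(missing) > 0)
    stop("model gene(s) missing from the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  x <- tpm[, model$genes, drop = FALSE]
  if (min(x) < 0) stop("TPM values must be non-negative", call. = FALSE)
  as.vector(log2(x + 1) %*% model$coefficients) |>
    setNames(rownames(tpm))
}

#' Youden-index optimal cutoff
#'
#' Scans the midpoints between adjacent sorted unique scores and returns the
#' threshold maximizing `J = sensitivity + specificity - 1`, where a
#' positive call is `score > threshold`. Ties in J resolve to the smallest
#' threshold.
#'
#' @param scores numeric vector.
#' @param outcome binary vector (0/1 or logical), same length; 1 = case.
#' @return list with `cutoff`, `J`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(scores, outcome) {
  outcome <- as.integer(outcome)
  stopifnot(length(scores) == length(outcome), all(outcome %in% c(0L, 1L)))
  if (length(unique(outcome)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  u <- sort(unique(scores))
  if (length(u) < 2)
    stop("scores are constant; no cutoff exists", call. = FALSE)
  cand <- (u[-1] + u[-length(u)]) / 2
  n_case <- sum(outcome == 1)
  n_ctrl <- sum(outcome == 0)
  best <- NULL
  for (t in cand) {
    pos <- scores > t
    sens <- sum(pos & outcome == 1) / n_case
    spec <- sum(!pos & outcome == 0) / n_ctrl
    J <- sens + spec - 1
    if (is.null(best) || J > best$J)  # strict: ties keep the smallest cutoff
      best <- list(cutoff = t, J = J, sensitivity = sens, specificity = spec)
  }
  best
}

#' Stratify samples at a cutoff
#'
#' High iff `score > cutoff` (ties go Low).
#'
#' @param scores named numeric per-sample scores.
#' @param cutoff finite threshold.
#' @param provenance free-text label of the cohort the cutoff came from.
#' @return data frame of class `stratified_cohort`: `sample_id`, `score`,
#'   `group` (factor High/Low), with the cutoff and provenance as
#'   attributes.
#' @export
stratify <- function(scores, cutoff, provenance = "unspecified") {
  .check_scalar(cutoff, "cutoff")
  out <- data.frame(
    sample_id = names(scores) %||% as.character(seq_along(scores)),
    score = as.numeric(scores),
    group = factor(ifelse(scores > cutoff, "High", "Low"),
                   levels = c("Low", "High")),
    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  attr(out, "provenance") <- provenance
  class(out) <- c("stratified_cohort", class(out))
  out
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit estimates per group plus the two-group log-rank chi-square
#' (1 df) and its p-value.
#'
#' @param survival data frame with `time`, `event`.
#' @param groups factor/character per sample with two non-empty levels.
#' @return list with `fit` (a `survfit` object), `chisq`, `pval`.
#' @export
km_logrank <- function(survival, groups) {
  stopifnot(is.data.frame(survival), all(c("time", "event") %in% names(survival)))
  groups <- factor(groups)
  if (nlevels(droplevels(groups)) != 2)
    stop("exactly two non-empty groups required", call. = FALSE)
  if (sum(survival$event) < 1)
    stop("at least one event required", call. = FALSE)
  df <- data.frame(time = survival$time, event = survival$event, group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sd2 <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  list(fit = fit, chisq = unname(sd2$chisq),
       pval = pchisq(sd2$chisq, df = 1, lower.tail = FALSE))
}

#' Time-dependent ROC AUC (cumulative cases / dynamic controls)
#'
#' Inverse-probability-of-censoring-weighted estimator at horizon `t`:
#' cases are subjects with an observed event by `t`, controls those still at
#' risk after `t`. Case pairs are weighted by `1 / G(T_i-)` and controls by
#' `1 / G(t)`, where `G` is the Kaplan-Meier estimate of the censoring
#' distribution; tied scores count one half.
#'
#' @param scores numeric per-sample risk scores (higher = riskier).
#' @param survival data frame with `time`, `event`.
#' @param horizon evaluation time, within follow-up range.
#' @return the AUC estimate.
#' @export
time_dependent_auc <- function(scores, survival, horizon) {
  stopifnot(length(scores) == nrow(survival))
  .check_scalar(horizon, "horizon", lo = 0, lo_open = TRUE)
  time <- survival$time
  event <- survival$event
  if (horizon >= max(time))
    stop("'horizon' must be inside the follow-up range", call. = FALSE)
  is_case <- time <= horizon & event == 1
  is_ctrl <- time > horizon
  if (sum(is_case) == 0 || sum(is_ctrl) == 0)
    stop("no cases or no controls at the requested horizon", call. = FALSE)

  # censoring survival G from the reversed-event Kaplan-Meier
  cfit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- function(s) {
    # left-continuous evaluation: G(s-) = P(C >= s)
    idx <- cfit$time < s
    if (!any(idx)) 1 else min(cfit$surv[idx])
  }
  w_case <- 1 / vapply(time[is_case], G, numeric(1))
  w_ctrl <- rep(1 / G(horizon + 1e-12), sum(is_ctrl))

  sc <- scores[is_case]
  sctrl <- scores[is_ctrl]
  num <- 0
  den <- 0
  for (i in seq_along(sc)) {
    conc <- sum(w_ctrl * ((sc[i] > sctrl) + 0.5 * (sc[i] == sctrl)))
    num <- num + w_case[i] * conc
    den <- den + w_case[i] * sum(w_ctrl)
  }
  num / den
}
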