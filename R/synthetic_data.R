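# Synthetic cohorts with planted ground truth.
#
# Two generators: a single-cell count simulator with a nested planted
# subpopulation structure (non-malignant / malignant, and within malignant a
# NecroLRS-High-like sub-subset), and a bulk survival cohort whose event times
# follow an exponential proportional-hazards model driven by planted lncRNA
# coefficients. Both are fully determined by their seed, so every downstream
# stage can be tested against known truth.

#' Configuration for the synthetic single-cell cohort
#'
#' Counts are negative-binomial with per-gene baseline means drawn log-normal
#' around `nb_mean` and variance `mu + mu^2 / nb_dispersion`. Four disjoint
#' marker sets of `n_marker_genes` genes each are planted: one up-regulated in
#' malignant cells, one in non-malignant cells, and — nested within the
#' malignant compartment — one up in the NecroLRS-High-like subset and one in
#' its complement. Marker means are multiplied by `marker_fold_change` in the
#' carrying subpopulation.
#'
#' @param n_cells,n_genes positive integers.
#' @param frac_malignant proportion of cells planted malignant.
#' @param frac_high_within_malignant proportion of malignant cells planted
#'   into the "high" sub-subset.
#' @param n_marker_genes markers per planted signature (four signatures).
#' @param marker_fold_change multiplicative fold (>= 1) applied to marker
#'   means in the carrying subpopulation.
#' @param nb_mean,nb_dispersion negative-binomial baseline mean and dispersion.
#' @param frac_mito_genes,frac_hemoglobin_genes proportions of non-marker
#'   genes flagged mitochondrial / hemoglobin (named with `MT-` / `HBB-`
#'   prefixes).
#' @param seed integer; fully determines the generated cohort.
#' @return an object of class `sc_sim_config`.
#' @export
sc_sim_config <- function(n_cells = 2000L, n_genes = 1000L,
                          frac_malignant = 0.5,
                          frac_high_within_malignant = 0.4,
                          n_marker_genes = 50L,
                          marker_fold_change = 4,
                          nb_mean = 2, nb_dispersion = 2,
                          frac_mito_genes = 0.05,
                          frac_hemoglobin_genes = 0.01,
                          seed = 1L) {
  .check_scalar(n_cells, "n_cells", lo = 1, integer = TRUE)
  .check_scalar(n_genes, "n_genes", lo = 1, integer = TRUE)
  .check_scalar(frac_malignant, "frac_malignant", 0, 1)
  .check_scalar(frac_high_within_malignant, "frac_high_within_malignant", 0, 1)
  .check_scalar(n_marker_genes, "n_marker_genes", lo = 1, integer = TRUE)
  .check_scalar(marker_fold_change, "marker_fold_change", lo = 1)
  .check_scalar(nb_mean, "nb_mean", lo = 0, lo_open = TRUE)
  .check_scalar(nb_dispersion, "nb_dispersion", lo = 0, lo_open = TRUE)
  .check_scalar(frac_mito_genes, "frac_mito_genes", 0, 1)
  .check_scalar(frac_hemoglobin_genes, "frac_hemoglobin_genes", 0, 1)
  .check_scalar(seed, "seed", integer = TRUE)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 frac_malignant = frac_malignant,
                 frac_high_within_malignant = frac_high_within_malignant,
                 n_marker_genes = as.integer(n_marker_genes),
                 marker_fold_change = marker_fold_change,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 frac_mito_genes = frac_mito_genes,
                 frac_hemoglobin_genes = frac_hemoglobin_genes,
                 seed = as.integer(seed)),
            class = "sc_sim_config")
}

# round a planted class size, keeping at least one member when frac > 0
.planted_size <- function(n, frac) {
  if (frac <= 0) return(0L)
  max(1L, as.integer(round(n * frac)))
}

#' Generate a synthetic single-cell cohort with nested planted subsets
#'
#' @param config an [sc_sim_config()].
#' @return a list of class `sc_cohort` with elements:
#'   * `counts`: sparse gene x cell integer count matrix (`dgCMatrix`);
#'   * `gene_meta`: data frame with `gene`, `is_mito`, `is_hemoglobin`;
#'   * `truth`: planted per-cell labels (factor with levels `non_malignant`,
#'     `malignant_high`, `malignant_low`) and the four planted marker lists
#'     (`malignant`, `non_malignant`, `high`, `low`);
#'   * `config`: the configuration used.
#' @export
generate_sc_cohort <- function(config) {
  stopifnot(inherits(config, "sc_sim_config"))
  n_mark_total <- 4L * config$n_marker_genes
  if (n_mark_total > config$n_genes)
    stop("signature overflow: ", n_mark_total, " planted marker genes ",
         "requested but only ", config$n_genes, " genes available",
         call. = FALSE)

  set.seed(config$seed)
  ng <- config$n_genes
  nc <- config$n_cells
  genes <- sprintf("G%05d", seq_len(ng))

  # planted marker sets, disjoint by construction
  idx <- seq_len(n_mark_total)
  mk <- split(idx, rep(c("malignant", "non_malignant", "high", "low"),
                       each = config$n_marker_genes))

  # mito / hemoglobin flags on non-marker genes only
  free <- setdiff(seq_len(ng), idx)
  n_mito <- min(length(free), round(config$frac_mito_genes * ng))
  mito_idx <- if (n_mito > 0) sample(free, n_mito) else integer(0)
  free2 <- setdiff(free, mito_idx)
  n_hb <- min(length(free2), round(config$frac_hemoglobin_genes * ng))
  hb_idx <- if (n_hb > 0) sample(free2, n_hb) else integer(0)
  genes[mito_idx] <- paste0("MT-", genes[mito_idx])
  genes[hb_idx] <- paste0("HBB-", genes[hb_idx])

  # planted cell labels
  n_mal <- .planted_size(nc, config$frac_malignant)
  n_mal <- min(n_mal, nc)
  n_high <- min(.planted_size(n_mal, config$frac_high_within_malignant), n_mal)
  labels <- rep("non_malignant", nc)
  if (n_mal > 0) {
    mal_cells <- sample(nc, n_mal)
    labels[mal_cells] <- "malignant_low"
    if (n_high > 0) labels[mal_cells[seq_len(n_high)]] <- "malignant_high"
  }
  labels <- factor(labels,
                   levels = c("non_malignant", "malignant_high", "malignant_low"))

  # per-gene baseline means, log-normal around nb_mean
  base_mu <- rlnorm(ng, meanlog = log(config$nb_mean), sdlog = 1)

  fc <- config$marker_fold_change
  mu_for <- function(lab) {
    mu <- base_mu
    if (lab == "non_malignant") {
      mu[mk$non_malignant] <- mu[mk$non_malignant] * fc
    } else {
      mu[mk$malignant] <- mu[mk$malignant] * fc
      if (lab == "malignant_high") mu[mk$high] <- mu[mk$high] * fc
      if (lab == "malignant_low") mu[mk$low] <- mu[mk$low] * fc
    }
    mu
  }

  counts <- matrix(0L, nrow = ng, ncol = nc)
  for (lab in levels(labels)) {
    cols <- which(labels == lab)
    if (length(cols) == 0) next
    mu <- mu_for(lab)
    counts[, cols] <- rnbinom(ng * length(cols), mu = mu,
                              size = config$nb_dispersion)
  }
  dimnames(counts) <- list(genes, sprintf("C%05d", seq_len(nc)))
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "dgCMatrix")

  gene_meta <- data.frame(
    gene = genes,
    is_mito = seq_len(ng) %in% mito_idx,
    is_hemoglobin = seq_len(ng) %in% hb_idx,
    stringsAsFactors = FALSE)

  truth <- list(
    cell_labels = setNames(labels, colnames(counts)),
    markers = lapply(mk, function(i) genes[i]))

  structure(list(counts = counts, gene_meta = gene_meta,
                 truth = truth, config = config),
            class = "sc_cohort")
}

#' Configuration for the synthetic bulk survival cohort
#'
#' Event times are exponential with subject hazard
#' `baseline_hazard * exp(lp - mean(lp))` where the linear predictor `lp` is
#' `true_coefficients . log2(TPM + 1)` of the four signature lncRNAs.
#' Censoring times are independent exponential with rate tuned so the expected
#' censored fraction equals `censoring_rate`. Non-signature genes are pure
#' noise.
#'
#' @param n_samples,n_genes positive integers (`n_genes` includes the
#'   signature genes).
#' @param signature_genes character vector of planted lncRNA names.
#' @param true_coefficients log-hazard per unit `log2(TPM + 1)`, one per
#'   signature gene.
#' @param baseline_hazard events per day for a subject at the mean linear
#'   predictor.
#' @param censoring_rate expected censored fraction, in `[0, 1)`.
#' @param expression_sd standard deviation of the signature genes'
#'   `log2(TPM + 1)` values.
#' @param seed integer.
#' @return an object of class `bulk_sim_config`.
#' @export
bulk_sim_config <- function(n_samples = 300L, n_genes = 200L,
                            signature_genes = c("FAM83A-AS1", "LINC02323",
                                                "OGFRP1", "WWC2-AS2"),
                            true_coefficients = c(1, 1, 1, 1),
                            baseline_hazard = 0.002,
                            censoring_rate = 0.3,
                            expression_sd = 1,
                            seed = 1L) {
  .check_scalar(n_samples, "n_samples", lo = 2, integer = TRUE)
  .check_scalar(n_genes, "n_genes", lo = 1, integer = TRUE)
  stopifnot(is.character(signature_genes), length(signature_genes) >= 1,
            !anyDuplicated(signature_genes))
  if (length(true_coefficients) != length(signature_genes))
    stop("'true_coefficients' must match 'signature_genes' in length",
         call. = FALSE)
  .check_scalar(baseline_hazard, "baseline_hazard", lo = 0, lo_open = TRUE)
  .check_scalar(censoring_rate, "censoring_rate", 0, 1, hi_open = TRUE)
  .check_scalar(expression_sd, "expression_sd", lo = 0, lo_open = TRUE)
  .check_scalar(seed, "seed", integer = TRUE)
  if (n_genes < length(signature_genes))
    stop("'n_genes' must be at least the number of signature genes",
         call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 signature_genes = signature_genes,
                 true_coefficients = as.numeric(true_coefficients),
                 baseline_hazard = baseline_hazard,
                 censoring_rate = censoring_rate,
                 expression_sd = expression_sd,
                 seed = as.integer(seed)),
            class = "bulk_sim_config")
}

#' Generate a synthetic bulk cohort with planted hazard structure
#'
#' @param config a [bulk_sim_config()].
#' @return a list of class `bulk_cohort` with elements `expression`
#'   (sample x gene TPM matrix), `survival` (data frame: `sample_id`,
#'   `time` in days, `event` in `{0, 1}`), `unit` (`"TPM"`), `truth`
#'   (per-sample true linear predictor and the planted coefficients), and
#'   `config`.
#' @export
generate_bulk_cohort <- function(config) {
  stopifnot(inherits(config, "bulk_sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  sig <- config$signature_genes
  p_sig <- length(sig)
  p_noise <- config$n_genes - p_sig

  # signature genes on the log2(TPM+1) scale, then back-transformed
  log_expr <- matrix(pmax(rnorm(n * p_sig, mean = 2, sd = config$expression_sd), 0),
                     nrow = n, dimnames = list(NULL, sig))
  lp <- as.vector(log_expr %*% config$true_coefficients)
  lp_c <- lp - mean(lp)
  rate_i <- config$baseline_hazard * exp(lp_c)

  samples <- sprintf("S%04d", seq_len(n))
  draw_surv <- function() {
    t_event <- rexp(n, rate = rate_i)
    if (config$censoring_rate == 0) {
      return(data.frame(sample_id = samples, time = t_event, event = 1L,
                        stringsAsFactors = FALSE))
    }
    # rate_c solving mean_i[ rc / (rc + rate_i) ] = censoring_rate
    f <- function(rc) mean(rc / (rc + rate_i)) - config$censoring_rate
    rate_c <- stats::uniroot(f, lower = 1e-12, upper = 1e6,
                             extendInt = "upX")$root
    t_cens <- rexp(n, rate = rate_c)
    data.frame(sample_id = samples,
               time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens),
               stringsAsFactors = FALSE)
  }
  surv <- draw_surv()
  tries <- 0L
  while (sum(surv$event) == 0L && tries < 100L) {
    tries <- tries + 1L
    surv <- draw_surv()
  }
  if (tries > 0L)
    warning("all-censored draw at the requested censoring rate; resampled (",
            tries, " extra draw", if (tries > 1) "s", ")")
  if (sum(surv$event) == 0L)
    stop("could not draw a cohort with at least one event", call. = FALSE)

  noise_names <- if (p_noise > 0) sprintf("NOISE%04d", seq_len(p_noise))
                 else character(0)
  noise <- if (p_noise > 0)
    matrix(rlnorm(n * p_noise, meanlog = 1, sdlog = 1), nrow = n,
           dimnames = list(NULL, noise_names))
  else matrix(0, nrow = n, ncol = 0)

  expression <- cbind(2^log_expr - 1, noise)
  rownames(expression) <- samples

  structure(list(expression = expression, survival = surv, unit = "TPM",
                 truth = list(true_risk = setNames(lp, samples),
                              coefficients = setNames(config$true_coefficients, sig),
                              signature_genes = sig),
                 config = config),
            class = "bulk_cohort")
}

#' Simulate per-sample subset compositions
#'
#' Generates, for a small panel of samples, NecroLRS-High / -Low malignant
#' cell counts (high fractions spread uniformly over `high_range`) and a
#' myeloid compartment in which the expected neutrophil proportion increases
#' linearly with the high fraction: `intercept + slope * Ratio_i`, the
#' remainder split evenly over the other subtypes. Counts are multinomial.
#'
#' @param n_samples number of samples (default 12).
#' @param cells_per_compartment malignant and myeloid cells per sample
#'   (default 200).
#' @param high_range range of planted high fractions (default `c(0.1, 0.9)`).
#' @param slope,intercept linear link from high fraction to expected
#'   neutrophil proportion (defaults 0.5 and 0.1).
#' @param subtypes myeloid subtype names; the first is the one tied to the
#'   high fraction.
#' @param seed integer.
#' @return list with `composition` (data frame `sample`, `subtype`, `count`),
#'   `malignant_counts` (data frame `sample`, `n_high`, `n_low`), and
#'   `true_high_frac`.
#' @export
simulate_sample_compositions <- function(n_samples = 12L,
                                         cells_per_compartment = 200L,
                                         high_range = c(0.1, 0.9),
                                         slope = 0.5, intercept = 0.1,
                                         subtypes = c("Neutrophil",
                                                      "Macrophage",
                                                      "Monocyte",
                                                      "Dendritic"),
                                         seed = 1L) {
  .check_scalar(n_samples, "n_samples", lo = 2, integer = TRUE)
  .check_scalar(cells_per_compartment, "cells_per_compartment", lo = 1,
                integer = TRUE)
  set.seed(seed)
  samples <- sprintf("P%02d", seq_len(n_samples))
  high_frac <- seq(high_range[1], high_range[2], length.out = n_samples)
  n_high <- rbinom(n_samples, cells_per_compartment, high_frac)
  mal <- data.frame(sample = samples, n_high = n_high,
                    n_low = cells_per_compartment - n_high)
  p_neut <- pmin(0.95, pmax(0.01, intercept + slope * high_frac))
  comp <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    probs <- c(p_neut[i], rep((1 - p_neut[i]) / (length(subtypes) - 1),
                              length(subtypes) - 1))
    cnt <- as.vector(stats::rmultinom(1, cells_per_compartment, probs))
    data.frame(sample = samples[i], subtype = subtypes, count = cnt)
  }))
  list(composition = comp, malignant_counts = mal, true_high_frac = high_frac)
}

#' Write a synthetic single-cell cohort as a 10x-style MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv` (gene, is_mito, is_hemoglobin),
#' `barcodes.tsv`, and the planted truth as `truth_cells.tsv` and
#' `truth_markers.tsv`.
#'
#' @param cohort an `sc_cohort`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_sc_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sc_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(cohort$counts, file.path(dir, "matrix.mtx"))
  write.table(cohort$gene_meta, file.path(dir, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(colnames(cohort$counts), file.path(dir, "barcodes.tsv"))
  write.table(data.frame(cell = names(cohort$truth$cell_labels),
                         label = as.character(cohort$truth$cell_labels)),
              file.path(dir, "truth_cells.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  mk <- cohort$truth$markers
  write.table(data.frame(signature = rep(names(mk), lengths(mk)),
                         gene = unlist(mk, use.names = FALSE)),
              file.path(dir, "truth_markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write a synthetic bulk cohort as TSV tables
#'
#' Writes `expression.tsv` (samples x genes), `survival.tsv`
#' (`sample_id`, `time`, `event`), and `truth_risk.tsv`.
#'
#' @param cohort a `bulk_cohort`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_bulk_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "bulk_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- data.frame(sample_id = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
  write.table(expr, file.path(dir, "expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$survival, file.path(dir, "survival.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample_id = names(cohort$truth$true_risk),
                         true_risk = unname(cohort$truth$true_risk)),
              file.path(dir, "truth_risk.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
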