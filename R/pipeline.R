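# End-to-end pipeline over the synthetic cohorts: generate -> QC -> score ->
# classify -> stratify -> evaluate -> subset stats, with every artifact
# written under one run directory and a single master seed driving all
# randomness through derived per-stage streams.

#' Pipeline configuration
#'
#' Collects every tunable of the workflow with the screening and QC
#' thresholds at their published defaults. The object round-trips through
#' JSON ([write_pipeline_config()] / [read_pipeline_config()]) and the
#' resolved configuration is written next to every run's outputs.
#'
#' @param seed master seed; per-stage streams derive from it.
#' @param outdir run directory.
#' @param sc an [sc_sim_config()] (its own seed is overridden by the derived
#'   stream).
#' @param bulk a [bulk_sim_config()] (likewise).
#' @param qc a [qc_thresholds()].
#' @param n_bins,n_per_gene module-score parameters (defaults 25, 100).
#' @param top_n signature size per side (default 50).
#' @param max_iter classifier iteration cap (default 20).
#' @param horizon_days time-dependent ROC horizon (default 365).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("necrostrat_run_"),
                            sc = sc_sim_config(),
                            bulk = bulk_sim_config(),
                            qc = qc_thresholds(),
                            n_bins = 25L, n_per_gene = 100L,
                            top_n = 50L, max_iter = 20L,
                            horizon_days = 365) {
  structure(list(seed = as.integer(seed), outdir = outdir, sc = sc,
                 bulk = bulk, qc = qc, n_bins = as.integer(n_bins),
                 n_per_gene = as.integer(n_per_gene),
                 top_n = as.integer(top_n), max_iter = as.integer(max_iter),
                 horizon_days = horizon_days),
            class = "pipeline_config")
}

#' Serialize a pipeline configuration to JSON
#'
#' @param config a [pipeline_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  jsonlite::write_json(strip(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a pipeline configuration from JSON
#'
#' @param path JSON written by [write_pipeline_config()].
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  pipeline_config(
    seed = x$seed, outdir = x$outdir,
    sc = do.call(sc_sim_config, x$sc),
    bulk = do.call(bulk_sim_config, x$bulk),
    qc = do.call(qc_thresholds, x$qc),
    n_bins = x$n_bins, n_per_gene = x$n_per_gene,
    top_n = x$top_n, max_iter = x$max_iter,
    horizon_days = x$horizon_days)
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes, in order: synthetic-data generation (single-cell and bulk), cell
#' QC with the doublet-rate report, log-normalization, nested three-way
#' classification seeded from the planted marker lists, NecroLRS scoring of
#' the bulk cohort with the published model, Youden-cutoff stratification,
#' Kaplan-Meier / log-rank / time-dependent-AUC evaluation, and the
#' per-sample NecroLRS-High ratio. Each stage logs an INFO summary; any stage
#' error aborts with the stage name, leaving earlier outputs in place.
#' Reruns with the same configuration are bit-reproducible.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with the per-stage objects and
#'   the run directory; artifacts (label TSVs, reports, resolved config) are
#'   written under `config$outdir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(config$outdir, "run.log")
  log_line <- function(stage, msg) {
    line <- sprintf("[%s] INFO %s", stage, msg)
    message(line)
    cat(line, "\n", file = logf, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  write_pipeline_config(config, file.path(config$outdir, "config.json"))

  # -- synth -----------------------------------------------------------------
  res <- stage("synth", {
    sc_cfg <- config$sc
    sc_cfg$seed <- derive_seed(config$seed, "synth_sc")
    bulk_cfg <- config$bulk
    bulk_cfg$seed <- derive_seed(config$seed, "synth_bulk")
    list(sc = generate_sc_cohort(sc_cfg), bulk = generate_bulk_cohort(bulk_cfg))
  })
  log_line("synth", sprintf("%d cells x %d genes; bulk %d samples",
                            ncol(res$sc$counts), nrow(res$sc$counts),
                            nrow(res$bulk$expression)))

  # -- qc ---------------------------------------------------------------------
  qc <- stage("qc", {
    metrics <- compute_qc_metrics(res$sc$counts, res$sc$gene_meta$is_mito,
                                  res$sc$gene_meta$is_hemoglobin)
    keep <- filter_cells(metrics, config$qc)
    dr <- expected_doublet_rate(sum(Matrix::rowSums(res$sc$counts) > 0))
    list(metrics = metrics, keep = keep, doublet_rate = dr)
  })
  log_line("qc", sprintf("%d / %d cells kept; expected doublet rate %.4f",
                         sum(qc$keep), length(qc$keep), qc$doublet_rate))
  write_tsv_provenance(cbind(qc$metrics, kept = qc$keep),
                       file.path(config$outdir, "qc_metrics.tsv"),
                       config = config$qc, seed = config$seed)
  counts_kept <- res$sc$counts[, qc$keep, drop = FALSE]

  # -- score + classify -------------------------------------------------------
  call3 <- stage("classify", {
    norm <- lognormalize(counts_kept)
    mk <- res$sc$truth$markers
    nested_three_way(
      norm,
      malignant_initial = signature_pair(mk$malignant, mk$non_malignant),
      necro_initial = signature_pair(mk$high, mk$low),
      max_iter = config$max_iter, top_n = config$top_n,
      n_bins = config$n_bins, n_per_gene = config$n_per_gene,
      seed = derive_seed(config$seed, "classify"))
  })
  log_line("classify", sprintf(
    "labels: %s; round 1 %s after %d iterations",
    paste(sprintf("%s=%d", levels(call3$labels), table(call3$labels)),
          collapse = ", "),
    if (call3$malignant_state$converged) "converged" else "not converged",
    call3$malignant_state$iterations))
  write_tsv_provenance(data.frame(cell = names(call3$labels),
                                  label = as.character(call3$labels)),
                       file.path(config$outdir, "cell_labels.tsv"),
                       config = config, seed = config$seed)

  # -- stratify + evaluate ----------------------------------------------------
  evalres <- stage("stratify", {
    scores <- necrolrs_score(res$bulk$expression,
                             necrolrs_model(genes = res$bulk$truth$signature_genes,
                                            coefficients = necrolrs_model()$coefficients))
    yc <- youden_cutoff(scores, res$bulk$survival$event)
    strat <- stratify(scores, yc$cutoff, provenance = "synthetic cohort")
    lr <- km_logrank(res$bulk$survival, strat$group)
    auc <- time_dependent_auc(scores, res$bulk$survival, config$horizon_days)
    list(scores = scores, cutoff = yc, stratified = strat, logrank = lr,
         auc = auc)
  })
  log_line("stratify", sprintf(
    "Youden cutoff %.4f (J=%.3f); log-rank chisq %.2f (p=%.2g); AUC(%gd)=%.3f",
    evalres$cutoff$cutoff, evalres$cutoff$J, evalres$logrank$chisq,
    evalres$logrank$pval, config$horizon_days, evalres$auc))
  write_tsv_provenance(as.data.frame(evalres$stratified),
                       file.path(config$outdir, "risk_groups.tsv"),
                       config = config, seed = config$seed)

  # -- subset stats -----------------------------------------------------------
  subset <- stage("subsets", {
    n_high <- sum(call3$labels == "NecroLRS-High")
    n_low <- sum(call3$labels == "NecroLRS-Low")
    list(n_high = n_high, n_low = n_low,
         ratio = if (n_high + n_low > 0) ratio_high(n_high, n_low) else NA_real_)
  })
  log_line("subsets", sprintf("NecroLRS-High ratio %.3f (%d high / %d low)",
                              subset$ratio, subset$n_high, subset$n_low))

  report <- list(
    doublet_rate = qc$doublet_rate,
    cells_kept = sum(qc$keep),
    label_counts = as.list(table(call3$labels)),
    youden_cutoff = evalres$cutoff$cutoff,
    logrank_chisq = evalres$logrank$chisq,
    logrank_pval = evalres$logrank$pval,
    auc = evalres$auc,
    ratio_high = subset$ratio)
  jsonlite::write_json(report, file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(config = config, sc = res$sc, bulk = res$bulk, qc = qc,
                 calls = call3, evaluation = evalres, subset = subset,
                 report = report, outdir = config$outdir),
            class = "pipeline_result")
}
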