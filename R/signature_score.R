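# Binned-control module scoring.
#
# The per-cell score of a gene signature is the mean (log-normalized)
# expression of the signature genes minus the mean over a pooled control
# multiset: for each signature gene, 100 control genes are drawn from the
# expression bin (of 25) holding genes of similar average expression. The
# subtraction removes the cell's overall expression level, so the score
# measures signature-specific activity.

#' Log-normalize a count matrix
#'
#' Per cell: counts divided by the cell's total, multiplied by `scale`, then
#' `log(1 + x)`. Cells with zero total counts are rejected — run QC first.
#'
#' @param counts gene x cell non-negative count matrix.
#' @param scale library-size scale factor (default `1e4`).
#' @return dense gene x cell matrix of log-normalized expression.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  .check_counts(counts)
  .check_scalar(scale, "scale", lo = 0, lo_open = TRUE)
  totals <- Matrix::colSums(counts)
  if (any(totals == 0))
    stop("cells with zero total counts present; apply QC filtering first",
         call. = FALSE)
  m <- as.matrix(counts)
  log1p(sweep(m, 2, totals, "/") * scale)
}

#' Bin genes by mean expression
#'
#' Genes are ranked by mean expression (ties broken by input order) and cut
#' into `n_bins` groups of near-equal size, lowest-expression genes in bin 1.
#'
#' @param mean_expression named numeric vector, one value per gene.
#' @param n_bins number of bins (default 25).
#' @return integer bin index per gene, named like the input.
#' @export
bin_genes <- function(mean_expression, n_bins = 25L) {
  stopifnot(is.numeric(mean_expression))
  n <- length(mean_expression)
  .check_scalar(n_bins, "n_bins", lo = 1, integer = TRUE)
  if (n < n_bins)
    stop("need at least 'n_bins' genes (", n_bins, "), got ", n, call. = FALSE)
  r <- rank(mean_expression, ties.method = "first")
  bins <- as.integer(floor((r - 1) * n_bins / n) + 1L)
  names(bins) <- names(mean_expression)
  bins
}

#' Sample expression-matched control genes for a signature
#'
#' For each signature gene, draws `n_per_gene` genes uniformly without
#' replacement from its expression bin, excluding the gene itself. When a bin
#' holds fewer eligible genes, the whole bin is taken. Controls are pooled
#' across signature genes into one multiset (a gene drawn for two signature
#' genes counts twice).
#'
#' @param signature character vector of signature gene names.
#' @param bins integer bin index per gene, named (from [bin_genes()]).
#' @param n_per_gene controls per signature gene (default 100).
#' @param seed integer seed for the draw.
#' @return list of class `control_set`: `per_gene` (named list of control
#'   vectors), `pooled` (the control multiset), `seed`.
#' @export
sample_controls <- function(signature, bins, n_per_gene = 100L, seed = 1L) {
  stopifnot(is.character(signature), length(signature) >= 1,
            !is.null(names(bins)))
  .check_scalar(n_per_gene, "n_per_gene", lo = 1, integer = TRUE)
  missing <- setdiff(signature, names(bins))
  if (length(missing) > 0)
    stop("signature genes absent from the binned gene universe: ",
         paste(head(missing, 5), collapse = ", "), call. = FALSE)
  set.seed(seed)
  per_gene <- lapply(signature, function(g) {
    pool <- names(bins)[bins == bins[[g]]]
    pool <- setdiff(pool, g)
    if (length(pool) == 0)
      stop("bin holding '", g, "' has no eligible control genes", call. = FALSE)
    if (length(pool) <= n_per_gene) pool else sample(pool, n_per_gene)
  })
  names(per_gene) <- signature
  structure(list(per_gene = per_gene,
                 pooled = unlist(per_gene, use.names = FALSE),
                 seed = as.integer(seed)),
            class = "control_set")
}

#' Binned-control module score
#'
#' Per cell: mean normalized expression over the signature genes minus the
#' mean over the pooled control multiset.
#'
#' @param norm_matrix gene x cell log-normalized matrix (from
#'   [lognormalize()]).
#' @param signature character vector of signature gene names; genes absent
#'   from the matrix are dropped, an empty intersection is an error.
#' @param controls a `control_set` from [sample_controls()].
#' @return numeric per-cell score vector, named by cell.
#' @export
module_score <- function(norm_matrix, signature, controls) {
  stopifnot(is.matrix(norm_matrix) || is(norm_matrix, "Matrix"),
            inherits(controls, "control_set"))
  sig <- intersect(signature, rownames(norm_matrix))
  if (length(sig) == 0)
    stop("no signature gene present in the expression matrix", call. = FALSE)
  ctrl <- controls$pooled
  if (!all(ctrl %in% rownames(norm_matrix)))
    stop("control genes absent from the expression matrix", call. = FALSE)
  sig_mean <- Matrix::colMeans(norm_matrix[sig, , drop = FALSE])
  # pooled multiset mean: duplicates keep their multiplicity
  ctrl_mean <- Matrix::colMeans(norm_matrix[ctrl, , drop = FALSE])
  as.numeric(sig_mean - ctrl_mean) |> setNames(colnames(norm_matrix))
}

#' Score a signature end to end
#'
#' Convenience wrapper: bins all genes of the matrix by their mean normalized
#' expression, samples controls, and computes the module score.
#'
#' @inheritParams module_score
#' @param n_bins,n_per_gene binning and control-set sizes (defaults 25, 100).
#' @param seed integer seed for the control draw.
#' @return list with `score` (per-cell vector), `controls`, `bins`.
#' @export
score_signature <- function(norm_matrix, signature, n_bins = 25L,
                            n_per_gene = 100L, seed = 1L) {
  mean_expr <- Matrix::rowMeans(norm_matrix)
  bins <- bin_genes(mean_expr, n_bins = n_bins)
  sig <- intersect(signature, rownames(norm_matrix))
  if (length(sig) == 0)
    stop("no signature gene present in the expression matrix", call. = FALSE)
  controls <- sample_controls(sig, bins, n_per_gene = n_per_gene, seed = seed)
  list(score = module_score(norm_matrix, sig, controls),
       controls = controls, bins = bins)
}

#' Read a two-column signature table
#'
#' @param path TSV with columns `signature_name`, `gene`.
#' @return named list of gene vectors, one per signature name.
#' @export
read_signatures <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("signature_name", "gene") %in% names(df)))
    stop("signature file needs columns 'signature_name' and 'gene'",
         call. = FALSE)
  split(df$gene, df$signature_name)
}

#' Write signatures as a two-column table
#'
#' @param signatures named list of gene vectors.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(signatures, path) {
  df <- data.frame(signature_name = rep(names(signatures), lengths(signatures)),
                   gene = unlist(signatures, use.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
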