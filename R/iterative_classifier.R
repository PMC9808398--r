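# Iterative module-score + K-means cell-state classifier.
#
# One round: score every cell with a "positive" and a "negative" signature
# (binned-control module scores), run 2-centroid K-means in the (Sm, Sn)
# plane, identify the positive centroid by the rule "higher mean positive
# score AND lower mean negative score", then refine both signatures by
# differential expression between the two called groups. Rounds repeat until
# the marker sets stabilize. Applied twice in a nested fashion, the
# classifier calls Non-malignant / NecroLRS-High / NecroLRS-Low epithelial
# cells.

#' A positive/negative signature pair
#'
#' @param positive,negative character vectors of gene names; must be
#'   disjoint and non-empty.
#' @return an object of class `signature_pair`.
#' @export
signature_pair <- function(positive, negative) {
  stopifnot(is.character(positive), is.character(negative),
            length(positive) >= 1, length(negative) >= 1)
  if (length(intersect(positive, negative)) > 0)
    stop("positive and negative signatures must be disjoint", call. = FALSE)
  structure(list(positive = unique(positive), negative = unique(negative)),
            class = "signature_pair")
}

#' Initial signature pair from a bulk differential-expression table
#'
#' Takes the `top_n` significant genes in each direction: the positive
#' signature collects the strongest up-regulated genes, the negative the
#' strongest down-regulated. When a side holds fewer than `top_n` significant
#' genes, all available are taken with a warning.
#'
#' @param bulk_de data frame with columns `gene`, `log2fc`, `padj`.
#' @param top_n genes per side (default 50).
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @return a [signature_pair()].
#' @export
derive_initial_signatures <- function(bulk_de, top_n = 50L, alpha = 0.05) {
  stopifnot(is.data.frame(bulk_de),
            all(c("gene", "log2fc", "padj") %in% names(bulk_de)))
  .check_scalar(top_n, "top_n", lo = 1, integer = TRUE)
  sig <- bulk_de[!is.na(bulk_de$padj) & bulk_de$padj < alpha, ]
  up <- sig[sig$log2fc > 0, ]
  down <- sig[sig$log2fc < 0, ]
  up <- up[order(-up$log2fc), ]
  down <- down[order(down$log2fc), ]
  if (nrow(up) < top_n || nrow(down) < top_n)
    warning("fewer than ", top_n, " significant genes on a side (",
            nrow(up), " up, ", nrow(down), " down); taking all available")
  if (nrow(up) == 0 || nrow(down) == 0)
    stop("no significant genes in one direction; cannot build a signature pair",
         call. = FALSE)
  signature_pair(head(up$gene, top_n), head(down$gene, top_n))
}

#' Two-centroid K-means on the score plane
#'
#' Standard K-means with k = 2 on the per-cell (Sm, Sn) points, 10 restarts,
#' best within-cluster sum of squares kept; the restart stream is derived
#' from `seed` so the result is deterministic.
#'
#' @param scores numeric matrix with one row per cell and two columns
#'   (positive score, negative score).
#' @param seed integer.
#' @param nstart number of random restarts (default 10).
#' @return list with `labels` (integer vector in `{1, 2}`) and `centroids`
#'   (2 x 2 matrix, rows = clusters).
#' @export
kmeans_two <- function(scores, seed = 1L, nstart = 10L) {
  scores <- as.matrix(scores)
  stopifnot(ncol(scores) == 2, nrow(scores) >= 2)
  if (nrow(unique(scores)) < 2)
    stop("all score points identical; K-means is degenerate", call. = FALSE)
  set.seed(derive_seed(seed, "kmeans"))
  km <- kmeans(scores, centers = 2, nstart = nstart, iter.max = 50)
  list(labels = as.integer(km$cluster), centroids = km$centers)
}

#' Identify the positive (malignant) centroid
#'
#' Cluster 1 is positive when it has the higher mean positive score AND the
#' lower mean negative score; cluster 2 in the mirrored case. The rule covers
#' only concordant patterns; when one cluster is higher in both scores the
#' positive score dominates (the cluster with the higher mean Sm wins, then
#' the lower mean Sn), and exactly tied means on both axes are an error.
#'
#' @param cluster_stats 2 x 2 numeric matrix: rows = clusters 1 and 2,
#'   columns = (mean positive score, mean negative score).
#' @return integer 1 or 2 — the positive cluster.
#' @export
assign_positive_centroid <- function(cluster_stats) {
  cluster_stats <- as.matrix(cluster_stats)
  stopifnot(nrow(cluster_stats) == 2, ncol(cluster_stats) == 2,
            all(is.finite(cluster_stats)))
  sm <- cluster_stats[, 1]
  sn <- cluster_stats[, 2]
  if (sm[1] > sm[2] && sn[1] < sn[2]) return(1L)
  if (sm[1] < sm[2] && sn[1] > sn[2]) return(2L)
  # discordant pattern: positive score dominates
  if (sm[1] != sm[2]) return(as.integer(which.max(sm)))
  if (sn[1] != sn[2]) return(as.integer(which.min(sn)))
  stop("cluster means identical on both scores; positive centroid unresolvable",
       call. = FALSE)
}

#' Refine a signature pair by differential expression between called groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test between the current positive and
#' negative cells on the normalized matrix, Benjamini-Hochberg adjustment.
#' Among genes significant at `alpha`, the `top_n` by absolute log fold
#' change (difference of group means of log-normalized expression) in each
#' direction form the refined pair.
#'
#' @param norm_matrix gene x cell log-normalized matrix.
#' @param positive_cells logical per-cell mask (TRUE = positive group).
#' @param top_n genes per side (default 50).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @param min_cells smallest group size allowed (default 3).
#' @return list with `pair` (a [signature_pair()], or `NULL` when no gene is
#'   significant in one of the directions) and `de` (the per-gene table).
#' @export
refine_markers <- function(norm_matrix, positive_cells, top_n = 50L,
                           alpha = 0.05, min_cells = 3L) {
  m <- as.matrix(norm_matrix)
  stopifnot(is.logical(positive_cells), length(positive_cells) == ncol(m))
  n_pos <- sum(positive_cells)
  n_neg <- sum(!positive_cells)
  if (n_pos < min_cells || n_neg < min_cells)
    stop("refinement unstable: a group has fewer than ", min_cells, " cells (",
         n_pos, " positive, ", n_neg, " negative)", call. = FALSE)

  logfc <- rowMeans(m[, positive_cells, drop = FALSE]) -
           rowMeans(m[, !positive_cells, drop = FALSE])
  pvals <- apply(m, 1, function(x) {
    if (all(x == x[1])) return(1)  # constant gene: no evidence
    wilcox.test(x[positive_cells], x[!positive_cells], exact = FALSE)$p.value
  })
  padj <- p.adjust(pvals, method = "BH")
  de <- data.frame(gene = rownames(m), logfc = logfc, pval = pvals,
                   padj = padj, row.names = NULL, stringsAsFactors = FALSE)

  sig <- de[de$padj < alpha, ]
  up <- sig[sig$logfc > 0, ]
  down <- sig[sig$logfc < 0, ]
  up <- up[order(-abs(up$logfc)), ]
  down <- down[order(-abs(down$logfc)), ]
  pair <- if (nrow(up) == 0 || nrow(down) == 0) NULL
          else signature_pair(head(up$gene, top_n), head(down$gene, top_n))
  list(pair = pair, de = de)
}

# centroid separation used to pick the best iteration under oscillation
.centroid_gap <- function(centroids) sqrt(sum((centroids[1, ] - centroids[2, ])^2))

#' Run the iterative classifier to convergence
#'
#' Loops score -> K-means -> centroid assignment -> marker refinement.
#' Convergence is declared when the refined positive AND negative sets are
#' each identical to the previous round's, or when both Jaccard similarities
#' are at least `jaccard_tol` for two consecutive rounds; a round whose
#' refinement finds no significant genes on a side leaves the signatures
#' unchanged and also converges. A revisited signature state (without
#' stability) is flagged as oscillation and the round with the widest
#' centroid separation is returned.
#'
#' @param norm_matrix gene x cell log-normalized matrix.
#' @param initial a [signature_pair()]; genes absent from the matrix are
#'   dropped at scoring time.
#' @param max_iter iteration cap (default 20).
#' @param top_n,alpha refinement parameters, see [refine_markers()].
#' @param n_bins,n_per_gene scoring parameters, see [score_signature()].
#' @param jaccard_tol near-stability threshold (default 0.99).
#' @param seed master seed; control draws and K-means restarts use derived
#'   streams.
#' @return a list of class `classifier_state`: `positive_cells` (logical
#'   per-cell call), `sm`, `sn` (final scores), `cluster_labels`,
#'   `centroids`, `positive_centroid`, `signatures` (final pair),
#'   `iterations`, `converged`, `oscillated`, and `history` (one record per
#'   round).
#' @export
run_iterative_classifier <- function(norm_matrix, initial, max_iter = 20L,
                                     top_n = 50L, alpha = 0.05,
                                     n_bins = 25L, n_per_gene = 100L,
                                     jaccard_tol = 0.99, seed = 1L) {
  stopifnot(inherits(initial, "signature_pair"))
  m <- as.matrix(norm_matrix)
  if (length(intersect(c(initial$positive, initial$negative), rownames(m))) == 0)
    stop("initial signatures do not intersect the expression matrix",
         call. = FALSE)

  pair <- initial
  history <- list()
  seen <- character(0)
  near_stable_prev <- FALSE
  converged <- FALSE
  oscillated <- FALSE
  best <- NULL

  state_key <- function(p) paste(c(sort(p$positive), "|", sort(p$negative)),
                                 collapse = ",")

  for (it in seq_len(max_iter)) {
    sm <- score_signature(m, pair$positive, n_bins = n_bins,
                          n_per_gene = n_per_gene,
                          seed = derive_seed(seed, "controls_pos", it))$score
    sn <- score_signature(m, pair$negative, n_bins = n_bins,
                          n_per_gene = n_per_gene,
                          seed = derive_seed(seed, "controls_neg", it))$score
    km <- kmeans_two(cbind(sm, sn), seed = derive_seed(seed, "km", it))
    cl_stats <- rbind(c(mean(sm[km$labels == 1]), mean(sn[km$labels == 1])),
                      c(mean(sm[km$labels == 2]), mean(sn[km$labels == 2])))
    pos_centroid <- assign_positive_centroid(cl_stats)
    positive_cells <- km$labels == pos_centroid

    ref <- refine_markers(m, positive_cells, top_n = top_n, alpha = alpha)

    rec <- list(iteration = it, signatures = pair, cluster_stats = cl_stats,
                positive_centroid = pos_centroid, n_positive = sum(positive_cells),
                centroid_gap = .centroid_gap(cl_stats))
    history[[it]] <- rec
    if (is.null(best) || rec$centroid_gap > best$state$centroid_gap)
      best <- list(state = rec, sm = sm, sn = sn, labels = km$labels,
                   centroids = km$centers, positive_cells = positive_cells)

    final <- list(positive_cells = setNames(positive_cells, colnames(m)),
                  sm = sm, sn = sn, cluster_labels = km$labels,
                  centroids = km$centers, positive_centroid = pos_centroid,
                  signatures = pair, iterations = it)

    if (is.null(ref$pair)) { converged <- TRUE; break }
    jp <- .jaccard(ref$pair$positive, pair$positive)
    jn <- .jaccard(ref$pair$negative, pair$negative)
    if (jp == 1 && jn == 1) { converged <- TRUE; break }
    near_stable <- jp >= jaccard_tol && jn >= jaccard_tol
    if (near_stable && near_stable_prev) { converged <- TRUE; break }
    near_stable_prev <- near_stable

    key <- state_key(ref$pair)
    if (key %in% seen) {
      oscillated <- TRUE
      final <- list(positive_cells = setNames(best$positive_cells, colnames(m)),
                    sm = best$sm, sn = best$sn,
                    cluster_labels = best$labels, centroids = best$centroids,
                    positive_centroid = best$state$positive_centroid,
                    signatures = best$state$signatures,
                    iterations = it)
      break
    }
    seen <- c(seen, state_key(pair))
    pair <- ref$pair
  }

  structure(c(final, list(converged = converged, oscillated = oscillated,
                          history = history, seed = seed)),
            class = "classifier_state")
}

#' Nested three-way cell calling
#'
#' Round 1 runs the iterative classifier with the malignant/non-malignant
#' signature pair on all epithelial cells; round 2 reruns it with the
#' NecroLRS-High/Low pair on the malignant cells only. Labels merge into a
#' three-way partition.
#'
#' @param epithelial_matrix gene x cell log-normalized matrix of epithelial
#'   cells.
#' @param malignant_initial,necro_initial [signature_pair()]s for the two
#'   rounds.
#' @param min_round2 smallest malignant set on which round 2 is attempted
#'   (default 10 cells).
#' @param seed master seed.
#' @param ... further parameters passed to [run_iterative_classifier()].
#' @return list of class `three_way_call`: `labels` (factor per cell with
#'   levels `Non-malignant`, `NecroLRS-High`, `NecroLRS-Low`),
#'   `malignant_state`, `necro_state` (the two classifier states; the second
#'   `NULL` when skipped), and `round2_skipped` with a reason.
#' @export
nested_three_way <- function(epithelial_matrix, malignant_initial,
                             necro_initial, min_round2 = 10L, seed = 1L, ...) {
  m <- as.matrix(epithelial_matrix)
  r1 <- run_iterative_classifier(m, malignant_initial,
                                 seed = derive_seed(seed, "round1"), ...)
  labels <- rep("Non-malignant", ncol(m))
  names(labels) <- colnames(m)
  mal <- r1$positive_cells
  r2 <- NULL
  skipped <- NULL
  if (sum(mal) == 0) {
    skipped <- "no malignant cells called in round 1"
  } else if (sum(mal) < min_round2) {
    skipped <- sprintf("only %d malignant cells called (need %d)",
                       sum(mal), min_round2)
    labels[mal] <- "NecroLRS-Low"
    warning("round 2 skipped: ", skipped)
  } else {
    r2 <- run_iterative_classifier(m[, mal, drop = FALSE], necro_initial,
                                   seed = derive_seed(seed, "round2"), ...)
    labels[names(r2$positive_cells)[r2$positive_cells]] <- "NecroLRS-High"
    labels[names(r2$positive_cells)[!r2$positive_cells]] <- "NecroLRS-Low"
  }
  structure(list(labels = factor(labels, levels = c("Non-malignant",
                                                    "NecroLRS-High",
                                                    "NecroLRS-Low")),
                 malignant_state = r1, necro_state = r2,
                 round2_skipped = skipped),
            class = "three_way_call")
}
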