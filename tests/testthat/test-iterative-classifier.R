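# small planted cohort used across classifier tests
small_cohort <- function(seed = 1, fc = 4) {
  generate_sc_cohort(sc_sim_config(n_cells = 400, n_genes = 300,
                                   n_marker_genes = 15,
                                   marker_fold_change = fc, seed = seed))
}

test_that("initial signatures come from the top significant genes per direction", {
  de <- data.frame(gene = sprintf("g%03d", 1:200),
                   log2fc = c(seq(3, 0.1, length.out = 100),
                              seq(-0.1, -3, length.out = 100)),
                   padj = rep(0.001, 200))
  pair <- derive_initial_signatures(de, top_n = 50)
  expect_length(pair$positive, 50)
  expect_length(pair$negative, 50)
  expect_length(intersect(pair$positive, pair$negative), 0)
  expect_true(all(pair$positive %in% de$gene[1:50]))

  expect_warning(p2 <- derive_initial_signatures(de, top_n = 150),
                 "taking all available")
  expect_length(p2$positive, 100)
})

test_that("initial signatures recover planted bulk up-markers", {
  set.seed(31)
  n <- 200
  genes <- sprintf("g%03d", 1:120)
  up <- genes[1:20]
  down <- genes[21:40]
  grp <- rep(c("normal", "tumor"), each = n / 2)
  base <- matrix(rlnorm(n * 120, 2, 0.5), nrow = n,
                 dimnames = list(NULL, genes))
  base[grp == "tumor", up] <- base[grp == "tumor", up] * 4
  base[grp == "tumor", down] <- base[grp == "tumor", down] / 4
  de <- differential_expression(round(base), grp, tumor_level = "tumor")
  names(de)[names(de) == "padj"] <- "padj"
  pair <- derive_initial_signatures(
    data.frame(gene = de$gene, log2fc = de$log2fc, padj = de$padj),
    top_n = 20)
  expect_gte(length(intersect(pair$positive, up)) / 20, 0.9)
})

test_that("2-centroid K-means separates well-separated clouds deterministically", {
  set.seed(4)
  pts <- rbind(matrix(rnorm(100, 0, 0.1), ncol = 2),
               matrix(rnorm(100, 3, 0.1), ncol = 2))
  km <- kmeans_two(pts, seed = 2)
  # oracle: threshold partition on the separating axis
  truth <- rep(1:2, each = 50)
  agree <- max(mean(km$labels == truth), mean(km$labels == 3 - truth))
  expect_equal(agree, 1)

  expect_identical(km$labels, kmeans_two(pts, seed = 2)$labels)
  expect_error(kmeans_two(matrix(1, 5, 2), seed = 1), "degenerate")
})

test_that("positive-centroid rule follows the concordant formula and its tie-break", {
  # concordant: cluster 1 scores higher positive, lower negative
  expect_equal(assign_positive_centroid(rbind(c(0.8, -0.2), c(-0.1, 0.5))), 1L)
  expect_equal(assign_positive_centroid(rbind(c(-0.1, 0.5), c(0.8, -0.2))), 2L)
  # discordant: cluster 1 higher in both -> positive score dominates
  expect_equal(assign_positive_centroid(rbind(c(0.8, 0.9), c(0.1, 0.2))), 1L)
  expect_error(assign_positive_centroid(rbind(c(1, 1), c(1, 1))),
               "unresolvable")
})

test_that("centroid rule is antisymmetric and matches a direct transcription", {
  set.seed(10)
  for (i in 1:50) {
    stats <- matrix(rnorm(4), 2, 2)
    if (stats[1, 1] == stats[2, 1] || stats[1, 2] == stats[2, 2]) next
    c1 <- assign_positive_centroid(stats)
    c2 <- assign_positive_centroid(stats[2:1, ])
    # piecewise transcription of the assignment formula (concordant branches)
    direct <- if (stats[1, 1] > stats[2, 1] && stats[1, 2] < stats[2, 2]) 1L
              else if (stats[1, 1] < stats[2, 1] && stats[1, 2] > stats[2, 2]) 2L
              else NA_integer_
    if (!is.na(direct)) {
      expect_equal(c1, direct)
      expect_equal(c2, 3L - direct)  # swapping cluster indices flips C
    }
  }
})

test_that("marker refinement finds planted differences and swaps under relabeling", {
  set.seed(21)
  m <- matrix(rnorm(100 * 60), nrow = 100,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%d", 1:60)))
  pos <- rep(c(TRUE, FALSE), each = 30)
  m[1:10, pos] <- m[1:10, pos] + 3    # up in positive cells
  m[11:20, !pos] <- m[11:20, !pos] + 3

  ref <- refine_markers(m, pos, top_n = 10)
  expect_gte(length(intersect(ref$pair$positive, sprintf("g%03d", 1:10))), 9)
  expect_gte(length(intersect(ref$pair$negative, sprintf("g%03d", 11:20))), 9)

  # permuted labels swap the two sides exactly
  ref_sw <- refine_markers(m, !pos, top_n = 10)
  expect_setequal(ref_sw$pair$positive, ref$pair$negative)
  expect_setequal(ref_sw$pair$negative, ref$pair$positive)

  # identical groups: nothing significant, no refined pair
  m0 <- matrix(rnorm(50 * 40), nrow = 50,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("c%d", 1:40)))
  ref0 <- refine_markers(m0, rep(c(TRUE, FALSE), 20))
  expect_null(ref0$pair)

  expect_error(refine_markers(m, c(rep(TRUE, 58), FALSE, FALSE)),
               "unstable")
})

test_that("iterative classifier recovers a planted two-population structure", {
  coh <- small_cohort(seed = 3)
  norm <- lognormalize(coh$counts)
  mk <- coh$truth$markers
  res <- run_iterative_classifier(norm,
                                  signature_pair(mk$malignant, mk$non_malignant),
                                  top_n = 15, seed = 3)
  truth <- coh$truth$cell_labels != "non_malignant"
  ari <- mclust::adjustedRandIndex(res$positive_cells, truth)
  expect_gte(ari, 0.9)
  expect_true(res$converged)
  expect_lte(res$iterations, 10)
  # cluster sizes always cover every cell; C well-defined
  expect_equal(length(res$positive_cells), ncol(norm))
  expect_true(res$positive_centroid %in% 1:2)

  # determinism of the full state at fixed seed
  res2 <- run_iterative_classifier(norm,
                                   signature_pair(mk$malignant, mk$non_malignant),
                                   top_n = 15, seed = 3)
  expect_identical(res$positive_cells, res2$positive_cells)
  expect_identical(res$sm, res2$sm)
  expect_identical(res$signatures, res2$signatures)
})

test_that("truth-initialized signatures are a fixed point of the iteration", {
  coh <- small_cohort(seed = 6)
  norm <- lognormalize(coh$counts)
  mk <- coh$truth$markers
  res <- run_iterative_classifier(norm,
                                  signature_pair(mk$malignant, mk$non_malignant),
                                  top_n = 15, seed = 6)
  expect_true(res$converged)
  expect_lte(res$iterations, 3)
})

test_that("no planted structure yields no confident call", {
  coh <- small_cohort(seed = 9, fc = 1)
  norm <- lognormalize(coh$counts)
  mk <- coh$truth$markers
  res <- run_iterative_classifier(norm,
                                  signature_pair(mk$malignant, mk$non_malignant),
                                  top_n = 15, seed = 9, max_iter = 8)
  truth <- coh$truth$cell_labels != "non_malignant"
  ari <- mclust::adjustedRandIndex(res$positive_cells, truth)
  # either the iteration fails to stabilize or the call is near chance
  expect_true(!res$converged || res$oscillated || ari < 0.1)
})

test_that("nested three-way call partitions cells and respects round structure", {
  coh <- small_cohort(seed = 12)
  norm <- lognormalize(coh$counts)
  mk <- coh$truth$markers
  res <- nested_three_way(norm,
                          signature_pair(mk$malignant, mk$non_malignant),
                          signature_pair(mk$high, mk$low),
                          top_n = 15, seed = 12)
  expect_equal(length(res$labels), ncol(norm))
  expect_false(anyNA(res$labels))
  # round 2 ran exactly on the round-1 positive set
  r1_pos <- names(res$malignant_state$positive_cells)[
    res$malignant_state$positive_cells]
  expect_setequal(names(res$necro_state$positive_cells), r1_pos)
  # non-malignant calls never carry a NecroLRS label
  expect_true(all(res$labels[setdiff(names(res$labels), r1_pos)] ==
                    "Non-malignant"))

  truth <- coh$truth$cell_labels
  ari3 <- mclust::adjustedRandIndex(res$labels, truth)
  expect_gte(ari3, 0.85)
})
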