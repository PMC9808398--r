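test_that("FPKM to TPM conversion normalizes, preserves proportions, idempotent", {
  expect_equal(unname(fpkm_to_tpm(matrix(42, 1, 1))[1, 1]), 1e6)
  expect_equal(unname(fpkm_to_tpm(matrix(c(1, 1, 2), 1))[1, ]),
               c(250000, 250000, 500000))

  set.seed(2)
  m <- matrix(rexp(200), nrow = 10)
  tpm <- fpkm_to_tpm(m)
  expect_equal(unname(rowSums(tpm)), rep(1e6, 10), tolerance = 1e-6)
  expect_equal(fpkm_to_tpm(tpm), tpm, tolerance = 1e-9)

  expect_error(fpkm_to_tpm(rbind(m[1, ], 0)), "all-zero")
})

test_that("differential expression: null, planted doubling, antisymmetry", {
  set.seed(3)
  counts <- matrix(rpois(40 * 60, 30), nrow = 40,
                   dimnames = list(NULL, sprintf("g%02d", 1:60)))
  grp <- rep(c("normal", "tumor"), each = 20)

  de0 <- differential_expression(counts, grp)
  expect_true(all(de0$padj > 0.05))

  counts2 <- counts
  counts2[grp == "tumor", "g01"] <- counts2[grp == "tumor", "g01"] * 2
  de1 <- differential_expression(counts2, grp, tumor_level = "tumor")
  # doubling a gene shifts log2 expression by ~1 (library-size dilution is
  # negligible with 60 genes)
  expect_equal(de1$log2fc[de1$gene == "g01"], 1, tolerance = 0.15)
  expect_lt(de1$padj[de1$gene == "g01"], 0.05)

  de_sw <- differential_expression(counts2, grp, tumor_level = "normal")
  expect_equal(de_sw$log2fc, -de1$log2fc, tolerance = 1e-12)
})

test_that("DELnc selection applies strict thresholds and the annotation", {
  de <- data.frame(gene = c("lncA", "lncB", "lncC", "pcG"),
                   log2fc = c(1.0, -1.5, 2.0, 3.0),
                   padj = c(0.01, 0.01, 0.05, 0.001))
  lncs <- c("lncA", "lncB", "lncC")
  out <- select_delncs(de, lncs)
  expect_false("lncA" %in% out)  # |log2FC| exactly 1: excluded
  expect_true("lncB" %in% out)
  expect_false("lncC" %in% out)  # padj exactly 0.05: excluded
  expect_false("pcG" %in% out)   # passes both thresholds but not a lncRNA
})

test_that("necroptosis correlation screen retains by strict |r| and p", {
  set.seed(4)
  n <- 60
  necro <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "RIPK3"))
  lnc <- cbind(identical_lnc = necro[, 1],
               noise_lnc = rnorm(n))
  out <- necroptosis_correlation(lnc, necro)
  expect_true("identical_lnc" %in% out$lncRNA)   # r = 1
  expect_false("noise_lnc" %in% out$lncRNA)

  # |r| exactly 0.4 in double arithmetic (constructed pair): excluded by the
  # strict coefficient gate even when the p-value gate is satisfied
  pr <- exact_r04_pair()                         # n = 50, r bit-exact 0.4
  expect_identical(cor(pr$x, pr$y), 0.4)
  expect_lt(cor.test(pr$x, pr$y)$p.value, 0.05)
  out2 <- necroptosis_correlation(matrix(pr$y, dimnames = list(NULL, "lncX")),
                                  matrix(pr$x, dimnames = list(NULL, "necroX")),
                                  p_threshold = 0.05)
  expect_false("lncX" %in% out2$lncRNA)

  expect_warning(
    necroptosis_correlation(cbind(lnc, flat = rep(1, n)), necro),
    "zero-variance")
})

test_that("Cox screen recovers planted effects and flags degenerate genes", {
  hits <- vapply(1:5, function(s) {
    coh <- generate_bulk_cohort(bulk_sim_config(
      n_samples = 500, n_genes = 3, signature_genes = "LNC1",
      true_coefficients = 1, seed = 100 + s))
    scr <- cox_screen(log2(coh$expression + 1), coh$survival)
    abs(scr$coef[scr$gene == "LNC1"] - 1) <= 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.8)

  surv <- data.frame(time = rexp(30, 0.01), event = rbinom(30, 1, 0.8))
  expr <- cbind(flat = rep(2, 30), ok = rnorm(30))
  scr <- cox_screen(expr, surv)
  expect_true(scr$flagged[scr$gene == "flat"])
  expect_false(scr$flagged[scr$gene == "ok"])
})

test_that("NecroLRS score matches the published linear model", {
  model <- necrolrs_model()
  # TPM = 1 gives log2(TPM + 1) = 1: the score isolates one coefficient
  unit <- function(g) {
    tpm <- setNames(numeric(4), model$genes)
    tpm[g] <- 1
    unname(necrolrs_score(tpm, model))
  }
  expect_equal(unit("FAM83A-AS1"), 0.2486147)
  expect_equal(unit("LINC02323"), 0.1862710)
  expect_equal(unit("OGFRP1"), 0.3906980)
  expect_equal(unit("WWC2-AS2"), 0.6592927)

  expect_equal(unname(necrolrs_score(setNames(rep(0, 4), model$genes))), 0)
  expect_equal(unname(necrolrs_score(setNames(rep(1, 4), model$genes))),
               1.4848764)

  # linear in each log2(TPM + 1) input with slope equal to the coefficient
  base <- setNames(c(3, 7, 1, 2), model$genes)
  for (g in model$genes) {
    up <- base
    up[g] <- 2 * (base[g] + 1) - 1   # log2(TPM + 1) increases by exactly 1
    expect_equal(unname(necrolrs_score(up) - necrolrs_score(base)),
                 unname(model$coefficients[g]), tolerance = 1e-12)
  }

  expect_error(necrolrs_score(setNames(rep(1, 3), model$genes[1:3])),
               "WWC2-AS2")
})

test_that("Youden cutoff maximizes J over midpoints, smallest on ties", {
  out <- youden_cutoff(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(out$cutoff, 0.5)
  expect_equal(out$J, 1)

  # equals the exhaustive brute-force maximizer on random instances
  set.seed(6)
  for (n in c(10, 50, 200)) {
    scores <- round(rnorm(n), 2)   # rounding forces score ties
    outcome <- rbinom(n, 1, plogis(scores))
    if (length(unique(outcome)) < 2) next
    ours <- youden_cutoff(scores, outcome)
    brute <- brute_youden(scores, outcome)
    expect_equal(ours$cutoff, brute$cutoff)
    expect_equal(ours$J, brute$J)
  }

  # outcome independent of score: no threshold achieves a large J
  set.seed(7)
  nullJ <- vapply(1:20, function(i) {
    youden_cutoff(rnorm(100), rbinom(100, 1, 0.5))$J
  }, numeric(1))
  expect_lt(median(nullJ), 0.3)

  expect_error(youden_cutoff(1:4, c(1, 1, 1, 1)), "both outcome classes")
})

test_that("stratification is strict at the cutoff and records provenance", {
  s <- stratify(setNames(c(0.2, 0.5, 0.9), c("a", "b", "c")), cutoff = 0.5,
                provenance = "training")
  expect_equal(as.character(s$group), c("Low", "Low", "High"))  # tie -> Low
  expect_equal(attr(s, "cutoff"), 0.5)
  expect_equal(attr(s, "provenance"), "training")

  all_low <- stratify(c(0.1, 0.2), cutoff = 1)
  expect_true(all(all_low$group == "Low"))
})

test_that("log-rank matches the hand hypergeometric oracle; KM starts at 1", {
  surv <- data.frame(time = c(5, 8, 12, 20, 25, 30),
                     event = c(1, 1, 0, 1, 1, 0))
  grp <- c("A", "B", "A", "B", "A", "B")
  res <- km_logrank(surv, grp)
  expect_equal(res$chisq, brute_logrank(surv$time, surv$event, grp),
               tolerance = 1e-10)
  expect_true(all(summary(res$fit, times = 0)$surv == 1))

  # identical survival in both groups: statistic near 0, p near 1
  surv2 <- data.frame(time = rep(c(3, 6, 9, 12), 2),
                      event = rep(c(1, 1, 0, 1), 2))
  res2 <- km_logrank(surv2, rep(c("A", "B"), each = 4))
  expect_lt(res2$chisq, 1e-10)
  expect_gt(res2$pval, 0.99)
})

test_that("time-dependent AUC behaves at null, under negation, and with effect", {
  set.seed(9)
  n <- 300
  # no censoring: negating scores maps AUC to 1 - AUC
  time <- rexp(n, 0.01)
  surv <- data.frame(time = time, event = 1L)
  scores <- rnorm(n)
  a <- time_dependent_auc(scores, surv, horizon = 50)
  a_neg <- time_dependent_auc(-scores, surv, horizon = 50)
  expect_equal(a + a_neg, 1, tolerance = 1e-10)

  # score independent of survival: AUC near 0.5
  null_auc <- vapply(1:10, function(i) {
    t2 <- rexp(n, 0.01)
    time_dependent_auc(rnorm(n), data.frame(time = t2, event = 1L),
                       horizon = 50)
  }, numeric(1))
  expect_lt(abs(mean(null_auc) - 0.5), 0.05)

  # AUC increases along an effect-size ladder when the score is the true risk
  aucs <- vapply(c(0.5, 1, 2), function(beta) {
    coh <- generate_bulk_cohort(bulk_sim_config(
      n_samples = 400, n_genes = 5, signature_genes = "LNC1",
      true_coefficients = beta, seed = 17))
    time_dependent_auc(coh$truth$true_risk, coh$survival, horizon = 365)
  }, numeric(1))
  expect_gt(aucs[1], 0.5)
  expect_true(all(diff(aucs) > 0))
})
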