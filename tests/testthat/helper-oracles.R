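# Independent brute-force oracles. These deliberately share no code with the
# package: explicit loops and textbook formulas only.

# module score by explicit loops over cells and genes
brute_module_score <- function(norm, signature, pooled_controls) {
  out <- numeric(ncol(norm))
  for (j in seq_len(ncol(norm))) {
    s <- 0
    for (g in signature) s <- s + norm[g, j]
    c0 <- 0
    for (g in pooled_controls) c0 <- c0 + norm[g, j]
    out[j] <- s / length(signature) - c0 / length(pooled_controls)
  }
  out
}

# exhaustive Youden maximizer over midpoint thresholds
brute_youden <- function(scores, outcome) {
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  best_J <- -Inf
  best_t <- NA_real_
  for (t in cand) {
    sens <- sum(scores > t & outcome == 1) / sum(outcome == 1)
    spec <- sum(scores <= t & outcome == 0) / sum(outcome == 0)
    J <- sens + spec - 1
    if (J > best_J) { best_J <- J; best_t <- t }
  }
  list(cutoff = best_t, J = best_J)
}

# Pearson correlation from the closed-form covariance formula
brute_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy / sqrt(sxx * syy)
}

# two-group log-rank chi-square from the hypergeometric observed-minus-
# expected form
brute_logrank <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  times <- sort(unique(time[event == 1]))
  O_minus_E <- 0
  V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O_minus_E <- O_minus_E + (d1 - d * n1 / n)
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  O_minus_E^2 / V
}

# small helper: build a control_set by hand for module-score tests
manual_controls <- function(per_gene) {
  structure(list(per_gene = per_gene,
                 pooled = unlist(per_gene, use.names = FALSE),
                 seed = 0L),
            class = "control_set")
}

# paired vectors whose Pearson r evaluates to exactly 0.4 in double
# arithmetic at copies = 10 (x = (2,1,0,-1,-2), y = (-1,2,1,0,-2): dot = 4,
# both sums of squares 10); callers assert the exactness before relying on it
exact_r04_pair <- function(copies = 10L) {
  list(x = rep(c(2, 1, 0, -1, -2), copies),
       y = rep(c(-1, 2, 1, 0, -2), copies))
}
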