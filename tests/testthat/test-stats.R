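# Inferential battery: statistic conventions, exact branches against
# enumeration oracles, effect sizes and the factorial ANOVA.

test_that("KS screen flags its caveat and rejects clear bimodality", {
  expect_error(ks_normality(rep(1, 10)), "zero variance")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
  set.seed(1)
  bimodal <- c(rnorm(100, -5, 0.3), rnorm(100, 5, 0.3))
  r <- ks_normality(bimodal)
  expect_lt(r$p_value, 0.001)
  expect_match(r$note, "Lilliefors")
  rl <- ks_normality(rnorm(200), p_method = "lilliefors")
  expect_gt(rl$p_value, 0.001)
})

test_that("Kruskal-Wallis H matches the hand-ranked formula", {
  groups <- list(c(1, 2), c(11, 12), c(21, 22))
  r <- kruskal_wallis(groups)
  expect_equal(unname(r$statistic), kw_H_oracle(groups),
               tolerance = 1e-12)
  expect_equal(r$df, 2)
  # identical groups: degenerate null case
  r0 <- kruskal_wallis(list(c(3, 3), c(3, 3), c(3, 3)))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p_value, 1)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "empty")
  # eta-squared stays in [0, 1] across random instances
  set.seed(8)
  for (i in 1:25) {
    g <- lapply(1:3, function(j) rnorm(sample(3:10, 1), j * runif(1)))
    e <- kruskal_wallis(g)$effect_size
    expect_gte(e, 0); expect_lte(e, 1)
  }
})

test_that("tests are invariant to the ordering of their inputs", {
  set.seed(14)
  x <- rnorm(12); y <- rnorm(12, 0.5)
  perm <- sample(12)
  expect_equal(wilcoxon_signed_rank(x, y)$p_value,
               wilcoxon_signed_rank(x[perm], y[perm])$p_value)
  expect_equal(wilcoxon_rank_sum(x, y)$statistic,
               wilcoxon_rank_sum(x[sample(12)], y)$statistic)
  expect_equal(kruskal_wallis(list(x, y))$statistic,
               kruskal_wallis(list(sample(x), sample(y)))$statistic)
  expect_equal(pearson_corr(x, y)$statistic,
               pearson_corr(x[perm], y[perm])$statistic)
})

test_that("signed-rank statistic is the positive-rank sum with exact p", {
  # all differences positive at n = 3: W = 1 + 2 + 3
  r <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_equal(unname(r$statistic), 6)
  expect_error(wilcoxon_signed_rank(1:5, 1:5), "zero")
  # exact p equals exhaustive sign-flip enumeration
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(6); y <- rnorm(6)
    r <- wilcoxon_signed_rank(x, y)
    expect_equal(r$p_value, signed_rank_enum_p(x, y),
                 tolerance = 1e-12)
    expect_match(r$note, "exact")
  }
  # zero differences are dropped, not counted
  rz <- wilcoxon_signed_rank(c(1, 2, 5, 7, 9, 4), c(1, 1, 4, 5, 6, 8))
  expect_match(rz$note, "1 zero difference")
  expect_equal(rz$n, 5)
})

test_that("signed-rank exact and approximate branches agree at the crossover", {
  set.seed(31)
  for (i in 1:50) {
    x <- rnorm(25); y <- rnorm(25, 0.2)
    pe <- wilcoxon_signed_rank(x, y, exact_max = 25)$p_value
    pa <- wilcoxon_signed_rank(x, y, exact_max = 0)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("rank-sum statistic is the first sample's pooled rank sum", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(unname(r$statistic), 3)
  # exchanging the samples complements the statistic
  x <- c(0.3, 1.2, 2.5, 0.9); y <- c(1.7, 3.1, 0.1, 2.2)
  N <- length(x) + length(y)
  expect_equal(unname(wilcoxon_rank_sum(x, y)$statistic) +
                 unname(wilcoxon_rank_sum(y, x)$statistic),
               N * (N + 1) / 2)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "empty")
  # exact p equals exhaustive assignment enumeration
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(4)
    expect_equal(wilcoxon_rank_sum(x, y)$p_value,
                 rank_sum_enum_p(x, y), tolerance = 1e-12)
  }
  # exact vs approximation at the crossover
  set.seed(32)
  for (i in 1:30) {
    x <- rnorm(25); y <- rnorm(25, 0.2)
    pe <- wilcoxon_rank_sum(x, y, exact_max = 25)$p_value
    pa <- wilcoxon_rank_sum(x, y, exact_max = 0)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("density pairing schemes produce the documented pairs", {
  ann <- annotation_set(
    data.frame(region_id = c("a", "b", "c"), level = c(1, 2, 2),
               t_start = c(2, 8, 14), t_end = c(4, 10, 16)),
    recording_id = "r", total_duration = 20)
  p <- build_partition(ann)
  dens <- region_densities(c(2.5, 3, 5, 9, 15, 17), p)
  pr <- pair_densities(dens, c("L2", "interstitial"))
  # each L2 region paired with the interstitial right after it
  expect_equal(length(pr$x), 2)
  l2_rows <- which(dens$class == "L2")
  expect_equal(pr$x, dens$density[l2_rows])
  expect_equal(pr$y, dens$density[l2_rows + 1])
  bi <- pair_densities(dens, c("L1", "L2"), scheme = "by_index")
  expect_equal(length(bi$x), 1)   # truncated to the smaller class
})

test_that("correlations and t tests match their closed forms", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(unname(pearson_corr(x, 2 * x + 1)$statistic), 1)
  expect_equal(unname(pearson_corr(x, -x)$statistic), -1)
  expect_equal(pearson_corr(x, 2 * x + 1)$df, 3)
  expect_error(pearson_corr(c(1, 1, 1), 1:3), "zero variance")
  # permuted responses decorrelate
  set.seed(9)
  x <- rnorm(30); y <- 0.8 * x + rnorm(30, 0, 0.3)
  rs <- replicate(1000, unname(pearson_corr(x, sample(y))$statistic))
  expect_lt(abs(mean(rs)), 0.1)          # null r centred on zero
  expect_lt(mean(abs(rs)), 2 / sqrt(29)) # and folded-normal sized

  a <- c(5, 6, 7, 8); b <- c(5, 6, 7, 8)
  expect_equal(unname(t_test_independent(a, b)$statistic), 0)
  expect_equal(t_test_independent(a, b)$df, 6)
  expect_error(t_test_independent(c(2, 2), c(2, 2)), "pooled variance")
  # hand formula with a known shift
  set.seed(10)
  a <- rnorm(8); b <- rnorm(10, 1)
  sp <- sqrt(((7 * var(a) + 9 * var(b)) / 16))
  t_hand <- (mean(a) - mean(b)) / (sp * sqrt(1 / 8 + 1 / 10))
  expect_equal(unname(t_test_independent(a, b)$statistic), t_hand,
               tolerance = 1e-12)
})

test_that("factorial ANOVA decomposition matches the projection oracle", {
  set.seed(12)
  df <- expand.grid(participant = 1:10, raga = c("A", "B"),
                    level = c("L1", "L2"))
  df$participant <- paste0(df$raga, df$participant)
  df$score <- rnorm(nrow(df)) + (df$level == "L1") * 0.5 +
    (df$raga == "A") * 0.2
  out <- factorial_anova(df)
  ss <- anova_proj_oracle(df)
  df_err <- nrow(df) - 4
  for (eff in c("raga", "level", "interaction")) {
    F_oracle <- ss[[eff]] / (ss$error / df_err)
    expect_equal(unname(out[[eff]]$statistic), F_oracle,
                 tolerance = 1e-10)
    expect_equal(out[[eff]]$effect_size,
                 ss[[eff]] / (ss[[eff]] + ss$error), tolerance = 1e-10)
    ci <- out[[eff]]$effect_ci
    expect_true(ci[1] >= 0 && ci[2] <= 1 && ci[1] <= ci[2])
    expect_true(out[[eff]]$effect_size >= ci[1] - 1e-8 &&
                  out[[eff]]$effect_size <= ci[2] + 1e-8)
  }
})

test_that("ANOVA identities: additive means, duplication invariance, missing cells", {
  # cell means differing only by level, balanced: interaction F = 0
  df <- expand.grid(participant = 1:6, raga = c("A", "B"),
                    level = c("L1", "L2"))
  df <- df[order(df$raga, df$level), ]
  # identical within-cell perturbations keep the cell means additive
  df$score <- ifelse(df$level == "L1", 1, 0) +
    rep(c(-.1, 0, .1, -.05, .05, 0), times = 4)
  out <- factorial_anova(df)
  expect_lt(abs(unname(out$interaction$statistic)), 1e-10)
  expect_gt(unname(out$level$statistic), 1)
  # duplicating every row leaves partial eta-squared unchanged
  out2 <- factorial_anova(rbind(df, df))
  expect_equal(out2$level$effect_size, out$level$effect_size,
               tolerance = 1e-12)
  expect_error(factorial_anova(df[df$raga == "A" | df$level == "L1", ]),
               "empty design cell")
})

test_that("the repeated-measures variant tests raga between participants", {
  set.seed(13)
  df <- expand.grid(participant = 1:12, level = c("L1", "L2"))
  df$raga <- ifelse(as.integer(df$participant) <= 6, "A", "B")
  df$participant <- paste0("p", df$participant)
  df$score <- rnorm(nrow(df)) + (df$level == "L1") * 0.8
  out <- factorial_anova(df, design = "mixed_within_level")
  expect_equal(out$raga$df[2], 10)         # participants - 2
  expect_equal(out$level$df[2], 10)        # within residual
  expect_lt(out$level$p_value, 0.05)
})
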