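# Nonparametric inferential battery: normality screening, rank tests
# with effect sizes, the raga x level factorial ANOVA with partial
# eta-squared CIs, and correlation screens.  Base R provides the
# reference distributions (psignrank, pwilcox, chi-squared, F, t); the
# statistic conventions, effect sizes and pairing schemes are defined
# here.

#' Construct a test-result record
#'
#' Uniform container used by every test in the battery; serialises
#' directly into the `stats.json` report.
#'
#' @param test_name short test label.
#' @param statistic named test statistic.
#' @param df degrees of freedom (scalar or vector), `NA` if not
#'   applicable.
#' @param p_value two-sided p value in `[0, 1]`.
#' @param effect_size effect-size value or `NA`.
#' @param effect_ci length-2 `c(lo, hi)` or `NULL`.
#' @param n sample size(s).
#' @param note free-text caveats (method switches, dropped values,
#'   pairing scheme used).
#' @param seed RNG seed for stochastic tests (bootstrap), else `NA`.
#' @return Object of class `stat_result`.
#' @export
stat_result <- function(test_name, statistic, df = NA_real_, p_value,
                        effect_size = NA_real_, effect_ci = NULL,
                        n = NA_integer_, note = NA_character_,
                        seed = NA_integer_) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1))
    stop("p value outside [0, 1]")
  if (!is.null(effect_ci)) {
    stopifnot(length(effect_ci) == 2)
    if (all(is.finite(effect_ci)) && effect_ci[1] > effect_ci[2])
      stop("effect CI lower bound exceeds upper bound")
  }
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 effect_ci = effect_ci, n = n, note = note, seed = seed),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- if (all(is.na(x$df))) "" else
    sprintf(", df = %s", paste(format(x$df, digits = 4), collapse = ","))
  es <- if (is.na(x$effect_size)) "" else
    sprintf(", effect = %.3f", x$effect_size)
  ci <- if (is.null(x$effect_ci)) "" else
    sprintf(" [%.3f, %.3f]", x$effect_ci[1], x$effect_ci[2])
  cat(sprintf("%s: %s = %.4g%s, p = %.4g%s%s\n", x$test_name,
              names(x$statistic)[1] %||% "stat", x$statistic[1], dfs,
              x$p_value, es, ci))
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Kolmogorov-Smirnov normality screen
#'
#' Standardises the sample by its own mean and SD and compares it with
#' the standard normal CDF.  Because the parameters are estimated from
#' the same sample, the classical KS p value is conservative (the
#' Lilliefors situation); the result carries a note to that effect, and
#' `p_method = "lilliefors"` switches to the Lilliefors-corrected p
#' value, which is properly calibrated.
#'
#' @param values numeric sample, `n >= 4`, non-zero variance.
#' @param p_method `"ks"` (standardised one-sample KS, conservative) or
#'   `"lilliefors"`.
#' @return A [stat_result()] with statistic `D`.
#' @export
ks_normality <- function(values, p_method = c("ks", "lilliefors")) {
  p_method <- match.arg(p_method)
  values <- values[!is.na(values)]
  if (length(values) < 4) stop("need at least 4 values")
  if (sd(values) == 0) stop("zero variance: normality screen undefined")
  if (p_method == "ks") {
    z <- (values - mean(values)) / sd(values)
    kt <- suppressWarnings(ks.test(z, "pnorm"))
    stat_result("ks_normality", c(D = unname(kt$statistic)),
                p_value = kt$p.value, n = length(values),
                note = paste("parameters estimated from the sample;",
                             "classical KS p is conservative",
                             "(Lilliefors caveat)"))
  } else {
    lt <- nortest::lillie.test(values)
    stat_result("ks_normality", c(D = unname(lt$statistic)),
                p_value = lt$p.value, n = length(values),
                note = "Lilliefors-corrected p value")
  }
}

#' Kruskal-Wallis test with eta-squared effect size
#'
#' Tie-corrected H statistic referred to the chi-squared distribution
#' with `k - 1` df, plus the eta-squared effect size
#' `(H - k + 1) / (n - k)`, clamped at 0 for H below its null mean.
#'
#' @param groups list of numeric samples (>= 2 groups, none empty,
#'   total n >= 5).
#' @return A [stat_result()] with statistic `H` (printed as chi-squared)
#'   and `effect_size` eta-squared.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(!vapply(groups, length, 1L)))
    stop("empty group in Kruskal-Wallis input")
  n <- sum(lengths(groups))
  if (n < 5) stop("need total n >= 5")
  k <- length(groups)
  if (length(unique(unlist(groups))) == 1)
    return(stat_result("kruskal_wallis", c(H = 0), df = k - 1,
                       p_value = 1, effect_size = 0,
                       n = lengths(groups),
                       note = "all values identical: H = 0 by convention"))
  kt <- kruskal.test(groups)
  H <- unname(kt$statistic)
  eta2 <- max(0, (H - k + 1) / (n - k))   # clamped at 0 for small H
  stat_result("kruskal_wallis", c(H = H), df = k - 1,
              p_value = kt$p.value, effect_size = eta2,
              n = lengths(groups))
}

#' Pair region densities for a signed-rank contrast
#'
#' Table-style contrasts compare density distributions of unequal-sized
#' region classes, so a pairing rule is needed.  The default
#' `"edbr_vs_next_interstitial"` pairs each boundary region of the first
#' class with the interstitial segment immediately following it (an
#' interpretation, not a prescription -- record which scheme you used).
#' `"by_index"` pairs the classes' segments in timeline order,
#' truncating to the shorter class; it is the fallback for
#' EDBR-vs-EDBR contrasts such as L1 vs L2.
#'
#' @param densities output of [region_densities()].
#' @param classes length-2 character, e.g. `c("L1", "interstitial")` or
#'   `c("L1", "L2")`.
#' @param scheme `"edbr_vs_next_interstitial"` or `"by_index"`.
#' @return list with paired vectors `x`, `y` and the `scheme` applied.
#' @export
pair_densities <- function(densities,
                           classes = c("L1", "interstitial"),
                           scheme = c("edbr_vs_next_interstitial",
                                      "by_index")) {
  scheme <- match.arg(scheme)
  stopifnot(length(classes) == 2,
            all(classes %in% c("L1", "L2", "interstitial")))
  if (scheme == "edbr_vs_next_interstitial" &&
      classes[2] == "interstitial" && classes[1] != "interstitial") {
    idx <- which(densities$class == classes[1])
    nxt <- idx + 1L
    keep <- nxt <= nrow(densities) &
      densities$class[pmin(nxt, nrow(densities))] == "interstitial"
    list(x = densities$density[idx[keep]],
         y = densities$density[nxt[keep]],
         scheme = scheme)
  } else {
    x <- densities$density[densities$class == classes[1]]
    y <- densities$density[densities$class == classes[2]]
    m <- min(length(x), length(y))
    list(x = x[seq_len(m)], y = y[seq_len(m)],
         scheme = if (scheme == "by_index") scheme
                  else "by_index (fallback: second class not interstitial)")
  }
}

#' Wilcoxon signed-rank test (paired)
#'
#' Statistic is the sum of positive-difference ranks (zero differences
#' dropped, tied absolute differences mid-ranked).  The p value is exact
#' (from the signed-rank distribution) when at most 25 non-zero
#' differences remain and their absolute values are untied; otherwise a
#' normal approximation with tie-corrected variance and continuity
#' correction is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param exact_max largest n for which the exact distribution is used.
#' @return A [stat_result()] with statistic `W` (sum of positive ranks).
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  d <- x[ok] - y[ok]
  zeros <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    stop("all paired differences are zero: signed-rank test degenerate")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  tied <- any(duplicated(abs(d)))
  note <- if (zeros) sprintf("%d zero difference(s) dropped", zeros)
  if (n <= exact_max && !tied) {
    p <- min(1, 2 * min(stats::psignrank(W, n),
                        1 - stats::psignrank(W - 1, n)))
    method <- "exact"
  } else {
    E <- n * (n + 1) / 4
    ties_tab <- table(r)
    V <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties_tab^3 - ties_tab) / 48
    z <- (W - E - 0.5 * sign(W - E)) / sqrt(V)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  stat_result("wilcoxon_signed_rank", c(W = W), p_value = min(1, p),
              n = n,
              note = paste(c(note, method), collapse = "; "))
}

#' Wilcoxon rank-sum test (independent samples)
#'
#' Statistic is the sum of the pooled ranks of the first sample.  Exact
#' p value (via the Mann-Whitney distribution) when both samples have at
#' most 25 untied observations; normal approximation with tie-corrected
#' variance and continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_max exact-branch size limit per sample.
#' @return A [stat_result()] with statistic `W` (rank sum of `x`).
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 25) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (!n1 || !n2) stop("empty sample in rank-sum test")
  pooled <- c(x, y)
  r <- rank(pooled)
  W <- sum(r[seq_len(n1)])
  U <- W - n1 * (n1 + 1) / 2
  tied <- any(duplicated(pooled))
  if (max(n1, n2) <= exact_max && !tied) {
    p <- min(1, 2 * min(stats::pwilcox(U, n1, n2),
                        1 - stats::pwilcox(U - 1, n1, n2)))
    method <- "exact"
  } else {
    E <- n1 * n2 / 2
    N <- n1 + n2
    ties_tab <- table(pooled)
    V <- n1 * n2 / 12 *
      ((N + 1) - sum(ties_tab^3 - ties_tab) / (N * (N - 1)))
    z <- (U - E - 0.5 * sign(U - E)) / sqrt(V)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with continuity correction"
  }
  stat_result("wilcoxon_rank_sum", c(W = W), p_value = min(1, p),
              n = c(n1, n2), note = method)
}

#' Pearson correlation
#'
#' @param x,y numeric vectors, `n >= 3`, finite non-zero variance.
#' @return A [stat_result()] with statistic `r`, `df = n - 2`, t-based
#'   two-sided p and the Fisher-z 95% CI as `effect_ci`.
#' @export
pearson_corr <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 for a correlation")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(x, y, method = "pearson")
  stat_result("pearson_corr", c(r = unname(ct$estimate)),
              df = unname(ct$parameter), p_value = ct$p.value,
              effect_size = unname(ct$estimate),
              effect_ci = as.numeric(ct$conf.int), n = length(x))
}

#' Independent-samples Student t test
#'
#' Pooled-variance t with `df = n1 + n2 - 2`.
#'
#' @param x,y numeric samples, both `n >= 2`.
#' @return A [stat_result()] with statistic `t`.
#' @export
t_test_independent <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 in both samples")
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 == 0) stop("zero pooled variance: t test undefined")
  tt <- t.test(x, y, var.equal = TRUE)
  stat_result("t_test_independent", c(t = unname(tt$statistic)),
              df = unname(tt$parameter), p_value = tt$p.value,
              n = c(length(x), length(y)))
}

# 95% CI for partial eta-squared by inverting the noncentral-F CDF at
# the observed F (two-sided, Steiger's method).  eta = ncp/(ncp+df1+df2+1).
partial_eta_ci <- function(F_obs, df1, df2, conf = 0.95) {
  alpha <- 1 - conf
  lim <- function(target) {
    f <- function(ncp) pf(F_obs, df1, df2, ncp = ncp) - target
    if (f(0) < 0) return(0)
    hi <- max(10, 4 * F_obs * df1)
    while (f(hi) > 0) hi <- hi * 2
    uniroot(f, c(0, hi), tol = 1e-8)$root
  }
  ncp_lo <- lim(1 - alpha / 2)
  ncp_hi <- lim(alpha / 2)
  c(ncp_lo / (ncp_lo + df1 + df2 + 1),
    ncp_hi / (ncp_hi + df1 + df2 + 1))
}

#' Raga x level factorial ANOVA on promptness scores
#'
#' Fits the 2 x 2 factorial (recording x hierarchy level) on
#' per-participant cumulative promptness.  The default design treats
#' every participant x level row as an independent cell observation
#' (error df = N - 4), matching how such designs are commonly reported;
#' `"mixed_within_level"` instead nests level within participant as a
#' repeated measure.  Effects are Type-III (sum-to-zero contrasts),
#' reported with partial eta-squared and its 95% noncentral-F CI, and
#' simple effects are tested at the pooled error term.
#'
#' @param data data.frame with columns `participant`, `raga` (2 levels),
#'   `level` (2 levels) and `score`.
#' @param design `"two_way_between"` (default) or
#'   `"mixed_within_level"`.
#' @return Named list of [stat_result()]s: `raga`, `level`,
#'   `interaction`, and simple effects `level_within_<raga>` and
#'   `raga_within_level<level>`.
#' @export
factorial_anova <- function(data,
                            design = c("two_way_between",
                                       "mixed_within_level")) {
  design <- match.arg(design)
  stopifnot(all(c("participant", "raga", "level", "score") %in%
                  names(data)))
  data$raga <- factor(data$raga)
  data$level <- factor(data$level)
  if (nlevels(data$raga) != 2 || nlevels(data$level) != 2)
    stop("both factors must have exactly two levels")
  cells <- table(data$raga, data$level)
  if (any(cells == 0)) stop("empty design cell(s): ANOVA undefined")

  mm <- model.matrix(~ raga * level, data = data,
                     contrasts.arg = list(raga = "contr.sum",
                                          level = "contr.sum"))
  y <- data$score
  rss <- function(X) {
    fit <- lm.fit(X, y)
    sum(fit$residuals^2)
  }
  rss_full <- rss(mm)
  N <- nrow(data)

  if (design == "two_way_between") {
    err <- list(ss = rss_full, df = N - 4)
    err_by_effect <- list(raga = err, level = err, interaction = err)
  } else {
    # level varies within participant: raga is tested against the
    # between-participant error, level and the interaction against the
    # participant-by-level (within) residual.
    data$participant <- factor(data$participant)
    mm_subj <- model.matrix(~ participant, data = data)
    X_within <- cbind(mm_subj, mm[, c("level1", "raga1:level1"),
                                  drop = FALSE])
    within <- list(ss = rss(X_within), df = N - qr(X_within)$rank)
    subj_means <- aggregate(score ~ participant + raga, data, mean)
    between <- list(
      ss = 2 * sum(lm.fit(model.matrix(~ raga, subj_means),
                          subj_means$score)$residuals^2),
      df = nrow(subj_means) - 2)
    err_by_effect <- list(raga = between, level = within,
                          interaction = within)
  }
  err <- err_by_effect[["level"]]   # pooled term for simple effects
  ms_err <- err$ss / err$df
  ss_err <- err$ss
  df_err <- err$df

  effect <- function(cols, name) {
    e <- err_by_effect[[name]]
    ss <- max(0, rss(mm[, setdiff(colnames(mm), cols),
                        drop = FALSE]) - rss_full)
    df1 <- length(cols)
    F_obs <- (ss / df1) / (e$ss / e$df)
    eta <- ss / (ss + e$ss)
    stat_result(paste0("anova_", name), c(F = F_obs),
                df = c(df1, e$df),
                p_value = pf(F_obs, df1, e$df, lower.tail = FALSE),
                effect_size = eta,
                effect_ci = partial_eta_ci(F_obs, df1, e$df),
                n = N, note = paste("design:", design))
  }
  out <- list(raga = effect("raga1", "raga"),
              level = effect("level1", "level"),
              interaction = effect("raga1:level1", "interaction"))

  # Simple effects against the pooled error term.
  simple <- function(sub, name) {
    m <- tapply(sub$score, droplevels(sub[[name]]), mean)
    ns <- tapply(sub$score, droplevels(sub[[name]]), length)
    ss <- diff(m)^2 / sum(1 / ns)
    F_obs <- ss / ms_err
    stat_result("anova_simple_effect", c(F = unname(F_obs)),
                df = c(1, df_err),
                p_value = pf(F_obs, 1, df_err, lower.tail = FALSE),
                effect_size = unname(ss / (ss + ss_err)),
                effect_ci = partial_eta_ci(F_obs, 1, df_err),
                n = nrow(sub), note = "pooled error term")
  }
  for (rg in levels(data$raga))
    out[[paste0("level_within_", rg)]] <-
      simple(data[data$raga == rg, ], "level")
  for (lv in levels(data$level))
    out[[paste0("raga_within_level", lv)]] <-
      simple(data[data$level == lv, ], "raga")
  out
}
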