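# Independent oracles used to validate the implementations.  Each one
# recomputes a quantity by a different route (bisection, exhaustive
# enumeration, linear programming, explicit projections) and stays
# independent of the code path it checks.

# Standard-normal quantile by bisection on pnorm.
probit_bisect <- function(p, tol = 1e-10) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign
# assignments (doubled smaller tail, the same two-sidedness convention
# as the implementation; the null distribution is the independent part).
signed_rank_enum_p <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(0:1), n)))
  W_all <- as.vector(signs %*% r)
  min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
rank_sum_enum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_len(n1)])
  W_all <- apply(utils::combn(length(pooled), n1), 2,
                 function(idx) sum(r[idx]))
  min(1, 2 * min(mean(W_all <= W_obs), mean(W_all >= W_obs)))
}

# Kruskal-Wallis H from the raw rank formula (untied data only).
kw_H_oracle <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  Rsum <- tapply(r, idx, sum)
  12 / (N * (N + 1)) * sum(Rsum^2 / lengths(groups)) - 3 * (N + 1)
}

# ---- LP dip oracle -------------------------------------------------------
# Minimal sup-distance d between the ECDF and a unimodal df, found by
# linear programming (boot::simplex) separately for every candidate mode
# knot and, optionally, virtual interior modes at knot midpoints.  The
# mode may carry an atom: the convex side's left limit gm and the
# concave side's start g_j are separate variables with gm <= g_j.

dip_lp_mode <- function(y, cum, n, j) {
  m <- length(y)
  has_gm <- j > 1
  nv <- m + as.integer(has_gm) + 1
  gm_i <- m + 1
  d_i <- nv
  upb <- c(0, cum[-m]) / n
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  add1 <- function(row, rhs) { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
  add2 <- function(row, rhs) { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
  z <- rep(0, nv)
  for (k in 1:m) {
    row <- z; row[k] <- 1; row[d_i] <- 1; add2(row, cum[k] / n)
    row <- z; row[k] <- 1; row[d_i] <- -1
    add1(row, if (k == j) cum[j] / n else upb[k])
  }
  for (k in seq_len(m - 1)) {
    row <- z; row[k] <- 1; row[k + 1] <- -1; add1(row, 0)
  }
  if (has_gm) {
    row <- z; row[gm_i] <- 1; row[d_i] <- -1; add1(row, upb[j])
    row <- z; row[j - 1] <- 1; row[gm_i] <- -1; add1(row, 0)
    row <- z; row[gm_i] <- 1; row[j] <- -1; add1(row, 0)
  }
  chain <- function(px, pv, convex) {
    if (length(px) < 3) return()
    for (q in 2:(length(px) - 1)) {
      d1 <- px[q] - px[q - 1]; d2 <- px[q + 1] - px[q]
      row <- z
      s <- if (convex) 1 else -1
      row[pv[q - 1]] <- row[pv[q - 1]] - s / d1
      row[pv[q]] <- row[pv[q]] + s / d1 + s / d2
      row[pv[q + 1]] <- row[pv[q + 1]] - s / d2
      add1(row, 0)
    }
  }
  chain(c(y[seq_len(j - 1)], if (has_gm) y[j]),
        c(seq_len(j - 1), if (has_gm) gm_i), convex = TRUE)
  chain(y[j:m], j:m, convex = FALSE)
  obj <- z; obj[d_i] <- -1
  res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       maxi = TRUE, n.iter = 2000)
  if (res$solved != 1) return(Inf)
  -res$value
}

dip_lp_interior <- function(y, cum, n, k, t_mode) {
  m <- length(y)
  nv <- m + 3                       # g_1..g_m, a, b, d
  a_i <- m + 1; b_i <- m + 2; d_i <- m + 3
  upb <- c(0, cum[-m]) / n
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  add1 <- function(row, rhs) { A1 <<- rbind(A1, row); b1 <<- c(b1, rhs) }
  add2 <- function(row, rhs) { A2 <<- rbind(A2, row); b2 <<- c(b2, rhs) }
  z <- rep(0, nv)
  for (kk in 1:m) {
    row <- z; row[kk] <- 1; row[d_i] <- 1; add2(row, cum[kk] / n)
    row <- z; row[kk] <- 1; row[d_i] <- -1; add1(row, upb[kk])
  }
  for (kk in seq_len(m - 1)) {
    row <- z; row[kk] <- 1; row[kk + 1] <- -1; add1(row, 0)
  }
  Fk <- cum[k] / n
  row <- z; row[a_i] <- 1; row[d_i] <- -1; add1(row, Fk)
  row <- z; row[b_i] <- 1; row[d_i] <- -1; add1(row, Fk)
  row <- z; row[b_i] <- 1; row[d_i] <- 1; add2(row, Fk)
  row <- z; row[k] <- 1; row[a_i] <- -1; add1(row, 0)
  row <- z; row[a_i] <- 1; row[b_i] <- -1; add1(row, 0)
  row <- z; row[b_i] <- 1; row[k + 1] <- -1; add1(row, 0)
  chain <- function(px, pv, convex) {
    if (length(px) < 3) return()
    for (q in 2:(length(px) - 1)) {
      d1 <- px[q] - px[q - 1]; d2 <- px[q + 1] - px[q]
      row <- z
      s <- if (convex) 1 else -1
      row[pv[q - 1]] <- row[pv[q - 1]] - s / d1
      row[pv[q]] <- row[pv[q]] + s / d1 + s / d2
      row[pv[q + 1]] <- row[pv[q + 1]] - s / d2
      add1(row, 0)
    }
  }
  chain(c(y[seq_len(k)], t_mode), c(seq_len(k), a_i), convex = TRUE)
  chain(c(t_mode, y[(k + 1):m]), c(b_i, (k + 1):m), convex = FALSE)
  obj <- z; obj[d_i] <- -1
  res <- boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                       maxi = TRUE, n.iter = 2000)
  if (res$solved != 1) return(Inf)
  -res$value
}

dip_oracle <- function(x, virtual = TRUE) {
  xs <- sort(x)
  n <- length(xs)
  y <- unique(xs)
  cum <- cumsum(tabulate(match(xs, y), nbins = length(y)))
  m <- length(y)
  if (m == 1) return(0)
  best <- Inf
  for (j in 1:m) best <- min(best, dip_lp_mode(y, cum, n, j))
  if (virtual && m >= 2)
    for (k in seq_len(m - 1))
      best <- min(best,
                  dip_lp_interior(y, cum, n, k, (y[k] + y[k + 1]) / 2))
  best
}

# ---- projection-matrix ANOVA oracle -------------------------------------
# Type-III sums of squares of a 2x2 factorial by explicit projection
# matrices (sum-to-zero contrasts).
anova_proj_oracle <- function(df) {
  X_full <- model.matrix(~ raga * level, df,
                         contrasts.arg = list(raga = "contr.sum",
                                              level = "contr.sum"))
  y <- df$score
  P <- function(X) X %*% solve(crossprod(X), t(X))
  Pf <- P(X_full)
  ss_drop <- function(col) {
    Xr <- X_full[, setdiff(colnames(X_full), col), drop = FALSE]
    drop(t(y) %*% (Pf - P(Xr)) %*% y)
  }
  list(raga = ss_drop("raga1"), level = ss_drop("level1"),
       interaction = ss_drop("raga1:level1"),
       error = drop(t(y) %*% (diag(nrow(df)) - Pf) %*% y))
}
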