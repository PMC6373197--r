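# Independent brute-force oracles. These deliberately avoid the code paths
# (and where possible the distribution functions) used by the package.

# Pearson r from explicit sums.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Two-sided correlation p-value by numeric integration of the t density.
oracle_cor_pvalue <- function(r, n) {
  df <- n - 2
  t_stat <- abs(r) * sqrt(df / (1 - r^2))
  dens <- function(u) {
    exp(lgamma((df + 1) / 2) - lgamma(df / 2)) / sqrt(df * pi) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, t_stat, Inf, rel.tol = 1e-13,
                       abs.tol = 1e-15)$value
}

# One-way ANOVA by hand: explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  levs <- unique(groups)
  ssb <- 0
  ssw <- 0
  for (g in levs) {
    x <- values[groups == g]
    ssb <- ssb + length(x) * (mean(x) - grand)^2
    ssw <- ssw + sum((x - mean(x))^2)
  }
  df1 <- length(levs) - 1
  df2 <- length(values) - length(levs)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df_between = df1, df_within = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE),
       ssb = ssb, ssw = ssw)
}

# Single-step Sidak by repeated multiplication (no power operator).
oracle_sidak <- function(p, m) {
  keep <- 1
  for (i in seq_len(m)) keep <- keep * (1 - p)
  min(1, 1 - keep)
}

# Holm-Sidak step-down enumerated with an explicit loop and running max.
oracle_holm_sidak <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    a <- oracle_sidak(p[ord[i]], m - i + 1)
    running <- max(running, a)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# Critical r above which the two-sided p at n - 2 df drops below p_max.
oracle_critical_r <- function(p_max, n) {
  df <- n - 2
  t_crit <- stats::qt(1 - p_max / 2, df)
  t_crit / sqrt(t_crit^2 + df)
}
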