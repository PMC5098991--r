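#' Interquartile-range outlier screening
#'
#' Flags values outside `[Q1 - k * IQR, Q3 + k * IQR]` with the usual fence
#' multiplier `k = 1.5`; quartiles use linear interpolation (type 7). The
#' screen is applied per condition to the time spent in each lateral
#' section, and a fish flagged on either side is discarded from all
#' observables.
#'
#' @param values Numeric vector, length >= 4.
#' @param k Fence multiplier, default 1.5.
#' @return Logical vector, `TRUE` = outlier.
#' @export
iqr_outliers <- function(values, k = 1.5) {
  if (length(values) < 4) stop("need at least 4 values for IQR screening")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Tail probability of the t distribution
#'
#' @param t t statistic.
#' @param df Degrees of freedom (>= 1).
#' @param tail `"greater"`, `"less"` or `"two.sided"`.
#' @return p-value.
#' @export
t_tail_p <- function(t, df, tail = c("greater", "less", "two.sided")) {
  tail <- match.arg(tail)
  if (df < 1) stop("df must be >= 1")
  switch(tail,
         greater = stats::pt(t, df, lower.tail = FALSE),
         less = stats::pt(t, df),
         two.sided = 2 * stats::pt(-abs(t), df))
}

#' One-sample t-test against a reference mean
#'
#' Tests whether group values (e.g. preference indices) exceed a reference
#' mean, chance level 0.5 by default. The default tail is one-sided
#' (greater than chance), matching the directional preference hypothesis;
#' the two-sided p is also reported.
#'
#' @param values Numeric vector (n >= 2, non-degenerate).
#' @param mu0 Reference mean, default 0.5.
#' @param tail Tail convention, default `"greater"`.
#' @return List: `statistic`, `df`, `p`, `p_two_sided`, `mean`, `se`,
#'   `tail`.
#' @export
one_sample_t <- function(values, mu0 = 0.5, tail = "greater") {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 finite values")
  s <- stats::sd(values)
  if (s == 0) stop("zero variance: t statistic undefined")
  se <- s / sqrt(n)
  t <- (mean(values) - mu0) / se
  list(statistic = t, df = n - 1, p = t_tail_p(t, n - 1, tail),
       p_two_sided = t_tail_p(t, n - 1, "two.sided"),
       mean = mean(values), se = se, tail = tail)
}

#' One-way analysis of variance
#'
#' Explicit between/within sum-of-squares decomposition across the
#' condition groups: `F = MS_between / MS_within` with `k - 1` and `N - k`
#' degrees of freedom.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each n >= 2).
#' @return List: `F`, `df1`, `df2`, `p`, `ss_between`, `ss_within`,
#'   `group_means`, `n`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(v) v[is.finite(v)])
  k <- length(groups)
  if (k < 2) stop("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2)) stop("each group needs at least 2 values")
  all_v <- unlist(groups)
  gm <- mean(all_v)
  means <- vapply(groups, mean, 0)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df1 <- k - 1; df2 <- sum(ns) - k
  if (ssw == 0) stop("zero within-group variance everywhere")
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, df1 = df1, df2 = df2,
       p = stats::pf(F, df1, df2, lower.tail = FALSE),
       ss_between = ssb, ss_within = ssw, group_means = means, n = ns)
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range pairwise p-values after a one-way ANOVA; unequal group
#' sizes use the Tukey-Kramer standard error
#' `sqrt(MS_within / 2 * (1/n_i + 1/n_j))`.
#'
#' @param groups Named list of numeric vectors (as [one_way_anova()]).
#' @return Symmetric matrix of adjusted p-values with unit diagonal.
#' @export
tukey_hsd <- function(groups) {
  aov1 <- one_way_anova(groups)
  groups <- lapply(groups, function(v) v[is.finite(v)])
  k <- length(groups)
  msw <- aov1$ss_within / aov1$df2
  means <- aov1$group_means
  ns <- aov1$n
  p <- matrix(1, k, k, dimnames = list(names(groups), names(groups)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(msw / 2 * (1 / ns[i] + 1 / ns[j]))
    q <- abs(means[i] - means[j]) / se
    p[i, j] <- p[j, i] <- stats::ptukey(q, k, aov1$df2, lower.tail = FALSE)
  }
  p
}

#' Direction-by-segment ANOVA on normalized transfer entropy
#'
#' Two-factor fixed-effects ANOVA (direction x segment) with Type-II sums
#' of squares on the possibly unbalanced long table of one condition,
#' pooling all segments into a single error stratum (this matches the
#' degrees-of-freedom bookkeeping of the direction tests, e.g. a direction
#' effect with numerator df 1).
#'
#' @param long data.frame with columns `direction`, `segment`, `te_norm`
#'   (the per-segment normalized transfer entropies of one condition, both
#'   directions).
#' @return data.frame with one row per effect (`direction`, `segment`,
#'   `direction:segment`): `F`, `df1`, `df2`, `p`.
#' @export
direction_segment_anova <- function(long) {
  stopifnot(all(c("direction", "segment", "te_norm") %in% names(long)))
  d <- factor(long$direction)
  s <- factor(long$segment)
  if (nlevels(d) < 2 || nlevels(s) < 2)
    stop("need at least 2 directions and 2 segments")
  y <- long$te_norm
  rss <- function(mm) {
    fit <- stats::lm.fit(mm, y)
    sum(fit$residuals^2)
  }
  mm_full <- stats::model.matrix(~ d * s)
  mm_ds <- stats::model.matrix(~ d + s)
  mm_d <- stats::model.matrix(~ d)
  mm_s <- stats::model.matrix(~ s)
  r_full <- rss(mm_full); r_ds <- rss(mm_ds)
  r_d <- rss(mm_d); r_s <- rss(mm_s)
  df_err <- length(y) - qr(mm_full)$rank
  if (df_err < 1) stop("no residual degrees of freedom (one observation per cell)")
  mse <- r_full / df_err
  eff <- data.frame(
    effect = c("direction", "segment", "direction:segment"),
    ss = c(r_s - r_ds, r_d - r_ds, r_ds - r_full),
    df1 = c(nlevels(d) - 1, nlevels(s) - 1,
            qr(mm_full)$rank - qr(mm_ds)$rank))
  eff$F <- (eff$ss / eff$df1) / mse
  eff$df2 <- df_err
  eff$p <- stats::pf(eff$F, eff$df1, eff$df2, lower.tail = FALSE)
  eff[, c("effect", "F", "df1", "df2", "p")]
}
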