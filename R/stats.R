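#' Pooled-variance independent-samples t-test
#'
#' Classical Student t with pooled variance (df = n1 + n2 - 2), matching the
#' degrees of freedom convention of standard neuropsychology reports. With
#' zero pooled variance the statistic is 0 for equal means and signed
#' infinity (flagged `degenerate`) otherwise.
#'
#' @param x,y Numeric samples (each n >= 2); `NA`s are dropped.
#' @return A one-row tibble: `t`, `df`, `p`, `design`, `n1`, `n2`,
#'   `degenerate`.
#' @export
t_independent <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  assert_that(n1 >= 2 && n2 >= 2, "both samples need n >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  diff <- mean(x) - mean(y)
  if (se == 0) {
    t <- if (diff == 0) 0 else sign(diff) * Inf
    degen <- diff != 0
  } else {
    t <- diff / se
    degen <- FALSE
  }
  p <- if (is.finite(t)) 2 * pt(-abs(t), df) else 0
  tibble(t = t, df = df, p = p, design = "independent",
         n1 = n1, n2 = n2, degenerate = degen)
}

#' Paired-samples t-test
#'
#' One-sample Student t on the pairwise differences. All-zero differences
#' give t = 0; a constant nonzero difference gives signed infinity (flagged
#' `degenerate`).
#'
#' @param x,y Paired numeric samples of equal length (n >= 2); pairs with an
#'   `NA` on either side are dropped.
#' @return A one-row tibble: `t`, `df`, `p`, `design`, `n`.
#' @export
t_paired <- function(x, y) {
  assert_that(length(x) == length(y), "paired samples must have equal length")
  ok <- !is.na(x) & !is.na(y)
  d <- x[ok] - y[ok]
  n <- length(d)
  assert_that(n >= 2, "need at least two complete pairs")
  se <- sd(d) / sqrt(n)
  if (se == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    degen <- mean(d) != 0
  } else {
    t <- mean(d) / se
    degen <- FALSE
  }
  p <- if (is.finite(t)) 2 * pt(-abs(t), n - 1) else 0
  tibble(t = t, df = n - 1, p = p, design = "paired", n = n,
         degenerate = degen)
}

#' JZS (default Cauchy prior) Bayes factor for t-designs
#'
#' Computes the default Bayes factor BF10 for a t-statistic by integrating
#' the standardised effect size over a zero-centred Cauchy prior of scale
#' `rscale` (default 0.707), against the point null, via adaptive numerical
#' quadrature over the auxiliary inverse-chi-square mixing variable. For an
#' independent design the effective sample size is `n1 * n2 / (n1 + n2)` with
#' `n1 + n2 - 2` degrees of freedom; for a paired/one-sample design (omit
#' `n2`) it is `n1` with `n1 - 1` degrees of freedom.
#'
#' @param t Observed t statistic (finite).
#' @param n1 First group size, or the number of pairs.
#' @param n2 Second group size, or `NULL` for the one-sample/paired form.
#' @param rscale Cauchy prior scale on the effect size.
#' @return A one-row tibble: `bf10`, `bf01`, `rscale`, `design`.
#' @export
jzs_bf_ttest <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2) {
  assert_that(is.numeric(t) && length(t) == 1 && is.finite(t),
              "t must be a finite scalar")
  if (is.null(n2)) {
    assert_that(n1 >= 2, "need n >= 2")
    N <- n1
    nu <- n1 - 1
    design <- "paired"
  } else {
    assert_that(n1 >= 2 && n2 >= 2, "need n >= 2 per group")
    N <- n1 * n2 / (n1 + n2)
    nu <- n1 + n2 - 2
    design <- "independent"
  }
  # marginal likelihood under H1, mixing over g ~ InvGamma(1/2, 1/2)
  integrand <- function(g) {
    s <- 1 + N * g * rscale^2
    s^(-1 / 2) * (1 + t^2 / (s * nu))^(-(nu + 1) / 2) *
      g^(-3 / 2) * exp(-1 / (2 * g)) / sqrt(2 * pi)
  }
  num <- integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  bf10 <- num / den
  tibble(bf10 = bf10, bf01 = 1 / bf10, rscale = rscale, design = design)
}

#' Greenhouse-Geisser sphericity correction factor
#'
#' Epsilon computed from the double-centred covariance matrix of the within
#' levels; degrees of freedom are multiplied by it downstream when the within
#' factor has more than two levels. Bounded in [1/(k-1), 1]; exactly 1 under
#' compound symmetry and, trivially, for k = 2.
#'
#' @param covariance k x k covariance matrix of the within-subject levels.
#' @return Epsilon (scalar).
#' @export
gg_epsilon <- function(covariance) {
  covariance <- as.matrix(covariance)
  assert_that(isTRUE(all.equal(covariance, t(covariance))),
              "covariance must be symmetric")
  k <- nrow(covariance)
  assert_that(k >= 2, "need k >= 2 within levels")
  Cc <- diag(k) - matrix(1 / k, k, k)
  S <- Cc %*% covariance %*% Cc
  sum(diag(S))^2 / ((k - 1) * sum(S * S))
}

#' Two-by-two mixed-design ANOVA
#'
#' Classical split-plot decomposition for one between-subjects factor (two
#' groups) and one within-subject factor (two levels, no missing cells): the
#' group effect is tested against the subject-within-group error, the within
#' effect and the interaction against the subject x within residual. With
#' two within levels sphericity is trivial (Greenhouse-Geisser epsilon = 1).
#'
#' @param values Numeric subjects x 2 matrix (or data frame) of the within
#'   levels, one row per subject.
#' @param group Per-subject group labels (two levels).
#' @return A tibble with one row per effect (`group`, `within`,
#'   `interaction`): `F`, `df_num`, `df_den`, `p`, plus `gg_epsilon`.
#' @export
mixed_anova_2x2 <- function(values, group) {
  values <- as.matrix(values)
  assert_that(ncol(values) == 2, "values must have exactly 2 within levels")
  assert_that(nrow(values) == length(group),
              "one group label per subject required")
  assert_that(!anyNA(values), "missing cell in the within-subject design")
  groups <- sort(unique(as.character(group)))
  assert_that(length(groups) == 2, "need exactly two groups")
  g <- as.character(group)
  n_g <- table(factor(g, levels = groups))
  assert_that(all(n_g >= 2), "need at least two subjects per group")
  N <- nrow(values)

  subj_mean <- rowMeans(values)
  d <- values[, 2] - values[, 1]
  grand <- mean(subj_mean)
  gmeans <- tapply(subj_mean, g, mean)

  # between-subjects stratum (2 observations per subject)
  ss_group <- 2 * sum(n_g * (gmeans[groups] - grand)^2)
  ss_err_b <- 2 * sum((subj_mean - gmeans[g])^2)

  # within-subjects stratum, expressed through the difference scores
  dmeans <- tapply(d, g, mean)
  dbar <- mean(d)
  ss_within <- N * dbar^2 / 2
  ss_inter <- sum(n_g * (dmeans[groups] - dbar)^2) / 2
  ss_err_w <- sum((d - dmeans[g])^2) / 2

  df_err <- N - 2
  safe_f <- function(ss, ss_err) {
    if (ss == 0) 0 else ss / (ss_err / df_err)  # 0 effect SS beats 0/0
  }
  eff <- tibble(
    effect = c("group", "within", "interaction"),
    F = c(safe_f(ss_group, ss_err_b),
          safe_f(ss_within, ss_err_w),
          safe_f(ss_inter, ss_err_w)),
    df_num = 1,
    df_den = df_err
  )
  eff$p <- pf(eff$F, eff$df_num, eff$df_den, lower.tail = FALSE)
  eff$gg_epsilon <- 1
  eff
}

#' Pearson correlation with t-based p-value
#'
#' Product-moment correlation; the two-sided p-value comes from the exact t
#' transform with n - 2 degrees of freedom. Zero variance in either variable
#' yields an `NA`-marked result rather than an error.
#'
#' @param x,y Numeric vectors; pairs with an `NA` are dropped.
#' @return A one-row tibble: `r`, `n`, `df`, `p`.
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "need at least three complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, n = n, df = n - 2, p = NA_real_))
  }
  r <- cor(x, y)
  t <- r * sqrt((n - 2) / (1 - r^2))
  tibble(r = r, n = n, df = n - 2, p = 2 * pt(-abs(t), n - 2))
}

#' Simple linear regression
#'
#' Ordinary least squares of `y` on `x`; the slope F equals the squared slope
#' t and the r-squared equals the squared Pearson correlation.
#'
#' @param x Predictor; must have nonzero variance.
#' @param y Response.
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `F`,
#'   `df_num`, `df_den`, `p`.
#' @export
simple_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  assert_that(length(x) >= 3, "need at least three complete pairs")
  assert_that(sd(x) > 0, "predictor has zero variance")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  tibble(
    slope = coef(fit)[["x"]],
    intercept = coef(fit)[["(Intercept)"]],
    r_squared = sm$r.squared,
    F = sm$fstatistic[["value"]],
    df_num = sm$fstatistic[["numdf"]],
    df_den = sm$fstatistic[["dendf"]],
    p = pf(sm$fstatistic[["value"]], sm$fstatistic[["numdf"]],
           sm$fstatistic[["dendf"]], lower.tail = FALSE)
  )
}

#' Bonferroni-adjusted per-comparison alpha
#'
#' @param alpha Family-wise alpha.
#' @param m Number of comparisons.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha, m) {
  assert_that(is_count(m), "m must be a positive integer")
  alpha / m
}
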