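test_that("pooled t matches the closed form and base R on fixtures", {
  tt <- t_independent(c(1, 2, 3), c(4, 5, 6))
  expect_equal(tt$t, -3.674235, tolerance = 1e-6)
  expect_equal(tt$df, 4)
  # identical samples
  same <- t_independent(c(2, 4, 9), c(2, 4, 9))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # location shift applied to both samples leaves t unchanged
  set.seed(1)
  x <- rnorm(10); y <- rnorm(12)
  expect_equal(t_independent(x + 5, y + 5)$t, t_independent(x, y)$t)
  # cross-check against stats::t.test with pooled variance
  ref <- t.test(x, y, var.equal = TRUE)
  mine <- t_independent(x, y)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  # zero pooled variance with unequal means
  degen <- t_independent(c(1, 1), c(2, 2))
  expect_true(is.infinite(degen$t) && degen$t < 0)
  expect_true(degen$degenerate)
})

test_that("paired t equals the one-sample formula on the differences", {
  set.seed(2)
  x <- rnorm(15); y <- rnorm(15)
  mine <- t_paired(x, y)
  ref <- t.test(x, y, paired = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$df, 14)
  expect_equal(t_paired(x, x)$t, 0)
  expect_equal(t_paired(x, x)$p, 1)
  degen <- t_paired(rep(5, 10), rep(2, 10))  # exactly constant difference
  expect_true(is.infinite(degen$t) && degen$t > 0)
  expect_error(t_paired(x, y[-1]), "equal length")
})

test_that("JZS Bayes factors match two independent formulations", {
  # oracle: integrate the noncentral-t likelihood directly over the Cauchy
  # effect-size prior (a different parametrisation and integrand entirely)
  bf_delta <- function(t, N, nu, r = sqrt(2) / 2) {
    num <- integrate(function(d) {
      suppressWarnings(dt(t, nu, ncp = d * sqrt(N))) * dcauchy(d, 0, r)
    }, -Inf, Inf, rel.tol = 1e-10, subdivisions = 400L)$value
    num / dt(t, nu)
  }
  cases <- list(c(2.0, 15, 15), c(3.19, 24, 32), c(-1.2, 10, 14),
                c(0.5, 8, 8))
  for (cs in cases) {
    expect_equal(
      jzs_bf_ttest(cs[1], cs[2], cs[3])$bf10,
      bf_delta(cs[1], cs[2] * cs[3] / (cs[2] + cs[3]), cs[2] + cs[3] - 2),
      tolerance = 1e-6
    )
  }
  expect_equal(jzs_bf_ttest(2.5, 20)$bf10, bf_delta(2.5, 20, 19),
               tolerance = 1e-6)
  # frozen values from a separately authored public implementation agree to
  # about four significant digits (its quadrature is the looser one)
  expect_equal(jzs_bf_ttest(3.19, 24, 32)$bf10, 15.17648935258866,
               tolerance = 2e-4)
  expect_equal(jzs_bf_ttest(2.0, 15, 15)$bf10, 1.488145989432979,
               tolerance = 2e-4)
  expect_equal(jzs_bf_ttest(1.0, 12)$bf10, 0.4366309633708353,
               tolerance = 2e-4)
  # bf10 * bf01 = 1; t = 0 favours the null for any n
  out <- jzs_bf_ttest(0, 12, 15)
  expect_equal(out$bf10 * out$bf01, 1, tolerance = 1e-12)
  expect_lt(out$bf10, 1)
  expect_lt(jzs_bf_ttest(0, 5)$bf10, 1)
  # monotone increasing in |t| for fixed n
  bfs <- vapply(c(0, 0.5, 1, 2, 3, 5),
                function(t) jzs_bf_ttest(t, 20, 20)$bf10, numeric(1))
  expect_true(all(diff(bfs) > 0))
  expect_error(jzs_bf_ttest(Inf, 10, 10), "finite")
})

test_that("Greenhouse-Geisser epsilon hits its analytic anchors", {
  expect_equal(gg_epsilon(diag(2)), 1)
  # any compound-symmetric covariance is spherical
  cs <- matrix(0.3, 4, 4) + diag(0.7, 4)
  expect_equal(gg_epsilon(cs), 1)
  # rank-one double-centred covariance reaches the 1/(k-1) floor
  lower <- outer(1:4, 1:4)
  expect_equal(gg_epsilon(lower), 1 / 3, tolerance = 1e-12)
  expect_error(gg_epsilon(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("the 2x2 mixed ANOVA reproduces aov and the difference-score t", {
  set.seed(4)
  for (ns in list(c(6, 6), c(5, 9))) {
    vals <- matrix(rnorm(2 * sum(ns)), sum(ns))
    grp <- rep(c("g1", "g2"), ns)
    res <- mixed_anova_2x2(vals, grp)
    df <- data.frame(
      y = c(vals), subj = factor(rep(seq_len(sum(ns)), 2)),
      w = factor(rep(1:2, each = sum(ns))), g = factor(rep(grp, 2))
    )
    ref <- summary(aov(y ~ g * w + Error(subj / w), data = df))
    between <- ref[["Error: subj"]][[1]]
    within <- ref[["Error: subj:w"]][[1]]
    expect_equal(res$F[res$effect == "group"], between["g", "F value"],
                 tolerance = 1e-9)
    expect_equal(res$F[res$effect == "within"], within["w", "F value"],
                 tolerance = 1e-9)
    expect_equal(res$F[res$effect == "interaction"], within["g:w", "F value"],
                 tolerance = 1e-9)
    # interaction F = squared independent t on difference scores
    d <- vals[, 2] - vals[, 1]
    expect_equal(res$F[res$effect == "interaction"],
                 t_independent(d[grp == "g1"], d[grp == "g2"])$t^2,
                 tolerance = 1e-9)
    # group F = squared independent t on subject means
    m <- rowMeans(vals)
    expect_equal(res$F[res$effect == "group"],
                 t_independent(m[grp == "g1"], m[grp == "g2"])$t^2,
                 tolerance = 1e-9)
    expect_equal(res$gg_epsilon, rep(1, 3))
  }
  # all-identical values -> all F = 0
  flat <- mixed_anova_2x2(matrix(5, 8, 2), rep(c("a", "b"), each = 4))
  expect_equal(flat$F, rep(0, 3))
  expect_error(mixed_anova_2x2(matrix(c(1, NA, 2, 3), 2),
                               c("a", "b")), "missing cell")
})

test_that("Pearson correlation and its p-value match cor.test", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  b_orth <- residuals(lm(b ~ a))
  expect_lt(abs(pearson_cor(a, b_orth)$r), 1e-12)
  ref <- cor.test(a, b)
  mine <- pearson_cor(a, b)
  expect_equal(mine$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  flat <- pearson_cor(rep(3, 5), rnorm(5))
  expect_true(is.na(flat$r) && is.na(flat$p))
})

test_that("simple regression agrees with the normal equations", {
  x <- c(1, 3, 4, 6, 8)
  y <- 2.5 * x - 1
  # lm warns about the numerically perfect fit; the values are still exact
  fit <- suppressWarnings(simple_regression(x, y))
  expect_equal(fit$slope, 2.5, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  set.seed(6)
  a <- rnorm(25); b <- 0.7 * a + rnorm(25)
  fit2 <- simple_regression(a, b)
  # normal-equations oracle
  X <- cbind(1, a)
  beta <- solve(t(X) %*% X, t(X) %*% b)
  expect_equal(fit2$intercept, beta[1], tolerance = 1e-10)
  expect_equal(fit2$slope, beta[2], tolerance = 1e-10)
  expect_equal(fit2$r_squared, pearson_cor(a, b)$r^2, tolerance = 1e-12)
  # F of the slope = squared slope t
  tslope <- coef(summary(lm(b ~ a)))["a", "t value"]
  expect_equal(fit2$F, tslope^2, tolerance = 1e-9)
  expect_error(simple_regression(rep(1, 5), rnorm(5)), "zero variance")
})

test_that("type-I error of the pooled t is calibrated at the nominal alpha", {
  set.seed(7)
  n_rep <- 2000
  rejections <- vapply(seq_len(n_rep), function(i) {
    t_independent(rnorm(12), rnorm(12))$p < 0.05
  }, logical(1))
  rate <- mean(rejections)
  mc_se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rate - 0.05), 2.5 * mc_se)
})

test_that("the Bonferroni helper reproduces the published adjusted alpha", {
  expect_equal(bonferroni_alpha(0.05, 40), 0.00125)
  expect_equal(bonferroni_alpha(0.05, 2), 0.025)
  expect_error(bonferroni_alpha(0.05, 0), "positive integer")
})
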