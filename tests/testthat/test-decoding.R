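test_that("the default grid tiles [-100, 300) into 40 disjoint 5-sample windows", {
  grid <- window_grid()
  expect_equal(nrow(grid), 40)
  expect_equal(attr(grid, "samples_per_window"), 5)
  expect_equal(grid$t_start[1], -100)
  expect_equal(grid$t_end[40], 300)
  # windows are contiguous and non-overlapping
  expect_equal(grid$t_start[-1], grid$t_end[-40])
  # window index 10 starts at the response (0 ms)
  expect_equal(grid$t_start[grid$window == 10], 0)
  # 40 windows x 5 samples tile the 200-sample epoch exactly
  expect_equal(nrow(grid) * attr(grid, "samples_per_window"), 200)
  expect_error(window_grid(c(-100, 305)), "whole number")
})

test_that("feature matrices concatenate channels channel-major", {
  times <- seq(-100, 298, by = 2)
  w <- matrix(seq_len(2 * length(times)), nrow = 2, byrow = TRUE)
  ep <- manual_epochs(list(w, 10 * w), times,
                      labels = c("detected_error", "correct_go"))
  grid <- window_grid()
  X <- build_features(ep, grid, 0)
  expect_equal(dim(X), c(2, 10))  # 2 channels x 5 samples
  # channel-major: first 5 features are channel 1's samples
  expect_equal(X[1, ], c(w[1, 1:5], w[2, 1:5]))
  expect_equal(X[2, ], 10 * c(w[1, 1:5], w[2, 1:5]))
  expect_error(build_features(ep, grid, 40), "out of range")
  # rejected epochs are excluded from the rows
  ep$qc$kept[1] <- FALSE
  X2 <- build_features(ep, grid, 0)
  expect_equal(nrow(X2), 1)
  expect_equal(attr(X2, "labels"), "correct_go")
})

test_that("61-channel epochs give 305 features per window", {
  mont <- montage_61()
  times <- seq(-100, 298, by = 2)
  dat <- matrix(0, 61, length(times))
  ep <- manual_epochs(list(dat), times, labels = "detected_error",
                      channels = mont$label)
  X <- build_features(ep, window_grid(), 0)
  expect_equal(ncol(X), 305)
})

test_that("class balancing subsamples the majority class deterministically", {
  labels <- c(rep("correct", 120), rep("error", 15))
  keep <- balance_classes(labels, seed = 1)
  expect_equal(sum(labels[keep] == "correct"), 15)
  expect_equal(sum(labels[keep] == "error"), 15)
  expect_false(is.unsorted(keep))  # order-preserving
  expect_identical(keep, balance_classes(labels, seed = 1))
  expect_false(identical(keep, balance_classes(labels, seed = 2)))
  # already balanced -> identity
  bal <- c(rep("a", 12), rep("b", 12))
  expect_identical(balance_classes(bal, seed = 1), 1:24)
  expect_error(balance_classes(c(rep("a", 9), rep("b", 30)), seed = 1),
               "inclusion error")
})

test_that("the linear SVM solves separable fixtures and is label-antisymmetric", {
  X <- matrix(c(-1, 1), ncol = 1)
  fit <- train_linear_classifier(X, c("a", "b"))
  expect_equal(predict(fit, matrix(c(-5, -0.1, 0.1, 5), ncol = 1)),
               c("a", "a", "b", "b"))
  expect_equal(as.numeric(X %*% fit$w + fit$b), c(-1, 1), tolerance = 1e-6)
  # swapping the labels negates the decision function
  fit2 <- train_linear_classifier(X, c("b", "a"))
  expect_equal(fit2$w, -fit$w, tolerance = 1e-6)
  # identical rows with conflicting labels: valid chance-level model, no crash
  Xd <- matrix(1, 4, 2)
  fitd <- train_linear_classifier(Xd, c("a", "b", "a", "b"))
  expect_true(all(is.finite(fitd$w)))
  expect_error(train_linear_classifier(X, c("a", "a")), "two classes")
})

test_that("SVM decision values match the exact dual-QP oracle on 6-point fixtures", {
  set.seed(42)
  for (k in 1:5) {
    X <- matrix(rnorm(12), 6, 2)
    y <- rep(c("a", "b"), 3)
    oracle <- qp_svm(X, y, C = 1)
    fit <- train_linear_classifier(X, y, C = 1)
    expect_lt(max(abs((X %*% oracle$w + oracle$b) - (X %*% fit$w + fit$b))),
              1e-4)
  }
})

test_that("repeated cross-validation performs 100 analyses and nails separable data", {
  set.seed(5)
  X <- rbind(matrix(rnorm(10 * 4, 5), 10), matrix(rnorm(10 * 4, -5), 10))
  y <- rep(c("a", "b"), each = 10)
  acc <- cv_accuracy(X, y, folds = 10, repeats = 10, seed = 1)
  expect_equal(attr(acc, "n_evaluations"), 100)
  expect_equal(as.numeric(acc), 1)
  # determinism
  expect_equal(as.numeric(cv_accuracy(X, y, seed = 7)),
               as.numeric(cv_accuracy(X, y, seed = 7)))
  expect_error(cv_accuracy(X[c(1:5, 11:15), ], y[c(1:5, 11:15)], folds = 10),
               "fewer trials")
})

test_that("shuffled labels stay at chance while real labels decode", {
  set.seed(6)
  X <- rbind(matrix(rnorm(10 * 5, 3), 10), matrix(rnorm(10 * 5, -3), 10))
  y <- rep(c("a", "b"), each = 10)
  real <- as.numeric(cv_accuracy(X, y, seed = 3))
  null <- as.numeric(shuffled_null(X, y, seed = 3))
  expect_gte(real - null, 0.3)
  expect_equal(as.numeric(shuffled_null(X, y, seed = 3)),
               as.numeric(shuffled_null(X, y, seed = 3)))
})

test_that("decoding accuracy is invariant to channel-wise affine rescaling", {
  set.seed(11)
  X <- rbind(matrix(rnorm(12 * 6, 2), 12), matrix(rnorm(12 * 6, -2), 12))
  y <- rep(c("a", "b"), each = 12)
  a1 <- as.numeric(cv_accuracy(X, y, folds = 6, repeats = 3, seed = 4))
  gains <- runif(6, 0.5, 2)
  offsets <- rnorm(6)
  X2 <- sweep(sweep(X, 2, gains, "*"), 2, offsets, "+")
  a2 <- as.numeric(cv_accuracy(X2, y, folds = 6, repeats = 3, seed = 4))
  expect_equal(a1, a2)
})

test_that("full-subject decoding finds response information where it was embedded", {
  mont <- tiny_montage()
  params <- agent_params(p_nogo_error = 0.5, p_detect = 0.8)
  tr <- classify_trials(simulate_behavior(params, seed = 7, n_trials = 240))
  rec <- regress_ocular(synthesize_recording(
    tr, mont, default_components("control", latency_jitter_sd = 5),
    noise_spec(rms = 3, blink_rate = 8), seed = 2
  ))
  ep <- csd_transform(
    reject_artifacts(extract_epochs(rec, tr, "response", c(-100, 300))), mont
  )
  grid <- window_grid()
  crv <- decode_subject(ep, "s1", grid, folds = 5, repeats = 2, seed = 11)
  expect_equal(nrow(crv), 40)
  expect_true(all(crv$acc_real >= 0 & crv$acc_real <= 1))
  expect_equal(length(unique(crv$n_per_class)), 1)
  # errors and correct responses differ in embedded Ne/Pe amplitude, so some
  # post-response window must decode well above chance
  expect_gt(max(crv$acc_real[crv$window >= 10]), 0.75)
  # the shuffled null stays near chance everywhere
  expect_lt(mean(crv$acc_shuffled), 0.55)
  expect_gt(mean(crv$acc_shuffled), 0.45)
  # bit-reproducible under the same seed
  crv2 <- decode_subject(ep, "s1", grid, folds = 5, repeats = 2, seed = 11)
  expect_identical(crv, crv2)
})

test_that("group statistics Bonferroni-correct over windows and flag nothing on identical curves", {
  grid <- window_grid()
  mk_curves <- function(ids, group, acc) {
    purrr::map_dfr(ids, function(id) {
      tibble::tibble(subject_id = id, group = group, window = grid$window,
                     t_start = grid$t_start, t_end = grid$t_end,
                     acc_real = acc, acc_shuffled = acc, n_per_class = 10)
    })
  }
  acc <- rep(0.6, 40)
  curves <- dplyr::bind_rows(mk_curves(paste0("p", 1:4), "patient", acc),
                             mk_curves(paste0("c", 1:4), "control", acc))
  res <- decode_group_stats(curves)
  expect_equal(nrow(res), 40)
  expect_equal(unique(res$alpha_adj), 0.05 / 40)
  expect_true(all(res$t_between == 0))
  expect_false(any(res$sig_between))
  # mismatched grids across subjects are rejected
  expect_error(decode_group_stats(curves[-1, ]), "grids differ")
})
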