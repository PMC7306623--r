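#' Sliding analysis-window grid
#'
#' Partitions a half-open epoch window into contiguous, non-overlapping
#' analysis windows of `width` ms. At 500 Hz the default grid over
#' `[-100, 300)` ms yields 40 windows of 5 samples each.
#'
#' @param window Half-open epoch window in ms.
#' @param width Analysis window width in ms (also the step: non-overlapping).
#' @param srate Sampling rate in Hz.
#' @return A tibble with `window` (0-based index), `t_start`, `t_end` and the
#'   number of samples per window as attribute `samples_per_window`.
#' @export
window_grid <- function(window = c(-100, 300), width = 10, srate = 500) {
  span <- window[2] - window[1]
  n_win <- span / width
  assert_that(isTRUE(all.equal(n_win, round(n_win))),
              "epoch window must be a whole number of analysis windows")
  spw <- width * srate / 1000
  assert_that(isTRUE(all.equal(spw, round(spw))),
              "analysis width must be a whole number of samples")
  t0 <- window[1]
  out <- tibble(window = seq_len(n_win) - 1L,
                t_start = t0 + (seq_len(n_win) - 1L) * width,
                t_end = t0 + seq_len(n_win) * width)
  attr(out, "samples_per_window") <- as.integer(round(spw))
  out
}

#' Build the feature matrix for one analysis window
#'
#' Concatenates, for every kept epoch, the samples of all scalp channels
#' inside the requested analysis window, channel-major (all samples of
#' channel 1, then channel 2, ...). With 61 channels and 5 samples per window
#' this yields 305 features per trial.
#'
#' @param ep An [epoch_set] whose time axis matches the grid.
#' @param grid A [window_grid()].
#' @param window_index 0-based window index into the grid.
#' @return A trials x features matrix with the kept epochs' labels as
#'   attribute `labels` and the source epoch indices as attribute `epochs`.
#' @export
build_features <- function(ep, grid, window_index) {
  assert_that(window_index %in% grid$window,
              "window_index out of range for this grid")
  row <- grid[grid$window == window_index, ]
  cols <- which(ep$times >= row$t_start & ep$times < row$t_end)
  assert_that(length(cols) == attr(grid, "samples_per_window"),
              "epoch time axis does not match the window grid")
  keep <- kept_idx(ep)
  n_chan <- dim(ep$data)[2]
  X <- matrix(0, nrow = length(keep), ncol = n_chan * length(cols))
  for (i in seq_along(keep)) {
    X[i, ] <- as.vector(t(ep$data[keep[i], , cols]))
  }
  attr(X, "labels") <- ep$labels[keep]
  attr(X, "epochs") <- keep
  X
}

#' Balance two classes by subsampling the majority class
#'
#' Randomly subsamples the majority class (seeded) down to the minority
#' count, preserving trial order. Both classes must have at least
#' `min_trials` trials.
#'
#' @param labels Per-trial class labels (two distinct values).
#' @param seed Integer seed.
#' @param min_trials Inclusion threshold per class.
#' @return Sorted integer indices of the kept trials.
#' @export
balance_classes <- function(labels, seed = 1, min_trials = 10) {
  classes <- sort(unique(labels))
  assert_that(length(classes) == 2, "balance_classes() needs exactly two classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < min_trials)) {
    abort(sprintf("inclusion error: class '%s' has %d < %d trials",
                  names(counts)[which.min(counts)], min(counts), min_trials))
  }
  n_min <- min(counts)
  with_seed(seed, {
    keep <- unlist(lapply(classes, function(cl) {
      idx <- which(labels == cl)
      if (length(idx) > n_min) sort(sample(idx, n_min)) else idx
    }))
  })
  sort(keep)
}

#' Train a linear soft-margin support vector machine
#'
#' Fits the linear C-SVM (minimising 0.5*||w||^2 + C * sum of hinge losses)
#' on the given trials. Deterministic for fixed input. The returned object
#' carries the primal weight vector and bias oriented so that the decision
#' value `x %*% w + b` is positive for the second class in sorted label
#' order.
#'
#' @param X Trials x features numeric matrix.
#' @param y Per-trial labels (two classes).
#' @param C Regularisation parameter (default 1).
#' @param tolerance Termination criterion of the quadratic-programming
#'   solver; tight by default so solutions are reproducible to high
#'   precision.
#' @return A `linear_svm` object with elements `w`, `b`, `levels`, `fit`.
#' @export
train_linear_classifier <- function(X, y, C = 1, tolerance = 1e-7) {
  assert_that(C > 0, "C must be positive")
  lv <- sort(unique(as.character(y)))
  assert_that(length(lv) == 2, "need exactly two classes")
  yf <- factor(as.character(y), levels = lv)
  fit <- e1071::svm(X, yf, kernel = "linear", cost = C, scale = FALSE,
                    tolerance = tolerance)
  # libsvm orients decision values towards the class seen first in the data;
  # read the orientation off the decision-value column name and re-orient so
  # positive scores mean the second sorted level
  w_raw <- as.vector(t(fit$coefs) %*% fit$SV)
  b_raw <- -fit$rho
  dv <- predict(fit, X[1, , drop = FALSE], decision.values = TRUE)
  pos_class <- strsplit(colnames(attr(dv, "decision.values")), "/")[[1]][1]
  flip <- if (pos_class == lv[2]) 1 else -1
  structure(
    list(w = flip * w_raw, b = flip * b_raw, levels = lv, C = C, fit = fit),
    class = "linear_svm"
  )
}

#' @export
predict.linear_svm <- function(object, newdata, ...) {
  scores <- as.vector(newdata %*% object$w + object$b)
  object$levels[ifelse(scores > 0, 2L, 1L)]
}

make_stratified_folds <- function(y, folds) {
  assign <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    assert_that(length(idx) >= folds,
                sprintf("class '%s' has fewer trials (%d) than folds (%d)",
                        cl, length(idx), folds))
    assign[idx[sample.int(length(idx))]] <-
      rep(seq_len(folds), length.out = length(idx))
  }
  assign
}

#' Repeated cross-validated decoding accuracy
#'
#' For each repeat, trials are randomly partitioned into `folds`
#' class-stratified folds; the classifier is trained on all but one fold and
#' scored on the held-out fold, rotating through all folds. With the defaults
#' (10 folds x 10 repeats) this yields 100 train/test evaluations whose
#' accuracies are averaged into a single score. With `shuffle = TRUE` the
#' label vector is randomly permuted independently before every
#' cross-validation step, which produces the empirical chance (shuffled-label
#' null) accuracy for the same data.
#'
#' @param X Trials x features matrix (balanced classes).
#' @param y Per-trial labels (two classes, balanced).
#' @param folds,repeats Cross-validation layout.
#' @param seed Integer seed; the full procedure is a pure function of it.
#' @param C SVM regularisation parameter.
#' @param shuffle Permute labels per cross-validation step (null analysis).
#' @return Mean accuracy over all `folds * repeats` evaluations.
#' @export
cv_accuracy <- function(X, y, folds = 10, repeats = 10, seed = 1, C = 1,
                        shuffle = FALSE) {
  y <- as.character(y)
  assert_that(length(y) == nrow(X), "labels must match rows of X")
  with_seed(seed, {
    accs <- numeric(0)
    for (r in seq_len(repeats)) {
      fold_of <- make_stratified_folds(y, folds)
      for (k in seq_len(folds)) {
        if (shuffle) {
          # permute the label assignment independently per cross-validation
          # step; folds are re-stratified on the permuted labels so that
          # train/test class imbalance does not bias the null below chance
          y_use <- sample(y)
          test <- make_stratified_folds(y_use, folds) == k
        } else {
          y_use <- y
          test <- fold_of == k
        }
        fit <- train_linear_classifier(X[!test, , drop = FALSE], y_use[!test], C = C)
        pred <- predict(fit, X[test, , drop = FALSE])
        accs <- c(accs, mean(pred == y_use[test]))
      }
    }
    structure(mean(accs), n_evaluations = length(accs))
  })
}

#' @rdname cv_accuracy
#' @export
shuffled_null <- function(X, y, folds = 10, repeats = 10, seed = 1, C = 1) {
  cv_accuracy(X, y, folds = folds, repeats = repeats, seed = seed, C = C,
              shuffle = TRUE)
}

#' Decode response type across all analysis windows of a subject
#'
#' Collapses detected and undetected errors into one error class, balances it
#' against correct go responses (subsampling the majority class), and runs
#' the repeated cross-validated decoder plus its shuffled-label null in every
#' analysis window. Fully deterministic given the seed.
#'
#' @param ep A response-locked [epoch_set] covering the grid.
#' @param subject_id Subject identifier carried into the output.
#' @param grid A [window_grid()].
#' @param folds,repeats,C Decoder settings.
#' @param seed Integer seed (expanded into per-step streams).
#' @param min_trials Per-class inclusion threshold.
#' @return A decoding-curve tibble: one row per window with `acc_real`,
#'   `acc_shuffled` and `n_per_class`.
#' @export
decode_subject <- function(ep, subject_id = "s01", grid = window_grid(),
                           folds = 10, repeats = 10, C = 1, seed = 1,
                           min_trials = 10) {
  classes <- dplyr::case_when(
    ep$labels %in% c("detected_error", "undetected_error") ~ "error",
    ep$labels == "correct_go" ~ "correct",
    TRUE ~ NA_character_
  )
  usable <- which(!is.na(classes) & ep$qc$kept)
  y_all <- classes[usable]
  bal <- balance_classes(y_all, seed = derive_seed(seed, subject_id, "balance"),
                         min_trials = min_trials)
  sel <- usable[bal]

  purrr::pmap_dfr(grid, function(window, t_start, t_end) {
    X_all <- build_features(ep, grid, window)
    rows <- match(sel, attr(X_all, "epochs"))
    X <- X_all[rows, , drop = FALSE]
    y <- classes[sel]
    tibble(
      subject_id = subject_id, window = window,
      t_start = t_start, t_end = t_end,
      acc_real = as.numeric(
        cv_accuracy(X, y, folds, repeats,
                    seed = derive_seed(seed, subject_id, "real", window),
                    C = C)),
      acc_shuffled = as.numeric(
        shuffled_null(X, y, folds, repeats,
                      seed = derive_seed(seed, subject_id, "null", window),
                      C = C)),
      n_per_class = length(sel) / 2
    )
  })
}

#' Group-level statistics on decoding curves
#'
#' Per analysis window: a paired t-test of real versus shuffled accuracy
#' within each group (is error-related information present above chance?) and
#' a pooled-variance independent t-test of the real accuracies between groups.
#' The per-comparison alpha is Bonferroni-adjusted for the number of windows
#' (`family_alpha / n_windows`, 0.00125 for the default 40-window grid).
#'
#' @param curves Decoding curves of all subjects (rows from
#'   [decode_subject()]) with an added `group` column (two levels).
#' @param family_alpha Family-wise alpha over the window family.
#' @return A tibble with one row per window: within-group t/p per group,
#'   between-group t/p on real accuracies, the adjusted alpha and
#'   significance flags.
#' @export
decode_group_stats <- function(curves, family_alpha = 0.05) {
  assert_that(all(c("group", "subject_id", "window", "acc_real",
                    "acc_shuffled") %in% names(curves)),
              "curves must have group, subject_id, window, acc_real, acc_shuffled")
  groups <- sort(unique(curves$group))
  assert_that(length(groups) == 2, "need exactly two groups")
  n_per_group <- curves |>
    dplyr::distinct(group, subject_id) |>
    dplyr::count(group)
  assert_that(all(n_per_group$n >= 2), "need at least 2 subjects per group")
  n_win <- dplyr::n_distinct(curves$window)
  complete <- curves |>
    dplyr::count(subject_id) |>
    dplyr::filter(n != n_win)
  assert_that(nrow(complete) == 0,
              "window grids differ between subjects")
  alpha_adj <- bonferroni_alpha(family_alpha, n_win)

  curves |>
    dplyr::group_by(window, t_start, t_end) |>
    dplyr::group_modify(function(d, key) {
      g1 <- d[d$group == groups[1], ]
      g2 <- d[d$group == groups[2], ]
      w1 <- t_paired(g1$acc_real, g1$acc_shuffled)
      w2 <- t_paired(g2$acc_real, g2$acc_shuffled)
      bt <- t_independent(g1$acc_real, g2$acc_real)
      tibble(
        t_within_1 = w1$t, p_within_1 = w1$p,
        t_within_2 = w2$t, p_within_2 = w2$p,
        t_between = bt$t, p_between = bt$p
      )
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      alpha_adj = alpha_adj,
      sig_within_1 = p_within_1 < alpha_adj,
      sig_within_2 = p_within_2 < alpha_adj,
      sig_between = p_between < alpha_adj
    )
}
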