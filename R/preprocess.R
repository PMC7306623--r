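#' Epoched EEG data
#'
#' An `epoch_set` holds a trials x channels x samples array cut around a lock
#' event, a time axis in ms (half-open window, time 0 = lock sample), the
#' per-epoch response-category labels, and a QC table marking epochs as kept
#' or rejected with a machine-readable reason. Units are microvolts before
#' the current source density transform and uV/m^2 after it.
#'
#' The preprocessing order is enforced: EOG regression on the continuous
#' recording ([regress_ocular()]), then epoching with baseline correction
#' ([extract_epochs()]), then amplitude-based artifact rejection
#' ([reject_artifacts()]), then [csd_transform()]. Calling a stage out of
#' order is an error.
#'
#' @name epoch_set
NULL

new_epoch_set <- function(data, times, lock, labels, qc, channels, srate,
                          baseline, units = "uV", csd_applied = FALSE,
                          artifact_checked = FALSE) {
  structure(
    list(data = data, times = times, lock = lock, labels = labels, qc = qc,
         channels = channels, srate = srate, baseline = baseline,
         units = units, csd_applied = csd_applied,
         artifact_checked = artifact_checked),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf(
    "<epoch_set: %d epochs x %d channels x %d samples, %s-locked [%g, %g) ms, %s, %d kept>\n",
    dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$lock,
    x$times[1], x$times[length(x$times)] + 1000 / x$srate, x$units,
    sum(x$qc$kept)))
  invisible(x)
}

kept_idx <- function(ep) which(ep$qc$kept)

#' Regress EOG activity out of scalp channels
#'
#' Replaces every scalp channel by its least-squares residual after
#' regression on all EOG channels (plus an intercept), with propagation
#' factors estimated over the whole recording. EOG channels are untouched.
#' This removes blink and eye-movement activity that propagates linearly to
#' the scalp.
#'
#' @param rec An [eeg_recording()].
#' @param eog_labels EOG channel labels to regress on; defaults to all
#'   channels of kind `"eog"`.
#' @return The corrected recording, flagged `ocular_corrected`.
#' @export
regress_ocular <- function(rec, eog_labels = NULL) {
  if (is.null(eog_labels)) {
    eog_labels <- rec$channels$label[rec$channels$kind == "eog"]
  }
  missing <- setdiff(eog_labels, rec$channels$label)
  assert_that(length(missing) == 0,
              paste0("EOG channel(s) not present: ",
                     paste(missing, collapse = ", ")))
  assert_that(length(eog_labels) >= 1, "need at least one EOG channel")

  eog <- t(rec$data[eog_labels, , drop = FALSE])
  X <- cbind(1, eog)
  # one QR factorisation, applied to all scalp channels at once
  qrX <- qr(X)
  scalp <- scalp_labels(rec)
  Y <- t(rec$data[scalp, , drop = FALSE])
  beta <- qr.coef(qrX, Y)
  beta[is.na(beta)] <- 0  # rank-deficient (e.g. silent) EOG columns
  resid <- Y - X %*% beta
  rec$data[scalp, ] <- t(resid)
  rec$meta$ocular_corrected <- TRUE
  rec
}

#' Cut epochs around stimulus or response events
#'
#' Cuts half-open windows `[t_min, t_max)` in ms around each trial's lock
#' event (stimulus onset, or stimulus onset plus first press for response
#' lock), subtracts the per-channel mean over the baseline window, and labels
#' each epoch with the trial's response category. Only scalp channels enter
#' the epochs (EOG is excluded from all downstream analyses). Epochs whose
#' window extends past the recording edge are flagged `rejected (edge)`
#' rather than dropped.
#'
#' @param rec An [eeg_recording()], already ocular-corrected if it contains
#'   EOG channels.
#' @param trials Trial table; classified with default rules if it has no
#'   `category` column.
#' @param lock `"stimulus"` or `"response"`.
#' @param window Half-open epoch window in ms, e.g. `c(-100, 800)`.
#' @param baseline Baseline window in ms, a subset of `[t_min, 0)`.
#' @return An [epoch_set].
#' @export
extract_epochs <- function(rec, trials, lock = c("stimulus", "response"),
                           window, baseline = c(-100, 0)) {
  lock <- match.arg(lock)
  if (any(rec$channels$kind == "eog") &&
      !isTRUE(rec$meta$ocular_corrected)) {
    abort("pipeline order: run regress_ocular() before extract_epochs()")
  }
  assert_that(length(window) == 2 && window[1] < window[2],
              "window must be an increasing pair")
  assert_that(baseline[1] >= window[1] && baseline[2] <= 0,
              "baseline must lie within [t_min, 0)")
  if (!"category" %in% names(trials)) trials <- classify_trials(trials)

  srate <- rec$srate
  dt <- 1000 / srate
  n_samp_ep <- round((window[2] - window[1]) / dt)
  assert_that(isTRUE(all.equal(n_samp_ep, (window[2] - window[1]) / dt)),
              "window length must be a whole number of samples")
  times <- window[1] + (seq_len(n_samp_ep) - 1) * dt

  use <- if (lock == "stimulus") rep(TRUE, nrow(trials)) else !is.na(trials$rt1)
  tr <- trials[use, ]
  lock_ms <- tr$stimulus_onset + if (lock == "response") tr$rt1 else 0
  lock_col <- ms_to_sample(lock_ms, srate) + 1L

  scalp <- scalp_labels(rec)
  dat <- array(0, dim = c(nrow(tr), length(scalp), n_samp_ep))
  kept <- rep(TRUE, nrow(tr))
  reason <- rep(NA_character_, nrow(tr))
  offsets <- round(times / dt)
  bl_cols <- which(times >= baseline[1] & times < baseline[2])
  scalp_dat <- rec$data[scalp, , drop = FALSE]

  for (i in seq_len(nrow(tr))) {
    cols <- lock_col[i] + offsets
    if (cols[1] < 1 || cols[length(cols)] > ncol(scalp_dat)) {
      kept[i] <- FALSE
      reason[i] <- "edge"
      ok <- cols >= 1 & cols <= ncol(scalp_dat)
      dat[i, , which(ok)] <- scalp_dat[, cols[ok]]
    } else {
      dat[i, , ] <- scalp_dat[, cols]
    }
    bl <- rowMeans(matrix(dat[i, , bl_cols], nrow = dim(dat)[2]))
    dat[i, , ] <- dat[i, , ] - bl
  }

  new_epoch_set(
    data = dat, times = times, lock = lock, labels = tr$category,
    qc = tibble(epoch = seq_len(nrow(tr)), trial = tr$trial,
                kept = kept, reason = reason),
    channels = tibble(label = scalp, kind = "scalp"),
    srate = srate, baseline = baseline
  )
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' Flags an epoch as `rejected (amplitude)` if any scalp-channel sample
#' strictly exceeds `+threshold` or falls strictly below `-threshold`
#' microvolts (samples touching the threshold exactly are kept). Kept epochs
#' are untouched. Must be applied to voltage data, before the CSD transform.
#'
#' @param ep An [epoch_set] in microvolts.
#' @param threshold Rejection threshold in microvolts.
#' @return The epoch set with updated QC flags, marked `artifact_checked`.
#' @export
reject_artifacts <- function(ep, threshold = 150) {
  if (ep$csd_applied) {
    abort("unit error: artifact rejection applies to voltage (pre-CSD) data")
  }
  for (i in seq_len(dim(ep$data)[1])) {
    if (!ep$qc$kept[i]) next
    x <- ep$data[i, , ]
    if (any(x > threshold) || any(x < -threshold)) {
      ep$qc$kept[i] <- FALSE
      ep$qc$reason[i] <- "amplitude"
    }
  }
  ep$artifact_checked <- TRUE
  ep
}
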