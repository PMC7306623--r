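#' Average kept epochs of one condition
#'
#' Pointwise mean over all kept epochs carrying the requested response
#' category label.
#'
#' @param ep An [epoch_set].
#' @param label Response category to average (e.g. `"detected_error"`), or a
#'   character vector of categories to collapse.
#' @return An `erp` object: channel x sample mean waveform with time axis,
#'   epoch count and condition label.
#' @export
condition_average <- function(ep, label) {
  idx <- intersect(kept_idx(ep), which(ep$labels %in% label))
  assert_that(length(idx) >= 1,
              paste0("no kept epochs with label ", paste(label, collapse = "/")))
  wave <- apply(ep$data[idx, , , drop = FALSE], c(2, 3), mean)
  rownames(wave) <- ep$channels$label
  structure(
    list(wave = wave, times = ep$times, n_epochs = length(idx),
         label = paste(label, collapse = "+"), units = ep$units,
         channels = ep$channels, srate = ep$srate),
    class = "erp"
  )
}

#' @export
print.erp <- function(x, ...) {
  cat(sprintf("<erp '%s': %d channels x %d samples, n = %d epochs, %s>\n",
              x$label, nrow(x$wave), ncol(x$wave), x$n_epochs, x$units))
  invisible(x)
}

erp_window_cols <- function(erp, window) {
  assert_that(window[1] >= erp$times[1] &&
                window[2] <= erp$times[length(erp$times)],
              "measurement window outside the epoch time axis")
  which(erp$times >= window[1] & erp$times <= window[2])
}

#' Peak amplitude and latency in a window
#'
#' Finds the most negative (or most positive) sample of the waveform at one
#' electrode inside the closed window and returns its amplitude and time.
#' Ties are broken towards the earliest sample. Latency resolution equals the
#' sampling step (2 ms at 500 Hz).
#'
#' @param erp An `erp` from [condition_average()].
#' @param electrode Channel label.
#' @param window Closed measurement window in ms, e.g. `c(0, 150)`.
#' @param polarity `"negative"` or `"positive"`.
#' @return A one-row tibble: `electrode`, `window_lo`, `window_hi`,
#'   `polarity`, `amplitude`, `latency`.
#' @export
peak_measure <- function(erp, electrode, window,
                         polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  assert_that(electrode %in% rownames(erp$wave),
              paste0("electrode not present: ", electrode))
  cols <- erp_window_cols(erp, window)
  v <- erp$wave[electrode, cols]
  j <- if (polarity == "negative") which.min(v) else which.max(v)
  tibble(electrode = electrode, window_lo = window[1], window_hi = window[2],
         polarity = polarity, amplitude = v[[j]],
         latency = erp$times[cols[j]])
}

#' Signed area under the curve in a window
#'
#' Trapezoidal integral of the signed waveform at one electrode over the
#' closed window, in (units x ms). No rectification is applied.
#'
#' @inheritParams peak_measure
#' @param per_ms Divide by the window length to report a mean amplitude.
#' @return The integral (scalar).
#' @export
area_under_curve <- function(erp, electrode, window, per_ms = FALSE) {
  assert_that(electrode %in% rownames(erp$wave),
              paste0("electrode not present: ", electrode))
  cols <- erp_window_cols(erp, window)
  v <- erp$wave[electrode, cols]
  t <- erp$times[cols]
  auc <- sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
  if (per_ms) auc / (t[length(t)] - t[1]) else auc
}

#' Peak-to-peak difference between a negative and a positive component
#'
#' Subtracts the negativity's peak amplitude and latency from the
#' positivity's (e.g. Pe minus Ne/ERN), yielding the build-up amplitude and
#' its duration.
#'
#' @param neg,pos One-row tibbles from [peak_measure()] with `"negative"` and
#'   `"positive"` polarity respectively.
#' @return A one-row tibble with `delta_amplitude` and `delta_latency`.
#' @export
peak_to_peak <- function(neg, pos) {
  assert_that(neg$polarity == "negative" && pos$polarity == "positive",
              "peak_to_peak() expects a negative and a positive measure")
  tibble(delta_amplitude = pos$amplitude - neg$amplitude,
         delta_latency = pos$latency - neg$latency)
}

#' Condition difference score
#'
#' Difference `a - b` of one field of two measures of the same component
#' family, e.g. the nogo-minus-go N2 amplitude or the error-minus-correct
#' Ne/ERN latency.
#'
#' @param a,b One-row tibbles from [peak_measure()].
#' @param field `"amplitude"` or `"latency"`.
#' @return The difference (scalar).
#' @export
delta_score <- function(a, b, field = c("amplitude", "latency")) {
  field <- match.arg(field)
  assert_that(a$polarity == b$polarity,
              "delta_score() expects measures of the same component family")
  a[[field]] - b[[field]]
}

#' Quantify all six standard components for one subject
#'
#' Convenience wrapper measuring N2 and P3 (stimulus-locked, FCz; correct go
#' vs correct withhold) and Ne/CRN (FCz) and Pe/Pc (Cz) (response-locked;
#' detected errors vs correct go) on condition averages, using the standard
#' windows: N2 200-350 ms, P3 350-500 ms, Ne/CRN 0-150 ms, Pe/Pc 150-300 ms.
#'
#' @param ep_stim Stimulus-locked [epoch_set] (may be `NULL` to skip).
#' @param ep_resp Response-locked [epoch_set] (may be `NULL` to skip).
#' @return A tibble with one row per component x condition: `component`,
#'   `condition`, `electrode`, `amplitude`, `latency`, `auc`, `n_epochs`.
#' @export
erp_measures <- function(ep_stim = NULL, ep_resp = NULL) {
  spec <- list(
    list("N2",  "stimulus", "correct_go",       "FCz", c(200, 350), "negative"),
    list("N2",  "stimulus", "correct_withhold", "FCz", c(200, 350), "negative"),
    list("P3",  "stimulus", "correct_go",       "FCz", c(350, 500), "positive"),
    list("P3",  "stimulus", "correct_withhold", "FCz", c(350, 500), "positive"),
    list("CRN", "response", "correct_go",       "FCz", c(0, 150),   "negative"),
    list("Ne",  "response", "detected_error",   "FCz", c(0, 150),   "negative"),
    list("Pc",  "response", "correct_go",       "Cz",  c(150, 300), "positive"),
    list("Pe",  "response", "detected_error",   "Cz",  c(150, 300), "positive")
  )
  purrr::map_dfr(spec, function(s) {
    ep <- if (s[[2]] == "stimulus") ep_stim else ep_resp
    if (is.null(ep)) return(tibble())
    if (!any(ep$labels %in% s[[3]] & ep$qc$kept)) return(tibble())
    avg <- condition_average(ep, s[[3]])
    pk <- peak_measure(avg, s[[4]], s[[5]], s[[6]])
    tibble(component = s[[1]], condition = s[[3]], electrode = s[[4]],
           amplitude = pk$amplitude, latency = pk$latency,
           auc = area_under_curve(avg, s[[4]], s[[5]]),
           n_epochs = avg$n_epochs)
  })
}
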