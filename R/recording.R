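#' Continuous multichannel EEG recordings
#'
#' An `eeg_recording` bundles a channels-by-samples data matrix in microvolts
#' with channel metadata, event markers and free-form provenance. Event sample
#' indices are 0-based and must lie inside the recording.
#'
#' @param data Numeric matrix, channels x samples, in microvolts.
#' @param channels Tibble with columns `label` (unique) and `kind`
#'   (`"scalp"` or `"eog"`), one row per data row.
#' @param srate Sampling rate in Hz (positive scalar).
#' @param events Tibble with columns `sample` (0-based integer index) and
#'   `code` (character marker code). May have zero rows.
#' @param meta Named list of provenance values.
#' @return An `eeg_recording` object.
#' @export
eeg_recording <- function(data, channels, srate, events = NULL, meta = list()) {
  assert_that(is.matrix(data), "data must be a channels x samples matrix")
  channels <- as_tibble(channels)
  assert_that(all(c("label", "kind") %in% names(channels)),
              "channels needs columns label and kind")
  assert_that(nrow(channels) == nrow(data),
              "channels table must have one row per data row")
  assert_that(!anyDuplicated(channels$label), "channel labels must be unique")
  assert_that(all(channels$kind %in% c("scalp", "eog")),
              "channel kind must be 'scalp' or 'eog'")
  assert_that(is.numeric(srate) && length(srate) == 1 && srate > 0,
              "srate must be a positive scalar")
  if (is.null(events)) events <- tibble(sample = integer(), code = character())
  events <- as_tibble(events)
  assert_that(all(c("sample", "code") %in% names(events)),
              "events needs columns sample and code")
  if (nrow(events)) {
    assert_that(all(events$sample >= 0 & events$sample < ncol(data)),
                "event sample indices must lie in [0, n_samples)")
  }
  rownames(data) <- channels$label
  structure(
    list(data = data, channels = channels, srate = srate,
         events = events, meta = meta),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording: %d channels (%d scalp, %d EOG) x %d samples @ %g Hz, %d events>\n",
    nrow(x$data), sum(x$channels$kind == "scalp"),
    sum(x$channels$kind == "eog"), ncol(x$data), x$srate, nrow(x$events)))
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)

scalp_labels <- function(rec) rec$channels$label[rec$channels$kind == "scalp"]
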