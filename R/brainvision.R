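# BrainVision Core format: a .vhdr INI header naming a .vmrk marker file and
# a .eeg binary. Supported binary dialects: MULTIPLEXED little-endian INT_16
# (with per-channel resolution) and IEEE_FLOAT_32. VECTORIZED orientation and
# other binary formats raise an unsupported-dialect error rather than being
# misread.

parse_ini <- function(lines) {
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      current <- gsub("^\\[|\\]$", "", ln)
      sections[[current]] <- character()
    } else if (!is.null(current) && grepl("=", ln, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      sections[[current]][key] <- val
    }
  }
  sections
}

#' Read a BrainVision recording
#'
#' Reads the `.vhdr`/`.vmrk`/`.eeg` triplet starting from the header file and
#' returns an [eeg_recording()] with data in microvolts (INT_16 samples are
#' multiplied by their per-channel resolution) and all markers parsed to
#' events with 0-based sample indices.
#'
#' @param header_path Path to the `.vhdr` header file.
#' @param eog_labels Channel labels to mark as EOG; all others are scalp.
#' @return An `eeg_recording`.
#' @export
read_brainvision <- function(header_path,
                             eog_labels = c("VEOGa", "VEOGb", "HEOGl", "HEOGr")) {
  assert_that(file.exists(header_path),
              paste0("header file not found: ", header_path))
  hdr <- parse_ini(readLines(header_path, warn = FALSE))
  ci <- hdr[["Common Infos"]]
  bi <- hdr[["Binary Infos"]]
  chi <- hdr[["Channel Infos"]]
  assert_that(!is.null(ci), "header lacks a [Common Infos] section")

  dir <- dirname(header_path)
  data_path <- file.path(dir, ci[["DataFile"]])
  marker_path <- file.path(dir, ci[["MarkerFile"]])
  assert_that(file.exists(data_path),
              paste0("data file named by header not found: ", data_path))
  assert_that(file.exists(marker_path),
              paste0("marker file named by header not found: ", marker_path))

  orientation <- toupper(ci[["DataOrientation"]] %||% "MULTIPLEXED")
  if (orientation != "MULTIPLEXED") {
    abort(paste0("unsupported data orientation: ", orientation))
  }
  fmt <- toupper(bi[["BinaryFormat"]] %||% "")
  if (!fmt %in% c("INT_16", "IEEE_FLOAT_32")) {
    abort(paste0("unsupported binary format: ", fmt))
  }

  n_chan <- as.integer(ci[["NumberOfChannels"]])
  srate <- 1e6 / as.numeric(ci[["SamplingInterval"]])  # interval is in us

  ch <- map(chi[order(as.integer(sub("^Ch", "", names(chi))))], function(v) {
    strsplit(v, ",", fixed = TRUE)[[1]]
  })
  labels <- vapply(ch, function(p) gsub("\\\\1", ",", p[1]), character(1))
  resolution <- vapply(ch, function(p) {
    r <- if (length(p) >= 3) p[3] else ""
    if (is.na(r) || r == "") 1 else as.numeric(r)
  }, numeric(1))
  assert_that(length(labels) == n_chan,
              "channel info count disagrees with NumberOfChannels")

  raw_n <- file.size(data_path)
  if (fmt == "INT_16") {
    vals <- readBin(data_path, "integer", n = raw_n / 2, size = 2,
                    endian = "little")
  } else {
    vals <- readBin(data_path, "double", n = raw_n / 4, size = 4,
                    endian = "little")
  }
  n_samp <- length(vals) %/% n_chan
  dat <- matrix(vals[seq_len(n_chan * n_samp)], nrow = n_chan)
  dat <- dat * resolution

  mrk <- parse_ini(readLines(marker_path, warn = FALSE))
  mk <- mrk[["Marker Infos"]] %||% character()
  ev <- purrr::map_dfr(unname(mk), function(v) {
    p <- strsplit(v, ",", fixed = TRUE)[[1]]
    tibble(type = p[1],
           code = if (length(p) >= 2) gsub("\\\\1", ",", p[2]) else "",
           sample = as.integer(p[3]) - 1L)
  })
  if (nrow(ev)) ev <- ev[ev$type != "New Segment", c("sample", "code")]
  else ev <- tibble(sample = integer(), code = character())

  eeg_recording(
    data = dat,
    channels = tibble(label = labels,
                      kind = ifelse(labels %in% eog_labels, "eog", "scalp")),
    srate = srate,
    events = ev,
    meta = list(source = header_path, binary_format = fmt)
  )
}

#' Write a recording as a BrainVision triplet
#'
#' Writes `<stem>.vhdr`, `<stem>.vmrk` and `<stem>.eeg` readable by
#' [read_brainvision()]. Events (sample indices and codes) are preserved
#' exactly; data are preserved within the resolution quantisation for
#' `"INT_16"` and within float32 precision for `"IEEE_FLOAT_32"`.
#'
#' @param rec An [eeg_recording()].
#' @param stem Output path without extension.
#' @param binary_format `"IEEE_FLOAT_32"` (default) or `"INT_16"`.
#' @param resolution Per-channel scaling in microvolts per integer unit,
#'   recycled across channels (INT_16 only).
#' @return The header path, invisibly.
#' @export
write_brainvision <- function(rec, stem, binary_format = "IEEE_FLOAT_32",
                              resolution = 0.1) {
  assert_that(binary_format %in% c("INT_16", "IEEE_FLOAT_32"),
              paste0("unsupported binary format: ", binary_format))
  dir <- dirname(stem)
  assert_that(dir.exists(dir), paste0("output directory does not exist: ", dir))
  base <- basename(stem)
  n_chan <- nrow(rec$data)
  resolution <- rep_len(resolution, n_chan)

  hdr <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    paste0("MarkerFile=", base, ".vmrk"),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", n_chan),
    paste0("SamplingInterval=", format(1e6 / rec$srate, scientific = FALSE)),
    "",
    "[Binary Infos]",
    paste0("BinaryFormat=", binary_format),
    "",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,%s,µV", seq_len(n_chan),
            gsub(",", "\\\\1", rec$channels$label),
            if (binary_format == "INT_16") format(resolution) else "")
  )
  writeLines(hdr, paste0(stem, ".vhdr"))

  mrk <- c(
    "Brain Vision Data Exchange Marker File, Version 1.0",
    "",
    "[Common Infos]",
    "Codepage=UTF-8",
    paste0("DataFile=", base, ".eeg"),
    "",
    "[Marker Infos]",
    paste0("Mk1=New Segment,,1,1,0")
  )
  if (nrow(rec$events)) {
    type <- ifelse(startsWith(rec$events$code, "R"), "Response", "Stimulus")
    mrk <- c(mrk, sprintf("Mk%d=%s,%s,%d,1,0",
                          seq_len(nrow(rec$events)) + 1L, type,
                          gsub(",", "\\\\1", rec$events$code),
                          rec$events$sample + 1L))
  }
  writeLines(mrk, paste0(stem, ".vmrk"))

  con <- file(paste0(stem, ".eeg"), "wb")
  on.exit(close(con))
  if (binary_format == "INT_16") {
    q <- round(rec$data / resolution)
    assert_that(all(abs(q) <= 32767),
                "data exceed INT_16 range at the chosen resolution")
    writeBin(as.integer(q), con, size = 2, endian = "little")
  } else {
    writeBin(as.vector(rec$data), con, size = 4, endian = "little")
  }
  invisible(paste0(stem, ".vhdr"))
}
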