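# Flat key-value serialisation of the run configuration. Nested parameter
# objects are flattened with dotted keys (csd.m, noise.rms, ...); vectors are
# comma-separated. Group profiles and the montage are structural R objects
# and are carried by their own formats, not by this file.

config_scalar_keys <- c(
  "n_patients", "n_controls", "n_trials", "threshold_uv", "decode_on_csd",
  "folds", "repeats", "C", "family_alpha", "correlation_alpha",
  "min_erp", "min_mvpa"
)
config_vector_keys <- c("stim_window", "resp_window", "decode_window",
                        "baseline", "stages")
config_csd_keys <- c("m", "legendre_terms", "lambda", "head_radius")
config_noise_keys <- c("alpha", "rms", "blink_rate", "blink_amplitude",
                       "blink_prop", "line_amplitude")

#' Read and write run configurations as flat key-value files
#'
#' One `key=value` pair per line; vector values are comma-separated and
#' nested parameters use dotted keys (`csd.lambda`, `noise.rms`).
#' `read_run_config()` starts from `base` and overrides every key present in
#' the file, so a config file only needs to name what it changes.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) paste(format(v, scientific = FALSE, trim = TRUE),
                           collapse = ",")
  lines <- c(
    vapply(config_scalar_keys, function(k) paste0(k, "=", fmt(config[[k]])),
           character(1)),
    vapply(config_vector_keys, function(k) paste0(k, "=", fmt(config[[k]])),
           character(1)),
    vapply(config_csd_keys, function(k) {
      paste0("csd.", k, "=", fmt(config$csd[[k]]))
    }, character(1)),
    vapply(config_noise_keys, function(k) {
      paste0("noise.", k, "=", fmt(config$noise[[k]]))
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @param base Configuration supplying every key the file does not set.
#' @export
read_run_config <- function(path, base = run_config()) {
  assert_that(file.exists(path), paste0("config file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- base
  for (pair in kv) {
    assert_that(length(pair) == 2,
                paste0("malformed config line: ", paste(pair, collapse = "=")))
    key <- trimws(pair[1])
    raw <- strsplit(trimws(pair[2]), ",", fixed = TRUE)[[1]]
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      val <- if (all(raw %in% c("TRUE", "FALSE"))) as.logical(raw) else raw
    }
    if (key %in% c(config_scalar_keys, config_vector_keys)) {
      cfg[[key]] <- val
    } else if (startsWith(key, "csd.")) {
      cfg$csd[[sub("^csd\\.", "", key)]] <- val
    } else if (startsWith(key, "noise.")) {
      cfg$noise[[sub("^noise\\.", "", key)]] <- val
    } else {
      abort(paste0("unknown config key: ", key))
    }
  }
  cfg$csd <- do.call(csd_params, cfg$csd[config_csd_keys])
  cfg$noise <- do.call(noise_spec, cfg$noise[config_noise_keys])
  cfg
}
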