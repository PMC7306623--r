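# TSV tables: per-trial behavioral records and per-subject metadata.
# Missing values are written as empty cells.

trial_cols <- readr::cols(
  trial = readr::col_integer(),
  block = readr::col_integer(),
  stimulus_kind = readr::col_character(),
  color_id = readr::col_integer(),
  stimulus_onset = readr::col_double(),
  rt1 = readr::col_double(),
  rt2 = readr::col_double(),
  .default = readr::col_character()
)

#' Read and write trial tables
#'
#' A trial table has one row per trial with 0-based `trial` index, `block`
#' (0-5), `stimulus_kind` (`"go"`/`"nogo"`), `color_id` (0-7, exactly one
#' colour designated nogo), `stimulus_onset` in ms from recording start, and
#' press latencies `rt1`/`rt2` in ms from stimulus onset (`NA` when absent).
#' A derived `category` column may be present (see [classify_trials()]).
#'
#' @param path File path.
#' @return `read_trial_table()` returns a tibble; `write_trial_table()`
#'   returns `path` invisibly.
#' @export
read_trial_table <- function(path) {
  tab <- readr::read_tsv(path, col_types = trial_cols, progress = FALSE)
  validate_trial_table(tab)
  tab
}

#' @rdname read_trial_table
#' @param trials A trial table tibble.
#' @export
write_trial_table <- function(trials, path) {
  readr::write_tsv(trials, path, na = "", progress = FALSE)
  invisible(path)
}

validate_trial_table <- function(trials) {
  assert_that(all(c("trial", "block", "stimulus_kind", "color_id",
                    "stimulus_onset", "rt1", "rt2") %in% names(trials)),
              "trial table is missing required columns")
  assert_that(all(diff(trials$stimulus_onset) > 0),
              "trial onsets must be strictly increasing")
  assert_that(all(trials$stimulus_kind %in% c("go", "nogo")),
              "stimulus_kind must be 'go' or 'nogo'")
  if (any(!is.na(trials$rt2) & is.na(trials$rt1))) {
    abort("data-integrity error: rt2 present without rt1")
  }
  nogo_colors <- unique(trials$color_id[trials$stimulus_kind == "nogo"])
  assert_that(length(nogo_colors) <= 1,
              "exactly one color_id may be designated nogo")
  invisible(trials)
}

#' Read and write subject metadata tables
#'
#' One row per subject: `subject_id`, `group` (`"patient"`/`"control"`),
#' `lesion_size` in cm^3 (`NA` for controls), `days_post_stroke` (`NA` for
#' controls). The derived `phase` column is recomputed on read via
#' [classify_phase()].
#'
#' @param path File path.
#' @return A tibble with a `phase` column.
#' @export
read_subject_meta <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    lesion_size = readr::col_double(),
    days_post_stroke = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  assert_that(all(tab$group %in% c("patient", "control")),
              "group must be 'patient' or 'control'")
  tab$phase <- vapply(tab$days_post_stroke, function(d) {
    if (is.na(d)) NA_character_ else classify_phase(d)
  }, character(1))
  tab
}

#' @rdname read_subject_meta
#' @param meta A subject metadata tibble.
#' @export
write_subject_meta <- function(meta, path) {
  readr::write_tsv(meta, path, na = "", progress = FALSE)
  invisible(path)
}

#' Classify stroke phase from days post-stroke
#'
#' Patients recruited 4-28 days after their stroke are classified as
#' sub-acute, later than 28 days as chronic. Recruitment starts more than
#' four days post-stroke, so smaller values are a validation error.
#'
#' @param days_post_stroke Days since the stroke (scalar or vector, >= 4).
#' @return `"subacute"` or `"chronic"`.
#' @export
classify_phase <- function(days_post_stroke) {
  assert_that(all(is.finite(days_post_stroke) & days_post_stroke >= 4),
              "days_post_stroke must be >= 4 (recruitment window)")
  ifelse(days_post_stroke <= 28, "subacute", "chronic")
}
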