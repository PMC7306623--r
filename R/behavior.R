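#' Classify trials into response categories
#'
#' Assigns exactly one category per trial: `correct_go` (go with a single
#' press), `miss_go` (go without a press), `incorrect_go` (go with a press
#' and a second, error-signaling press inside the signaling window),
#' `correct_withhold` (nogo without a press), `detected_error` (nogo press
#' signaled by a second press inside the window) or `undetected_error`
#' (nogo press without a valid second press). Second presses outside the
#' signaling window are ignored, i.e. such errors count as undetected.
#'
#' @param trials A trial table with raw press latencies.
#' @param signaling_window Window (ms from stimulus onset) in which the
#'   second press counts as error signaling.
#' @return The trial table with a `category` column.
#' @export
classify_trials <- function(trials, signaling_window = c(1200, 2000)) {
  validate_trial_table(trials)
  has1 <- !is.na(trials$rt1)
  has2 <- !is.na(trials$rt2) &
    trials$rt2 >= signaling_window[1] & trials$rt2 <= signaling_window[2]
  go <- trials$stimulus_kind == "go"
  trials$category <- dplyr::case_when(
    go & !has1 ~ "miss_go",
    go & has1 & has2 ~ "incorrect_go",
    go & has1 ~ "correct_go",
    !go & !has1 ~ "correct_withhold",
    !go & has1 & has2 ~ "detected_error",
    !go & has1 ~ "undetected_error"
  )
  trials
}

response_categories <- c("correct_go", "miss_go", "incorrect_go",
                         "correct_withhold", "detected_error",
                         "undetected_error")

#' Summarise a classified session
#'
#' Computes, per stimulus type, the relative rate (percent) of every response
#' category, the error detection rate (detected errors as a percentage of all
#' nogo errors), median RTs for correct go responses and detected errors, and
#' the post-error slowing contrast ([delta_pes()]). Undefined quantities
#' (e.g. the detection rate of a session without errors) are `NA`, never zero.
#'
#' @param trials A classified trial table.
#' @return A one-row tibble.
#' @export
summarize_behavior <- function(trials) {
  if (!"category" %in% names(trials)) abort("classify_trials() first")
  n_go <- sum(trials$stimulus_kind == "go")
  n_nogo <- sum(trials$stimulus_kind == "nogo")
  assert_that(n_nogo > 0, "session has zero nogo trials")
  counts <- table(factor(trials$category, levels = response_categories))
  n_det <- counts[["detected_error"]]
  n_und <- counts[["undetected_error"]]
  rt_med <- function(cat) {
    v <- trials$rt1[trials$category == cat]
    if (length(v)) median(v) else NA_real_
  }
  tibble(
    n_go = n_go, n_nogo = n_nogo,
    correct_go_rate = 100 * counts[["correct_go"]] / n_go,
    miss_go_rate = 100 * counts[["miss_go"]] / n_go,
    incorrect_go_rate = 100 * counts[["incorrect_go"]] / n_go,
    correct_withhold_rate = 100 * counts[["correct_withhold"]] / n_nogo,
    detected_error_rate = 100 * n_det / n_nogo,
    undetected_error_rate = 100 * n_und / n_nogo,
    nogo_error_rate = 100 * (n_det + n_und) / n_nogo,
    error_detection_rate = if (n_det + n_und > 0) {
      100 * n_det / (n_det + n_und)
    } else {
      NA_real_
    },
    baseline_rt = rt_med("correct_go"),
    error_rt = rt_med("detected_error"),
    delta_pes = delta_pes(trials)
  )
}

#' Post-error slowing contrast
#'
#' PES is the median RT of correct go trials whose immediately preceding
#' trial (within the same block) was a detected error; PCS is the median RT
#' of correct go trials whose preceding trial was a correct go. The contrast
#' is `PES - PCS` in ms. Trials following misses, undetected errors or
#' incorrect go trials enter neither term, and pairs crossing a block
#' boundary are excluded. With no qualifying pair on either side the result
#' is `NA`.
#'
#' @param trials A classified trial table.
#' @return Post-error slowing minus post-correct slowing, ms.
#' @export
delta_pes <- function(trials) {
  if (!"category" %in% names(trials)) abort("classify_trials() first")
  n <- nrow(trials)
  if (n < 2) return(NA_real_)
  cur <- trials$category[-1]
  prev <- trials$category[-n]
  same_block <- trials$block[-1] == trials$block[-n]
  rt <- trials$rt1[-1]
  post_err <- rt[cur == "correct_go" & prev == "detected_error" & same_block]
  post_cor <- rt[cur == "correct_go" & prev == "correct_go" & same_block]
  if (!length(post_err) || !length(post_cor)) return(NA_real_)
  median(post_err) - median(post_cor)
}

#' Trial-count inclusion criteria
#'
#' For ERP analyses a subject is included if every analysed response type
#' (correct go responses and detected errors) has at least `min_erp` trials;
#' for decoding, if the collapsed error count (detected plus undetected) is
#' at least `min_mvpa`.
#'
#' @param trials A classified trial table (or a named vector of category
#'   counts).
#' @param purpose `"erp"` or `"mvpa"`.
#' @param min_erp,min_mvpa Minimum trial counts.
#' @return A one-row tibble with `include` (logical) and `reason`.
#' @export
check_inclusion <- function(trials, purpose = c("erp", "mvpa"),
                            min_erp = 6, min_mvpa = 10) {
  purpose <- match.arg(purpose)
  counts <- if (is.data.frame(trials)) {
    table(factor(trials$category, levels = response_categories))
  } else {
    trials
  }
  cnt <- function(cat) if (cat %in% names(counts)) as.numeric(counts[[cat]]) else 0
  if (purpose == "erp") {
    fails <- character()
    if (cnt("correct_go") < min_erp) {
      fails <- c(fails, sprintf("correct_go<%d", min_erp))
    }
    if (cnt("detected_error") < min_erp) {
      fails <- c(fails, sprintf("detected_error<%d", min_erp))
    }
    tibble(purpose = purpose, include = length(fails) == 0,
           reason = if (length(fails)) paste(fails, collapse = ";") else NA_character_)
  } else {
    n_err <- cnt("detected_error") + cnt("undetected_error")
    tibble(purpose = purpose, include = n_err >= min_mvpa,
           reason = if (n_err >= min_mvpa) NA_character_ else {
             sprintf("collapsed_errors<%d", min_mvpa)
           })
  }
}
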