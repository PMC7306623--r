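#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an ERP into a long tibble
#'
#' @param x An `erp` object.
#' @param ... Unused.
#' @return A tibble with `channel`, `time`, `amplitude`, `condition`.
#' @method tidy erp
#' @export
tidy.erp <- function(x, ...) {
  tibble(
    channel = rep(rownames(x$wave), times = ncol(x$wave)),
    time = rep(x$times, each = nrow(x$wave)),
    amplitude = as.vector(x$wave),
    condition = x$label
  )
}

#' Tidy a linear SVM into per-feature weights
#'
#' @param x A `linear_svm` object.
#' @param ... Unused.
#' @return A tibble with `term` (feature index), `estimate`, plus the bias
#'   as term `"(bias)"`.
#' @method tidy linear_svm
#' @export
tidy.linear_svm <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = paste0("x", seq_along(x$w)), estimate = x$w),
    tibble(term = "(bias)", estimate = x$b)
  )
}

#' One-row summary of a cohort report
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return A one-row tibble with subject counts and inclusion tallies.
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tibble(
    n_subjects = nrow(x$subjects),
    n_patients = sum(x$subjects$group == "patient"),
    n_controls = sum(x$subjects$group == "control"),
    n_erp_included = if (is.null(x$inclusion)) NA_integer_ else {
      sum(x$inclusion$include[x$inclusion$purpose == "erp"])
    },
    n_mvpa_included = if (is.null(x$inclusion)) NA_integer_ else {
      sum(x$inclusion$include[x$inclusion$purpose == "mvpa"])
    },
    seed = x$seed
  )
}
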