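#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_dbl map_int map2 pmap imap
#' @importFrom stats median pt pf qt rnorm runif rlnorm rbinom integrate
#'   lm coef cor aov fft setNames sd var quantile
#' @importFrom utils head tail
NULL

# Run `code` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed and a stream label, staying inside
# the 32-bit integer range R requires for set.seed().
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  codes <- utf8ToInt(key)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 2147483647L
  as.integer(h)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == round(x)

is_prob <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1

ms_to_sample <- function(ms, srate) as.integer(round(ms * srate / 1000))
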