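#' Behavioral agent parameters
#'
#' Parameters of the stochastic agent used to generate Go/Nogo sessions.
#' Reaction times follow a shifted lognormal,
#' `rt = rt_shift + exp(Normal(rt_location, rt_scale))` ms; nogo errors use
#' the same draw plus the (negative) `error_rt_shift`, reproducing the
#' error-faster-than-correct ordering. The go trial immediately following a
#' nogo error gets `pes_increment` ms added to its draw, which is what the
#' one-trial-back post-error slowing contrast recovers. Second (signaling)
#' presses on detected errors fall uniformly inside `rt2_window`.
#'
#' The defaults encode the task-level calibration: a ~20% nogo error rate by
#' design, a ~78% detection rate, a ~416 ms median correct-go RT, errors
#' ~66 ms faster, and ~86 ms of post-error slowing.
#'
#' @param p_nogo_error Probability of a button press on a nogo trial.
#' @param p_detect Probability that an error is signaled by a second press.
#' @param p_miss_go Probability of missing a go trial.
#' @param rt_location,rt_scale Meanlog/sdlog of the lognormal RT part.
#' @param rt_shift Additive RT shift in ms.
#' @param error_rt_shift Added to error-trial RTs (negative = faster errors).
#' @param pes_increment Added to the go RT draw immediately after an error.
#' @param rt2_window Allowed window (ms from stimulus onset) for the second
#'   press.
#' @return A list of class `agent_params`.
#' @export
agent_params <- function(p_nogo_error = 0.20,
                         p_detect = 0.78,
                         p_miss_go = 0.045,
                         rt_location = log(266),
                         rt_scale = 0.28,
                         rt_shift = 150,
                         error_rt_shift = -66,
                         pes_increment = 86,
                         rt2_window = c(1200, 2000)) {
  assert_that(is_prob(p_nogo_error) && is_prob(p_detect) && is_prob(p_miss_go),
              "probabilities must lie in [0, 1]")
  assert_that(rt_scale > 0, "rt_scale must be positive")
  assert_that(length(rt2_window) == 2 && rt2_window[1] < rt2_window[2],
              "rt2_window must be an increasing pair")
  structure(
    list(p_nogo_error = p_nogo_error, p_detect = p_detect,
         p_miss_go = p_miss_go, rt_location = rt_location,
         rt_scale = rt_scale, rt_shift = rt_shift,
         error_rt_shift = error_rt_shift, pes_increment = pes_increment,
         rt2_window = rt2_window),
    class = "agent_params"
  )
}

#' Simulate one Go/Nogo behavioral session
#'
#' Generates a trial table for a session of `n_trials` trials in six equal
#' blocks with `round(nogo_fraction * n_trials)` nogo trials randomly
#' interleaved. Each trial lasts 2000 ms with a uniform 600-1000 ms
#' inter-trial interval. Go trials receive a first press unless missed; nogo
#' trials receive an erroneous press with probability `p_nogo_error`, which
#' is then signaled by a second press inside `rt2_window` with probability
#' `p_detect`. Same seed, same table.
#'
#' @param params An [agent_params()] object.
#' @param n_trials Number of trials (divisible by the number of blocks).
#' @param nogo_fraction Proportion of nogo trials, in (0, 1).
#' @param seed Integer seed; the session is a pure function of it.
#' @param n_blocks Number of blocks.
#' @return A trial-table tibble (see [read_trial_table()]).
#' @export
simulate_behavior <- function(params = agent_params(), n_trials = 360,
                              nogo_fraction = 0.2, seed = 1, n_blocks = 6) {
  assert_that(inherits(params, "agent_params"), "params must be agent_params()")
  assert_that(nogo_fraction > 0 && nogo_fraction < 1,
              "nogo_fraction must lie strictly inside (0, 1)")
  assert_that(is_count(n_trials) && n_trials %% n_blocks == 0,
              "n_trials must be divisible by the block count")
  with_seed(seed, {
    n_nogo <- round(nogo_fraction * n_trials)
    kind <- rep("go", n_trials)
    kind[sample.int(n_trials, n_nogo)] <- "nogo"
    color <- ifelse(kind == "nogo", 0L,
                    sample(1:7, n_trials, replace = TRUE))
    iti <- runif(n_trials, 600, 1000)
    onset <- 1000 + cumsum(c(0, (2000 + iti)[-n_trials]))

    rt1 <- rep(NA_real_, n_trials)
    rt2 <- rep(NA_real_, n_trials)
    prev_error <- FALSE
    for (i in seq_len(n_trials)) {
      draw <- params$rt_shift + rlnorm(1, params$rt_location, params$rt_scale)
      if (kind[i] == "go") {
        if (runif(1) >= params$p_miss_go) {
          rt1[i] <- draw + if (prev_error) params$pes_increment else 0
        }
        prev_error <- FALSE
      } else {
        if (runif(1) < params$p_nogo_error) {
          rt1[i] <- draw + params$error_rt_shift
          if (runif(1) < params$p_detect) {
            rt2[i] <- runif(1, params$rt2_window[1], params$rt2_window[2])
          }
          prev_error <- TRUE
        } else {
          prev_error <- FALSE
        }
      }
    }
    tibble(
      trial = seq_len(n_trials) - 1L,
      block = as.integer((seq_len(n_trials) - 1L) %/% (n_trials / n_blocks)),
      stimulus_kind = kind,
      color_id = as.integer(color),
      stimulus_onset = round(onset),
      rt1 = round(rt1),
      rt2 = round(rt2)
    )
  })
}
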