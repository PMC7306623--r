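times_resp <- seq(-100, 598, by = 2)

test_that("condition averages are pointwise means over kept epochs", {
  set.seed(4)
  w1 <- matrix(rnorm(2 * length(times_resp)), 2)
  w2 <- matrix(rnorm(2 * length(times_resp)), 2)
  ep <- manual_epochs(list(w1, w2, -w1), times_resp,
                      labels = c("detected_error", "correct_go",
                                 "detected_error"))
  avg <- condition_average(ep, "detected_error")
  expect_equal(avg$wave, (w1 - w1) / 2, ignore_attr = TRUE)
  expect_equal(avg$n_epochs, 2)
  one <- condition_average(ep, "correct_go")
  expect_equal(one$wave, w2, ignore_attr = TRUE)  # single epoch identity
  # rejected epochs never enter the average
  ep$qc$kept[3] <- FALSE
  avg2 <- condition_average(ep, "detected_error")
  expect_equal(avg2$wave, w1, ignore_attr = TRUE)
  expect_error(condition_average(ep, "miss_go"), "no kept epochs")
})

test_that("peak measures find the windowed extremum with earliest-tie rule", {
  w <- matrix(0, 2, length(times_resp))
  w[1, times_resp == 60] <- -25
  ep <- manual_epochs(list(w), times_resp, labels = "detected_error")
  avg <- condition_average(ep, "detected_error")
  pk <- peak_measure(avg, "FCz", c(0, 150), "negative")
  expect_equal(pk$amplitude, -25)
  expect_equal(pk$latency, 60)
  # two equal minima -> earliest wins
  w2 <- w
  w2[1, times_resp == 40] <- -25
  w2[1, times_resp == 90] <- -25
  w2[1, times_resp == 60] <- 0
  ep2 <- manual_epochs(list(w2), times_resp, labels = "detected_error")
  pk2 <- peak_measure(condition_average(ep2, "detected_error"),
                      "FCz", c(0, 150), "negative")
  expect_equal(pk2$latency, 40)
  # polarity antisymmetry: peak(-x, positive) = -peak(x, negative), same time
  ep3 <- manual_epochs(list(-w), times_resp, labels = "detected_error")
  pk3 <- peak_measure(condition_average(ep3, "detected_error"),
                      "FCz", c(0, 150), "positive")
  expect_equal(pk3$amplitude, -pk$amplitude)
  expect_equal(pk3$latency, pk$latency)
  expect_error(peak_measure(avg, "FCz", c(500, 700), "negative"), "window")
  expect_error(peak_measure(avg, "Pz", c(0, 150), "negative"), "not present")
})

test_that("area under the curve integrates the signed waveform", {
  zero <- matrix(0, 2, length(times_resp))
  epz <- manual_epochs(list(zero), times_resp, labels = "x")
  avgz <- condition_average(epz, "x")
  expect_equal(area_under_curve(avgz, "FCz", c(0, 150)), 0)

  const <- zero
  const[1, ] <- 2
  epc <- manual_epochs(list(const), times_resp, labels = "x")
  expect_equal(area_under_curve(condition_average(epc, "x"), "FCz", c(0, 150)),
               300)  # 2 uV/m^2 x 150 ms
  expect_equal(area_under_curve(condition_average(epc, "x"), "FCz", c(0, 150),
                                per_ms = TRUE), 2)

  # half-sine of amplitude A and width W integrates to 2*A*W/pi
  A <- 30
  W <- 100
  hs <- zero
  idx <- times_resp >= 100 & times_resp <= 200
  hs[1, idx] <- A * sin(pi * (times_resp[idx] - 100) / W)
  eph <- manual_epochs(list(hs), times_resp, labels = "x")
  auc <- area_under_curve(condition_average(eph, "x"), "FCz", c(100, 200))
  expect_equal(auc, 2 * A * W / pi, tolerance = 0.005)

  # linearity in the waveform
  lin <- manual_epochs(list(2 * hs + 3 * const), times_resp, labels = "x")
  expect_equal(
    area_under_curve(condition_average(lin, "x"), "FCz", c(100, 200)),
    2 * auc + 3 * area_under_curve(condition_average(epc, "x"), "FCz",
                                   c(100, 200)),
    tolerance = 1e-9
  )
})

test_that("peak-to-peak and difference scores are plain subtractions", {
  ne <- tibble::tibble(electrode = "FCz", window_lo = 0, window_hi = 150,
                       polarity = "negative", amplitude = -20, latency = 50)
  pe <- tibble::tibble(electrode = "Cz", window_lo = 150, window_hi = 300,
                       polarity = "positive", amplitude = 40, latency = 220)
  pp <- peak_to_peak(ne, pe)
  expect_equal(pp$delta_amplitude, 60)
  expect_equal(pp$delta_latency, 170)
  same <- peak_to_peak(ne, dplyr::mutate(ne, polarity = "positive"))
  expect_equal(same$delta_amplitude, 0)
  expect_equal(same$delta_latency, 0)
  expect_error(peak_to_peak(pe, ne), "negative and a positive")

  expect_equal(delta_score(ne, dplyr::mutate(ne, amplitude = -5)), -15)
  expect_equal(delta_score(ne, ne, "latency"), 0)
  expect_error(delta_score(ne, pe), "same component family")
})

test_that("noise-free pipeline recovers every embedded component exactly", {
  mont <- montage_61()
  params <- agent_params(p_nogo_error = 0.4, p_detect = 0.9, p_miss_go = 0.05)
  tr <- classify_trials(simulate_behavior(params, seed = 9, n_trials = 60))
  quiet <- noise_spec(rms = 0, blink_rate = 0)

  # grid-aligned latencies; stimulus- and response-locked sets synthesised
  # separately so cross-lock overlap cannot blur the identity
  resp <- list(
    component_spec("Ne", "response", "error", 50, -27.7, 60, "FCz"),
    component_spec("CRN", "response", "correct", 36, -11.8, 60, "FCz"),
    component_spec("Pe", "response", "error", 218, 39.5, 150, "Cz"),
    component_spec("Pc", "response", "correct", 218, 20.3, 150, "Cz")
  )
  rec <- regress_ocular(synthesize_recording(tr, mont, resp, quiet, seed = 1))
  ep <- reject_artifacts(extract_epochs(rec, tr, "response", c(-100, 600)))
  err <- condition_average(ep, c("detected_error", "undetected_error"))
  cor_ <- condition_average(ep, "correct_go")
  ne <- peak_measure(err, "FCz", c(0, 150), "negative")
  crn <- peak_measure(cor_, "FCz", c(0, 150), "negative")
  pe <- peak_measure(err, "Cz", c(150, 300), "positive")
  pc <- peak_measure(cor_, "Cz", c(150, 300), "positive")
  expect_equal(ne$amplitude, -27.7)
  expect_equal(ne$latency, 50)
  expect_equal(crn$amplitude, -11.8)
  expect_equal(crn$latency, 36)
  expect_equal(pe$amplitude, 39.5)
  expect_equal(pe$latency, 218)
  expect_equal(pc$amplitude, 20.3)
  expect_equal(pc$latency, 218)
  # peak-to-peak and difference scores on the recovered measures
  expect_equal(peak_to_peak(ne, pe)$delta_latency, 168)
  expect_equal(delta_score(ne, crn), -27.7 - (-11.8))

  stim <- list(
    component_spec("N2", "stimulus", "go", 280, -20.8, 120, "FCz"),
    component_spec("N2", "stimulus", "nogo", 280, -24.2, 120, "FCz"),
    component_spec("P3", "stimulus", "go", 446, 20.4, 200, "FCz"),
    component_spec("P3", "stimulus", "nogo", 460, 33.9, 200, "FCz")
  )
  rec2 <- regress_ocular(synthesize_recording(tr, mont, stim, quiet, seed = 1))
  ep2 <- reject_artifacts(extract_epochs(rec2, tr, "stimulus", c(-100, 800)))
  go <- condition_average(ep2, "correct_go")
  nogo <- condition_average(ep2, "correct_withhold")
  expect_equal(peak_measure(go, "FCz", c(200, 350), "negative")$amplitude, -20.8)
  expect_equal(peak_measure(go, "FCz", c(200, 350), "negative")$latency, 280)
  expect_equal(peak_measure(nogo, "FCz", c(200, 350), "negative")$amplitude, -24.2)
  expect_equal(peak_measure(go, "FCz", c(350, 500), "positive")$latency, 446)
  expect_equal(peak_measure(nogo, "FCz", c(350, 500), "positive")$amplitude, 33.9)
})

test_that("components are recovered with small bias under default noise", {
  mont <- tiny_montage()
  params <- agent_params(p_nogo_error = 0.4, p_detect = 0.9)
  resp <- list(
    component_spec("CRN", "response", "correct", 36, -12, 60, "FCz"),
    component_spec("Pc", "response", "correct", 218, 27, 150, "Cz")
  )
  amps <- t(vapply(1:6, function(s) {
    tr <- classify_trials(simulate_behavior(params, seed = s, n_trials = 120))
    rec <- regress_ocular(synthesize_recording(tr, mont, resp, noise_spec(),
                                               seed = s))
    ep <- reject_artifacts(extract_epochs(rec, tr, "response", c(-100, 600)))
    avg <- condition_average(ep, "correct_go")
    c(peak_measure(avg, "FCz", c(0, 150), "negative")$amplitude,
      peak_measure(avg, "Cz", c(150, 300), "positive")$amplitude)
  }, numeric(2)))
  # extremum search inflates |amplitude| under noise; with ~90 trials per
  # average the bias stays below 5% of the embedded value
  expect_lt(abs(mean(amps[, 1]) - (-12)) / 12, 0.05)
  expect_lt(abs(mean(amps[, 2]) - 27) / 27, 0.05)
})

test_that("erp_measures tabulates all six components per subject", {
  mont <- tiny_montage()
  params <- agent_params(p_nogo_error = 0.5, p_detect = 1)
  tr <- classify_trials(simulate_behavior(params, seed = 12, n_trials = 60))
  rec <- regress_ocular(synthesize_recording(
    tr, mont, default_components("control", latency_jitter_sd = 0),
    noise_spec(rms = 0, blink_rate = 0), seed = 1
  ))
  ep_s <- reject_artifacts(extract_epochs(rec, tr, "stimulus", c(-100, 800)))
  ep_r <- reject_artifacts(extract_epochs(rec, tr, "response", c(-100, 600)))
  tab <- erp_measures(ep_s, ep_r)
  expect_setequal(tab$component, c("N2", "P3", "CRN", "Ne", "Pc", "Pe"))
  expect_equal(nrow(tab), 8)  # N2/P3 x 2 conditions + 4 response components
  # correct withholds have no button press, so no response-locked component
  # can overlap them: their N2/P3 measures are exact
  expect_equal(tab$amplitude[tab$component == "N2" &
                               tab$condition == "correct_withhold"], -24.2)
  expect_equal(tab$latency[tab$component == "N2" &
                             tab$condition == "correct_withhold"], 280)
  expect_equal(tab$amplitude[tab$component == "P3" &
                               tab$condition == "correct_withhold"], 33.9)
  # response-locked peaks overlap the tail of the stimulus response (as in
  # real data); sign and window membership still hold
  ne <- tab[tab$component == "Ne", ]
  expect_lt(ne$amplitude, 0)
  expect_true(ne$latency >= 0 && ne$latency <= 150)
  expect_true(all(tab$n_epochs >= 1))
})
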