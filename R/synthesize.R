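#' ERP component specification for the forward model
#'
#' Each component is a Gaussian-windowed half-sine of the given width whose
#' value at `latency` equals `amplitude` exactly, multiplied by a spatial
#' topography that peaks (weight 1) at `peak_electrode` and falls off as a
#' Gaussian of the angular distance on the scalp sphere. Stimulus-locked
#' components are inserted at stimulus onset, response-locked components at
#' stimulus onset plus the first press.
#'
#' @param name Component name (`"N2"`, `"P3"`, `"Ne"`, `"CRN"`, `"Pe"`, `"Pc"`).
#' @param lock `"stimulus"` or `"response"`.
#' @param condition Trials the component applies to: `"go"`/`"nogo"` for
#'   stimulus lock, `"error"`/`"correct"` for response lock.
#' @param latency Peak latency in ms relative to the lock event.
#' @param amplitude Signed peak amplitude in microvolts.
#' @param width Total waveform width (support) in ms, positive.
#' @param peak_electrode Montage label at which the topography peaks.
#' @param latency_jitter_sd Per-trial latency jitter SD in ms.
#' @param topography_sd Angular SD (radians) of the topography falloff.
#' @return A list of class `component_spec`.
#' @export
component_spec <- function(name, lock, condition, latency, amplitude, width,
                           peak_electrode, latency_jitter_sd = 0,
                           topography_sd = 0.9) {
  assert_that(lock %in% c("stimulus", "response"), "lock must be stimulus|response")
  ok_cond <- if (lock == "stimulus") c("go", "nogo") else c("error", "correct")
  assert_that(condition %in% ok_cond,
              paste0("condition must be one of: ", paste(ok_cond, collapse = "|")))
  assert_that(width > 0, "width must be positive")
  structure(
    list(name = name, lock = lock, condition = condition, latency = latency,
         amplitude = amplitude, width = width,
         peak_electrode = peak_electrode,
         latency_jitter_sd = latency_jitter_sd, topography_sd = topography_sd),
    class = "component_spec"
  )
}

#' Default component sets per group profile
#'
#' Returns the six-component forward model (N2/P3 stimulus-locked at FCz with
#' separate go/nogo amplitudes; Ne/CRN response-locked at FCz; Pe/Pc
#' response-locked at Cz) calibrated so that group-level condition averages
#' emulate the published clinical cohort: patients have a delayed N2
#' (303 vs 280 ms), a strongly reduced P3, and Ne/Pe amplitudes in the
#' reported range, while controls carry the control-group values.
#'
#' @param profile `"control"` or `"patient"`.
#' @param latency_jitter_sd Per-trial latency jitter SD in ms.
#' @return A list of [component_spec()] objects.
#' @export
default_components <- function(profile = c("control", "patient"),
                               latency_jitter_sd = 8) {
  profile <- match.arg(profile)
  p <- profile == "patient"
  j <- latency_jitter_sd
  list(
    component_spec("N2", "stimulus", "go", latency = if (p) 303 else 280,
                   amplitude = if (p) -19.8 else -20.8, width = 120,
                   peak_electrode = "FCz", latency_jitter_sd = j),
    component_spec("N2", "stimulus", "nogo", latency = if (p) 303 else 280,
                   amplitude = if (p) -23.2 else -24.2, width = 120,
                   peak_electrode = "FCz", latency_jitter_sd = j),
    component_spec("P3", "stimulus", "go", latency = 445,
                   amplitude = if (p) 2.3 else 20.4, width = 200,
                   peak_electrode = "FCz", latency_jitter_sd = j),
    component_spec("P3", "stimulus", "nogo", latency = 460,
                   amplitude = if (p) 15.8 else 33.9, width = 200,
                   peak_electrode = "FCz", latency_jitter_sd = j),
    component_spec("Ne", "response", "error", latency = 50,
                   amplitude = if (p) -27.7 else -19.4, width = 60,
                   peak_electrode = "FCz", latency_jitter_sd = j),
    component_spec("CRN", "response", "correct", latency = 36,
                   amplitude = if (p) -11.8 else -12.0, width = 60,
                   peak_electrode = "FCz", latency_jitter_sd = j),
    component_spec("Pe", "response", "error", latency = if (p) 218 else 228,
                   amplitude = if (p) 39.5 else 48.1, width = 150,
                   peak_electrode = "Cz", latency_jitter_sd = j),
    component_spec("Pc", "response", "correct", latency = if (p) 218 else 228,
                   amplitude = if (p) 20.3 else 27.0, width = 150,
                   peak_electrode = "Cz", latency_jitter_sd = j)
  )
}

#' Noise specification for synthetic EEG
#'
#' Background noise has a 1/f^alpha amplitude-shaped power spectrum with the
#' requested RMS per channel; blinks are smooth ~300 ms positive deflections
#' entering the vertical EOG channels and propagating to anterior scalp
#' channels with a factor proportional to the squared anterior coordinate.
#'
#' @param alpha Spectral exponent of the background (power ~ 1/f^alpha).
#' @param rms Background RMS in microvolts (0 disables noise).
#' @param blink_rate Blink events per minute (0 disables blinks).
#' @param blink_amplitude Peak blink amplitude in the vertical EOG, microvolts.
#' @param blink_prop Maximal scalp propagation factor, in [0, 1].
#' @param line_amplitude Optional 50 Hz line-noise amplitude, microvolts.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(alpha = 1, rms = 8, blink_rate = 10,
                       blink_amplitude = 150, blink_prop = 0.4,
                       line_amplitude = 0) {
  assert_that(rms >= 0, "rms must be nonnegative")
  assert_that(is_prob(blink_prop), "blink_prop must lie in [0, 1]")
  structure(
    list(alpha = alpha, rms = rms, blink_rate = blink_rate,
         blink_amplitude = blink_amplitude, blink_prop = blink_prop,
         line_amplitude = line_amplitude),
    class = "noise_spec"
  )
}

# Gaussian-windowed half-sine, peak exactly `amplitude` at `latency`.
component_waveform <- function(t_ms, latency, amplitude, width) {
  rel <- t_ms - latency
  inside <- abs(rel) <= width / 2
  out <- numeric(length(t_ms))
  out[inside] <- amplitude *
    sin(pi * (rel[inside] + width / 2) / width) *
    exp(-rel[inside]^2 / (2 * (width / 4)^2))
  out
}

# Topography weights over scalp channels: 1 at the peak electrode, Gaussian
# falloff in angular distance.
component_topography <- function(comp, mont, labels) {
  assert_that(comp$peak_electrode %in% mont$label,
              paste0("component electrode absent from montage: ",
                     comp$peak_electrode))
  assert_that(all(labels %in% mont$label),
              "all scalp channels must be present in the montage")
  cosang <- montage_cosines(mont, labels)[, match(comp$peak_electrode,
                                                  labels)]
  ang <- acos(pmin(pmax(cosang, -1), 1))
  exp(-ang^2 / (2 * comp$topography_sd^2))
}

one_over_f_noise <- function(n, alpha, rms) {
  # pad to a 2-3-smooth length: R's mixed-radix FFT is quadratic when the
  # length has a large prime factor
  nfft <- stats::nextn(n, c(2L, 3L))
  spec <- complex(real = rnorm(nfft), imaginary = rnorm(nfft))
  f <- c(1, seq_len(nfft - 1))
  f <- pmin(f, nfft - f + 1)        # mirrored frequency index
  shape <- f^(-alpha / 2)
  shape[1] <- 0                     # no DC
  x <- Re(fft(spec * shape, inverse = TRUE))[seq_len(n)]
  x * rms / sd(x)
}

blink_waveform <- function(srate, width_ms = 300) {
  n <- ms_to_sample(width_ms, srate)
  sin(pi * seq_len(n) / n)^2
}

#' Synthesize a continuous EEG recording from a trial table
#'
#' The forward model inserts each applicable component per trial at its lock
#' time (stimulus onset, or onset plus first press for response-locked
#' components), with optional per-trial latency jitter, then adds background
#' noise, blinks and line noise per [noise_spec()]. Events are emitted using
#' the marker scheme `S<kind><color_id>` for stimuli and `R1`/`R2` for first
#' and second presses. The output is deterministic given the seed, and with
#' `noise_spec(rms = 0, blink_rate = 0)` the recording is the exact noise-free
#' superposition of the component templates (so downstream peak measures
#' recover each amplitude/latency exactly).
#'
#' @param trials A trial table (see [simulate_behavior()]).
#' @param mont A [montage()]; its labels define the scalp channels.
#' @param components List of [component_spec()] objects.
#' @param noise A [noise_spec()].
#' @param srate Sampling rate in Hz.
#' @param seed Integer seed for jitter and noise.
#' @param eog_labels Labels for the four EOG channels appended after the
#'   scalp channels.
#' @return An [eeg_recording()].
#' @export
synthesize_recording <- function(trials, mont, components = default_components(),
                                 noise = noise_spec(), srate = 500, seed = 1,
                                 eog_labels = c("VEOGa", "VEOGb",
                                                "HEOGl", "HEOGr")) {
  validate_trial_table(trials)
  labels <- mont$label
  n_scalp <- length(labels)
  n_chan <- n_scalp + length(eog_labels)
  last_ms <- max(trials$stimulus_onset) + 3000
  n_samp <- ms_to_sample(last_ms, srate)
  dat <- matrix(0, nrow = n_chan, ncol = n_samp)

  with_seed(seed, {
    for (comp in components) {
      topo <- component_topography(comp, mont, labels)
      use <- if (comp$lock == "stimulus") {
        trials$stimulus_kind == comp$condition
      } else if (comp$condition == "error") {
        trials$stimulus_kind == "nogo" & !is.na(trials$rt1)
      } else {
        trials$stimulus_kind == "go" & !is.na(trials$rt1)
      }
      for (i in which(use)) {
        t0_ms <- trials$stimulus_onset[i] +
          if (comp$lock == "response") trials$rt1[i] else 0
        lat <- comp$latency +
          if (comp$latency_jitter_sd > 0) rnorm(1, 0, comp$latency_jitter_sd) else 0
        s0 <- ms_to_sample(t0_ms, srate) + 1L  # column of the lock sample
        half <- ceiling((comp$width / 2 + abs(lat)) * srate / 1000) + 2
        idx <- (s0 - half):(s0 + half)
        idx <- idx[idx >= 1 & idx <= n_samp]
        t_rel <- (idx - s0) * 1000 / srate  # ms relative to lock
        wav <- component_waveform(t_rel, lat, comp$amplitude, comp$width)
        nz <- wav != 0
        if (any(nz)) {
          dat[seq_len(n_scalp), idx[nz]] <-
            dat[seq_len(n_scalp), idx[nz]] + outer(topo, wav[nz])
        }
      }
    }

    if (noise$rms > 0) {
      for (ch in seq_len(n_chan)) {
        dat[ch, ] <- dat[ch, ] + one_over_f_noise(n_samp, noise$alpha, noise$rms)
      }
    }
    if (noise$blink_rate > 0) {
      n_blinks <- stats::rpois(1, noise$blink_rate * (n_samp / srate) / 60)
      bw <- blink_waveform(srate)
      prop <- noise$blink_prop * pmax(mont$y, 0)^2
      gain <- c(prop, c(1, 0.7, 0.1, 0.1)[seq_along(eog_labels)])
      if (n_blinks > 0) {
        starts <- sort(sample.int(n_samp - length(bw), n_blinks))
        for (s in starts) {
          span <- s:(s + length(bw) - 1)
          dat[, span] <- dat[, span] +
            noise$blink_amplitude * outer(gain, bw)
        }
      }
    }
    if (noise$line_amplitude > 0) {
      tt <- seq_len(n_samp) / srate
      dat <- dat + matrix(noise$line_amplitude * sin(2 * pi * 50 * tt),
                          nrow = n_chan, ncol = n_samp, byrow = TRUE)
    }
  })

  ev <- dplyr::bind_rows(
    tibble(sample = ms_to_sample(trials$stimulus_onset, srate),
           code = paste0("S", trials$stimulus_kind, trials$color_id)),
    tibble(sample = ms_to_sample(trials$stimulus_onset + trials$rt1, srate),
           code = "R1")[!is.na(trials$rt1), ],
    tibble(sample = ms_to_sample(trials$stimulus_onset + trials$rt2, srate),
           code = "R2")[!is.na(trials$rt2), ]
  )
  ev <- ev[order(ev$sample), ]

  eeg_recording(
    data = dat,
    channels = tibble(
      label = c(labels, eog_labels),
      kind = c(rep("scalp", n_scalp), rep("eog", length(eog_labels)))
    ),
    srate = srate, events = ev,
    meta = list(generator = "errmon forward model", seed = seed)
  )
}
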