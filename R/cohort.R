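#' Group profiles for cohort generation
#'
#' A group profile bundles the behavioral agent, the ERP component set, and
#' (for patients) the clinical covariate model: lesion size in cm^3 and days
#' post-stroke are drawn from lognormal distributions matching the published
#' cohort ranges, and an optional linear coupling shifts the subject's Ne
#' latency by `lesion_ne_slope` ms per cm^3 of lesion so covariate-recovery
#' analyses have a known ground truth.
#'
#' @param params An [agent_params()].
#' @param components List of [component_spec()]s.
#' @param lesion_meanlog,lesion_sdlog Lognormal parameters for lesion size.
#' @param days_meanlog,days_sdlog Lognormal parameters for days post-stroke
#'   (shifted to respect the >= 4 day recruitment window, capped at 268).
#' @param lesion_ne_slope Ne-latency shift per cm^3 lesion (ms).
#' @return A list of class `group_profile`.
#' @export
group_profile <- function(params, components,
                          lesion_meanlog = log(25), lesion_sdlog = 0.8,
                          days_meanlog = log(35), days_sdlog = 0.9,
                          lesion_ne_slope = 0) {
  structure(
    list(params = params, components = components,
         lesion_meanlog = lesion_meanlog, lesion_sdlog = lesion_sdlog,
         days_meanlog = days_meanlog, days_sdlog = days_sdlog,
         lesion_ne_slope = lesion_ne_slope),
    class = "group_profile"
  )
}

#' Default patient and control profiles
#'
#' Encodes the behavioral calibration of the emulated cohort (patients:
#' 22.1% nogo errors, 77.8% detection, 433 ms baseline RT, errors 81 ms
#' faster, 65 ms post-error slowing; controls: 24.3%, 78.3%, 416 ms, 66 ms,
#' 86 ms) together with the group component sets of [default_components()].
#'
#' @param lesion_ne_slope Optional lesion-size to Ne-latency coupling (ms/cm^3)
#'   for the patient profile.
#' @return Named list with `patient` and `control` [group_profile()]s.
#' @export
default_group_profiles <- function(lesion_ne_slope = 0) {
  list(
    patient = group_profile(
      agent_params(p_nogo_error = 0.221, p_detect = 0.778,
                   rt_location = log(283), error_rt_shift = -81,
                   pes_increment = 65),
      default_components("patient"),
      lesion_ne_slope = lesion_ne_slope
    ),
    control = group_profile(
      agent_params(p_nogo_error = 0.243, p_detect = 0.783,
                   rt_location = log(266), error_rt_shift = -66,
                   pes_increment = 86),
      default_components("control")
    )
  )
}

shift_ne_latency <- function(components, shift_ms) {
  map(components, function(comp) {
    if (comp$name == "Ne") comp$latency <- comp$latency + shift_ms
    comp
  })
}

#' Generate an on-disk synthetic cohort
#'
#' Writes, per subject, a BrainVision triplet plus a trial-table TSV under
#' `<out_dir>/<subject_id>/`, a cohort-level subject metadata TSV and a
#' manifest. Patient lesion size and days post-stroke are drawn from the
#' profile's covariate model; when `lesion_ne_slope` is nonzero the embedded
#' Ne latency is shifted by `slope * (lesion_size - median lesion size)` so
#' the generating covariate effect is known. Fully deterministic given the
#' seed.
#'
#' @param n_patients,n_controls Subjects per group (>= 1).
#' @param profiles Named list with `patient` and `control`
#'   [group_profile()]s.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; per-subject streams are derived from it.
#' @param n_trials Trials per session.
#' @param mont Montage for the EEG forward model.
#' @param noise A [noise_spec()].
#' @param write_eeg Write the BrainVision triplets (set `FALSE` for
#'   behavior-only datasets).
#' @return Invisibly, the manifest tibble (one row per subject with paths).
#' @export
generate_cohort <- function(n_patients, n_controls,
                            profiles = default_group_profiles(),
                            out_dir, seed = 1, n_trials = 360,
                            mont = montage_61(), noise = noise_spec(),
                            write_eeg = TRUE) {
  assert_that(is_count(n_patients) && is_count(n_controls),
              "need at least one subject per group")
  assert_that(all(c("patient", "control") %in% names(profiles)),
              "profiles must name both groups")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  groups <- c(rep("patient", n_patients), rep("control", n_controls))
  ids <- sprintf("%s%02d", ifelse(groups == "patient", "pat", "ctl"),
                 c(seq_len(n_patients), seq_len(n_controls)))

  meta <- purrr::map2_dfr(ids, groups, function(id, grp) {
    prof <- profiles[[grp]]
    if (grp == "patient") {
      with_seed(derive_seed(seed, id, "covariates"), {
        lesion <- round(rlnorm(1, prof$lesion_meanlog, prof$lesion_sdlog), 1)
        days <- min(268, 4 + round(rlnorm(1, prof$days_meanlog, prof$days_sdlog)))
      })
      tibble(subject_id = id, group = grp, lesion_size = lesion,
             days_post_stroke = days, phase = classify_phase(days))
    } else {
      tibble(subject_id = id, group = grp, lesion_size = NA_real_,
             days_post_stroke = NA_real_, phase = NA_character_)
    }
  })

  lesion_center <- if (n_patients > 1) {
    median(meta$lesion_size, na.rm = TRUE)
  } else {
    exp(profiles$patient$lesion_meanlog)
  }

  manifest <- purrr::pmap_dfr(meta, function(subject_id, group, lesion_size,
                                             days_post_stroke, phase, ...) {
    prof <- profiles[[group]]
    sdir <- file.path(out_dir, subject_id)
    dir.create(sdir, showWarnings = FALSE)
    trials <- simulate_behavior(prof$params, n_trials = n_trials,
                                seed = derive_seed(seed, subject_id, "beh"))
    trial_path <- file.path(sdir, "trials.tsv")
    write_trial_table(trials, trial_path)
    hdr_path <- NA_character_
    if (write_eeg) {
      comps <- prof$components
      if (group == "patient" && prof$lesion_ne_slope != 0) {
        comps <- shift_ne_latency(
          comps, prof$lesion_ne_slope * (lesion_size - lesion_center))
      }
      rec <- synthesize_recording(trials, mont, comps, noise,
                                  seed = derive_seed(seed, subject_id, "eeg"))
      hdr_path <- write_brainvision(rec, file.path(sdir, subject_id))
    }
    tibble(subject_id = subject_id, group = group,
           trials = trial_path, eeg_header = hdr_path)
  })

  write_subject_meta(meta, file.path(out_dir, "subjects.tsv"))
  # the on-disk manifest uses paths relative to the dataset root so that a
  # dataset is byte-identical wherever it is generated
  rel <- manifest
  prefix <- paste0(out_dir, "/")
  for (col in c("trials", "eeg_header")) {
    v <- rel[[col]]
    strip <- !is.na(v) & startsWith(v, prefix)
    v[strip] <- substring(v[strip], nchar(prefix) + 1)
    rel[[col]] <- v
  }
  readr::write_tsv(rel, file.path(out_dir, "manifest.tsv"),
                   na = "", progress = FALSE)
  invisible(manifest)
}
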