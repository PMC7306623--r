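#' Run configuration
#'
#' Collects every tunable of the end-to-end pipeline in one list: cohort
#' sizes, trial count, group profiles, noise model, epoch windows, the
#' artifact threshold, CSD parameters, decoder layout and alphas, and stage
#' toggles. The configuration (and the master seed) fully determines the run.
#'
#' @param n_patients,n_controls Cohort sizes.
#' @param n_trials Trials per session.
#' @param profiles Group profiles ([default_group_profiles()]).
#' @param noise A [noise_spec()].
#' @param mont A [montage()].
#' @param stim_window,resp_window,decode_window Epoch windows in ms.
#' @param baseline Baseline window in ms.
#' @param threshold_uv Artifact rejection threshold, microvolts.
#' @param csd A [csd_params()].
#' @param decode_on_csd Decode CSD-transformed (`TRUE`) or voltage epochs.
#' @param folds,repeats,C Decoder settings.
#' @param family_alpha Family-wise alpha for the window family.
#' @param correlation_alpha Per-comparison alpha for clinical correlations.
#' @param min_erp,min_mvpa Inclusion thresholds.
#' @param stages Character subset of `c("behavior", "erp", "decode")`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_patients = 24, n_controls = 32, n_trials = 360,
                       profiles = default_group_profiles(),
                       noise = noise_spec(), mont = montage_61(),
                       stim_window = c(-100, 800), resp_window = c(-100, 600),
                       decode_window = c(-100, 300), baseline = c(-100, 0),
                       threshold_uv = 150, csd = csd_params(),
                       decode_on_csd = TRUE, folds = 10, repeats = 10, C = 1,
                       family_alpha = 0.05, correlation_alpha = 0.025,
                       min_erp = 6, min_mvpa = 10,
                       stages = c("behavior", "erp", "decode")) {
  assert_that(all(stages %in% c("behavior", "erp", "decode")),
              "unknown stage name")
  structure(as.list(environment()), class = "run_config")
}

subject_epochs <- function(rec, trials, config) {
  rec <- regress_ocular(rec)
  eps <- list()
  for (lock_win in list(c("stimulus", "stim_window"),
                        c("response", "resp_window"),
                        c("decode", "decode_window"))) {
    lock <- if (lock_win[1] == "decode") "response" else lock_win[1]
    ep <- extract_epochs(rec, trials, lock = lock,
                         window = config[[lock_win[2]]],
                         baseline = config$baseline)
    ep <- reject_artifacts(ep, threshold = config$threshold_uv)
    if (lock_win[1] != "decode" || config$decode_on_csd) {
      ep <- csd_transform(ep, config$mont, config$csd)
    }
    eps[[lock_win[1]]] <- ep
  }
  eps
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulates the cohort to disk, then per subject: classifies and summarises
#' behavior, applies the inclusion criteria, preprocesses the EEG (EOG
#' regression, epoching with baseline correction, amplitude-based artifact
#' rejection, CSD transform), quantifies the six ERP components, and runs the
#' sliding-window decoder with its shuffled-label null. Group-level
#' statistics (pooled t-tests with JZS Bayes factors on the behavioral
#' variables, mixed ANOVAs on ERP measures, clinical correlations in the
#' patient group, per-window decoding comparisons) are assembled into a
#' cohort report. Deterministic given config and seed.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for the generated dataset and tables.
#' @param seed Master seed.
#' @return A `cohort_report` list of tibbles: `behavior`, `behavior_stats`,
#'   `inclusion`, `erp`, `erp_stats`, `decoding`, `decoding_stats`,
#'   `correlations`, `subjects`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("errmon_"),
                         seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "run_config.txt")
  write_run_config(config, cfg_path)
  config_hash <- unname(tools::md5sum(cfg_path))
  manifest <- generate_cohort(
    config$n_patients, config$n_controls, profiles = config$profiles,
    out_dir = file.path(out_dir, "data"), seed = seed,
    n_trials = config$n_trials, mont = config$mont, noise = config$noise,
    write_eeg = any(c("erp", "decode") %in% config$stages)
  )
  subjects <- read_subject_meta(file.path(out_dir, "data", "subjects.tsv"))

  behavior <- NULL
  inclusion <- NULL
  erp_tab <- NULL
  curves <- NULL

  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    trials <- classify_trials(read_trial_table(manifest$trials[i]))
    beh <- summarize_behavior(trials) |>
      dplyr::mutate(subject_id = id, group = manifest$group[i], .before = 1)
    behavior <- dplyr::bind_rows(behavior, beh)
    inc <- dplyr::bind_rows(
      check_inclusion(trials, "erp", min_erp = config$min_erp),
      check_inclusion(trials, "mvpa", min_mvpa = config$min_mvpa)
    ) |>
      dplyr::mutate(subject_id = id, group = manifest$group[i], .before = 1)
    inclusion <- dplyr::bind_rows(inclusion, inc)

    if (!any(c("erp", "decode") %in% config$stages)) next
    rec <- read_brainvision(manifest$eeg_header[i])
    eps <- subject_epochs(rec, trials, config)

    if ("erp" %in% config$stages &&
        inc$include[inc$purpose == "erp"]) {
      meas <- erp_measures(eps$stimulus, eps$response) |>
        dplyr::mutate(subject_id = id, group = manifest$group[i], .before = 1)
      erp_tab <- dplyr::bind_rows(erp_tab, meas)
    }
    if ("decode" %in% config$stages &&
        inc$include[inc$purpose == "mvpa"]) {
      grid <- window_grid(config$decode_window, srate = eps$decode$srate)
      crv <- decode_subject(eps$decode, subject_id = id, grid = grid,
                            folds = config$folds, repeats = config$repeats,
                            C = config$C, seed = derive_seed(seed, id, "decode"),
                            min_trials = config$min_mvpa) |>
        dplyr::mutate(group = manifest$group[i])
      curves <- dplyr::bind_rows(curves, crv)
    }
  }

  behavior_stats <- behavior_group_stats(behavior)
  erp_stats <- if (!is.null(erp_tab)) erp_group_stats(erp_tab) else NULL
  enough_curves <- !is.null(curves) &&
    all(table(unique(curves[c("subject_id", "group")])$group) >= 2) &&
    dplyr::n_distinct(curves$group) == 2
  decoding_stats <- if (enough_curves) {
    decode_group_stats(curves, config$family_alpha)
  } else {
    NULL
  }
  correlations <- if (!is.null(erp_tab)) {
    clinical_correlations(behavior, erp_tab, subjects,
                          alpha = config$correlation_alpha)
  } else {
    NULL
  }

  report <- structure(
    list(behavior = behavior, behavior_stats = behavior_stats,
         inclusion = inclusion, erp = erp_tab, erp_stats = erp_stats,
         decoding = curves, decoding_stats = decoding_stats,
         correlations = correlations, subjects = subjects,
         seed = seed, config_hash = config_hash),
    class = "cohort_report"
  )
  tab_dir <- file.path(out_dir, "tables")
  dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    if (is.data.frame(report[[nm]])) {
      readr::write_tsv(report[[nm]], file.path(tab_dir, paste0(nm, ".tsv")),
                       na = "", progress = FALSE)
    }
  }
  report
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  for (nm in names(x)) {
    if (is.data.frame(x[[nm]])) {
      cat(sprintf("  $%s: %d x %d\n", nm, nrow(x[[nm]]), ncol(x[[nm]])))
    }
  }
  invisible(x)
}

#' Group comparison of behavioral variables
#'
#' Pooled-variance t-tests with JZS Bayes factors for each behavioral summary
#' variable (rates from the complete sample, RT variables from the subjects
#' with a defined value), patients versus controls.
#'
#' @param behavior Per-subject behavioral summaries with a `group` column.
#' @return A tibble with one row per variable: group means, `t`, `df`, `p`,
#'   `bf10`, `bf01`.
#' @export
behavior_group_stats <- function(behavior) {
  vars <- c("correct_go_rate", "incorrect_go_rate", "miss_go_rate",
            "nogo_error_rate", "error_detection_rate",
            "baseline_rt", "error_rt", "delta_pes")
  purrr::map_dfr(vars, function(v) {
    x <- behavior[[v]][behavior$group == "patient"]
    y <- behavior[[v]][behavior$group == "control"]
    x <- x[!is.na(x)]
    y <- y[!is.na(y)]
    tt <- t_independent(x, y)
    bf <- if (is.finite(tt$t)) {
      jzs_bf_ttest(tt$t, length(x), length(y))
    } else {
      tibble(bf10 = NA_real_, bf01 = NA_real_)
    }
    tibble(variable = v, mean_patient = mean(x), mean_control = mean(y),
           n_patient = length(x), n_control = length(y),
           t = tt$t, df = tt$df, p = tt$p, bf10 = bf$bf10, bf01 = bf$bf01)
  })
}

#' Mixed ANOVAs on the ERP measures
#'
#' For each component pair (N2/P3 over correct go versus correct withhold;
#' Ne-CRN and Pe-Pc over correct versus error) and each of amplitude and
#' latency, a 2x2 mixed ANOVA with between factor group and within factor
#' response type, using only subjects with both conditions.
#'
#' @param erp_tab Per-subject ERP measures (from the pipeline).
#' @return A tibble with one row per component x field x effect.
#' @export
erp_group_stats <- function(erp_tab) {
  pairs <- list(
    N2 = c("N2", "correct_go", "N2", "correct_withhold"),
    P3 = c("P3", "correct_go", "P3", "correct_withhold"),
    Ne = c("CRN", "correct_go", "Ne", "detected_error"),
    Pe = c("Pc", "correct_go", "Pe", "detected_error")
  )
  purrr::imap_dfr(pairs, function(pr, nm) {
    purrr::map_dfr(c("amplitude", "latency", "auc"), function(field) {
      a <- erp_tab[erp_tab$component == pr[1] & erp_tab$condition == pr[2], ]
      b <- erp_tab[erp_tab$component == pr[3] & erp_tab$condition == pr[4], ]
      common <- intersect(a$subject_id, b$subject_id)
      if (length(common) < 4) return(tibble())
      a <- a[match(common, a$subject_id), ]
      b <- b[match(common, b$subject_id), ]
      res <- mixed_anova_2x2(cbind(a[[field]], b[[field]]), a$group)
      res |>
        dplyr::mutate(component = nm, field = field, n = length(common),
                      .before = 1)
    })
  })
}

#' Clinical covariate correlations in the patient group
#'
#' Pearson correlations of lesion size and days post-stroke with the
#' behavioral variables and the ERP difference scores (nogo-minus-go for
#' stimulus-locked, error-minus-correct for response-locked components),
#' flagged at the adjusted alpha.
#'
#' @param behavior,erp_tab,subjects Pipeline tables.
#' @param alpha Per-comparison alpha (default 0.025).
#' @return A tibble with one row per (covariate, variable).
#' @export
clinical_correlations <- function(behavior, erp_tab, subjects, alpha = 0.025) {
  pat <- subjects[subjects$group == "patient", ]
  beh <- behavior[match(pat$subject_id, behavior$subject_id), ]
  delta <- function(comp_a, cond_a, comp_b, cond_b, field) {
    a <- erp_tab[erp_tab$component == comp_a & erp_tab$condition == cond_a, ]
    b <- erp_tab[erp_tab$component == comp_b & erp_tab$condition == cond_b, ]
    av <- a[[field]][match(pat$subject_id, a$subject_id)]
    bv <- b[[field]][match(pat$subject_id, b$subject_id)]
    av - bv
  }
  vars <- list(
    baseline_rt = beh$baseline_rt,
    error_rate = beh$nogo_error_rate,
    error_detection_rate = beh$error_detection_rate,
    dN2_amplitude = delta("N2", "correct_withhold", "N2", "correct_go", "amplitude"),
    dN2_latency = delta("N2", "correct_withhold", "N2", "correct_go", "latency"),
    dP3_amplitude = delta("P3", "correct_withhold", "P3", "correct_go", "amplitude"),
    dP3_latency = delta("P3", "correct_withhold", "P3", "correct_go", "latency"),
    dNe_amplitude = delta("Ne", "detected_error", "CRN", "correct_go", "amplitude"),
    dNe_latency = delta("Ne", "detected_error", "CRN", "correct_go", "latency"),
    dPe_amplitude = delta("Pe", "detected_error", "Pc", "correct_go", "amplitude"),
    dPe_latency = delta("Pe", "detected_error", "Pc", "correct_go", "latency")
  )
  covs <- list(lesion_size = pat$lesion_size,
               days_post_stroke = pat$days_post_stroke)
  purrr::imap_dfr(covs, function(cv, cv_name) {
    purrr::imap_dfr(vars, function(v, v_name) {
      ok <- !is.na(cv) & !is.na(v)
      if (sum(ok) < 3) return(tibble())
      pc <- pearson_cor(cv[ok], v[ok])
      tibble(covariate = cv_name, variable = v_name, r = pc$r, n = pc$n,
             p = pc$p, significant = !is.na(pc$p) & pc$p < alpha)
    })
  })
}
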