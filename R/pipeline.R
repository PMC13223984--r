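#' Build a pipeline run configuration
#'
#' Collects every tunable of the simulate -> preprocess -> spectral ->
#' thresholds -> statistics chain in one serialisable list. Defaults give a
#' small but complete demonstration cohort.
#'
#' @param n_participants Simulated cohort size.
#' @param conditions Sweep conditions to run.
#' @param n_trials Sweep trials per direction and condition.
#' @param montage_labels Electrode subset to simulate (must contain the
#'   occipital reference set and the topography peak).
#' @param srate Simulation sampling rate, Hz.
#' @param true_threshold Named per-condition ground-truth thresholds
#'   (native units) for the cohort mean.
#' @param threshold_sd Named per-condition between-participant SD of the
#'   true threshold on the easiness scale (log10 units for contrast and
#'   orientation, cycles/degree for spatial frequency).
#' @param gain,amplitude_cap,harmonic_ratio Response-model parameters.
#' @param noise A [noise_model()].
#' @param preproc List: `target_srate`, `lowpass`, `ptp_limit_uv`,
#'   `reference`.
#' @param spectrum A [spectrum_config()].
#' @param selection A [selection_config()].
#' @param quest List: `beta` (named per-condition observer spread on the
#'   easiness scale), `n_trials`, `n_alternatives`, `n_repetitions`.
#' @param retest_pairing `"directions"` (default: EEG repetition 1/2 are
#'   the increasing/decreasing thresholds) or `"repetition_halves"`
#'   (repetitions are trial halves, each averaged over directions).
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(n_participants = 8,
                       conditions = c("contrast", "spatial_frequency", "orientation"),
                       n_trials = 2,
                       montage_labels = c("Fpz", "Fz", "Cz", "Pz", "P3", "P4",
                                          "P7", "P8", "CP1", "CP2", "PO3",
                                          "PO4", "PO7", "PO8", "POz", "O1",
                                          "O2", "Oz", "Iz"),
                       srate = 256,
                       true_threshold = c(contrast = 0.8,
                                          spatial_frequency = 22,
                                          orientation = 0.6),
                       threshold_sd = c(contrast = 0.15,
                                        spatial_frequency = 3,
                                        orientation = 0.15),
                       gain = 4, amplitude_cap = 8, harmonic_ratio = 0.3,
                       noise = noise_model(white_sd = 1, pink_scale = 2),
                       preproc = list(target_srate = 250, lowpass = 45,
                                      ptp_limit_uv = 150,
                                      reference = "occipital_mean"),
                       spectrum = spectrum_config(),
                       selection = selection_config(),
                       quest = list(beta = c(contrast = 0.2,
                                             spatial_frequency = 1.5,
                                             orientation = 0.2),
                                    n_trials = 60,
                                    n_alternatives = 2, n_repetitions = 2),
                       retest_pairing = c("directions", "repetition_halves"),
                       seed = 1) {
  retest_pairing <- match.arg(retest_pairing)
  structure(
    list(n_participants = n_participants, conditions = conditions,
         n_trials = n_trials, montage_labels = montage_labels, srate = srate,
         true_threshold = true_threshold, threshold_sd = threshold_sd,
         gain = gain, amplitude_cap = amplitude_cap,
         harmonic_ratio = harmonic_ratio, noise = noise, preproc = preproc,
         spectrum = spectrum, selection = selection, quest = quest,
         retest_pairing = retest_pairing, seed = seed),
    class = "run_config"
  )
}

#' Validate a run configuration
#'
#' @param config A [run_config()].
#' @return Character vector of problems; empty when the config is runnable.
#' @export
validate_config <- function(config) {
  issues <- character()
  chk <- function(cond, msg) if (!cond) issues <<- c(issues, msg)
  chk(config$n_participants >= 1, "n_participants must be >= 1")
  chk(all(config$conditions %in%
            c("contrast", "spatial_frequency", "orientation")),
      "unknown condition name")
  chk(all(config$conditions %in% names(config$true_threshold)),
      "true_threshold missing for some condition")
  chk(all(c(occipital_set(), "Oz") %in% config$montage_labels),
      "montage must contain the occipital reference set")
  chk(config$srate >= 100, "srate must be >= 100 Hz")
  chk(config$preproc$lowpass < config$preproc$target_srate / 2,
      "low-pass cutoff must be below the post-downsampling Nyquist")
  chk(config$preproc$ptp_limit_uv > 0, "ptp_limit_uv must be positive")
  chk(config$selection$run_min_sig <= config$selection$run_window,
      "run_min_sig cannot exceed run_window")
  gamma <- 1 / config$quest$n_alternatives
  chk(gamma + (1 - gamma) / 2 > gamma,
      "QUEST target probability must exceed the guess rate")
  chk(all(config$quest$beta > 0), "quest beta must be positive")
  chk(all(config$conditions %in% names(config$threshold_sd)) &&
        all(config$conditions %in% names(config$quest$beta)),
      "threshold_sd and quest beta must be named per condition")
  chk(is.numeric(config$seed) && config$seed == round(config$seed),
      "seed must be an integer")
  chk(config$retest_pairing != "repetition_halves" || config$n_trials >= 2,
      "repetition_halves pairing needs at least 2 trials per direction")
  issues
}

#' Run the full simulated pipeline
#'
#' Simulates a cohort with per-participant ground-truth thresholds, runs
#' the EEG arm (sweep recordings -> preprocessing -> spectral table ->
#' electrode selection -> Sig/Reg thresholds per direction) and the
#' behavioural arm (QUEST sessions against matched simulated observers),
#' assembles the long-format score table and the correlation battery, and
#' writes every table as CSV into `out_dir`. Rerunning with the same
#' config reproduces the outputs exactly.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `scores`, `thresholds`, `reports`,
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = tempfile("sweepvep_run")) {
  issues <- validate_config(config)
  if (length(issues) > 0) {
    stop("invalid configuration:\n- ", paste(issues, collapse = "\n- "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  montage <- montage_1020(config$montage_labels)
  part_seeds <- derive_seeds(config$seed, config$n_participants * 2 + 1)

  thresholds <- list()
  scores <- list()
  rejection_log <- list()

  for (p in seq_len(config$n_participants)) {
    # participant-specific true thresholds on the easiness scale
    set.seed(as.integer(part_seeds[p]))
    shifts <- stats::rnorm(length(config$conditions)) *
      config$threshold_sd[config$conditions]
    names(shifts) <- config$conditions
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      thr_native <- easiness_inverse(
        easiness_scale(config$true_threshold[[cond]], cond) + shifts[[cond]],
        cond
      )
      resp <- response_model(thr_native, cond, gain = config$gain,
                             amplitude_cap = config$amplitude_cap,
                             harmonic_ratio = config$harmonic_ratio)
      dir_results <- list()
      half_results <- list()
      for (dir_ in c("increasing", "decreasing")) {
        design <- make_sweep_design(cond, dir_)
        sim_seed <- (part_seeds[p] + 7919 * ci +
                       1e4 * (dir_ == "decreasing")) %% 2147483647
        rec <- simulate_sweep_recording(design, resp, config$noise, montage,
                                        srate = config$srate,
                                        n_trials = config$n_trials,
                                        seed = sim_seed)
        ep <- preprocess_recording(rec,
                                   target_srate = config$preproc$target_srate,
                                   lowpass = config$preproc$lowpass,
                                   ptp_limit_uv = config$preproc$ptp_limit_uv,
                                   reference = config$preproc$reference)
        if (nrow(ep$rejected) > 0) {
          rejection_log[[length(rejection_log) + 1L]] <-
            dplyr::mutate(ep$rejected, participant = p, condition = cond,
                          direction = dir_)
        }
        tab <- build_spectral_table(ep, config$spectrum)
        res <- extract_thresholds(tab, design, config$selection, "both")
        res$participant <- p
        thresholds[[length(thresholds) + 1L]] <- res
        dir_results[[dir_]] <- res
        if (config$retest_pairing == "repetition_halves") {
          halves <- split_trials(config$n_trials)
          half_results[[dir_]] <- lapply(halves, function(tr) {
            sub <- subset_epochs(ep, tr)
            stab <- build_spectral_table(sub, config$spectrum)
            extract_thresholds(stab, design, config$selection, "sig")
          })
        }
      }
      scores[[length(scores) + 1L]] <- eeg_scores_for(
        dir_results, half_results, cond, p, config$retest_pairing
      )
    }

    # behavioural arm: QUEST against an observer at the same easiness alpha
    q_seed_base <- part_seeds[config$n_participants + p]
    for (ci in seq_along(config$conditions)) {
      cond <- config$conditions[ci]
      alpha <- easiness_scale(config$true_threshold[[cond]], cond) +
        shifts[[cond]]
      beta_c <- config$quest$beta[[cond]]
      obs <- observer(alpha, beta_c,
                      gamma = 1 / config$quest$n_alternatives)
      cfg_q <- session_config(
        n_trials = config$quest$n_trials,
        n_alternatives = config$quest$n_alternatives,
        initial_level = alpha + 2 * beta_c, prior_sd = 5 * beta_c,
        level_bounds = c(alpha - 25 * beta_c, alpha + 25 * beta_c),
        assumed_beta = beta_c
      )
      for (r in seq_len(config$quest$n_repetitions)) {
        s <- (q_seed_base + 131 * ci + r) %% 2147483647
        est <- run_session(obs, cfg_q, seed = s)$estimate
        scores[[length(scores) + 1L]] <- tibble::tibble(
          participant = p, method = "psychophysics", test = cond,
          repetition = r, score = easiness_inverse(est, cond), valid = TRUE
        )
      }
    }
  }

  thresholds <- dplyr::bind_rows(thresholds)
  scores <- dplyr::bind_rows(scores)
  reports <- correlation_battery(scores)

  readr::write_csv(thresholds, file.path(out_dir, "thresholds.csv"))
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(reports, file.path(out_dir, "reports.csv"))
  rej <- if (length(rejection_log) > 0) dplyr::bind_rows(rejection_log) else
    tibble::tibble(trial = integer(), step_index = integer(),
                   reason = character(), participant = integer(),
                   condition = character(), direction = character())
  readr::write_csv(rej, file.path(out_dir, "rejections.csv"))
  writeLines(provenance_lines(config), file.path(out_dir, "provenance.txt"))

  invisible(list(scores = scores, thresholds = thresholds, reports = reports,
                 out_dir = out_dir))
}

split_trials <- function(n_trials) {
  first <- seq_len(ceiling(n_trials / 2))
  list(first, setdiff(seq_len(n_trials), first))
}

# EEG repetition scores under the configured test-retest pairing:
# "directions" treats increasing/decreasing thresholds as repetitions 1/2;
# "repetition_halves" scores each trial half as a repetition, averaging the
# two directions within a half
eeg_scores_for <- function(dir_results, half_results, cond, participant,
                           pairing) {
  if (pairing == "directions") {
    sig_inc <- dir_results$increasing[dir_results$increasing$method == "sig", ]
    sig_dec <- dir_results$decreasing[dir_results$decreasing$method == "sig", ]
    tibble::tibble(
      participant = participant, method = "eeg", test = cond,
      repetition = c(1L, 2L),
      score = c(sig_inc$threshold_value, sig_dec$threshold_value),
      valid = c(isTRUE(sig_inc$valid), isTRUE(sig_dec$valid))
    )
  } else {
    purrr::map_dfr(1:2, function(h) {
      comb <- combine_directions(half_results$increasing[[h]],
                                 half_results$decreasing[[h]])
      tibble::tibble(
        participant = participant, method = "eeg", test = cond,
        repetition = as.integer(h), score = comb$score,
        valid = comb$n_valid > 0
      )
    })
  }
}

provenance_lines <- function(config) {
  c("sweepvep pipeline run",
    paste0("package_version: ", as.character(utils::packageVersion("sweepvep"))),
    paste0("timestamp: (omitted for reproducibility)"),
    paste0("seed: ", config$seed),
    paste0("n_participants: ", config$n_participants),
    paste0("conditions: ", paste(config$conditions, collapse = ", ")),
    paste0("n_trials_per_direction: ", config$n_trials),
    paste0("srate: ", config$srate),
    paste0("retest_pairing: ", config$retest_pairing))
}
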