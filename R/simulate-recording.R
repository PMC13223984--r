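#' Simulate a multichannel sweep ssVEP recording
#'
#' Generates a continuous EEG-like recording for one or more sweep trials of
#' a single design: at each step the response model's 20 Hz (and 40 Hz
#' harmonic) sinusoids are emitted with amplitude [amplitude_response()]
#' scaled by the electrode's topography weight, on top of 1/f + white noise.
#' The sinusoid phase is coherent across a trial (plus any per-step drift),
#' and every presented step — preview, 18 cores, postview — is annotated.
#'
#' @param design A [make_sweep_design()] design.
#' @param response A [response_model()].
#' @param noise A [noise_model()].
#' @param montage Montage tibble; must contain the topography peak.
#' @param srate Sampling rate in Hz (default 256; >= 100).
#' @param n_trials Number of sweep trials to concatenate (default 1).
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return An `eeg_recording`: list with `labels`, `srate`, `samples`
#'   (electrodes x time matrix, microvolt) and `annotations` (tibble with
#'   `onset`, `duration`, `trial`, `slot`, `step_index`, `step_value`,
#'   `phase`, `condition`, `direction`).
#' @export
simulate_sweep_recording <- function(design, response, noise = noise_model(),
                                     montage = montage_1020(), srate = 256,
                                     n_trials = 1, seed = 1) {
  if (srate < 100) stop("srate must be >= 100 Hz")
  if (!response$topography_peak %in% montage$electrode) {
    stop("montage does not contain topography peak electrode ",
         response$topography_peak)
  }
  if (anyDuplicated(montage$electrode)) stop("duplicate electrode labels")
  set.seed(as.integer(seed))

  n_ch <- nrow(montage)
  step_dur <- attr(design, "step_duration")
  trial_dur <- attr(design, "total_duration")
  n_trial_samp <- round(trial_dur * srate)
  n_step_samp <- round(step_dur * srate)
  w <- topography_weights(response, montage)

  samples <- matrix(0, nrow = n_ch, ncol = n_trial_samp * n_trials,
                    dimnames = list(montage$electrode, NULL))
  ann <- vector("list", n_trials)

  for (tr in seq_len(n_trials)) {
    t0 <- (tr - 1L) * n_trial_samp
    tt <- (seq_len(n_trial_samp) - 1) / srate   # trial-local time
    sig <- numeric(n_trial_samp)
    for (s in seq_len(nrow(design))) {
      idx <- (round(design$onset[s] * srate) + 1L):
             (round(design$onset[s] * srate) + n_step_samp)
      a <- amplitude_response(design$step_value[s], response)
      ph <- response$phase + response$phase_drift * (design$step_index[s] - 1)
      if (a > 0) {
        sig[idx] <- a * sin(2 * pi * response$fundamental * tt[idx] + ph) +
          a * response$harmonic_ratio *
            sin(2 * pi * 2 * response$fundamental * tt[idx] + ph)
      }
    }
    block <- outer(unname(w), sig)
    if (noise$pink_scale > 0) {
      for (ch in seq_len(n_ch)) {
        block[ch, ] <- block[ch, ] +
          noise$pink_scale * pink_noise(n_trial_samp, noise$pink_exponent)
      }
    }
    if (noise$white_sd > 0) {
      block <- block + matrix(stats::rnorm(length(block), sd = noise$white_sd),
                              nrow = n_ch)
    }
    if (noise$blink_rate > 0) {
      block <- add_blinks(block, montage, srate, noise)
    }
    samples[, t0 + seq_len(n_trial_samp)] <- block
    ann[[tr]] <- tibble::tibble(
      onset = design$onset + (tr - 1) * trial_dur,
      duration = step_dur,
      trial = tr,
      slot = design$slot,
      step_index = design$step_index,
      step_value = design$step_value,
      phase = design$phase,
      condition = attr(design, "condition"),
      direction = attr(design, "direction")
    )
  }

  structure(
    list(labels = montage$electrode, srate = srate, samples = samples,
         annotations = dplyr::bind_rows(ann), montage = montage),
    class = "eeg_recording"
  )
}

# biphasic frontal transients at Poisson times; exercises epoch rejection
add_blinks <- function(block, montage, srate, noise) {
  n <- ncol(block)
  frontal <- grepl("^(Fp|AF)", montage$electrode)
  if (!any(frontal)) return(block)
  n_events <- stats::rpois(1, noise$blink_rate * n / srate / 60)
  if (n_events == 0) return(block)
  onsets <- sort(sample.int(max(1L, n - srate), n_events))
  tt <- seq(0, 0.4, by = 1 / srate)
  shape <- noise$blink_amplitude *
    (exp(-((tt - 0.1) / 0.05)^2) - 0.4 * exp(-((tt - 0.22) / 0.08)^2))
  for (o in onsets) {
    idx <- o:min(n, o + length(shape) - 1L)
    block[frontal, idx] <- block[frontal, idx] +
      matrix(shape[seq_along(idx)], nrow = sum(frontal), ncol = length(idx),
             byrow = TRUE)
  }
  block
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d annotations\n",
              nrow(x$samples), ncol(x$samples), x$srate,
              ncol(x$samples) / x$srate, nrow(x$annotations)))
  invisible(x)
}

#' Write / read a recording in the columnar text format
#'
#' The exchange format is plain text: a samples file (TSV, one row per
#' sample, one column per electrode, microvolt) whose header line carries
#' the electrode labels, preceded by `#`-comment lines with the sampling
#' rate, plus a sidecar `<path>.annotations.csv` with the step onsets.
#'
#' @param rec An `eeg_recording`.
#' @param path Samples file path (the annotation sidecar is derived from it).
#' @return `write_recording` returns `path` invisibly; `load_recording`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  writeLines(sprintf("# sweepvep columnar recording v1"), con)
  writeLines(sprintf("# srate=%.10g", rec$srate), con)
  close(con)
  df <- tibble::as_tibble(t(rec$samples), .name_repair = "minimal")
  names(df) <- rec$labels
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  readr::write_csv(rec$annotations, annotation_path(path))
  invisible(path)
}

annotation_path <- function(path) paste0(path, ".annotations.csv")

#' @rdname write_recording
#' @param montage Optional montage to attach on load (labels must match).
#' @export
load_recording <- function(path, montage = NULL) {
  if (!file.exists(path)) stop("no such recording file: ", path)
  header <- readLines(path, n = 10)
  sr_line <- grep("^# srate=", header, value = TRUE)
  if (length(sr_line) != 1) stop("malformed recording file (missing srate header): ", path)
  srate <- as.numeric(sub("^# srate=", "", sr_line))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        name_repair = "minimal")
  labels <- names(df)
  if (anyDuplicated(labels)) {
    stop("malformed recording file (duplicate electrode labels): ",
         paste(labels[duplicated(labels)], collapse = ", "))
  }
  ann_file <- annotation_path(path)
  if (!file.exists(ann_file)) stop("missing annotation sidecar: ", ann_file)
  ann <- readr::read_csv(ann_file, show_col_types = FALSE)
  if (nrow(ann) > 0 && any(ann$onset + ann$duration > nrow(df) / srate + 1e-9)) {
    stop("malformed recording: annotations extend past the recording end")
  }
  if (is.null(montage)) {
    full <- montage_1020()
    montage <- if (all(labels %in% full$electrode)) montage_1020(labels) else
      tibble::tibble(electrode = labels, x = NA_real_, y = NA_real_)
  }
  structure(
    list(labels = labels, srate = srate,
         samples = t(as.matrix(df)), annotations = ann, montage = montage),
    class = "eeg_recording"
  )
}
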