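#' Downsample a recording
#'
#' Resamples every channel to `target_srate`: a zero-phase FIR anti-alias
#' low-pass at 80% of the new Nyquist, then evaluation on the new sample
#' grid by linear interpolation (the filtered signal is band-limited well
#' below the old rate, so interpolation error at the analysis frequencies
#' is negligible). Annotation onsets are in seconds and are preserved
#' unchanged.
#'
#' @param rec An `eeg_recording`.
#' @param target_srate Target rate in Hz; must be positive and not exceed
#'   the current rate.
#' @return The resampled `eeg_recording`.
#' @export
downsample <- function(rec, target_srate) {
  if (!is.numeric(target_srate) || target_srate <= 0) {
    stop("target_srate must be positive")
  }
  if (target_srate > rec$srate) {
    stop("target_srate (", target_srate, ") exceeds recording rate (",
         rec$srate, ")")
  }
  if (target_srate == rec$srate) return(rec)
  n_in <- ncol(rec$samples)
  t_in <- (seq_len(n_in) - 1) / rec$srate
  n_out <- floor((n_in - 1) / rec$srate * target_srate) + 1L
  t_out <- (seq_len(n_out) - 1) / target_srate
  b <- fir_lowpass(0.8 * target_srate / 2, rec$srate)
  out <- matrix(0, nrow = nrow(rec$samples), ncol = n_out,
                dimnames = list(rownames(rec$samples), NULL))
  for (ch in seq_len(nrow(rec$samples))) {
    y <- signal::filtfilt(b, 1, rec$samples[ch, ])
    out[ch, ] <- stats::approx(t_in, y, xout = t_out)$y
  }
  rec$samples <- out
  rec$srate <- target_srate
  rec
}

#' Linear detrend and zero-phase low-pass filter
#'
#' Removes each channel's least-squares linear trend, then applies a
#' zero-phase FIR low-pass (Hamming window design, transition bandwidth 25%
#' of the cutoff, forward-backward via [signal::filtfilt()]).
#'
#' @param rec An `eeg_recording`.
#' @param cutoff Low-pass cutoff in Hz (default 45); must be below Nyquist.
#' @return The filtered `eeg_recording`.
#' @export
detrend_lowpass <- function(rec, cutoff = 45) {
  nyq <- rec$srate / 2
  if (cutoff >= nyq) stop("cutoff (", cutoff, " Hz) must be below Nyquist (",
                          nyq, " Hz)")
  n <- ncol(rec$samples)
  tt <- seq_len(n)
  tt_c <- tt - mean(tt)
  denom <- sum(tt_c^2)
  b <- fir_lowpass(cutoff, rec$srate)
  for (ch in seq_len(nrow(rec$samples))) {
    x <- rec$samples[ch, ]
    slope <- sum(tt_c * x) / denom
    x <- x - mean(x) - slope * tt_c
    rec$samples[ch, ] <- signal::filtfilt(b, 1, x)
  }
  rec
}

# Hamming-window FIR low-pass; transition bandwidth 25% of cutoff.
# plain numeric taps so filtfilt() uses its (b, a, x) default method
fir_lowpass <- function(cutoff, srate, tbw_frac = 0.25) {
  tbw <- tbw_frac * cutoff
  n <- ceiling(3.3 * srate / tbw)           # Hamming main-lobe rule
  if (n %% 2 == 1) n <- n + 1               # even order -> odd-length taps
  b <- as.numeric(signal::fir1(n, cutoff / (srate / 2), type = "low",
                               window = signal::hamming(n + 1)))
  b / sum(b)                                # exact unit DC gain
}

#' Cut a recording into 1-second step epochs
#'
#' Extracts one epoch per annotated core step (preview and postview slots
#' are dropped). Epochs are keyed by trial and step index.
#'
#' @param rec An `eeg_recording` whose annotations carry `trial`,
#'   `step_index`, `phase`, `step_value`, `condition`, `direction`.
#' @param keep_phases Annotation phases to keep (default `"core"`).
#' @return An `epoch_set`: list with `data` (3-d array electrodes x samples
#'   x epochs), `index` (tibble: `epoch`, `trial`, `step_index`,
#'   `step_value`, `condition`, `direction`), `labels`, `srate`, `montage`,
#'   `rejected` (empty tibble), `reference` (`"native"`).
#' @export
epoch <- function(rec, keep_phases = "core") {
  ann <- rec$annotations
  need <- c("onset", "duration", "trial", "step_index", "step_value",
            "phase", "condition", "direction")
  if (!all(need %in% names(ann))) {
    stop("annotations lack required columns: ",
         paste(setdiff(need, names(ann)), collapse = ", "))
  }
  ann <- ann[ann$phase %in% keep_phases, ]
  n_samp <- if (nrow(ann) > 0) round(ann$duration[1] * rec$srate) else 0L
  if (nrow(ann) > 0 &&
      any(round(ann$onset * rec$srate) + n_samp > ncol(rec$samples))) {
    stop("annotation extends past the end of the recording")
  }
  data <- array(0, dim = c(nrow(rec$samples), n_samp, nrow(ann)),
                dimnames = list(rec$labels, NULL, NULL))
  for (i in seq_len(nrow(ann))) {
    start <- round(ann$onset[i] * rec$srate) + 1L
    data[, , i] <- rec$samples[, start:(start + n_samp - 1L)]
  }
  index <- tibble::tibble(
    epoch = seq_len(nrow(ann)),
    trial = ann$trial, step_index = ann$step_index,
    step_value = ann$step_value,
    condition = ann$condition, direction = ann$direction
  )
  new_epoch_set(data, index, rec$labels, rec$srate, rec$montage)
}

new_epoch_set <- function(data, index, labels, srate, montage,
                          rejected = NULL, reference = "native") {
  if (is.null(rejected)) {
    rejected <- tibble::tibble(trial = integer(), step_index = integer(),
                               reason = character())
  }
  structure(
    list(data = data, index = index, labels = labels, srate = srate,
         montage = montage, rejected = rejected, reference = reference),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d rejected), %d channels x %d samples @ %g Hz, reference: %s\n",
              dim(x$data)[3], nrow(x$rejected), dim(x$data)[1], dim(x$data)[2],
              x$srate, x$reference))
  invisible(x)
}

#' Reject epochs by peak-to-peak amplitude
#'
#' Moves every epoch whose peak-to-peak amplitude on any channel exceeds
#' `ptp_limit_uv` into the rejected set. This automated criterion stands in
#' for visual inspection; the limit is a tunable, not an estimate of any
#' particular reviewer's behaviour.
#'
#' @param epochs An `epoch_set`.
#' @param ptp_limit_uv Peak-to-peak limit in microvolt (default 150).
#' @return The `epoch_set` with offending epochs removed from `data` and
#'   recorded in `rejected`.
#' @export
reject_epochs <- function(epochs, ptp_limit_uv = 150) {
  if (ptp_limit_uv <= 0) stop("ptp_limit_uv must be positive")
  n_ep <- dim(epochs$data)[3]
  if (n_ep == 0) return(epochs)
  ptp <- apply(epochs$data, 3, function(m) {
    max(apply(m, 1, function(x) diff(range(x))))
  })
  bad <- which(ptp > ptp_limit_uv)
  if (length(bad) > 0) {
    rej <- tibble::tibble(
      trial = epochs$index$trial[bad],
      step_index = epochs$index$step_index[bad],
      reason = sprintf("peak-to-peak %.1f uV > %.1f uV", ptp[bad], ptp_limit_uv)
    )
    epochs$rejected <- dplyr::bind_rows(epochs$rejected, rej)
    epochs$data <- epochs$data[, , -bad, drop = FALSE]
    epochs$index <- epochs$index[-bad, ]
    epochs$index$epoch <- seq_len(nrow(epochs$index))
  }
  epochs
}

#' Re-reference epochs
#'
#' @param epochs An `epoch_set`.
#' @param scheme `"occipital_mean"` (default; subtracts the mean of the
#'   occipital set, the local-reference scheme that sharpens occipital
#'   ssVEP signals), `"common_average"`, or `"single:<label>"` (e.g.
#'   `"single:Fpz"`).
#' @param occipital Electrode labels used by `"occipital_mean"`.
#' @return The re-referenced `epoch_set` (reference recorded).
#' @export
rereference <- function(epochs, scheme = "occipital_mean",
                        occipital = occipital_set()) {
  ref_labels <- if (scheme == "occipital_mean") {
    occipital
  } else if (scheme == "common_average") {
    epochs$labels
  } else if (grepl("^single:", scheme)) {
    sub("^single:", "", scheme)
  } else {
    stop("unknown reference scheme: ", scheme)
  }
  missing <- setdiff(ref_labels, epochs$labels)
  if (length(missing) > 0) {
    stop("reference electrode(s) not in montage: ",
         paste(missing, collapse = ", "))
  }
  ref_idx <- match(ref_labels, epochs$labels)
  for (i in seq_len(dim(epochs$data)[3])) {
    ref_sig <- colMeans(epochs$data[ref_idx, , i, drop = FALSE])
    epochs$data[, , i] <- sweep(epochs$data[, , i], 2, ref_sig)
  }
  epochs$reference <- scheme
  epochs
}

#' Interpolate bad channels
#'
#' Replaces each bad channel, in every epoch, by the inverse-distance
#' weighted mean of its `k` nearest good neighbours on the idealised
#' montage layout.
#'
#' @param epochs An `epoch_set` with montage positions.
#' @param bad_labels Channels to interpolate.
#' @param k Number of neighbours (default 4).
#' @return The `epoch_set` with bad channels replaced.
#' @export
interpolate_channels <- function(epochs, bad_labels, k = 4) {
  if (length(bad_labels) == 0) return(epochs)
  missing <- setdiff(bad_labels, epochs$labels)
  if (length(missing) > 0) stop("unknown channel(s): ", paste(missing, collapse = ", "))
  if (length(bad_labels) >= length(epochs$labels) / 2) {
    stop("too many bad channels (", length(bad_labels), " of ",
         length(epochs$labels), ")")
  }
  m <- epochs$montage
  good <- setdiff(epochs$labels, bad_labels)
  for (bl in bad_labels) {
    d <- montage_distances(m, from = bl)[good]
    nb <- names(sort(d)[seq_len(min(k, length(good)))])
    wgt <- 1 / pmax(d[nb], 1e-6)
    wgt <- wgt / sum(wgt)
    bi <- match(bl, epochs$labels)
    ni <- match(nb, epochs$labels)
    for (i in seq_len(dim(epochs$data)[3])) {
      slice <- epochs$data[ni, , i, drop = FALSE]
      dim(slice) <- dim(slice)[1:2]
      epochs$data[bi, , i] <- as.numeric(wgt %*% slice)
    }
  }
  epochs
}

#' Subset an epoch set by trial
#'
#' @param epochs An `epoch_set`.
#' @param trials Trial ids to keep.
#' @return The reduced `epoch_set` (rejection log untouched).
#' @export
subset_epochs <- function(epochs, trials) {
  keep <- which(epochs$index$trial %in% trials)
  epochs$data <- epochs$data[, , keep, drop = FALSE]
  epochs$index <- epochs$index[keep, ]
  epochs$index$epoch <- seq_len(nrow(epochs$index))
  epochs
}

#' Run the standard preprocessing chain
#'
#' Convenience wrapper: downsample, linear detrend + 45 Hz low-pass, epoch
#' core steps, peak-to-peak rejection, occipital re-reference.
#'
#' @param rec An `eeg_recording`.
#' @param target_srate Rate after downsampling (default 250 Hz; skipped if
#'   the recording is already at or below it).
#' @param lowpass Low-pass cutoff, Hz.
#' @param ptp_limit_uv Epoch rejection limit, microvolt.
#' @param reference Reference scheme passed to [rereference()].
#' @return An `epoch_set`.
#' @export
preprocess_recording <- function(rec, target_srate = 250, lowpass = 45,
                                 ptp_limit_uv = 150,
                                 reference = "occipital_mean") {
  if (rec$srate > target_srate) rec <- downsample(rec, target_srate)
  rec <- detrend_lowpass(rec, lowpass)
  ep <- epoch(rec)
  ep <- reject_epochs(ep, ptp_limit_uv)
  rereference(ep, reference)
}
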