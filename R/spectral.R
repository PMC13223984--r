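#' Average epochs in the time domain per step
#'
#' Pointwise mean across trials of the same (condition, direction, step).
#' Steps with no retained epoch are flagged missing and propagate as
#' undefined spectral rows.
#'
#' @param epochs An `epoch_set`.
#' @param condition,direction Optional filters; by default every
#'   (condition, direction) present is averaged.
#' @return A `step_average` object: list with `data` (3-d array electrodes
#'   x samples x rows), `index` (tibble `condition`, `direction`,
#'   `step_index`, `step_value`, `n_epochs`), `labels`, `srate`.
#' @export
trial_average <- function(epochs, condition = NULL, direction = NULL) {
  idx <- epochs$index
  keep <- rep(TRUE, nrow(idx))
  if (!is.null(condition)) keep <- keep & idx$condition %in% condition
  if (!is.null(direction)) keep <- keep & idx$direction %in% direction
  idx <- idx[keep, ]
  groups <- dplyr::distinct(idx, .data$condition, .data$direction,
                            .data$step_index, .data$step_value)
  groups <- dplyr::arrange(groups, .data$condition, .data$direction,
                           .data$step_index)
  n_samp <- dim(epochs$data)[2]
  data <- array(NA_real_, dim = c(length(epochs$labels), n_samp, nrow(groups)),
                dimnames = list(epochs$labels, NULL, NULL))
  n_epochs <- integer(nrow(groups))
  for (g in seq_len(nrow(groups))) {
    rows <- which(idx$condition == groups$condition[g] &
                  idx$direction == groups$direction[g] &
                  idx$step_index == groups$step_index[g])
    sel <- idx$epoch[rows]
    n_epochs[g] <- length(sel)
    if (length(sel) == 1) {
      data[, , g] <- epochs$data[, , sel]
    } else if (length(sel) > 1) {
      data[, , g] <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
    }
  }
  groups$n_epochs <- n_epochs
  structure(
    list(data = data, index = groups, labels = epochs$labels,
         srate = epochs$srate),
    class = "step_average"
  )
}

#' Single-bin discrete Fourier transform
#'
#' Amplitude and phase of one frequency bin, normalised so a sinusoid
#' `a * sin(2*pi*f*t + phi)` returns amplitude `a` and phase `phi`
#' (sine-basis convention, reported in (-pi, pi]).
#'
#' @param waveform Numeric vector, one analysis window (1 s at 1 Hz
#'   resolution).
#' @param srate Sampling rate, Hz.
#' @param freq Analysis frequency, Hz; must sit on the window's bin grid
#'   and below Nyquist.
#' @param resolution Frequency resolution, Hz (default 1); the window must
#'   contain `srate / resolution` samples.
#' @return Named list `amplitude` (same units as the waveform) and `phase`
#'   (radians).
#' @examples
#' t <- seq(0, 1 - 1/250, by = 1/250)
#' dft_bin(3 * sin(2 * pi * 20 * t + pi/4), 250, 20)
#' @export
dft_bin <- function(waveform, srate, freq, resolution = 1) {
  n <- length(waveform)
  expect_n <- srate / resolution
  if (abs(n - expect_n) > 1e-9) {
    stop("waveform has ", n, " samples; ", expect_n,
         " required for ", resolution, " Hz resolution at ", srate, " Hz")
  }
  k <- freq / resolution
  if (abs(k - round(k)) > 1e-9 || freq >= srate / 2 || freq < 0) {
    stop("frequency ", freq, " Hz is not on the ", resolution,
         " Hz bin grid below Nyquist")
  }
  k <- round(k)
  t_idx <- seq_len(n) - 1
  coef <- sum(waveform * exp(-2i * pi * k * t_idx / n))
  amplitude <- if (k == 0) Mod(coef) / n else 2 * Mod(coef) / n
  # sine-basis phase: a*sin(wt + phi) -> Arg(coef) = phi - pi/2
  phase <- Arg(coef) + pi / 2
  phase <- ((phase + pi) %% (2 * pi)) - pi
  if (phase <= -pi) phase <- phase + 2 * pi
  list(amplitude = amplitude, phase = phase)
}

#' Amplitude spectrum of a window on the analysis bin grid
#' @inheritParams dft_bin
#' @return Tibble with `freq` (0..Nyquist) and `amplitude`.
#' @export
amplitude_spectrum <- function(waveform, srate, resolution = 1) {
  n <- length(waveform)
  sp <- stats::fft(waveform)
  n_half <- floor(n / 2)
  amp <- c(Mod(sp[1]) / n, 2 * Mod(sp[2:(n_half + 1)]) / n)
  tibble::tibble(freq = (0:n_half) * resolution, amplitude = amp)
}

#' Spectrum configuration for noise-floor estimation
#'
#' @param analysis_freq Analysis frequency, Hz (default 20).
#' @param resolution Bin width, Hz (default 1).
#' @param n_neighbors_per_side Noise bins on each side (default 6).
#' @param skip_adjacent Bins skipped immediately next to the analysis bin
#'   (default 1, i.e. 19 and 21 Hz are excluded).
#' @return A `spectrum_config` list.
#' @export
spectrum_config <- function(analysis_freq = 20, resolution = 1,
                            n_neighbors_per_side = 6, skip_adjacent = 1) {
  stopifnot(analysis_freq > 0, resolution > 0, n_neighbors_per_side >= 1,
            skip_adjacent >= 0)
  structure(
    list(analysis_freq = analysis_freq, resolution = resolution,
         n_neighbors_per_side = n_neighbors_per_side,
         skip_adjacent = skip_adjacent),
    class = "spectrum_config"
  )
}

#' Neighbour frequencies used for the noise floor
#' @param cfg A [spectrum_config()].
#' @return Numeric vector of neighbour-bin frequencies (12 by default:
#'   13-18 and 22-27 Hz).
#' @export
noise_bins <- function(cfg = spectrum_config()) {
  off <- (cfg$skip_adjacent + 1):(cfg$skip_adjacent + cfg$n_neighbors_per_side)
  sort(c(cfg$analysis_freq - rev(off) * cfg$resolution,
         cfg$analysis_freq + off * cfg$resolution))
}

#' Noise floor from neighbouring bins
#'
#' Mean and sample standard deviation (n-1 normalisation) of the neighbour
#' bin amplitudes around the analysis frequency.
#'
#' @param spectrum Tibble with columns `freq` and `amplitude` (as from
#'   [amplitude_spectrum()]).
#' @param cfg A [spectrum_config()].
#' @return Named list `noise_mean`, `noise_sd`.
#' @export
noise_floor <- function(spectrum, cfg = spectrum_config()) {
  nb <- noise_bins(cfg)
  idx <- match(round(nb / cfg$resolution), round(spectrum$freq / cfg$resolution))
  if (anyNA(idx)) {
    stop("noise bins outside the available spectrum: ",
         paste(nb[is.na(idx)], collapse = ", "), " Hz")
  }
  amps <- spectrum$amplitude[idx]
  list(noise_mean = mean(amps), noise_sd = stats::sd(amps))
}

#' Build the spectral table
#'
#' For every (condition, direction, electrode, step): the amplitude and
#' phase at the analysis frequency of the trial-averaged epoch, the noise
#' floor (mean and SD of the 12 neighbouring 1 Hz bins, skipping the
#' immediately adjacent ones), the noise-adjusted amplitude
#' `adj_amp = amp - noise_mean`, the z-score `z = adj_amp / noise_sd` and
#' `snr = amp / noise_mean`. Degenerate rows (zero noise SD or mean, or a
#' step with no retained epochs) carry `NA` in the affected columns and
#' `flagged = TRUE`.
#'
#' @param averages A `step_average` from [trial_average()] (or an
#'   `epoch_set`, which is trial-averaged first).
#' @param cfg A [spectrum_config()].
#' @return A tibble (the spectral table) with columns `condition`,
#'   `direction`, `electrode`, `step_index`, `step_value`, `amp`,
#'   `noise_mean`, `noise_sd`, `adj_amp`, `z`, `snr`, `phase`,
#'   `n_epochs`, `flagged`.
#' @export
build_spectral_table <- function(averages, cfg = spectrum_config()) {
  if (inherits(averages, "epoch_set")) averages <- trial_average(averages)
  idx <- averages$index
  out <- vector("list", nrow(idx) * length(averages$labels))
  pos <- 0L
  for (g in seq_len(nrow(idx))) {
    for (e in seq_along(averages$labels)) {
      pos <- pos + 1L
      wave <- averages$data[e, , g]
      if (idx$n_epochs[g] == 0 || anyNA(wave)) {
        out[[pos]] <- tibble::tibble(
          condition = idx$condition[g], direction = idx$direction[g],
          electrode = averages$labels[e], step_index = idx$step_index[g],
          step_value = idx$step_value[g],
          amp = NA_real_, noise_mean = NA_real_, noise_sd = NA_real_,
          adj_amp = NA_real_, z = NA_real_, snr = NA_real_,
          phase = NA_real_, n_epochs = idx$n_epochs[g], flagged = TRUE
        )
        next
      }
      spec <- amplitude_spectrum(wave, averages$srate, cfg$resolution)
      bin <- dft_bin(wave, averages$srate, cfg$analysis_freq, cfg$resolution)
      nf <- noise_floor(spec, cfg)
      adj <- bin$amplitude - nf$noise_mean
      z <- if (nf$noise_sd > 0) adj / nf$noise_sd else NA_real_
      snr <- if (nf$noise_mean > 0) bin$amplitude / nf$noise_mean else NA_real_
      out[[pos]] <- tibble::tibble(
        condition = idx$condition[g], direction = idx$direction[g],
        electrode = averages$labels[e], step_index = idx$step_index[g],
        step_value = idx$step_value[g],
        amp = bin$amplitude, noise_mean = nf$noise_mean,
        noise_sd = nf$noise_sd, adj_amp = adj, z = z, snr = snr,
        phase = bin$phase, n_epochs = idx$n_epochs[g],
        flagged = is.na(z) || is.na(snr)
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Pooled mean periodogram at one electrode
#'
#' Mean power spectrum across all retained epochs (increasing and
#' decreasing pooled) at a single electrode, optionally under a different
#' reference — the classic diagnostic view that shows the 20 Hz response
#' peak and its 40 Hz harmonic.
#'
#' @param epochs An `epoch_set`.
#' @param electrode Electrode to plot (default `"Oz"`).
#' @param reference Optional reference scheme applied first (e.g.
#'   `"single:Fpz"` for a mediofrontal reference); `NULL` keeps the epochs'
#'   current reference.
#' @param resolution Bin width, Hz.
#' @return Tibble with `freq` and `power` (microvolt^2).
#' @export
pooled_periodogram <- function(epochs, electrode = "Oz", reference = NULL,
                               resolution = 1) {
  if (!electrode %in% epochs$labels) stop("electrode not present: ", electrode)
  if (!is.null(reference)) epochs <- rereference(epochs, reference)
  ei <- match(electrode, epochs$labels)
  n_ep <- dim(epochs$data)[3]
  if (n_ep == 0) {
    return(tibble::tibble(freq = numeric(), power = numeric()))
  }
  acc <- NULL
  for (i in seq_len(n_ep)) {
    sp <- amplitude_spectrum(epochs$data[ei, , i], epochs$srate, resolution)
    p <- sp$amplitude^2
    acc <- if (is.null(acc)) p else acc + p
  }
  tibble::tibble(freq = amplitude_spectrum(epochs$data[ei, , 1], epochs$srate,
                                           resolution)$freq,
                 power = acc / n_ep)
}

#' Noise-adjusted amplitude topography for one step
#'
#' @param table Spectral table from [build_spectral_table()].
#' @param condition,direction,step_index Row selector.
#' @param montage Montage providing the electrode order and positions.
#' @return Tibble in montage order with `electrode`, `x`, `y`, `adj_amp`.
#' @export
topography_array <- function(table, condition, direction, step_index,
                             montage = montage_1020()) {
  rows <- table[table$condition == condition & table$direction == direction &
                table$step_index == step_index, ]
  if (nrow(rows) == 0) stop("no spectral rows for the requested step")
  i <- match(montage$electrode, rows$electrode)
  if (anyNA(i)) {
    stop("spectral table is missing electrode(s): ",
         paste(montage$electrode[is.na(i)], collapse = ", "))
  }
  tibble::tibble(electrode = montage$electrode, x = montage$x, y = montage$y,
                 adj_amp = rows$adj_amp[i])
}
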