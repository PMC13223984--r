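#' Selection and threshold-rule configuration
#'
#' @param z_criterion Significance criterion on the z-scored amplitude
#'   (default 2.33, the one-sided standard-normal 0.01 point).
#' @param easy_half Named list of per-condition stimulus ranges (native
#'   units) defining the "easiest half" of steps over which electrode
#'   selection averages z. Defaults: contrast 2.05-30 %, spatial frequency
#'   2.7-11.2 cpd, orientation 0.34-4.96 degrees.
#' @param run_window Number of preceding steps inspected by the run rule
#'   (default 4).
#' @param run_min_sig Minimum qualifying steps within the window
#'   (default 3).
#' @param sig_rule `"mirrored"` (default): the increasing-intensity rule is
#'   the time-mirror of the decreasing one (first significant step preceded
#'   by mostly non-significant steps). `"swapped"`: alternative literal
#'   reading in which only the roles of significant/non-significant and
#'   last/first are exchanged.
#' @param reg_snr_onset SNR at which the regression fit window opens
#'   (default 3).
#' @param phase_tolerance Radians allowed around constancy / per-step drift
#'   in the phase validity check (default pi/4).
#' @return A `selection_config` list.
#' @export
selection_config <- function(z_criterion = 2.33,
                             easy_half = list(
                               contrast = c(2.05, 30),
                               spatial_frequency = c(2.7, 11.2),
                               orientation = c(0.34, 4.96)
                             ),
                             run_window = 4, run_min_sig = 3,
                             sig_rule = c("mirrored", "swapped"),
                             reg_snr_onset = 3,
                             phase_tolerance = pi / 4) {
  sig_rule <- match.arg(sig_rule)
  if (run_min_sig > run_window) stop("run_min_sig cannot exceed run_window")
  if (z_criterion <= 0) stop("z_criterion must be positive")
  structure(
    list(z_criterion = z_criterion, easy_half = easy_half,
         run_window = run_window, run_min_sig = run_min_sig,
         sig_rule = sig_rule, reg_snr_onset = reg_snr_onset,
         phase_tolerance = phase_tolerance),
    class = "selection_config"
  )
}

#' Select the analysis electrode
#'
#' The electrode with the highest mean z over the easiest half of steps
#' (per-condition stimulus ranges in the config). Ties break to the first
#' electrode in montage label order.
#'
#' @param table Spectral table for one (condition, direction) or pooled.
#' @param cfg A [selection_config()].
#' @return Electrode label.
#' @export
select_electrode <- function(table, cfg = selection_config()) {
  cond <- unique(table$condition)
  if (length(cond) != 1) stop("spectral table must cover a single condition")
  rng <- cfg$easy_half[[cond]]
  if (is.null(rng)) stop("no easy-half range configured for condition ", cond)
  easy <- table[table$step_value >= rng[1] & table$step_value <= rng[2], ]
  if (nrow(easy) == 0) stop("no steps fall in the easy-half range")
  mean_z <- easy |>
    dplyr::group_by(.data$electrode) |>
    dplyr::summarise(mz = mean(.data$z, na.rm = TRUE), .groups = "drop")
  mean_z <- mean_z[match(unique(table$electrode), mean_z$electrode), ]
  mean_z <- mean_z[!is.nan(mean_z$mz) & !is.na(mean_z$mz), ]
  if (nrow(mean_z) == 0) stop("z undefined for every electrode; cannot select")
  mean_z$electrode[which.max(mean_z$mz)]
}

#' Step significance mask
#'
#' Strict comparison `z > criterion`, with undefined z counting as
#' non-significant.
#'
#' @param z_by_step z values in sweep-time order (one per core step).
#' @param criterion Significance criterion (default 2.33).
#' @return Logical vector of the same length.
#' @export
significance_mask <- function(z_by_step, criterion = 2.33) {
  m <- z_by_step > criterion
  m[is.na(m)] <- FALSE
  m
}

#' Threshold by the significance-run ("Sig") rule
#'
#' For a decreasing-intensity sweep, the threshold step is the *last*
#' non-significant step (in sweep-time order) with at least `run_min_sig`
#' significant steps among the `run_window` immediately preceding steps.
#' For an increasing-intensity sweep the default rule is the time-mirror:
#' the *first* significant step with at least `run_min_sig` non-significant
#' steps among the preceding window. Steps without a full preceding window
#' are never candidates.
#'
#' The sweep's *intensity* direction is derived from the design: a
#' parameter-increasing spatial-frequency sweep is a decreasing-intensity
#' sweep (finer gratings are harder).
#'
#' @param mask Logical significance mask in sweep-time order (length =
#'   number of core steps).
#' @param design The sweep's [make_sweep_design()].
#' @param cfg A [selection_config()].
#' @param electrode Optional electrode label stored in the result.
#' @return A `threshold_result` tibble row: `method`, `condition`,
#'   `direction`, `electrode`, `step_index`, `threshold_value`, `valid`,
#'   `reason`.
#' @export
sig_threshold <- function(mask, design, cfg = selection_config(),
                          electrode = NA_character_) {
  steps <- design_steps(design)
  if (length(mask) != length(steps)) {
    stop("mask length (", length(mask), ") does not match design steps (",
         length(steps), ")")
  }
  intensity_increasing <- is_intensity_increasing(design)
  w <- cfg$run_window
  k <- cfg$run_min_sig
  n <- length(mask)

  candidate <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (i <= w) next                       # no full preceding window
    window <- mask[(i - w):(i - 1)]
    candidate[i] <- if (intensity_increasing) {
      # significant step emerging from a mostly non-significant run
      mask[i] && sum(!window) >= k
    } else {
      # quoted rule: non-significant step after a mostly significant run
      !mask[i] && sum(window) >= k
    }
  }
  hits <- which(candidate)
  # decreasing-intensity sweeps take the LAST candidate (both readings);
  # increasing take the FIRST under the mirrored rule, LAST under "swapped"
  pick <- if (length(hits) == 0) {
    NA_integer_
  } else if (intensity_increasing && cfg$sig_rule == "mirrored") {
    hits[1]
  } else {
    hits[length(hits)]
  }

  threshold_result(
    method = "sig",
    condition = attr(design, "condition"),
    direction = attr(design, "direction"),
    electrode = electrode,
    step_index = pick,
    threshold_value = if (is.na(pick)) NA_real_ else steps[pick],
    valid = !is.na(pick),
    reason = if (is.na(pick)) "no qualifying run of significant steps" else NA_character_
  )
}

# intensity (easiness) direction over sweep time
is_intensity_increasing <- function(design) {
  e <- design_easiness(design)
  e[length(e)] > e[1]
}

threshold_result <- function(method, condition, direction, electrode,
                             step_index, threshold_value, valid, reason,
                             diagnostics = NULL) {
  res <- tibble::tibble(
    method = method, condition = condition, direction = direction,
    electrode = electrode,
    step_index = as.integer(step_index), threshold_value = threshold_value,
    valid = valid, reason = reason
  )
  attr(res, "diagnostics") <- diagnostics
  class(res) <- c("threshold_result", class(res))
  res
}

#' Threshold by linear extrapolation ("Reg" method)
#'
#' Fits a line to the raw analysis-frequency amplitude as a function of the
#' condition's fit axis (log contrast, linear cycles/degree, log degrees of
#' tilt), between the first amplitude peak with SNR >= 3 (in easy-to-hard
#' order) and the point where the amplitude drops below the mean noise
#' floor. The threshold is the zero-crossing of the fitted line, mapped
#' back to stimulus units. The result is valid only when the slope has the
#' amplitude-declining sign (towards harder stimuli), the zero-crossing
#' lies on the hard side of the fit window, and the phase check passes
#' (constant or gradually leading for contrast, lagging for spatial
#' frequency, constant for orientation).
#'
#' @param rows Spectral-table rows for one electrode and one
#'   (condition, direction), any order.
#' @param design The sweep design.
#' @param cfg A [selection_config()].
#' @return A `threshold_result` row; diagnostics attribute carries the fit
#'   window, slope and phase-check outcome.
#' @export
reg_threshold <- function(rows, design, cfg = selection_config()) {
  condition <- attr(design, "condition")
  electrode <- if (length(unique(rows$electrode)) == 1)
    rows$electrode[1] else NA_character_
  # order easy -> hard on the easiness axis
  ord <- order(easiness_scale(rows$step_value, condition), decreasing = TRUE)
  rows <- rows[ord, ]
  amp <- rows$amp
  snr <- rows$snr
  fail <- function(reason) threshold_result(
    "reg", condition, attr(design, "direction"), electrode,
    NA_integer_, NA_real_, FALSE, reason
  )
  if (all(is.na(amp))) return(fail("no amplitudes available"))

  onset <- first_peak(amp, snr, cfg$reg_snr_onset)
  if (is.na(onset)) return(fail("no-onset: no peak reaches the SNR criterion"))
  below <- which(seq_along(amp) > onset & amp < rows$noise_mean)
  offset <- if (length(below) > 0) below[1] else length(amp)
  if (offset - onset + 1 < 2) return(fail("fit window shorter than 2 points"))

  win <- onset:offset
  # fit axis: log10 % contrast, linear cpd, log10 degrees
  axis_vals <- fit_axis(rows$step_value, condition)
  fit <- stats::lm(amp[win] ~ axis_vals[win])
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!all(is.finite(c(slope, intercept))) || slope == 0) {
    return(fail("degenerate fit"))
  }
  # amplitude must decline towards harder stimuli: positive slope on an
  # axis where easier = larger (contrast/orientation log axis), negative
  # slope on linear cpd (harder = larger cpd)
  declining <- if (condition == "spatial_frequency") slope < 0 else slope > 0
  if (!declining) return(fail("slope has the wrong sign"))

  x0 <- -intercept / slope
  if (!is.finite(x0)) return(fail("non-finite zero-crossing"))
  # crossing must lie on the hard side of the fit window start
  hard_ok <- if (condition == "spatial_frequency") {
    x0 > axis_vals[win[1]]
  } else {
    x0 < axis_vals[win[1]]
  }
  if (!hard_ok) return(fail("zero-crossing on the wrong side of the fit window"))

  # phase is only interpretable where there is signal: the validity check
  # runs over fit-window steps meeting the same SNR criterion as the onset
  # (near- and below-floor steps carry essentially random phase)
  phase_win <- win[!is.na(snr[win]) & snr[win] >= cfg$reg_snr_onset]
  phase_ok <- phase_check(rows$phase[phase_win], condition, cfg$phase_tolerance)
  value <- if (condition == "spatial_frequency") x0 else 10^x0
  threshold_result(
    "reg", condition, attr(design, "direction"), electrode,
    NA_integer_, value, phase_ok,
    if (phase_ok) NA_character_ else "phase check failed",
    diagnostics = list(onset = onset, offset = offset, slope = slope,
                       intercept = intercept, phase_ok = phase_ok,
                       window_steps = rows$step_index[win])
  )
}

fit_axis <- function(step_value, condition) {
  switch(condition,
    contrast = log10(step_value),
    orientation = log10(step_value),
    spatial_frequency = step_value,
    stop("unknown condition: ", condition)
  )
}

# first local maximum (easy->hard order, plateaus count, leftmost index)
# whose SNR meets the criterion
first_peak <- function(amp, snr, snr_min) {
  n <- length(amp)
  for (i in seq_len(n)) {
    if (is.na(amp[i]) || is.na(snr[i]) || snr[i] < snr_min) next
    left_ok <- i == 1 || is.na(amp[i - 1]) || amp[i] >= amp[i - 1]
    right_ok <- i == n || is.na(amp[i + 1]) || amp[i] >= amp[i + 1]
    if (left_ok && right_ok) return(i)
  }
  NA_integer_
}

#' Phase validity check for the Reg method
#'
#' Phases are unwrapped first. `"constant"`: the maximum deviation from the
#' window mean is within tolerance. `"leading"` / `"lagging"`: every
#' per-step increment lies in `[0, tol]` / `[-tol, 0]` (the constant case
#' qualifies). Contrast accepts constant-or-leading, spatial frequency
#' constant-or-lagging, orientation constant only.
#'
#' @param phases Phases (radians) over the fit window, easy-to-hard order.
#' @param condition Sweep condition.
#' @param tolerance Radians (default pi/4).
#' @return Logical.
#' @export
phase_check <- function(phases, condition, tolerance = pi / 4) {
  phases <- phases[!is.na(phases)]
  if (length(phases) < 2) return(TRUE)
  up <- unwrap_phase(phases)
  constant <- max(abs(up - mean(up))) <= tolerance
  inc <- diff(up)
  leading <- all(inc >= 0 & inc <= tolerance)
  lagging <- all(inc <= 0 & inc >= -tolerance)
  switch(condition,
    contrast = constant || leading,
    spatial_frequency = constant || lagging,
    orientation = constant,
    stop("unknown condition: ", condition)
  )
}

unwrap_phase <- function(p) {
  d <- diff(p)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(p[1], d))
}

#' Combine increasing- and decreasing-sweep thresholds
#'
#' One score per (condition, repetition): the mean of the two directions'
#' thresholds on the condition's spacing scale — geometric mean in native
#' units for contrast and orientation (log-spaced sweeps), arithmetic for
#' spatial frequency. A single valid input passes through, flagged.
#'
#' @param inc,dec `threshold_result` rows for the two sweep directions.
#' @return Tibble with `condition`, `method`, `score`, `n_valid`,
#'   `flagged`.
#' @export
combine_directions <- function(inc, dec) {
  stopifnot(inc$condition == dec$condition, inc$method == dec$method)
  condition <- inc$condition
  vals <- c(if (isTRUE(inc$valid)) inc$threshold_value,
            if (isTRUE(dec$valid)) dec$threshold_value)
  score <- if (length(vals) == 0) {
    NA_real_
  } else if (condition %in% c("contrast", "orientation")) {
    exp(mean(log(vals)))
  } else {
    mean(vals)
  }
  tibble::tibble(
    condition = condition, method = inc$method, score = score,
    n_valid = length(vals), flagged = length(vals) < 2
  )
}

#' Extract both-method thresholds for one sweep
#'
#' Runs electrode selection on the spectral table, then the Sig and/or Reg
#' rules at the selected electrode.
#'
#' @param table Spectral table for one (condition, direction).
#' @param design The matching sweep design.
#' @param cfg A [selection_config()].
#' @param method `"sig"`, `"reg"` or `"both"`.
#' @param electrode Optional electrode override (skips selection).
#' @return A tibble of `threshold_result` rows.
#' @export
extract_thresholds <- function(table, design, cfg = selection_config(),
                               method = c("both", "sig", "reg"),
                               electrode = NULL) {
  method <- match.arg(method)
  if (is.null(electrode)) electrode <- select_electrode(table, cfg)
  rows <- table[table$electrode == electrode, ]
  rows <- rows[order(rows$step_index), ]
  out <- list()
  if (method %in% c("both", "sig")) {
    mask <- significance_mask(rows$z, cfg$z_criterion)
    out$sig <- sig_threshold(mask, design, cfg, electrode = electrode)
  }
  if (method %in% c("both", "reg")) {
    out$reg <- reg_threshold(rows, design, cfg)
  }
  dplyr::bind_rows(out)
}
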