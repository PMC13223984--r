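#' Steady-state response model for the simulator
#'
#' Describes how the oscillatory 20 Hz response grows with stimulus
#' intensity above a known true threshold. Amplitude is zero at and below
#' `true_threshold`, then grows linearly on the condition's easiness scale
#' (log units for contrast/orientation, negated cpd for spatial frequency)
#' with slope `gain`, capped at `amplitude_cap`. A weaker component at the
#' fourth harmonic (40 Hz) is controlled by `harmonic_ratio`, and the scalp
#' distribution is a Gaussian over layout distance from a peak electrode
#' (Oz by default).
#'
#' @param true_threshold Ground-truth threshold in native stimulus units.
#' @param condition Sweep condition the threshold refers to.
#' @param gain Amplitude gain, microvolt per easiness unit (default 4).
#' @param amplitude_cap Saturation amplitude in microvolt (default 8).
#' @param fundamental Response frequency in Hz (default 20).
#' @param harmonic_ratio 40 Hz amplitude as a fraction of the fundamental
#'   (default 0.3).
#' @param topography_peak Electrode at which the response peaks.
#' @param topography_sigma Gaussian width of the scalp spread, in montage
#'   layout units (default 0.15: a focal occipital response whose occipital
#'   neighbours carry roughly 10% of the peak amplitude, so the local
#'   occipital-mean reference retains most of the peak signal).
#' @param phase Baseline response phase in radians.
#' @param phase_drift Phase change per step in radians (default 0).
#' @return A `response_model` object (list).
#' @export
response_model <- function(true_threshold, condition,
                           gain = 4, amplitude_cap = 8,
                           fundamental = 20, harmonic_ratio = 0.3,
                           topography_peak = "Oz", topography_sigma = 0.15,
                           phase = 0, phase_drift = 0) {
  stopifnot(true_threshold > 0, gain >= 0, amplitude_cap >= 0,
            harmonic_ratio >= 0, topography_sigma > 0)
  structure(
    list(true_threshold = true_threshold, condition = condition, gain = gain,
         amplitude_cap = amplitude_cap, fundamental = fundamental,
         harmonic_ratio = harmonic_ratio, topography_peak = topography_peak,
         topography_sigma = topography_sigma, phase = phase,
         phase_drift = phase_drift),
    class = "response_model"
  )
}

#' Response amplitude at a stimulus intensity
#'
#' @param intensity Stimulus value(s) in the sweep's native units.
#' @param model A [response_model()].
#' @return Amplitude(s) in microvolt: 0 at and below the true threshold,
#'   then `min(cap, gain * (easiness(intensity) - easiness(threshold)))`.
#' @examples
#' m <- response_model(1, "contrast", gain = 2, amplitude_cap = Inf)
#' amplitude_response(10, m)  # 2 * log10(10/1) = 2
#' @export
amplitude_response <- function(intensity, model) {
  if (any(intensity < 0, na.rm = TRUE)) stop("negative stimulus intensity")
  e <- easiness_scale(intensity, model$condition)
  e0 <- easiness_scale(model$true_threshold, model$condition)
  pmin(model$amplitude_cap, pmax(0, model$gain * (e - e0)))
}

#' Per-electrode topography weights of a response model
#' @param model A [response_model()].
#' @param montage Montage tibble ([montage_1020()]).
#' @return Named weight vector in (0, 1], 1 at the peak electrode.
#' @export
topography_weights <- function(model, montage = montage_1020()) {
  d <- montage_distances(montage, from = model$topography_peak)
  exp(-d^2 / (2 * model$topography_sigma^2))
}

#' Background noise model for the simulator
#'
#' Additive per-channel noise: Gaussian white noise plus 1/f ("pink")
#' noise synthesised in the frequency domain, and optional stereotyped
#' biphasic blink transients on frontal channels (default off) so that
#' epoch rejection has something to reject.
#'
#' @param white_sd White-noise standard deviation, microvolt (default 1).
#' @param pink_scale Standard deviation of the 1/f component, microvolt
#'   (default 2).
#' @param pink_exponent Spectral slope: amplitude ~ f^(-exponent/2)
#'   (default 1, i.e. power ~ 1/f).
#' @param blink_rate Blink events per minute (default 0).
#' @param blink_amplitude Peak blink deflection, microvolt (default 400).
#' @return A `noise_model` object (list).
#' @export
noise_model <- function(white_sd = 1, pink_scale = 2, pink_exponent = 1,
                        blink_rate = 0, blink_amplitude = 400) {
  stopifnot(white_sd >= 0, pink_scale >= 0, pink_exponent >= 0,
            blink_rate >= 0, blink_amplitude >= 0)
  structure(
    list(white_sd = white_sd, pink_scale = pink_scale,
         pink_exponent = pink_exponent, blink_rate = blink_rate,
         blink_amplitude = blink_amplitude),
    class = "noise_model"
  )
}

# 1/f noise via frequency-domain synthesis, unit variance then scaled
pink_noise <- function(n, exponent) {
  if (n < 2) return(numeric(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))                      # avoid DC blow-up
  f <- pmin(f, n - f + 1)                        # mirror for negative freqs
  spec <- spec * f^(-exponent / 2)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}
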