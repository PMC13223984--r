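# shared fixtures: a small posterior-weighted montage and quick simulations

small_montage <- function() {
  montage_1020(c("Fpz", "Fz", "Cz", "Pz", "POz", "O1", "O2", "Oz", "Iz"))
}

# one sweep recording with sensible defaults; epochs cut without filtering
# so analytic amplitude identities hold exactly
quick_recording <- function(condition = "contrast", direction = "increasing",
                            true_threshold = 0.8, noise = noise_model(),
                            n_trials = 2, srate = 256, seed = 1, ...) {
  design <- make_sweep_design(condition, direction)
  resp <- response_model(true_threshold, condition, ...)
  simulate_sweep_recording(design, resp, noise, small_montage(),
                           srate = srate, n_trials = n_trials, seed = seed)
}

quick_epochs <- function(...) epoch(quick_recording(...))

# hand-built spectral rows for one electrode: amplitude linear on the fit
# axis, constant phase, flat noise floor
linear_spectral_rows <- function(design, slope = 2, crossing = -0.5,
                                 noise_mean = 0.05, noise_sd = 0.02,
                                 phase = 0.3) {
  condition <- attr(design, "condition")
  steps <- design_steps(design)
  axis <- switch(condition,
                 spatial_frequency = steps,
                 log10(steps))
  # amplitudes lie exactly on the line, including (slightly negative)
  # values beyond the crossing, so regression recovery is exact
  amp <- slope * (axis - crossing) *
    ifelse(condition == "spatial_frequency", -1, 1)
  tibble::tibble(
    condition = condition, direction = attr(design, "direction"),
    electrode = "Oz", step_index = seq_along(steps), step_value = steps,
    amp = amp, noise_mean = noise_mean, noise_sd = noise_sd,
    adj_amp = amp - noise_mean, z = (amp - noise_mean) / noise_sd,
    snr = amp / noise_mean, phase = phase, n_epochs = 1L,
    flagged = FALSE
  )
}
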