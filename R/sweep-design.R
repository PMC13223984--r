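#' Construct a sweep stimulus design
#'
#' A sweep trial steps one stimulus parameter — Michelson contrast (%),
#' spatial frequency (cycles/degree) or orientation tilt (degrees) — through
#' `n_steps` logarithmically spaced values, one second per step, at 20
#' pattern reversals per second. The first and last steps are repeated once
#' as preview/postview, so the default trial lasts 20 s.
#'
#' `direction` refers to the swept parameter value: `"increasing"` runs from
#' `low` to `high`. Note that for spatial frequency an increasing parameter
#' sweep is a *decreasing-intensity* (easy-to-hard) sweep, since coarser
#' gratings drive the larger response; [design_easiness()] exposes the
#' easy-to-hard axis explicitly.
#'
#' @param condition One of `"contrast"`, `"spatial_frequency"`,
#'   `"orientation"`.
#' @param direction `"increasing"` or `"decreasing"` (parameter value over
#'   sweep time).
#' @param low,high Positive sweep endpoints in native units. Defaults are the
#'   standard ranges: 0.1–30 % contrast, 2.7–40 cpd, 0.05–4.96 degrees
#'   (orientation sweeps are nominally "from 0", but geometric spacing needs
#'   a nonzero floor; 0.05 degrees is the configured default floor).
#' @param n_steps Number of core steps (default 18).
#' @param step_duration Seconds per step (default 1).
#' @param reversal_rate Pattern reversals per second (default 20); the
#'   response is analysed at this frequency.
#' @return A `sweep_design`: a tibble with one row per presented epoch
#'   (preview, cores, postview) and columns `slot` (presentation index),
#'   `step_index` (1..n_steps, preview/postview carry the repeated step's
#'   index), `step_value`, `phase` (`"preview"`, `"core"`, `"postview"`),
#'   `onset` (s). Design parameters are attached as attributes.
#' @examples
#' d <- make_sweep_design("contrast", "increasing")
#' attr(d, "total_duration")  # 20 s
#' @export
make_sweep_design <- function(condition = c("contrast", "spatial_frequency", "orientation"),
                              direction = c("increasing", "decreasing"),
                              low = NULL, high = NULL, n_steps = 18,
                              step_duration = 1, reversal_rate = 20) {
  condition <- match.arg(condition)
  direction <- match.arg(direction)
  defaults <- list(
    contrast = c(0.1, 30),
    spatial_frequency = c(2.7, 40),
    orientation = c(0.05, 4.96)
  )[[condition]]
  if (is.null(low)) low <- defaults[1]
  if (is.null(high)) high <- defaults[2]
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    stop("invalid sweep design: need 0 < low < high (got low=", low,
         ", high=", high, ")")
  }
  if (n_steps < 2) stop("invalid sweep design: n_steps must be >= 2")

  values <- exp(seq(log(low), log(high), length.out = n_steps))
  if (direction == "decreasing") values <- rev(values)
  slots <- tibble::tibble(
    slot = seq_len(n_steps + 2L),
    step_index = c(1L, seq_len(n_steps), as.integer(n_steps)),
    phase = c("preview", rep("core", n_steps), "postview")
  )
  slots$step_value <- values[slots$step_index]
  slots$onset <- (slots$slot - 1L) * step_duration

  structure(
    slots[, c("slot", "step_index", "step_value", "phase", "onset")],
    condition = condition,
    direction = direction,
    low = low, high = high,
    n_steps = as.integer(n_steps),
    step_duration = step_duration,
    reversal_rate = reversal_rate,
    total_duration = (n_steps + 2L) * step_duration,
    class = c("sweep_design", class(slots))
  )
}

#' Core step values of a design in sweep-time order
#' @param design A `sweep_design`.
#' @return Numeric vector of length `n_steps`.
#' @export
design_steps <- function(design) {
  core <- design[design$phase == "core", ]
  core$step_value[order(core$step_index)]
}

#' @export
print.sweep_design <- function(x, ...) {
  cat(sprintf("<sweep_design> %s, %s: %d log steps %.4g..%.4g, %g s/step\n",
              attr(x, "condition"), attr(x, "direction"), attr(x, "n_steps"),
              attr(x, "low"), attr(x, "high"), attr(x, "step_duration")))
  NextMethod()
}

#' Stimulus "easiness" scale
#'
#' Maps native stimulus units onto the axis along which response amplitude
#' is modelled and regression fits are performed: log10 units for contrast
#' and orientation (larger = easier), negated linear cycles/degree for
#' spatial frequency (coarser = easier).
#'
#' @param value Stimulus value(s) in native units.
#' @param condition Sweep condition.
#' @return Numeric easiness value(s).
#' @export
easiness_scale <- function(value, condition) {
  if (any(value < 0, na.rm = TRUE)) stop("negative stimulus intensity")
  switch(condition,
    contrast = log10(value),
    orientation = log10(value),
    spatial_frequency = -value,
    stop("unknown condition: ", condition)
  )
}

#' Inverse of [easiness_scale()]
#' @param e Easiness value(s).
#' @param condition Sweep condition.
#' @return Stimulus value(s) in native units.
#' @export
easiness_inverse <- function(e, condition) {
  switch(condition,
    contrast = 10^e,
    orientation = 10^e,
    spatial_frequency = -e,
    stop("unknown condition: ", condition)
  )
}

#' Easiness of each core step of a design
#' @inheritParams design_steps
#' @return Numeric vector: easiness of steps 1..n in step-index order.
#' @export
design_easiness <- function(design) {
  easiness_scale(design_steps(design), attr(design, "condition"))
}
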