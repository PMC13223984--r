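#' Simulated psychophysical observer
#'
#' A cumulative-Gaussian observer for forced-choice tasks: the probability
#' of a correct response at stimulus level `x` (on the task's working scale,
#' typically log units) is
#' `gamma + (1 - gamma - lambda) * pnorm((x - alpha) / beta)`.
#' `alpha` is the threshold (the function's steepest point), `beta` the
#' spread, `gamma` the guess rate (0.5 for 2AFC, 0.25 for 4AFC) and
#' `lambda` the lapse rate.
#'
#' @param alpha Threshold location on the working scale.
#' @param beta Spread (> 0).
#' @param gamma Guess rate in [0, 1).
#' @param lambda Lapse rate in [0, 0.5).
#' @return An `observer` object (list).
#' @export
observer <- function(alpha, beta, gamma = 0.5, lambda = 0) {
  stopifnot(beta > 0, gamma >= 0, gamma < 1, lambda >= 0, lambda < 0.5)
  structure(list(alpha = alpha, beta = beta, gamma = gamma, lambda = lambda),
            class = "observer")
}

#' True probability of a correct response
#' @param obs An [observer()].
#' @param level Stimulus level(s) on the working scale.
#' @return Probability/ies in [gamma, 1 - lambda].
#' @export
psychometric_p <- function(obs, level) {
  obs$gamma + (1 - obs$gamma - obs$lambda) *
    stats::pnorm((level - obs$alpha) / obs$beta)
}

#' Draw one forced-choice response from an observer
#' @inheritParams psychometric_p
#' @return Logical: `TRUE` for a correct response.
#' @export
simulate_observer_response <- function(obs, level) {
  if (!is.finite(level)) stop("stimulus level must be finite")
  stats::runif(1) < psychometric_p(obs, level)
}
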