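#' QUEST session configuration
#'
#' @param n_trials Trials per session (60 for the 2AFC tests, 30 for the
#'   4AFC acuity analogue).
#' @param n_alternatives 2 or 4; sets the guess rate `gamma = 1/n` and the
#'   design point (75% correct for 2AFC, 62.5% for 4AFC, the probability at
#'   the cumulative Gaussian's steepest point with zero lapse).
#' @param initial_level Starting level (working scale; prior mean).
#' @param prior_sd Prior standard deviation over candidate thresholds.
#' @param level_bounds Length-2 numeric: admissible stimulus levels; must
#'   cover the prior mean +/- 4 prior SDs.
#' @param min_testable Hard floor on presented levels (e.g. 0.25 degrees
#'   for the orientation task, on the working scale); `-Inf` disables it.
#' @param assumed_beta Psychometric spread assumed by the staircase
#'   likelihood.
#' @param assumed_lambda Lapse rate assumed by the staircase.
#' @param grid_n Number of candidate-threshold grid points.
#' @param placement `"mean"` (posterior mean, default) or `"mode"`.
#' @return A `session_config` list.
#' @export
session_config <- function(n_trials = 60, n_alternatives = 2,
                           initial_level = 0, prior_sd = 1,
                           level_bounds = c(-4.5, 4.5), min_testable = -Inf,
                           assumed_beta = 0.3, assumed_lambda = 0.01,
                           grid_n = 301, placement = c("mean", "mode")) {
  placement <- match.arg(placement)
  stopifnot(n_trials >= 1, n_alternatives %in% c(2, 4), prior_sd > 0,
            assumed_beta > 0, assumed_lambda >= 0, assumed_lambda < 0.5,
            length(level_bounds) == 2, level_bounds[1] < level_bounds[2])
  gamma <- 1 / n_alternatives
  target_p <- gamma + (1 - gamma) / 2       # steepest-point probability
  structure(
    list(n_trials = as.integer(n_trials), n_alternatives = n_alternatives,
         gamma = gamma, target_p = target_p,
         initial_level = initial_level, prior_sd = prior_sd,
         level_bounds = level_bounds, min_testable = min_testable,
         assumed_beta = assumed_beta, assumed_lambda = assumed_lambda,
         grid_n = as.integer(grid_n), placement = placement),
    class = "session_config"
  )
}

#' Initialise a QUEST state
#'
#' Gaussian prior over a discrete grid of candidate thresholds.
#'
#' @param cfg A [session_config()].
#' @param prior_mean Prior mean (defaults to the config's initial level).
#' @param prior_sd Prior SD (defaults to the config's).
#' @return A `quest_state`: list with `grid`, `log_posterior` (normalised),
#'   `cfg`, `history` (tibble of `trial`, `level`, `correct`).
#' @export
quest_init <- function(cfg = session_config(), prior_mean = NULL,
                       prior_sd = NULL) {
  if (is.null(prior_mean)) prior_mean <- cfg$initial_level
  if (is.null(prior_sd)) prior_sd <- cfg$prior_sd
  if (prior_sd <= 0) stop("prior_sd must be positive")
  grid <- seq(cfg$level_bounds[1], cfg$level_bounds[2], length.out = cfg$grid_n)
  if (length(unique(grid)) < 2) stop("degenerate candidate grid")
  if (prior_mean - 4 * prior_sd < grid[1] - 1e-12 ||
      prior_mean + 4 * prior_sd > grid[length(grid)] + 1e-12) {
    stop("grid does not cover prior_mean +/- 4 prior_sd; widen level_bounds")
  }
  lp <- stats::dnorm(grid, prior_mean, prior_sd, log = TRUE)
  lp <- lp - log_sum_exp(lp)
  structure(
    list(grid = grid, log_posterior = lp, cfg = cfg,
         history = tibble::tibble(trial = integer(), level = numeric(),
                                  correct = logical())),
    class = "quest_state"
  )
}

log_sum_exp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Posterior over candidate thresholds as a tibble
#' @param x A `quest_state`.
#' @param ... Unused.
#' @return Tibble with `threshold` (grid) and `posterior` (probability).
#' @method tidy quest_state
#' @export
tidy.quest_state <- function(x, ...) {
  tibble::tibble(threshold = x$grid, posterior = exp(x$log_posterior))
}

#' One-line summary of a QUEST state
#' @param x A `quest_state`.
#' @param ... Unused.
#' @return Tibble with `n_trials`, `estimate`, `posterior_sd`.
#' @method glance quest_state
#' @export
glance.quest_state <- function(x, ...) {
  p <- exp(x$log_posterior)
  m <- sum(p * x$grid)
  tibble::tibble(
    n_trials = nrow(x$history),
    estimate = m,
    posterior_sd = sqrt(sum(p * (x$grid - m)^2))
  )
}

# likelihood of a correct response at `level` for each candidate threshold
quest_likelihood <- function(state, level) {
  cfg <- state$cfg
  cfg$gamma + (1 - cfg$gamma - cfg$assumed_lambda) *
    stats::pnorm((level - state$grid) / cfg$assumed_beta)
}

#' Bayesian update of a QUEST state
#'
#' Multiplies the posterior by the likelihood of the observed response at
#' the tested level under each candidate threshold, then renormalises.
#'
#' @param state A `quest_state`.
#' @param level Tested stimulus level (working scale).
#' @param correct Logical response.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, level, correct) {
  p_correct <- quest_likelihood(state, level)
  like <- if (isTRUE(correct)) p_correct else 1 - p_correct
  lp <- state$log_posterior + log(pmax(like, 1e-300))
  state$log_posterior <- lp - log_sum_exp(lp)
  state$history <- dplyr::bind_rows(
    state$history,
    tibble::tibble(trial = nrow(state$history) + 1L, level = level,
                   correct = isTRUE(correct))
  )
  state
}

#' Next level to test
#'
#' Posterior-mean candidate threshold (or mode, per config), clipped to the
#' level bounds and the minimum testable value.
#'
#' @param state A `quest_state`.
#' @return Stimulus level (working scale).
#' @export
quest_next <- function(state) {
  p <- exp(state$log_posterior)
  level <- if (state$cfg$placement == "mean") {
    sum(p * state$grid)
  } else {
    state$grid[which.max(p)]
  }
  level <- max(level, state$cfg$min_testable)
  min(max(level, state$cfg$level_bounds[1]), state$cfg$level_bounds[2])
}

#' Run one simulated QUEST session
#'
#' Repeats propose-respond-update for `cfg$n_trials` trials against a
#' simulated [observer()]; the final estimate is the posterior mean (or
#' mode) on the working scale.
#'
#' @param obs An [observer()]; its guess rate should equal `1/n_alternatives`.
#' @param cfg A [session_config()].
#' @param seed Integer seed for the response stream.
#' @return List with `estimate`, `state` and `trials` (tibble log).
#' @export
run_session <- function(obs, cfg = session_config(), seed = 1) {
  if (abs(obs$gamma - cfg$gamma) > 1e-9) {
    stop("observer guess rate (", obs$gamma,
         ") does not match the session's alternatives (gamma ", cfg$gamma, ")")
  }
  set.seed(as.integer(seed))
  state <- quest_init(cfg)
  for (i in seq_len(cfg$n_trials)) {
    level <- quest_next(state)
    correct <- simulate_observer_response(obs, level)
    state <- quest_update(state, level, correct)
  }
  est <- glance.quest_state(state)$estimate
  est <- max(est, cfg$min_testable)
  list(estimate = est, state = state, trials = state$history)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' `p(correct) = gamma + (1 - gamma - lambda) * pnorm((x - alpha)/beta)`
#' with `gamma` and `lambda` fixed. The threshold is `alpha`, the steepest
#' point, where p = 0.75 for a 2AFC task with zero lapse (0.625 for 4AFC).
#'
#' @param levels Tested levels.
#' @param responses Logical (or 0/1) correctness.
#' @param gamma Guess rate (fixed).
#' @param lambda Lapse rate (fixed, default 0).
#' @return List with `alpha`, `beta`, `logLik`, `converged`.
#' @export
fit_psychometric <- function(levels, responses, gamma = 0.5, lambda = 0) {
  responses <- as.logical(responses)
  if (length(levels) != length(responses)) stop("levels/responses length mismatch")
  if (length(unique(levels)) < 2) {
    stop("psychometric fit needs at least 2 distinct levels")
  }
  if (all(responses) || !any(responses)) {
    stop("psychometric fit needs both correct and incorrect responses ",
         "(no asymptote support)")
  }
  nll <- function(par) {
    alpha <- par[1]
    beta <- exp(par[2])
    p <- gamma + (1 - gamma - lambda) * stats::pnorm((levels - alpha) / beta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(ifelse(responses, log(p), log(1 - p)))
  }
  start <- c(stats::median(levels), log(stats::sd(levels) + 0.1))
  fit <- stats::optim(start, nll, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  list(alpha = fit$par[1], beta = exp(fit$par[2]), logLik = -fit$value,
       converged = fit$convergence == 0)
}

#' Simulate many QUEST sessions and evaluate staircase calibration
#'
#' Runs replicate sessions against one observer and evaluates the
#' observer's *true* percent-correct at each final estimate — the standard
#' convergence check that the staircase homes in on its design point
#' (75% for 2AFC, 62.5% for 4AFC).
#'
#' @param obs An [observer()].
#' @param cfg A [session_config()].
#' @param n_sessions Number of replicate sessions.
#' @param seed Integer master seed (per-session seeds derived from it).
#' @return Tibble with one row per session: `session`, `estimate`,
#'   `true_p` (probability correct at the estimate).
#' @export
simulate_quest_calibration <- function(obs, cfg = session_config(),
                                       n_sessions = 200, seed = 1) {
  seeds <- derive_seeds(seed, n_sessions)
  purrr::map_dfr(seq_len(n_sessions), function(i) {
    est <- run_session(obs, cfg, seed = seeds[i])$estimate
    tibble::tibble(session = i, estimate = est,
                   true_p = psychometric_p(obs, est))
  })
}

# deterministic per-task seed splitting from one master seed (kept < 2^31)
derive_seeds <- function(seed, n) {
  (as.double(seed) * 48271 + 1664525 * seq_len(n)) %% 2147483647
}
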