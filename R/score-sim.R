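#' Simulate a threshold score table with known reliability structure
#'
#' Generates a long-format score table (participant x method x test x
#' repetition) from a latent common-factor model, so that the statistics
#' battery can be exercised against known targets. For each test `t`,
#' participant `i` has a stable latent trait
#' `u_it = loading_t * g_i + sqrt(1 - loading_t^2) * s_it`
#' (`g` a shared factor, `s` test-specific, both standard normal), and each
#' repetition observes `u_it` plus occasion noise with variance
#' `(1 - icc_t) / icc_t`, which makes the expected ICC of test `t` equal to
#' `icc_t`. The between-test target applies to repetition-averaged scores
#' (what the correlation battery correlates): loadings are
#' `sqrt(rho_pearson * (1 + occ_var_t / n_repetitions))`, which exactly
#' undoes the attenuation caused by occasion noise, with the Pearson
#' correlation derived from the target Spearman via the Gaussian
#' rank-correlation identity `rho_pearson = 2 * sin(pi * rho_s / 6)`.
#' Scores are affine-mapped to per-test means/SDs; affine maps leave both
#' ICC and Spearman intact.
#'
#' @param n_participants Number of participants (default 35).
#' @param tests Character vector of test names.
#' @param methods Character vector of method names.
#' @param icc_targets Named (by test) or scalar target ICC(3,1) in (0, 1].
#' @param rho_target Target between-test Spearman correlation in [0, 1).
#' @param n_repetitions Repetitions per test (default 2).
#' @param score_mean,score_sd Named (by test) or scalar affine map of the
#'   latent scale onto score units.
#' @param invalid_rate Probability that any single score is marked invalid.
#' @param seed Integer seed.
#' @return A tibble with columns `participant`, `method`, `test`,
#'   `repetition`, `score`, `valid`.
#' @examples
#' st <- simulate_score_table(12, seed = 1)
#' dplyr::count(st, method, test)
#' @export
simulate_score_table <- function(n_participants = 35,
                                 tests = c("contrast", "spatial_frequency", "orientation"),
                                 methods = c("psychophysics", "eeg"),
                                 icc_targets = 0.75, rho_target = 0.4,
                                 n_repetitions = 2,
                                 score_mean = 0, score_sd = 1,
                                 invalid_rate = 0, seed = 1) {
  if (any(icc_targets <= 0) || any(icc_targets > 1)) {
    stop("icc_targets must lie in (0, 1]")
  }
  if (rho_target < 0 || rho_target >= 1) {
    stop("rho_target must lie in [0, 1)")
  }
  rho_pearson <- 2 * sin(pi * rho_target / 6)
  icc <- expand_by(icc_targets, tests)
  mu <- expand_by(score_mean, tests)
  sd_ <- expand_by(score_sd, tests)
  occ_var <- lapply(icc, function(v) (1 - v) / v)
  loading <- lapply(occ_var, function(o) {
    l2 <- rho_pearson * (1 + o / n_repetitions)
    if (l2 > 1) stop("requested correlation structure is not positive definite ",
                     "(rho_target too high for the given icc_targets)")
    sqrt(l2)
  })

  set.seed(as.integer(seed))
  out <- list()
  for (m in methods) {
    g <- stats::rnorm(n_participants)
    for (t in tests) {
      l <- loading[[t]]
      u <- l * g + sqrt(1 - l^2) * stats::rnorm(n_participants)
      occ_sd <- sqrt(occ_var[[t]])
      for (r in seq_len(n_repetitions)) {
        score <- mu[[t]] + sd_[[t]] * (u + occ_sd * stats::rnorm(n_participants))
        out[[length(out) + 1L]] <- tibble::tibble(
          participant = seq_len(n_participants),
          method = m, test = t, repetition = r,
          score = score,
          valid = stats::runif(n_participants) >= invalid_rate
        )
      }
    }
  }
  dplyr::arrange(dplyr::bind_rows(out),
                 .data$participant, .data$method, .data$test, .data$repetition)
}

expand_by <- function(x, tests) {
  if (is.null(names(x))) {
    stats::setNames(as.list(rep_len(x, length(tests))), tests)
  } else {
    if (!all(tests %in% names(x))) stop("missing names for tests: ",
                                        paste(setdiff(tests, names(x)), collapse = ", "))
    as.list(x[tests])
  }
}
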