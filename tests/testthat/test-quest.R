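test_that("observer psychometric function has the right asymptotes and midpoint", {
  obs <- observer(alpha = 0.5, beta = 0.2, gamma = 0.5, lambda = 0)
  expect_equal(psychometric_p(obs, -1e3), 0.5)
  expect_equal(psychometric_p(obs, 1e3), 1)
  # at alpha the 2AFC observer is at 75% by construction
  expect_equal(psychometric_p(obs, 0.5), 0.75)
  obs4 <- observer(alpha = 0, beta = 0.2, gamma = 0.25, lambda = 0)
  expect_equal(psychometric_p(obs4, 0), 0.625)
  lapse <- observer(alpha = 0, beta = 0.2, gamma = 0.5, lambda = 0.1)
  expect_equal(psychometric_p(lapse, 1e3), 0.9)
  expect_error(simulate_observer_response(obs, Inf), "finite")
  expect_error(observer(0, -1), "beta")
})

test_that("quest prior is normalised, centred, and checks grid coverage", {
  st <- quest_init(session_config())
  expect_equal(sum(exp(st$log_posterior)), 1, tolerance = 1e-9)
  expect_equal(glance(st)$estimate, 0, tolerance = 1e-9)
  expect_equal(quest_next(st), 0, tolerance = 1e-9)   # prior mean before data
  expect_error(
    quest_init(session_config(initial_level = 0, prior_sd = 2,
                              level_bounds = c(-3, 3))),
    "cover"
  )
})

test_that("updates follow Bayes rule against a direct-summation oracle", {
  cfg <- session_config()
  st <- quest_init(cfg)
  levels <- c(0.4, -0.2, 0.1, 0.6)
  responses <- c(TRUE, FALSE, TRUE, TRUE)
  for (i in seq_along(levels)) st <- quest_update(st, levels[i], responses[i])
  expect_equal(sum(exp(st$log_posterior)), 1, tolerance = 1e-9)

  # oracle: direct product of prior and likelihood terms over the grid
  grid <- st$grid
  post <- dnorm(grid, cfg$initial_level, cfg$prior_sd)
  for (i in seq_along(levels)) {
    pc <- cfg$gamma + (1 - cfg$gamma - cfg$assumed_lambda) *
      pnorm((levels[i] - grid) / cfg$assumed_beta)
    post <- post * (if (responses[i]) pc else 1 - pc)
  }
  post <- post / sum(post)
  expect_equal(exp(st$log_posterior), post, tolerance = 1e-9)
})

test_that("posterior drifts below a level that keeps being answered correctly", {
  st <- quest_init(session_config())
  for (i in 1:25) st <- quest_update(st, 0.5, TRUE)
  expect_lt(glance(st)$estimate, 0.5)
  # an uninformative likelihood leaves the posterior unchanged
  flat_cfg <- session_config(assumed_lambda = 0.4999)
  st2 <- quest_init(flat_cfg)
  before <- st2$log_posterior
  st2 <- quest_update(st2, 0.5, TRUE)
  expect_equal(st2$log_posterior, before, tolerance = 1e-3)
})

test_that("proposed levels respect bounds and the minimum testable value", {
  cfg <- session_config(initial_level = 0, min_testable = 0.25,
                        level_bounds = c(-5, 5))
  st <- quest_init(cfg)
  # posterior mass far below the floor still proposes the floor
  for (i in 1:30) st <- quest_update(st, 0.3, TRUE)
  expect_lt(glance(st)$estimate, 0.25)
  expect_equal(quest_next(st), 0.25)
})

test_that("sessions are reproducible and converge in the no-noise limit", {
  obs <- observer(alpha = -0.4, beta = 0.2, gamma = 0.5)
  cfg <- session_config(n_trials = 30, initial_level = 0.2,
                        level_bounds = c(-6, 6))
  a <- run_session(obs, cfg, seed = 5)
  b <- run_session(obs, cfg, seed = 5)
  expect_identical(a$trials, b$trials)
  expect_identical(a$estimate, b$estimate)

  # near-deterministic observer pins the estimate to alpha
  sharp <- observer(alpha = 0.8, beta = 1e-4, gamma = 0.5)
  cfg2 <- session_config(n_trials = 60, initial_level = 0.5,
                         level_bounds = c(-6, 6), assumed_beta = 0.1)
  est <- run_session(sharp, cfg2, seed = 3)$estimate
  expect_equal(est, 0.8, tolerance = 0.1)

  mismatched <- observer(alpha = 0, beta = 0.2, gamma = 0.25)
  expect_error(run_session(mismatched, cfg, seed = 1), "guess rate")
})

test_that("cumulative-Gaussian fit recovers parameters and rejects degenerate data", {
  set.seed(31)
  obs <- observer(alpha = 1, beta = 0.2, gamma = 0.5, lambda = 0)
  levels <- runif(2000, 0, 2)
  responses <- runif(2000) < psychometric_p(obs, levels)
  fit <- fit_psychometric(levels, responses, gamma = 0.5, lambda = 0)
  expect_equal(fit$alpha, 1, tolerance = 0.05)
  expect_equal(fit$beta, 0.2, tolerance = 0.05)
  # by construction the fitted curve passes 75% at alpha
  p_at_alpha <- 0.5 + 0.5 * pnorm(0)
  expect_equal(p_at_alpha, 0.75)

  expect_error(fit_psychometric(levels, rep(TRUE, 2000), 0.5), "both correct")
  expect_error(fit_psychometric(rep(1, 10), rep(c(TRUE, FALSE), 5), 0.5),
               "distinct")
})
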