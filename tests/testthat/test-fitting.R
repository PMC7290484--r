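test_that("log posterior is the likelihood plus independent prior terms", {
  cfg <- task_config()
  log3 <- three_trial_log(cfg)
  priors <- prior_spec()
  ap <- agent_params(.6, .7, 3, .4, .1)
  naive <- session_loglik(ap, log3, cfg) +
    dbeta(.6, 2, 2, log = TRUE) + dbeta(.7, 2, 2, log = TRUE) +
    dgamma(3, shape = 3, scale = 2, log = TRUE) +
    dbeta(.4, 2, 2, log = TRUE) + dnorm(.1, 0, 1, log = TRUE)
  expect_equal(log_posterior(ap, log3, priors, cfg), naive,
               tolerance = 1e-12)

  # flat priors: posterior differs from likelihood by a params-free constant
  fp <- flat_priors()
  offs <- sapply(list(c(.2, .3, 1, .5, -.4), c(.9, .9, 7, .1, .3)),
                 function(v) {
                   a <- agent_params(v[1], v[2], v[3], v[4], v[5])
                   log_posterior(a, log3, fp, cfg) -
                     session_loglik(a, log3, cfg)
                 })
  expect_equal(offs[1], offs[2], tolerance = 1e-6)
  expect_identical(log_posterior(c(-0.1, .5, 1, .5, 0), log3, fp, cfg),
                   -Inf)
})

test_that("bic reproduces its closed form", {
  expect_equal(bic(500 * log(0.5), 5, 500),
               -2 * 500 * log(0.5) + 5 * log(500))
  expect_equal(round(bic(500 * log(0.5), 5, 500), 2), 724.22)
  expect_equal(bic(-123.4, 0, 77), 246.8)
  for (i in 1:10) {
    ll <- -runif(1, 10, 500); k <- sample(1:6, 1); n <- sample(10:1000, 1)
    expect_equal(bic(ll, k, n), -2 * ll + k * log(n))
  }
})

test_that("MAP fitting is deterministic and beats a coarse grid", {
  cfg <- task_config()
  walk <- cached_default_walk()
  truth <- agent_params(.85, .9, 5, .5, .15)
  s <- simulate_session(truth, walk, cfg, seed = 31)
  f1 <- fit_map(s, seed = 4, n_restarts = 4)
  f2 <- fit_map(s, seed = 4, n_restarts = 4)
  expect_identical(f1, f2)
  expect_lte(f1$log_likelihood, 0)
  expect_equal(f1$bic, bic(f1$log_likelihood, 5, f1$n_obs))
  expect_equal(f1$n_obs, 500L)

  # 5-point-per-axis grid oracle on the same posterior
  grid_axis <- c(.1, .3, .5, .7, .9)
  best_grid <- -Inf
  priors <- prior_spec()
  for (om in grid_axis) for (al in grid_axis) for (be in grid_axis * 10)
    for (la in grid_axis) for (p in grid_axis - 0.5) {
      lp <- log_posterior(c(om, al, be, la, p), s, priors, cfg)
      if (lp > best_grid) best_grid <- lp
    }
  expect_gte(f1$log_posterior, best_grid)
})

test_that("a tight prior pulls weakly informed estimates towards its
           center", {
  cfg <- task_config()
  walk <- cached_default_walk()
  s <- simulate_session(agent_params(.5, .5, 0.3, .5, 0), walk, cfg,
                        seed = 11)  # nearly random data: weak likelihood
  tight <- prior_spec(omega = c(300, 700))  # concentrated near 0.3
  f <- fit_map(s, priors = tight, seed = 2, n_restarts = 4)
  expect_lt(abs(f$params_hat$omega - 0.3), 0.05)
  loose <- prior_spec(omega = c(3, 7))
  f2 <- fit_map(s, priors = loose, seed = 2, n_restarts = 4)
  expect_gt(abs(f2$params_hat$omega - 0.3), abs(f$params_hat$omega - 0.3) - 0.01)
})

test_that("fitting refuses sessions with too few completed trials", {
  cfg <- task_config(n_trials = 30, n_blocks = 1)
  walk <- generate_reward_walk(cfg, seed = 1)
  s <- simulate_session(agent_params(.8, .9, 5, .5, .1), walk, cfg, seed = 1)
  expect_error(fit_map(s, config = cfg), "at least 50")
})

test_that("optimal choice rates hit their analytic limits", {
  cfg <- task_config()
  walk <- cached_default_walk()
  # near-argmax agent refit on its own data: rate close to 1 at stage 2
  det <- agent_params(.9, .9, 60, .5, 0)
  s <- simulate_session(det, walk, cfg, seed = 5)
  fit <- structure(list(params_hat = det, q_init = 0.5),
                   class = "twostep_fit")
  expect_gt(optimal_choice_rate(s, fit, cfg, stage = 1L), 0.95)
  expect_gt(optimal_choice_rate(s, fit, cfg, stage = 2L), 0.95)

  # random agent: rate near one half under any replay parameters
  rnd <- simulate_session(agent_params(.5, .5, 0, .5, 0), walk, cfg,
                          seed = 6)
  fit_r <- structure(list(params_hat = agent_params(.8, .9, 5, .5, .1),
                          q_init = 0.5), class = "twostep_fit")
  expect_lt(abs(optimal_choice_rate(rnd, fit_r, cfg, 2L) - 0.5), 0.08)
})

test_that("fit results serialize to CSV", {
  cfg <- task_config()
  walk <- cached_default_walk()
  s <- simulate_session(agent_params(.8, .9, 5, .5, .1), walk, cfg, seed = 9)
  f <- fit_map(s, seed = 1, n_restarts = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  out <- write_fit_results(list(f), data.frame(subject_id = "S01"), path)
  back <- read.csv(path)
  expect_equal(back$bic, f$bic, tolerance = 1e-9)
  expect_equal(back$omega, f$params_hat$omega, tolerance = 1e-9)
})
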