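test_that("parameter and value-table constructors validate their inputs", {
  expect_error(agent_params(1.2, .5, 1, .5, 0), "omega")
  expect_error(agent_params(.5, .5, -1, .5, 0), "beta")
  q <- initialize_q(task_config(), init_value = 0)
  expect_true(all(q$q_mf_stage1 == 0) && all(q$q_mf_stage2 == 0))
  q5 <- initialize_q(task_config())
  # equal values: uniform softmax at both stages, equal model-based values
  expect_equal(choice_probabilities(q5$q_mf_stage1, beta = 3), c(.5, .5))
  expect_equal(model_based_values(q5, task_config()), c(0.5, 0.5))
})

test_that("model-based values implement the transition-weighted maximum", {
  cfg <- task_config()
  q <- initialize_q(cfg, 0)
  q$q_mf_stage2 <- rbind(c(1, 0), c(0, 0))
  expect_equal(model_based_values(q, cfg), c(0.8, 0.2))

  q$q_mf_stage2 <- rbind(c(0.3, 0.7), c(0.2, 0.9))
  got <- model_based_values(q, cfg)
  expect_equal(got, c(0.8 * 0.7 + 0.2 * 0.9, 0.8 * 0.9 + 0.2 * 0.7))
})

test_that("softmax probabilities are exact, stable, and shift-invariant", {
  expect_equal(choice_probabilities(c(5, -3), beta = 0), c(.5, .5))
  expect_equal(choice_probabilities(c(1, 0), beta = 500), c(1, 0),
               tolerance = 1e-12)
  expect_equal(
    choice_probabilities(c(0, 0), beta = 1, pi = log(3), prev_choice = 0),
    c(0.75, 0.25))
  v <- c(0.2, 0.9)
  expect_equal(choice_probabilities(v, 2.5, 0.3, prev_choice = 1),
               choice_probabilities(v + 17, 2.5, 0.3, prev_choice = 1))
  expect_equal(sum(choice_probabilities(c(1e4, 0), beta = 100)), 1)
})

test_that("the SARSA(lambda) update matches hand evaluation", {
  cfg <- task_config()
  trial <- list(s1_choice = 0L, s2_state = 0L, s2_choice = 1L,
                points = 5L, timeout = FALSE)

  # alpha = 0: only the perseveration memory moves
  q <- initialize_q(cfg, 0.5)
  q0 <- update_after_trial(q, trial, agent_params(.5, 0, 1, .5, 0), cfg)
  expect_equal(q0$q_mf_stage1, q$q_mf_stage1)
  expect_equal(q0$q_mf_stage2, q$q_mf_stage2)
  expect_identical(q0$prev_first_choice, 0L)

  # alpha = 1, lambda = 1, all Q at 0, normalized r = 1
  q <- initialize_q(cfg, 0)
  q1 <- update_after_trial(q, list(s1_choice = 0L, s2_state = 0L,
                                   s2_choice = 1L, points = 5L,
                                   timeout = FALSE),
                           agent_params(.5, 1, 1, 1, 0), cfg)
  expect_equal(q1$q_mf_stage2[1, 2], 1)
  expect_equal(q1$q_mf_stage1[1], 1)  # 0 + 1*(0-0) + 1*1*(1-0)

  # timeout: untouched
  qt <- update_after_trial(q, list(s1_choice = NA, s2_state = NA,
                                   s2_choice = NA, points = NA,
                                   timeout = TRUE),
                           agent_params(.5, 1, 1, 1, 0), cfg)
  expect_identical(qt, q)
})

test_that("repeated constant reward converges the stage-2 value
           geometrically", {
  cfg <- task_config()
  params <- agent_params(.5, 0.3, 1, .5, 0)
  q <- initialize_q(cfg, 0)
  trial <- list(s1_choice = 0L, s2_state = 0L, s2_choice = 0L,
                points = 5L, timeout = FALSE)
  r_star <- (5 - cfg$points_min) / (cfg$points_max - cfg$points_min)
  errs <- numeric(30)
  for (i in 1:30) {
    q <- update_after_trial(q, trial, params, cfg)
    errs[i] <- abs(q$q_mf_stage2[1, 1] - r_star)
  }
  expect_equal(errs, r_star * 0.7^(1:30), tolerance = 1e-12)
})

test_that("session log-likelihood matches an independently unrolled
           computation", {
  cfg <- task_config()
  log3 <- three_trial_log(cfg)
  for (pars in list(c(.6, .4, 2.5, .3, .2), c(1, .9, 6, .8, -.4),
                    c(0, .2, 1, 0, 0.5))) {
    ap <- agent_params(pars[1], pars[2], pars[3], pars[4], pars[5])
    expect_equal(session_loglik(ap, log3, cfg),
                 oracle_loglik(pars[1], pars[2], pars[3], pars[4], pars[5],
                               log3),
                 tolerance = 1e-12)
  }
  # longer simulated session against the oracle as well
  walk <- cached_default_walk()
  ap <- agent_params(.7, .6, 3, .4, .15)
  s <- simulate_session(ap, walk, cfg, seed = 77)
  expect_equal(session_loglik(ap, s, cfg),
               oracle_loglik(.7, .6, 3, .4, .15, s), tolerance = 1e-10)
})

test_that("beta = 0 yields the uniform-choice likelihood and timeouts are
           skipped", {
  cfg <- task_config()
  walk <- cached_default_walk()
  s <- simulate_session(agent_params(.8, .9, 5, .5, .1), walk, cfg, seed = 3)
  unif <- agent_params(.5, .5, 0, .5, 0)
  expect_equal(session_loglik(unif, s, cfg), 2 * 250 * log(0.5))

  s$timeout[10] <- TRUE
  expect_equal(session_loglik(unif, s, cfg), 2 * 249 * log(0.5))
})

test_that("the generating parameters win a coarse likelihood grid", {
  cfg <- task_config()
  walk <- cached_default_walk()
  truth <- agent_params(.9, .8, 6, .5, .1)
  lls <- sapply(1:20, function(i)
    session_loglik(truth, simulate_session(truth, walk, cfg, seed = 100 + i),
                   cfg))
  for (om in c(.1, .5)) {
    other <- agent_params(om, .4, 2, .5, .1)
    lls_o <- sapply(1:20, function(i)
      session_loglik(other,
                     simulate_session(truth, walk, cfg, seed = 100 + i),
                     cfg))
    expect_gt(mean(lls), mean(lls_o))
  }
})

test_that("simulated choice frequencies agree with replay probabilities", {
  cfg <- task_config(n_trials = 5000, n_blocks = 1)
  walk <- generate_reward_walk(cfg, seed = 8)
  ap <- agent_params(.7, .7, 3, .5, .2)
  s <- simulate_session(ap, walk, cfg, seed = 21)
  rep_out <- replay_session(ap, s, cfg)
  # mean assigned probability of choosing option 0 tracks its frequency
  expect_equal(mean(rep_out$p_stage1[, 1]), mean(s$s1_choice == 0),
               tolerance = 0.03)
  expect_equal(mean(rep_out$p_stage2[, 1]), mean(s$s2_choice == 0),
               tolerance = 0.03)
  expect_equal(rowSums(rep_out$p_stage1), rep(1, 5000), tolerance = 1e-12)
})

test_that("net values interpolate linearly in omega", {
  cfg <- task_config()
  log3 <- three_trial_log(cfg)
  qn <- function(om) {
    replay_session(agent_params(om, .5, 2, .5, 0), log3, cfg)$q_net[1, ]
  }
  expect_equal(qn(0.5), 0.5 * qn(0) + 0.5 * qn(1), tolerance = 1e-12)
  expect_equal(qn(0.3), 0.7 * qn(0) + 0.3 * qn(1), tolerance = 1e-12)
})

test_that("stay patterns separate model-based from model-free agents", {
  cfg <- task_config()
  walk <- cached_default_walk()
  cells_of <- function(params, seeds) {
    m <- sapply(seeds, function(sd) {
      st <- stay_probabilities(simulate_session(params, walk, cfg, sd))
      st$stay_prob
    })
    rowMeans(m, na.rm = TRUE)  # win_common, win_rare, loss_common, loss_rare
  }
  mb <- cells_of(agent_params(1, .9, 8, .5, 0), 1:40)
  # crossover: stays after common-win and rare-loss exceed rare-win and
  # common-loss
  expect_gt(mb[1], mb[2])
  expect_gt(mb[4], mb[3])

  mf <- cells_of(agent_params(0, .9, 8, 1, 0), 41:80)
  # pure reinforcement: wins retain, losses repel, regardless of transition
  expect_gt(mean(mf[1:2]), mean(mf[3:4]))

  rand <- cells_of(agent_params(.5, .5, 0, .5, 0), 81:100)
  expect_true(all(abs(rand - 0.5) < 0.08))
})
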