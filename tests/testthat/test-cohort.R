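small_design <- function(...) {
  cohort_design(n_subjects = 6L, seed = 5L, ...)
}

test_that("cohort generation is deterministic, balanced, and respects
           parameter bounds", {
  cfg <- task_config()
  walk <- cached_default_walk()
  d <- small_design()
  c1 <- generate_cohort(d, cfg, walk)
  c2 <- generate_cohort(d, cfg, walk)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$sessions[[3]]$s1_choice, c2$sessions[[3]]$s1_choice)

  expect_equal(sum(c1$subjects$order == "sober_first"), 3L)
  expect_equal(nrow(c1$truth), 12L)
  expect_true(all(c1$truth$omega >= 0 & c1$truth$omega <= 1))
  expect_true(all(c1$truth$alpha >= 0 & c1$truth$alpha <= 1))
  expect_true(all(c1$truth$lambda >= 0 & c1$truth$lambda <= 1))
  expect_true(all(c1$truth$beta >= 0))
  expect_true(all(c1$subjects$audit >= 2 & c1$subjects$audit <= 19))
})

test_that("the default population approximates the target parameter
           quartiles", {
  set.seed(2)
  pop <- default_param_population()
  draws <- sapply(c("omega", "alpha", "beta", "lambda", "pi"), function(p)
    twostepr:::draw_population_param(pop[[p]], 20000))
  q <- apply(draws, 2, quantile, probs = c(.25, .5, .75))
  expect_equal(unname(q[2, "omega"]), 0.83, tolerance = 0.05)
  expect_equal(unname(q[2, "alpha"]), 0.89, tolerance = 0.05)
  expect_equal(unname(q[2, "beta"]), 4.70, tolerance = 0.25)
  expect_equal(unname(q[2, "pi"]), 0.16, tolerance = 0.02)
  expect_true(q[1, "omega"] > 0.55 && q[3, "omega"] < 0.99)
})

test_that("a null cohort has exchangeable sessions; an omega shift
           depresses hungover MB-scores", {
  cfg <- task_config()
  walk <- cached_default_walk()
  null_d <- cohort_design(n_subjects = 20L, seed = 8L)
  coh <- generate_cohort(null_d, cfg, walk)
  tab <- score_table(coh$sessions)
  diff_null <- mean(tab$mb_score[tab$session == "sober"]) -
    mean(tab$mb_score[tab$session == "hungover"])
  expect_lt(abs(diff_null), 0.25)

  shift_d <- cohort_design(n_subjects = 20L, seed = 8L,
                           session_effect = c(omega = -0.7))
  coh2 <- generate_cohort(shift_d, cfg, walk)
  tab2 <- score_table(coh2$sessions)
  diff_shift <- mean(tab2$mb_score[tab2$session == "sober"]) -
    mean(tab2$mb_score[tab2$session == "hungover"])
  expect_gt(diff_shift, 0.15)
  # the hungover truth actually carries the shift
  tr <- coh2$truth
  expect_true(all(tr$omega[tr$session == "hungover"] <=
                    tr$omega[tr$session == "sober"]))
})

test_that("cohort stay-cell means agree with the model's replay
           probabilities", {
  cfg <- task_config()
  walk <- cached_default_walk()
  d <- cohort_design(n_subjects = 10L, seed = 3L)
  coh <- generate_cohort(d, cfg, walk)
  # mean stay frequency vs mean replayed stage-1 repeat probability
  freq <- prob <- numeric(0)
  for (key in names(coh$sessions)) {
    ses <- coh$sessions[[key]]
    tr <- coh$truth[paste(coh$truth$subject_id, coh$truth$session,
                          sep = ".") == key, ]
    ap <- agent_params(tr$omega, tr$alpha, tr$beta, tr$lambda, tr$pi)
    rp <- replay_session(ap, ses, cfg)
    n <- nrow(ses)
    stay_obs <- ses$s1_choice[-1] == ses$s1_choice[-n]
    p_stay <- rp$p_stage1[cbind(2:n, ses$s1_choice[-n] + 1L)]
    freq <- c(freq, mean(stay_obs))
    prob <- c(prob, mean(p_stay))
  }
  expect_equal(mean(freq), mean(prob), tolerance = 0.03)
})

test_that("a small recovery study is reproducible and tracks strong
           parameters", {
  cfg <- task_config()
  walk <- cached_default_walk()
  d <- cohort_design(n_subjects = 8L, seed = 21L)
  r1 <- recovery_study(d, cfg, walk, n_restarts = 3L, seed = 2L,
                       sessions = "sober")
  r2 <- recovery_study(d, cfg, walk, n_restarts = 3L, seed = 2L,
                       sessions = "sober")
  expect_identical(r1$per_parameter, r2$per_parameter)
  expect_equal(nrow(r1$recovered), 8L)
  expect_true(all(abs(r1$per_parameter$spearman) <= 1))
  expect_gt(r1$per_parameter$spearman[
    r1$per_parameter$parameter == "omega"], 0)
})

test_that("the detection-rate curve saturates for extreme omega shifts", {
  cfg <- task_config()
  walk <- cached_default_walk()
  d <- cohort_design(n_subjects = 8L, seed = 13L,
                     param_population = modifyList(
                       default_param_population(),
                       list(omega = list(dist = "fixed", par = c(0.95)),
                            beta = list(dist = "fixed", par = c(8)))))
  pc <- power_curve(d, cfg, walk, effect_grid = c(0.9),
                    n_replicates = 2L, seed = 4L, n_restarts = 2L)
  expect_equal(pc$detection_rate_t, 1)
  expect_equal(pc$detection_rate_bf, 1)
})
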