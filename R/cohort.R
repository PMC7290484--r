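#' Design of a synthetic crossover cohort
#'
#' Describes a balanced two-session (sober/hungover) crossover study whose
#' subjects are hybrid agents with parameters drawn from a population
#' distribution. The defaults centre each parameter on the sober-session
#' population medians (omega 0.83, alpha 0.89, beta 4.70, lambda 0.48,
#' pi 0.16) with dispersions chosen so the sampled quartiles approximate
#' the observed interquartile ranges. A `session_effect` shifts each
#' parameter additively in the hungover session; the all-zero default is
#' the null world in which the two sessions are exchangeable.
#'
#' @param n_subjects Even integer >= 2 (default 25 is rounded up to 26
#'   only if `require_balance = TRUE`; the default keeps 25 and balances
#'   12/13).
#' @param param_population Named list of per-parameter sampling rules,
#'   each `list(dist, par)` with `dist` one of `"beta"`, `"lnorm"`,
#'   `"norm"`, `"fixed"`.
#' @param session_effect Named numeric vector of additive hungover shifts
#'   on `omega`, `alpha`, `beta`, `lambda`, `pi` (default all zero).
#'   Shifted values are clamped to the parameter bounds.
#' @param rt_model List with `meanlog1`, `meanlog2`, `sdlog`: lognormal
#'   response-time parameters (defaults give means near 491 and 585 ms).
#' @param seed Integer seed used by [generate_cohort()].
#' @return An object of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 25L,
                          param_population = default_param_population(),
                          session_effect = c(omega = 0, alpha = 0, beta = 0,
                                             lambda = 0, pi = 0),
                          rt_model = list(meanlog1 = log(491) - 0.03125,
                                          meanlog2 = log(585) - 0.03125,
                                          sdlog = 0.25),
                          seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L) stop("n_subjects must be >= 2")
  stopifnot(all(param_names %in% names(param_population)))
  eff <- c(omega = 0, alpha = 0, beta = 0, lambda = 0, pi = 0)
  eff[names(session_effect)] <- session_effect
  structure(list(n_subjects = n_subjects,
                 param_population = param_population,
                 session_effect = eff,
                 rt_model = rt_model,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

#' @rdname cohort_design
#' @export
default_param_population <- function() {
  list(
    omega = list(dist = "beta", par = c(4, 1)),
    alpha = list(dist = "beta", par = c(6, 1)),
    beta = list(dist = "lnorm", par = c(log(4.70), 0.35)),
    lambda = list(dist = "beta", par = c(0.7, 0.75)),
    pi = list(dist = "norm", par = c(0.16, 0.06))
  )
}

draw_population_param <- function(rule, n) {
  switch(rule$dist,
         beta = rbeta(n, rule$par[1], rule$par[2]),
         lnorm = rlnorm(n, rule$par[1], rule$par[2]),
         norm = rnorm(n, rule$par[1], rule$par[2]),
         fixed = rep(rule$par[1], n),
         stop("unknown population distribution: ", rule$dist))
}

clamp_params <- function(v) {
  c(omega = min(max(v[["omega"]], 0), 1),
    alpha = min(max(v[["alpha"]], 0), 1),
    beta = max(v[["beta"]], 0),
    lambda = min(max(v[["lambda"]], 0), 1),
    pi = v[["pi"]])
}

#' Generate a full synthetic crossover study
#'
#' For each subject, draws true parameters from the population (the
#' hungover session adds the design's `session_effect`), simulates one
#' session per condition on the shared reward walk, attaches lognormal
#' response times, assigns balanced session orders (half sober-first), and
#' draws a synthetic AUDIT-like covariate. Deterministic given
#' `design$seed`.
#'
#' @param design A [cohort_design()].
#' @param config A [task_config()].
#' @param walk A `twostep_walk` shared by all subjects and sessions.
#' @return An object of class `twostep_cohort`: `subjects` (id, order,
#'   audit), `truth` (one row per subject x session with the generating
#'   parameters), `sessions` (named list of `twostep_session`), and the
#'   design and seed echo.
#' @export
generate_cohort <- function(design, config, walk) {
  stopifnot(inherits(design, "cohort_design"), inherits(walk, "twostep_walk"))
  validate_task_config(config)
  n <- design$n_subjects
  set.seed(design$seed)
  pop <- design$param_population
  base <- sapply(param_names, function(p)
    draw_population_param(pop[[p]], n))
  base <- matrix(base, nrow = n, dimnames = list(NULL, param_names))
  audit <- pmin(pmax(round(rnorm(n, 10.1, 2.8)), 2), 19)
  rt_seed_base <- sample.int(2^30, 1L)
  sim_seed_base <- sample.int(2^30, 1L)

  order <- rep(c("sober_first", "hungover_first"), length.out = n)
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n)),
    order = order, audit = audit, stringsAsFactors = FALSE)

  truth <- list()
  sessions <- list()
  for (i in seq_len(n)) {
    for (sess in c("sober", "hungover")) {
      v <- base[i, ]
      if (sess == "hungover") v <- v + design$session_effect
      v <- clamp_params(v)
      params <- agent_params(v[["omega"]], v[["alpha"]], v[["beta"]],
                             v[["lambda"]], v[["pi"]])
      sim_seed <- (sim_seed_base + 2L * i +
                     (sess == "hungover")) %% .Machine$integer.max
      dat <- simulate_session(params, walk, config, seed = sim_seed,
                              subject_id = subjects$subject_id[i],
                              session = sess)
      set.seed((rt_seed_base + 2L * i +
                  (sess == "hungover")) %% .Machine$integer.max)
      dat$rt1_ms <- rlnorm(nrow(dat), design$rt_model$meanlog1,
                           design$rt_model$sdlog)
      dat$rt2_ms <- rlnorm(nrow(dat), design$rt_model$meanlog2,
                           design$rt_model$sdlog)
      key <- paste(subjects$subject_id[i], sess, sep = ".")
      sessions[[key]] <- dat
      truth[[key]] <- data.frame(
        subject_id = subjects$subject_id[i], session = sess,
        omega = v[["omega"]], alpha = v[["alpha"]], beta = v[["beta"]],
        lambda = v[["lambda"]], pi = v[["pi"]], stringsAsFactors = FALSE)
    }
  }
  structure(list(subjects = subjects,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE)),
                 sessions = sessions,
                 design = design,
                 seed = design$seed),
            class = "twostep_cohort")
}

#' @export
print.twostep_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic crossover cohort: %d subjects x 2 sessions (seed %d)\n",
    x$design$n_subjects, x$seed))
  invisible(x)
}

#' Fit every session of a cohort
#'
#' @param cohort A `twostep_cohort`.
#' @param config A [task_config()].
#' @param priors A [prior_spec()].
#' @param n_restarts Restarts per fit (default 10).
#' @param seed Base seed; each fit uses a distinct derived seed.
#' @return A named list of `twostep_fit`, parallel to `cohort$sessions`.
#' @export
fit_cohort <- function(cohort, config, priors = prior_spec(),
                       n_restarts = 10L, seed = 1L) {
  stopifnot(inherits(cohort, "twostep_cohort"))
  keys <- names(cohort$sessions)
  fits <- vector("list", length(keys))
  names(fits) <- keys
  for (k in seq_along(keys)) {
    fits[[k]] <- fit_map(cohort$sessions[[keys[k]]], priors, config,
                         n_restarts = n_restarts,
                         seed = (seed + 7L * k) %% .Machine$integer.max)
  }
  fits
}

fits_to_frame <- function(fits) {
  keys <- names(fits)
  do.call(rbind, lapply(seq_along(fits), function(k) {
    parts <- strsplit(keys[k], ".", fixed = TRUE)[[1]]
    p <- fits[[k]]$params_hat
    data.frame(subject_id = parts[1], session = parts[2],
               omega = p$omega, alpha = p$alpha, beta = p$beta,
               lambda = p$lambda, pi = p$pi,
               bic = fits[[k]]$bic,
               log_likelihood = fits[[k]]$log_likelihood,
               optimal_choice_rate_stage1 =
                 fits[[k]]$optimal_choice_rate_stage1,
               optimal_choice_rate_stage2 =
                 fits[[k]]$optimal_choice_rate_stage2,
               stringsAsFactors = FALSE)
  }))
}

#' Parameter-recovery study
#'
#' Generates a synthetic cohort, fits every subject-session by MAP, and
#' compares recovered to generating parameters: Spearman rank correlation,
#' mean bias (recovered minus true) and RMSE per parameter. This is the
#' pipeline's primary validation surface.
#'
#' @param design A [cohort_design()].
#' @param config A [task_config()].
#' @param walk A `twostep_walk`; defaults to a fresh walk from the seed.
#' @param priors A [prior_spec()].
#' @param n_restarts Restarts per fit.
#' @param seed Integer seed (controls the walk default and the fits).
#' @param sessions Which sessions to fit (default both).
#' @return An object of class `recovery_report`: `per_parameter` data
#'   frame (spearman, bias, rmse), `truth`, `recovered`, `design`, `seed`.
#' @export
recovery_study <- function(design, config, walk = NULL,
                           priors = prior_spec(), n_restarts = 10L,
                           seed = 1L,
                           sessions = c("sober", "hungover")) {
  if (is.null(walk)) walk <- generate_reward_walk(config, seed = seed)
  cohort <- generate_cohort(design, config, walk)
  keep <- sub("^[^.]*\\.", "", names(cohort$sessions)) %in% sessions
  cohort$sessions <- cohort$sessions[keep]
  fits <- fit_cohort(cohort, config, priors, n_restarts, seed)
  rec <- fits_to_frame(fits)
  truth <- cohort$truth[cohort$truth$session %in% sessions, ]
  m <- merge(truth, rec, by = c("subject_id", "session"),
             suffixes = c("_true", "_hat"))
  per_param <- do.call(rbind, lapply(param_names, function(p) {
    tr <- m[[paste0(p, "_true")]]
    ht <- m[[paste0(p, "_hat")]]
    data.frame(parameter = p,
               spearman = suppressWarnings(
                 cor(tr, ht, method = "spearman")),
               bias = mean(ht - tr),
               rmse = sqrt(mean((ht - tr)^2)),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_parameter = per_param, truth = truth, recovered = rec,
                 merged = m, design = design, seed = seed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery (%d fits, seed %d)\n",
              nrow(x$recovered), x$seed))
  print(x$per_parameter, row.names = FALSE)
  invisible(x)
}

#' Detection-rate curve for hungover shifts of omega
#'
#' For each shift magnitude on the grid, replicate cohorts are generated
#' with that (negative) additive hungover effect on omega, every session
#' is fitted, and the fraction of replicates in which the paired t test on
#' fitted omega rejects at alpha = 0.05 — and in which BF01 < 1/3 —
#' is recorded.
#'
#' @param design A [cohort_design()] (its `session_effect` is overridden
#'   per grid point).
#' @param config A [task_config()].
#' @param walk A `twostep_walk`.
#' @param effect_grid Non-negative shift magnitudes applied as
#'   `omega -> omega - effect` in the hungover session.
#' @param n_replicates Replicate cohorts per grid point.
#' @param seed Integer base seed.
#' @param priors,n_restarts Fitting settings.
#' @return Data frame: `effect`, `detection_rate_t`, `detection_rate_bf`,
#'   `n_replicates`.
#' @export
power_curve <- function(design, config, walk, effect_grid,
                        n_replicates = 10L, seed = 1L,
                        priors = prior_spec(), n_restarts = 5L) {
  stopifnot(all(effect_grid >= 0))
  rows <- lapply(seq_along(effect_grid), function(g) {
    eff <- effect_grid[g]
    hit_t <- hit_bf <- logical(n_replicates)
    for (r in seq_len(n_replicates)) {
      d <- design
      d$session_effect[["omega"]] <- -eff
      d$seed <- (seed + 1000L * g + r) %% .Machine$integer.max
      cohort <- generate_cohort(d, config, walk)
      fits <- fit_cohort(cohort, config, priors, n_restarts,
                         seed = d$seed + 1L)
      rec <- fits_to_frame(fits)
      sob <- rec[rec$session == "sober", ]
      hun <- rec[rec$session == "hungover", ]
      hun <- hun[match(sob$subject_id, hun$subject_id), ]
      cmp <- paired_compare(sob$omega, hun$omega, measure = "omega")
      hit_t[r] <- !is.na(cmp$p_two_sided) && cmp$p_two_sided < 0.05
      hit_bf[r] <- !is.na(cmp$bf01) && cmp$bf01 < 1 / 3
    }
    data.frame(effect = eff, detection_rate_t = mean(hit_t),
               detection_rate_bf = mean(hit_bf),
               n_replicates = n_replicates)
  })
  do.call(rbind, rows)
}

#' Write a cohort's trial logs and truth table to CSV
#'
#' @param cohort A `twostep_cohort`.
#' @param trials_path,truth_path Output paths.
#' @return Invisibly, the combined trial data frame.
#' @export
write_cohort <- function(cohort, trials_path, truth_path = NULL) {
  stopifnot(inherits(cohort, "twostep_cohort"))
  write_trials(cohort$sessions, trials_path)
  if (!is.null(truth_path))
    write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(do.call(rbind, lapply(cohort$sessions, as.data.frame)))
}
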