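#' Generate a drifting reward walk for the four second-stage options
#'
#' Each of the four second-stage options carries an independent latent value
#' that starts at the midpoint of `walk_bounds` and takes Gaussian steps
#' (mean 0, sd `walk_drift_sd`) with reflecting boundaries: a value that
#' overshoots a bound is folded back by the overshoot amount, re-applied
#' until it lies inside the interval. Latent values are quantized to integer
#' points via [latent_to_points()].
#'
#' @param config A [task_config()].
#' @param seed Integer seed; the walk is deterministic given the seed.
#' @param n_trials Optional override of `config$n_trials` (e.g. to study
#'   the walk's stationary distribution at large length).
#'
#' @return An object of class `twostep_walk`: a list with `latent`
#'   (`n_trials x 4` matrix in `walk_bounds`) and `points` (integer matrix
#'   of the same shape). Option columns 1:2 belong to second-stage state 0,
#'   columns 3:4 to state 1.
#' @export
generate_reward_walk <- function(config, seed, n_trials = config$n_trials) {
  validate_task_config(config)
  n_opt <- config$n_second_stage_states * config$n_options_per_state
  lo <- config$walk_bounds[1]
  hi <- config$walk_bounds[2]
  set.seed(as.integer(seed))
  latent <- matrix(NA_real_, nrow = n_trials, ncol = n_opt)
  # midpoint start: unbiased, and mixing to the walk's stationary
  # distribution takes only a handful of sd-0.2 steps
  x <- rep((lo + hi) / 2, n_opt)
  latent[1L, ] <- x
  if (n_trials > 1L) {
    steps <- matrix(rnorm((n_trials - 1L) * n_opt, 0, config$walk_drift_sd),
                    nrow = n_trials - 1L)
    for (t in 2:n_trials) {
      x <- reflect_into(x + steps[t - 1L, ], lo, hi)
      latent[t, ] <- x
    }
  }
  walk <- list(
    latent = latent,
    points = matrix(latent_to_points(latent, config),
                    nrow = n_trials, ncol = n_opt),
    seed = as.integer(seed)
  )
  class(walk) <- "twostep_walk"
  walk
}

# Iterated fold-back reflection into [lo, hi]: overshoot past a bound is
# mirrored (x -> 2*bound - x) until the value lies inside.
reflect_into <- function(x, lo, hi) {
  out <- x
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- ifelse(out[bad] > hi, 2 * hi - out[bad], out[bad])
    out[bad] <- ifelse(out[bad] < lo, 2 * lo - out[bad], out[bad])
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Map a latent walk value onto the integer point scale
#'
#' Linear quantization of the latent `[0, 1]` value onto the closed integer
#' range `points_min..points_max`, rounding halves away from zero so that
#' all ten outcomes (including 0, "nothing") are reachable and the
#' endpoints map to the extremes.
#'
#' @param latent Numeric vector/matrix of latent values inside
#'   `config$walk_bounds`.
#' @param config A [task_config()].
#' @return Integer points, same shape as `latent`.
#' @export
#' @examples
#' latent_to_points(c(0, 0.5, 1), task_config())  # -4, 1, 5
latent_to_points <- function(latent, config) {
  lo <- config$walk_bounds[1]
  hi <- config$walk_bounds[2]
  if (any(latent < lo | latent > hi, na.rm = TRUE))
    stop("latent value outside walk_bounds")
  u <- (latent - lo) / (hi - lo)
  span <- config$points_max - config$points_min
  # round-half-away-from-zero; base round() would send 0.5*span to the
  # nearest even integer instead
  as.integer(floor(u * span + 0.5)) + config$points_min
}

#' Sample a second-stage transition
#'
#' The first-stage option `j` (0-based) reaches its designated common state
#' `j` with probability `p_common` and the other state otherwise. The
#' option-to-common-state mapping is fixed for a session.
#'
#' @param first_stage_choice 0 or 1.
#' @param config A [task_config()].
#' @param n Number of draws (default 1). Uses the current RNG stream.
#' @return A list with integer vector `state` and character vector
#'   `transition` (`"common"`/`"rare"`).
#' @export
sample_transition <- function(first_stage_choice, config, n = 1L) {
  stopifnot(first_stage_choice %in% c(0L, 1L))
  common <- runif(n) < config$p_common
  state <- ifelse(common, first_stage_choice, 1L - first_stage_choice)
  list(state = as.integer(state),
       transition = ifelse(common, "common", "rare"))
}

#' Select a reward walk on which model-based play pays off
#'
#' Candidate walks are generated from consecutive seeds and evaluated by
#' simulating reference agents: a purely model-based agent (omega = 1) and a
#' purely model-free agent (omega = 0), each `n_sims_per_candidate` times.
#' The walk maximizing the mean final-score advantage of the model-based
#' agent is returned, provided that advantage is positive; otherwise the
#' selection fails with a diagnostic. This mirrors the pre-simulation used
#' to guarantee that the costlier model-based strategy earns more points.
#'
#' @param config A [task_config()].
#' @param n_candidates Number of candidate walks (default 20).
#' @param reference_params_mb,reference_params_mf Reference
#'   [agent_params()]; defaults are omega = 1 vs omega = 0 with the other
#'   parameters at the sober population medians (alpha 0.89, beta 4.70,
#'   lambda 0.48, pi 0.16).
#' @param n_sims_per_candidate Simulated sessions per agent per candidate
#'   (default 100).
#' @param seed Integer seed controlling both walk generation and the
#'   evaluation simulations.
#' @return A list with `walk` (the selected `twostep_walk`) and `report`
#'   (class `walk_selection_report`: candidate count, per-agent mean final
#'   scores on the selected walk, their difference `advantage`,
#'   `selected_index`, and the seed).
#' @export
select_reward_walk <- function(config,
                               n_candidates = 20L,
                               reference_params_mb = agent_params(
                                 omega = 1, alpha = 0.89, beta = 4.70,
                                 lambda = 0.48, pi = 0.16),
                               reference_params_mf = agent_params(
                                 omega = 0, alpha = 0.89, beta = 4.70,
                                 lambda = 0.48, pi = 0.16),
                               n_sims_per_candidate = 100L,
                               seed = 1L) {
  validate_task_config(config)
  stopifnot(n_candidates >= 1L, n_sims_per_candidate >= 1L)
  seed <- as.integer(seed)
  mb_means <- mf_means <- numeric(n_candidates)
  walks <- vector("list", n_candidates)
  for (k in seq_len(n_candidates)) {
    walks[[k]] <- generate_reward_walk(config, seed = seed + k - 1L)
    mb_scores <- mf_scores <- numeric(n_sims_per_candidate)
    for (s in seq_len(n_sims_per_candidate)) {
      sim_seed <- seed + 1000L * k + s
      mb_scores[s] <- final_score(simulate_session(
        reference_params_mb, walks[[k]], config, seed = sim_seed))
      mf_scores[s] <- final_score(simulate_session(
        reference_params_mf, walks[[k]], config, seed = sim_seed + 500000L))
    }
    mb_means[k] <- mean(mb_scores)
    mf_means[k] <- mean(mf_scores)
  }
  adv <- mb_means - mf_means
  best <- which.max(adv)
  if (adv[best] <= 0)
    stop("no candidate walk gives the model-based agent a positive ",
         "final-score advantage (best: ", signif(adv[best], 4),
         "); increase n_candidates or check the task configuration")
  report <- structure(
    list(n_candidates = n_candidates,
         mb_mean_score = mb_means[best],
         mf_mean_score = mf_means[best],
         advantage = adv[best],
         selected_index = best,
         seed = seed),
    class = "walk_selection_report")
  list(walk = walks[[best]], report = report)
}

#' @export
print.walk_selection_report <- function(x, ...) {
  cat(sprintf(
    "Walk selection: candidate %d of %d (seed %d)\n  MB mean %.1f vs MF mean %.1f points (advantage %.1f)\n",
    x$selected_index, x$n_candidates, x$seed,
    x$mb_mean_score, x$mf_mean_score, x$advantage))
  invisible(x)
}

#' Read/write a reward walk as CSV
#'
#' Long format with columns `trial` (1-based), `option_id` (0-3),
#' `latent_value` and `points`.
#'
#' @param walk A `twostep_walk`.
#' @param path File path.
#' @param config A [task_config()] used to re-validate on read.
#' @return `write_reward_walk()` returns `path` invisibly;
#'   `read_reward_walk()` returns a `twostep_walk`.
#' @export
write_reward_walk <- function(walk, path) {
  stopifnot(inherits(walk, "twostep_walk"))
  n <- nrow(walk$latent)
  df <- data.frame(
    trial = rep(seq_len(n), times = ncol(walk$latent)),
    option_id = rep(seq_len(ncol(walk$latent)) - 1L, each = n),
    latent_value = as.vector(walk$latent),
    points = as.vector(walk$points)
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reward_walk
#' @export
read_reward_walk <- function(path, config = task_config()) {
  df <- read.csv(path)
  need <- c("trial", "option_id", "latent_value", "points")
  if (!all(need %in% names(df)))
    stop("walk file must have columns: ", paste(need, collapse = ", "))
  n <- max(df$trial)
  n_opt <- max(df$option_id) + 1L
  latent <- matrix(NA_real_, n, n_opt)
  points <- matrix(NA_integer_, n, n_opt)
  latent[cbind(df$trial, df$option_id + 1L)] <- df$latent_value
  points[cbind(df$trial, df$option_id + 1L)] <- df$points
  if (anyNA(latent)) stop("walk file is missing trial/option combinations")
  lo <- config$walk_bounds[1]; hi <- config$walk_bounds[2]
  if (any(latent < lo | latent > hi))
    stop("latent values outside configured walk_bounds")
  structure(list(latent = latent, points = points, seed = NA_integer_),
            class = "twostep_walk")
}
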