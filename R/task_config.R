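#' Task configuration for the two-step decision task
#'
#' Bundles the structural constants of the two-step (Markov decision) task:
#' a first-stage choice between two options leads, with probability
#' `p_common`, to that option's designated second-stage state (the "common"
#' transition) and otherwise to the other state ("rare"). Each second-stage
#' state offers two options whose latent values drift on `[0, 1]` as
#' independent reflected Gaussian random walks and are paid out as integer
#' points.
#'
#' @param n_trials Number of trials per session (default 250).
#' @param n_blocks Number of equally sized blocks (default 2); `n_trials`
#'   must be divisible by `n_blocks`.
#' @param p_common Probability of the common transition, in `(0.5, 1]`
#'   (default 0.80).
#' @param walk_drift_sd Standard deviation of the Gaussian random-walk step
#'   on the latent `[0, 1]` scale (default 0.20).
#' @param walk_bounds Closed reflecting interval for the latent value
#'   (default `c(0, 1)`).
#' @param points_min,points_max Integer outcome range (defaults -4 and +5).
#' @param timeout_penalty_points Points lost on a missed response (default 5).
#' @param response_limit_s Per-choice response window in seconds (default 2).
#'
#' @return An object of class `twostep_config` (a validated list). The
#'   option structure (2 first-stage options, 2 second-stage states with 2
#'   options each) is fixed; first-stage option `j` (0-based) has state `j`
#'   as its common destination.
#' @export
#' @examples
#' cfg <- task_config()
#' cfg$p_common
task_config <- function(n_trials = 250L,
                        n_blocks = 2L,
                        p_common = 0.80,
                        walk_drift_sd = 0.20,
                        walk_bounds = c(0, 1),
                        points_min = -4L,
                        points_max = 5L,
                        timeout_penalty_points = 5L,
                        response_limit_s = 2) {
  cfg <- list(
    n_trials = as.integer(n_trials),
    n_blocks = as.integer(n_blocks),
    p_common = as.numeric(p_common),
    walk_drift_sd = as.numeric(walk_drift_sd),
    walk_bounds = as.numeric(walk_bounds),
    points_min = as.integer(points_min),
    points_max = as.integer(points_max),
    timeout_penalty_points = as.integer(timeout_penalty_points),
    response_limit_s = as.numeric(response_limit_s),
    n_first_stage_options = 2L,
    n_second_stage_states = 2L,
    n_options_per_state = 2L
  )
  class(cfg) <- "twostep_config"
  validate_task_config(cfg)
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "twostep_config"))
  if (cfg$n_trials < 1L) stop("n_trials must be a positive integer")
  if (cfg$n_blocks < 1L) stop("n_blocks must be a positive integer")
  if (cfg$n_trials %% cfg$n_blocks != 0L)
    stop("n_trials must be divisible by n_blocks")
  if (!(cfg$p_common > 0.5 && cfg$p_common <= 1))
    stop("p_common must lie in (0.5, 1]")
  if (cfg$walk_drift_sd < 0) stop("walk_drift_sd must be non-negative")
  if (length(cfg$walk_bounds) != 2L || cfg$walk_bounds[1] >= cfg$walk_bounds[2])
    stop("walk_bounds must be an interval c(lo, hi) with lo < hi")
  if (cfg$points_min >= cfg$points_max) stop("points_min must be < points_max")
  if (cfg$timeout_penalty_points < 0) stop("timeout_penalty_points must be >= 0")
  if (cfg$response_limit_s <= 0) stop("response_limit_s must be positive")
  cfg
}

#' @export
print.twostep_config <- function(x, ...) {
  cat("Two-step task configuration\n")
  cat(sprintf("  trials: %d in %d block(s)\n", x$n_trials, x$n_blocks))
  cat(sprintf("  common transition probability: %.2f\n", x$p_common))
  cat(sprintf("  reward walk: reflected Gaussian, sd %.3f on [%g, %g]\n",
              x$walk_drift_sd, x$walk_bounds[1], x$walk_bounds[2]))
  cat(sprintf("  points: %d..%d, timeout penalty %d\n",
              x$points_min, x$points_max, x$timeout_penalty_points))
  invisible(x)
}

# Normalize raw points onto the [0,1] learning scale.
normalize_points <- function(points, cfg) {
  (points - cfg$points_min) / (cfg$points_max - cfg$points_min)
}
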