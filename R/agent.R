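#' Parameters of the hybrid dual-system agent
#'
#' The five free parameters of the hybrid model-based/model-free learner:
#' `omega` weights model-based against model-free valuation at the first
#' stage (0 = purely model-free, 1 = purely model-based); `alpha` is the
#' SARSA(lambda) learning rate; `beta` the softmax inverse temperature;
#' `lambda` the eligibility-trace decay that down-weights the second-stage
#' prediction error in the first-stage update; `pi` an additive stickiness
#' bonus for repeating the previous first-stage choice (perseveration if
#' positive, switching if negative).
#'
#' @param omega,alpha,lambda Reals in `[0, 1]`.
#' @param beta Non-negative real.
#' @param pi Real.
#' @return An object of class `agent_params`.
#' @export
#' @examples
#' agent_params(omega = 0.83, alpha = 0.89, beta = 4.70,
#'              lambda = 0.48, pi = 0.16)
agent_params <- function(omega, alpha, beta, lambda, pi) {
  p <- list(omega = as.numeric(omega), alpha = as.numeric(alpha),
            beta = as.numeric(beta), lambda = as.numeric(lambda),
            pi = as.numeric(pi))
  if (!all(vapply(p, function(v) length(v) == 1L && is.finite(v), TRUE)))
    stop("all parameters must be finite scalars")
  if (p$omega < 0 || p$omega > 1) stop("omega must lie in [0, 1]")
  if (p$alpha < 0 || p$alpha > 1) stop("alpha must lie in [0, 1]")
  if (p$lambda < 0 || p$lambda > 1) stop("lambda must lie in [0, 1]")
  if (p$beta < 0) stop("beta must be non-negative")
  class(p) <- "agent_params"
  p
}

as_param_vector <- function(params) {
  stopifnot(inherits(params, "agent_params"))
  c(params$omega, params$alpha, params$beta, params$lambda, params$pi)
}

param_names <- c("omega", "alpha", "beta", "lambda", "pi")

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf(
    "Hybrid agent: omega=%.3f alpha=%.3f beta=%.3f lambda=%.3f pi=%.3f\n",
    x$omega, x$alpha, x$beta, x$lambda, x$pi))
  invisible(x)
}

#' Initialize the model-free value table
#'
#' @param config A [task_config()].
#' @param init_value Common starting Q-value; the default 0.5 is the
#'   midpoint of the normalized reward scale, an unbiased start.
#' @return An object of class `q_state`: `q_mf_stage1` (length 2),
#'   `q_mf_stage2` (2 states x 2 options matrix) and `prev_first_choice`
#'   (`NA` before the first completed trial).
#' @export
initialize_q <- function(config, init_value = 0.5) {
  q <- list(
    q_mf_stage1 = rep(init_value, config$n_first_stage_options),
    q_mf_stage2 = matrix(init_value, config$n_second_stage_states,
                         config$n_options_per_state),
    prev_first_choice = NA_integer_
  )
  class(q) <- "q_state"
  q
}

#' Model-based first-stage values
#'
#' Combines the known transition structure with the current model-free
#' second-stage values: for first-stage option `j`,
#' `Q_MB(j) = p_common * max(Q_MF(common state of j, .)) +
#' (1 - p_common) * max(Q_MF(other state, .))`.
#'
#' @param q A `q_state`.
#' @param config A [task_config()].
#' @return Numeric vector of length 2.
#' @export
model_based_values <- function(q, config) {
  stopifnot(inherits(q, "q_state"))
  m <- apply(q$q_mf_stage2, 1L, max)
  p <- config$p_common
  c(p * m[1] + (1 - p) * m[2],
    p * m[2] + (1 - p) * m[1])
}

#' Softmax choice probabilities with optional stickiness
#'
#' `P(a)` is proportional to `exp(beta * (value(a) + pi * rep(a)))` where
#' `rep(a) = 1` iff `a` equals the previous first-stage choice. `rep` is
#' identically 0 at the second stage and before the first completed trial
#' (pass `prev_choice = NA`). Numerically stable for large `beta`.
#'
#' @param values Numeric vector of decision values.
#' @param beta Inverse temperature (>= 0).
#' @param pi Stickiness bonus (default 0).
#' @param prev_choice 0-based index of the previous choice, or `NA`.
#' @return Probability vector summing to 1.
#' @export
#' @examples
#' choice_probabilities(c(0, 0), beta = 1, pi = log(3), prev_choice = 0)
choice_probabilities <- function(values, beta, pi = 0, prev_choice = NA) {
  stopifnot(all(is.finite(values)), beta >= 0)
  v <- values
  if (!is.na(prev_choice)) v[prev_choice + 1L] <- v[prev_choice + 1L] + pi
  z <- beta * v
  e <- exp(z - max(z))
  e / sum(e)
}

#' Apply the end-of-trial SARSA(lambda) update
#'
#' With pre-update values, the first-stage prediction error is
#' `d1 = Q_MF(s2, a2) - Q_MF(s1, a1)` and the second-stage error
#' `d2 = r - Q_MF(s2, a2)` (reward on the normalized `[0, 1]` scale). The
#' chosen second-stage value moves by `alpha * d2`; the chosen first-stage
#' value by `alpha * d1 + alpha * lambda * d2`. Unchosen values are
#' untouched. Timeout trials change nothing except that they never update
#' `prev_first_choice` either.
#'
#' @param q A `q_state`.
#' @param trial One-row data frame (or list) with `s1_choice`, `s2_state`,
#'   `s2_choice`, `points` and `timeout`.
#' @param params An [agent_params()].
#' @param config A [task_config()].
#' @return The updated `q_state`.
#' @export
update_after_trial <- function(q, trial, params, config) {
  stopifnot(inherits(q, "q_state"), inherits(params, "agent_params"))
  if (isTRUE(as.logical(trial$timeout))) return(q)
  a1 <- trial$s1_choice + 1L
  st <- trial$s2_state + 1L
  a2 <- trial$s2_choice + 1L
  r <- normalize_points(trial$points, config)
  d1 <- q$q_mf_stage2[st, a2] - q$q_mf_stage1[a1]
  d2 <- r - q$q_mf_stage2[st, a2]
  q$q_mf_stage2[st, a2] <- q$q_mf_stage2[st, a2] + params$alpha * d2
  q$q_mf_stage1[a1] <- q$q_mf_stage1[a1] +
    params$alpha * d1 + params$alpha * params$lambda * d2
  q$prev_first_choice <- as.integer(trial$s1_choice)
  q
}

#' Simulate one session of the two-step task
#'
#' Runs the hybrid agent generatively on a reward walk: first-stage choice
#' from the omega-weighted net values (with stickiness), a sampled
#' common/rare transition, a second-stage choice from the realized state's
#' model-free values (no stickiness), point delivery from the walk, and the
#' end-of-trial SARSA(lambda) update. Deterministic given `seed`.
#'
#' @param params An [agent_params()].
#' @param walk A `twostep_walk` with at least `config$n_trials` rows.
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @param subject_id,session Labels stored in the trial log.
#' @param q_init Initial Q-value (default 0.5).
#' @return A `twostep_session`: a data frame with one row per trial
#'   (columns `subject_id`, `session`, `block`, `trial`, `s1_choice`,
#'   `transition`, `s2_state`, `s2_choice`, `points`, `rt1_ms`, `rt2_ms`,
#'   `timeout`), carrying the task config as an attribute.
#' @export
simulate_session <- function(params, walk, config, seed,
                             subject_id = "sim", session = "sober",
                             q_init = 0.5) {
  stopifnot(inherits(params, "agent_params"), inherits(walk, "twostep_walk"))
  validate_task_config(config)
  if (nrow(walk$points) < config$n_trials)
    stop("walk has fewer rows than config$n_trials")
  set.seed(as.integer(seed))
  span <- config$points_max - config$points_min
  sim <- cpp_simulate(as_param_vector(params),
                      walk$points, config$n_trials, config$p_common,
                      q_init, config$points_min, span)
  n <- config$n_trials
  block_len <- n %/% config$n_blocks
  df <- data.frame(
    subject_id = subject_id,
    session = session,
    block = ((seq_len(n) - 1L) %/% block_len) + 1L,
    trial = seq_len(n),
    s1_choice = sim$s1_choice,
    transition = sim$transition,
    s2_state = sim$s2_state,
    s2_choice = sim$s2_choice,
    points = sim$points,
    rt1_ms = NA_real_,
    rt2_ms = NA_real_,
    timeout = FALSE,
    stringsAsFactors = FALSE
  )
  as_twostep_session(df, config)
}

as_twostep_session <- function(df, config) {
  attr(df, "task_config") <- config
  class(df) <- c("twostep_session", "data.frame")
  df
}

session_config <- function(data, config = NULL) {
  if (!is.null(config)) return(validate_task_config(config))
  cfg <- attr(data, "task_config")
  if (is.null(cfg)) cfg <- task_config()
  cfg
}

completed_trials <- function(data) {
  !as.logical(data$timeout)
}

#' Log-likelihood of an observed session under the hybrid model
#'
#' Replays the SARSA(lambda)/model-based learner along the observed trial
#' sequence and sums the log of the softmax probability assigned to each
#' observed choice at both stages. Timeout trials contribute no terms and
#' trigger no updates.
#'
#' @param params An [agent_params()].
#' @param data A `twostep_session` (or plain data frame with the session
#'   columns).
#' @param config A [task_config()]; defaults to the one attached to `data`.
#' @param q_init Initial Q-value (default 0.5).
#' @return The summed log-likelihood (<= 0).
#' @export
session_loglik <- function(params, data, config = NULL, q_init = 0.5) {
  replay_session(params, data, config, q_init)$loglik
}

#' Replay a session and expose per-trial model quantities
#'
#' @inheritParams session_loglik
#' @return A list: `loglik`, and `n x 2` matrices `p_stage1`, `p_stage2`
#'   (choice probabilities), `q_net` (omega-mixed first-stage values before
#'   the trial's choice) and `q_stage2` (model-free values of the realized
#'   second-stage state). Timeout rows are `NA`.
#' @export
replay_session <- function(params, data, config = NULL, q_init = 0.5) {
  stopifnot(inherits(params, "agent_params"))
  cfg <- session_config(data, config)
  timeout <- as.logical(data$timeout)
  done <- !timeout
  if (any(done & (is.na(data$s1_choice) | is.na(data$s2_choice) |
                  is.na(data$s2_state) | is.na(data$points))))
    stop("completed trials must have both choices, the realized state, ",
         "and the outcome")
  r <- normalize_points(as.numeric(data$points), cfg)
  out <- cpp_replay(as_param_vector(params),
                    as.integer(data$s1_choice), as.integer(data$s2_state),
                    as.integer(data$s2_choice),
                    ifelse(is.na(r), 0, r), timeout,
                    cfg$p_common, q_init)
  if (!is.finite(out$loglik))
    stop("non-finite log-likelihood: corrupt parameters or data")
  out
}
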