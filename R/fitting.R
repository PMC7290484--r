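#' Prior specification for MAP fitting
#'
#' Independent priors over the five agent parameters: Beta priors for the
#' unit-interval parameters (omega, alpha, lambda), a Gamma prior for the
#' inverse temperature beta, and a Normal prior for the stickiness pi. The
#' defaults are weakly informative and unimodal on each support; use
#' [flat_priors()] for maximum-likelihood behaviour.
#'
#' @param omega,alpha,lambda Length-2 numeric `c(shape1, shape2)` of a Beta
#'   prior.
#' @param beta Length-2 numeric `c(shape, scale)` of a Gamma prior.
#' @param pi Length-2 numeric `c(mean, sd)` of a Normal prior.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(omega = c(2, 2), alpha = c(2, 2), lambda = c(2, 2),
                       beta = c(3, 2), pi = c(0, 1)) {
  ps <- list(omega = as.numeric(omega), alpha = as.numeric(alpha),
             lambda = as.numeric(lambda), beta = as.numeric(beta),
             pi = as.numeric(pi))
  if (!all(lengths(ps) == 2L)) stop("each prior takes two hyperparameters")
  if (any(ps$omega <= 0) || any(ps$alpha <= 0) || any(ps$lambda <= 0))
    stop("Beta hyperparameters must be positive")
  if (any(ps$beta <= 0)) stop("Gamma hyperparameters must be positive")
  if (ps$pi[2] <= 0) stop("Normal prior sd must be positive")
  class(ps) <- "prior_spec"
  ps
}

#' @rdname prior_spec
#' @export
flat_priors <- function() {
  # Beta(1,1) is exactly flat on [0,1]; the Gamma and Normal components are
  # made diffuse enough to be constant over the plausible range
  prior_spec(omega = c(1, 1), alpha = c(1, 1), lambda = c(1, 1),
             beta = c(1, 1e6), pi = c(0, 1e3))
}

log_prior_density <- function(params, priors) {
  stopifnot(inherits(priors, "prior_spec"))
  dbeta(params$omega, priors$omega[1], priors$omega[2], log = TRUE) +
    dbeta(params$alpha, priors$alpha[1], priors$alpha[2], log = TRUE) +
    dbeta(params$lambda, priors$lambda[1], priors$lambda[2], log = TRUE) +
    dgamma(params$beta, shape = priors$beta[1], scale = priors$beta[2],
           log = TRUE) +
    dnorm(params$pi, priors$pi[1], priors$pi[2], log = TRUE)
}

#' Log posterior density of agent parameters given a session
#'
#' [session_loglik()] plus the sum of log prior densities; `-Inf` outside
#' the parameter support.
#'
#' @param params An [agent_params()] (or a named numeric vector in the
#'   order omega, alpha, beta, lambda, pi).
#' @param data A `twostep_session`.
#' @param priors A [prior_spec()].
#' @param config A [task_config()]; defaults to the one attached to `data`.
#' @param q_init Initial Q-value for the replay (default 0.5).
#' @return A scalar log posterior value.
#' @export
log_posterior <- function(params, data, priors = prior_spec(),
                          config = NULL, q_init = 0.5) {
  if (!inherits(params, "agent_params")) {
    v <- as.numeric(params)
    if (v[1] < 0 || v[1] > 1 || v[2] < 0 || v[2] > 1 || v[3] < 0 ||
        v[4] < 0 || v[4] > 1 || !all(is.finite(v)))
      return(-Inf)
    params <- agent_params(v[1], v[2], v[3], v[4], v[5])
  }
  session_loglik(params, data, config, q_init) +
    log_prior_density(params, priors)
}

draw_from_priors <- function(priors) {
  agent_params(
    omega = rbeta(1, priors$omega[1], priors$omega[2]),
    alpha = rbeta(1, priors$alpha[1], priors$alpha[2]),
    beta = min(rgamma(1, shape = priors$beta[1], scale = priors$beta[2]), 20),
    lambda = rbeta(1, priors$lambda[1], priors$lambda[2]),
    pi = rnorm(1, priors$pi[1], priors$pi[2])
  )
}

#' Bayesian information criterion
#'
#' `-2 * log_likelihood + n_params * log(n_obs)`. For a complete 250-trial
#' session the observation count is 500: each completed trial contributes
#' two modeled choices.
#'
#' @param log_likelihood Maximized log-likelihood (<= 0 for discrete data).
#' @param n_params Number of free parameters (5 for the hybrid model).
#' @param n_obs Number of modeled observations (>= 1).
#' @return The BIC value.
#' @export
bic <- function(log_likelihood, n_params, n_obs) {
  stopifnot(n_obs >= 1)
  -2 * log_likelihood + n_params * log(n_obs)
}

#' MAP estimation of agent parameters for one session
#'
#' Bounded multi-start local optimization (L-BFGS-B) of [log_posterior()]:
#' `n_restarts` starting points are drawn from the priors, each refined to
#' a local optimum, and the best restart wins (ties broken by lowest
#' restart index). Deterministic given `seed`.
#'
#' @param data A `twostep_session`.
#' @param priors A [prior_spec()].
#' @param config A [task_config()]; defaults to the one attached to `data`.
#' @param n_restarts Number of random restarts (default 10).
#' @param seed Integer seed for the restart draws.
#' @param q_init Initial Q-value (default 0.5).
#' @param min_trials Minimum number of completed trials required
#'   (default 50).
#' @param beta_max Upper optimization bound for beta (default 20).
#' @param pi_bound Symmetric optimization bound for pi (default 5).
#' @return An object of class `twostep_fit`: MAP `params_hat`,
#'   `log_posterior`, `log_likelihood`, `bic`, `n_obs` (modeled choices),
#'   `n_restarts`, `converged`, and `optimal_choice_rate_stage1/_stage2`.
#' @export
fit_map <- function(data, priors = prior_spec(), config = NULL,
                    n_restarts = 10L, seed = 1L, q_init = 0.5,
                    min_trials = 50L, beta_max = 20, pi_bound = 5) {
  cfg <- session_config(data, config)
  n_done <- sum(completed_trials(data))
  if (n_done < min_trials)
    stop("need at least ", min_trials, " completed trials, got ", n_done)

  eps <- 1e-6
  lower <- c(eps, eps, eps, eps, -pi_bound)
  upper <- c(1 - eps, 1 - eps, beta_max, 1 - eps, pi_bound)
  objective <- function(v) {
    lp <- log_posterior(v, data, priors, cfg, q_init)
    if (!is.finite(lp)) return(1e10)
    -lp
  }

  set.seed(as.integer(seed))
  starts <- lapply(seq_len(n_restarts), function(i) {
    p <- draw_from_priors(priors)
    pmin(pmax(as_param_vector(p), lower), upper)
  })

  best <- NULL
  any_converged <- FALSE
  for (i in seq_len(n_restarts)) {
    res <- tryCatch(
      optim(starts[[i]], objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500L, factr = 1e7)),
      error = function(e) NULL)
    if (is.null(res)) next
    conv <- res$convergence == 0L
    any_converged <- any_converged || conv
    if (is.null(best) || res$value < best$value - 1e-9) best <- res
  }
  if (is.null(best)) stop("all optimization restarts failed")

  params_hat <- agent_params(best$par[1], best$par[2], best$par[3],
                             best$par[4], best$par[5])
  ll <- session_loglik(params_hat, data, cfg, q_init)
  n_obs <- 2L * n_done
  fit <- structure(list(
    params_hat = params_hat,
    log_posterior = -best$value,
    log_likelihood = ll,
    bic = bic(ll, 5L, n_obs),
    n_obs = n_obs,
    n_restarts = n_restarts,
    converged = any_converged,
    q_init = q_init
  ), class = "twostep_fit")
  fit$optimal_choice_rate_stage1 <- optimal_choice_rate(data, fit, cfg, 1L)
  fit$optimal_choice_rate_stage2 <- optimal_choice_rate(data, fit, cfg, 2L)
  fit
}

#' @export
print.twostep_fit <- function(x, ...) {
  p <- x$params_hat
  cat("MAP fit of the hybrid dual-system model\n")
  cat(sprintf(
    "  omega=%.3f alpha=%.3f beta=%.3f lambda=%.3f pi=%.3f\n",
    p$omega, p$alpha, p$beta, p$lambda, p$pi))
  cat(sprintf("  logLik %.2f, BIC %.2f on %d choices (%s)\n",
              x$log_likelihood, x$bic, x$n_obs,
              if (x$converged) "converged" else "no restart converged"))
  cat(sprintf("  optimal choice rate: stage 1 %.3f, stage 2 %.3f\n",
              x$optimal_choice_rate_stage1, x$optimal_choice_rate_stage2))
  invisible(x)
}

#' Proportion of choices favouring the higher-valued option
#'
#' Replays the session under the fitted parameters and reports the
#' fraction of completed trials whose chosen option carried the strictly
#' highest decision value at that stage — the omega-mixed net value at
#' stage 1, the realized state's model-free value at stage 2. Exact ties
#' are credited 0.5.
#'
#' @param data A `twostep_session`.
#' @param fit A `twostep_fit` for that session.
#' @param config A [task_config()]; defaults to the one attached to `data`.
#' @param stage 1 or 2.
#' @return A proportion in `[0, 1]`.
#' @export
optimal_choice_rate <- function(data, fit, config = NULL, stage = 1L) {
  stopifnot(inherits(fit, "twostep_fit"), stage %in% c(1L, 2L))
  cfg <- session_config(data, config)
  rep_out <- replay_session(fit$params_hat, data, cfg, fit$q_init)
  vals <- if (stage == 1L) rep_out$q_net else rep_out$q_stage2
  choice <- if (stage == 1L) data$s1_choice else data$s2_choice
  done <- completed_trials(data)
  chosen <- vals[cbind(seq_len(nrow(vals)), choice + 1L)]
  other <- vals[cbind(seq_len(nrow(vals)), 2L - choice)]
  credit <- ifelse(chosen > other, 1, ifelse(chosen == other, 0.5, 0))
  mean(credit[done])
}

#' Write fit results for a set of sessions as CSV
#'
#' @param fits A list of `twostep_fit` objects.
#' @param info A data frame with one row per fit (e.g. subject and session
#'   labels), or `NULL`.
#' @param path Output file path.
#' @return The combined data frame, invisibly.
#' @export
write_fit_results <- function(fits, info = NULL, path) {
  rows <- lapply(fits, function(f) {
    p <- f$params_hat
    data.frame(omega = p$omega, alpha = p$alpha, beta = p$beta,
               lambda = p$lambda, pi = p$pi,
               log_posterior = f$log_posterior,
               log_likelihood = f$log_likelihood,
               bic = f$bic, n_obs = f$n_obs,
               converged = f$converged,
               optimal_choice_rate_stage1 = f$optimal_choice_rate_stage1,
               optimal_choice_rate_stage2 = f$optimal_choice_rate_stage2)
  })
  out <- do.call(rbind, rows)
  if (!is.null(info)) out <- cbind(info, out)
  write.csv(out, path, row.names = FALSE)
  invisible(out)
}
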