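# Independent reference implementations used as oracles. These are written
# naively (explicit trial-by-trial bookkeeping in plain R) and never call
# the package's replay code.

# Hand-unrolled hybrid-model log-likelihood: SARSA(lambda) updates, fixed
# transition model, softmax with stage-1 stickiness. `trials` is a data
# frame with s1_choice, s2_state, s2_choice, points, timeout.
oracle_loglik <- function(omega, alpha, beta, lambda, pi, trials,
                          p_common = 0.8, points_min = -4, points_max = 5,
                          q_init = 0.5) {
  q1 <- c(q_init, q_init)
  q2 <- matrix(q_init, 2, 2)  # [state, option]
  prev <- NA
  ll <- 0
  softmax <- function(v) {
    e <- exp(v - max(v))
    e / sum(e)
  }
  for (t in seq_len(nrow(trials))) {
    tr <- trials[t, ]
    if (isTRUE(as.logical(tr$timeout))) next
    a1 <- tr$s1_choice + 1
    st <- tr$s2_state + 1
    a2 <- tr$s2_choice + 1
    # model-based values from the known transition structure
    qmb <- c(p_common * max(q2[1, ]) + (1 - p_common) * max(q2[2, ]),
             p_common * max(q2[2, ]) + (1 - p_common) * max(q2[1, ]))
    qnet <- omega * qmb + (1 - omega) * q1
    rep_bonus <- c(0, 0)
    if (!is.na(prev)) rep_bonus[prev] <- pi
    p1 <- softmax(beta * (qnet + rep_bonus))
    p2 <- softmax(beta * q2[st, ])
    ll <- ll + log(p1[a1]) + log(p2[a2])
    r <- (tr$points - points_min) / (points_max - points_min)
    d1 <- q2[st, a2] - q1[a1]
    d2 <- r - q2[st, a2]
    q2[st, a2] <- q2[st, a2] + alpha * d2
    q1[a1] <- q1[a1] + alpha * d1 + alpha * lambda * d2
    prev <- a1
  }
  ll
}

# Exact two-sided signed-rank p-value by enumeration of all 2^n sign
# assignments (no zeros, no ties assumed).
oracle_wilcoxon_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% rk
  mu <- n * (n + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# Default-prior Bayes factor for the one-sample/paired t statistic via the
# g-representation of the Cauchy prior: effect-size prior Cauchy(0, r)
# equals delta | g ~ N(0, g), g ~ InverseGamma(1/2, r^2/2). BF10 is a
# one-dimensional integral over g.
oracle_bf01_t <- function(t, n, r = 1 / sqrt(2)) {
  nu <- n - 1
  integrand <- function(g) {
    (1 + n * g)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g) * nu))^(-(nu + 1) / 2) *
      r / (sqrt(2 * pi) * g^(3 / 2)) * exp(-r^2 / (2 * g))
  }
  num <- integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  den / num
}

# Shared tiny fixtures -------------------------------------------------

tiny_config <- function(...) task_config(...)

# A deterministic 3-trial log exercising both transition types and a
# negative outcome.
three_trial_log <- function(cfg = task_config()) {
  df <- data.frame(
    subject_id = "T1", session = "sober", block = 1L, trial = 1:3,
    s1_choice = c(0L, 0L, 1L),
    transition = c("common", "rare", "common"),
    s2_state = c(0L, 1L, 1L),
    s2_choice = c(1L, 0L, 0L),
    points = c(5L, -3L, 2L),
    rt1_ms = 500, rt2_ms = 600, timeout = FALSE,
    stringsAsFactors = FALSE)
  twostepr:::as_twostep_session(df, cfg)
}

cached_default_walk <- local({
  walk <- NULL
  function() {
    if (is.null(walk)) walk <<- default_reward_walk()
    walk
  }
})
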