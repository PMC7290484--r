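#include <Rcpp.h>
using namespace Rcpp;

// Hybrid dual-system agent: SARSA(lambda) model-free values mixed with
// transition-aware model-based values at stage 1, softmax choice with a
// stage-1 perseveration bonus. Parameters: omega, alpha, beta, lambda, pi.
//
// State layout: 2 first-stage options; first-stage option j's common
// second-stage state is j; each state offers 2 options. Rewards arrive on
// the normalized [0,1] scale.

// p0/p1 are computed by direct division (not 1 - p) so that a vanishing
// probability keeps its subnormal value instead of rounding to zero; the
// log-probability of a chosen option is returned via log-sum-exp.
static inline void softmax2(double v0, double v1, double beta,
                            double &p0, double &p1, double &lse) {
  double m = std::max(beta * v0, beta * v1);
  double e0 = std::exp(beta * v0 - m);
  double e1 = std::exp(beta * v1 - m);
  lse = m + std::log(e0 + e1);
  p0 = e0 / (e0 + e1);
  p1 = e1 / (e0 + e1);
}

static inline void mb_values(const double q2[2][2], double p_common,
                             double &qmb0, double &qmb1) {
  double m0 = std::max(q2[0][0], q2[0][1]);
  double m1 = std::max(q2[1][0], q2[1][1]);
  qmb0 = p_common * m0 + (1.0 - p_common) * m1;
  qmb1 = p_common * m1 + (1.0 - p_common) * m0;
}

// Replay a fixed trial sequence under given parameters. Returns the
// summed log-likelihood of the observed choices plus per-trial choice
// probabilities and pre-choice decision values (for optimal-choice-rate
// and diagnostic use). Timeout trials contribute nothing and leave the
// learner untouched.
// [[Rcpp::export]]
List cpp_replay(NumericVector par, IntegerVector s1, IntegerVector s2s,
                IntegerVector s2c, NumericVector reward,
                LogicalVector timeout, double p_common, double q_init) {
  const double omega = par[0], alpha = par[1], beta = par[2],
               lambda = par[3], pi = par[4];
  const int n = s1.size();
  double q1[2] = {q_init, q_init};
  double q2[2][2] = {{q_init, q_init}, {q_init, q_init}};
  int prev = -1;
  double ll = 0.0;
  NumericMatrix p1m(n, 2), p2m(n, 2), qnetm(n, 2), q2m(n, 2);
  std::fill(p1m.begin(), p1m.end(), NA_REAL);
  std::fill(p2m.begin(), p2m.end(), NA_REAL);
  std::fill(qnetm.begin(), qnetm.end(), NA_REAL);
  std::fill(q2m.begin(), q2m.end(), NA_REAL);

  for (int t = 0; t < n; ++t) {
    if (timeout[t]) continue;
    const int a1 = s1[t], st = s2s[t], a2 = s2c[t];
    double qmb0, qmb1;
    mb_values(q2, p_common, qmb0, qmb1);
    double qnet0 = omega * qmb0 + (1.0 - omega) * q1[0];
    double qnet1 = omega * qmb1 + (1.0 - omega) * q1[1];
    double v0 = qnet0 + (prev == 0 ? pi : 0.0);
    double v1 = qnet1 + (prev == 1 ? pi : 0.0);
    double p0, p1, lse1;
    softmax2(v0, v1, beta, p0, p1, lse1);
    ll += beta * (a1 == 0 ? v0 : v1) - lse1;
    double p20, p21, lse2;
    softmax2(q2[st][0], q2[st][1], beta, p20, p21, lse2);
    ll += beta * q2[st][a2] - lse2;

    p1m(t, 0) = p0;       p1m(t, 1) = p1;
    p2m(t, 0) = p20;      p2m(t, 1) = p21;
    qnetm(t, 0) = qnet0;  qnetm(t, 1) = qnet1;
    q2m(t, 0) = q2[st][0]; q2m(t, 1) = q2[st][1];

    // end-of-trial SARSA(lambda) updates with pre-update prediction errors
    double d1 = q2[st][a2] - q1[a1];
    double d2 = reward[t] - q2[st][a2];
    q2[st][a2] += alpha * d2;
    q1[a1] += alpha * d1 + alpha * lambda * d2;
    prev = a1;
  }
  return List::create(_["loglik"] = ll, _["p_stage1"] = p1m,
                      _["p_stage2"] = p2m, _["q_net"] = qnetm,
                      _["q_stage2"] = q2m);
}

// Generative counterpart of cpp_replay: samples choices and transitions
// with R's RNG (so set.seed() in R controls it) and pays out points from
// the walk. points is n x 4 (state 0 options in cols 0..1, state 1 in
// cols 2..3), raw scale; rewards enter learning normalized by
// (points - points_min) / span.
// [[Rcpp::export]]
List cpp_simulate(NumericVector par, IntegerMatrix points, int n_trials,
                  double p_common, double q_init, double points_min,
                  double span) {
  const double omega = par[0], alpha = par[1], beta = par[2],
               lambda = par[3], pi = par[4];
  double q1[2] = {q_init, q_init};
  double q2[2][2] = {{q_init, q_init}, {q_init, q_init}};
  int prev = -1;
  IntegerVector s1(n_trials), s2s(n_trials), s2c(n_trials), pts(n_trials);
  CharacterVector trans(n_trials);
  RNGScope scope;

  for (int t = 0; t < n_trials; ++t) {
    double qmb0, qmb1;
    mb_values(q2, p_common, qmb0, qmb1);
    double v0 = omega * qmb0 + (1.0 - omega) * q1[0] + (prev == 0 ? pi : 0.0);
    double v1 = omega * qmb1 + (1.0 - omega) * q1[1] + (prev == 1 ? pi : 0.0);
    double p0, p1, lse;
    softmax2(v0, v1, beta, p0, p1, lse);
    int a1 = (unif_rand() < p0) ? 0 : 1;
    bool common = unif_rand() < p_common;
    int st = common ? a1 : 1 - a1;
    double p20, p21;
    softmax2(q2[st][0], q2[st][1], beta, p20, p21, lse);
    int a2 = (unif_rand() < p20) ? 0 : 1;
    int r_pts = points(t, 2 * st + a2);
    double r = (static_cast<double>(r_pts) - points_min) / span;

    double d1 = q2[st][a2] - q1[a1];
    double d2 = r - q2[st][a2];
    q2[st][a2] += alpha * d2;
    q1[a1] += alpha * d1 + alpha * lambda * d2;
    prev = a1;

    s1[t] = a1; s2s[t] = st; s2c[t] = a2; pts[t] = r_pts;
    trans[t] = common ? "common" : "rare";
  }
  return List::create(_["s1_choice"] = s1, _["transition"] = trans,
                      _["s2_state"] = s2s, _["s2_choice"] = s2c,
                      _["points"] = pts);
}
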