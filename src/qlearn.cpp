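#include <Rcpp.h>
using namespace Rcpp;

// Overflow-safe logistic: exp() is only ever taken of a non-positive argument.
static inline double logistic(double z) {
  if (z >= 0.0) {
    return 1.0 / (1.0 + std::exp(-z));
  }
  double e = std::exp(z);
  return e / (1.0 + e);
}

// Negative log-likelihood of observed choices under the Q-learning family.
//
// choice:     1 = left, 2 = right
// reward:     0/1
// session_id: integer run id; action values (and uncertainty accumulators)
//             are re-initialized whenever it changes, so concatenated
//             sessions are scored independently.
// par:        alpha_pos, alpha_neg, beta, bias, gamma_win, gamma_lose,
//             epsilon, rho (constrained parameters already substituted).
// q_init:     initial value of both actions at each session start.
// prob_floor: lower clamp on the predicted probability before log().
//
// Softmax argument: beta*(Q_L - Q_R) + rho*(U_L - U_R) - bias, so that
// P_L = 1 / (1 + exp(-beta*(Q_L - Q_R) + bias)) when rho = 0.
// [[Rcpp::export]]
double qlearn_negloglik_cpp(IntegerVector choice, IntegerVector reward,
                            IntegerVector session_id, NumericVector par,
                            double q_init, double prob_floor) {
  const double ap = par[0], an = par[1], beta = par[2], b = par[3];
  const double gw = par[4], gl = par[5], eps = par[6], rho = par[7];
  const int n = choice.size();
  double qL = q_init, qR = q_init, uL = 0.0, uR = 0.0, nll = 0.0;
  int cur = 0;
  bool have_cur = false;
  for (int t = 0; t < n; ++t) {
    if (!have_cur || session_id[t] != cur) {
      qL = qR = q_init;
      uL = uR = 0.0;
      cur = session_id[t];
      have_cur = true;
    }
    double pL = logistic(beta * (qL - qR) + rho * (uL - uR) - b);
    double p = (choice[t] == 1) ? pL : 1.0 - pL;
    if (p < prob_floor) p = prob_floor;
    nll -= std::log(p);
    if (choice[t] == 1) {
      qL = (reward[t] == 1) ? (1.0 - ap) * qL + ap - gw
                            : (1.0 - an) * qL - gl;
      uL = 0.0;
      uR += eps;
    } else {
      qR = (reward[t] == 1) ? (1.0 - ap) * qR + ap - gw
                            : (1.0 - an) * qR - gl;
      uR = 0.0;
      uL += eps;
    }
  }
  return nll;
}

// Pre-choice value trajectory: replays observed choices/rewards and returns
// an n x 5 matrix with columns q_left, q_right, u_left, u_right, p_left,
// each row taken *before* that trial's choice is applied.
// [[Rcpp::export]]
NumericMatrix qlearn_trajectory_cpp(IntegerVector choice, IntegerVector reward,
                                    NumericVector par, double q_init) {
  const double ap = par[0], an = par[1], beta = par[2], b = par[3];
  const double gw = par[4], gl = par[5], eps = par[6], rho = par[7];
  const int n = choice.size();
  NumericMatrix out(n, 5);
  double qL = q_init, qR = q_init, uL = 0.0, uR = 0.0;
  for (int t = 0; t < n; ++t) {
    out(t, 0) = qL;
    out(t, 1) = qR;
    out(t, 2) = uL;
    out(t, 3) = uR;
    out(t, 4) = logistic(beta * (qL - qR) + rho * (uL - uR) - b);
    if (choice[t] == 1) {
      qL = (reward[t] == 1) ? (1.0 - ap) * qL + ap - gw
                            : (1.0 - an) * qL - gl;
      uL = 0.0;
      uR += eps;
    } else {
      qR = (reward[t] == 1) ? (1.0 - ap) * qR + ap - gw
                            : (1.0 - an) * qR - gl;
      uR = 0.0;
      uL += eps;
    }
  }
  return out;
}
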