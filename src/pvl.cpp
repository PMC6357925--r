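#include <Rcpp.h>
using namespace Rcpp;

// Prospect utility: u(x) = x^a for x >= 0, -lambda * |x|^a for x < 0.
// x = 0 takes the non-negative branch and returns 0 for any a.
static inline double pvl_u(double x, double a, double lam) {
  if (x >= 0.0) return (x == 0.0) ? 0.0 : std::pow(x, a);
  return -lam * std::pow(-x, a);
}

// Sensitivity theta for the softmax. rule 0 = constant 3^c - 1 (as printed),
// rule 1 = trial-dependent (t/10)^c with t the 1-based index of the trial
// being predicted.
static inline double theta_val(double c, int t, int rule) {
  if (rule == 0) return std::pow(3.0, c) - 1.0;
  return std::pow((double)t / 10.0, c);
}

// Softmax over theta*E with max-subtraction; fills prob[4].
static inline void softmax4(const double E[4], double th, double prob[4]) {
  double m = th * E[0];
  for (int j = 1; j < 4; ++j) if (th * E[j] > m) m = th * E[j];
  double denom = 0.0;
  for (int j = 0; j < 4; ++j) { prob[j] = std::exp(th * E[j] - m); denom += prob[j]; }
  for (int j = 0; j < 4; ++j) prob[j] /= denom;
}

// [[Rcpp::export]]
double pvl_loglik_cpp(IntegerVector deck, NumericVector net,
                      double a, double lam, double A, double c,
                      int theta_rule, double payoff_scale, double prob_floor) {
  int n = deck.size();
  double E[4] = {0.0, 0.0, 0.0, 0.0};
  double prob[4];
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    int j = deck[t] - 1;
    if (j < 0 || j > 3) stop("deck index out of range at trial %d", t + 1);
    double th = theta_val(c, t + 1, theta_rule);
    softmax4(E, th, prob);
    double p = prob[j];
    if (p < prob_floor) p = prob_floor;
    ll += std::log(p);
    double u = pvl_u(net[t] * payoff_scale, a, lam);
    for (int k = 0; k < 4; ++k) E[k] *= A;
    E[j] += u;
  }
  return ll;
}

// Simulate one PVL agent on a 4-deck schedule. loss_mode 0 = deterministic
// cycle (loss_pos is a 4 x cycle 0/1 matrix of loss positions), 1 = bernoulli
// with per-draw probability loss_events/cycle. Uses R's RNG.
// [[Rcpp::export]]
List simulate_agent_cpp(double a, double lam, double A, double c,
                        NumericVector gain, NumericVector loss_events,
                        NumericVector loss_magnitude, int loss_mode,
                        IntegerMatrix loss_pos, int n_trials,
                        int theta_rule, double payoff_scale) {
  int cycle = loss_pos.ncol();
  double E[4] = {0.0, 0.0, 0.0, 0.0};
  double prob[4];
  int count[4] = {0, 0, 0, 0};
  IntegerVector deck(n_trials);
  NumericVector g(n_trials), l(n_trials);
  for (int t = 0; t < n_trials; ++t) {
    double th = theta_val(c, t + 1, theta_rule);
    softmax4(E, th, prob);
    double u1 = unif_rand(), cum = 0.0;
    int j = 3;
    for (int k = 0; k < 4; ++k) { cum += prob[k]; if (u1 < cum) { j = k; break; } }
    count[j]++;
    double gg = gain[j], loss = 0.0;
    if (loss_mode == 0) {
      int pos = (count[j] - 1) % cycle;
      if (loss_pos(j, pos) == 1) loss = -loss_magnitude[j];
    } else {
      if (unif_rand() < loss_events[j] / (double)cycle) loss = -loss_magnitude[j];
    }
    deck[t] = j + 1;
    g[t] = gg;
    l[t] = loss;
    double u = pvl_u((gg + loss) * payoff_scale, a, lam);
    for (int k = 0; k < 4; ++k) E[k] *= A;
    E[j] += u;
  }
  return List::create(_["deck"] = deck, _["gain"] = g, _["loss"] = l);
}
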