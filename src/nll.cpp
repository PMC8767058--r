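#include <Rcpp.h>
using namespace Rcpp;

// Session negative log-likelihood of the seven-parameter hybrid model.
// Runs the SARSA(lambda) / model-based forward pass over the observed
// events, accumulating -log P(choice1) - log P(choice2) per trial.
// par = (alpha1, alpha2, beta1, beta2, lam, w, rho) in constrained space.
// [[Rcpp::export]]
double nll_hybrid_cpp(NumericVector par, IntegerVector choice1,
                      IntegerVector state2, IntegerVector choice2,
                      IntegerVector outcome, double p_common) {
  const double a1 = par[0], a2 = par[1], b1 = par[2], b2 = par[3],
               lam = par[4], w = par[5], rho = par[6];
  double q1[2] = {0.0, 0.0};
  double q2[2][2] = {{0.0, 0.0}, {0.0, 0.0}};
  int prev = -1;
  double nll = 0.0;
  const int n = choice1.size();
  for (int t = 0; t < n; ++t) {
    const int c1 = choice1[t], s2 = state2[t], c2 = choice2[t];
    const double r = (double) outcome[t];
    const double m0 = std::max(q2[0][0], q2[0][1]);
    const double m1 = std::max(q2[1][0], q2[1][1]);
    const double qmb0 = p_common * m0 + (1.0 - p_common) * m1;
    const double qmb1 = p_common * m1 + (1.0 - p_common) * m0;
    double v0 = w * qmb0 + (1.0 - w) * q1[0];
    double v1 = w * qmb1 + (1.0 - w) * q1[1];
    if (prev == 0) v0 += rho; else if (prev == 1) v1 += rho;
    const double x0 = b1 * v0, x1 = b1 * v1;
    const double mx = std::max(x0, x1);
    const double lse1 = mx + std::log(std::exp(x0 - mx) + std::exp(x1 - mx));
    nll -= (c1 == 0 ? x0 : x1) - lse1;
    const double y0 = b2 * q2[s2][0], y1 = b2 * q2[s2][1];
    const double my = std::max(y0, y1);
    const double lse2 = my + std::log(std::exp(y0 - my) + std::exp(y1 - my));
    nll -= (c2 == 0 ? y0 : y1) - lse2;
    const double d1 = q2[s2][c2] - q1[c1];
    q1[c1] += a1 * d1;
    const double d2 = r - q2[s2][c2];
    q2[s2][c2] += a2 * d2;
    q1[c1] += a1 * lam * d2;
    prev = c1;
  }
  return nll;
}
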