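#include <Rcpp.h>
using namespace Rcpp;

// Two-pathway gamma-sprinkling likelihood for DH gamete crossover data.
//
// Gamete P1 crossovers form a stationary renewal process obtained by
// thinning (retention 1/2) a bivalent renewal process with inter-arrival
// Gamma(shape nu, rate beta = 2 nu (1-p)). The gamete inter-crossover
// density is therefore the geometric mixture
//   g(d) = sum_{m>=1} 2^{-m} dgamma(d; m nu, beta),
// truncated at M terms (2^{-M} tail). P2 crossovers are an independent
// Poisson process of intensity p per Morgan. The likelihood of an observed
// gamete configuration sums over all assignments of observed crossovers to
// P2 (subset A) of
//   p^{|A|} exp(-pL) * [h(y1) prod g(gaps) (1 - G(L - y_k))],
// the bracket being the stationary ordered-point density of the P1
// complement, with the empty complement contributing the void probability
//   V(L) = 1 - lambda1 * int_0^L (1 - G(t)) dt.

static const int M_TERMS = 40;

// Terms decay both geometrically (2^-m) and, once m*nu exceeds beta*d,
// super-exponentially in the gamma tail; stop as soon as a term is
// negligible past the mode.
static double g_mix(double d, double nu, double beta) {
  if (d <= 0) return 0.0;
  double w = 1.0, s = 0.0;
  for (int m = 1; m <= M_TERMS; ++m) {
    w *= 0.5;
    double t = w * R::dgamma(d, m * nu, 1.0 / beta, 0);
    s += t;
    if (m * nu > beta * d && t < 1e-15 * (s + 1e-300)) break;
  }
  return s;
}

static double G_mix(double d, double nu, double beta) {
  if (d <= 0) return 0.0;
  double w = 1.0, s = 0.0;
  for (int m = 1; m <= M_TERMS; ++m) {
    w *= 0.5;
    double t = w * R::pgamma(d, m * nu, 1.0 / beta, 1, 0);
    s += t;
    if (m * nu > beta * d && t < 1e-15 * (s + 1e-300)) break;
  }
  return s;
}

// int_0^x (1 - G(t)) dt, using the closed form
// int_0^x (1 - F_{k,beta}(t)) dt = x (1 - F_{k}(x)) + (k/beta) F_{k+1}(x)
static double int_one_minus_G(double x, double nu, double beta) {
  double w = 1.0, s = 0.0;
  for (int m = 1; m <= M_TERMS; ++m) {
    w *= 0.5;
    double k = m * nu;
    double term = x * (1.0 - R::pgamma(x, k, 1.0 / beta, 1, 0)) +
                  (k / beta) * R::pgamma(x, k + 1.0, 1.0 / beta, 1, 0);
    s += w * term;
    if (k > beta * x && w * x < 1e-15 * (s + 1e-300)) break;
  }
  return s;
}

// [[Rcpp::export]]
double void_probability_cpp(double L, double nu, double p) {
  double lambda1 = 1.0 - p;
  double beta = 2.0 * nu * lambda1;
  return 1.0 - lambda1 * int_one_minus_G(L, nu, beta);
}

// [[Rcpp::export]]
NumericVector g_kernel_cpp(NumericVector d, double nu, double p) {
  double beta = 2.0 * nu * (1.0 - p);
  NumericVector out(d.size());
  for (int i = 0; i < d.size(); ++i) out[i] = g_mix(d[i], nu, beta);
  return out;
}

// [[Rcpp::export]]
NumericVector G_kernel_cpp(NumericVector d, double nu, double p) {
  double beta = 2.0 * nu * (1.0 - p);
  NumericVector out(d.size());
  for (int i = 0; i < d.size(); ++i) out[i] = G_mix(d[i], nu, beta);
  return out;
}

// log-likelihood of one gamete's ordered crossover positions; V = void
// probability for this L (precomputable across gametes sharing L)
static double gamete_ll(const std::vector<double>& y, double L,
                        double nu, double p, double V) {
  double lambda1 = 1.0 - p;
  double beta = 2.0 * nu * lambda1;
  int k = (int)y.size();
  if (k == 0) return std::log(V) - p * L; // P1 void times P2 void e^{-pL}

  // precompute stationary first-event density, tails, and pairwise g
  std::vector<double> h(k), tail(k);
  for (int i = 0; i < k; ++i) {
    h[i] = lambda1 * (1.0 - G_mix(y[i], nu, beta));
    tail[i] = 1.0 - G_mix(L - y[i], nu, beta);
  }
  std::vector<std::vector<double> > gm(k, std::vector<double>(k, 0.0));
  for (int i = 0; i < k; ++i)
    for (int j = i + 1; j < k; ++j)
      gm[i][j] = g_mix(y[j] - y[i], nu, beta);

  double lik = 0.0;
  unsigned long nmask = 1UL << k;
  for (unsigned long mask = 0; mask < nmask; ++mask) {
    // bits set in mask: positions assigned to P2
    int a = 0;
    double dens = 1.0;
    int prev = -1;
    for (int i = 0; i < k; ++i) {
      if (mask & (1UL << i)) { ++a; continue; }
      if (prev < 0) dens *= h[i]; else dens *= gm[prev][i];
      prev = i;
    }
    if (prev < 0) dens = V; else dens *= tail[prev];
    double p2part = (a == 0) ? 1.0 : std::pow(p, a);
    if (p == 0.0 && a > 0) continue;
    lik += p2part * dens;
  }
  lik *= std::exp(-p * L);
  if (lik <= 0.0) return -1e300;
  return std::log(lik);
}

// [[Rcpp::export]]
double gamete_loglik_cpp(NumericVector positions, double L,
                         double nu, double p) {
  std::vector<double> y(positions.begin(), positions.end());
  return gamete_ll(y, L, nu, p, void_probability_cpp(L, nu, p));
}

// total log-likelihood over a set of gametes
// [[Rcpp::export]]
double sprinkle_loglik_cpp(List positions, NumericVector L,
                           double nu, double p) {
  double total = 0.0;
  int n = positions.size();
  double lastL = -1.0, V = 0.0;
  for (int i = 0; i < n; ++i) {
    NumericVector yi = positions[i];
    std::vector<double> y(yi.begin(), yi.end());
    if (L[i] != lastL) { V = void_probability_cpp(L[i], nu, p); lastL = L[i]; }
    total += gamete_ll(y, L[i], nu, p, V);
  }
  return total;
}
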