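// Exact Polya-Gamma PG(1, z) sampling for the logistic data-augmentation
// Gibbs sampler. Devroye-style alternating-series rejection sampler on the
// Jacobi J*(1, z/2) density (Polson, Scott & Windle 2013; Windle 2013),
// with PG(1, z) = J*(1, z/2) / 4.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_PI     = 1.1447298858494001741;
static const double PI2        = 9.8696044010893586188;  // pi^2
static const double PI2_2      = 4.9348022005446793094;  // pi^2 / 2
static const double TWO_OVER_PI = 0.63661977236758134308;
static const double HALF_PI    = 1.5707963267948966192;
static const double LOG_2_OVER_PI = -0.45158270528945486473;
static const double SQRT_PI_2  = 1.2533141373155002512;  // sqrt(pi/2)

static double exprnd(void) {
  return -std::log(1.0 - R::unif_rand());
}

// Piecewise coefficients a_n(x) of the alternating series for the J* density,
// with the cutpoint t = 2/pi separating the left (inverse-Gaussian-like) and
// right (exponential-like) expansions.
static double aterm(int n, double x, double t) {
  double f;
  if (x <= t) {
    f = LOG_PI + std::log(n + 0.5) + 1.5 * (LOG_2_OVER_PI - std::log(x))
        - 2.0 * (n + 0.5) * (n + 0.5) / x;
  } else {
    f = LOG_PI + std::log(n + 0.5) - x * PI2_2 * (n + 0.5) * (n + 0.5);
  }
  return std::exp(f);
}

// Gamma(1/2, rate 1/2) truncated to (pi/2, Inf): shifted-exponential proposal
// with acceptance sqrt(pi / (2x)).
static double truncgamma(void) {
  double X;
  for (;;) {
    X = 2.0 * exprnd() + HALF_PI;
    if (R::unif_rand() <= SQRT_PI_2 / std::sqrt(X)) return X;
  }
}

// Inverse-Gaussian(mu, lambda = 1) by Michael-Schucany-Haas transformation.
static double randinvg(double mu) {
  double u = R::norm_rand();
  double V = u * u;
  double out = mu + 0.5 * mu * (mu * V - std::sqrt(4.0 * mu * V + mu * mu * V * V));
  if (R::unif_rand() > mu / (mu + out)) out = mu * mu / out;
  return out;
}

// Inverse-Gaussian(1/z, 1) truncated to (0, t).
static double tinvgauss(double z, double t) {
  double X;
  double mu = 1.0 / z;
  if (mu > t) {
    // one-over-truncated-gamma proposal (Windle 2013, alg. 3)
    for (;;) {
      X = 1.0 / truncgamma();
      if (std::log(R::unif_rand()) < -z * z * 0.5 * X) return X;
    }
  } else {
    do {
      X = randinvg(mu);
    } while (X >= t);
    return X;
  }
}

static double samplepg(double z) {
  // PG(1, z) = 0.25 * J*(1, z/2)
  z = std::fabs(z) * 0.5;
  double t = TWO_OVER_PI;

  // Mixing weight between the truncated-exponential (x > t) and
  // truncated-inverse-Gaussian (x < t) components of the proposal.
  double K = z * z / 2.0 + PI2 / 8.0;
  double logA = std::log(4.0) - LOG_PI - z;
  double logK = std::log(K);
  double Kt = K * t;
  double w = std::sqrt(HALF_PI);

  double logf1 = logA + R::pnorm(w * (t * z - 1.0), 0.0, 1.0, 1, 1) + logK + Kt;
  double logf2 = logA + 2.0 * z + R::pnorm(-w * (t * z + 1.0), 0.0, 1.0, 1, 1)
                 + logK + Kt;
  double p_over_q = std::exp(logf1) + std::exp(logf2);
  double ratio = 1.0 / (1.0 + p_over_q);

  for (;;) {
    double X;
    if (R::unif_rand() < ratio) {
      X = t + exprnd() / K;        // truncated exponential tail
    } else {
      X = tinvgauss(z, t);         // truncated inverse-Gaussian head
    }

    // Accept/reject by the alternating partial sums S_n of the series.
    int i = 1;
    double Sn = aterm(0, X, t);
    double U = R::unif_rand() * Sn;
    int asgn = -1;
    bool even = false;
    for (;;) {
      Sn += asgn * aterm(i, X, t);
      if (!even && U <= Sn) return 0.25 * X;   // accepted at an odd partial sum
      if (even && U > Sn) break;               // rejected at an even partial sum
      even = !even;
      asgn = -asgn;
      ++i;
    }
  }
}

//' @rdname rpolyagamma
//' @name rpolyagamma
// [[Rcpp::export(name = "rpg_cpp")]]
NumericVector rpg_cpp(NumericVector z) {
  int n = z.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = samplepg(z[i]);
  return out;
}
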