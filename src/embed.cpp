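#include <Rcpp.h>
#include <vector>
#include <random>
#include <cmath>
using namespace Rcpp;

// Stable log p and log(1-p) for the logistic law p = 1/(1+e^z),
// z = beta/2 * (x - R); both clamped at log(1e-15).
static inline double softplus(double z) {
  return z > 0.0 ? z + log1p(std::exp(-z)) : log1p(std::exp(z));
}
static const double LOG_CLAMP = -34.538776394910684; // log(1e-15)

static inline void pair_terms(double z, double &logp, double &log1mp) {
  double sp = softplus(z);
  logp = -sp;
  log1mp = z - sp;
  if (logp < LOG_CLAMP) logp = LOG_CLAMP;
  if (log1mp < LOG_CLAMP) log1mp = LOG_CLAMP;
}

// Contribution of node i to the log-likelihood: sum over all j != i of the
// Bernoulli term at the exact hyperbolic distance.
static double node_loglik(int i, double theta_i, const std::vector<double> &theta,
                          const std::vector<double> &chr,
                          const std::vector<double> &shr,
                          const std::vector<unsigned char> &adjmat, int n,
                          double half_beta, double R) {
  double acc = 0.0;
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    // angles live in [0, 2*pi), so |difference| < 2*pi already
    double dt = std::fabs(theta_i - theta[j]);
    if (dt > M_PI) dt = 2.0 * M_PI - dt;
    double arg = chr[i] * chr[j] - shr[i] * shr[j] * std::cos(dt);
    double x = arg <= 1.0 ? 0.0 : std::acosh(arg);
    double z = half_beta * (x - R);
    double logp, log1mp;
    pair_terms(z, logp, log1mp);
    acc += adjmat[(size_t)i * n + j] ? logp : log1mp;
  }
  return acc;
}

// Bernoulli pair term at the exact hyperbolic distance, for explicit angles.
static inline double pair_term(int i, int j, double ti, double tj,
                               const std::vector<double> &chr,
                               const std::vector<double> &shr,
                               const std::vector<unsigned char> &adjmat,
                               int n, double half_beta, double R) {
  double dt = std::fabs(ti - tj);
  if (dt > M_PI) dt = 2.0 * M_PI - dt;
  double arg = chr[i] * chr[j] - shr[i] * shr[j] * std::cos(dt);
  double x = arg <= 1.0 ? 0.0 : std::acosh(arg);
  double z = half_beta * (x - R);
  double logp, log1mp;
  pair_terms(z, logp, log1mp);
  return adjmat[(size_t)i * n + j] ? logp : log1mp;
}

static inline double wrap2pi(double t) {
  t -= 2.0 * M_PI * std::floor(t / (2.0 * M_PI));
  return t;
}

// Metropolis-Hastings over node angles with radii held fixed.
// Proposals: local Gaussian step (sd = local_sigma) or, with probability
// global_prob, a uniform redraw on the circle. Plateau stopping: quit after
// `plateau` sweeps without a best-likelihood gain above `tol`.
// [[Rcpp::export]]
List embed_mh_cpp(IntegerMatrix edges, int n, NumericVector r_, double R,
                  double beta, NumericVector theta0, int max_sweeps,
                  int plateau, double tol, double local_sigma,
                  double global_prob, int seed) {
  std::vector<unsigned char> adjmat((size_t)n * n, 0);
  for (int e = 0; e < edges.nrow(); ++e) {
    int i = edges(e, 0), j = edges(e, 1);
    adjmat[(size_t)i * n + j] = 1;
    adjmat[(size_t)j * n + i] = 1;
  }
  std::vector<double> theta(theta0.begin(), theta0.end());
  std::vector<double> chr(n), shr(n);
  for (int i = 0; i < n; ++i) {
    chr[i] = std::cosh(r_[i]);
    shr[i] = std::sinh(r_[i]);
  }
  double half_beta = beta / 2.0;

  // full initial log-likelihood (each pair counted once)
  double logl = 0.0;
  for (int i = 0; i < n; ++i)
    logl += node_loglik(i, theta[i], theta, chr, shr, adjmat, n, half_beta, R);
  logl /= 2.0;

  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> norm(0.0, 1.0);

  double best_logl = logl;
  std::vector<double> best_theta = theta;
  std::vector<double> trace;
  trace.reserve(max_sweeps);
  int since_gain = 0;
  long accepted = 0, proposed = 0;

  // Annealing phase (first 60% of the sweep budget): the local proposal
  // width decays from pi to local_sigma and the acceptance temperature
  // from temp0 to 1, after which sampling is plain Metropolis at T = 1.
  // Plateau stopping is armed only once the annealing phase is over.
  int anneal_end = (int)(0.6 * max_sweeps);
  double decay = std::pow(local_sigma / M_PI, 1.0 / std::max(1, anneal_end));
  double temp0 = 8.0;
  double tdecay = std::pow(1.0 / temp0, 1.0 / std::max(1, anneal_end));
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double sigma = M_PI * std::pow(decay, (double)sweep);
    if (sigma < local_sigma) sigma = local_sigma;
    double temp = temp0 * std::pow(tdecay, (double)sweep);
    if (temp < 1.0) temp = 1.0;
    for (int i = 0; i < n; ++i) {
      double prop;
      if (unif(rng) < global_prob) {
        prop = 2.0 * M_PI * unif(rng);
      } else {
        prop = theta[i] + sigma * norm(rng);
        prop -= 2.0 * M_PI * std::floor(prop / (2.0 * M_PI));
      }
      double oldc = node_loglik(i, theta[i], theta, chr, shr, adjmat, n,
                                half_beta, R);
      double newc = node_loglik(i, prop, theta, chr, shr, adjmat, n,
                                half_beta, R);
      double delta = newc - oldc;
      ++proposed;
      if (delta >= 0.0 || unif(rng) < std::exp(delta / temp)) {
        theta[i] = prop;
        logl += delta;
        ++accepted;
      }
    }
    // Block proposals: a random arc of the circle is either reflected about
    // its own bisector (reversing the node order within it) or translated
    // to a new location. Within-arc separations are preserved, so only
    // arc-to-rest pair terms change. These moves unstick flipped or
    // misplaced segments that single-node moves cannot repair.
    for (int bp = 0; bp < 4; ++bp) {
      double u = 2.0 * M_PI * unif(rng);
      double w = M_PI * unif(rng);
      std::vector<int> inside;
      inside.reserve(n / 2);
      std::vector<unsigned char> is_in(n, 0);
      for (int j = 0; j < n; ++j) {
        double dloc = theta[j] - u;
        dloc -= 2.0 * M_PI * std::floor(dloc / (2.0 * M_PI));
        if (dloc < w) {
          inside.push_back(j);
          is_in[j] = 1;
        }
      }
      int m = (int)inside.size();
      if (m == 0 || m == n) continue;
      std::vector<double> newt(m);
      if (unif(rng) < 0.5) {
        double c2 = 2.0 * u + w; // 2 * arc center
        for (int k = 0; k < m; ++k) newt[k] = wrap2pi(c2 - theta[inside[k]]);
      } else {
        double shift = 2.0 * M_PI * unif(rng);
        for (int k = 0; k < m; ++k) newt[k] = wrap2pi(theta[inside[k]] + shift);
      }
      double delta = 0.0;
      for (int k = 0; k < m; ++k) {
        int i = inside[k];
        for (int j = 0; j < n; ++j) {
          if (is_in[j]) continue;
          delta += pair_term(i, j, newt[k], theta[j], chr, shr, adjmat, n,
                             half_beta, R) -
                   pair_term(i, j, theta[i], theta[j], chr, shr, adjmat, n,
                             half_beta, R);
        }
      }
      if (delta >= 0.0 || unif(rng) < std::exp(delta / temp)) {
        for (int k = 0; k < m; ++k) theta[inside[k]] = newt[k];
        logl += delta;
      }
    }
    trace.push_back(logl);
    if (logl > best_logl + tol) {
      best_logl = logl;
      best_theta = theta;
      since_gain = 0;
    } else {
      if (logl > best_logl) {
        best_logl = logl;
        best_theta = theta;
      }
      ++since_gain;
      if (sweep >= anneal_end && since_gain >= plateau) break;
    }
  }

  return List::create(Named("theta") = NumericVector(best_theta.begin(), best_theta.end()),
                      Named("loglik") = best_logl,
                      Named("trace") = NumericVector(trace.begin(), trace.end()),
                      Named("acceptance_rate") = proposed > 0 ? (double)accepted / proposed : 0.0);
}
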