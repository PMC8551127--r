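#include <Rcpp.h>
using namespace Rcpp;

// Exact-update Monte-Carlo simulators for the joint linear system
// (x, y): xdot = -gamma x + y, tau_y ydot = -y + sqrt(2D) xi.
// One step over h uses the state-transition matrix
//   Phi = [[p11, p12], [0, p22]]
// and the Cholesky factor (l11, l21, l22) of the step-noise covariance,
// both precomputed on the R side, so the only discretization artifact
// is grid-sign-change crossing detection (O(sqrt(h)) bias).
// All randomness comes from R's RNG (norm_rand), so set.seed() on the
// R side makes every run reproducible.

// First-passage times of x(t) against a moving boundary b[0..N-1].
// Start: x = 0 (zero variance) or joint stationary draw; y stationary.
// Returns crossing time (first grid index with x >= b), NA if censored.
// [[Rcpp::export]]
NumericVector cpp_xy_fpt(NumericVector b, double dt, int n_trials,
                         double p11, double p12, double p22,
                         double l11, double l21, double l22,
                         double sigma_y, bool stationary,
                         double st_l11, double st_l21, double st_l22) {
  const int N = b.size();
  NumericVector out(n_trials, NA_REAL);
  for (int tr = 0; tr < n_trials; ++tr) {
    double x, y;
    if (stationary) {
      double z1 = norm_rand(), z2 = norm_rand();
      x = st_l11 * z1;
      y = st_l21 * z1 + st_l22 * z2;
    } else {
      x = 0.0;
      y = sigma_y * norm_rand();
    }
    if (x >= b[0]) { out[tr] = 0.0; continue; }
    for (int n = 0; n + 1 < N; ++n) {
      double z1 = norm_rand(), z2 = norm_rand();
      double xn = p11 * x + p12 * y + l11 * z1;
      double yn = p22 * y + l21 * z1 + l22 * z2;
      x = xn; y = yn;
      if (x >= b[n + 1]) { out[tr] = (n + 1) * dt; break; }
    }
  }
  return out;
}

// Interspike-interval samples of the LIF model: membrane potential
// V(t) = deterministic drive + x-like fluctuation, simulated from the
// last spike at grid index 0. During the initial n_ref steps V is
// clamped at V_R while the noise keeps evolving; the returned time is
// the full interval (refractory period included). force[n] is the
// deterministic potential increment over step n (piecewise-linear mu,
// computed on the R side). No reset: only the first crossing matters.
// [[Rcpp::export]]
NumericVector cpp_lif_isi(NumericVector force, double dt, int n_trials,
                          int n_ref, double V_R, double V_T,
                          double p11, double p12, double p22,
                          double l11, double l21, double l22,
                          double sigma_y) {
  const int N = force.size() + 1;
  NumericVector out(n_trials, NA_REAL);
  for (int tr = 0; tr < n_trials; ++tr) {
    double V = V_R;
    double y = sigma_y * norm_rand();
    for (int n = 0; n + 1 < N; ++n) {
      double z1 = norm_rand(), z2 = norm_rand();
      double w1 = l11 * z1;
      double w2 = l21 * z1 + l22 * z2;
      if (n < n_ref) {
        y = p22 * y + w2;           // V clamped, noise keeps running
        continue;
      }
      double Vn = p11 * V + p12 * y + force[n] + w1;
      y = p22 * y + w2;
      V = Vn;
      if (V >= V_T) { out[tr] = (n + 1) * dt; break; }
    }
  }
  return out;
}

// Population of unconnected LIF neurons with reset and absolute
// refractoriness; every neuron fires a synchronized spike at grid
// index 0. Returns the number of spikes per grid step (bin (t_n,
// t_{n+1}] recorded at index n+1); the colored noise is carried
// through spikes un-reset, which is what makes the microscopic model
// non-renewal.
// [[Rcpp::export]]
IntegerVector cpp_lif_population(NumericVector force, double dt,
                                 int n_neurons, int n_ref,
                                 double V_R, double V_T,
                                 double p11, double p12, double p22,
                                 double l11, double l21, double l22,
                                 double sigma_y) {
  const int N = force.size() + 1;
  IntegerVector counts(N);
  for (int nr = 0; nr < n_neurons; ++nr) {
    double V = V_R;
    double y = sigma_y * norm_rand();
    int refr = n_ref;
    for (int n = 0; n + 1 < N; ++n) {
      double z1 = norm_rand(), z2 = norm_rand();
      double w1 = l11 * z1;
      double w2 = l21 * z1 + l22 * z2;
      if (refr > 0) {
        --refr;
        y = p22 * y + w2;
        continue;
      }
      double Vn = p11 * V + p12 * y + force[n] + w1;
      y = p22 * y + w2;
      V = Vn;
      if (V >= V_T) {
        ++counts[n + 1];
        V = V_R;
        refr = n_ref;
      }
    }
  }
  return counts;
}
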