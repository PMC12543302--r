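#include <Rcpp.h>
using namespace Rcpp;

// Stable resting phase of the theta neuron: -Re(acos((1 + i0)/(1 - i0))).
// For |ratio| > 1 the acos is complex; the real-part convention gives 0
// (ratio > 1) or -pi (ratio < -1).
static double theta_rest(double i0) {
  double ratio = (1.0 + i0) / (1.0 - i0);
  if (ratio > 1.0) return 0.0;
  if (ratio < -1.0) return -M_PI;
  return -std::acos(ratio);
}

// [[Rcpp::export]]
double theta_rest_cpp(double i0) { return theta_rest(i0); }

// Euler-Maruyama integration of the coupled theta-neuron network.
// dtheta_j = [1 - cos(theta_j) + (1 + cos(theta_j)) * (i0 + c_j)] dt
//            + (1 + cos(theta_j)) * sigma * sqrt(dt) * dW_j
// with c_j = (K/N) * sum_i A(i,j) * (1 - cos(theta_i - theta_s)).
// Returns the per-node fraction of samples classified ictal,
// i.e. samples with 1 - cos(theta_j - theta_s) > h.
// [[Rcpp::export]]
NumericVector theta_ictal_fraction_cpp(NumericMatrix A, double i0, double K,
                                       double sigma, int n_steps, double dt,
                                       double h, int burn_in) {
  int n = A.nrow();
  double ths = theta_rest(i0);
  double sqdt = std::sqrt(dt);
  std::vector<double> theta(n, ths), cs(n), newtheta(n);
  std::vector<long> ictal(n, 0);
  long counted = 0;
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) cs[i] = 1.0 - std::cos(theta[i] - ths);
    for (int j = 0; j < n; ++j) {
      double coup = 0.0;
      for (int i = 0; i < n; ++i) coup += A(i, j) * cs[i];
      double input = i0 + (K / n) * coup;
      double cj = std::cos(theta[j]);
      double drift = 1.0 - cj + (1.0 + cj) * input;
      double diff = sigma > 0.0 ? (1.0 + cj) * sigma * sqdt * norm_rand() : 0.0;
      newtheta[j] = theta[j] + drift * dt + diff;
    }
    for (int j = 0; j < n; ++j) {
      theta[j] = newtheta[j];
      if (t >= burn_in && 1.0 - std::cos(theta[j] - ths) > h) ictal[j]++;
    }
    if (t >= burn_in) counted++;
  }
  NumericVector out(n);
  for (int j = 0; j < n; ++j)
    out[j] = counted > 0 ? (double)ictal[j] / (double)counted : NA_REAL;
  return out;
}

// Full phase trajectories of the theta-neuron network (small runs only).
// [[Rcpp::export]]
NumericMatrix theta_trajectory_cpp(NumericMatrix A, double i0, double K,
                                   double sigma, int n_steps, double dt) {
  int n = A.nrow();
  double ths = theta_rest(i0);
  double sqdt = std::sqrt(dt);
  std::vector<double> theta(n, ths), cs(n);
  NumericMatrix out(n_steps + 1, n);
  for (int j = 0; j < n; ++j) out(0, j) = theta[j];
  for (int t = 0; t < n_steps; ++t) {
    for (int i = 0; i < n; ++i) cs[i] = 1.0 - std::cos(theta[i] - ths);
    for (int j = 0; j < n; ++j) {
      double coup = 0.0;
      for (int i = 0; i < n; ++i) coup += A(i, j) * cs[i];
      double input = i0 + (K / n) * coup;
      double cj = std::cos(theta[j]);
      double drift = 1.0 - cj + (1.0 + cj) * input;
      double diff = sigma > 0.0 ? (1.0 + cj) * sigma * sqdt * norm_rand() : 0.0;
      out(t + 1, j) = theta[j] + drift * dt + diff;
    }
    for (int j = 0; j < n; ++j) theta[j] = out(t + 1, j);
  }
  return out;
}

// Coupled stochastic phase oscillators generating multichannel signals.
// Each channel advances at the carrier frequency with Wiener phase noise;
// coupled pairs are pulled toward a fixed target phase lag lag(i,j)
// (antisymmetric, radians) with rate pull * coupling(i,j). The emitted
// signal is amp * cos(phase) + measurement noise.
// [[Rcpp::export]]
NumericMatrix phase_recording_cpp(NumericMatrix coupling, NumericMatrix lag,
                                  double carrier_hz, double rate_hz,
                                  int n_samples, double pull,
                                  double phase_noise_sd, double noise_sd,
                                  double amp) {
  int n = coupling.nrow();
  double dt = 1.0 / rate_hz;
  double omega = 2.0 * M_PI * carrier_hz;
  double sqdt = std::sqrt(dt);
  std::vector<double> phi(n), dphi(n);
  for (int j = 0; j < n; ++j) phi[j] = unif_rand() * 2.0 * M_PI;
  NumericMatrix out(n, n_samples);
  for (int t = 0; t < n_samples; ++t) {
    for (int j = 0; j < n; ++j) {
      double pull_j = 0.0;
      for (int i = 0; i < n; ++i) {
        double c = coupling(i, j);
        if (c > 0.0 && i != j)
          pull_j += c * std::sin(phi[i] - lag(i, j) - phi[j]);
      }
      dphi[j] = omega * dt + pull * pull_j * dt +
                (phase_noise_sd > 0.0 ? phase_noise_sd * sqdt * norm_rand() : 0.0);
    }
    for (int j = 0; j < n; ++j) {
      phi[j] += dphi[j];
      out(j, t) = amp * std::cos(phi[j]) +
                  (noise_sd > 0.0 ? noise_sd * norm_rand() : 0.0);
    }
  }
  return out;
}
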