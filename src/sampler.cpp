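// Core chain simulators.  All randomness comes from R's RNG (RNGScope), so
// set.seed() on the R side makes every run reproducible.  One uniform draw
// is consumed per neuron update (absolute/relative chains), per Gibbs site
// update, and per event decision in the jump process, in simulation order.

#include <Rcpp.h>
using namespace Rcpp;

static inline double sigmoidc(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// piecewise-constant (nearest-node) lookup of the tabulated activation
static inline double flookup(const NumericVector& fv, double u0, double step,
                             double u) {
  int idx = (int)std::lround((u - u0) / step);
  if (idx < 0) idx = 0;
  int n = fv.size();
  if (idx >= n) idx = n - 1;
  return fv[idx];
}

// [[Rcpp::export]]
List cpp_run_chain(const NumericMatrix& W, const NumericVector& b, int tau,
                   int n_sweeps, int burn_in, int mechanism,
                   const NumericVector& g,        // g[0..tau], g[0] = 1
                   const NumericVector& f_values, // empty for absolute
                   double f_u0, double f_step,
                   const IntegerVector& clamp,    // -1 free, 0 off, 1 on
                   bool random_order, int thin, double dt,
                   bool record_spikes, bool record_states, bool count_states,
                   int psp_mode,                  // 0 rect, 1 alpha
                   double kappa, double tau_rise, double tau_fall,
                   const NumericVector& zeta_init) {
  RNGScope scope;
  const int K = b.size();
  std::vector<int> zeta(K, 0);
  std::vector<double> u(K);
  std::vector<int> v(K, 0);

  for (int k = 0; k < K; ++k) {
    if (clamp[k] == 1) zeta[k] = tau;
    else if (clamp[k] == 0) zeta[k] = 0;
    else if (zeta_init.size() == K) zeta[k] = (int)zeta_init[k];
    v[k] = zeta[k] > 0 ? 1 : 0;
  }

  // membrane potentials, maintained incrementally in rect mode
  for (int k = 0; k < K; ++k) {
    double s = b[k];
    for (int j = 0; j < K; ++j) s += W(k, j) * v[j];
    u[k] = s;
  }

  // alpha-PSP traces: psp_j = kappa * (A_j - B_j)
  std::vector<double> A(K, 0.0), B(K, 0.0);
  const double decF = std::exp(-dt / tau_fall), decR = std::exp(-dt / tau_rise);

  const double logtau = std::log((double)tau);
  const int total = burn_in + n_sweeps;
  const int n_rec = (thin > 0) ? n_sweeps / thin : 0;

  IntegerMatrix states;
  if (record_states) states = IntegerMatrix(n_rec, K);
  NumericVector counts;
  if (count_states) {
    if (K > 20) stop("state counting requires K <= 20");
    counts = NumericVector(1 << K);
  }
  std::vector<double> sp_t;
  std::vector<int> sp_id;

  std::vector<int> order(K);
  for (int k = 0; k < K; ++k) order[k] = k;
  int rec_row = 0;

  for (int sweep = 0; sweep < total; ++sweep) {
    if (psp_mode == 1) {
      // decay traces one step, then refresh all membrane potentials
      for (int j = 0; j < K; ++j) { A[j] *= decF; B[j] *= decR; }
      for (int k = 0; k < K; ++k) {
        double s = b[k];
        for (int j = 0; j < K; ++j) s += W(k, j) * kappa * (A[j] - B[j]);
        u[k] = s;
      }
    }
    if (random_order) {
      for (int k = K - 1; k > 0; --k) {
        int j = (int)std::floor(unif_rand() * (k + 1));
        if (j > k) j = k;
        std::swap(order[k], order[j]);
      }
    }
    for (int kk = 0; kk < K; ++kk) {
      int k = order[kk];
      if (clamp[k] >= 0) continue;
      int z = zeta[k];
      bool spike = false;
      if (mechanism == 0) {          // absolute
        if (z <= 1) spike = unif_rand() < sigmoidc(u[k] - logtau);
        else { zeta[k] = z - 1; continue; }
        zeta[k] = spike ? tau : 0;
      } else {                       // relative
        double pf = g[z] * flookup(f_values, f_u0, f_step, u[k]);
        spike = unif_rand() < pf;
        if (spike) zeta[k] = tau;
        else zeta[k] = (z >= 1) ? z - 1 : 0;
      }
      int vnew = zeta[k] > 0 ? 1 : 0;
      if (vnew != v[k]) {
        if (psp_mode == 0) {
          double d = vnew - v[k];
          for (int i = 0; i < K; ++i) u[i] += W(i, k) * d;
        }
        v[k] = vnew;
      }
      if (spike) {
        if (psp_mode == 1) { A[k] += 1.0; B[k] += 1.0; }
        if (record_spikes && sweep >= burn_in) {
          sp_t.push_back((sweep - burn_in + 1) * dt);
          sp_id.push_back(k + 1);
        }
      }
    }
    if (sweep >= burn_in && thin > 0) {
      int i = sweep - burn_in;
      if ((i + 1) % thin == 0 && rec_row < n_rec) {
        if (record_states)
          for (int k = 0; k < K; ++k) states(rec_row, k) = v[k];
        if (count_states) {
          int code = 0;
          for (int k = 0; k < K; ++k) code |= v[k] << k;
          counts[code] += 1.0;
        }
        ++rec_row;
      }
    }
  }

  List out = List::create(
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["zeta_final"] = IntegerVector(zeta.begin(), zeta.end()));
  if (record_states) out["states"] = states;
  if (count_states) out["counts"] = counts;
  return out;
}

// [[Rcpp::export]]
List cpp_gibbs(const NumericMatrix& W, const NumericVector& b, int n_scans,
               int burn_in, int thin, bool record_states, bool count_states) {
  RNGScope scope;
  const int K = b.size();
  std::vector<int> v(K, 0);
  std::vector<double> u(K);
  for (int k = 0; k < K; ++k) u[k] = b[k];

  const int total = burn_in + n_scans;
  const int n_rec = (thin > 0) ? n_scans / thin : 0;
  IntegerMatrix states;
  if (record_states) states = IntegerMatrix(n_rec, K);
  NumericVector counts;
  if (count_states) {
    if (K > 20) stop("state counting requires K <= 20");
    counts = NumericVector(1 << K);
  }
  int rec_row = 0;
  for (int scan = 0; scan < total; ++scan) {
    for (int k = 0; k < K; ++k) {
      int vnew = unif_rand() < sigmoidc(u[k]) ? 1 : 0;
      if (vnew != v[k]) {
        double d = vnew - v[k];
        for (int i = 0; i < K; ++i) u[i] += W(i, k) * d;
        v[k] = vnew;
      }
    }
    if (scan >= burn_in && thin > 0) {
      int i = scan - burn_in;
      if ((i + 1) % thin == 0 && rec_row < n_rec) {
        if (record_states)
          for (int k = 0; k < K; ++k) states(rec_row, k) = v[k];
        if (count_states) {
          int code = 0;
          for (int k = 0; k < K; ++k) code |= v[k] << k;
          counts[code] += 1.0;
        }
        ++rec_row;
      }
    }
  }
  List out = List::create(_["dummy"] = 0);
  if (record_states) out["states"] = states;
  if (count_states) out["counts"] = counts;
  return out;
}

// Event-driven continuous-time sampler, absolute mechanism.  Between events
// every resting neuron fires as a Poisson process with rate exp(u)/tau;
// refractory neurons recover (v -> 0) exactly tau_ms after their spike.
// Rates are piecewise constant between events, so competing exponential
// clocks sampled at each event give an exact simulation.
// [[Rcpp::export]]
List cpp_jump_process(const NumericMatrix& W, const NumericVector& b,
                      double tau_ms, double t_total, double burn_in,
                      bool record_spikes, bool track_occupancy) {
  RNGScope scope;
  const int K = b.size();
  if (track_occupancy && K > 20) stop("occupancy tracking requires K <= 20");
  std::vector<double> recover(K, -1.0);  // recovery time; <0 means resting
  std::vector<int> v(K, 0);
  std::vector<double> u(K);
  for (int k = 0; k < K; ++k) u[k] = b[k];

  NumericVector occupancy(track_occupancy ? (1 << K) : 1);
  NumericVector active_ms(K);
  std::vector<double> sp_t;
  std::vector<int> sp_id;

  double t = 0.0;
  const double t_end = burn_in + t_total;
  int code = 0;

  while (t < t_end) {
    // next scheduled recovery
    double t_rec = R_PosInf;
    int k_rec = -1;
    for (int k = 0; k < K; ++k)
      if (v[k] && recover[k] < t_rec) { t_rec = recover[k]; k_rec = k; }
    // total firing rate of resting neurons
    double R = 0.0;
    for (int k = 0; k < K; ++k) if (!v[k]) R += std::exp(u[k]) / tau_ms;
    double t_fire = (R > 0.0) ? t + exp_rand() / R : R_PosInf;

    double t_next = std::min(std::min(t_rec, t_fire), t_end);
    double dur = t_next - t;
    if (dur > 0.0) {
      double lo = std::max(t, burn_in), hi = std::min(t_next, t_end);
      if (hi > lo) {
        if (track_occupancy) occupancy[code] += hi - lo;
        for (int k = 0; k < K; ++k) if (v[k]) active_ms[k] += hi - lo;
      }
    }
    t = t_next;
    if (t >= t_end) break;

    if (t_rec <= t_fire) {           // recovery event
      int k = k_rec;
      v[k] = 0; recover[k] = -1.0;
      for (int i = 0; i < K; ++i) u[i] -= W(i, k);
      if (track_occupancy) code &= ~(1 << k);
    } else {                         // spike among resting neurons
      double pick = unif_rand() * R, acc = 0.0;
      int k = -1;
      for (int j = 0; j < K; ++j) {
        if (v[j]) continue;
        acc += std::exp(u[j]) / tau_ms;
        if (pick <= acc) { k = j; break; }
      }
      if (k < 0) { for (int j = K - 1; j >= 0; --j) if (!v[j]) { k = j; break; } }
      v[k] = 1; recover[k] = t + tau_ms;
      for (int i = 0; i < K; ++i) u[i] += W(i, k);
      if (track_occupancy) code |= (1 << k);
      if (record_spikes && t >= burn_in) {
        sp_t.push_back(t - burn_in);
        sp_id.push_back(k + 1);
      }
    }
  }

  return List::create(
    _["occupancy"] = occupancy,
    _["active_ms"] = active_ms,
    _["spike_t"] = NumericVector(sp_t.begin(), sp_t.end()),
    _["spike_id"] = IntegerVector(sp_id.begin(), sp_id.end()));
}

// Contrastive-divergence training of a masked Boltzmann machine using the
// relative-refractory sampling network for the free-running (negative)
// phase.  Posterior samples are drawn from the tuning-curve generative
// model: phi ~ U[0, pi), v+_k ~ Bernoulli(tc_k(phi)).
// [[Rcpp::export]]
List cpp_cd_train(const NumericMatrix& W0, const NumericVector& b0,
                  const LogicalMatrix& mask,
                  const NumericVector& phi_hat, double tune_base,
                  double tune_contrast, double tune_peak, int tau,
                  const NumericVector& g, const NumericVector& f_values,
                  double f_u0, double f_step, int n_patterns, int free_steps,
                  double eta) {
  RNGScope scope;
  NumericMatrix W = clone(W0);
  NumericVector b = clone(b0);
  const int K = b.size();
  std::vector<int> vp(K), vm(K), zeta(K);
  std::vector<double> u(K);

  for (int pat = 0; pat < n_patterns; ++pat) {
    // posterior sample from the tuning model
    double phi = unif_rand() * M_PI;
    for (int k = 0; k < K; ++k) {
      double tc = tune_base + tune_contrast *
        std::exp(tune_peak * (std::cos(2.0 * (phi - phi_hat[k])) - 1.0));
      if (tc < 0.0) tc = 0.0;
      if (tc > 1.0) tc = 1.0;
      vp[k] = unif_rand() < tc ? 1 : 0;
    }
    // initialise chain at the posterior sample: zeta ~ U{1..tau} if active
    for (int k = 0; k < K; ++k) {
      if (vp[k]) {
        int z = 1 + (int)std::floor(unif_rand() * tau);
        if (z > tau) z = tau;
        zeta[k] = z;
      } else zeta[k] = 0;
    }
    for (int k = 0; k < K; ++k) {
      double s = b[k];
      for (int j = 0; j < K; ++j) s += W(k, j) * (zeta[j] > 0 ? 1.0 : 0.0);
      u[k] = s;
    }
    // free-run (negative phase)
    for (int step = 0; step < free_steps; ++step) {
      for (int k = 0; k < K; ++k) {
        int z = zeta[k];
        double pf = g[z] * flookup(f_values, f_u0, f_step, u[k]);
        int znew = (unif_rand() < pf) ? tau : (z >= 1 ? z - 1 : 0);
        int vold = z > 0 ? 1 : 0, vnew = znew > 0 ? 1 : 0;
        zeta[k] = znew;
        if (vnew != vold) {
          double d = vnew - vold;
          for (int i = 0; i < K; ++i) u[i] += W(i, k) * d;
        }
      }
    }
    for (int k = 0; k < K; ++k) vm[k] = zeta[k] > 0 ? 1 : 0;
    // parameter update within the connectivity mask, symmetric, zero diag
    for (int k = 0; k < K; ++k) {
      b[k] += eta * (vp[k] - vm[k]);
      for (int j = k + 1; j < K; ++j) {
        if (!mask(k, j)) continue;
        double d = eta * ((double)(vp[k] * vp[j]) - (double)(vm[k] * vm[j]));
        W(k, j) += d;
        W(j, k) += d;
      }
    }
  }
  return List::create(_["W"] = W, _["b"] = b);
}
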