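#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact stochastic simulation of the Schloegl birth-death chain.
//
// Channels (state X, volume omega, reservoir concentrations a and b):
//   +1 : X -> X+1   W =  k1 * a * omega
//   -1 : X -> X-1   W =  km1 * X
//   +2 : X -> X-1   W =  k2 * X (X-1) (X-2) / omega^2      (3X -> 2X + B)
//   -2 : X -> X+1   W =  km2 * b * X (X-1) / omega         (2X + B -> 3X)
//
// Each jump carries a medium-entropy increment ln(W_r(X->X') / W_{-r}(X'->X)),
// the forward rate out of the current state over the reverse rate out of the
// landing state, which telescopes to the trajectory entropy flow.
//
// Jump records (times, states, channels, per-jump entropy) are kept up to
// `record_limit` events; occupancy times and cumulative entropy are always
// accumulated, so arbitrarily long runs stay in O(max X) memory.  Occupancy
// only counts time past `burn_in`.  Uses R's RNG (reproducible via set.seed).

// [[Rcpp::export(name = ".ssa_core")]]
List ssa_core(double k1a, double km1, double k2, double km2, double b,
              double omega, int X0, double tmax, double burn_in = 0.0,
              double record_limit = 1e6) {
  if (X0 < 0) stop("X0 must be a nonnegative integer");
  if (tmax <= 0) stop("tmax must be positive");

  RNGScope scope;

  const double W1 = k1a * omega;  // constant birth propensity
  long long X = X0;
  double t = 0.0;
  double ds_total = 0.0;
  double n_events = 0.0;
  bool absorbed = false;

  std::vector<double> occ;  // holding time per state, past burn_in
  occ.resize(std::max<long long>(X + 2, 64), 0.0);

  const bool record0 = record_limit > 0;
  std::vector<double> rec_t, rec_ds;
  std::vector<int> rec_X, rec_ch;
  bool recording = record0, recorded_all = true;
  if (record0) {
    size_t cap = (size_t)std::min(record_limit, 1e6);
    rec_t.reserve(cap); rec_X.reserve(cap); rec_ch.reserve(cap); rec_ds.reserve(cap);
  }

  while (t < tmax) {
    double Xd = (double)X;
    double Wm1 = km1 * Xd;
    double W2 = (X >= 3) ? k2 * Xd * (Xd - 1.0) * (Xd - 2.0) / (omega * omega) : 0.0;
    double Wm2 = (X >= 2) ? km2 * b * Xd * (Xd - 1.0) / omega : 0.0;
    double Rtot = W1 + Wm1 + W2 + Wm2;

    if (Rtot <= 0.0) { absorbed = true; break; }

    double dt = R::exp_rand() / Rtot;
    double t_new = t + dt;

    // occupancy of the state being left, clipped to [burn_in, tmax]
    double lo = std::max(t, burn_in), hi = std::min(t_new, tmax);
    if (hi > lo) {
      if ((size_t)X >= occ.size()) occ.resize((size_t)X * 2 + 2, 0.0);
      occ[(size_t)X] += hi - lo;
    }
    if (t_new >= tmax) { t = tmax; break; }
    t = t_new;

    double u = unif_rand() * Rtot;
    int ch; double ds;
    if (u < W1) {                       // +1 birth
      ch = 1;
      ds = std::log(W1 / (km1 * (Xd + 1.0)));
      X += 1;
    } else if (u < W1 + Wm1) {          // -1 death
      ch = -1;
      ds = std::log((km1 * Xd) / W1);
      X -= 1;
    } else if (u < W1 + Wm1 + W2) {     // +2 death (3X -> 2X + B)
      // reverse: -2 birth out of X-1 with rate km2 b (X-1)(X-2)/omega
      ch = 2;
      ds = std::log((k2 * Xd) / (km2 * b * omega));
      X -= 1;
    } else {                            // -2 birth (2X + B -> 3X)
      // reverse: +2 death out of X+1 with rate k2 (X+1)X(X-1)/omega^2
      ch = -2;
      ds = std::log((km2 * b * omega) / (k2 * (Xd + 1.0)));
      X += 1;
    }
    ds_total += ds;
    n_events += 1.0;

    if (recording) {
      if (n_events <= record_limit) {
        rec_t.push_back(t); rec_X.push_back((int)X);
        rec_ch.push_back(ch); rec_ds.push_back(ds);
      } else {
        recording = false; recorded_all = false;
      }
    } else if (record0) {
      recorded_all = false;
    }
  }

  return List::create(
    _["t_end"] = std::min(t, tmax),
    _["n_events"] = n_events,
    _["ds_total"] = ds_total,
    _["X_final"] = (double)X,
    _["occupancy"] = NumericVector(occ.begin(), occ.end()),
    _["absorbed"] = absorbed,
    _["recorded_all"] = record0 ? recorded_all : false,
    _["times"] = NumericVector(rec_t.begin(), rec_t.end()),
    _["states"] = IntegerVector(rec_X.begin(), rec_X.end()),
    _["channels"] = IntegerVector(rec_ch.begin(), rec_ch.end()),
    _["ds_increments"] = NumericVector(rec_ds.begin(), rec_ds.end()));
}

// Batch runner: n independent trajectories from given initial states, no jump
// records; returns total medium entropy and final state per trajectory.
// Used for ensemble entropy-production estimates and fluctuation-theorem
// checks where only trajectory totals are needed.

// [[Rcpp::export(name = ".ssa_ensemble")]]
List ssa_ensemble(double k1a, double km1, double k2, double km2, double b,
                  double omega, IntegerVector X0, double tmax) {
  RNGScope scope;
  int n = X0.size();
  NumericVector ds(n), Xf(n);
  const double W1 = k1a * omega;
  for (int i = 0; i < n; ++i) {
    long long X = X0[i];
    double t = 0.0, s = 0.0;
    while (true) {
      double Xd = (double)X;
      double Wm1 = km1 * Xd;
      double W2 = (X >= 3) ? k2 * Xd * (Xd - 1.0) * (Xd - 2.0) / (omega * omega) : 0.0;
      double Wm2 = (X >= 2) ? km2 * b * Xd * (Xd - 1.0) / omega : 0.0;
      double Rtot = W1 + Wm1 + W2 + Wm2;
      if (Rtot <= 0.0) break;
      t += R::exp_rand() / Rtot;
      if (t >= tmax) break;
      double u = unif_rand() * Rtot;
      if (u < W1) { s += std::log(W1 / (km1 * (Xd + 1.0))); X += 1; }
      else if (u < W1 + Wm1) { s += std::log((km1 * Xd) / W1); X -= 1; }
      else if (u < W1 + Wm1 + W2) { s += std::log((k2 * Xd) / (km2 * b * omega)); X -= 1; }
      else { s += std::log((km2 * b * omega) / (k2 * (Xd + 1.0))); X += 1; }
    }
    ds[i] = s;
    Xf[i] = (double)X;
  }
  return List::create(_["ds_total"] = ds, _["X_final"] = Xf);
}
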