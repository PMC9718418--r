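#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Gillespie direct-method kernel for one perturbation-free segment.
//
// The reaction network arrives flattened in CSR-like form (all indices
// 0-based):
//   react_ptr[j] .. react_ptr[j+1]-1 index into (react_idx, react_mult):
//     the distinct reactant species of reaction j and their multiplicities.
//   net_ptr / net_idx / net_delta: net stoichiometric change of reaction j.
//
// Propensity convention: rate * prod_s C(x_s, m_s) (combination counting);
// zero when any reactant count is below its multiplicity.
//
// Randomness comes from R's RNG (unif_rand), so a set.seed() in the caller
// makes the whole event sequence reproducible.  Each event consumes exactly
// two uniforms (waiting time, reaction identity); idle periods consume none.
// That makes the event sequence invariant (up to exact time rescaling) when
// all rates are scaled by a constant.
//
// Samples: states are recorded at the given sample_times (must lie within
// [t0, t1] and be increasing); the state recorded at time s reflects every
// reaction with firing time <= s.
//
// stop_idx >= 0 turns on first-passage mode: the kernel returns as soon as
// state[stop_idx] <= stop_leq (checked at entry and after every firing).

static inline double combinations(int x, int m) {
  if (x < m) return 0.0;
  double c = 1.0;
  for (int i = 0; i < m; ++i) c *= (double)(x - i);
  for (int i = 2; i <= m; ++i) c /= (double)i;
  return c;
}

// [[Rcpp::export]]
List ssa_segment(IntegerVector react_ptr, IntegerVector react_idx,
                 IntegerVector react_mult, IntegerVector net_ptr,
                 IntegerVector net_idx, IntegerVector net_delta,
                 NumericVector rates, IntegerVector state0, double t0,
                 double t1, NumericVector sample_times, bool record_events,
                 int stop_idx, int stop_leq) {
  const int n_rxn = rates.size();
  const int n_sp = state0.size();
  std::vector<int> x(state0.begin(), state0.end());
  std::vector<double> a(n_rxn);

  const int n_samp = sample_times.size();
  IntegerMatrix samples(n_samp, n_sp);
  int sp = 0;  // next sample slot to fill

  std::vector<double> ev_times;
  std::vector<int> ev_rxn;

  double t = t0;
  bool stopped = false;
  double stop_time = NA_REAL;
  double n_events = 0.0;

  RNGScope scope;

  if (stop_idx >= 0 && x[stop_idx] <= stop_leq) {
    stopped = true;
    stop_time = t0;
  }

  while (!stopped) {
    double a0 = 0.0;
    for (int j = 0; j < n_rxn; ++j) {
      double aj = rates[j];
      if (aj > 0.0) {
        for (int k = react_ptr[j]; k < react_ptr[j + 1]; ++k) {
          const int m = react_mult[k];
          const int xs = x[react_idx[k]];
          if (xs < m) { aj = 0.0; break; }
          aj *= (m == 1) ? (double)xs : combinations(xs, m);
        }
      }
      a[j] = aj;
      a0 += aj;
    }

    if (a0 <= 0.0) break;  // idle until end of segment

    double u = unif_rand();
    if (u <= 0.0) u = DBL_MIN;
    const double tnew = t + (-std::log(u) / a0);
    if (tnew > t1) break;

    // emit samples strictly before the firing time
    while (sp < n_samp && sample_times[sp] < tnew) {
      for (int s = 0; s < n_sp; ++s) samples(sp, s) = x[s];
      ++sp;
    }

    // pick the reaction proportionally to propensity
    double r = unif_rand() * a0;
    int j = n_rxn - 1;
    double cum = 0.0;
    for (int jj = 0; jj < n_rxn; ++jj) {
      cum += a[jj];
      if (r <= cum) { j = jj; break; }
    }

    for (int k = net_ptr[j]; k < net_ptr[j + 1]; ++k) {
      x[net_idx[k]] += net_delta[k];
      if (x[net_idx[k]] < 0)
        stop("negative count for species index %d after reaction %d",
             net_idx[k] + 1, j + 1);
    }
    t = tnew;
    n_events += 1.0;
    if (record_events) {
      ev_times.push_back(t);
      ev_rxn.push_back(j + 1);
    }
    if (stop_idx >= 0 && x[stop_idx] <= stop_leq) {
      stopped = true;
      stop_time = t;
    }
  }

  // remaining samples see the final state
  while (sp < n_samp) {
    for (int s = 0; s < n_sp; ++s) samples(sp, s) = x[s];
    ++sp;
  }

  IntegerVector out_state(x.begin(), x.end());
  return List::create(
      _["state"] = out_state, _["samples"] = samples,
      _["stopped"] = stopped, _["stop_time"] = stop_time,
      _["n_events"] = n_events,
      _["event_times"] = NumericVector(ev_times.begin(), ev_times.end()),
      _["event_rxn"] = IntegerVector(ev_rxn.begin(), ev_rxn.end()));
}
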