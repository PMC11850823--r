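#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Michaelis-Menten clearance: dC/dt = -vmax * C / (km + C)
static inline double mm_rate(double c, double vmax, double km) {
  return -vmax * c / (km + c);
}

// One RK4 step of the clearance ODE.
static inline double rk4_step(double c, double h, double vmax, double km) {
  double k1 = mm_rate(c, vmax, km);
  double k2 = mm_rate(c + 0.5 * h * k1, vmax, km);
  double k3 = mm_rate(c + 0.5 * h * k2, vmax, km);
  double k4 = mm_rate(c + h * k3, vmax, km);
  double out = c + h / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
  return out < 0.0 ? 0.0 : out;
}

// Integrate the release/uptake model over [0, max(out_times)].
// Each pulse adds `dap` instantaneously at its pulse time; output values at a
// pulse time are post-increment. Integration proceeds piecewise between the
// sorted knots (output times union pulse times) with RK4 substeps of at most
// `dt` seconds.
// [[Rcpp::export(name = ".mm_integrate")]]
NumericVector mm_integrate(NumericVector out_times, NumericVector pulse_times,
                           double dap, double vmax, double km, double dt) {
  int n_out = out_times.size();
  int n_pulse = pulse_times.size();
  NumericVector out(n_out);
  if (n_out == 0) return out;

  // knots: merged sorted event times, tagged by kind
  std::vector<std::pair<double, int>> knots; // kind: 0 = output, 1 = pulse
  knots.reserve(n_out + n_pulse);
  for (int i = 0; i < n_out; ++i) knots.push_back(std::make_pair(out_times[i], 0));
  for (int i = 0; i < n_pulse; ++i) knots.push_back(std::make_pair(pulse_times[i], 1));
  // pulses sort before outputs at equal time so outputs see the increment
  std::stable_sort(knots.begin(), knots.end(),
                   [](const std::pair<double, int>& a, const std::pair<double, int>& b) {
                     if (a.first != b.first) return a.first < b.first;
                     return a.second > b.second;
                   });

  double t = 0.0, c = 0.0;
  int i_out = 0;
  for (size_t k = 0; k < knots.size(); ++k) {
    double tk = knots[k].first;
    double span = tk - t;
    if (span > 1e-12) {
      int nstep = (int)std::ceil(span / dt);
      double h = span / nstep;
      for (int s = 0; s < nstep; ++s) c = rk4_step(c, h, vmax, km);
    }
    t = tk;
    if (knots[k].second == 1) {
      c += dap;
    } else {
      out[i_out++] = c;
    }
  }
  return out;
}
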