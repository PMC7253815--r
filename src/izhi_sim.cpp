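#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the two-variable quadratic neuron model with
// after-spike reset.  `current` holds the injected current at every grid
// point; step i uses current[i-1] (the state's own time).  Spike samples are
// stored clipped at `peak` and the reset is applied to the carried state.
// [[Rcpp::export]]
List izhi_simulate_cpp(double a, double b, double c, double d,
                       NumericVector current, double dt,
                       double v0, double u0, double peak) {
  const int n = current.size();
  NumericVector v(n), u(n);
  std::vector<int> spike_idx;
  double cv = v0, cu = u0;
  v[0] = cv;
  u[0] = cu;
  for (int i = 1; i < n; ++i) {
    const double I = current[i - 1];
    const double nv = cv + dt * (0.04 * cv * cv + 5.0 * cv + 140.0 - cu + I);
    const double nu = cu + dt * a * (b * cv - cu);
    if (!std::isfinite(nv) || !std::isfinite(nu)) {
      return List::create(_["diverged"] = true, _["step"] = i,
                          _["v"] = v, _["u"] = u,
                          _["spike_idx"] = IntegerVector(0));
    }
    if (nv >= peak) {
      v[i] = peak;              // clipped apex for plotting/MSE
      spike_idx.push_back(i);   // 0-based grid index of the spike sample
      cv = c;
      cu = nu + d;
    } else {
      v[i] = nv;
      cv = nv;
      cu = nu;
    }
    u[i] = cu;
  }
  return List::create(_["diverged"] = false, _["step"] = -1,
                      _["v"] = v, _["u"] = u,
                      _["spike_idx"] = wrap(spike_idx));
}
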