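#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire membrane with spike-triggered adaptation and a
// slow hyperpolarization-activated (H-like) inward current.  Spikes are
// rendered as a stylized piecewise-linear template (upstroke to
// v_th + spike_amp, downstroke to v_th + ahp_depth) so that waveform
// features (dv/dt extrema, amplitude, half-width, AHP) are well defined and
// analytically predictable from the parameters.
//
// Units: mV, pA, ms, MOhm, pF, nS.  tau_m (ms) = r_MOhm * c_pF / 1000.
//
// [[Rcpp::export(name = ".lif_integrate")]]
List lif_integrate(NumericVector current_pA, double dt_ms, double v0,
                   double e_leak, double r_MOhm, double c_pF,
                   double v_th, double spike_amp, double ahp_depth,
                   double dvdt_max, double dvdt_min,
                   double adapt_increment_pA, double adapt_tau_ms,
                   double gh_nS, double sag_tau_ms, double sag_vhalf,
                   double sag_slope, double e_h,
                   double w0, double s0) {
  const int n = current_pA.size();
  const double tau_ms = r_MOhm * c_pF / 1000.0;
  if (dt_ms <= 0.0)
    stop("dt must be positive");
  if (dt_ms > tau_ms / 5.0)
    stop("unstable integration: dt = %f ms too large for tau_m = %f ms",
         dt_ms, tau_ms);

  // spike template geometry (in samples, at least one sample per limb)
  const double t_rise = spike_amp / dvdt_max;                    // ms
  const double t_fall = (spike_amp - ahp_depth) / (-dvdt_min);   // ms
  const int n_rise = std::max(1, (int)std::lround(t_rise / dt_ms));
  const int n_fall = std::max(1, (int)std::lround(t_fall / dt_ms));
  // brief post-AHP recovery limb so the waveform minimum is interior
  const double rec_ms = 3.0, rec_frac = 0.5;
  const int n_rec = std::max(1, (int)std::lround(rec_ms / dt_ms));

  NumericVector v(n);
  std::vector<int> spikes;
  double V = v0, w = w0, s = s0;
  v[0] = V;

  int i = 1;
  while (i < n) {
    // gating/adaptation dynamics
    const double s_inf = 1.0 / (1.0 + std::exp((V - sag_vhalf) / sag_slope));
    s += dt_ms * (s_inf - s) / sag_tau_ms;
    w += -dt_ms * w / adapt_tau_ms;
    const double i_h = gh_nS * s * (e_h - V);  // nS * mV = pA
    const double i_total =
        1000.0 * (e_leak - V) / r_MOhm + current_pA[i - 1] + i_h - w;
    V += dt_ms * i_total / c_pF;

    if (V >= v_th) {
      // threshold crossing: paste the stylized spike template
      spikes.push_back(i);  // 1-based index returned below
      w += adapt_increment_pA;
      int k = 0;
      for (; k <= n_rise && i + k < n; ++k)
        v[i + k] = v_th + spike_amp * (double)k / n_rise;
      for (int j = 1; j <= n_fall && i + n_rise + j < n; ++j)
        v[i + n_rise + j] =
            v_th + spike_amp - (spike_amp - ahp_depth) * (double)j / n_fall;
      for (int j = 1; j <= n_rec && i + n_rise + n_fall + j < n; ++j)
        v[i + n_rise + n_fall + j] =
            v_th + ahp_depth * (1.0 - (1.0 - rec_frac) * (double)j / n_rec);
      // advance state past the template; decay w passively meanwhile
      const int n_tpl = n_rise + n_fall + n_rec;
      w *= std::exp(-n_tpl * dt_ms / adapt_tau_ms);  // H-gate frozen
      V = v_th + ahp_depth * rec_frac;
      i += n_tpl + 1;
      if (i <= n) {
        if (i < n) v[i] = V;
        ++i;
      }
      continue;
    }
    v[i] = V;
    ++i;
  }

  IntegerVector sp(spikes.size());
  for (size_t j = 0; j < spikes.size(); ++j) sp[j] = spikes[j] + 1;
  return List::create(_["v_mV"] = v, _["spike_samples"] = sp,
                      _["w_final"] = w, _["s_final"] = s,
                      _["n_rise"] = n_rise, _["n_fall"] = n_fall);
}
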