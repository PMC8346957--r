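#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// 1-D Yee FDTD stepper with an auxiliary-differential-equation fractional
// Drude medium. Normalized units: c = dx = eps0 = mu0 = 1, so dt is the
// Courant number. The polarization update is
//   P_{t+1} = coef_E * (E_t + E_{t+1})/2 + sum_{j=0..N} coef_hist[j] * P_{t-j}
// with coef_hist the combined Grunwald-Letnikov memory coefficients
// precomputed in R. The field average is solved jointly with the E update
// (the polarization current (P_{t+1}-P_t)/dt enters Ampere's law), which
// keeps the coupled scheme stable up to the vacuum Courant limit dt = 1;
// first-order Mur absorbing terminations at both ends.
//
// med_start/med_end are 0-based inclusive cell indices of the medium slab.
// probe_cells are 0-based. Returns probe E and P series plus a divergence
// flag (max |E| exceeding div_threshold, checked every check_every steps).
// [[Rcpp::export(name = ".fdtd_run_cpp")]]
List fdtd_run_cpp(int n_cells,
                  int med_start, int med_end,
                  double eps_inf, double sigma_dc,
                  double dt,
                  NumericVector coef_hist, double coef_E,
                  int n_steps,
                  int src_pos, int source_kind,
                  double omega, double amplitude, double ramp_steps,
                  double pulse_center, double pulse_width,
                  IntegerVector probe_cells,
                  double div_threshold, int check_every,
                  int record_full_every) {
  const int N1 = coef_hist.size();      // N + 1 history slots
  const int n_med = (med_end >= med_start) ? (med_end - med_start + 1) : 0;
  const int n_probe = probe_cells.size();

  std::vector<double> E(n_cells, 0.0), H(std::max(n_cells - 1, 0), 0.0);
  // ring buffer: hist[slot * n_med + cell]; head points at P_t
  std::vector<double> hist((size_t)N1 * std::max(n_med, 1), 0.0);
  int head = 0;
  std::vector<double> Pnew(std::max(n_med, 1), 0.0);

  // joint E/P update factors for medium cells (vacuum: eps = 1, sigma = 0):
  //   denomE * E_{t+1} = numE * E_t + dt * curlH - H_P + P_t
  //   P_{t+1} = H_P + coef_E * (E_t + E_{t+1}) / 2
  // with H_P the polarization history sum.
  const double denomE = eps_inf + 0.5 * coef_E + 0.5 * sigma_dc * dt;
  const double numE = eps_inf - 0.5 * coef_E - 0.5 * sigma_dc * dt;
  if (n_med > 0 && denomE == 0.0)
    stop("degenerate medium: joint E/P update denominator vanishes");

  const double mur = (dt - 1.0) / (dt + 1.0);

  NumericMatrix e_rec(n_steps, n_probe), p_rec(n_steps, n_probe);
  NumericVector energy(record_full_every > 0 ? n_steps : 0);
  bool diverged = false;
  int steps_done = 0;

  for (int t = 0; t < n_steps; ++t) {
    // H at half step
    for (int i = 0; i < n_cells - 1; ++i) H[i] += dt * (E[i + 1] - E[i]);

    // polarization history sum H_P per medium cell
    if (n_med > 0) {
      for (int c = 0; c < n_med; ++c) Pnew[c] = 0.0;
      for (int j = 0; j < N1; ++j) {
        const double w = coef_hist[j];
        if (w == 0.0) continue;
        const double* ph = &hist[(size_t)((head + j) % N1) * n_med];
        for (int c = 0; c < n_med; ++c) Pnew[c] += w * ph[c];
      }
    }

    // joint E/P update (store edge values for Mur before overwriting)
    const double e0_old = E[0], e1_old = E[1];
    const double eM_old = E[n_cells - 1], eM1_old = E[n_cells - 2];
    for (int i = 1; i < n_cells - 1; ++i) {
      const double curl = H[i] - H[i - 1];
      if (i >= med_start && i <= med_end) {
        const int c = i - med_start;
        const double hp = Pnew[c];
        const double p_t = hist[(size_t)head * n_med + c];
        const double e_old = E[i];
        E[i] = (numE * e_old + dt * curl - hp + p_t) / denomE;
        Pnew[c] = hp + 0.5 * coef_E * (e_old + E[i]);
      } else {
        E[i] += dt * curl;
      }
    }
    // first-order Mur terminations
    E[0] = e1_old + mur * (E[1] - e0_old);
    E[n_cells - 1] = eM1_old + mur * (E[n_cells - 2] - eM_old);

    // push Pnew into the ring buffer
    if (n_med > 0) {
      head = (head + N1 - 1) % N1;
      double* ph = &hist[(size_t)head * n_med];
      for (int c = 0; c < n_med; ++c) ph[c] = Pnew[c];
    }

    // soft source
    const double tt = (t + 1) * dt;
    if (source_kind == 0) {            // monochromatic with raised-cosine ramp
      double ramp = 1.0;
      if (ramp_steps > 0 && (t + 1) < ramp_steps)
        ramp = 0.5 * (1.0 - std::cos(M_PI * (t + 1) / ramp_steps));
      E[src_pos] += amplitude * ramp * std::sin(omega * tt);
    } else {                           // gaussian pulse
      const double arg = (tt - pulse_center) / pulse_width;
      E[src_pos] += amplitude * std::exp(-arg * arg);
    }

    for (int p = 0; p < n_probe; ++p) {
      const int pc = probe_cells[p];
      e_rec(t, p) = E[pc];
      p_rec(t, p) = (pc >= med_start && pc <= med_end && n_med > 0)
                        ? hist[(size_t)head * n_med + (pc - med_start)]
                        : 0.0;
    }

    if (record_full_every > 0) {
      double en = 0.0;
      for (int i = 0; i < n_cells; ++i) en += E[i] * E[i];
      for (int i = 0; i < n_cells - 1; ++i) en += H[i] * H[i];
      energy[t] = 0.5 * en;
    }

    steps_done = t + 1;
    if (check_every > 0 && ((t + 1) % check_every == 0)) {
      double emax = 0.0;
      for (int i = 0; i < n_cells; ++i) {
        const double a = std::fabs(E[i]);
        if (a > emax) emax = a;
      }
      if (!std::isfinite(emax) || emax > div_threshold) {
        diverged = true;
        break;
      }
    }
  }

  List out = List::create(_["e"] = e_rec, _["p"] = p_rec,
                          _["diverged"] = diverged,
                          _["steps_done"] = steps_done);
  if (record_full_every > 0) {
    out["E_final"] = NumericVector(E.begin(), E.end());
    out["H_final"] = NumericVector(H.begin(), H.end());
    out["energy"] = energy;
  }
  return out;
}
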