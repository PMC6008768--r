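// Dormand-Prince 5(4) adaptive integrator for the whole-body compartment
// model. The system is linear with a piecewise-constant infusion input of
// duration T; the integration is split at T so the discontinuity never sits
// inside a step. Twelve states: the nine compartments B, H1, H2, G, R1, R2,
// T1, T2, U plus three cumulative fluxes (H2->G, G->H1, B->G) used for
// excretion bookkeeping.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int NS = 12;

// rate order shared with R/pbpk_model.R
// 0 k_bh1, 1 k_h1b, 2 k_h1h2, 3 k_h2g, 4 k_gh1, 5 k_bg,
// 6 k_br1, 7 k_r1b, 8 k_r1r2, 9 k_r2r1, 10 k_r1u,
// 11 k_bt, 12 k_tb1, 13 k_tb2
struct Model {
  double k[14];
  double f;        // f_bt1
  double rate_in;  // dose / T during infusion
  double T;        // infusion duration
  bool infusing;   // integration is split at T; the flag, not t, gates input

  void rhs(double t, const double* x, double* dx) const {
    (void)t;
    const double in = infusing ? rate_in : 0.0;
    const double B = x[0], H1 = x[1], H2 = x[2], G = x[3];
    const double R1 = x[4], R2 = x[5], T1 = x[6], T2 = x[7];
    dx[0] = in - (k[0] + k[6] + k[5] + k[11]) * B +
            k[1] * H1 + k[7] * R1 + k[12] * T1 + k[13] * T2;
    dx[1] = k[0] * B + k[4] * G - (k[1] + k[2]) * H1;
    dx[2] = k[2] * H1 - k[3] * H2;
    dx[3] = k[3] * H2 + k[5] * B - k[4] * G;
    dx[4] = k[6] * B + k[9] * R2 - (k[7] + k[8] + k[10]) * R1;
    dx[5] = k[8] * R1 - k[9] * R2;
    dx[6] = f * k[11] * B - k[12] * T1;
    dx[7] = (1.0 - f) * k[11] * B - k[13] * T2;
    dx[8] = k[10] * R1;
    dx[9] = k[3] * H2;   // cumulative hepatobiliary flux H2 -> G
    dx[10] = k[4] * G;   // cumulative reabsorbed flux G -> H1
    dx[11] = k[5] * B;   // cumulative transintestinal flux B -> G
  }
};

// Butcher tableau (Dormand-Prince RK5(4)7M)
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
                    a63 = 46732.0 / 5247, a64 = 49.0 / 176,
                    a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100,
                    e7 = -1.0 / 40;

// Advance x from t to t_end (t_end > t), adaptive steps, no interior output.
static void advance(const Model& m, double& t, double t_end, double* x,
                    double rtol, double atol) {
  if (t_end <= t) return;
  double h = std::min(1e-2, t_end - t);
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];
  double xs[NS], xn[NS];
  long nstep = 0;
  m.rhs(t, x, k1);
  while (t < t_end) {
    if (++nstep > 2000000L)
      stop("pbpk integrator: step limit exceeded (parameters may be extreme)");
    bool last = false;
    if (h >= t_end - t) { h = t_end - t; last = true; }
    for (int i = 0; i < NS; ++i) xs[i] = x[i] + h * a21 * k1[i];
    m.rhs(t + c2 * h, xs, k2);
    for (int i = 0; i < NS; ++i) xs[i] = x[i] + h * (a31 * k1[i] + a32 * k2[i]);
    m.rhs(t + c3 * h, xs, k3);
    for (int i = 0; i < NS; ++i)
      xs[i] = x[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    m.rhs(t + c4 * h, xs, k4);
    for (int i = 0; i < NS; ++i)
      xs[i] = x[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    m.rhs(t + c5 * h, xs, k5);
    for (int i = 0; i < NS; ++i)
      xs[i] = x[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    m.rhs(t + h, xs, k6);
    for (int i = 0; i < NS; ++i)
      xn[i] = x[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                          b5 * k5[i] + b6 * k6[i]);
    m.rhs(t + h, xn, k7);
    double err = 0.0;
    for (int i = 0; i < NS; ++i) {
      double e = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                      e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(x[i]), std::fabs(xn[i]));
      double r = e / sc;
      err += r * r;
    }
    err = std::sqrt(err / NS);
    if (err <= 1.0) {
      t += h;
      for (int i = 0; i < NS; ++i) { x[i] = xn[i]; k1[i] = k7[i]; } // FSAL
      if (last) break;
    }
    double fac = (err > 0.0) ? 0.9 * std::pow(err, -0.2) : 5.0;
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-14)
      stop("pbpk integrator: step size underflow");
  }
}

// [[Rcpp::export(name = ".solve_pbpk_cpp")]]
NumericMatrix solve_pbpk_cpp(NumericVector rates, double f_bt1,
                             NumericVector times, double dose, double T_inf,
                             double rtol = 1e-8, double atol = 1e-12) {
  if (rates.size() != 14) stop("rates must have 14 elements");
  if (T_inf <= 0) stop("T_inf must be > 0");
  for (int i = 0; i < 14; ++i)
    if (rates[i] < 0 || !std::isfinite(rates[i]))
      stop("rate constants must be finite and >= 0");
  if (f_bt1 < 0 || f_bt1 > 1) stop("f_bt1 must lie in [0, 1]");
  const int nt = times.size();
  for (int i = 1; i < nt; ++i)
    if (times[i] < times[i - 1]) stop("times must be non-decreasing");
  if (nt > 0 && times[0] < 0) stop("times must be >= 0");

  Model m;
  for (int i = 0; i < 14; ++i) m.k[i] = rates[i];
  m.f = f_bt1; m.T = T_inf; m.rate_in = dose / T_inf;
  m.infusing = true;

  NumericMatrix out(nt, NS);
  double x[NS] = {0};
  double t = 0.0;
  bool crossed = false;
  for (int j = 0; j < nt; ++j) {
    double target = times[j];
    if (!crossed && target >= T_inf) {
      advance(m, t, T_inf, x, rtol, atol);
      m.infusing = false;
      crossed = true;
    }
    advance(m, t, target, x, rtol, atol);
    for (int i = 0; i < NS; ++i) out(j, i) = x[i];
  }
  colnames(out) = CharacterVector::create(
      "B", "H1", "H2", "G", "R1", "R2", "T1", "T2", "U",
      "cum_h2g", "cum_gh1", "cum_bg");
  return out;
}

// Frame-averaged observed amounts for the fit objective. Returns an
// n_frames x 5 matrix (plasma, liver, gi, kidney, tissue): compartment sums
// plus vascular terms, averaged over each frame by the trapezoid rule on
// npts points per frame. C_blood(t) = (B/V_plasma) * (1 - hct).
// [[Rcpp::export(name = ".pbpk_frame_observed_cpp")]]
NumericMatrix pbpk_frame_observed_cpp(NumericVector rates, double f_bt1,
                                      double v_tissue, NumericMatrix frames,
                                      double dose, double T_inf, double bw,
                                      double v_blood, double hct,
                                      double v_liver, double v_kidney,
                                      int npts = 21,
                                      double rtol = 1e-8, double atol = 1e-12) {
  const int nf = frames.nrow();
  if (npts < 2) stop("npts must be >= 2");
  const double v_plasma = v_blood * (1.0 - hct) * bw;
  const double cb_per_B = (1.0 - hct) / v_plasma; // C_blood per unit B
  const double vl = v_blood * (v_liver * bw) * cb_per_B;   // liver vascular / B
  const double vk = v_blood * (v_kidney * bw) * cb_per_B;  // kidney vascular / B
  const double vt = v_blood * v_tissue * cb_per_B;         // tissue vascular / B

  // dense grid: npts per frame
  std::vector<double> grid(nf * npts);
  for (int i = 0; i < nf; ++i) {
    double a = frames(i, 0), b = frames(i, 1);
    if (b <= a) stop("frame end must exceed start");
    for (int j = 0; j < npts; ++j)
      grid[i * npts + j] = a + (b - a) * j / (npts - 1.0);
  }
  NumericVector tv(grid.begin(), grid.end());
  NumericMatrix sol = solve_pbpk_cpp(rates, f_bt1, tv, dose, T_inf, rtol, atol);

  NumericMatrix out(nf, 5);
  for (int i = 0; i < nf; ++i) {
    double acc[5] = {0, 0, 0, 0, 0};
    double span = grid[i * npts + npts - 1] - grid[i * npts];
    for (int j = 0; j + 1 < npts; ++j) {
      int r0 = i * npts + j, r1 = r0 + 1;
      double dt = grid[r1] - grid[r0];
      double y0[5], y1[5];
      for (int s = 0; s < 2; ++s) {
        int r = s == 0 ? r0 : r1;
        double* y = s == 0 ? y0 : y1;
        double B = sol(r, 0);
        y[0] = B;
        y[1] = sol(r, 1) + sol(r, 2) + vl * B;
        y[2] = sol(r, 3);
        y[3] = sol(r, 4) + sol(r, 5) + vk * B;
        y[4] = sol(r, 6) + sol(r, 7) + vt * B;
      }
      for (int q = 0; q < 5; ++q) acc[q] += dt * (y0[q] + y1[q]) / 2.0;
    }
    for (int q = 0; q < 5; ++q) out(i, q) = acc[q] / span;
  }
  colnames(out) = CharacterVector::create("plasma", "liver", "gi",
                                          "kidney", "tissue");
  return out;
}
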