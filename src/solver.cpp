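#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// State layout: 0=S stomach, 1=J jejunum, 2=R delay, 3=L ileum,
//               4=G plasma glucose (mM), 5=I plasma insulin (pM),
//               6=A cumulative absorbed gut glucose (mmol, bookkeeping state)
// Parameter vector layout (kept in step with .simo_param_vector in R/model.R):
// 0 k_js, 1 k_gj, 2 k_rj, 3 k_lr, 4 k_gl, 5 k_xg, 6 k_xgi, 7 k_xi,
// 8 k_ig_max, 9 gamma, 10 lambda_1g, 11 f, 12 f_gj, 13 V, 14 body_weight,
// 15 T_1g, 16 T_2gi, 17 lambda_2g, 18 G_star

static const int NS = 7;

static inline void simo_deriv(const double* y, const double* p, double* dy) {
  const double S = y[0], J = y[1], R = y[2], L = y[3];
  const double G = y[4] > 0.0 ? y[4] : 0.0;
  const double I = y[5] > 0.0 ? y[5] : 0.0;

  const double k_js = p[0], k_gj = p[1], k_rj = p[2], k_lr = p[3], k_gl = p[4];
  const double k_xg = p[5], k_xgi = p[6], k_xi = p[7], k_ig_max = p[8];
  const double gam = p[9], l1g = p[10], f = p[11], f_gj = p[12];
  const double Vd = p[13] * p[14];                 // distribution volume, L
  const double T_1g = p[15], T_2gi = p[16], l2g = p[17], G_star = p[18];

  const double absorb = k_gj * J + k_gl * L;        // mmol/min leaving the gut
  const double ra = f * absorb / Vd;                // mM/min appearing in plasma
  const double gprod = T_1g * std::exp(-l1g * G) + T_2gi * std::exp(-l2g * G * I);

  // incretin-augmented secretion drive: gut glucose content acts as a
  // plasma-glucose-concentration equivalent through f_gj
  const double H = G + f_gj * (J + L);
  double secr;
  if (H <= 0.0) {
    secr = 0.0;
  } else {
    const double hg = std::pow(H, gam);
    secr = k_ig_max * hg / (std::pow(G_star, gam) + hg);
  }

  dy[0] = -k_js * S;
  dy[1] = k_js * S - (k_gj + k_rj) * J;
  dy[2] = k_rj * J - k_lr * R;
  dy[3] = k_lr * R - k_gl * L;
  dy[4] = -k_xg * G - k_xgi * I * G + gprod + ra;
  dy[5] = -k_xi * I + secr;
  dy[6] = absorb;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                    a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
static const double e1 = 35.0 / 384 - 5179.0 / 57600,
                    e3 = 500.0 / 1113 - 7571.0 / 16695,
                    e4 = 125.0 / 192 - 393.0 / 640,
                    e5 = -2187.0 / 6784 + 92097.0 / 339200,
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// [[Rcpp::export(name = ".simo_solve_cpp")]]
NumericMatrix simo_solve_cpp(NumericVector p, double G_b, double I_b,
                             double dose, NumericVector times,
                             double rtol = 1e-8, double atol = 1e-10) {
  const int nt = times.size();
  NumericMatrix out(nt, NS);
  double y[NS] = {dose, 0.0, 0.0, 0.0, G_b, I_b, 0.0};
  double k1[NS], k2[NS], k3[NS], k4[NS], k5[NS], k6[NS], k7[NS];
  double yt[NS], ynew[NS];
  const double* pp = p.begin();

  int it = 0;
  double t = times[0];
  for (int j = 0; j < NS; ++j) out(0, j) = y[j];
  it = 1;
  if (it >= nt) return out;

  double h = 0.5;
  const double tend = times[nt - 1];
  long maxsteps = 2000000;
  bool have_k1 = false;

  while (t < tend && maxsteps-- > 0) {
    double tnext = times[it];
    if (t + h > tnext) h = tnext - t;
    if (h < 1e-12) h = 1e-12;

    if (!have_k1) simo_deriv(y, pp, k1);
    for (int j = 0; j < NS; ++j) yt[j] = y[j] + h * a21 * k1[j];
    simo_deriv(yt, pp, k2);
    for (int j = 0; j < NS; ++j) yt[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
    simo_deriv(yt, pp, k3);
    for (int j = 0; j < NS; ++j)
      yt[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
    simo_deriv(yt, pp, k4);
    for (int j = 0; j < NS; ++j)
      yt[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] + a54 * k4[j]);
    simo_deriv(yt, pp, k5);
    for (int j = 0; j < NS; ++j)
      yt[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] + a64 * k4[j] +
                          a65 * k5[j]);
    simo_deriv(yt, pp, k6);
    for (int j = 0; j < NS; ++j)
      ynew[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] + b5 * k5[j] +
                            b6 * k6[j]);
    simo_deriv(ynew, pp, k7);

    double err = 0.0;
    for (int j = 0; j < NS; ++j) {
      const double ej = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                             e6 * k6[j] + e7 * k7[j]);
      const double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(ynew[j]));
      const double r = ej / sc;
      err += r * r;
    }
    err = std::sqrt(err / NS);
    if (!std::isfinite(err)) stop("non-finite state encountered during integration");

    if (err <= 1.0) {
      t += h;
      for (int j = 0; j < NS; ++j) {
        y[j] = ynew[j];
        if (y[j] < 0.0) y[j] = (y[j] > -1e-8) ? 0.0 : y[j];
        k1[j] = k7[j];  // FSAL
      }
      have_k1 = true;
      while (it < nt && std::fabs(t - times[it]) < 1e-9) {
        for (int j = 0; j < NS; ++j) out(it, j) = y[j];
        ++it;
      }
      if (it >= nt) break;
    } else {
      have_k1 = true;  // k1 still valid at unchanged (t, y)
    }
    double fac = 0.9 * std::pow(err > 1e-16 ? 1.0 / err : 1e16, 0.2);
    if (fac < 0.2) fac = 0.2;
    if (fac > 5.0) fac = 5.0;
    h *= fac;
    if (h < 1e-10) stop("integration step size underflow");
  }
  if (it < nt) stop("integration failed to reach final time (step budget exhausted)");
  return out;
}
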