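// Per-sample profiling of the fluorophore totals (D0, A0) and Laplace
// marginalization of the Gaussian-noise energy. This is the inner loop of
// every Metropolis-Hastings proposal: for each sample the energy is
// minimized over (D0, A0) with Nelder-Mead, the 2x2 Hessian is taken by
// central finite differences, and the 2-D Gaussian integral over the totals
// is evaluated analytically.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Stable smaller root of DA^2 - (D0 + A0 + Kd) DA + D0 A0 = 0. The
// rationalized form avoids catastrophic cancellation when Kd >> D0 + A0.
static inline double solve_da(double D0, double A0, double Kd) {
  double b = D0 + A0 + Kd;
  double disc = b * b - 4.0 * D0 * A0;
  if (disc < 0.0) disc = 0.0;          // roundoff guard
  double denom = b + std::sqrt(disc);
  if (denom <= 0.0) return 0.0;
  return 2.0 * D0 * A0 / denom;
}

struct SampleStats {
  double n;          // replicates per channel
  double m[3];       // per-channel replicate means
  double ssq0[3];    // (n-1) * sample variance per channel
  double w[3];       // 1 / (2 sigma_k^2)
};

// Residual energy: sum_k w_k * [ ssq0_k + n (m_k - Ipred_k)^2 ].
// Identical to the replicate-wise sum of squared residuals because the
// prediction is constant across replicates. Negative totals are clamped,
// which also makes the (unconstrained) simplex search respect positivity.
static double res_energy(double D0, double A0, double Kd, double Efr,
                         const double *kD, const double *kA, const double *kF,
                         const SampleStats &st) {
  if (D0 < 0.0) D0 = 0.0;
  if (A0 < 0.0) A0 = 0.0;
  double DA = solve_da(D0, A0, Kd);
  double eDA = Efr * DA;
  double e = 0.0;
  for (int k = 0; k < 3; ++k) {
    double Ip = kD[k] * D0 + kA[k] * A0 + (kF[k] - kD[k]) * eDA;
    double d = st.m[k] - Ip;
    e += st.w[k] * (st.ssq0[k] + st.n * d * d);
  }
  return e;
}

// Compact 2-D Nelder-Mead (reflection/expansion/contraction/shrink),
// relative tolerance on the simplex energy spread.
static void nm2(double x0, double y0, double Kd, double Efr,
                const double *kD, const double *kA, const double *kF,
                const SampleStats &st, double *xout, double *fout) {
  const double alpha = 1.0, gamma = 2.0, rho = 0.5, sigma = 0.5;
  const double reltol = 1e-10;
  const int maxit = 500;

  double px[3], py[3], pf[3];
  double sx = 0.05 * std::fabs(x0) + 1e-10;
  double sy = 0.05 * std::fabs(y0) + 1e-10;
  px[0] = x0;      py[0] = y0;
  px[1] = x0 + sx; py[1] = y0;
  px[2] = x0;      py[2] = y0 + sy;
  for (int i = 0; i < 3; ++i)
    pf[i] = res_energy(px[i], py[i], Kd, Efr, kD, kA, kF, st);

  for (int it = 0; it < maxit; ++it) {
    // order: 0 best, 2 worst
    for (int a = 0; a < 2; ++a)
      for (int b = a + 1; b < 3; ++b)
        if (pf[b] < pf[a]) {
          std::swap(pf[a], pf[b]);
          std::swap(px[a], px[b]);
          std::swap(py[a], py[b]);
        }
    if (pf[2] - pf[0] <= reltol * (std::fabs(pf[0]) + reltol)) break;

    double cx = 0.5 * (px[0] + px[1]), cy = 0.5 * (py[0] + py[1]);
    double rx = cx + alpha * (cx - px[2]), ry = cy + alpha * (cy - py[2]);
    double fr = res_energy(rx, ry, Kd, Efr, kD, kA, kF, st);
    if (fr < pf[0]) {
      double ex = cx + gamma * (rx - cx), ey = cy + gamma * (ry - cy);
      double fe = res_energy(ex, ey, Kd, Efr, kD, kA, kF, st);
      if (fe < fr) { px[2] = ex; py[2] = ey; pf[2] = fe; }
      else         { px[2] = rx; py[2] = ry; pf[2] = fr; }
    } else if (fr < pf[1]) {
      px[2] = rx; py[2] = ry; pf[2] = fr;
    } else {
      double kx = cx + rho * (px[2] - cx), ky = cy + rho * (py[2] - cy);
      double fk = res_energy(kx, ky, Kd, Efr, kD, kA, kF, st);
      if (fk < pf[2]) { px[2] = kx; py[2] = ky; pf[2] = fk; }
      else {
        for (int i = 1; i < 3; ++i) {
          px[i] = px[0] + sigma * (px[i] - px[0]);
          py[i] = py[0] + sigma * (py[i] - py[0]);
          pf[i] = res_energy(px[i], py[i], Kd, Efr, kD, kA, kF, st);
        }
      }
    }
  }
  int best = 0;
  for (int i = 1; i < 3; ++i) if (pf[i] < pf[best]) best = i;
  xout[0] = px[best] > 0.0 ? px[best] : 0.0;
  xout[1] = py[best] > 0.0 ? py[best] : 0.0;
  fout[0] = pf[best];
}

// Multi-start profile + Laplace for one sample. starts: k x 2 matrix.
static void laplace_one(const SampleStats &st, double Kd, double Efr,
                        const double *kD, const double *kA, const double *kF,
                        const double *starts, int nstart, double hfac,
                        double *D0s, double *A0s, double *emin,
                        double *logdet, double *Hout, int *valid) {
  double bx[2] = {0.0, 0.0}, bf = R_PosInf;
  for (int s = 0; s < nstart; ++s) {
    double x0 = starts[s], y0 = starts[s + nstart];
    if (!R_finite(x0) || !R_finite(y0)) continue;
    double xo[2], fo;
    nm2(x0, y0, Kd, Efr, kD, kA, kF, st, xo, &fo);
    if (fo < bf) { bf = fo; bx[0] = xo[0]; bx[1] = xo[1]; }
  }
  double hx = std::max(hfac * bx[0], 1e-12);
  double hy = std::max(hfac * bx[1], 1e-12);
  double f0 = res_energy(bx[0], bx[1], Kd, Efr, kD, kA, kF, st);
  if (f0 < bf) bf = f0;
  double fxx = (res_energy(bx[0] + hx, bx[1], Kd, Efr, kD, kA, kF, st)
                - 2.0 * f0
                + res_energy(bx[0] - hx, bx[1], Kd, Efr, kD, kA, kF, st))
               / (hx * hx);
  double fyy = (res_energy(bx[0], bx[1] + hy, Kd, Efr, kD, kA, kF, st)
                - 2.0 * f0
                + res_energy(bx[0], bx[1] - hy, Kd, Efr, kD, kA, kF, st))
               / (hy * hy);
  double fxy = (res_energy(bx[0] + hx, bx[1] + hy, Kd, Efr, kD, kA, kF, st)
                - res_energy(bx[0] + hx, bx[1] - hy, Kd, Efr, kD, kA, kF, st)
                - res_energy(bx[0] - hx, bx[1] + hy, Kd, Efr, kD, kA, kF, st)
                + res_energy(bx[0] - hx, bx[1] - hy, Kd, Efr, kD, kA, kF, st))
               / (4.0 * hx * hy);
  double det = fxx * fyy - fxy * fxy;
  *D0s = bx[0];
  *A0s = bx[1];
  *emin = bf;
  Hout[0] = fxx; Hout[1] = fxy; Hout[2] = fxy; Hout[3] = fyy;
  if (fxx > 0.0 && det > 0.0) {
    *valid = 1;
    *logdet = std::log(det);
  } else {
    *valid = 0;
    *logdet = NA_REAL;
  }
}

// stats: m x 10 matrix, columns (n, m1..m3, ssq0_1..3, sigma1..3).
// kappa: 3 x 3 matrix, columns (D, A, F), rows = channels.
// warm, moment: m x 2 start matrices (warm may hold NA).
// Returns the residual-scale Laplace pieces for every sample; the caller
// adds the per-sample Gaussian normalization constants.
// [[Rcpp::export]]
List fb_laplace_dataset(NumericMatrix stats, double Kd, double Efr,
                        NumericMatrix kappa, NumericMatrix warm,
                        NumericMatrix moment, bool multistart,
                        double hfac) {
  int m = stats.nrow();
  double kD[3], kA[3], kF[3];
  for (int k = 0; k < 3; ++k) {
    kD[k] = kappa(k, 0); kA[k] = kappa(k, 1); kF[k] = kappa(k, 2);
  }
  NumericMatrix optima(m, 2);
  NumericVector emin(m), logdet(m);
  LogicalVector valid(m);
  NumericVector hess(4 * m);
  double total = 0.0;
  bool all_ok = true;
  for (int i = 0; i < m; ++i) {
    SampleStats st;
    st.n = stats(i, 0);
    for (int k = 0; k < 3; ++k) {
      st.m[k] = stats(i, 1 + k);
      st.ssq0[k] = stats(i, 4 + k);
      double sg = stats(i, 7 + k);
      st.w[k] = 1.0 / (2.0 * sg * sg);
    }
    // starts in column-major layout: x values first, then y values
    double starts[6];
    int ns;
    if (multistart) {
      starts[0] = warm(i, 0);          starts[3] = warm(i, 1);
      starts[1] = moment(i, 0);        starts[4] = moment(i, 1);
      starts[2] = 10.0 * moment(i, 0); starts[5] = 10.0 * moment(i, 1);
      ns = 3;
    } else {
      double wx = warm(i, 0), wy = warm(i, 1);
      if (R_finite(wx) && R_finite(wy)) {
        starts[0] = wx; starts[1] = wy;
      } else {
        starts[0] = moment(i, 0); starts[1] = moment(i, 1);
      }
      ns = 1;
    }
    int ok = 0;
    double D0s, A0s, em, ld, H[4];
    laplace_one(st, Kd, Efr, kD, kA, kF, starts, ns, hfac,
                &D0s, &A0s, &em, &ld, H, &ok);
    optima(i, 0) = D0s;
    optima(i, 1) = A0s;
    emin[i] = em;
    logdet[i] = ld;
    valid[i] = ok == 1;
    for (int j = 0; j < 4; ++j) hess[4 * i + j] = H[j];
    if (ok) total += -em + std::log(2.0 * M_PI) - 0.5 * ld;
    else all_ok = false;
  }
  return List::create(_["total"] = all_ok ? total : R_NegInf,
                      _["optima"] = optima,
                      _["emin"] = emin,
                      _["logdet"] = logdet,
                      _["hessian"] = hess,
                      _["valid"] = valid,
                      _["all_valid"] = all_ok);
}

// Residual energy for a single (D0, A0) point, one sample.
// [[Rcpp::export]]
double fb_res_energy(double D0, double A0, double Kd, double Efr,
                     NumericMatrix kappa, NumericVector stat) {
  double kD[3], kA[3], kF[3];
  for (int k = 0; k < 3; ++k) {
    kD[k] = kappa(k, 0); kA[k] = kappa(k, 1); kF[k] = kappa(k, 2);
  }
  SampleStats st;
  st.n = stat[0];
  for (int k = 0; k < 3; ++k) {
    st.m[k] = stat[1 + k];
    st.ssq0[k] = stat[4 + k];
    double sg = stat[7 + k];
    st.w[k] = 1.0 / (2.0 * sg * sg);
  }
  return res_energy(D0, A0, Kd, Efr, kD, kA, kF, st);
}
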