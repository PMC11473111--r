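#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Reaction type codes shared with R/kinetic-model.R (compile_model):
//   1 constant source           dy[i1] += k * sscale[i1]
//   2 first-order sink          dy[i1] -= k * y[i1]
//   3 linear activation         dy[i1] += k * y[i2]
//   4 saturating activation     dy[i1] += k * y[i2] / (km + y[i2])
//   5 miRNA-mediated decay      dy[i1] -= k * y[i2] * y[i1]
//   6 inhibited conversion      flux = k*y[i1]/(1+sum inh); dy[i1]-=flux; dy[i2]+=flux
//   7 inhibited source          dy[i1] += k * sscale[i1] / (1+sum inh)
// Inhibitor rows (reaction index, species index, coefficient) must be sorted
// by reaction index; inh_start/inh_end give each reaction's slice.

static void deriv(const std::vector<double>& y, std::vector<double>& dy,
                  const std::vector<double>& sscale,
                  const NumericMatrix& reac,
                  const std::vector<int>& inh_start,
                  const std::vector<int>& inh_end,
                  const NumericMatrix& inh) {
  std::fill(dy.begin(), dy.end(), 0.0);
  const int m = reac.nrow();
  for (int r = 0; r < m; ++r) {
    const int type = (int)reac(r, 0);
    const int i1 = (int)reac(r, 1);
    const int i2 = (int)reac(r, 2);
    const double k = reac(r, 3);
    const double km = reac(r, 4);
    double denom, flux;
    switch (type) {
    case 1:
      dy[i1] += k * sscale[i1];
      break;
    case 2:
      dy[i1] -= k * y[i1];
      break;
    case 3:
      dy[i1] += k * y[i2];
      break;
    case 4:
      dy[i1] += k * y[i2] / (km + y[i2]);
      break;
    case 5:
      dy[i1] -= k * y[i2] * y[i1];
      break;
    case 6:
      denom = 1.0;
      for (int q = inh_start[r]; q < inh_end[r]; ++q)
        denom += inh(q, 2) * y[(int)inh(q, 1)];
      flux = k * y[i1] / denom;
      dy[i1] -= flux;
      dy[i2] += flux;
      break;
    case 7:
      denom = 1.0;
      for (int q = inh_start[r]; q < inh_end[r]; ++q)
        denom += inh(q, 2) * y[(int)inh(q, 1)];
      dy[i1] += k * sscale[i1] / denom;
      break;
    default:
      stop("unknown reaction type code");
    }
  }
}

// Dormand-Prince 5(4) coefficients
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
                    e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

// Integrate one segment [t0, t1] with no interior discontinuities.
static void integrate_segment(std::vector<double>& y, double t0, double t1,
                              const std::vector<double>& sscale,
                              const NumericMatrix& reac,
                              const std::vector<int>& inh_start,
                              const std::vector<int>& inh_end,
                              const NumericMatrix& inh, double rtol,
                              double atol, long& naccept, long& nreject) {
  const int n = (int)y.size();
  if (t1 <= t0) return;
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n), yt(n),
      y5(n);
  double t = t0;
  double h = std::min(1e-3, t1 - t0);
  deriv(y, k1, sscale, reac, inh_start, inh_end, inh);
  long guard = 0;
  while (t < t1) {
    if (++guard > 2000000L) stop("integration failed: step limit exceeded");
    if (t + h > t1) h = t1 - t;
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * a21 * k1[i];
    deriv(yt, k2, sscale, reac, inh_start, inh_end, inh);
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
    deriv(yt, k3, sscale, reac, inh_start, inh_end, inh);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
    deriv(yt, k4, sscale, reac, inh_start, inh_end, inh);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
    deriv(yt, k5, sscale, reac, inh_start, inh_end, inh);
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                          a64 * k4[i] + a65 * k5[i]);
    deriv(yt, k6, sscale, reac, inh_start, inh_end, inh);
    for (int i = 0; i < n; ++i)
      y5[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] + b5 * k5[i] +
                          b6 * k6[i]);
    deriv(y5, k7, sscale, reac, inh_start, inh_end, inh);
    double errnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      double err = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] + e5 * k5[i] +
                        e6 * k6[i] + e7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(y5[i]));
      double r = err / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / n);
    if (!std::isfinite(errnorm)) stop("integration failed: non-finite state");
    if (errnorm <= 1.0) {
      t += h;
      y.swap(y5);
      k1.swap(k7);  // FSAL
      ++naccept;
    } else {
      ++nreject;
    }
    double fac = 0.9 * std::pow(errnorm > 1e-14 ? errnorm : 1e-14, -0.2);
    fac = std::min(5.0, std::max(0.2, fac));
    h *= fac;
    if (h < 1e-14) stop("integration failed: step size underflow");
  }
}

// [[Rcpp::export]]
List sim_ode_cpp(NumericVector y0, NumericVector times, NumericMatrix reac,
                 NumericMatrix inh, NumericVector ev_times,
                 NumericMatrix ev_mult, NumericMatrix ev_assign,
                 NumericMatrix ev_sscale, double rtol, double atol) {
  const int n = y0.size(), nt = times.size(), m = reac.nrow();
  const int nev = ev_times.size();
  // inhibitor slices per reaction (inh sorted by reaction index)
  std::vector<int> inh_start(m, 0), inh_end(m, 0);
  {
    int q = 0;
    for (int r = 0; r < m; ++r) {
      while (q < inh.nrow() && (int)inh(q, 0) < r) ++q;
      inh_start[r] = q;
      while (q < inh.nrow() && (int)inh(q, 0) == r) ++q;
      inh_end[r] = q;
    }
  }
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> sscale(n, 1.0);
  NumericMatrix out(nt, n);
  long naccept = 0, nreject = 0;

  // breakpoints: output times plus event times inside the span, pre-event
  // recording when an output time coincides with an event time
  double t = times[0];
  int iout = 0, iev = 0;
  while (iev < nev && ev_times[iev] < t) ++iev;  // events before start ignored
  // record outputs at the start time
  while (iout < nt && times[iout] <= t) {
    for (int i = 0; i < n; ++i) out(iout, i) = y[i];
    ++iout;
  }
  // fire events exactly at the start time (after recording: pre-event values)
  while (iev < nev && ev_times[iev] <= t) {
    for (int i = 0; i < n; ++i) {
      y[i] *= ev_mult(iev, i);
      if (!NumericVector::is_na(ev_assign(iev, i))) y[i] = ev_assign(iev, i);
      if (!NumericVector::is_na(ev_sscale(iev, i))) sscale[i] = ev_sscale(iev, i);
    }
    ++iev;
  }
  while (iout < nt) {
    double tnext = times[iout];
    if (iev < nev && ev_times[iev] < tnext) tnext = ev_times[iev];
    integrate_segment(y, t, tnext, sscale, reac, inh_start, inh_end, inh, rtol,
                      atol, naccept, nreject);
    t = tnext;
    // record any outputs at t (pre-event), then fire events at t
    while (iout < nt && times[iout] <= t) {
      for (int i = 0; i < n; ++i) out(iout, i) = y[i];
      ++iout;
    }
    while (iev < nev && ev_times[iev] <= t) {
      for (int i = 0; i < n; ++i) {
        y[i] *= ev_mult(iev, i);
        if (!NumericVector::is_na(ev_assign(iev, i))) y[i] = ev_assign(iev, i);
        if (!NumericVector::is_na(ev_sscale(iev, i)))
          sscale[i] = ev_sscale(iev, i);
      }
      ++iev;
    }
  }
  return List::create(_["states"] = out, _["naccept"] = (double)naccept,
                      _["nreject"] = (double)nreject);
}
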