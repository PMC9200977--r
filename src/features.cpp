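#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Kinetic feature extraction core. Operates on pre-smoothed series
// (Savitzky-Golay smoothing/differentiation happens in R via the `signal`
// package); kept in C++ because a full cohort holds ~4e4 traces and the
// bootstrap-calibration checks extract hundreds of cohorts.

static double med(std::vector<double> x) {
  if (x.empty()) return NA_REAL;
  size_t k = x.size() / 2;
  std::nth_element(x.begin(), x.begin() + k, x.end());
  double m = x[k];
  if (x.size() % 2 == 0) {
    std::nth_element(x.begin(), x.begin() + k - 1, x.begin() + k);
    m = 0.5 * (m + x[k - 1]);
  }
  return m;
}

// first index i (>=1) with v[i], v[i+1], v[i+2] all < -thr and
// time[i] <= searchEnd; returns interpolated crossing time of -thr,
// or NA if no trigger.
static double crossing(const NumericVector& time, const NumericVector& v,
                       double thr, double searchEnd) {
  int n = v.size();
  double dt = time[1] - time[0];
  for (int i = 1; i + 2 < n; ++i) {
    if (time[i] > searchEnd) break;
    if (v[i] < -thr && v[i + 1] < -thr && v[i + 2] < -thr) {
      double t;
      if (v[i] >= v[i - 1]) t = time[i - 1];
      else t = time[i - 1] + dt * (-thr - v[i - 1]) / (v[i] - v[i - 1]);
      if (t < time[i - 1]) t = time[i - 1];
      if (t > time[i]) t = time[i];
      return t;
    }
  }
  return NA_REAL;
}

// Pupil response latency: adaptive velocity-threshold onset detector.
// thr = max(thrFrac * MCV, noiseK * robust SD of pre-onset velocity);
// the crossing of thr is interpolated linearly between the bracketing
// samples, and the noise-driven part of the threshold (thr - thrFrac*MCV)
// is removed by extrapolating along the secant to a higher crossing.
static double detect_onset_core(const NumericVector& time,
                                const NumericVector& vOnset,
                                const NumericVector& vMain,
                                double searchEnd, double thrFrac,
                                double noiseK, double minMCV) {
  int n = time.size();
  if (n < 8) return NA_REAL;
  double dt = time[1] - time[0];
  double mcv = R_NegInf;
  for (int i = 0; i < n; ++i) {
    if (time[i] > searchEnd) break;
    if (-vMain[i] > mcv) mcv = -vMain[i];
  }
  if (!R_FINITE(mcv)) return NA_REAL;

  int preN = std::min(n, std::max(5, (int)std::lround(0.3 / dt)));
  std::vector<double> pre(vOnset.begin(), vOnset.begin() + preN);
  double m0 = med(pre);
  std::vector<double> dev(preN);
  for (int i = 0; i < preN; ++i) dev[i] = std::fabs(pre[i] - m0);
  double rsd = 1.4826 * med(dev);

  double floorv = std::max(noiseK * rsd, minMCV);
  if (mcv < floorv) return NA_REAL;

  double thr0 = thrFrac * mcv;
  double thr = std::max(thr0, noiseK * rsd);
  double t1 = crossing(time, vOnset, thr, searchEnd);
  if (!R_FINITE(t1)) return NA_REAL;
  double extra = thr - thr0;
  if (extra > 0) {
    double thrHi = std::min(std::max(0.6 * mcv, 2.0 * thr), 0.8 * mcv);
    if (thrHi > thr) {
      double t3 = crossing(time, vOnset, thrHi, searchEnd + 1.0);
      if (R_FINITE(t3) && t3 > t1)
        t1 -= extra * (t3 - t1) / (thrHi - thr);
    }
  }
  return t1 < 0 ? 0.0 : t1;
}

// [[Rcpp::export(name = ".cpp_detect_onset")]]
double cpp_detect_onset(NumericVector time, NumericVector vOnset,
                        NumericVector vMain, double searchEnd,
                        double thrFrac, double noiseK, double minMCV) {
  return detect_onset_core(time, vOnset, vMain, searchEnd, thrFrac, noiseK,
                           minMCV);
}

// extremum of sign*x over [i0, i1]; writes value/time through pointers,
// NA when the extremum is not positive (wrong-sign = undefined feature)
static void extremum(const NumericVector& time, const NumericVector& x,
                     int i0, int i1, double sign, double* val, double* at) {
  *val = NA_REAL; *at = NA_REAL;
  double best = 0.0; int bi = -1;
  for (int i = i0; i <= i1; ++i) {
    double s = sign * x[i];
    if (s > best) { best = s; bi = i; }
  }
  if (bi >= 0) { *val = best; *at = time[bi]; }
}

// The 17 PLR parameters, in canonical order:
// AC PPC PRL LMP MCV LMCV MCA LMCA MCD LMCD MRV LMRV MRA LMRA MRD LMRD PRP
//
// `draw` is the raw (gap-interpolated, unsmoothed) diameter: the trough is
// located on it because the redilation factor puts a kink at the waveform
// minimum, and a symmetric smoother biases the argmin of the smoothed
// trace ~1-2 samples early. The trough VALUE is refined by a parabola
// through the raw argmin and its two neighbours on the smooth (pre-peak)
// branch.
// [[Rcpp::export(name = ".cpp_extract_one")]]
NumericVector cpp_extract_one(NumericVector time, NumericVector d,
                              NumericVector v, NumericVector a,
                              NumericVector vOnset, NumericVector draw,
                              double stimDur,
                              double thrFrac, double noiseK, double minMCV,
                              double contractionExtra) {
  NumericVector out(17, NA_REAL);
  int n = time.size();
  if (n < 8) return out;
  double dt = time[1] - time[0];

  double prl = detect_onset_core(time, vOnset, v, stimDur + 1.0, thrFrac,
                                 noiseK, minMCV);
  if (!R_FINITE(prl)) return out;

  // trough within the contraction window [PRL, PRL + stimDur + extra]
  double tEnd = prl + stimDur + contractionExtra;
  int jmin = -1; double dmin = R_PosInf;
  int iStart = -1;
  for (int i = 0; i < n; ++i) {
    if (time[i] < prl) continue;
    if (iStart < 0) iStart = i;
    if (time[i] > tEnd) break;
    if (d[i] < dmin) { dmin = d[i]; jmin = i; }
  }
  if (jmin < 0 || iStart < 0) return out;

  // refine on the raw trace within the smoothing half-width of the coarse
  // (smoothed) argmin
  int w = 4;
  int lo = std::max(iStart, jmin - w), hi = std::min(n - 1, jmin + w);
  int imin = lo;
  for (int i = lo; i <= hi; ++i) if (draw[i] < draw[imin]) imin = i;
  double lmp = time[imin];
  double dmin_r = draw[imin];
  // sub-sample trough: exact cubic through 4 raw samples around the
  // argmin; if the argmin sample sits just past the trough kink (detected
  // by its excess over a parabolic extrapolation of the three preceding
  // samples), shift the window one sample left to stay on the smooth
  // pre-trough branch
  if (imin >= 4 && imin + 1 < n) {
    double pred = 3.0 * draw[imin - 1] - 3.0 * draw[imin - 2]
      + draw[imin - 3];
    bool contaminated = (draw[imin] - pred) >
      0.15 * (draw[imin - 1] - draw[imin - 2]) + 2e-4;
    int i0 = contaminated ? imin - 4 : imin - 3;
    double y0 = draw[i0], y1 = draw[i0 + 1], y2 = draw[i0 + 2],
      y3 = draw[i0 + 3];
    double d1 = y1 - y0, d2 = y2 - 2 * y1 + y0,
      d3 = y3 - 3 * y2 + 3 * y1 - y0;
    double a1 = d1 - d2 / 2 + d3 / 3, a2 = d2 / 2 - d3 / 2, a3 = d3 / 6;
    double x = NA_REAL;
    if (std::fabs(a3) > 1e-12) {
      double disc = 4 * a2 * a2 - 12 * a3 * a1;
      if (disc >= 0) {
        double r1 = (-2 * a2 + std::sqrt(disc)) / (6 * a3);
        double r2 = (-2 * a2 - std::sqrt(disc)) / (6 * a3);
        x = (2 * a2 + 6 * a3 * r1 > 0) ? r1 : r2;
      }
    } else if (a2 > 1e-12) {
      x = -a1 / (2 * a2);
    }
    if (R_FINITE(x)) {
      double tmin = time[i0] + x * dt;
      if (tmin >= time[imin] - 1.5 * dt && tmin <= time[imin] + dt) {
        double vv = ((a3 * x + a2) * x + a1) * x + y0;
        if (vv <= dmin_r) { dmin_r = vv; lmp = tmin; }
      }
    }
  }
  dmin = dmin_r;
  jmin = imin;

  // baseline from pre-onset samples (the recording starts at stimulus
  // onset, so "pre-onset" means before the detected response onset)
  double db = 0.0; int nb = 0;
  for (int i = 0; i < n && time[i] < prl - 2 * dt; ++i) { db += d[i]; ++nb; }
  if (nb < 2) { db = d[0] + d[1]; nb = 2; }
  db /= nb;
  if (db <= 0) return out;

  double ac = db - dmin;
  if (ac < 0) ac = 0;
  out[0] = ac;                 // AC
  out[1] = 100.0 * ac / db;    // PPC
  out[2] = prl;                // PRL
  out[3] = lmp;                // LMP

  extremum(time, v, iStart, jmin, -1.0, &out[4], &out[5]);   // MCV, LMCV
  extremum(time, a, iStart, jmin, -1.0, &out[6], &out[7]);   // MCA, LMCA
  extremum(time, a, iStart, jmin, +1.0, &out[8], &out[9]);   // MCD, LMCD

  if (jmin + 1 < n) {
    extremum(time, v, jmin + 1, n - 1, +1.0, &out[10], &out[11]); // MRV
    extremum(time, a, jmin + 1, n - 1, +1.0, &out[12], &out[13]); // MRA
    extremum(time, a, jmin + 1, n - 1, -1.0, &out[14], &out[15]); // MRD
  }

  if (ac > 1e-9) {
    double prp = 100.0 * (d[n - 1] - dmin) / ac;
    if (prp < 0) prp = 0;
    if (prp > 100) prp = 100;
    out[16] = prp;             // PRP
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_extract_many")]]
NumericMatrix cpp_extract_many(NumericVector time, NumericMatrix d,
                               NumericMatrix v, NumericMatrix a,
                               NumericMatrix vOnset, NumericMatrix draw,
                               double stimDur,
                               double thrFrac, double noiseK, double minMCV,
                               double contractionExtra) {
  int m = d.ncol();
  NumericMatrix out(17, m);
  for (int j = 0; j < m; ++j) {
    NumericVector f = cpp_extract_one(time, d(_, j), v(_, j), a(_, j),
                                      vOnset(_, j), draw(_, j), stimDur,
                                      thrFrac,
                                      noiseK, minMCV, contractionExtra);
    for (int k = 0; k < 17; ++k) out(k, j) = f[k];
  }
  return out;
}
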