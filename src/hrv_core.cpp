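#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Beat-time generation for the IPFM-style tachogram simulator.
// The instantaneous interval (ms) at time t is
//   mean_nn + sum_b amp[b] * sin(2*pi*freq[b]*t + phase[b]) + mod(t)
// where mod(t) is an optional extra modulation sampled on a uniform grid
// (linear interpolation; used for band-limited-noise modulation).
// Intervals are floored at min_nn to keep the point process well defined.
// [[Rcpp::export]]
NumericVector cpp_ipfm_beats(double duration_s, double mean_nn_ms,
                             NumericVector amp, NumericVector freq,
                             NumericVector phase, NumericVector mod_grid,
                             double mod_dt, double min_nn_ms) {
  std::vector<double> beats;
  beats.reserve((size_t)(duration_s / (mean_nn_ms / 1000.0) + 16));
  const int nb = amp.size();
  const int ng = mod_grid.size();
  double t = 0.0;
  const double two_pi = 2.0 * M_PI;
  while (t <= duration_s) {
    beats.push_back(t);
    double nn = mean_nn_ms;
    for (int b = 0; b < nb; ++b)
      nn += amp[b] * std::sin(two_pi * freq[b] * t + phase[b]);
    if (ng > 0) {
      double x = t / mod_dt;
      int i0 = (int)std::floor(x);
      if (i0 >= ng - 1) {
        nn += mod_grid[ng - 1];
      } else {
        double w = x - i0;
        nn += (1.0 - w) * mod_grid[i0] + w * mod_grid[i0 + 1];
      }
    }
    if (nn < min_nn_ms) nn = min_nn_ms;
    t += nn / 1000.0;
  }
  return wrap(beats);
}

// Adaptive-threshold scan for QRS detection, canonical Pan-Tompkins
// bookkeeping run jointly on the moving-window-integrated (MWI) signal and
// the band-passed signal: a candidate MWI peak is accepted only when both
// its MWI amplitude and the local band-passed amplitude exceed their
// adaptive thresholds. Includes a refractory period (with replacement by a
// larger peak inside it), a T-wave veto inside 360 ms, and search-back at
// halved thresholds when an expected beat is missed. Returns 0-based
// indices into `mwi` of accepted QRS candidates.
// [[Rcpp::export]]
IntegerVector cpp_pt_scan(NumericVector mwi, NumericVector xf, double fs,
                          double refractory_s) {
  const int n = mwi.size();
  std::vector<int> cand;
  for (int i = 1; i + 1 < n; ++i)
    if (mwi[i] > mwi[i - 1] && mwi[i] >= mwi[i + 1] && mwi[i] > 0) cand.push_back(i);
  std::vector<int> out;
  if (cand.empty()) return IntegerVector(0);

  const int refr = (int)std::lround(refractory_s * fs);
  const int twave = (int)std::lround(0.360 * fs);
  const int half = (int)std::lround(0.075 * fs);  // band-passed lookup window

  // local band-passed amplitude around a candidate
  auto famp = [&](int i) {
    int lo = std::max(0, i - half), hi = std::min(n - 1, i + half);
    double m = xf[lo];
    for (int j = lo + 1; j <= hi; ++j) if (xf[j] > m) m = xf[j];
    return m;
  };

  // initialise estimates from the first two seconds of signal
  int init_n = std::min(n, (int)(2.0 * fs));
  double mx = 0.0, mn = 0.0, fmx = 0.0, fmn = 0.0;
  for (int i = 0; i < init_n; ++i) {
    if (mwi[i] > mx) mx = mwi[i];
    mn += mwi[i];
    if (xf[i] > fmx) fmx = xf[i];
    fmn += std::fabs(xf[i]);
  }
  mn /= std::max(1, init_n);
  fmn /= std::max(1, init_n);
  double spki = mx, npki = 0.5 * mn;
  double spkf = fmx, npkf = 0.5 * fmn;
  double thr1 = npki + 0.25 * (spki - npki);
  double thrf = npkf + 0.25 * (spkf - npkf);

  double rr_avg = 0.0;      // running mean of recent accepted RR gaps (samples)
  int n_rr = 0;
  int last = -1;            // index of last accepted peak
  double last_amp = 0.0;
  std::vector<int> pending; // skipped candidates since last accepted peak

  auto update_thr = [&]() {
    thr1 = npki + 0.25 * (spki - npki);
    thrf = npkf + 0.25 * (spkf - npkf);
  };
  auto note_rr = [&](int gap) {
    rr_avg = n_rr == 0 ? gap
                       : (rr_avg * std::min(n_rr, 8) + gap) / (std::min(n_rr, 8) + 1);
    if (n_rr < 8) ++n_rr;
  };

  for (size_t k = 0; k < cand.size(); ++k) {
    int i = cand[k];
    double a = mwi[i];
    if (last >= 0 && i - last < refr) {
      // a larger peak inside the refractory window replaces the previous
      // acceptance (the earlier one was noise riding ahead of the QRS)
      if (a > last_amp && a > thr1 && famp(i) > thrf && !out.empty()) {
        out.back() = i;
        spki = 0.125 * a + 0.875 * spki;
        last = i; last_amp = a;
        update_thr();
      }
      continue;
    }
    double fa = famp(i);
    bool is_twave = (last >= 0 && i - last < twave && a < 0.5 * last_amp);
    // amplitude floors at a fraction of the running signal estimates guard
    // against threshold erosion during long RR intervals
    bool accept = (a > thr1) && (a > 0.25 * spki) &&
                  (fa > thrf) && (fa > 0.25 * spkf) && !is_twave;

    if (!accept && last >= 0 && n_rr > 0 && (i - last) > 1.66 * rr_avg) {
      // search back among pending candidates for the largest passing both
      // halved thresholds
      int best = -1; double besta = 0.5 * thr1;
      for (size_t j = 0; j < pending.size(); ++j) {
        int p = pending[j];
        if (p - last >= refr && mwi[p] > besta && mwi[p] > 0.125 * spki &&
            famp(p) > 0.5 * thrf && famp(p) > 0.125 * spkf) {
          best = p; besta = mwi[p];
        }
      }
      if (best >= 0) {
        spki = 0.25 * mwi[best] + 0.75 * spki;
        spkf = 0.25 * famp(best) + 0.75 * spkf;
        note_rr(best - last);
        last = best; last_amp = mwi[best];
        out.push_back(best);
        pending.clear();
        update_thr();
        if (i - last >= refr && a > thr1 && fa > thrf &&
            !(i - last < twave && a < 0.5 * last_amp))
          accept = true;  // re-test the current candidate against updated state
      }
    }

    if (accept) {
      spki = 0.125 * a + 0.875 * spki;
      spkf = 0.125 * fa + 0.875 * spkf;
      if (last >= 0) note_rr(i - last);
      last = i; last_amp = a;
      out.push_back(i);
      pending.clear();
    } else {
      npki = 0.125 * a + 0.875 * npki;
      npkf = 0.125 * fa + 0.875 * npkf;
      pending.push_back(i);
    }
    update_thr();
  }
  return wrap(out);
}

// Sample-entropy template counts (Richman & Moorman): B = pairs of m-length
// templates within Chebyshev tolerance r, A = pairs of (m+1)-length
// templates, both over the N-m templates starting at 1..N-m, self-matches
// excluded. Returns c(B, A).
// [[Rcpp::export]]
NumericVector cpp_sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates
  double B = 0.0, A = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm > d) d = dm;
        if (d <= r) A += 1.0;
      }
    }
  }
  return NumericVector::create(B, A);
}

// Lomb-Scargle periodogram on a uniform frequency grid f0 + (0..nf-1)*df,
// classic tau-offset form. Uses a per-point recurrence across frequencies so
// only two trig evaluations are needed per (point, grid) rather than per
// (point, frequency). Returns raw periodogram powers; a sinusoid of
// amplitude A at a grid frequency gives approximately N*A^2/4.
// [[Rcpp::export]]
NumericVector cpp_lomb(NumericVector t, NumericVector y,
                       double f0, double df, int nf) {
  const int n = t.size();
  NumericVector P(nf);
  if (n < 2 || nf < 1) return P;
  double ybar = 0.0;
  for (int j = 0; j < n; ++j) ybar += y[j];
  ybar /= n;

  std::vector<double> Syc(nf, 0.0), Sys(nf, 0.0), S2c(nf, 0.0), S2s(nf, 0.0);
  const double two_pi = 2.0 * M_PI;
  for (int j = 0; j < n; ++j) {
    double yj = y[j] - ybar;
    double a0 = two_pi * f0 * t[j];
    double ad = two_pi * df * t[j];
    double c = std::cos(a0), s = std::sin(a0);
    double dc = std::cos(ad), ds = std::sin(ad);
    for (int k = 0; k < nf; ++k) {
      Syc[k] += yj * c;
      Sys[k] += yj * s;
      // double-angle terms from the single-angle values
      S2c[k] += 2.0 * c * c - 1.0;
      S2s[k] += 2.0 * s * c;
      double cn = c * dc - s * ds;
      s = s * dc + c * ds;
      c = cn;
    }
  }
  for (int k = 0; k < nf; ++k) {
    double wt = 0.5 * std::atan2(S2s[k], S2c[k]);  // omega * tau
    double cwt = std::cos(wt), swt = std::sin(wt);
    double ac = cwt * Syc[k] + swt * Sys[k];
    double as = cwt * Sys[k] - swt * Syc[k];
    // sum cos^2(w(t-tau)) = n/2 + (cos(2*w*tau)*S2c + sin(2*w*tau)*S2s)/2
    double c2 = std::cos(2.0 * wt), s2 = std::sin(2.0 * wt);
    double sumc2 = 0.5 * n + 0.5 * (c2 * S2c[k] + s2 * S2s[k]);
    double sums2 = 0.5 * n - 0.5 * (c2 * S2c[k] + s2 * S2s[k]);
    double p = 0.0;
    if (sumc2 > 1e-12) p += ac * ac / sumc2;
    if (sums2 > 1e-12) p += as * as / sums2;
    P[k] = 0.5 * p;
  }
  return P;
}
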