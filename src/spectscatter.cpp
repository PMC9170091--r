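#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Unnormalized Klein-Nishina differential cross-section in cos(theta),
// in units of (r_e^2 / 2); alpha = E / 511 keV.  Bounded above by 2 for
// any alpha >= 0 (since E'/E <= 1), which gives a simple rejection envelope.
static inline double kn_unnorm(double c, double alpha) {
  double r = 1.0 / (1.0 + alpha * (1.0 - c));   // E'/E
  return r * r * (r + 1.0 / r - (1.0 - c * c));
}

static inline double sample_kn_cos(double alpha) {
  double c;
  do {
    c = unif_rand() * 2.0 - 1.0;
  } while (unif_rand() * 2.0 > kn_unnorm(c, alpha));
  return c;
}

// [[Rcpp::export]]
List cpp_sample_compton(int n, double E) {
  double alpha = E / 511.0;
  NumericVector Eout(n), theta(n);
  for (int i = 0; i < n; ++i) {
    double c = sample_kn_cos(alpha);
    theta[i] = std::acos(c);
    Eout[i] = E / (1.0 + alpha * (1.0 - c));
  }
  return List::create(_["energy"] = Eout, _["theta"] = theta);
}

// Analogue Monte-Carlo transport of photons through a 2D attenuation grid
// with Woodcock (delta) tracking, Compton redirection via Klein-Nishina,
// Gaussian energy blur at the detector and parallel-beam angular acceptance.
// Coordinates: pixel (i = row, j = col) center at
//   x = (j - (n-1)/2) * voxel, y = (i - (n-1)/2) * voxel   (0-based i,j).
// Detector bin coordinate at gantry angle t: s = -x sin t + y cos t, bin
// centers at (b - (nbins-1)/2) * bin_mm.
// [[Rcpp::export]]
List cpp_simulate(NumericMatrix activity, NumericMatrix mu_mm,
                  NumericMatrix cfrac, double voxel_mm,
                  int n_angles, double arc_deg, int n_bins, double bin_mm,
                  NumericVector win_lower, NumericVector win_upper,
                  int main_idx, int histories, int max_order,
                  double r140, double accept_deg, double E0,
                  double e_min, double spec_bin, double spec_max) {
  const int n = activity.nrow();
  if (activity.ncol() != n) stop("activity grid must be square");
  const double v = voxel_mm, half = n * v / 2.0;
  const int n_win = win_lower.size();

  // cumulative activity for emission sampling (column-major like R)
  std::vector<double> cum((size_t)n * n);
  double tot = 0.0;
  for (size_t k = 0; k < (size_t)n * n; ++k) {
    double a = activity[k];
    if (a < 0) stop("negative activity");
    tot += a;
    cum[k] = tot;
  }
  if (tot <= 0) stop("phantom has zero total activity");

  double mumax = 0.0;
  for (size_t k = 0; k < (size_t)n * n; ++k)
    if (mu_mm[k] > mumax) mumax = mu_mm[k];

  std::vector<NumericMatrix> counts;
  for (int w = 0; w < n_win; ++w) counts.push_back(NumericMatrix(n_angles, n_bins));
  NumericMatrix prim(n_angles, n_bins), scat(n_angles, n_bins);
  const int n_spec = (int)std::ceil(spec_max / spec_bin);
  NumericVector spectrum(n_spec);

  const double dang = arc_deg / n_angles;
  const double rad = M_PI / 180.0;
  long n_detected = 0;

  for (int h = 0; h < histories; ++h) {
    // emission position
    double u = unif_rand() * tot;
    size_t lo = 0, hi = (size_t)n * n - 1;
    while (lo < hi) {
      size_t mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    int j = (int)(lo / n), i = (int)(lo % n);
    double x = (j - (n - 1) / 2.0) * v + (unif_rand() - 0.5) * v;
    double y = (i - (n - 1) / 2.0) * v + (unif_rand() - 0.5) * v;
    double phi = unif_rand() * 2.0 * M_PI;
    double ux = std::cos(phi), uy = std::sin(phi);
    double E = E0;
    int order = 0;
    bool alive = true;

    if (mumax > 1e-12) {
      for (;;) {
        double d = -std::log(unif_rand()) / mumax;
        double x0 = x, y0 = y;
        x += ux * d; y += uy * d;
        if (x <= -half || x >= half || y <= -half || y >= half) {
          // clamp to the grid-boundary exit point so the detector-bin
          // coordinate is evaluated at the collimator face, not meters away
          double tExit = d;
          if (ux > 0) tExit = std::min(tExit, (half - x0) / ux);
          else if (ux < 0) tExit = std::min(tExit, (-half - x0) / ux);
          if (uy > 0) tExit = std::min(tExit, (half - y0) / uy);
          else if (uy < 0) tExit = std::min(tExit, (-half - y0) / uy);
          x = x0 + ux * tExit; y = y0 + uy * tExit;
          break;
        }
        int jj = (int)std::floor(x / v + n / 2.0);
        int ii = (int)std::floor(y / v + n / 2.0);
        if (ii < 0) ii = 0; if (ii >= n) ii = n - 1;
        if (jj < 0) jj = 0; if (jj >= n) jj = n - 1;
        double mu = mu_mm(ii, jj);
        if (unif_rand() * mumax < mu) {           // real interaction
          if (unif_rand() < cfrac(ii, jj)) {      // Compton
            ++order;
            if (order > max_order) { alive = false; break; }
            double alpha = E / 511.0;
            double c = sample_kn_cos(alpha);
            E = E / (1.0 + alpha * (1.0 - c));
            if (E < e_min) { alive = false; break; }
            double th = std::acos(c);
            if (unif_rand() < 0.5) th = -th;      // in-plane deflection sign
            double ct = std::cos(th), st = std::sin(th);
            double nx = ux * ct - uy * st, ny = ux * st + uy * ct;
            ux = nx; uy = ny;
          } else {                                // photoelectric absorption
            alive = false; break;
          }
        }
      }
    }
    if (!alive) continue;

    // parallel-beam angular acceptance around the nearest gantry angle
    double phid = std::atan2(uy, ux) / rad;
    if (phid < 0) phid += 360.0;
    int a = (int)std::floor(phid / dang + 0.5);
    double res = phid - a * dang;
    if (a >= n_angles) a -= n_angles;
    if (std::fabs(res) > accept_deg) continue;

    double th_a = a * dang * rad;
    double s = -x * std::sin(th_a) + y * std::cos(th_a);
    int b = (int)std::floor(s / bin_mm + (n_bins - 1) / 2.0 + 0.5);
    if (b < 0 || b >= n_bins) continue;

    double fwhm = r140 * 140.0 * std::sqrt(140.0 / E);
    double Ed = E + norm_rand() * fwhm / 2.3548200450309493;

    ++n_detected;
    int sb = (int)std::floor(Ed / spec_bin);
    if (sb >= 0 && sb < n_spec) spectrum[sb] += 1.0;

    for (int w = 0; w < n_win; ++w) {
      if (Ed >= win_lower[w] && Ed < win_upper[w]) {
        counts[w](a, b) += 1.0;
        if (w == main_idx) {
          if (order == 0) prim(a, b) += 1.0; else scat(a, b) += 1.0;
        }
      }
    }
  }

  List cl(n_win);
  for (int w = 0; w < n_win; ++w) cl[w] = counts[w];
  return List::create(_["counts"] = cl, _["primary"] = prim,
                      _["scatter"] = scat, _["spectrum"] = spectrum,
                      _["n_detected"] = (double)n_detected);
}

// Survival factors exp(-integral mu dl) from every pixel center to the grid
// edge along the detector direction of each gantry angle.  Midpoint marching
// with step = step_frac * voxel and nearest-pixel mu lookup.
// [[Rcpp::export]]
NumericMatrix cpp_attenuation_factors(NumericMatrix mu_mm, double voxel_mm,
                                      NumericVector angles_rad,
                                      double step_frac) {
  const int n = mu_mm.nrow(), n_ang = angles_rad.size();
  const double v = voxel_mm, half = n * v / 2.0, step = v * step_frac;
  NumericMatrix attn(n * n, n_ang);
  for (int a = 0; a < n_ang; ++a) {
    double ux = std::cos(angles_rad[a]), uy = std::sin(angles_rad[a]);
    for (int j = 0; j < n; ++j) {
      double x0 = (j - (n - 1) / 2.0) * v;
      for (int i = 0; i < n; ++i) {
        double y0 = (i - (n - 1) / 2.0) * v;
        double acc = 0.0, t = step * 0.5;
        for (;;) {
          double x = x0 + ux * t, y = y0 + uy * t;
          if (x <= -half || x >= half || y <= -half || y >= half) break;
          int jj = (int)std::floor(x / v + n / 2.0);
          int ii = (int)std::floor(y / v + n / 2.0);
          if (ii < 0) ii = 0; if (ii >= n) ii = n - 1;
          if (jj < 0) jj = 0; if (jj >= n) jj = n - 1;
          acc += mu_mm(ii, jj);
          t += step;
        }
        attn(j * n + i, a) = std::exp(-acc * step);
      }
    }
  }
  return attn;
}

// Pixel-driven attenuated parallel-beam forward projection with linear
// detector-bin interpolation.  angle_cols are 0-based columns into attn.
// [[Rcpp::export]]
NumericMatrix cpp_forward(NumericVector img, int n, double voxel_mm,
                          NumericVector angles_rad, IntegerVector angle_cols,
                          NumericMatrix attn, int n_bins, double bin_mm,
                          double scale) {
  const int n_ang = angles_rad.size();
  const double v = voxel_mm;
  NumericMatrix out(n_ang, n_bins);
  for (int a = 0; a < n_ang; ++a) {
    double sn = std::sin(angles_rad[a]), cs = std::cos(angles_rad[a]);
    int col = angle_cols[a];
    for (int j = 0; j < n; ++j) {
      double x = (j - (n - 1) / 2.0) * v;
      for (int i = 0; i < n; ++i) {
        double val = img[(size_t)j * n + i];
        if (val <= 0) continue;
        double y = (i - (n - 1) / 2.0) * v;
        double t = (-x * sn + y * cs) / bin_mm + (n_bins - 1) / 2.0;
        int b0 = (int)std::floor(t);
        double w = t - b0;
        double contrib = val * attn((size_t)j * n + i, col) * scale;
        if (b0 >= 0 && b0 < n_bins) out(a, b0) += contrib * (1.0 - w);
        if (b0 + 1 >= 0 && b0 + 1 < n_bins) out(a, b0 + 1) += contrib * w;
      }
    }
  }
  return out;
}

// Exact transpose of cpp_forward.
// [[Rcpp::export]]
NumericVector cpp_backward(NumericMatrix sino, int n, double voxel_mm,
                           NumericVector angles_rad, IntegerVector angle_cols,
                           NumericMatrix attn, double bin_mm, double scale) {
  const int n_ang = angles_rad.size(), n_bins = sino.ncol();
  const double v = voxel_mm;
  NumericVector img((size_t)n * n);
  for (int a = 0; a < n_ang; ++a) {
    double sn = std::sin(angles_rad[a]), cs = std::cos(angles_rad[a]);
    int col = angle_cols[a];
    for (int j = 0; j < n; ++j) {
      double x = (j - (n - 1) / 2.0) * v;
      for (int i = 0; i < n; ++i) {
        double y = (i - (n - 1) / 2.0) * v;
        double t = (-x * sn + y * cs) / bin_mm + (n_bins - 1) / 2.0;
        int b0 = (int)std::floor(t);
        double w = t - b0;
        double acc = 0.0;
        if (b0 >= 0 && b0 < n_bins) acc += sino(a, b0) * (1.0 - w);
        if (b0 + 1 >= 0 && b0 + 1 < n_bins) acc += sino(a, b0 + 1) * w;
        img[(size_t)j * n + i] += acc * attn((size_t)j * n + i, col) * scale;
      }
    }
  }
  return img;
}
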