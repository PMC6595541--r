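#include <Rcpp.h>
using namespace Rcpp;

// Biot-Savart midpoint-rule sums over straight filament segments.
// Inputs are in metres; current in amperes.
//   A(r) = (mu0 I / 4 pi) * sum_s dl_s / |r - m_s|
//   B(r) = (mu0 I / 4 pi) * sum_s dl_s x (r - m_s) / |r - m_s|^3
// where m_s is the segment midpoint and dl_s its vector length.
// `comp` selects one output component (1..3) or all (0).
// `clamp` > 0 regularises the kernel by flooring |r - m_s| at `clamp`
// (field inside a conductor of that radius does not exceed its surface
// value); clamp <= 0 means no regularisation and the caller is expected
// to have enforced a guard distance.

static const double MU0_OVER_4PI = 1e-7;

// [[Rcpp::export(name = ".bs_vector_potential")]]
NumericMatrix bs_vector_potential(NumericMatrix pts, NumericMatrix seg_start,
                                  NumericMatrix seg_end, double current,
                                  int comp, double clamp) {
  const int np = pts.nrow(), ns = seg_start.nrow();
  const int ncol_out = (comp == 0) ? 3 : 1;
  NumericMatrix out(np, ncol_out);
  std::vector<double> mx(ns), my(ns), mz(ns), dlx(ns), dly(ns), dlz(ns);
  for (int s = 0; s < ns; ++s) {
    mx[s] = 0.5 * (seg_start(s, 0) + seg_end(s, 0));
    my[s] = 0.5 * (seg_start(s, 1) + seg_end(s, 1));
    mz[s] = 0.5 * (seg_start(s, 2) + seg_end(s, 2));
    dlx[s] = seg_end(s, 0) - seg_start(s, 0);
    dly[s] = seg_end(s, 1) - seg_start(s, 1);
    dlz[s] = seg_end(s, 2) - seg_start(s, 2);
  }
  const double c0 = MU0_OVER_4PI * current;
  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double ax = 0.0, ay = 0.0, az = 0.0;
    for (int s = 0; s < ns; ++s) {
      const double rx = px - mx[s], ry = py - my[s], rz = pz - mz[s];
      double d = std::sqrt(rx * rx + ry * ry + rz * rz);
      if (clamp > 0.0 && d < clamp) d = clamp;
      const double inv = 1.0 / d;
      ax += dlx[s] * inv;
      ay += dly[s] * inv;
      az += dlz[s] * inv;
    }
    if (comp == 0) {
      out(p, 0) = c0 * ax; out(p, 1) = c0 * ay; out(p, 2) = c0 * az;
    } else if (comp == 1) out(p, 0) = c0 * ax;
    else if (comp == 2) out(p, 0) = c0 * ay;
    else out(p, 0) = c0 * az;
  }
  return out;
}

// [[Rcpp::export(name = ".bs_b_field")]]
NumericMatrix bs_b_field(NumericMatrix pts, NumericMatrix seg_start,
                         NumericMatrix seg_end, double current,
                         double clamp) {
  const int np = pts.nrow(), ns = seg_start.nrow();
  NumericMatrix out(np, 3);
  std::vector<double> mx(ns), my(ns), mz(ns), dlx(ns), dly(ns), dlz(ns);
  for (int s = 0; s < ns; ++s) {
    mx[s] = 0.5 * (seg_start(s, 0) + seg_end(s, 0));
    my[s] = 0.5 * (seg_start(s, 1) + seg_end(s, 1));
    mz[s] = 0.5 * (seg_start(s, 2) + seg_end(s, 2));
    dlx[s] = seg_end(s, 0) - seg_start(s, 0);
    dly[s] = seg_end(s, 1) - seg_start(s, 1);
    dlz[s] = seg_end(s, 2) - seg_start(s, 2);
  }
  const double c0 = MU0_OVER_4PI * current;
  for (int p = 0; p < np; ++p) {
    const double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    double bx = 0.0, by = 0.0, bz = 0.0;
    for (int s = 0; s < ns; ++s) {
      const double rx = px - mx[s], ry = py - my[s], rz = pz - mz[s];
      double d = std::sqrt(rx * rx + ry * ry + rz * rz);
      if (clamp > 0.0 && d < clamp) d = clamp;
      const double inv3 = 1.0 / (d * d * d);
      bx += (dly[s] * rz - dlz[s] * ry) * inv3;
      by += (dlz[s] * rx - dlx[s] * rz) * inv3;
      bz += (dlx[s] * ry - dly[s] * rx) * inv3;
    }
    out(p, 0) = c0 * bx; out(p, 1) = c0 * by; out(p, 2) = c0 * bz;
  }
  return out;
}

// Minimum distance from each point to any segment midpoint (guard check).
// [[Rcpp::export(name = ".bs_min_dist")]]
double bs_min_dist(NumericMatrix pts, NumericMatrix seg_start,
                   NumericMatrix seg_end) {
  const int np = pts.nrow(), ns = seg_start.nrow();
  double best = R_PosInf;
  for (int s = 0; s < ns; ++s) {
    const double mx = 0.5 * (seg_start(s, 0) + seg_end(s, 0));
    const double my = 0.5 * (seg_start(s, 1) + seg_end(s, 1));
    const double mz = 0.5 * (seg_start(s, 2) + seg_end(s, 2));
    for (int p = 0; p < np; ++p) {
      const double rx = pts(p, 0) - mx, ry = pts(p, 1) - my,
                   rz = pts(p, 2) - mz;
      const double d2 = rx * rx + ry * ry + rz * rz;
      if (d2 < best) best = d2;
    }
  }
  return std::sqrt(best);
}
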