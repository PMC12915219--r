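// Isotropic first-order fast-marching eikonal solver with analytic source
// initialisation, bilinear field refinement and steepest-descent ray tracing.
// All quantities SI: positions m, speeds m/s, times s.  Grids are square,
// cell-centred: node (ix, iy) sits at ((ix+0.5)*h - E/2, (iy+0.5)*h - E/2).
// R matrices are indexed [row, col] = [iy+1, ix+1] (rows = y/axial).
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// node coordinate helpers
static inline double nodeCoord(int i, double h, double extent) {
  return (i + 0.5) * h - extent / 2.0;
}

// Bilinear interpolation with linear edge-cell extrapolation (exact on
// linear fields everywhere, including beyond the outermost node centres).
static double bilinear(const double* v, int n, double h, double extent,
                       double x, double y, bool clamp) {
  double fx = (x + extent / 2.0) / h - 0.5;
  double fy = (y + extent / 2.0) / h - 0.5;
  if (clamp) {
    fx = std::min(std::max(fx, 0.0), (double)(n - 1));
    fy = std::min(std::max(fy, 0.0), (double)(n - 1));
  }
  int ix = (int)std::floor(fx), iy = (int)std::floor(fy);
  ix = std::min(std::max(ix, 0), n - 2);
  iy = std::min(std::max(iy, 0), n - 2);
  double tx = fx - ix, ty = fy - iy;
  const double v00 = v[iy * n + ix],     v01 = v[iy * n + ix + 1];
  const double v10 = v[(iy + 1) * n + ix], v11 = v[(iy + 1) * n + ix + 1];
  return (1 - ty) * ((1 - tx) * v00 + tx * v01) +
         ty       * ((1 - tx) * v10 + tx * v11);
}

// [[Rcpp::export(name = ".fmm_solve")]]
NumericMatrix fmm_solve(NumericMatrix speed, double pitch, double extent,
                        double src_x, double src_y, int init_radius = 3) {
  const int n = speed.nrow();
  if (speed.ncol() != n) stop("speed map must be square");
  std::vector<double> T((size_t)n * n, INF);
  std::vector<unsigned char> state((size_t)n * n, 0); // 0 FAR 1 TRIAL 2 KNOWN

  // speed at the node nearest the source (analytic-disk initialisation)
  int sx = std::min(std::max((int)std::floor((src_x + extent / 2) / pitch), 0), n - 1);
  int sy = std::min(std::max((int)std::floor((src_y + extent / 2) / pitch), 0), n - 1);
  const double c_src = speed(sy, sx);
  if (!(c_src > 0)) stop("non-positive speed at source");

  typedef std::pair<double, int> QN; // (time, flat index iy*n+ix)
  std::priority_queue<QN, std::vector<QN>, std::greater<QN> > heap;

  const double r_init = init_radius * pitch;
  for (int iy = std::max(0, sy - init_radius - 1);
       iy <= std::min(n - 1, sy + init_radius + 1); ++iy) {
    for (int ix = std::max(0, sx - init_radius - 1);
         ix <= std::min(n - 1, sx + init_radius + 1); ++ix) {
      double dx = nodeCoord(ix, pitch, extent) - src_x;
      double dy = nodeCoord(iy, pitch, extent) - src_y;
      double d = std::sqrt(dx * dx + dy * dy);
      if (d <= r_init) {
        int id = iy * n + ix;
        T[id] = d / c_src;
        state[id] = 2;
      }
    }
  }
  // seed the trial front from the frozen disk
  const int dxs[4] = {1, -1, 0, 0}, dys[4] = {0, 0, 1, -1};
  for (int iy = 0; iy < n; ++iy) for (int ix = 0; ix < n; ++ix) {
    if (state[iy * n + ix] != 2) continue;
    heap.push(QN(T[iy * n + ix], iy * n + ix));
  }
  if (heap.empty()) stop("source outside grid: analytic disk covers no node");

  while (!heap.empty()) {
    QN top = heap.top(); heap.pop();
    int id = top.second;
    if (top.first > T[id]) continue; // stale entry
    state[id] = 2;
    int ix = id % n, iy = id / n;
    for (int k = 0; k < 4; ++k) {
      int jx = ix + dxs[k], jy = iy + dys[k];
      if (jx < 0 || jx >= n || jy < 0 || jy >= n) continue;
      int jd = jy * n + jx;
      if (state[jd] == 2) continue;
      double c = speed(jy, jx);
      if (!(c > 0)) stop("non-positive speed in map");
      double f = pitch / c;
      // upwind values along x and y: first-order neighbour T1 and, when the
      // second node in the same direction is also accepted with T2 <= T1,
      // the second-order one-sided difference (standard high-accuracy FMM;
      // falls back to first order when the stencil is incomplete)
      double a1 = INF, b1 = INF, a2 = INF, b2 = INF;
      if (jx > 0     && state[jd - 1] == 2 && T[jd - 1] < a1) {
        a1 = T[jd - 1];
        if (jx > 1 && state[jd - 2] == 2 && T[jd - 2] <= a1) a2 = T[jd - 2];
      }
      if (jx < n - 1 && state[jd + 1] == 2 && T[jd + 1] < a1) {
        a1 = T[jd + 1]; a2 = INF;
        if (jx < n - 2 && state[jd + 2] == 2 && T[jd + 2] <= a1) a2 = T[jd + 2];
      }
      if (jy > 0     && state[jd - n] == 2 && T[jd - n] < b1) {
        b1 = T[jd - n];
        if (jy > 1 && state[jd - 2 * n] == 2 && T[jd - 2 * n] <= b1)
          b2 = T[jd - 2 * n];
      }
      if (jy < n - 1 && state[jd + n] == 2 && T[jd + n] < b1) {
        b1 = T[jd + n]; b2 = INF;
        if (jy < n - 2 && state[jd + 2 * n] == 2 && T[jd + 2 * n] <= b1)
          b2 = T[jd + 2 * n];
      }
      if (a1 == INF && b1 == INF) continue;

      // solve sum_axes (alpha T - beta)^2 = f^2 for the largest root;
      // second-order axis: alpha = 3/2, beta = 2 T1 - T2/2
      auto solve = [&](bool useA2, bool useB2) {
        double A = 0, B = 0, C = -f * f;
        double lo = 0;
        if (a1 != INF) {
          double al = 1.0, be = a1;
          if (useA2) { al = 1.5; be = 2.0 * a1 - 0.5 * a2; }
          A += al * al; B += al * be; C += be * be;
          lo = std::max(lo, a1);
        }
        if (b1 != INF) {
          double al = 1.0, be = b1;
          if (useB2) { al = 1.5; be = 2.0 * b1 - 0.5 * b2; }
          A += al * al; B += al * be; C += be * be;
          lo = std::max(lo, b1);
        }
        double disc = B * B - A * C;
        if (disc < 0) return INF;
        double t = (B + std::sqrt(disc)) / A;
        // causality: the solution must not precede its upwind data; for a
        // two-axis solve that failed it, use the better single axis + f
        if (a1 != INF && b1 != INF && t < lo) return INF;
        return t;
      };
      double tnew = solve(a2 != INF, b2 != INF);
      if (tnew == INF) tnew = solve(false, false);
      if (tnew == INF) tnew = std::min(a1, b1) + f;
      if (tnew < T[jd]) {
        T[jd] = tnew;
        state[jd] = 1;
        heap.push(QN(tnew, jd));
      }
    }
  }

  NumericMatrix out(n, n);
  for (int iy = 0; iy < n; ++iy)
    for (int ix = 0; ix < n; ++ix) out(iy, ix) = T[iy * n + ix];
  return out;
}

// [[Rcpp::export(name = ".bilinear_refine")]]
NumericMatrix bilinear_refine(NumericMatrix field, double extent, int factor) {
  const int n = field.nrow();
  if (factor < 1) stop("refinement factor must be >= 1");
  if (factor == 1) return clone(field);
  const int nf = n * factor;
  const double h = extent / n, hf = extent / nf;
  std::vector<double> v((size_t)n * n);
  for (int iy = 0; iy < n; ++iy)
    for (int ix = 0; ix < n; ++ix) v[iy * n + ix] = field(iy, ix);
  NumericMatrix out(nf, nf);
  for (int iy = 0; iy < nf; ++iy) {
    double y = nodeCoord(iy, hf, extent);
    for (int ix = 0; ix < nf; ++ix) {
      double x = nodeCoord(ix, hf, extent);
      out(iy, ix) = bilinear(v.data(), n, h, extent, x, y, false);
    }
  }
  return out;
}

// [[Rcpp::export(name = ".bilinear_lookup")]]
double bilinear_lookup(NumericMatrix field, double extent, double x, double y,
                       bool clamp = true) {
  const int n = field.nrow();
  std::vector<double> v((size_t)n * n);
  for (int iy = 0; iy < n; ++iy)
    for (int ix = 0; ix < n; ++ix) v[iy * n + ix] = field(iy, ix);
  return bilinear(v.data(), n, extent / n, extent, x, y, clamp);
}

struct RayResult {
  std::vector<double> px, py;
  double time;
  bool ok;
};

// steepest descent on the fine time field from det to src
static RayResult trace_one(const std::vector<double>& Tf,
                           const std::vector<double>& gx,
                           const std::vector<double>& gy,
                           int nf, double hf, double extent,
                           const std::vector<double>& speed, int n, double h,
                           double det_x, double det_y,
                           double src_x, double src_y, double stop_radius) {
  RayResult res; res.ok = true; res.time = 0.0;
  const double step = 0.25 * hf;
  // Terminate once inside the analytic-initialisation disk (the field is
  // exactly radial there, so the closing straight segment is the geodesic);
  // never below one fine pixel.
  const double stop_r = std::max(stop_radius, hf);
  const long max_steps = 10L * nf * 4L; // step is a quarter fine-pixel
  double x = det_x, y = det_y;
  res.px.push_back(x); res.py.push_back(y);
  long it = 0;
  for (; it < max_steps; ++it) {
    double dx = x - src_x, dy = y - src_y;
    if (std::sqrt(dx * dx + dy * dy) <= stop_r) break;
    double g1 = bilinear(gx.data(), nf, hf, extent, x, y, true);
    double g2 = bilinear(gy.data(), nf, hf, extent, x, y, true);
    double gn = std::sqrt(g1 * g1 + g2 * g2);
    if (!(gn > 1e-16)) { res.ok = false; break; }
    x -= step * g1 / gn;
    y -= step * g2 / gn;
    // keep the walker inside the physical domain
    double lim = extent / 2.0;
    x = std::min(std::max(x, -lim), lim);
    y = std::min(std::max(y, -lim), lim);
    res.px.push_back(x); res.py.push_back(y);
  }
  if (it >= max_steps) res.ok = false;
  // final straight segment to the exact source point
  res.px.push_back(src_x); res.py.push_back(src_y);
  // trapezoidal slowness integral with bilinear (clamped) speed lookup
  double t = 0.0;
  for (size_t k = 1; k < res.px.size(); ++k) {
    double ax = res.px[k - 1], ay = res.py[k - 1];
    double bx = res.px[k],     by = res.py[k];
    double len = std::sqrt((bx - ax) * (bx - ax) + (by - ay) * (by - ay));
    if (len == 0.0) continue;
    double sa = 1.0 / bilinear(speed.data(), n, h, extent, ax, ay, true);
    double sb = 1.0 / bilinear(speed.data(), n, h, extent, bx, by, true);
    t += len * 0.5 * (sa + sb);
  }
  res.time = t;
  return res;
}

static void central_gradients(const std::vector<double>& Tf, int nf, double hf,
                              std::vector<double>& gx, std::vector<double>& gy) {
  gx.assign((size_t)nf * nf, 0.0);
  gy.assign((size_t)nf * nf, 0.0);
  for (int iy = 0; iy < nf; ++iy) {
    for (int ix = 0; ix < nf; ++ix) {
      int id = iy * nf + ix;
      int xm = std::max(ix - 1, 0), xp = std::min(ix + 1, nf - 1);
      int ym = std::max(iy - 1, 0), yp = std::min(iy + 1, nf - 1);
      gx[id] = (Tf[iy * nf + xp] - Tf[iy * nf + xm]) / ((xp - xm) * hf);
      gy[id] = (Tf[yp * nf + ix] - Tf[ym * nf + ix]) / ((yp - ym) * hf);
    }
  }
}

// [[Rcpp::export(name = ".trace_ray")]]
List trace_ray_cpp(NumericMatrix fineT, double extent,
                   NumericMatrix speed,
                   double det_x, double det_y,
                   double src_x, double src_y, int init_radius = 3) {
  const int nf = fineT.nrow(), n = speed.nrow();
  const double hf = extent / nf, h = extent / n;
  std::vector<double> Tf((size_t)nf * nf), sp((size_t)n * n);
  for (int iy = 0; iy < nf; ++iy)
    for (int ix = 0; ix < nf; ++ix) Tf[iy * nf + ix] = fineT(iy, ix);
  for (int iy = 0; iy < n; ++iy)
    for (int ix = 0; ix < n; ++ix) sp[iy * n + ix] = speed(iy, ix);
  std::vector<double> gx, gy;
  central_gradients(Tf, nf, hf, gx, gy);
  RayResult r = trace_one(Tf, gx, gy, nf, hf, extent, sp, n, h,
                          det_x, det_y, src_x, src_y, init_radius * h);
  NumericMatrix path(r.px.size(), 2);
  for (size_t k = 0; k < r.px.size(); ++k) {
    path(k, 0) = r.px[k];
    path(k, 1) = r.py[k];
  }
  return List::create(_["path"] = path, _["time"] = r.time, _["ok"] = r.ok,
                      _["last_x"] = r.px[r.px.size() - 2],
                      _["last_y"] = r.py[r.py.size() - 2]);
}

// One eikonal solve per generation element; ToF(i, j) = traced-ray slowness
// integral from generation i to detection j (fallback: interpolated field).
// [[Rcpp::export(name = ".tof_matrix")]]
List tof_matrix_cpp(NumericMatrix speed, double extent,
                    NumericMatrix gen_pos, NumericMatrix det_pos,
                    int factor, int init_radius = 3) {
  const int n = speed.nrow();
  const int ng = gen_pos.nrow(), nd = det_pos.nrow();
  const double h = extent / n;
  const int nf = n * factor;
  const double hf = extent / nf;
  NumericMatrix tof(ng, nd);
  IntegerMatrix fellback(ng, nd);
  std::vector<double> sp((size_t)n * n);
  for (int iy = 0; iy < n; ++iy)
    for (int ix = 0; ix < n; ++ix) sp[iy * n + ix] = speed(iy, ix);
  for (int i = 0; i < ng; ++i) {
    NumericMatrix T = fmm_solve(speed, h, extent, gen_pos(i, 0), gen_pos(i, 1),
                                init_radius);
    NumericMatrix Tfm = bilinear_refine(T, extent, factor);
    std::vector<double> Tf((size_t)nf * nf);
    for (int iy = 0; iy < nf; ++iy)
      for (int ix = 0; ix < nf; ++ix) Tf[iy * nf + ix] = Tfm(iy, ix);
    std::vector<double> gx, gy;
    central_gradients(Tf, nf, hf, gx, gy);
    for (int j = 0; j < nd; ++j) {
      RayResult r = trace_one(Tf, gx, gy, nf, hf, extent, sp, n, h,
                              det_pos(j, 0), det_pos(j, 1),
                              gen_pos(i, 0), gen_pos(i, 1), init_radius * h);
      if (r.ok) {
        tof(i, j) = r.time;
      } else {
        tof(i, j) = bilinear(Tf.data(), nf, hf, extent,
                             det_pos(j, 0), det_pos(j, 1), true);
        fellback(i, j) = 1;
      }
    }
  }
  return List::create(_["tof"] = tof, _["fallback"] = fellback);
}

// Sliding-window kurtosis, population moments, window anchored at its
// leading edge: kappa[k] covers samples k .. k+N-1 (1-based in R).
// Zero-variance windows yield NA.
// [[Rcpp::export(name = ".sliding_kurtosis")]]
NumericVector sliding_kurtosis_cpp(NumericVector x, int N) {
  const int L = x.size();
  if (N < 4) stop("kurtosis window must span at least 4 samples");
  if (N > L) stop("kurtosis window longer than signal");
  const int M = L - N + 1;
  NumericVector out(M);
  for (int k = 0; k < M; ++k) {
    double m = 0.0;
    for (int i = 0; i < N; ++i) m += x[k + i];
    m /= N;
    double m2 = 0.0, m4 = 0.0;
    for (int i = 0; i < N; ++i) {
      double d = x[k + i] - m, d2 = d * d;
      m2 += d2; m4 += d2 * d2;
    }
    m2 /= N; m4 /= N;
    out[k] = (m2 > 0.0) ? m4 / (m2 * m2) : NA_REAL;
  }
  return out;
}

// Unnormalised cross-correlation R(m) = sum_j x(j) y(m + j) for the given
// integer lags (1-based j over the full length of x; y zero-padded).
// [[Rcpp::export(name = ".xcorr_lags")]]
NumericVector xcorr_lags_cpp(NumericVector x, NumericVector y,
                             IntegerVector lags) {
  const int L = x.size(), Ly = y.size();
  NumericVector out(lags.size());
  for (int q = 0; q < lags.size(); ++q) {
    int m = lags[q];
    double acc = 0.0;
    int jlo = std::max(0, -m), jhi = std::min(L, Ly - m);
    for (int j = jlo; j < jhi; ++j) acc += x[j] * y[j + m];
    out[q] = acc;
  }
  return out;
}
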