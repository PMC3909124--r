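#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static void get_dims(const RObject &x, int d[3]) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 3) stop("expected a 3D array");
  d[0] = dim[0]; d[1] = dim[1]; d[2] = dim[2];
}

// ---------------------------------------------------------------------------
// Separable Gaussian convolution with mirror boundary, per-axis sigma (voxels)
// ---------------------------------------------------------------------------

static void conv_axis(const std::vector<double> &in, std::vector<double> &out,
                      const int n[3], int axis, const std::vector<double> &k) {
  int R = ((int)k.size() - 1) / 2;
  long s[3] = {1, (long)n[0], (long)n[0] * n[1]};
  int a1 = (axis + 1) % 3, a2 = (axis + 2) % 3;
  int na = n[axis];
  long sa = s[axis];
  for (int j2 = 0; j2 < n[a2]; ++j2)
    for (int j1 = 0; j1 < n[a1]; ++j1) {
      long base = j1 * s[a1] + j2 * s[a2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int t = -R; t <= R; ++t) {
          int ii = i + t;
          if (ii < 0) ii = -ii - 1;
          else if (ii >= na) ii = 2 * na - ii - 1;
          acc += k[t + R] * in[base + (long)ii * sa];
        }
        out[base + (long)i * sa] = acc;
      }
    }
}

// [[Rcpp::export]]
NumericVector blur3d_cpp(NumericVector x, NumericVector sigma_vox) {
  int d[3]; get_dims(x, d);
  long ntot = (long)d[0] * d[1] * d[2];
  std::vector<double> a(x.begin(), x.end()), b(ntot);
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int R = std::max(1, (int)std::ceil(4.0 * s));
    std::vector<double> k(2 * R + 1);
    double tot = 0;
    for (int t = -R; t <= R; ++t) { k[t + R] = std::exp(-0.5 * t * t / (s * s)); tot += k[t + R]; }
    for (double &v : k) v /= tot;
    conv_axis(a, b, d, axis, k);
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = x.attr("dim");
  return out;
}

// ---------------------------------------------------------------------------
// Eigen-decomposition of a field of symmetric 3x3 matrices.
// Eigenvalues returned sorted by |lambda| ascending; v1 is the eigenvector of
// the smallest-|lambda| eigenvalue (vessel direction for tubular structures).
// ---------------------------------------------------------------------------

static inline void cross3(const double *a, const double *b, double *c) {
  c[0] = a[1] * b[2] - a[2] * b[1];
  c[1] = a[2] * b[0] - a[0] * b[2];
  c[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double norm3(const double *a) {
  return std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
}

// eigenvector of symmetric A (packed xx,yy,zz,xy,xz,yz) for eigenvalue lam;
// returns false when the cross-product construction degenerates
static bool eigvec_sym3(const double A[6], double lam, double *v) {
  double r0[3] = {A[0] - lam, A[3], A[4]};
  double r1[3] = {A[3], A[1] - lam, A[5]};
  double r2[3] = {A[4], A[5], A[2] - lam};
  double c[3][3];
  cross3(r0, r1, c[0]); cross3(r0, r2, c[1]); cross3(r1, r2, c[2]);
  int best = 0; double bn = norm3(c[0]);
  for (int i = 1; i < 3; ++i) { double n = norm3(c[i]); if (n > bn) { bn = n; best = i; } }
  double scale = std::abs(A[0]) + std::abs(A[1]) + std::abs(A[2]) +
                 2 * (std::abs(A[3]) + std::abs(A[4]) + std::abs(A[5])) + 1e-300;
  if (bn < 1e-12 * scale * scale) return false;
  for (int i = 0; i < 3; ++i) v[i] = c[best][i] / bn;
  return true;
}

// [[Rcpp::export]]
List eig3_field_cpp(NumericVector xx, NumericVector yy, NumericVector zz,
                    NumericVector xy, NumericVector xz, NumericVector yz) {
  R_xlen_t n = xx.size();
  NumericMatrix lam(n, 3), V1(n, 3), V2(n, 3), V3(n, 3);
  const double twopi3 = 2.0943951023931953; // 2*pi/3
  for (R_xlen_t i = 0; i < n; ++i) {
    double A[6] = {xx[i], yy[i], zz[i], xy[i], xz[i], yz[i]};
    double e[3];
    double p1 = A[3] * A[3] + A[4] * A[4] + A[5] * A[5];
    if (p1 == 0.0) {
      e[0] = A[0]; e[1] = A[1]; e[2] = A[2];
    } else {
      double q = (A[0] + A[1] + A[2]) / 3.0;
      double p2 = (A[0] - q) * (A[0] - q) + (A[1] - q) * (A[1] - q) +
                  (A[2] - q) * (A[2] - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      // det of (A - qI)/p
      double b0 = (A[0] - q) / p, b1 = (A[1] - q) / p, b2 = (A[2] - q) / p;
      double b3 = A[3] / p, b4 = A[4] / p, b5 = A[5] / p;
      double detB = b0 * (b1 * b2 - b5 * b5) - b3 * (b3 * b2 - b5 * b4) +
                    b4 * (b3 * b5 - b1 * b4);
      double r = detB / 2.0;
      if (r < -1.0) r = -1.0; else if (r > 1.0) r = 1.0;
      double phi = std::acos(r) / 3.0;
      e[0] = q + 2.0 * p * std::cos(phi);
      e[2] = q + 2.0 * p * std::cos(phi + 2.0 * twopi3);
      e[1] = 3.0 * q - e[0] - e[2];
    }
    // order by |lambda| ascending
    int ord[3] = {0, 1, 2};
    for (int a = 0; a < 2; ++a)
      for (int b = a + 1; b < 3; ++b)
        if (std::abs(e[ord[b]]) < std::abs(e[ord[a]])) std::swap(ord[a], ord[b]);
    double l[3] = {e[ord[0]], e[ord[1]], e[ord[2]]};
    lam(i, 0) = l[0]; lam(i, 1) = l[1]; lam(i, 2) = l[2];
    // eigenvectors: start with the best-separated eigenvalue
    double sep[3];
    for (int a = 0; a < 3; ++a) {
      double s = R_PosInf;
      for (int b = 0; b < 3; ++b) if (b != a) s = std::min(s, std::abs(l[a] - l[b]));
      sep[a] = s;
    }
    int k0 = 0;
    for (int a = 1; a < 3; ++a) if (sep[a] > sep[k0]) k0 = a;
    double v[3][3];
    bool ok0 = eigvec_sym3(A, l[k0], v[k0]);
    if (!ok0) { // (near-)isotropic: any orthonormal basis works
      v[0][0] = 1; v[0][1] = 0; v[0][2] = 0;
      v[1][0] = 0; v[1][1] = 1; v[1][2] = 0;
      v[2][0] = 0; v[2][1] = 0; v[2][2] = 1;
    } else {
      int k1 = (k0 + 1) % 3, k2 = (k0 + 2) % 3;
      if (sep[k2] > sep[k1]) std::swap(k1, k2);
      double w[3];
      bool ok1 = eigvec_sym3(A, l[k1], w);
      if (ok1) {
        // orthogonalize against v[k0] to be safe near degeneracy
        double d = w[0] * v[k0][0] + w[1] * v[k0][1] + w[2] * v[k0][2];
        for (int t = 0; t < 3; ++t) w[t] -= d * v[k0][t];
        double nw = norm3(w);
        if (nw > 1e-12) { for (int t = 0; t < 3; ++t) v[k1][t] = w[t] / nw; ok1 = true; }
        else ok1 = false;
      }
      if (!ok1) { // pick any unit vector orthogonal to v[k0]
        double ref[3] = {1, 0, 0};
        if (std::abs(v[k0][0]) > 0.9) { ref[0] = 0; ref[1] = 1; }
        cross3(v[k0], ref, w);
        double nw = norm3(w);
        for (int t = 0; t < 3; ++t) v[k1][t] = w[t] / nw;
      }
      cross3(v[k0], v[k1], v[k2]);
    }
    for (int t = 0; t < 3; ++t) { V1(i, t) = v[0][t]; V2(i, t) = v[1][t]; V3(i, t) = v[2][t]; }
  }
  return List::create(_["lam"] = lam, _["v1"] = V1, _["v2"] = V2, _["v3"] = V3);
}

// ---------------------------------------------------------------------------
// Trilinear sampling at continuous (0-based) voxel coordinates
// ---------------------------------------------------------------------------

static inline double trilin_one(const double *a, const int d[3],
                                double x, double y, double z, double fill) {
  if (x < 0 || y < 0 || z < 0 || x > d[0] - 1 || y > d[1] - 1 || z > d[2] - 1)
    return fill;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == d[0] - 1) i0--; if (j0 == d[1] - 1) j0--; if (k0 == d[2] - 1) k0--;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  long s1 = d[0], s2 = (long)d[0] * d[1];
  const double *p = a + i0 + (long)j0 * s1 + (long)k0 * s2;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[s1] * (1 - fx) + p[s1 + 1] * fx;
  double c01 = p[s2] * (1 - fx) + p[s2 + 1] * fx;
  double c11 = p[s2 + s1] * (1 - fx) + p[s2 + s1 + 1] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector trilin_cpp(NumericVector vol, NumericMatrix pts, double fill = 0.0) {
  int d[3]; get_dims(vol, d);
  R_xlen_t n = pts.nrow();
  NumericVector out(n);
  const double *a = vol.begin();
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = trilin_one(a, d, pts(i, 0), pts(i, 1), pts(i, 2), fill);
  return out;
}

// ---------------------------------------------------------------------------
// Connected components (BFS), 6- or 26-connectivity
// ---------------------------------------------------------------------------

static int make_offsets(const int d[3], int conn, long off[26], int doff[26][3]) {
  int m = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        if (conn == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1) continue;
        off[m] = dx + (long)dy * d[0] + (long)dz * d[0] * d[1];
        doff[m][0] = dx; doff[m][1] = dy; doff[m][2] = dz;
        ++m;
      }
  return m;
}

// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, int conn = 26) {
  int d[3]; get_dims(mask, d);
  long ntot = (long)d[0] * d[1] * d[2];
  IntegerVector lab(ntot, 0);
  lab.attr("dim") = mask.attr("dim");
  long off[26]; int doff[26][3];
  int m = make_offsets(d, conn, off, doff);
  std::vector<long> q;
  int cur = 0;
  for (long s = 0; s < ntot; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++cur;
    q.clear(); q.push_back(s); lab[s] = cur;
    size_t head = 0;
    while (head < q.size()) {
      long p = q[head++];
      int pi = (int)(p % d[0]);
      int pj = (int)((p / d[0]) % d[1]);
      int pk = (int)(p / ((long)d[0] * d[1]));
      for (int t = 0; t < m; ++t) {
        int ii = pi + doff[t][0], jj = pj + doff[t][1], kk = pk + doff[t][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
        long np = p + off[t];
        if (mask[np] && !lab[np]) { lab[np] = cur; q.push_back(np); }
      }
    }
  }
  return lab;
}

// Component of `mask` containing 0-based linear index `seed` (26-connectivity)
// [[Rcpp::export]]
LogicalVector cc_of_seed_cpp(LogicalVector mask, double seed) {
  int d[3]; get_dims(mask, d);
  long ntot = (long)d[0] * d[1] * d[2];
  long s = (long)seed;
  LogicalVector out(ntot, false);
  out.attr("dim") = mask.attr("dim");
  if (s < 0 || s >= ntot || !mask[s]) return out;
  long off[26]; int doff[26][3];
  int m = make_offsets(d, 26, off, doff);
  std::vector<long> q; q.push_back(s); out[s] = true;
  size_t head = 0;
  while (head < q.size()) {
    long p = q[head++];
    int pi = (int)(p % d[0]);
    int pj = (int)((p / d[0]) % d[1]);
    int pk = (int)(p / ((long)d[0] * d[1]));
    for (int t = 0; t < m; ++t) {
      int ii = pi + doff[t][0], jj = pj + doff[t][1], kk = pk + doff[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
      long np = p + off[t];
      if (mask[np] && !out[np]) { out[np] = true; q.push_back(np); }
    }
  }
  return out;
}

// Multi-source BFS label fill: every voxel gets the label of the nearest
// (in grid steps, 26-connectivity) seed; ties resolved by arrival order
// (seeds enqueued in increasing label).
// [[Rcpp::export]]
IntegerVector label_propagate_cpp(IntegerVector labels) {
  int d[3]; get_dims(labels, d);
  long ntot = (long)d[0] * d[1] * d[2];
  IntegerVector out = clone(labels);
  long off[26]; int doff[26][3];
  int m = make_offsets(d, 26, off, doff);
  std::vector<long> q;
  int maxlab = 0;
  for (long s = 0; s < ntot; ++s) if (out[s] > maxlab) maxlab = out[s];
  for (int l = 1; l <= maxlab; ++l)
    for (long s = 0; s < ntot; ++s) if (out[s] == l) q.push_back(s);
  size_t head = 0;
  while (head < q.size()) {
    long p = q[head++];
    int pi = (int)(p % d[0]);
    int pj = (int)((p / d[0]) % d[1]);
    int pk = (int)(p / ((long)d[0] * d[1]));
    for (int t = 0; t < m; ++t) {
      int ii = pi + doff[t][0], jj = pj + doff[t][1], kk = pk + doff[t][2];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= d[0] || jj >= d[1] || kk >= d[2]) continue;
      long np = p + off[t];
      if (!out[np]) { out[np] = out[p]; q.push_back(np); }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Dijkstra shortest-path tree (binary heap); edges 0-based, undirected
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List dijkstra_tree_cpp(int n, IntegerVector ei, IntegerVector ej,
                       NumericVector w, int source) {
  std::vector<std::vector<std::pair<int, double>>> adj(n);
  for (R_xlen_t e = 0; e < ei.size(); ++e) {
    adj[ei[e]].push_back({ej[e], w[e]});
    adj[ej[e]].push_back({ei[e], w[e]});
  }
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> parent(n, -1);
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  dist[source] = 0.0;
  pq.push({0.0, source});
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    for (auto &pr : adj[u]) {
      double nd = dist[u] + pr.second;
      if (nd < dist[pr.first]) {
        dist[pr.first] = nd;
        parent[pr.first] = u;
        pq.push({nd, pr.first});
      }
    }
  }
  return List::create(_["parent"] = IntegerVector(parent.begin(), parent.end()),
                      _["dist"] = NumericVector(dist.begin(), dist.end()));
}

// ---------------------------------------------------------------------------
// Offset-medialness ray sampling.
// For each point (0-based voxel coords) with unit direction (physical/mm
// space): sample the image gradient at n_rays points on the circle of
// `radius` mm perpendicular to the direction, score each ray by the inward
// radial gradient (boundary evidence), and also report the gradient
// magnitude at the point itself. Rays leaving the volume contribute zero.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericMatrix medialness_cpp(NumericVector gx, NumericVector gy, NumericVector gz,
                             NumericVector spacing, NumericMatrix pts,
                             NumericMatrix dirs, double radius, int n_rays) {
  int d[3]; get_dims(gx, d);
  const double *ax = gx.begin(), *ay = gy.begin(), *az = gz.begin();
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  R_xlen_t n = pts.nrow();
  NumericMatrix out(n, 3); // mean ray response, min ray response, central |grad|
  for (R_xlen_t i = 0; i < n; ++i) {
    double dx = dirs(i, 0), dy = dirs(i, 1), dz = dirs(i, 2);
    // orthonormal in-plane basis (mm space)
    double ux, uy, uz;
    double rx = (std::abs(dx) < 0.9) ? 1.0 : 0.0;
    double ry = (std::abs(dx) < 0.9) ? 0.0 : 1.0;
    double rz = 0.0;
    // u = d x r, normalized
    ux = dy * rz - dz * ry; uy = dz * rx - dx * rz; uz = dx * ry - dy * rx;
    double nu = std::sqrt(ux * ux + uy * uy + uz * uz);
    ux /= nu; uy /= nu; uz /= nu;
    // w = d x u
    double wx = dy * uz - dz * uy, wy = dz * ux - dx * uz, wz = dx * uy - dy * ux;
    double px = pts(i, 0), py = pts(i, 1), pz = pts(i, 2);
    double sum = 0.0, mn = R_PosInf;
    for (int k = 0; k < n_rays; ++k) {
      double th = 2.0 * M_PI * k / n_rays;
      double cth = std::cos(th), sth = std::sin(th);
      double ox = cth * ux + sth * wx; // outward radial unit vector (mm)
      double oy = cth * uy + sth * wy;
      double oz = cth * uz + sth * wz;
      double qx = px + radius * ox / sx;
      double qy = py + radius * oy / sy;
      double qz = pz + radius * oz / sz;
      double gxx = trilin_one(ax, d, qx, qy, qz, 0.0);
      double gyy = trilin_one(ay, d, qx, qy, qz, 0.0);
      double gzz = trilin_one(az, d, qx, qy, qz, 0.0);
      // inward radial gradient: bright tube -> gradient points inward at rim
      double b = -(gxx * ox + gyy * oy + gzz * oz);
      if (b < 0) b = 0;
      sum += b;
      if (b < mn) mn = b;
    }
    double g0x = trilin_one(ax, d, px, py, pz, 0.0);
    double g0y = trilin_one(ay, d, px, py, pz, 0.0);
    double g0z = trilin_one(az, d, px, py, pz, 0.0);
    out(i, 0) = sum / n_rays;
    out(i, 1) = (n_rays > 0) ? mn : 0.0;
    out(i, 2) = std::sqrt(g0x * g0x + g0y * g0y + g0z * g0z);
  }
  return out;
}
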