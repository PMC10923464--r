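// Spatial core: cell-list cross-pair search, boundary-fraction edge
// weights, ring-wise bivariate Ripley sums, and the Monte-Carlo CSR null.
// Coordinates are continuous physical nm with the origin at the corner of
// pixel (0,0); the mask grid is an R logical array in column-major order
// with dim (ny, nx[, nz]) so that x maps to columns, y to rows, z to slices.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

struct MaskView {
  const int *grid;   // LGLSXP payload (0/1/NA treated as 0 unless 1)
  int ny, nx, nz;    // nz = 1 in 2D
  double psx, psy, psz;
  int dim;           // 2 or 3

  inline bool inside(double x, double y, double z) const {
    double cx = std::floor(x / psx);
    double cy = std::floor(y / psy);
    if (cx < 0 || cy < 0 || cx >= nx || cy >= ny) return false;
    int c = (int)cx, r = (int)cy, s = 0;
    if (dim == 3) {
      double cz = std::floor(z / psz);
      if (cz < 0 || cz >= nz) return false;
      s = (int)cz;
    }
    return grid[r + (R_xlen_t)ny * c + (R_xlen_t)ny * nx * s] == 1;
  }
};

MaskView make_view(const LogicalVector &grid, const IntegerVector &dims,
                   const NumericVector &pixel_size) {
  MaskView v;
  v.grid = LOGICAL(grid);
  v.ny = dims[0];
  v.nx = dims[1];
  v.nz = dims.size() == 3 ? dims[2] : 1;
  v.dim = dims.size() == 3 ? 3 : 2;
  v.psx = pixel_size[0];
  v.psy = pixel_size[1];
  v.psz = pixel_size.size() == 3 ? pixel_size[2] : 1.0;
  return v;
}

// Direction table: unit vectors used to sample the circle (2D) or the
// sphere surface (3D, Fibonacci lattice). Stored as M rows x dim cols.
std::vector<double> direction_table(int M, int dim) {
  std::vector<double> t((size_t)M * dim);
  if (dim == 2) {
    for (int m = 0; m < M; ++m) {
      double th = (2.0 * M_PI * (double)m) / (double)M;
      t[2 * (size_t)m] = std::cos(th);
      t[2 * (size_t)m + 1] = std::sin(th);
    }
  } else {
    const double ga = M_PI * (3.0 - std::sqrt(5.0));
    for (int m = 0; m < M; ++m) {
      double z = 1.0 - 2.0 * ((double)m + 0.5) / (double)M;
      double rad = std::sqrt(std::max(0.0, 1.0 - z * z));
      double ph = ga * (double)m;
      t[3 * (size_t)m] = rad * std::cos(ph);
      t[3 * (size_t)m + 1] = rad * std::sin(ph);
      t[3 * (size_t)m + 2] = z;
    }
  }
  return t;
}

inline double sampled_weight(const MaskView &v, const double *p, double d,
                             const std::vector<double> &dirs, int M,
                             double floor_frac) {
  int in = 0;
  if (v.dim == 2) {
    for (int m = 0; m < M; ++m) {
      if (v.inside(p[0] + d * dirs[2 * (size_t)m],
                   p[1] + d * dirs[2 * (size_t)m + 1], 0.0))
        ++in;
    }
  } else {
    for (int m = 0; m < M; ++m) {
      if (v.inside(p[0] + d * dirs[3 * (size_t)m],
                   p[1] + d * dirs[3 * (size_t)m + 1],
                   p[2] + d * dirs[3 * (size_t)m + 2]))
        ++in;
    }
  }
  double frac = (double)in / (double)M;
  if (frac < floor_frac) frac = floor_frac;
  return 1.0 / frac;
}

// Clearance: a lower bound on the distance from point p to the nearest
// point lying outside the mask (non-mask pixel region or grid border),
// truncated at rmax. Any circle/sphere of radius d < clearance is fully
// inside, so its edge weight is exactly 1 and sampling can be skipped.
double clearance_at(const MaskView &v, const double *p, double rmax) {
  double best = rmax;
  // distance to the grid border
  double bx = std::min(p[0], v.nx * v.psx - p[0]);
  double by = std::min(p[1], v.ny * v.psy - p[1]);
  best = std::min(best, std::min(bx, by));
  double pz = 0.0;
  if (v.dim == 3) {
    pz = p[2];
    best = std::min(best, std::min(pz, v.nz * v.psz - pz));
  }
  if (best <= 0) return 0.0;
  int c0 = (int)std::floor((p[0] - rmax) / v.psx), c1 = (int)std::floor((p[0] + rmax) / v.psx);
  int r0 = (int)std::floor((p[1] - rmax) / v.psy), r1 = (int)std::floor((p[1] + rmax) / v.psy);
  int s0 = 0, s1 = 0;
  if (v.dim == 3) {
    s0 = (int)std::floor((pz - rmax) / v.psz);
    s1 = (int)std::floor((pz + rmax) / v.psz);
  }
  c0 = std::max(c0, 0); r0 = std::max(r0, 0); s0 = std::max(s0, 0);
  c1 = std::min(c1, v.nx - 1); r1 = std::min(r1, v.ny - 1);
  s1 = std::min(s1, v.nz - 1);
  for (int s = s0; s <= s1; ++s)
    for (int c = c0; c <= c1; ++c)
      for (int r = r0; r <= r1; ++r) {
        if (v.grid[r + (R_xlen_t)v.ny * c + (R_xlen_t)v.ny * v.nx * s] == 1)
          continue;
        // axis-wise distance from p to the pixel box [c,c+1)x[r,r+1)(x[s,s+1))
        double dx = std::max(0.0, std::max(c * v.psx - p[0], p[0] - (c + 1) * v.psx));
        double dy = std::max(0.0, std::max(r * v.psy - p[1], p[1] - (r + 1) * v.psy));
        double dz = 0.0;
        if (v.dim == 3)
          dz = std::max(0.0, std::max(s * v.psz - pz, pz - (s + 1) * v.psz));
        double dd = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dd < best) best = dd;
        if (best <= 0) return 0.0;
      }
  return best;
}

// Cell list over one point set with cell side h (= rmax); query returns
// candidate indices from the 3^D neighborhood of the query point's cell.
struct CellList {
  double h;
  int dim;
  std::unordered_map<long long, std::vector<int> > cells;

  static inline long long key(long long a, long long b, long long c) {
    // coordinates are bounded (positions / rmax); pack with large strides
    return (a + 1048576LL) + ((b + 1048576LL) << 21) + ((c + 1048576LL) << 42);
  }

  void build(const NumericMatrix &pos, double h_, int dim_) {
    h = h_;
    dim = dim_;
    cells.clear();
    for (int i = 0; i < pos.nrow(); ++i) {
      long long a = (long long)std::floor(pos(i, 0) / h);
      long long b = (long long)std::floor(pos(i, 1) / h);
      long long c = dim == 3 ? (long long)std::floor(pos(i, 2) / h) : 0;
      cells[key(a, b, c)].push_back(i);
    }
  }

  template <typename F>
  void visit_near(const double *q, F f) const {
    long long a = (long long)std::floor(q[0] / h);
    long long b = (long long)std::floor(q[1] / h);
    long long c = dim == 3 ? (long long)std::floor(q[2] / h) : 0;
    long long clo = dim == 3 ? c - 1 : 0, chi = dim == 3 ? c + 1 : 0;
    for (long long cc = clo; cc <= chi; ++cc)
      for (long long bb = b - 1; bb <= b + 1; ++bb)
        for (long long aa = a - 1; aa <= a + 1; ++aa) {
          std::unordered_map<long long, std::vector<int> >::const_iterator it =
              cells.find(key(aa, bb, cc));
          if (it == cells.end()) continue;
          for (size_t u = 0; u < it->second.size(); ++u) f(it->second[u]);
        }
  }
};

inline double dist_between(const NumericMatrix &A, int i,
                           const double *q, int dim) {
  double dx = A(i, 0) - q[0], dy = A(i, 1) - q[1];
  double s = dx * dx + dy * dy;
  if (dim == 3) {
    double dz = A(i, 2) - q[2];
    s += dz * dz;
  }
  return std::sqrt(s);
}

inline int ring_of(double d, const NumericVector &radii) {
  // radii = (0 = r0, r1, ..., rK); half-open bins [r_{k-1}, r_k)
  int K = radii.size() - 1;
  if (d >= radii[K]) return 0;
  for (int k = 1; k <= K; ++k)
    if (d < radii[k]) return k;
  return 0;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
List cpp_cross_pairs(NumericMatrix pos1, NumericMatrix pos2, double rmax) {
  int dim = pos1.ncol();
  CellList cl;
  cl.build(pos2, rmax, dim);
  std::vector<int> ii, jj;
  std::vector<double> dd;
  for (int i = 0; i < pos1.nrow(); ++i) {
    double q[3] = {pos1(i, 0), pos1(i, 1), dim == 3 ? pos1(i, 2) : 0.0};
    cl.visit_near(q, [&](int j) {
      double d = dist_between(pos2, j, q, dim);
      if (d < rmax) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(d);
      }
    });
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj), _["d"] = wrap(dd));
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_edge_weights(NumericMatrix points, NumericVector d,
                               LogicalVector grid, IntegerVector dims,
                               NumericVector pixel_size, int M,
                               double floor_frac) {
  MaskView v = make_view(grid, dims, pixel_size);
  std::vector<double> dirs = direction_table(M, v.dim);
  int n = points.nrow();
  NumericVector w(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {points(i, 0), points(i, 1),
                   v.dim == 3 ? points(i, 2) : 0.0};
    w[i] = sampled_weight(v, p, d[i], dirs, M, floor_frac);
  }
  return w;
}

//' @noRd
// [[Rcpp::export]]
List cpp_khat(NumericMatrix pos1, NumericMatrix pos2, NumericVector radii,
              LogicalVector grid, IntegerVector dims,
              NumericVector pixel_size, int M, double floor_frac,
              double measure) {
  MaskView v = make_view(grid, dims, pixel_size);
  std::vector<double> dirs = direction_table(M, v.dim);
  int dim = pos1.ncol();
  int K = radii.size() - 1;
  double rmax = radii[K];
  int n1 = pos1.nrow(), n2 = pos2.nrow();

  std::vector<double> clear1((size_t)n1);
  for (int i = 0; i < n1; ++i) {
    double p[3] = {pos1(i, 0), pos1(i, 1), dim == 3 ? pos1(i, 2) : 0.0};
    clear1[(size_t)i] = clearance_at(v, p, rmax);
  }

  CellList cl;
  cl.build(pos2, rmax, dim);
  std::vector<int> ii, jj, rr;
  std::vector<double> dd, ww;
  NumericVector khat(K);
  for (int i = 0; i < n1; ++i) {
    double p[3] = {pos1(i, 0), pos1(i, 1), dim == 3 ? pos1(i, 2) : 0.0};
    cl.visit_near(p, [&](int j) {
      double d = dist_between(pos2, j, p, dim);
      if (d >= rmax) return;
      int k = ring_of(d, radii);
      if (k == 0) return;
      double w = d < clear1[(size_t)i]
                     ? 1.0
                     : sampled_weight(v, p, d, dirs, M, floor_frac);
      khat[k - 1] += w;
      ii.push_back(i + 1);
      jj.push_back(j + 1);
      dd.push_back(d);
      ww.push_back(w);
      rr.push_back(k);
    });
  }
  double scale = measure / ((double)n1 * (double)n2);
  for (int k = 0; k < K; ++k) khat[k] *= scale;
  return List::create(_["khat"] = khat, _["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["d"] = wrap(dd), _["w"] = wrap(ww),
                      _["ring"] = wrap(rr));
}

//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_null_khat(NumericMatrix pos1, int n2, NumericVector radii,
                            LogicalVector grid, IntegerVector dims,
                            NumericVector pixel_size, int M,
                            double floor_frac, double measure, int B,
                            IntegerVector occupied) {
  MaskView v = make_view(grid, dims, pixel_size);
  std::vector<double> dirs = direction_table(M, v.dim);
  int dim = v.dim;
  int K = radii.size() - 1;
  double rmax = radii[K];
  int n1 = pos1.nrow();
  R_xlen_t nocc = occupied.size();

  std::vector<double> clear1((size_t)n1);
  for (int i = 0; i < n1; ++i) {
    double p[3] = {pos1(i, 0), pos1(i, 1), dim == 3 ? pos1(i, 2) : 0.0};
    clear1[(size_t)i] = clearance_at(v, p, rmax);
  }

  CellList cl;
  cl.build(pos1, rmax, dim);
  double scale = measure / ((double)n1 * (double)n2);
  NumericMatrix out(B, K);
  RNGScope scope;
  for (int b = 0; b < B; ++b) {
    std::vector<double> acc((size_t)K, 0.0);
    for (int jpt = 0; jpt < n2; ++jpt) {
      // uniform point in the mask: uniform occupied voxel + uniform offset
      R_xlen_t u = (R_xlen_t)(unif_rand() * (double)nocc);
      if (u >= nocc) u = nocc - 1;
      long long lin = occupied[u]; // 0-based linear index into the grid
      long long r = lin % v.ny;
      long long c = (lin / v.ny) % v.nx;
      long long s = lin / ((long long)v.ny * v.nx);
      double q[3];
      q[0] = ((double)c + unif_rand()) * v.psx;
      q[1] = ((double)r + unif_rand()) * v.psy;
      q[2] = dim == 3 ? ((double)s + unif_rand()) * v.psz : 0.0;
      cl.visit_near(q, [&](int i) {
        double d = dist_between(pos1, i, q, dim);
        if (d >= rmax) return;
        int k = ring_of(d, radii);
        if (k == 0) return;
        double p[3] = {pos1(i, 0), pos1(i, 1), dim == 3 ? pos1(i, 2) : 0.0};
        double w = d < clear1[(size_t)i]
                       ? 1.0
                       : sampled_weight(v, p, d, dirs, M, floor_frac);
        acc[(size_t)(k - 1)] += w;
      });
    }
    for (int k = 0; k < K; ++k) out(b, k) = acc[(size_t)k] * scale;
  }
  return out;
}

//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector keep, IntegerVector dims) {
  // full-neighborhood (8-connected in 2D, 26-connected in 3D) labeling
  int ny = dims[0], nx = dims[1], nz = dims.size() == 3 ? dims[2] : 1;
  R_xlen_t n = (R_xlen_t)ny * nx * nz;
  IntegerVector lab(n, 0);
  const int *k = LOGICAL(keep);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (k[start] != 1 || lab[start] != 0) continue;
    ++cur;
    stack.push_back(start);
    lab[start] = cur;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int r = (int)(p % ny);
      int c = (int)((p / ny) % nx);
      int s = (int)(p / ((R_xlen_t)ny * nx));
      for (int ds = (nz > 1 ? -1 : 0); ds <= (nz > 1 ? 1 : 0); ++ds)
        for (int dc = -1; dc <= 1; ++dc)
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0 && ds == 0) continue;
            int rr = r + dr, cc = c + dc, ss = s + ds;
            if (rr < 0 || rr >= ny || cc < 0 || cc >= nx || ss < 0 ||
                ss >= nz)
              continue;
            R_xlen_t q = rr + (R_xlen_t)ny * cc + (R_xlen_t)ny * nx * ss;
            if (k[q] == 1 && lab[q] == 0) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
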