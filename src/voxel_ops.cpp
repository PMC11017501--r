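#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel grids are R arrays dim = c(ny, nx, nz): [row = y, col = x, plane = z],
// column-major.  All distances are physical micrometres; vox = c(vx, vy, vz)
// gives the voxel pitch along x, y, z.  Linear indices here are 0-based.

namespace {

struct Grid {
  int ny, nx, nz;
  double vx, vy, vz;
  long n() const { return (long)ny * nx * nz; }
  void decode(long l, int &i, int &j, int &k) const {
    i = (int)(l % ny);
    j = (int)((l / ny) % nx);
    k = (int)(l / ((long)ny * nx));
  }
  long encode(int i, int j, int k) const {
    return (long)i + (long)j * ny + (long)k * ny * nx;
  }
  bool inside(int i, int j, int k) const {
    return i >= 0 && i < ny && j >= 0 && j < nx && k >= 0 && k < nz;
  }
};

Grid make_grid(const IntegerVector &dims, const NumericVector &vox) {
  Grid g;
  g.ny = dims[0]; g.nx = dims[1]; g.nz = dims[2];
  g.vx = vox[0];  g.vy = vox[1];  g.vz = vox[2];
  return g;
}

// the 26 neighbour offsets with their physical step lengths
struct Nbr { int di, dj, dk; double len; };

std::vector<Nbr> neighbours26(const Grid &g) {
  std::vector<Nbr> nb;
  nb.reserve(26);
  for (int di = -1; di <= 1; ++di)
    for (int dj = -1; dj <= 1; ++dj)
      for (int dk = -1; dk <= 1; ++dk) {
        if (di == 0 && dj == 0 && dk == 0) continue;
        double len = std::sqrt(di * g.vy * di * g.vy +
                               dj * g.vx * dj * g.vx +
                               dk * g.vz * dk * g.vz);
        nb.push_back({di, dj, dk, len});
      }
  return nb;
}

typedef std::pair<double, long> QItem;  // (distance, voxel)

}  // namespace

// Minimum-cost path between two voxels on the 26-connected voxel graph.
// Edge cost into voxel v: step_length_um * (1 + kappa / max(I[v], floor)).
// Returns 0-based linear voxel indices from start to end (inclusive).
// [[Rcpp::export]]
IntegerVector cpp_trace_path(NumericVector img, IntegerVector dims,
                             NumericVector vox, long start, long end,
                             double kappa, double floor_) {
  Grid g = make_grid(dims, vox);
  std::vector<Nbr> nb = neighbours26(g);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(g.n(), INF);
  std::vector<long> prev(g.n(), -1);
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
  dist[start] = 0.0;
  pq.push({0.0, start});
  while (!pq.empty()) {
    QItem top = pq.top(); pq.pop();
    double d = top.first; long u = top.second;
    if (d > dist[u]) continue;
    if (u == end) break;
    int i, j, k; g.decode(u, i, j, k);
    for (const Nbr &e : nb) {
      int i2 = i + e.di, j2 = j + e.dj, k2 = k + e.dk;
      if (!g.inside(i2, j2, k2)) continue;
      long v = g.encode(i2, j2, k2);
      double iv = img[v];
      double cost = e.len * (1.0 + kappa / std::max(iv, floor_));
      double nd = d + cost;
      if (nd < dist[v]) {
        dist[v] = nd;
        prev[v] = u;
        pq.push({nd, v});
      }
    }
  }
  if (!std::isfinite(dist[end])) stop("no path between seeds");
  std::vector<long> path;
  for (long v = end; v != -1; v = prev[v]) path.push_back(v);
  std::reverse(path.begin(), path.end());
  IntegerVector out(path.size());
  for (size_t t = 0; t < path.size(); ++t) out[t] = (int)path[t];
  out.attr("cost") = dist[end];
  return out;
}

// Multi-source geodesic region growing for lumen filling.
// seeds: 0-based voxel indices; bound: per-seed maximum geodesic reach (um).
// A voxel joins the region if its intensity >= thr (or its flag is 2 =
// force-include) and its geodesic distance from the nearest seed is within
// that seed's bound.  flag 1 = force-exclude (blocked).  Growth proceeds
// through accepted voxels only (26-connectivity, physical edge lengths).
// Returns accepted voxel indices with their geodesic distance and the index
// (0-based, into seeds) of the seed that reached them.
// [[Rcpp::export]]
List cpp_fill_region(NumericVector img, IntegerVector dims, NumericVector vox,
                     IntegerVector seeds, NumericVector bound, double thr,
                     IntegerVector flag) {
  Grid g = make_grid(dims, vox);
  std::vector<Nbr> nb = neighbours26(g);
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(g.n(), INF);
  std::vector<int> src(g.n(), -1);
  std::priority_queue<QItem, std::vector<QItem>, std::greater<QItem> > pq;
  bool use_flag = flag.size() == (R_xlen_t)g.n();
  for (int s = 0; s < seeds.size(); ++s) {
    long v = seeds[s];
    if (use_flag && flag[v] == 1) continue;
    if (0.0 < dist[v] || src[v] == -1) {
      dist[v] = 0.0; src[v] = s;
      pq.push({0.0, v});
    }
  }
  while (!pq.empty()) {
    QItem top = pq.top(); pq.pop();
    double d = top.first; long u = top.second;
    if (d > dist[u]) continue;
    int i, j, k; g.decode(u, i, j, k);
    for (const Nbr &e : nb) {
      int i2 = i + e.di, j2 = j + e.dj, k2 = k + e.dk;
      if (!g.inside(i2, j2, k2)) continue;
      long v = g.encode(i2, j2, k2);
      int fl = use_flag ? flag[v] : 0;
      if (fl == 1) continue;
      if (fl != 2 && img[v] < thr) continue;
      double nd = d + e.len;
      int s = src[u];
      if (nd > bound[s]) continue;
      if (nd < dist[v]) {
        dist[v] = nd;
        src[v] = s;
        pq.push({nd, v});
      }
    }
  }
  std::vector<long> idx;
  for (long v = 0; v < g.n(); ++v)
    if (std::isfinite(dist[v])) idx.push_back(v);
  IntegerVector oidx(idx.size()), osrc(idx.size());
  NumericVector odist(idx.size());
  for (size_t t = 0; t < idx.size(); ++t) {
    oidx[t] = (int)idx[t];
    odist[t] = dist[idx[t]];
    osrc[t] = src[idx[t]];
  }
  return List::create(_["idx"] = oidx, _["dist"] = odist, _["src"] = osrc);
}

// Distance field of a polyline tube.  pts: n x 3 matrix of (x, y, z) um;
// radii: per-point tube radius.  For every voxel whose distance to the
// centerline is below (local radius + maxdist) returns the centerline
// distance, the arclength of the nearest centerline point, and the radius
// interpolated there; voxels beyond get +Inf / NA.  Only voxels inside the
// per-segment bounding box (padded by radius + maxdist) are visited.
// [[Rcpp::export]]
List cpp_tube_geometry(IntegerVector dims, NumericVector vox,
                       NumericMatrix pts, NumericVector radii,
                       double maxdist) {
  Grid g = make_grid(dims, vox);
  const double INF = std::numeric_limits<double>::infinity();
  long n = g.n();
  NumericVector dcen(n, INF), arc(n, NA_REAL), rad(n, NA_REAL);
  int np = pts.nrow();
  std::vector<double> cum(np, 0.0);
  for (int s = 1; s < np; ++s) {
    double dx = pts(s,0) - pts(s-1,0), dy = pts(s,1) - pts(s-1,1),
           dz = pts(s,2) - pts(s-1,2);
    cum[s] = cum[s-1] + std::sqrt(dx*dx + dy*dy + dz*dz);
  }
  for (int s = 0; s + 1 < np; ++s) {
    double ax = pts(s,0), ay = pts(s,1), az = pts(s,2);
    double bx = pts(s+1,0), by = pts(s+1,1), bz = pts(s+1,2);
    double ra = radii[s], rb = radii[s+1];
    double pad = std::max(ra, rb) + maxdist;
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double L2 = ux*ux + uy*uy + uz*uz;
    // voxel index ranges covered by the padded segment bbox
    int j0 = (int)std::floor((std::min(ax,bx) - pad) / g.vx - 0.5);
    int j1 = (int)std::ceil ((std::max(ax,bx) + pad) / g.vx - 0.5);
    int i0 = (int)std::floor((std::min(ay,by) - pad) / g.vy - 0.5);
    int i1 = (int)std::ceil ((std::max(ay,by) + pad) / g.vy - 0.5);
    int k0 = (int)std::floor((std::min(az,bz) - pad) / g.vz - 0.5);
    int k1 = (int)std::ceil ((std::max(az,bz) + pad) / g.vz - 0.5);
    i0 = std::max(i0, 0); j0 = std::max(j0, 0); k0 = std::max(k0, 0);
    i1 = std::min(i1, g.ny - 1); j1 = std::min(j1, g.nx - 1);
    k1 = std::min(k1, g.nz - 1);
    for (int k = k0; k <= k1; ++k) {
      double pz = (k + 0.5) * g.vz;
      for (int j = j0; j <= j1; ++j) {
        double px = (j + 0.5) * g.vx;
        for (int i = i0; i <= i1; ++i) {
          double py = (i + 0.5) * g.vy;
          double t = 0.0;
          if (L2 > 0.0) {
            t = ((px-ax)*ux + (py-ay)*uy + (pz-az)*uz) / L2;
            t = std::min(1.0, std::max(0.0, t));
          }
          double cx = ax + t*ux, cy = ay + t*uy, cz = az + t*uz;
          double dx = px-cx, dy = py-cy, dz = pz-cz;
          double d = std::sqrt(dx*dx + dy*dy + dz*dz);
          double r = ra + t * (rb - ra);
          if (d > r + maxdist) continue;
          long l = g.encode(i, j, k);
          if (d < dcen[l]) {
            dcen[l] = d;
            arc[l] = cum[s] + t * (cum[s+1] - cum[s]);
            rad[l] = r;
          }
        }
      }
    }
  }
  return List::create(_["dcen"] = dcen, _["arc"] = arc, _["rad"] = rad);
}

// 26-connected component labelling of a logical mask.  Labels start at 1;
// background is 0.  Returns an integer vector of length prod(dims).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  Grid g; g.ny = dims[0]; g.nx = dims[1]; g.nz = dims[2];
  g.vx = g.vy = g.vz = 1.0;
  long n = g.n();
  IntegerVector lab(n, 0);
  int cur = 0;
  std::vector<long> stack;
  for (long v0 = 0; v0 < n; ++v0) {
    if (!mask[v0] || lab[v0] != 0) continue;
    ++cur;
    stack.push_back(v0);
    lab[v0] = cur;
    while (!stack.empty()) {
      long u = stack.back(); stack.pop_back();
      int i, j, k; g.decode(u, i, j, k);
      for (int di = -1; di <= 1; ++di)
        for (int dj = -1; dj <= 1; ++dj)
          for (int dk = -1; dk <= 1; ++dk) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int i2 = i + di, j2 = j + dj, k2 = k + dk;
            if (!g.inside(i2, j2, k2)) continue;
            long v = g.encode(i2, j2, k2);
            if (mask[v] && lab[v] == 0) {
              lab[v] = cur;
              stack.push_back(v);
            }
          }
    }
  }
  return lab;
}
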