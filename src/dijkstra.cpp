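#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Volumes are stored as R arrays with dim = (nz, ny, nx), column-major,
// so linear index (0-based) = z + nz * (y + ny * x).

namespace {

struct QNode {
  double d;
  int64_t idx;
  bool operator>(const QNode& o) const {
    if (d != o.d) return d > o.d;
    return idx > o.idx;  // deterministic tie-break: lowest linear index first
  }
};

// neighbour offsets for 6- or 26-connectivity, with step lengths
void build_offsets(int conn, std::vector<int>& dz, std::vector<int>& dy,
                   std::vector<int>& dx, std::vector<double>& step) {
  for (int ax = -1; ax <= 1; ++ax)
    for (int ay = -1; ay <= 1; ++ay)
      for (int az = -1; az <= 1; ++az) {
        if (ax == 0 && ay == 0 && az == 0) continue;
        int manh = std::abs(ax) + std::abs(ay) + std::abs(az);
        if (conn == 6 && manh > 1) continue;
        dz.push_back(az); dy.push_back(ay); dx.push_back(ax);
        step.push_back(std::sqrt((double)manh));
      }
}

}  // namespace

// Dijkstra over the voxel grid. Node costs in `nodecost`; edge cost between
// u and v is 0.5 * (c(u) + c(v)) * Euclidean step length. `allowed` may be
// length 0 (all voxels allowed) or a logical mask. If dst >= 0 the search
// stops as soon as dst is settled. Returns dist (+Inf = unreached) and
// parent (0-based linear index, -1 = none).
// [[Rcpp::export]]
List cpp_grid_dijkstra(IntegerVector dims, NumericVector nodecost,
                       double src, double dst, LogicalVector allowed,
                       int conn) {
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int64_t n = (int64_t)nz * ny * nx;
  const int64_t isrc = (int64_t)src, idst = (int64_t)dst;
  if (isrc < 0 || isrc >= n) stop("source voxel out of bounds");
  const bool use_mask = allowed.size() > 0;
  if (use_mask && (int64_t)allowed.size() != n) stop("mask size mismatch");

  std::vector<int> dz, dy, dx; std::vector<double> step;
  build_offsets(conn, dz, dy, dx, step);
  const int noff = (int)dz.size();

  std::vector<double> dist(n, R_PosInf);
  std::vector<double> plen(n, R_PosInf);  // Euclidean length of the SPT path
  std::vector<double> parent(n, -1.0);
  std::vector<uint8_t> done(n, 0);

  std::priority_queue<QNode, std::vector<QNode>, std::greater<QNode> > pq;
  dist[isrc] = 0.0;
  plen[isrc] = 0.0;
  pq.push({0.0, isrc});

  while (!pq.empty()) {
    QNode top = pq.top(); pq.pop();
    const int64_t u = top.idx;
    if (done[u]) continue;
    done[u] = 1;
    if (u == idst) break;
    const int uz = (int)(u % nz);
    const int uy = (int)((u / nz) % ny);
    const int ux = (int)(u / ((int64_t)nz * ny));
    const double cu = nodecost[u];
    for (int k = 0; k < noff; ++k) {
      const int vz = uz + dz[k], vy = uy + dy[k], vx = ux + dx[k];
      if (vz < 0 || vz >= nz || vy < 0 || vy >= ny || vx < 0 || vx >= nx)
        continue;
      const int64_t v = vz + (int64_t)nz * (vy + (int64_t)ny * vx);
      if (done[v]) continue;
      if (use_mask && !allowed[v]) continue;
      const double nd = dist[u] + 0.5 * (cu + nodecost[v]) * step[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        plen[v] = plen[u] + step[k];
        parent[v] = (double)u;
        pq.push({nd, v});
      }
    }
  }

  return List::create(_["dist"] = NumericVector(dist.begin(), dist.end()),
                      _["pathlen"] = NumericVector(plen.begin(), plen.end()),
                      _["parent"] = NumericVector(parent.begin(), parent.end()));
}
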