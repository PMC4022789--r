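#include <Rcpp.h>
#include <queue>
#include <vector>
#include <tuple>
using namespace Rcpp;

// Connected-component labeling of a 2D logical matrix, 8-connectivity.
// Labels are assigned in raster order (column-major, as stored by R), so the
// component containing the lexicographically smallest (row, col) foreground
// pixel always gets label 1 — deterministic tie-breaking relies on this.
// [[Rcpp::export(name = ".label2d8")]]
IntegerMatrix label2d8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int,int> > stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(r, c));
      lab(r, c) = next;
      while (!stack.empty()) {
        std::pair<int,int> p = stack.back();
        stack.pop_back();
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int rr = p.first + dr, cc = p.second + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(std::make_pair(rr, cc));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Connected-component labeling of a 3D logical array, 6-connectivity.
// [[Rcpp::export(name = ".label3d6")]]
IntegerVector label3d6(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  const int dx[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dz[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t idx = 0; idx < n; ++idx) {
    if (!mask[idx] || lab[idx] != 0) continue;
    ++next;
    stack.clear();
    stack.push_back(idx);
    lab[idx] = next;
    while (!stack.empty()) {
      R_xlen_t p = stack.back();
      stack.pop_back();
      int x = p % nx, y = (p / nx) % ny, z = p / ((R_xlen_t)nx * ny);
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        R_xlen_t q = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (mask[q] && lab[q] == 0) {
          lab[q] = next;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = dims;
  lab.attr("ncomp") = next;
  return lab;
}

struct QNode {
  double cost;
  long counter;
  int idx;
};
struct QNodeCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.cost != b.cost) return a.cost > b.cost;
    return a.counter > b.counter;  // earlier insertion wins on ties
  }
};

// Uniform cost search (Dijkstra with a goal set) on the 8-connected pixel
// graph restricted to `region`. The cost of traversing an edge is the cost
// value of the destination pixel (start pixels contribute nothing), exactly
// the edge-cost convention of the tracing stage; optionally diagonal steps
// are scaled by sqrt(2). Ties are broken by insertion counter, and
// neighbours are expanded in a fixed order, so the result is deterministic.
// Inputs are 0-based pixel indices into the cost matrix.
// [[Rcpp::export(name = ".ucs_path")]]
List ucs_path(NumericMatrix cost, LogicalMatrix region,
              IntegerVector start, IntegerVector goal,
              bool diag_scale = false) {
  int nr = cost.nrow(), nc = cost.ncol();
  R_xlen_t n = (R_xlen_t)nr * nc;
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> parent(n, -1);
  std::vector<char> done(n, 0), isgoal(n, 0);
  for (int i = 0; i < goal.size(); ++i) isgoal[goal[i]] = 1;
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  long counter = 0;
  for (int i = 0; i < start.size(); ++i) {
    int s = start[i];
    if (!region[s]) continue;
    if (dist[s] > 0.0) {
      dist[s] = 0.0;
      QNode nd; nd.cost = 0.0; nd.counter = counter++; nd.idx = s;
      pq.push(nd);
    }
  }
  const int dr[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double sq2 = std::sqrt(2.0);
  int found = -1;
  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    int u = nd.idx;
    if (done[u]) continue;
    done[u] = 1;
    if (isgoal[u]) { found = u; break; }
    int r = u % nr, c = u / nr;
    for (int k = 0; k < 8; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int v = rr + nr * cc;
      if (!region[v] || done[v]) continue;
      double w = cost[v];
      if (diag_scale && k >= 4) w *= sq2;
      double alt = dist[u] + w;
      if (alt < dist[v]) {
        dist[v] = alt;
        parent[v] = u;
        QNode nn; nn.cost = alt; nn.counter = counter++; nn.idx = v;
        pq.push(nn);
      }
    }
  }
  if (found < 0)
    return List::create(_["found"] = false);
  std::vector<int> path;
  for (int u = found; u >= 0; u = parent[u]) path.push_back(u);
  std::reverse(path.begin(), path.end());
  return List::create(_["found"] = true,
                      _["path"] = IntegerVector(path.begin(), path.end()),
                      _["cost"] = dist[found]);
}
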