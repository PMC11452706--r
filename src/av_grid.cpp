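#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

static int gcd3(int a, int b, int c) {
  a = std::abs(a); b = std::abs(b); c = std::abs(c);
  int g = a;
  while (b) { int t = g % b; g = b; b = t; }
  while (c) { int t = g % c; g = c; c = t; }
  return g;
}

// Geodesic accessible-volume search on a cubic grid.
//
// A grid point is reachable if a path from the attachment point of total
// length <= L exists whose every vertex clears all atom surfaces by
// `halfwidth` (the linker half-width). A reachable point belongs to the AV
// of a dye radius r if it additionally clears all atom surfaces by r.
// Dijkstra runs over a 7x7x7 neighbourhood (collinear duplicates removed),
// which keeps the chamfer metric error around one percent.
//
// xyz/vdw: obstacle atoms (attachment residue already excluded by caller);
// attach: attachment coordinates; dye_radii: one AV per entry.
// Returns, per dye radius, the allowed grid coordinates (absolute, in the
// same units as the inputs) plus the grid geodesic distances.
// [[Rcpp::export]]
List av_grid_kernel(NumericMatrix xyz, NumericVector vdw, NumericVector attach,
                    double L, double halfwidth, NumericVector dye_radii,
                    double spacing) {
  const int half = (int)std::floor(L / spacing) + 1;
  const int n = 2 * half + 1;
  const size_t ncell = (size_t)n * n * n;
  const double BIG = 1e30;

  double maxclear = halfwidth;
  for (int i = 0; i < dye_radii.size(); ++i)
    maxclear = std::max(maxclear, dye_radii[i]);

  // minimum distance from each cell to any atom surface, capped: cells
  // farther than (vdw + maxclear + spacing) from every atom stay at BIG
  std::vector<double> surf(ncell, BIG);
  const int na = xyz.nrow();
  for (int a = 0; a < na; ++a) {
    const double ax = xyz(a, 0) - attach[0];
    const double ay = xyz(a, 1) - attach[1];
    const double az = xyz(a, 2) - attach[2];
    const double reach = vdw[a] + maxclear + 2.0 * spacing;
    int i0 = std::max(0, (int)std::floor((ax - reach) / spacing) + half);
    int i1 = std::min(n - 1, (int)std::ceil((ax + reach) / spacing) + half);
    int j0 = std::max(0, (int)std::floor((ay - reach) / spacing) + half);
    int j1 = std::min(n - 1, (int)std::ceil((ay + reach) / spacing) + half);
    int k0 = std::max(0, (int)std::floor((az - reach) / spacing) + half);
    int k1 = std::min(n - 1, (int)std::ceil((az + reach) / spacing) + half);
    for (int i = i0; i <= i1; ++i) {
      double dx = (i - half) * spacing - ax;
      for (int j = j0; j <= j1; ++j) {
        double dy = (j - half) * spacing - ay;
        for (int k = k0; k <= k1; ++k) {
          double dz = (k - half) * spacing - az;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz) - vdw[a];
          size_t idx = ((size_t)i * n + j) * n + k;
          if (d < surf[idx]) surf[idx] = d;
        }
      }
    }
  }

  // neighbour offsets within Chebyshev distance 3, collinear duplicates out
  std::vector<int> di, dj, dk;
  std::vector<double> dlen;
  for (int a = -3; a <= 3; ++a)
    for (int b = -3; b <= 3; ++b)
      for (int c = -3; c <= 3; ++c) {
        if (!a && !b && !c) continue;
        if (gcd3(a, b, c) != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
        dlen.push_back(spacing * std::sqrt((double)(a * a + b * b + c * c)));
      }
  const int noff = (int)di.size();
  // intermediate sample points along each offset (nearest-cell rounded), so
  // that multi-cell steps cannot hop across thin obstacles
  std::vector< std::vector<int> > mids(noff);
  for (int o = 0; o < noff; ++o) {
    int m = std::max(std::abs(di[o]), std::max(std::abs(dj[o]), std::abs(dk[o])));
    for (int s = 1; s < m; ++s) {
      double t = (double)s / m;
      int mi = (int)std::lround(t * di[o]);
      int mj = (int)std::lround(t * dj[o]);
      int mk = (int)std::lround(t * dk[o]);
      if (!mi && !mj && !mk) continue;
      mids[o].push_back(mi); mids[o].push_back(mj); mids[o].push_back(mk);
    }
  }

  std::vector<double> dist(ncell, BIG);
  typedef std::pair<double, size_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  const size_t start = ((size_t)half * n + half) * n + half;
  dist[start] = 0.0;            // seed is always allowed
  pq.push(QE(0.0, start));
  const double eps = 1e-9;
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d0 = top.first;
    size_t u = top.second;
    if (d0 > dist[u] + eps) continue;
    int ui = (int)(u / ((size_t)n * n));
    int uj = (int)((u / n) % n);
    int uk = (int)(u % n);
    for (int o = 0; o < noff; ++o) {
      int vi = ui + di[o], vj = uj + dj[o], vk = uk + dk[o];
      if (vi < 0 || vi >= n || vj < 0 || vj >= n || vk < 0 || vk >= n) continue;
      size_t v = ((size_t)vi * n + vj) * n + vk;
      if (surf[v] < halfwidth) continue;      // path clearance at endpoint
      double nd = d0 + dlen[o];
      if (nd > L + eps) continue;             // linker length budget
      bool blocked = false;                   // clearance along the segment
      const std::vector<int> &mv = mids[o];
      for (size_t s = 0; s < mv.size(); s += 3) {
        int mi = ui + mv[s], mj = uj + mv[s + 1], mk = uk + mv[s + 2];
        size_t w = ((size_t)mi * n + mj) * n + mk;
        if (surf[w] < halfwidth) { blocked = true; break; }
      }
      if (blocked) continue;
      if (nd < dist[v] - eps) {
        dist[v] = nd;
        pq.push(QE(nd, v));
      }
    }
  }

  // per dye radius: linear cell indices of the allowed grid points
  List avs(dye_radii.size());
  for (int r = 0; r < dye_radii.size(); ++r) {
    double rr = dye_radii[r];
    std::vector<double> cells;   // double to avoid 32-bit overflow worries
    for (size_t u = 0; u < ncell; ++u)
      if (dist[u] <= L + eps && surf[u] >= rr)
        cells.push_back((double)u);
    avs[r] = NumericVector(cells.begin(), cells.end());
  }
  return List::create(_["n"] = n, _["half"] = half, _["spacing"] = spacing,
                      _["avs"] = avs);
}
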