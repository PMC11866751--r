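// Leath growth of site-percolation clusters on the simple cubic lattice.
//
// Site codes follow the bitmap convention used throughout the package:
//   0 = diluted (unavailable), 1 = available & unoccupied, 2 = available &
//   occupied by a chain monomer (code 2 only ever appears during chain growth).
// A separate visited flag records that a site's dilution status has been
// decided; a decision is made exactly once, so the disorder is quenched.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <deque>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// splitmix64: used to derive independent substream seeds from one master seed
static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

uint64_t cm_substream(uint64_t master, uint64_t idx) {
  return splitmix64(splitmix64(master) ^ (0x9E3779B97F4A7C15ULL * (idx + 1)));
}

// fixed neighbour order: +x, -x, +y, -y, +z, -z (no special directions)
static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

// [[Rcpp::export]]
List leath_grow_cpp(int L, double p, double seed, bool breadth_first) {
  const R_xlen_t n_sites = (R_xlen_t)L * L * L;
  IntegerVector state(n_sites, 0);
  LogicalVector visited(n_sites, false);

  std::mt19937_64 rng(cm_substream((uint64_t)seed, 0));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  const int c = (L - 1) / 2;
  const R_xlen_t seed_site = (R_xlen_t)c + (R_xlen_t)L * (c + (R_xlen_t)L * c);
  state[seed_site] = 1;   // centre occupied by construction
  visited[seed_site] = true;

  // explicit container instead of recursion so L = 599 cannot overflow a stack;
  // LIFO = depth-first, FIFO = breadth-first
  std::deque<R_xlen_t> frontier;
  frontier.push_back(seed_site);

  R_xlen_t cluster_size = 1;
  while (!frontier.empty()) {
    R_xlen_t site;
    if (breadth_first) {
      site = frontier.front();
      frontier.pop_front();
    } else {
      site = frontier.back();
      frontier.pop_back();
    }
    const int x = (int)(site % L);
    const int y = (int)((site / L) % L);
    const int z = (int)(site / ((R_xlen_t)L * L));
    for (int d = 0; d < 6; ++d) {
      const int nx = x + DX[d], ny = y + DY[d], nz = z + DZ[d];
      if (nx < 0 || nx >= L || ny < 0 || ny >= L || nz < 0 || nz >= L)
        continue;  // growth halts at the box faces
      const R_xlen_t ns = (R_xlen_t)nx + (R_xlen_t)L * (ny + (R_xlen_t)L * nz);
      if (visited[ns]) continue;
      visited[ns] = true;  // decided exactly once (quenched)
      if (unif(rng) < p) {
        state[ns] = 1;
        ++cluster_size;
        frontier.push_back(ns);
      }  // else stays 0: diluted
    }
  }

  return List::create(_["state"] = state, _["visited"] = visited,
                      _["cluster_size"] = (double)cluster_size);
}

// [[Rcpp::export]]
bool is_spanning_cpp(IntegerVector state, int L) {
  // cluster sites are exactly the state >= 1 sites (Leath marks nothing else);
  // spanning = at least one cluster site on each of the six faces
  bool face[6] = {false, false, false, false, false, false};
  for (int z = 0; z < L; ++z)
    for (int y = 0; y < L; ++y)
      for (int x = 0; x < L; ++x) {
        const R_xlen_t s = (R_xlen_t)x + (R_xlen_t)L * (y + (R_xlen_t)L * z);
        if (state[s] < 1) continue;
        if (x == 0) face[0] = true;
        if (x == L - 1) face[1] = true;
        if (y == 0) face[2] = true;
        if (y == L - 1) face[3] = true;
        if (z == 0) face[4] = true;
        if (z == L - 1) face[5] = true;
      }
  for (int f = 0; f < 6; ++f)
    if (!face[f]) return false;
  return true;
}

// Cumulative mass within concentric unit-width shells about the cluster's
// centre of mass: masses[r-1] = number of cluster sites with distance <= r.
// [[Rcpp::export]]
List mass_radius_cpp(IntegerVector state, int L, int r_max) {
  double cx = 0, cy = 0, cz = 0;
  R_xlen_t m = 0;
  for (int z = 0; z < L; ++z)
    for (int y = 0; y < L; ++y)
      for (int x = 0; x < L; ++x) {
        const R_xlen_t s = (R_xlen_t)x + (R_xlen_t)L * (y + (R_xlen_t)L * z);
        if (state[s] >= 1) { cx += x; cy += y; cz += z; ++m; }
      }
  if (m == 0) stop("empty cluster");
  cx /= m; cy /= m; cz /= m;

  std::vector<double> shell(r_max, 0.0);
  for (int z = 0; z < L; ++z)
    for (int y = 0; y < L; ++y)
      for (int x = 0; x < L; ++x) {
        const R_xlen_t s = (R_xlen_t)x + (R_xlen_t)L * (y + (R_xlen_t)L * z);
        if (state[s] < 1) continue;
        const double d = std::sqrt((x - cx) * (x - cx) + (y - cy) * (y - cy) +
                                   (z - cz) * (z - cz));
        int bin = (int)std::ceil(d);  // shell (r-1, r]
        if (bin < 1) bin = 1;
        if (bin <= r_max) shell[bin - 1] += 1.0;
      }
  NumericVector radii(r_max), masses(r_max);
  double cum = 0;
  for (int r = 1; r <= r_max; ++r) {
    cum += shell[r - 1];
    radii[r - 1] = r;
    masses[r - 1] = cum;
  }
  return List::create(_["radius"] = radii, _["mass"] = masses,
                      _["center"] = NumericVector::create(cx, cy, cz),
                      _["cluster_size"] = (double)m);
}
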