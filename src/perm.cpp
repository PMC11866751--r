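// Two-strand PERM (pruned-enriched Rosenbluth method) for the lattice
// Poland-Scheraga DNA on a (possibly site-diluted) cubic lattice.
//
// Both strands grow simultaneously from the pinned origin (the lattice
// centre).  At each step the candidate set is the Cartesian product of the
// free nearest neighbours of the two growing ends; an element with equal
// sites is a base-pair contact carrying Boltzmann weight exp(beta), all
// others weight 1.  The running Rosenbluth weight W_n is the product of the
// one-step local partition sums (importance-corrected when the pyramidal
// look-ahead bias is on), and Z_n = <W_n> over started tours.
//
// Population control follows the ratio r = W_n / Z_n:
//   r < 0.9  -> kill with probability 1 - r, else continue with W_n = Z_n
//              (exactly unbiased: E[weight after] = r * Z_n = W_n)
//   r > 1.1  -> k = min(floor(r), |S_n|) copies, each with weight W_n / k
// Weights are tracked in log space; accumulators carry per-length offsets so
// N = 500 at low temperature neither overflows nor underflows.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

uint64_t cm_substream(uint64_t master, uint64_t idx);  // lattice.cpp

static const int DX[6] = {1, -1, 0, 0, 0, 0};
static const int DY[6] = {0, 0, 1, -1, 0, 0};
static const int DZ[6] = {0, 0, 0, 0, 1, -1};

namespace {

struct PermEngine {
  int L, N, h;
  double beta, boltz;
  bool popctl;
  std::vector<int8_t> state;       // lattice codes 0/1/2, mutated + restored
  std::mt19937_64 rng;
  std::uniform_real_distribution<double> unif{0.0, 1.0};

  // strand configuration (monomer 0..n)
  std::vector<R_xlen_t> posA, posB;
  std::vector<char> bound;
  int n_cur = 0, nc_cur = 0;

  // per-length accumulators with log-space offsets
  long long tours_started = 0;
  std::vector<double> off, sW, sWnc, sWnc2;
  std::vector<long long> nsamp;

  // target-length (n = N) accumulators, sharing one offset
  double offN = 0.0;
  bool offN_set = false;
  std::vector<double> constrained;  // indexed by n_c = 0..N+1
  std::vector<double> bubbleW;      // indexed by bubble size 0..N
  double sWnb = 0.0;

  // per-tour weight at N (for the Grassberger P(ln W) diagnostic)
  double tour_off = 0.0, tour_s = 0.0;
  std::vector<double> tour_lnW;
  bool keep_tour_lnW;
  long long tours_reached = 0, branches_reached = 0;
  bool tour_hit = false;

  PermEngine(IntegerVector st, int L_, int N_, double beta_, int h_,
             bool popctl_, bool keep_lnw)
      : L(L_), N(N_), h(h_), beta(beta_), boltz(std::exp(beta_)),
        popctl(popctl_), state(st.begin(), st.end()),
        posA(N_ + 1), posB(N_ + 1), bound(N_ + 1),
        off(N_ + 1, 0.0), sW(N_ + 1, 0.0), sWnc(N_ + 1, 0.0),
        sWnc2(N_ + 1, 0.0), nsamp(N_ + 1, 0),
        constrained(N_ + 2, 0.0), bubbleW(N_ + 1, 0.0),
        keep_tour_lnW(keep_lnw) {}

  inline R_xlen_t idx(int x, int y, int z) const {
    return (R_xlen_t)x + (R_xlen_t)L * (y + (R_xlen_t)L * z);
  }

  // free (code 1) nearest neighbours of a site; returns count, fills sites/dirs
  inline int free_neighbours(R_xlen_t site, R_xlen_t *sites, int *dirs) const {
    const int x = (int)(site % L);
    const int y = (int)((site / L) % L);
    const int z = (int)(site / ((R_xlen_t)L * L));
    int m = 0;
    for (int d = 0; d < 6; ++d) {
      const int nx = x + DX[d], ny = y + DY[d], nz = z + DZ[d];
      if (nx < 0 || nx >= L || ny < 0 || ny >= L || nz < 0 || nz >= L) continue;
      const R_xlen_t s = idx(nx, ny, nz);
      if (state[s] == 1) { sites[m] = s; dirs[m] = d; ++m; }
    }
    return m;
  }

  // pyramidal look-ahead: layers k = 1..h are (2k+1)^2 squares at depth k,
  // clipped at the box; f = n_as / (1 + n_os), floored at 1e-6 when n_as = 0
  double bias_factor(R_xlen_t apex, int dir) const {
    const int ax = (int)(apex % L);
    const int ay = (int)((apex / L) % L);
    const int az = (int)(apex / ((R_xlen_t)L * L));
    long n_as = 0, n_os = 0;
    for (int k = 1; k <= h; ++k) {
      const int bx = ax + k * DX[dir], by = ay + k * DY[dir],
                bz = az + k * DZ[dir];
      for (int i = -k; i <= k; ++i)
        for (int j = -k; j <= k; ++j) {
          int x = bx, y = by, z = bz;
          if (DX[dir] != 0) { y += i; z += j; }
          else if (DY[dir] != 0) { x += i; z += j; }
          else { x += i; y += j; }
          if (x < 0 || x >= L || y < 0 || y >= L || z < 0 || z >= L) continue;
          const int s = state[idx(x, y, z)];
          if (s >= 1) { ++n_as; if (s == 2) ++n_os; }
        }
    }
    if (n_as == 0) return 1e-6;
    return (double)n_as / (1.0 + (double)n_os);
  }

  void accumulate(int n, double logW) {
    ++nsamp[n];
    if (sW[n] == 0.0) {
      off[n] = logW;
    } else if (logW > off[n]) {
      const double sc = std::exp(off[n] - logW);
      sW[n] *= sc; sWnc[n] *= sc; sWnc2[n] *= sc;
      off[n] = logW;
    }
    const double e = std::exp(logW - off[n]);
    sW[n] += e;
    sWnc[n] += e * nc_cur;
    sWnc2[n] += e * (double)nc_cur * nc_cur;

    if (n == N) {
      ++branches_reached;
      tour_hit = true;
      // shared-offset block: constrained P(n_c), bubble histogram, <n_b>
      if (!offN_set) { offN = logW; offN_set = true; }
      else if (logW > offN) {
        const double sc = std::exp(offN - logW);
        for (double &v : constrained) v *= sc;
        for (double &v : bubbleW) v *= sc;
        sWnb *= sc;
        offN = logW;
      }
      const double eN = std::exp(logW - offN);
      constrained[nc_cur] += eN;
      int n_b = 0, last_bound = 0;
      for (int i = 1; i <= N; ++i) {
        if (bound[i]) {
          if (i - last_bound >= 2) { bubbleW[i - last_bound] += eN; ++n_b; }
          last_bound = i;
        }
      }  // trailing open run is the Y-fork, never a bubble
      sWnb += eN * n_b;
      // per-tour weight
      if (tour_s == 0.0) { tour_off = logW; tour_s = 1.0; }
      else if (logW > tour_off) {
        tour_s = tour_s * std::exp(tour_off - logW) + 1.0;
        tour_off = logW;
      } else tour_s += std::exp(logW - tour_off);
    }
  }

  inline double logZ_at(int n) const {
    if (sW[n] <= 0.0) return R_NegInf;
    return off[n] + std::log(sW[n]) - std::log((double)tours_started);
  }

  // grow the branch: config at length n with log-weight logW, already
  // population-controlled; accumulates, then extends recursively
  void grow(int n, double logW) {
    accumulate(n, logW);
    if (n == N) return;

    R_xlen_t sA[6], sB[6];
    int dA[6], dB[6];
    const int mA = free_neighbours(posA[n], sA, dA);
    if (mA == 0) return;
    const int mB = free_neighbours(posB[n], sB, dB);
    if (mB == 0) return;

    double fA[6], fB[6];
    if (h > 0) {
      for (int i = 0; i < mA; ++i) fA[i] = bias_factor(posA[n], dA[i]);
      for (int i = 0; i < mB; ++i) fB[i] = bias_factor(posB[n], dB[i]);
    }

    // Cartesian-product step set: weight = Boltzmann x bias
    double w[36], corr[36];
    int nel = 0;
    double wsum = 0.0;
    bool contact[36];
    int elA[36], elB[36];
    for (int i = 0; i < mA; ++i)
      for (int j = 0; j < mB; ++j) {
        const bool ctc = (sA[i] == sB[j]);
        double wt = ctc ? boltz : 1.0;
        double f = 1.0;
        if (h > 0) { f = fA[i] * fB[j]; wt *= f; }
        w[nel] = wt; corr[nel] = f; contact[nel] = ctc;
        elA[nel] = i; elB[nel] = j;
        wsum += wt;
        ++nel;
      }
    if (wsum <= 0.0) return;

    // roulette selection proportional to weight
    double u = unif(rng) * wsum;
    int ch = 0;
    for (; ch < nel - 1; ++ch) { u -= w[ch]; if (u <= 0.0) break; }

    // importance-corrected Rosenbluth increment: W <- W * w_n / f_chosen
    double logWnext = logW + std::log(wsum) - std::log(corr[ch]);

    // population control at length n + 1
    int k = 1;
    const int np1 = n + 1;
    if (popctl && tours_started >= 10 && sW[np1] > 0.0) {
      const double d = logWnext - logZ_at(np1);
      const double r = (d > 100.0) ? std::exp(100.0) : std::exp(d);
      if (r < 0.9) {
        if (unif(rng) < 1.0 - r) return;       // pruned
        logWnext = logZ_at(np1);               // survivor: W_n = Z_n
      } else if (r > 1.1) {
        k = (int)r;
        if (k > nel) k = nel;
        if (k < 1) k = 1;
      }
    }

    // apply the chosen step
    const R_xlen_t a = sA[elA[ch]], b = sB[elB[ch]];
    posA[np1] = a; posB[np1] = b;
    bound[np1] = contact[ch] ? 1 : 0;
    state[a] = 2;
    if (!contact[ch]) state[b] = 2;
    if (contact[ch]) ++nc_cur;

    const double logChild = logWnext - std::log((double)k);
    for (int copy = 0; copy < k; ++copy) grow(np1, logChild);

    // undo (backtrack within the tour tree)
    if (contact[ch]) --nc_cur;
    state[a] = 1;
    if (!contact[ch]) state[b] = 1;
  }

  void run(int tours, uint64_t master_seed) {
    const int c = (L - 1) / 2;
    const R_xlen_t origin = idx(c, c, c);
    if (state[origin] == 0)
      stop("lattice seed site is diluted; cannot pin the DNA origin");
    state[origin] = 2;  // both index-0 monomers live here
    posA[0] = posB[0] = origin;
    bound[0] = 1;
    nc_cur = 1;

    for (int t = 0; t < tours; ++t) {
      rng.seed(cm_substream(master_seed, (uint64_t)t + 1));
      ++tours_started;
      tour_hit = false;
      tour_s = 0.0;
      grow(0, 0.0);  // W_0 = 1
      if (tour_hit) ++tours_reached;
      if (tour_s > 0.0 && keep_tour_lnW)
        tour_lnW.push_back(tour_off + std::log(tour_s));
      if ((t & 0x3FF) == 0) Rcpp::checkUserInterrupt();
    }
    state[origin] = 1;  // restore
  }
};

}  // namespace

// [[Rcpp::export]]
List perm_run_cpp(IntegerVector state, int L, int N, double beta, int tours,
                  double seed, int bias_depth, bool population_control,
                  bool keep_tour_weights) {
  PermEngine eng(state, L, N, beta, bias_depth, population_control,
                 keep_tour_weights);
  eng.run(tours, (uint64_t)seed);

  const int M = N + 1;
  NumericVector logZ(M), mean_nc(M), mean_nc2(M);
  NumericVector sumW_log(M);
  IntegerVector nsamp(M);
  for (int n = 0; n < M; ++n) {
    nsamp[n] = (int)std::min<long long>(eng.nsamp[n], INT_MAX);
    if (eng.sW[n] > 0.0) {
      logZ[n] = eng.off[n] + std::log(eng.sW[n]) -
                std::log((double)eng.tours_started);
      sumW_log[n] = eng.off[n] + std::log(eng.sW[n]);
      mean_nc[n] = eng.sWnc[n] / eng.sW[n];
      mean_nc2[n] = eng.sWnc2[n] / eng.sW[n];
    } else {
      logZ[n] = R_NegInf; sumW_log[n] = R_NegInf;
      mean_nc[n] = NA_REAL; mean_nc2[n] = NA_REAL;
    }
  }

  // normalized constrained distribution P(n_c) and bubble histogram at n = N
  double ctot = 0.0, btot = 0.0;
  for (double v : eng.constrained) ctot += v;
  for (double v : eng.bubbleW) btot += v;
  NumericVector p_nc(N + 2), p_bubble(N + 1);
  for (int i = 0; i <= N + 1; ++i)
    p_nc[i] = (ctot > 0.0) ? eng.constrained[i] / ctot : NA_REAL;
  for (int i = 0; i <= N; ++i)
    p_bubble[i] = (btot > 0.0) ? eng.bubbleW[i] / btot : 0.0;
  const double swN = (eng.sW[N] > 0.0) ? eng.sW[N] : NA_REAL;
  // sWnb shares offN while sW[N] uses off[N]; reconcile offsets
  double mean_nb = NA_REAL;
  if (eng.sW[N] > 0.0 && eng.offN_set)
    mean_nb = (eng.sWnb * std::exp(eng.offN - eng.off[N])) / eng.sW[N];
  else if (eng.sW[N] > 0.0)
    mean_nb = 0.0;
  (void)swN;

  return List::create(
      _["n"] = seq_len(M) - 1, _["log_Z"] = logZ, _["log_sum_W"] = sumW_log,
      _["mean_nc"] = mean_nc, _["mean_nc2"] = mean_nc2, _["n_samples"] = nsamp,
      _["p_nc"] = p_nc, _["p_bubble"] = p_bubble, _["mean_nb"] = mean_nb,
      _["tours"] = (double)eng.tours_started,
      _["tours_reached"] = (double)eng.tours_reached,
      _["branches_reached"] = (double)eng.branches_reached,
      _["tour_lnW"] = wrap(eng.tour_lnW));
}

// Exposed pyramid geometry/bias for unit tests and diagnostics.
// apex is a 0-based (x, y, z) triple, dir in 0..5 = (+x,-x,+y,-y,+z,-z).
// [[Rcpp::export]]
List pyramid_scan_cpp(IntegerVector state, int L, IntegerVector apex, int dir,
                      int h) {
  std::vector<int> xs, ys, zs;
  long n_as = 0, n_os = 0;
  for (int k = 1; k <= h; ++k) {
    const int bx = apex[0] + k * DX[dir], by = apex[1] + k * DY[dir],
              bz = apex[2] + k * DZ[dir];
    for (int i = -k; i <= k; ++i)
      for (int j = -k; j <= k; ++j) {
        int x = bx, y = by, z = bz;
        if (DX[dir] != 0) { y += i; z += j; }
        else if (DY[dir] != 0) { x += i; z += j; }
        else { x += i; y += j; }
        if (x < 0 || x >= L || y < 0 || y >= L || z < 0 || z >= L) continue;
        xs.push_back(x); ys.push_back(y); zs.push_back(z);
        const int s = state[(R_xlen_t)x + (R_xlen_t)L * (y + (R_xlen_t)L * z)];
        if (s >= 1) { ++n_as; if (s == 2) ++n_os; }
      }
  }
  double f = (n_as == 0) ? 1e-6 : (double)n_as / (1.0 + (double)n_os);
  return List::create(_["x"] = wrap(xs), _["y"] = wrap(ys), _["z"] = wrap(zs),
                      _["n_as"] = (double)n_as, _["n_os"] = (double)n_os,
                      _["f_bias"] = f);
}
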