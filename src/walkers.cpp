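// Core lattice walkers.  All randomness comes from a self-contained
// splitmix64 stream so that batches are reproducible bit-for-bit across
// platforms and independent of R's RNG state.  Each walk in a batch gets
// its own substream, so censoring one walk never perturbs the others.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>

using namespace Rcpp;

namespace {

inline uint64_t sm64(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) : s(seed) { sm64(s); sm64(s); }
  double unif() { return (sm64(s) >> 11) * (1.0 / 9007199254740992.0); }
  // 2^64 is divisible by 4, so masking is exactly unbiased
  int dir() { return static_cast<int>(sm64(s) & 3ULL); }
};

inline uint64_t substream(uint64_t base, uint64_t idx) {
  uint64_t s = base ^ (0xD1B54A32D192ED03ULL * (idx + 1ULL));
  sm64(s);
  return s;
}

const int DX[4] = {1, -1, 0, 0};
const int DY[4] = {0, 0, 1, -1};

// -1 = absorbing exterior (Euclidean distance >= R), 0 = open, 1 = obstacle
struct Grid {
  int R, side;
  std::vector<signed char> v;
  void init(int R_) {
    R = R_;
    side = 2 * R + 1;
    v.assign(static_cast<size_t>(side) * side, -1);
  }
  signed char at(int x, int y) const {
    return v[static_cast<size_t>(y + R) * side + (x + R)];
  }
  void set(int x, int y, signed char z) {
    v[static_cast<size_t>(y + R) * side + (x + R)] = z;
  }
};

void fill_grid(Grid &g, int R, double q, Rng &rng) {
  g.init(R);
  const int R2 = R * R;
  for (int y = -R; y <= R; ++y)
    for (int x = -R; x <= R; ++x) {
      if (x * x + y * y >= R2) continue;
      if (x == 0 && y == 0) { g.set(x, y, 0); continue; }
      g.set(x, y, (q > 0.0 && rng.unif() < q) ? 1 : 0);
    }
}

// Flood fill from the origin over open nodes; connected means some open
// node reachable from the origin has a neighbour in the absorbing region.
bool grid_connected(const Grid &g) {
  const int R = g.R, R2 = R * R, side = g.side;
  std::vector<signed char> seen(static_cast<size_t>(side) * side, 0);
  std::vector<int> stack;
  const int origin = R * side + R;
  seen[origin] = 1;
  stack.push_back(origin);
  while (!stack.empty()) {
    const int idx = stack.back();
    stack.pop_back();
    const int x = idx % side - R, y = idx / side - R;
    for (int d = 0; d < 4; ++d) {
      const int nx = x + DX[d], ny = y + DY[d];
      if (nx * nx + ny * ny >= R2) return true;
      if (g.at(nx, ny) != 0) continue;
      const int nidx = (ny + R) * side + (nx + R);
      if (!seen[nidx]) { seen[nidx] = 1; stack.push_back(nidx); }
    }
  }
  return false;
}

// Unbiased walker; blocked moves leave the walker in place but consume
// the iteration (probability current into an obstacle is returned).
// Returns -1 when step_cap is exceeded; sets censored when absorb_cap
// truncates the walk (used only for histogram overflow pooling).
long long walk_obstacles(const Grid &g, Rng &rng, long long step_cap,
                         long long absorb_cap, bool &censored) {
  const int R2 = g.R * g.R;
  int x = 0, y = 0;
  long long steps = 0;
  for (;;) {
    const int d = rng.dir();
    const int nx = x + DX[d], ny = y + DY[d];
    ++steps;
    if (nx * nx + ny * ny >= R2) return steps;
    if (g.at(nx, ny) != 1) { x = nx; y = ny; }
    if (absorb_cap > 0 && steps >= absorb_cap) { censored = true; return steps; }
    if (steps >= step_cap) return -1;
  }
}

// Outward-biased walker: proposal uniform over 4 directions, accepted
// with probability exp(-C/eps), C = (1 - cos(theta))/2 between the
// displacement-from-origin and the proposed step.  The first step from
// the origin is always accepted.  When count_rejected, a rejected
// proposal consumes one iteration (the default deliberation model).
// Acceptance probabilities depend only on (x, y, direction), so they
// are tabulated once per batch.
struct DdmTable {
  int R, side;
  std::vector<double> acc; // side*side*4
  void init(int R_, double eps) {
    R = R_;
    side = 2 * R + 1;
    acc.assign(static_cast<size_t>(side) * side * 4, 1.0);
    for (int y = -R; y <= R; ++y)
      for (int x = -R; x <= R; ++x) {
        if (x == 0 && y == 0) continue;
        const double nz = std::sqrt(static_cast<double>(x * x + y * y));
        for (int d = 0; d < 4; ++d) {
          const double C = 0.5 * (1.0 - (x * DX[d] + y * DY[d]) / nz);
          at(x, y, d) = std::exp(-C / eps);
        }
      }
  }
  double &at(int x, int y, int d) {
    return acc[(static_cast<size_t>(y + R) * side + (x + R)) * 4 + d];
  }
};

long long walk_ddm(const DdmTable &tab, Rng &rng, long long step_cap,
                   long long absorb_cap, bool &censored, bool count_rejected) {
  const int R = tab.R, R2 = R * R, side = tab.side;
  int x = 0, y = 0;
  long long steps = 0, iters = 0;
  for (;;) {
    const int d = rng.dir();
    const double pa =
        tab.acc[(static_cast<size_t>(y + R) * side + (x + R)) * 4 + d];
    const bool accept = pa >= 1.0 || rng.unif() < pa;
    ++iters;
    if (count_rejected || accept) ++steps;
    if (accept) {
      const int nx = x + DX[d], ny = y + DY[d];
      if (nx * nx + ny * ny >= R2) return steps;
      x = nx; y = ny;
    }
    if (absorb_cap > 0 && steps >= absorb_cap) { censored = true; return steps; }
    if (steps >= step_cap || iters >= 8 * step_cap) return -1;
  }
}

Grid grid_from_matrix(const IntegerMatrix &m) {
  const int side = m.nrow();
  Grid g;
  g.init((side - 1) / 2);
  for (int c = 0; c < side; ++c)
    for (int r = 0; r < side; ++r)
      g.v[static_cast<size_t>(r) * side + c] = static_cast<signed char>(m(r, c));
  return g;
}

IntegerMatrix grid_to_matrix(const Grid &g) {
  IntegerMatrix m(g.side, g.side);
  for (int c = 0; c < g.side; ++c)
    for (int r = 0; r < g.side; ++r)
      m(r, c) = g.v[static_cast<size_t>(r) * g.side + c];
  return m;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_build_grid(int radius, double density, double seed) {
  Rng rng(static_cast<uint64_t>(seed));
  Grid g;
  fill_grid(g, radius, density, rng);
  return grid_to_matrix(g);
}

// [[Rcpp::export]]
bool cpp_is_connected(IntegerMatrix occupancy) {
  return grid_connected(grid_from_matrix(occupancy));
}

// [[Rcpp::export]]
List cpp_sample_connected_grid(int radius, double density, double seed,
                               int max_retries) {
  Rng rng(static_cast<uint64_t>(seed));
  Grid g;
  int tries = 0;
  for (;;) {
    fill_grid(g, radius, density, rng);
    ++tries;
    if (density <= 0.0 || grid_connected(g))
      return List::create(_["ok"] = true, _["occupancy"] = grid_to_matrix(g),
                          _["rejected"] = tries - 1);
    if (tries >= max_retries)
      return List::create(_["ok"] = false, _["rejected"] = tries);
    if ((tries & 1023) == 0) Rcpp::checkUserInterrupt();
  }
}

// [[Rcpp::export]]
List cpp_batch_obstacles(int radius, double density, double seed, int n,
                         bool quenched, Nullable<IntegerMatrix> grid,
                         int max_retries, double step_cap, double absorb_cap) {
  IntegerVector steps(n);
  double resamples = 0;
  int ncens = 0;
  const long long scap = static_cast<long long>(step_cap);
  const long long acap = static_cast<long long>(absorb_cap);
  Grid G;
  bool haveG = false;
  if (grid.isNotNull()) {
    G = grid_from_matrix(grid.get());
    haveG = true;
  } else if (quenched) {
    Rng grng(substream(static_cast<uint64_t>(seed), 0));
    int tries = 0;
    for (;;) {
      fill_grid(G, radius, density, grng);
      ++tries;
      if (density <= 0.0 || grid_connected(G)) break;
      if (tries >= max_retries)
        stop("connectivity: no connected grid realization in %d attempts", tries);
    }
    resamples = tries - 1;
    haveG = true;
  }
  Grid Gi;
  for (int i = 0; i < n; ++i) {
    Rng rng(substream(static_cast<uint64_t>(seed), static_cast<uint64_t>(i) + 1));
    const Grid *use = &G;
    if (!haveG) {
      int tries = 0;
      for (;;) {
        fill_grid(Gi, radius, density, rng);
        ++tries;
        if (density <= 0.0 || grid_connected(Gi)) break;
        if (tries >= max_retries)
          stop("connectivity: walk %d found no connected grid in %d attempts",
               i + 1, tries);
      }
      resamples += tries - 1;
      use = &Gi;
    }
    bool cens = false;
    const long long s = walk_obstacles(*use, rng, scap, acap, cens);
    if (s < 0) stop("runaway: walk %d exceeded the step cap", i + 1);
    if (cens) ++ncens;
    steps[i] = static_cast<int>(s);
    if ((i & 2047) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["steps"] = steps, _["resamples"] = resamples,
                      _["censored"] = ncens);
}

// [[Rcpp::export]]
List cpp_batch_ddm(int radius, double epsilon, double seed, int n,
                   double step_cap, double absorb_cap, bool count_rejected) {
  IntegerVector steps(n);
  int ncens = 0;
  const long long scap = static_cast<long long>(step_cap);
  const long long acap = static_cast<long long>(absorb_cap);
  DdmTable tab;
  tab.init(radius, epsilon);
  for (int i = 0; i < n; ++i) {
    Rng rng(substream(static_cast<uint64_t>(seed), static_cast<uint64_t>(i) + 1));
    bool cens = false;
    const long long s =
        walk_ddm(tab, rng, scap, acap, cens, count_rejected);
    if (s < 0) stop("runaway: walk %d exceeded the step cap", i + 1);
    if (cens) ++ncens;
    steps[i] = static_cast<int>(s);
    if ((i & 2047) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["steps"] = steps, _["resamples"] = 0.0,
                      _["censored"] = ncens);
}
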