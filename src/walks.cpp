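#include <Rcpp.h>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// Lattice dynamics of the persistent self-attracting walk (PSATW) in 1D:
// interior reversal probability p_ri = 1/(1 + e^{2k}), edge reversal
// probability p_re = 1/(1 + e^{2k + beta}). A step is an "edge" step iff the
// site ahead in the current direction has never been visited. Visit counts
// are incremented on arrival, before the next step is classified. All
// randomness comes from R's RNG stream (seed it from R).

// [[Rcpp::export]]
IntegerVector cpp_psatw_path(double k, double beta, int n_steps) {
  double p_ri = 1.0 / (1.0 + std::exp(2.0 * k));
  double p_re = 1.0 / (1.0 + std::exp(2.0 * k + beta));
  IntegerVector path(n_steps + 1);
  std::vector<int> visits(2 * n_steps + 3, 0);
  int off = n_steps + 1;
  int pos = 0;
  visits[off] = 1;
  int dir = (unif_rand() < 0.5) ? 1 : -1;
  path[0] = 0;
  for (int t = 1; t <= n_steps; ++t) {
    bool edge = (visits[off + pos + dir] == 0);
    double p = edge ? p_re : p_ri;
    if (unif_rand() < p) dir = -dir;
    pos += dir;
    visits[off + pos] += 1;
    path[t] = pos;
  }
  return path;
}

// First-passage time of a 1D PSATW to the single target site +r on the
// infinite line (walker starts at 0, initial direction uniform). Returns the
// step index at which the walker first stands on +r, or -1 if the target
// survives past t_max steps.

// [[Rcpp::export]]
int cpp_psatw_first_passage(double k, double beta, int r, int t_max) {
  double p_ri = 1.0 / (1.0 + std::exp(2.0 * k));
  double p_re = 1.0 / (1.0 + std::exp(2.0 * k + beta));
  std::vector<int> visits(2 * (size_t)t_max + 3, 0);
  int off = t_max + 1;
  int pos = 0;
  visits[off] = 1;
  int dir = (unif_rand() < 0.5) ? 1 : -1;
  for (int t = 1; t <= t_max; ++t) {
    bool edge = (visits[off + pos + dir] == 0);
    double p = edge ? p_re : p_ri;
    if (unif_rand() < p) dir = -dir;
    pos += dir;
    visits[off + pos] += 1;
    if (pos == r) return t;
  }
  return -1;
}

// 2D self-attracting walk (no persistence) on the 4-neighbour square
// lattice: jump probability to neighbour j proportional to
// exp(-beta * f(n_j)) with the saturating memory f(0) = 0, f(n > 0) = 1.

// [[Rcpp::export]]
IntegerMatrix cpp_satw2d_path(double beta, int n_steps) {
  IntegerMatrix path(n_steps + 1, 2);
  std::unordered_map<long long, int> visits;
  visits.reserve(2 * (size_t)n_steps);
  const long long OFF = 1LL << 31;
  auto key = [OFF](long long x, long long y) {
    return ((x + OFF) << 32) | (y + OFF);
  };
  long long x = 0, y = 0;
  visits[key(x, y)] = 1;
  const int dx[4] = {1, -1, 0, 0};
  const int dy[4] = {0, 0, 1, -1};
  double w_new = std::exp(-beta * 0.0);   // unvisited neighbour: f = 0
  double w_old = std::exp(-beta * 1.0);   // visited neighbour: f = 1
  for (int t = 1; t <= n_steps; ++t) {
    double w[4], W = 0.0;
    for (int j = 0; j < 4; ++j) {
      auto it = visits.find(key(x + dx[j], y + dy[j]));
      bool seen = (it != visits.end() && it->second > 0);
      w[j] = seen ? w_old : w_new;
      W += w[j];
    }
    double u = unif_rand() * W;
    int j = 0;
    double acc = w[0];
    while (j < 3 && u >= acc) acc += w[++j];
    x += dx[j];
    y += dy[j];
    visits[key(x, y)] += 1;
    path(t, 0) = (int)x;
    path(t, 1) = (int)y;
  }
  return path;
}
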