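#include <Rcpp.h>
#include <unordered_map>
#include <random>
#include <cstdint>

using namespace Rcpp;

// Flat representation of a multi-valued logical network, unpacked once per
// call from the R-side list produced by net_lowlevel().  All node and
// regulator indices are 0-based.  `clamp[i] >= 0` pins node i to that level
// (gene deletion / environment node); `cap[i]` truncates rule outputs
// (hypomorphic alleles).  State indices are held in uint64: the largest
// supported state space is 2^64, far beyond the 2^53 documented limit of
// the R-side encoding.
struct FlatNet {
  int n;
  std::vector<int> levels;
  std::vector<std::vector<int>> regs;
  std::vector<std::vector<int>> tables;
  std::vector<int> clamp;
  std::vector<int> cap;
  std::vector<uint64_t> place; // little-endian mixed-radix place values

  explicit FlatNet(const List& net) {
    IntegerVector lv = net["levels"];
    n = lv.size();
    levels.assign(lv.begin(), lv.end());
    List rg = net["regs"], tb = net["tables"];
    for (int i = 0; i < n; ++i) {
      IntegerVector r = rg[i], t = tb[i];
      regs.emplace_back(r.begin(), r.end());
      tables.emplace_back(t.begin(), t.end());
    }
    IntegerVector cl = net["clamp"], cp = net["cap"];
    clamp.assign(cl.begin(), cl.end());
    cap.assign(cp.begin(), cp.end());
    place.resize(n);
    uint64_t m = 1;
    for (int i = 0; i < n; ++i) { place[i] = m; m *= (uint64_t)levels[i]; }
  }

  inline int rule_output(int i, const std::vector<int>& s) const {
    const std::vector<int>& r = regs[i];
    uint64_t idx = 0, mult = 1;
    for (size_t j = 0; j < r.size(); ++j) {
      idx += (uint64_t)s[r[j]] * mult;
      mult *= (uint64_t)levels[r[j]];
    }
    int v = tables[i][idx];
    if (v > cap[i]) v = cap[i];
    return v;
  }

  inline void step(const std::vector<int>& s, std::vector<int>& out) const {
    for (int i = 0; i < n; ++i)
      out[i] = (clamp[i] >= 0) ? clamp[i] : rule_output(i, s);
  }

  inline uint64_t encode(const std::vector<int>& s) const {
    uint64_t e = 0;
    for (int i = 0; i < n; ++i) e += (uint64_t)s[i] * place[i];
    return e;
  }

  // Uniform initial state over the admissible space: clamped nodes fixed,
  // capped nodes uniform on 0..cap.
  template <class RNG>
  void random_state(RNG& rng, std::vector<int>& s) const {
    for (int i = 0; i < n; ++i) {
      if (clamp[i] >= 0) { s[i] = clamp[i]; continue; }
      std::uniform_int_distribution<int> d(0, cap[i]);
      s[i] = d(rng);
    }
  }
};

// Follow the synchronous map from `init` until a state repeats.  Returns the
// cycle (rotated so the minimal encoded state comes first) and the transient
// length.
static void run_to_cycle(const FlatNet& net, std::vector<int> s,
                         std::vector<std::vector<int>>& cycle, int& transient) {
  std::unordered_map<uint64_t, int> seen;
  std::vector<std::vector<int>> path;
  std::vector<int> nxt(net.n);
  for (;;) {
    uint64_t e = net.encode(s);
    auto it = seen.find(e);
    if (it != seen.end()) {
      transient = it->second;
      cycle.assign(path.begin() + it->second, path.end());
      break;
    }
    seen.emplace(e, (int)path.size());
    path.push_back(s);
    net.step(s, nxt);
    s.swap(nxt);
  }
  // canonical rotation: minimal encoded state first
  size_t arg = 0;
  uint64_t best = net.encode(cycle[0]);
  for (size_t k = 1; k < cycle.size(); ++k) {
    uint64_t e = net.encode(cycle[k]);
    if (e < best) { best = e; arg = k; }
  }
  if (arg > 0)
    std::rotate(cycle.begin(), cycle.begin() + arg, cycle.end());
}

static IntegerMatrix cycle_matrix(const std::vector<std::vector<int>>& cycle) {
  int L = cycle.size(), n = cycle[0].size();
  IntegerMatrix m(L, n);
  for (int k = 0; k < L; ++k)
    for (int i = 0; i < n; ++i) m(k, i) = cycle[k][i];
  return m;
}

// [[Rcpp::export]]
List cpp_find_attractor(List net, IntegerVector init) {
  FlatNet fn(net);
  std::vector<int> s(init.begin(), init.end());
  std::vector<std::vector<int>> cycle;
  int transient = 0;
  run_to_cycle(fn, s, cycle, transient);
  return List::create(_["cycle"] = cycle_matrix(cycle),
                      _["transient"] = transient);
}

// Monte-Carlo basin estimation: sample initial conditions with replacement,
// follow each to its attractor, and pool counts per canonical attractor.
// Attractors are disjoint state sets, so the minimal encoded cycle state is
// a unique key.
// [[Rcpp::export]]
List cpp_sample_attractors(List net, int n_samples, double seed) {
  FlatNet fn(net);
  std::mt19937_64 rng((uint64_t)seed);
  std::unordered_map<uint64_t, int> key2idx;
  std::vector<IntegerMatrix> cycles;
  std::vector<int> counts;
  std::vector<int> s(fn.n);
  for (int k = 0; k < n_samples; ++k) {
    fn.random_state(rng, s);
    std::vector<std::vector<int>> cycle;
    int transient = 0;
    run_to_cycle(fn, s, cycle, transient);
    uint64_t key = fn.encode(cycle[0]);
    auto it = key2idx.find(key);
    if (it == key2idx.end()) {
      key2idx.emplace(key, (int)cycles.size());
      cycles.push_back(cycle_matrix(cycle));
      counts.push_back(1);
    } else {
      counts[it->second] += 1;
    }
  }
  return List::create(_["cycles"] = wrap(cycles),
                      _["counts"] = wrap(counts));
}

// Exhaustive landscape: enumerate the admissible state space (clamped
// dimensions collapsed, capped dimensions truncated), memoize every state's
// successor implicitly through a coloring sweep, and count exact basins.
// [[Rcpp::export]]
List cpp_enumerate_attractors(List net) {
  FlatNet fn(net);
  int n = fn.n;
  std::vector<int> eff(n); // admissible levels per node
  double omega_d = 1.0;
  for (int i = 0; i < n; ++i) {
    eff[i] = (fn.clamp[i] >= 0) ? 1 : fn.cap[i] + 1;
    omega_d *= eff[i];
  }
  if (omega_d > 2e9) stop("state space too large for exhaustive enumeration");
  uint64_t omega = (uint64_t)omega_d;

  std::vector<uint64_t> eplace(n); // place values in the admissible space
  { uint64_t m = 1; for (int i = 0; i < n; ++i) { eplace[i] = m; m *= eff[i]; } }

  auto decode_eff = [&](uint64_t idx, std::vector<int>& s) {
    for (int i = 0; i < n; ++i) {
      int d = (int)(idx % eff[i]); idx /= eff[i];
      s[i] = (fn.clamp[i] >= 0) ? fn.clamp[i] : d;
    }
  };
  auto encode_eff = [&](const std::vector<int>& s) {
    uint64_t e = 0;
    for (int i = 0; i < n; ++i)
      if (fn.clamp[i] < 0) e += (uint64_t)s[i] * eplace[i];
    return e;
  };

  std::vector<int32_t> color(omega, -1);
  std::vector<IntegerMatrix> cycles;
  std::vector<double> basin;
  std::vector<int> s(n), nxt(n);
  std::vector<uint64_t> path;

  for (uint64_t start = 0; start < omega; ++start) {
    if (color[start] >= 0) continue;
    path.clear();
    uint64_t cur = start;
    int attr = -1;
    for (;;) {
      if (color[cur] >= 0) { attr = color[cur]; break; }
      if (color[cur] == -2) {
        // closed a new cycle inside the current path
        attr = (int)cycles.size();
        std::vector<std::vector<int>> cyc;
        size_t k0 = 0;
        while (path[k0] != cur) ++k0;
        uint64_t best = UINT64_MAX; size_t arg = k0;
        for (size_t k = k0; k < path.size(); ++k) {
          decode_eff(path[k], s);
          uint64_t e = fn.encode(s);
          if (e < best) { best = e; arg = k; }
        }
        for (size_t k = arg; k < path.size(); ++k) {
          decode_eff(path[k], s); cyc.push_back(s);
        }
        for (size_t k = k0; k < arg; ++k) {
          decode_eff(path[k], s); cyc.push_back(s);
        }
        cycles.push_back(cycle_matrix(cyc));
        basin.push_back(0.0);
        break;
      }
      color[cur] = -2;
      path.push_back(cur);
      decode_eff(cur, s);
      fn.step(s, nxt);
      cur = encode_eff(nxt);
    }
    for (size_t k = 0; k < path.size(); ++k) color[path[k]] = attr;
    basin[attr] += (double)path.size();
    // states beyond the path already counted when first colored
  }
  return List::create(_["cycles"] = wrap(cycles),
                      _["basin_counts"] = wrap(basin),
                      _["omega"] = omega_d);
}

// Long-run per-node means under asynchronous updating.  One round updates
// every node once (scheme 1 random permutation, scheme 2 fixed order) or
// performs n single uniformly-chosen updates (scheme 0).  Means are taken
// over the states at the end of each post-burn-in round.
// [[Rcpp::export]]
NumericVector cpp_async_longrun(List net, IntegerVector init, int scheme,
                                int burn_in, int window, double seed) {
  FlatNet fn(net);
  int n = fn.n;
  std::mt19937_64 rng((uint64_t)seed);
  std::vector<int> s(init.begin(), init.end());
  for (int i = 0; i < n; ++i) if (fn.clamp[i] >= 0) s[i] = fn.clamp[i];
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  NumericVector acc(n);
  int total = burn_in + window;
  for (int round = 0; round < total; ++round) {
    if (scheme == 0) {
      std::uniform_int_distribution<int> d(0, n - 1);
      for (int k = 0; k < n; ++k) {
        int i = d(rng);
        s[i] = (fn.clamp[i] >= 0) ? fn.clamp[i] : fn.rule_output(i, s);
      }
    } else {
      if (scheme == 1) std::shuffle(order.begin(), order.end(), rng);
      for (int k = 0; k < n; ++k) {
        int i = order[k];
        s[i] = (fn.clamp[i] >= 0) ? fn.clamp[i] : fn.rule_output(i, s);
      }
    }
    if (round >= burn_in)
      for (int i = 0; i < n; ++i) acc[i] += s[i];
  }
  for (int i = 0; i < n; ++i) acc[i] /= (double)window;
  return acc;
}

// Synchronous trajectory, exported for the fast path of long simulations.
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_sync(List net, IntegerVector init, int horizon) {
  FlatNet fn(net);
  int n = fn.n;
  IntegerMatrix out(horizon + 1, n);
  std::vector<int> s(init.begin(), init.end()), nxt(n);
  for (int i = 0; i < n; ++i) if (fn.clamp[i] >= 0) s[i] = fn.clamp[i];
  for (int i = 0; i < n; ++i) out(0, i) = s[i];
  for (int t = 1; t <= horizon; ++t) {
    fn.step(s, nxt);
    s.swap(nxt);
    for (int i = 0; i < n; ++i) out(t, i) = s[i];
  }
  return out;
}
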