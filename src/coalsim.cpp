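// Backward-time structured coalescent for few-deme demographies with
// piecewise-constant sizes, continuous migration, admixture pulses and
// deme mergers. Tuned for many independent small genealogies: the joint-SFS
// composite likelihood needs 1e4-1e5 genealogies per evaluation, so the
// event loop uses flat fixed-capacity arrays and per-epoch rate tables
// precomputed once per demography.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

#define MAX_DEMES 4
#define MAX_SAMPLES 512

// xoshiro256++ with splitmix64 seeding: fast, explicitly seeded so that
// likelihood evaluations can reuse common random numbers independently of
// R's global RNG state.
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  inline double unif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  inline double rexp() { return -std::log(unif()); }
  inline int unif_int(int n) { return (int)(unif() * n) % n; }
};

// Demography passed from R (validated there):
//   n_demes K
//   ev_time  ascending event times (ties allowed only as emitted by the R
//            builder, processed in listed order)
//   ev_type  0 = pulse (each lineage in src moves to dst w.p. prob)
//            1 = merge (all lineages in src move to dst; src inactive)
//   sizes    K x (E+1) diploid Ne per deme per epoch (<= 0 means inactive)
//   mig      K x K x (E+1) backward per-generation migration rates
struct Demography {
  int K, E;
  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_src, ev_dst;
  std::vector<double> ev_prob;
  std::vector<double> sizes;        // K * (E+1), raw (for error messages)
  std::vector<double> inv4N;        // 1/(4N), 0 when inactive
  std::vector<double> mig_out;      // per-deme total outward rate, K*(E+1)
  std::vector<double> mig;          // K*K*(E+1), row = source deme
  inline double i4n(int d, int ep) const { return inv4N[d + K * ep]; }
  inline double mout(int d, int ep) const { return mig_out[d + K * ep]; }
  inline double m(int from, int to, int ep) const {
    return mig[from + K * to + K * K * ep];
  }
};

static Demography unpack_demography(const List& dem) {
  Demography D;
  D.K = as<int>(dem["n_demes"]);
  if (D.K < 1 || D.K > MAX_DEMES) stop("n_demes must be 1..%d", MAX_DEMES);
  NumericVector t = dem["ev_time"];
  IntegerVector ty = dem["ev_type"], sr = dem["ev_src"], ds = dem["ev_dst"];
  NumericVector pr = dem["ev_prob"];
  D.E = t.size();
  D.ev_time.assign(t.begin(), t.end());
  D.ev_type.assign(ty.begin(), ty.end());
  D.ev_src.assign(sr.begin(), sr.end());
  D.ev_dst.assign(ds.begin(), ds.end());
  D.ev_prob.assign(pr.begin(), pr.end());
  NumericVector sz = dem["sizes"];
  NumericVector mg = dem["mig"];
  D.sizes.assign(sz.begin(), sz.end());
  D.mig.assign(mg.begin(), mg.end());
  if ((int)D.sizes.size() != D.K * (D.E + 1))
    stop("sizes must be K x (n_events + 1)");
  if ((int)D.mig.size() != D.K * D.K * (D.E + 1))
    stop("mig must be K x K x (n_events + 1)");
  for (int i = 1; i < D.E; ++i)
    if (D.ev_time[i] < D.ev_time[i - 1]) stop("event times must be sorted");
  int nep = D.E + 1;
  D.inv4N.assign(D.K * nep, 0.0);
  D.mig_out.assign(D.K * nep, 0.0);
  for (int ep = 0; ep < nep; ++ep) {
    for (int d = 0; d < D.K; ++d) {
      double N = D.sizes[d + D.K * ep];
      D.inv4N[d + D.K * ep] = (N > 0.0) ? 1.0 / (4.0 * N) : 0.0;
      double s = 0.0;
      for (int e = 0; e < D.K; ++e) s += D.m(d, e, ep);
      D.mig_out[d + D.K * ep] = s;
    }
  }
  return D;
}

struct Engine {
  const Demography& D;
  Xoshiro& rng;
  int n_tot;
  int lin[MAX_DEMES][MAX_SAMPLES];  // lineage node ids per deme
  int nlin[MAX_DEMES];
  double birth[2 * MAX_SAMPLES];    // node creation times
  int config[2 * MAX_SAMPLES];      // packed leaf-count index
  int parent[2 * MAX_SAMPLES];
  double node_time[2 * MAX_SAMPLES];
  bool record_tree;

  Engine(const Demography& d, Xoshiro& r) : D(d), rng(r), record_tree(false) {}

  // n_per_deme: haploid sample sizes (length K); mult: config multipliers
  // (length K, 0 where a deme's counts are not tracked). sfs_acc (may be
  // NULL) accumulates branch length per config.
  void run(const int* n_per_deme, const int* mult, double* sfs_acc,
           double* tmrca_out) {
    const int K = D.K;
    n_tot = 0;
    for (int d = 0; d < K; ++d) {
      nlin[d] = n_per_deme[d];
      n_tot += n_per_deme[d];
    }
    if (n_tot > MAX_SAMPLES) stop("total sample size exceeds %d", MAX_SAMPLES);
    int id = 0;
    for (int d = 0; d < K; ++d) {
      for (int i = 0; i < n_per_deme[d]; ++i) {
        lin[d][i] = id;
        birth[id] = 0.0;
        config[id] = mult[d];
        if (record_tree) { parent[id] = -1; node_time[id] = 0.0; }
        ++id;
      }
    }
    int next_node = n_tot;
    int k_active = n_tot;
    double t = 0.0;
    int ev = 0, epoch = 0;
    double coal_rate[MAX_DEMES], mig_rate[MAX_DEMES];

    while (k_active > 1) {
      double next_ev = (ev < D.E) ? D.ev_time[ev] : R_PosInf;
      double R = 0.0;
      for (int d = 0; d < K; ++d) {
        int k = nlin[d];
        double cr = 0.0, mr = 0.0;
        if (k > 0) {
          if (k > 1) {
            double i4n = D.i4n(d, epoch);
            if (i4n <= 0.0)
              stop("deme %d has %d lineages but non-positive size in epoch %d",
                   d + 1, k, epoch + 1);
            cr = (double)k * (k - 1) * i4n;
          }
          mr = k * D.mout(d, epoch);
        }
        coal_rate[d] = cr;
        mig_rate[d] = mr;
        R += cr + mr;
      }
      double dt = (R > 0.0) ? rng.rexp() / R : R_PosInf;
      if (t + dt >= next_ev) {
        if (!std::isfinite(next_ev))
          stop("lineages cannot coalesce: no events left and total rate is 0");
        t = next_ev;
        // apply every event scheduled at this time, in listed order
        while (ev < D.E && D.ev_time[ev] == next_ev) {
          int s = D.ev_src[ev], dd = D.ev_dst[ev];
          if (D.ev_type[ev] == 0) {  // pulse
            double p = D.ev_prob[ev];
            for (int i = 0; i < nlin[s];) {
              if (rng.unif() < p) {
                lin[dd][nlin[dd]++] = lin[s][i];
                lin[s][i] = lin[s][--nlin[s]];
              } else ++i;
            }
          } else {  // merge
            for (int i = 0; i < nlin[s]; ++i) lin[dd][nlin[dd]++] = lin[s][i];
            nlin[s] = 0;
          }
          ++ev;
          ++epoch;
        }
        continue;
      }
      t += dt;
      double u = rng.unif() * R;
      int d = 0;
      bool is_coal = true;
      for (d = 0; d < K; ++d) {
        if (u < coal_rate[d]) { is_coal = true; break; }
        u -= coal_rate[d];
        if (u < mig_rate[d]) { is_coal = false; break; }
        u -= mig_rate[d];
      }
      if (d >= K) { d = K - 1; is_coal = (coal_rate[d] > 0); }  // fp guard
      if (is_coal) {
        int k = nlin[d];
        int i = rng.unif_int(k);
        int j = rng.unif_int(k - 1);
        if (j >= i) ++j;
        int c1 = lin[d][i], c2 = lin[d][j];
        if (sfs_acc) {
          sfs_acc[config[c1]] += t - birth[c1];
          sfs_acc[config[c2]] += t - birth[c2];
        }
        int p = next_node++;
        birth[p] = t;
        config[p] = config[c1] + config[c2];
        if (record_tree) {
          parent[c1] = p; parent[c2] = p; parent[p] = -1; node_time[p] = t;
        }
        int hi = i > j ? i : j, lo = i > j ? j : i;
        lin[d][lo] = p;
        lin[d][hi] = lin[d][--nlin[d]];
        --k_active;
      } else {
        int k = nlin[d];
        int i = rng.unif_int(k);
        double v = rng.unif() * D.mout(d, epoch);
        int e = 0;
        for (e = 0; e < K; ++e) {
          v -= D.m(d, e, epoch);
          if (v < 0) break;
        }
        if (e >= K) e = K - 1;
        lin[e][nlin[e]++] = lin[d][i];
        lin[d][i] = lin[d][--nlin[d]];
      }
    }
    if (tmrca_out) *tmrca_out = t;
  }
};

// packed index: i1 + i2*(n1+1) + i3*(n1+1)(n2+1) + ... over sampled demes
static void config_multipliers(const std::vector<int>& n_per_deme, int* mult) {
  int m = 1;
  for (size_t d = 0; d < n_per_deme.size(); ++d) {
    if (n_per_deme[d] > 0) {
      mult[d] = m;
      m *= n_per_deme[d] + 1;
    } else {
      mult[d] = 0;
    }
  }
}

static int config_len(const std::vector<int>& n_per_deme) {
  int m = 1;
  for (size_t d = 0; d < n_per_deme.size(); ++d)
    if (n_per_deme[d] > 0) m *= n_per_deme[d] + 1;
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_expected_branch_sfs(List dem, IntegerVector n_per_deme,
                                      int n_sims, double seed) {
  Demography D = unpack_demography(dem);
  if ((int)n_per_deme.size() != D.K) stop("n_per_deme length != n_demes");
  std::vector<int> n(n_per_deme.begin(), n_per_deme.end());
  int mult[MAX_DEMES];
  config_multipliers(n, mult);
  int L = config_len(n);
  NumericVector out(L);
  Xoshiro rng((uint64_t)seed);
  Engine eng(D, rng);
  for (int s = 0; s < n_sims; ++s) {
    eng.run(n.data(), mult, REAL(out), nullptr);
    if ((s & 0xfff) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_sim_tmrca(List dem, IntegerVector n_per_deme, int n_sims,
                            double seed) {
  Demography D = unpack_demography(dem);
  std::vector<int> n(n_per_deme.begin(), n_per_deme.end());
  int mult[MAX_DEMES];
  config_multipliers(n, mult);
  NumericVector out(n_sims);
  Xoshiro rng((uint64_t)seed);
  Engine eng(D, rng);
  for (int s = 0; s < n_sims; ++s) {
    double tm = 0.0;
    eng.run(n.data(), mult, nullptr, &tm);
    out[s] = tm;
    if ((s & 0xfff) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// One biallelic variant per locus, placed uniformly on total branch length
// (infinite sites); rows = loci, cols = haploid samples grouped by deme in
// the order of n_per_deme. Every locus is polymorphic in the full sample by
// construction (no branch subtends all leaves).
//
// Loci that carry a SNP are an ascertained, length-biased draw from the
// genealogy distribution: with a small per-site mutation rate, a locus
// yields a SNP with probability proportional to its total branch length, so
// P(configuration) = E[l_config] / E[L]. Genealogies are therefore accepted
// with probability L / cap (rejection sampling, cap calibrated from a
// warm-up batch), which also keeps SNP data consistent with the
// branch-length-based expected SFS used in the composite likelihood.
// [[Rcpp::export]]
IntegerMatrix cpp_simulate_snps(List dem, IntegerVector n_per_deme,
                                int n_loci, double seed) {
  Demography D = unpack_demography(dem);
  std::vector<int> n(n_per_deme.begin(), n_per_deme.end());
  int mult[MAX_DEMES];
  config_multipliers(n, mult);
  int n_tot = 0;
  for (size_t d = 0; d < n.size(); ++d) n_tot += n[d];
  IntegerMatrix out(n_loci, n_tot);
  Xoshiro rng((uint64_t)seed);
  Engine eng(D, rng);
  eng.record_tree = true;
  int n_nodes = 2 * n_tot - 1;
  std::vector<double> blen(n_nodes);
  std::vector<int> stack;
  std::vector<std::vector<int>> children(n_nodes);

  auto total_length = [&]() {
    double total = 0.0;
    for (int v = 0; v < n_nodes; ++v) {
      blen[v] = (eng.parent[v] >= 0)
                    ? eng.node_time[eng.parent[v]] - eng.node_time[v]
                    : 0.0;
      total += blen[v];
    }
    return total;
  };

  // calibrate the rejection cap: 12x the mean total length puts the
  // truncated tail mass far below Monte-Carlo resolution
  const int warmup = 256;
  double mean_l = 0.0;
  for (int w = 0; w < warmup; ++w) {
    eng.run(n.data(), mult, nullptr, nullptr);
    mean_l += total_length();
  }
  double cap = 12.0 * (mean_l / warmup);

  for (int loc = 0; loc < n_loci; ++loc) {
    double total;
    for (;;) {
      eng.run(n.data(), mult, nullptr, nullptr);
      total = total_length();
      if (total >= cap || rng.unif() < total / cap) break;
    }
    double u = rng.unif() * total;
    int hit = 0;
    for (int v = 0; v < n_nodes; ++v) {
      u -= blen[v];
      if (u < 0) { hit = v; break; }
      hit = v;
    }
    for (int v = 0; v < n_nodes; ++v) children[v].clear();
    for (int v = 0; v < n_nodes; ++v)
      if (eng.parent[v] >= 0) children[eng.parent[v]].push_back(v);
    stack.clear();
    stack.push_back(hit);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v < n_tot) out(loc, v) = 1;
      else for (size_t c = 0; c < children[v].size(); ++c)
        stack.push_back(children[v][c]);
    }
    if ((loc & 0xff) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
List cpp_simulate_genealogy(List dem, IntegerVector n_per_deme, double seed) {
  Demography D = unpack_demography(dem);
  std::vector<int> n(n_per_deme.begin(), n_per_deme.end());
  int mult[MAX_DEMES];
  config_multipliers(n, mult);
  Xoshiro rng((uint64_t)seed);
  Engine eng(D, rng);
  eng.record_tree = true;
  eng.run(n.data(), mult, nullptr, nullptr);
  int n_tot = eng.n_tot;
  int n_nodes = 2 * n_tot - 1;
  IntegerVector parent(n_nodes);
  NumericVector time(n_nodes);
  IntegerVector leaf_deme(n_tot);
  for (int v = 0; v < n_nodes; ++v) {
    parent[v] = eng.parent[v] >= 0 ? eng.parent[v] + 1 : NA_INTEGER;
    time[v] = v < n_tot ? 0.0 : eng.node_time[v];
  }
  int id = 0;
  for (int d = 0; d < D.K; ++d)
    for (int i = 0; i < n_per_deme[d]; ++i) leaf_deme[id++] = d + 1;
  return List::create(_["parent"] = parent, _["time"] = time,
                      _["leaf_deme"] = leaf_deme);
}

// Accumulate a 3-deme joint SFS from per-locus derived counts with expected
// hypergeometric projection to (m1, m2, m3) haploid copies. d, nobs are
// n_loci x 3 (derived count and non-missing haploid count per deme). Loci
// with nobs < m in any deme contribute nothing.
// [[Rcpp::export]]
NumericVector cpp_project_joint_sfs(IntegerMatrix d, IntegerMatrix nobs,
                                    IntegerVector proj) {
  int n_loci = d.nrow();
  int m1 = proj[0], m2 = proj[1], m3 = proj[2];
  int L1 = m1 + 1, L2 = m2 + 1, L3 = m3 + 1;
  NumericVector out(L1 * L2 * L3);
  std::vector<double> h1(L1), h2(L2), h3(L3);
  for (int loc = 0; loc < n_loci; ++loc) {
    bool ok = true;
    for (int k = 0; k < 3; ++k)
      if (nobs(loc, k) < proj[k]) { ok = false; break; }
    if (!ok) continue;
    std::vector<double>* hs[3] = {&h1, &h2, &h3};
    for (int k = 0; k < 3; ++k) {
      int nn = nobs(loc, k), dd = d(loc, k), m = proj[k];
      std::vector<double>& h = *hs[k];
      double denom = ::Rf_lchoose(nn, m);
      for (int j = 0; j <= m; ++j) {
        if (j > dd || m - j > nn - dd) { h[j] = 0.0; continue; }
        h[j] = std::exp(::Rf_lchoose(dd, j) + ::Rf_lchoose(nn - dd, m - j) -
                        denom);
      }
    }
    for (int k = 0; k <= m3; ++k) {
      if (h3[k] == 0.0) continue;
      for (int j = 0; j <= m2; ++j) {
        double w = h3[k] * h2[j];
        if (w == 0.0) continue;
        double* row = REAL(out) + (size_t)L1 * (j + (size_t)L2 * k);
        for (int i = 0; i <= m1; ++i) row[i] += w * h1[i];
      }
    }
  }
  return out;
}
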