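// Clock-driven simulation of a two-population LIF network with delta
// synapses, per-synapse integer-step delays and Poisson external drive.
// Membrane decay is exact between steps; arriving spikes add their efficacy
// to the target's potential after the synaptic delay; threshold crossing
// resets and clamps the neuron for the refractory period.
#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

// ---- xoshiro256** seeded via splitmix64: fast, reproducible across
// platforms, independent of R's RNG stream ----
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
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * 0x1.0p-53; }
  // Knuth sampler with the threshold exp(-lambda) precomputed by the caller
  int poisson_knuth(double L) {
    double p = unif();
    int k = 0;
    while (p > L) { ++k; p *= unif(); }
    return k;
  }
  int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 12.0) return poisson_knuth(std::exp(-lambda));
    // normal approximation for large means (external drive aggregates)
    double u1 = unif(), u2 = unif();
    double z = std::sqrt(-2.0 * std::log(u1 + 1e-300)) *
               std::cos(6.283185307179586 * u2);
    int k = (int)std::lround(lambda + std::sqrt(lambda) * z);
    return k < 0 ? 0 : k;
  }
};

// sample `k` distinct integers from {0..n-1} \ {self} (self < 0 to disable)
static void sample_distinct(Xoshiro& rng, int n, int k, int self,
                            std::vector<int>& out) {
  out.clear();
  std::unordered_set<int> seen;
  if (self >= 0) seen.insert(self);
  int avail = n - (self >= 0 ? 1 : 0);
  if (k > avail) stop("in-degree exceeds presynaptic population size");
  while ((int)out.size() < k) {
    int c = (int)(rng.unif() * n);
    if (c >= n) c = n - 1;
    if (seen.insert(c).second) out.push_back(c);
  }
}

// [[Rcpp::export]]
List build_network_cpp(int NE, int NI, int KEE, int KEI, int KIE, int KII,
                       bool erdos_renyi, double dminE, double dmaxE,
                       double dminI, double dmaxI, double dt, double seed) {
  const int N = NE + NI;
  Xoshiro rng((uint64_t)seed * 2654435761ULL + 12345ULL);
  // in-lists per postsynaptic neuron, then inverted to out-CSR
  std::vector<std::vector<int>> pre(N);
  std::vector<int> buf;
  for (int post = 0; post < N; ++post) {
    bool postE = post < NE;
    int kE = postE ? KEE : KIE, kI = postE ? KEI : KII;
    if (erdos_renyi) {
      // Bernoulli per ordered pair == Binomial count + uniform subset
      double pE = (double)kE / NE, pI = (double)kI / NI;
      int selfE = postE ? post : -1, selfI = postE ? -1 : post - NE;
      int nE_eff = NE - (selfE >= 0 ? 1 : 0), nI_eff = NI - (selfI >= 0 ? 1 : 0);
      int cE = 0, cI = 0;
      for (int j = 0; j < nE_eff; ++j) cE += rng.unif() < pE;
      for (int j = 0; j < nI_eff; ++j) cI += rng.unif() < pI;
      sample_distinct(rng, NE, cE, selfE, buf);
      for (int s : buf) pre[post].push_back(s);
      sample_distinct(rng, NI, cI, selfI, buf);
      for (int s : buf) pre[post].push_back(NE + s);
    } else {
      sample_distinct(rng, NE, kE, postE ? post : -1, buf);
      for (int s : buf) pre[post].push_back(s);
      sample_distinct(rng, NI, kI, postE ? -1 : post - NE, buf);
      for (int s : buf) pre[post].push_back(NE + s);
    }
  }
  // out-CSR keyed by presynaptic neuron; per-synapse delay drawn once
  std::vector<int> odeg(N, 0);
  for (int post = 0; post < N; ++post)
    for (int s : pre[post]) ++odeg[s];
  IntegerVector offs(N + 1);
  for (int i = 0; i < N; ++i) offs[i + 1] = offs[i] + odeg[i];
  long long M = offs[N];
  IntegerVector targets(M), delays(M);
  std::vector<int> fill(N, 0);
  for (int post = 0; post < N; ++post) {
    for (int s : pre[post]) {
      long long idx = offs[s] + fill[s]++;
      targets[idx] = post;
      bool preE = s < NE;
      double dms = preE ? (dminE + (dmaxE - dminE) * rng.unif())
                        : (dminI + (dmaxI - dminI) * rng.unif());
      int dst = (int)std::ceil(dms / dt);
      delays[idx] = dst < 1 ? 1 : dst;
    }
  }
  IntegerVector indeg(N);
  for (int i = 0; i < N; ++i) indeg[i] = (int)pre[i].size();
  return List::create(_["offsets"] = offs, _["targets"] = targets,
                      _["delay_steps"] = delays, _["in_degree"] = indeg,
                      _["NE"] = NE, _["NI"] = NI);
}

// Out-CSR from an external pool of NX Poisson units: each of the Nt target
// neurons samples K distinct sources (fixed external in-degree).
// [[Rcpp::export]]
List build_x_cpp(int NX, int Nt, int K, double seed) {
  Xoshiro rng((uint64_t)seed * 40503ULL + 977ULL);
  std::vector<std::vector<int>> tgt(NX);
  std::vector<int> buf;
  for (int post = 0; post < Nt; ++post) {
    sample_distinct(rng, NX, K, -1, buf);
    for (int s : buf) tgt[s].push_back(post);
  }
  IntegerVector offs(NX + 1);
  for (int i = 0; i < NX; ++i) offs[i + 1] = offs[i] + (int)tgt[i].size();
  IntegerVector targets(offs[NX]);
  long long idx = 0;
  for (int i = 0; i < NX; ++i)
    for (int t : tgt[i]) targets[idx++] = t;
  return List::create(_["offsets"] = offs, _["targets"] = targets,
                      _["NX"] = NX);
}

// [[Rcpp::export]]
List simulate_net_cpp(List net, NumericVector nu_X_phase,
                      NumericVector t_phase, LogicalVector measure_phase,
                      double JEE, double JEI, double JIE, double JII,
                      double JEX, double JIX, int KEX, int KIX,
                      double alpha_E, double alpha_I,
                      double theta, double vr, double tau_E, double tau_I,
                      double trp, double dt_ms, double seed,
                      int init_mode, bool record_spikes,
                      double pop_bin_ms, List xE, List xI) {
  const int NE = as<int>(net["NE"]), NI = as<int>(net["NI"]);
  const int N = NE + NI;
  IntegerVector offs = net["offsets"], targets = net["targets"],
                delays = net["delay_steps"];
  const double dt = dt_ms / 1000.0;
  const double decayE = std::exp(-dt_ms / tau_E);
  const double decayI = std::exp(-dt_ms / tau_I);
  const int ref_steps = (int)std::lround(trp / dt_ms);
  int max_delay = 1;
  for (R_xlen_t i = 0; i < delays.size(); ++i)
    if (delays[i] > max_delay) max_delay = delays[i];
  int n_slots = 1;
  while (n_slots < max_delay + 2) n_slots <<= 1;
  const int mask = n_slots - 1;
  std::vector<float> buf((size_t)n_slots * N, 0.0f);
  std::vector<double> V(N);
  std::vector<int> ref(N, 0);
  Xoshiro rng((uint64_t)seed * 1099511628211ULL + 7ULL);
  for (int i = 0; i < N; ++i)
    V[i] = (init_mode == 1) ? vr + (theta - vr) * rng.unif() : vr;

  // explicit shared-Poisson-unit external drive (replica mode); the default
  // aggregate mode draws one Poisson count per neuron per step instead
  const bool replica = xE.size() > 0;
  IntegerVector xEoffs, xEtgt, xIoffs, xItgt;
  int NXE = 0, NXI = 0;
  if (replica) {
    xEoffs = as<IntegerVector>(xE["offsets"]);
    xEtgt = as<IntegerVector>(xE["targets"]);
    NXE = as<int>(xE["NX"]);
    xIoffs = as<IntegerVector>(xI["offsets"]);
    xItgt = as<IntegerVector>(xI["targets"]);
    NXI = as<int>(xI["NX"]);
  }

  const int n_phase = nu_X_phase.size();
  List phases(n_phase);
  std::vector<double> last_spike(N);
  std::vector<int> isi_n(N);
  std::vector<double> isi_sum(N), isi_sum2(N);
  std::vector<int> counts(N);
  std::vector<int> spk_id;
  std::vector<double> spk_t;
  const int bin_steps = std::max(1, (int)std::lround(pop_bin_ms / dt_ms));

  long long t_global = 0;
  for (int ph = 0; ph < n_phase; ++ph) {
    const long long steps = (long long)std::lround(t_phase[ph] / dt);
    const bool meas = measure_phase[ph];
    const double lamE = KEX * alpha_E * nu_X_phase[ph] * dt;
    const double lamI = KIX * alpha_I * nu_X_phase[ph] * dt;
    std::fill(counts.begin(), counts.end(), 0);
    std::fill(isi_n.begin(), isi_n.end(), 0);
    std::fill(isi_sum.begin(), isi_sum.end(), 0.0);
    std::fill(isi_sum2.begin(), isi_sum2.end(), 0.0);
    std::fill(last_spike.begin(), last_spike.end(), -1.0);
    const long long n_bins = steps / bin_steps + 1;
    std::vector<int> binE(meas ? n_bins : 1, 0), binI(meas ? n_bins : 1, 0);

    const double lamXE = alpha_E * nu_X_phase[ph] * dt;  // per replica unit
    const double lamXI = alpha_I * nu_X_phase[ph] * dt;

    for (long long s = 0; s < steps; ++s) {
      const int slot = (int)(t_global & mask);
      float* brow = &buf[(size_t)slot * N];
      const double tnow = t_global * dt;
      if (replica) {
        const int wslot = (int)((t_global + 1) & mask);
        float* wrow = &buf[(size_t)wslot * N];
        for (int u = 0; u < NXE; ++u) {
          int k = rng.poisson(lamXE);
          if (k)
            for (int e = xEoffs[u]; e < xEoffs[u + 1]; ++e)
              wrow[xEtgt[e]] += (float)(k * JEX);
        }
        for (int u = 0; u < NXI; ++u) {
          int k = rng.poisson(lamXI);
          if (k)
            for (int e = xIoffs[u]; e < xIoffs[u + 1]; ++e)
              wrow[xItgt[e]] += (float)(k * JIX);
        }
      }
      auto process = [&](int i0, int i1, double decay, double L, double Jx,
                         double Jrow_E, double Jrow_I, std::vector<int>& bin) {
        const long long bidx = s / bin_steps;
        for (int i = i0; i < i1; ++i) {
          if (ref[i] > 0) {
            --ref[i];
            V[i] = vr;
            brow[i] = 0.0f;
            continue;
          }
          double v = V[i] * decay + brow[i];
          brow[i] = 0.0f;
          if (L < 1.0) {
            int k = rng.poisson_knuth(L);
            if (k) v += k * Jx;
          }
          if (v >= theta) {
            if (meas) {
              ++counts[i];
              if (last_spike[i] >= 0.0) {
                double isi = tnow - last_spike[i];
                ++isi_n[i];
                isi_sum[i] += isi;
                isi_sum2[i] += isi * isi;
              }
              last_spike[i] = tnow;
              bin[bidx] += 1;
              if (record_spikes) {
                spk_id.push_back(i + 1);
                spk_t.push_back(tnow);
              }
            }
            v = vr;
            ref[i] = ref_steps;
            const int e0 = offs[i], e1 = offs[i + 1];
            for (int e = e0; e < e1; ++e) {
              const int tgt = targets[e];
              const int wslot = (int)((t_global + delays[e]) & mask);
              buf[(size_t)wslot * N + tgt] +=
                (float)(tgt < NE ? Jrow_E : Jrow_I);
            }
          }
          V[i] = v;
        }
      };
      const double LE = replica ? 1.0 : std::exp(-lamE);
      const double LI = replica ? 1.0 : std::exp(-lamI);
      process(0, NE, decayE, LE, JEX, JEE, JIE, binE);
      process(NE, N, decayI, LI, JIX, JEI, JII, binI);
      ++t_global;
      if ((s & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    if (meas) {
      phases[ph] = List::create(
        _["nu_X"] = nu_X_phase[ph], _["t"] = t_phase[ph],
        _["counts"] = IntegerVector(counts.begin(), counts.end()),
        _["isi_n"] = IntegerVector(isi_n.begin(), isi_n.end()),
        _["isi_sum"] = NumericVector(isi_sum.begin(), isi_sum.end()),
        _["isi_sum2"] = NumericVector(isi_sum2.begin(), isi_sum2.end()),
        _["bin_E"] = IntegerVector(binE.begin(), binE.end() - 1),
        _["bin_I"] = IntegerVector(binI.begin(), binI.end() - 1));
    } else {
      phases[ph] = List::create(_["nu_X"] = nu_X_phase[ph],
                                _["t"] = t_phase[ph]);
    }
  }
  List out = List::create(_["phases"] = phases, _["NE"] = NE, _["NI"] = NI);
  if (record_spikes) {
    out["spikes"] = DataFrame::create(
      _["neuron_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
      _["time_s"] = NumericVector(spk_t.begin(), spk_t.end()));
  }
  return out;
}
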