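// Continuous-time lattice SSA core for reaction-diffusion of tethered
// membrane reactions (CRDME sampler).
//
// Molecules occupy voxels of a square/cubic Cartesian mesh and hop between
// nearest-neighbour voxels at rate D/h^2 per direction (periodic wrap or
// reflecting rejection at the walls; a rejected hop is a self-loop and
// leaves the law of the process unchanged).  First-order reactions fire
// with exponential clocks.  Pairwise tethered reactions fire at a
// separation-dependent rate looked up from a per-rule table indexed by the
// integer squared lattice distance (minimal image on periodic domains),
// which makes Gaussian-kernel propensities O(1) per lookup with no
// transcendental calls in the hot loop.
//
// The sampler is the direct (Gillespie) method over three propensity
// groups: hops, unimolecular rules, pairwise rules.  Hop events update the
// affected molecule's pairwise contributions incrementally; reaction events
// trigger a full propensity rebuild (they are rare), which also curbs
// floating-point drift, as does a periodic scheduled rebuild.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// xoshiro256++ (Blackman & Vigna), seeded from R's RNG stream at entry so
// runs remain reproducible through set.seed(); much cheaper per draw than
// calling back into R's generator from the event loop.
struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  void seed_from_R() {
    // splitmix64 over a 64-bit seed assembled from two R uniforms
    uint64_t seed = (uint64_t)(unif_rand() * 4294967296.0) << 32 |
                    (uint64_t)(unif_rand() * 4294967296.0);
    for (int i = 0; i < 4; ++i) {
      seed += 0x9e3779b97f4a7c15ULL;
      uint64_t z = seed;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double runif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rexp() { return -std::log(runif()); }
};

struct PairRule {
  int sp_a, sp_b, prod_a, prod_b;
  const double *table;
  int table_len;
};

struct Sim {
  int dim, nside, n_species;
  bool periodic;
  std::vector<int> pos;         // n x dim, wrapped voxel coords
  std::vector<int> upos;        // unwrapped coords (for MSD tracking)
  std::vector<int> species;     // per molecule
  std::vector<std::vector<int>> by_species;
  std::vector<int> slot;        // index of molecule in its species list
  std::vector<int> counts;      // per species
  std::vector<double> hop_per_dir;   // per species
  std::vector<PairRule> prules;
  std::vector<double> rtot;     // pairwise totals per rule
  std::vector<int> uni_reactant, uni_product;
  std::vector<double> uni_rate;
  double hop_tot, uni_tot;
  // squared minimal-image axis distance, indexed by raw coordinate
  // difference + (nside-1); branch-free distance computation
  std::vector<int> sqfold;

  void build_sqfold() {
    sqfold.assign(2 * nside - 1, 0);
    for (int d = -(nside - 1); d <= nside - 1; ++d) {
      int f = d;
      if (periodic) {
        if (2 * f > nside) f -= nside;
        else if (2 * f < -nside) f += nside;
      }
      sqfold[d + nside - 1] = f * f;
    }
  }

  int n() const { return (int)species.size(); }

  int m2(int i, int j) const {
    const int *pi = &pos[(size_t)i * dim], *pj = &pos[(size_t)j * dim];
    const int *sq = sqfold.data() + nside - 1;
    int m = sq[pi[0] - pj[0]] + sq[pi[1] - pj[1]];
    if (dim == 3) m += sq[pi[2] - pj[2]];
    return m;
  }

  double pair_val(const PairRule &r, int i, int j) const {
    int m = m2(i, j);
    return (m < r.table_len) ? r.table[m] : 0.0;
  }

  void refresh_group_totals() {
    hop_tot = 0;
    for (int s = 0; s < n_species; ++s)
      hop_tot += counts[s] * hop_per_dir[s] * 2 * dim;
    uni_tot = 0;
    for (size_t u = 0; u < uni_rate.size(); ++u)
      uni_tot += uni_rate[u] * counts[uni_reactant[u]];
  }

  void rebuild_pair_totals() {
    for (size_t r = 0; r < prules.size(); ++r) {
      const PairRule &pr = prules[r];
      double tot = 0;
      const std::vector<int> &la = by_species[pr.sp_a];
      if (pr.sp_a == pr.sp_b) {
        for (size_t a = 0; a < la.size(); ++a)
          for (size_t b = a + 1; b < la.size(); ++b)
            tot += pair_val(pr, la[a], la[b]);
      } else {
        const std::vector<int> &lb = by_species[pr.sp_b];
        for (size_t a = 0; a < la.size(); ++a)
          for (size_t b = 0; b < lb.size(); ++b)
            tot += pair_val(pr, la[a], lb[b]);
      }
      rtot[r] = tot;
    }
  }



  void set_species(int i, int ns) {
    int os = species[i];
    if (os == ns) return;
    std::vector<int> &lo = by_species[os];
    int sl = slot[i];
    int last = lo.back();
    lo[sl] = last;
    slot[last] = sl;
    lo.pop_back();
    species[i] = ns;
    slot[i] = (int)by_species[ns].size();
    by_species[ns].push_back(i);
    counts[os]--;
    counts[ns]++;
  }
};

} // namespace

// [[Rcpp::export]]
List crdme_run(int dim, int nside, bool periodic,
               IntegerVector mol_species, IntegerMatrix mol_pos,
               NumericVector hop_per_dir,
               IntegerVector uni_reactant, IntegerVector uni_product,
               NumericVector uni_rate,
               List pair_rules,
               double t_end, NumericVector sample_times,
               bool stop_on_first_pair,
               double avg_start,
               int track_molecule,
               double max_events) {
  Sim S;
  S.dim = dim; S.nside = nside; S.periodic = periodic;
  S.n_species = hop_per_dir.size();
  int n = mol_species.size();
  S.species.assign(mol_species.begin(), mol_species.end());
  S.pos.resize((size_t)n * dim);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < dim; ++k)
      S.pos[(size_t)i * dim + k] = mol_pos(i, k);
  S.upos = S.pos;
  S.hop_per_dir.assign(hop_per_dir.begin(), hop_per_dir.end());
  S.counts.assign(S.n_species, 0);
  S.by_species.assign(S.n_species, std::vector<int>());
  S.slot.resize(n);
  for (int i = 0; i < n; ++i) {
    int s = S.species[i];
    S.counts[s]++;
    S.slot[i] = (int)S.by_species[s].size();
    S.by_species[s].push_back(i);
  }
  S.uni_reactant.assign(uni_reactant.begin(), uni_reactant.end());
  S.uni_product.assign(uni_product.begin(), uni_product.end());
  S.uni_rate.assign(uni_rate.begin(), uni_rate.end());

  int nrules = pair_rules.size();
  std::vector<NumericVector> tables(nrules); // keep alive
  for (int r = 0; r < nrules; ++r) {
    List pr = pair_rules[r];
    PairRule p;
    p.sp_a = as<int>(pr["sp_a"]); p.sp_b = as<int>(pr["sp_b"]);
    p.prod_a = as<int>(pr["prod_a"]); p.prod_b = as<int>(pr["prod_b"]);
    tables[r] = as<NumericVector>(pr["table"]);
    p.table = REAL(tables[r]);
    p.table_len = tables[r].size();
    S.prules.push_back(p);
  }
  S.build_sqfold();
  S.rtot.assign(nrules, 0.0);
  S.refresh_group_totals();
  S.rebuild_pair_totals();

  Xoshiro rng;
  rng.seed_from_R();

  int nsamp = sample_times.size();
  NumericMatrix counts_out(S.n_species, nsamp);
  IntegerMatrix track_out(track_molecule >= 0 ? nsamp : 0, dim);
  NumericVector acc_full(S.n_species), acc_h1(S.n_species), acc_h2(S.n_species);
  double avg_mid = (avg_start + t_end) / 2.0;
  NumericVector pair_events(nrules), uni_events(uni_rate.size());
  double hop_events = 0;

  double t = 0.0, events = 0.0;
  int samp_idx = 0;
  int status = 0;        // 0 done, 1 stopped on pair event, 2 stalled, 3 event cap
  double stop_time = NA_REAL;

  // lazily flushed time-averages (counts are piecewise constant, so the
  // accumulators only need attention when counts change or at boundaries)
  double t_acc = 0.0;
  auto flush_acc = [&](double tt) {
    double hi = std::min(tt, t_end);
    if (hi > avg_start && hi > t_acc) {
      double lo = std::max(t_acc, avg_start);
      if (hi > lo) {
        double hi1 = std::min(hi, avg_mid), lo2 = std::max(lo, avg_mid);
        for (int s = 0; s < S.n_species; ++s) {
          double c = S.counts[s];
          acc_full[s] += c * (hi - lo);
          if (hi1 > lo) acc_h1[s] += c * (hi1 - lo);
          if (hi > lo2) acc_h2[s] += c * (hi - lo2);
        }
      }
    }
    if (hi > t_acc) t_acc = hi;
  };
  auto record_samples_to = [&](double tt) {
    while (samp_idx < nsamp && sample_times[samp_idx] <= tt &&
           sample_times[samp_idx] <= t_end) {
      for (int s = 0; s < S.n_species; ++s)
        counts_out(s, samp_idx) = S.counts[s];
      if (track_molecule >= 0)
        for (int k = 0; k < dim; ++k)
          track_out(samp_idx, k) = S.upos[(size_t)track_molecule * dim + k];
      samp_idx++;
    }
  };
  double next_samp = nsamp ? sample_times[0] : R_PosInf;

  long rebuild_clock = 0;
  while (true) {
    double tot = S.hop_tot + S.uni_tot;
    for (int r = 0; r < nrules; ++r) tot += S.rtot[r];
    if (tot <= 1e-300) {
      flush_acc(t_end); record_samples_to(t_end);
      t = t_end; status = 2; break;
    }
    double t2 = t + rng.rexp() / tot;
    if (t2 >= t_end) {
      flush_acc(t_end); record_samples_to(t_end);
      t = t_end; break;
    }
    if (t2 >= next_samp) {
      record_samples_to(t2);
      next_samp = (samp_idx < nsamp) ? sample_times[samp_idx] : R_PosInf;
    }
    t = t2;
    events += 1.0;
    if (events >= max_events) { status = 3; break; }
    if (++rebuild_clock >= (1L << 22)) {
      rebuild_clock = 0;
      S.rebuild_pair_totals();
    }

    double u = rng.runif() * tot;
    if (u < S.hop_tot) {
      // ---- hop ----
      hop_events += 1.0;
      int sp = 0;
      for (; sp < S.n_species - 1; ++sp) {
        double g = S.counts[sp] * S.hop_per_dir[sp] * 2 * dim;
        if (u < g) break;
        u -= g;
      }
      if (S.counts[sp] == 0) continue; // numerical sliver; skip
      int idx = (int)(rng.runif() * S.counts[sp]);
      if (idx >= S.counts[sp]) idx = S.counts[sp] - 1;
      int i = S.by_species[sp][idx];
      int dir = (int)(rng.runif() * 2 * dim);
      if (dir >= 2 * dim) dir = 2 * dim - 1;
      int axis = dir >> 1, sgn = (dir & 1) ? 1 : -1;
      int oldx = S.pos[(size_t)i * dim + axis];
      int x = oldx + sgn;
      if (periodic) {
        if (x < 0) x += nside; else if (x >= nside) x -= nside;
      } else {
        if (x < 0 || x >= nside) continue; // reflecting: rejected self-loop
      }
      S.pos[(size_t)i * dim + axis] = x;
      S.upos[(size_t)i * dim + axis] += sgn;
      if (nrules > 0) {
        const int *sq = S.sqfold.data() + nside - 1;
        const int *pi = &S.pos[(size_t)i * dim];
        const int spv = S.species[i];
        for (int r = 0; r < nrules; ++r) {
          const PairRule &prr = S.prules[r];
          int partner_sp;
          if (prr.sp_a == spv) partner_sp = prr.sp_b;
          else if (prr.sp_b == spv) partner_sp = prr.sp_a;
          else continue;
          const std::vector<int> &lp = S.by_species[partner_sp];
          const int *pbase = S.pos.data();
          double d = 0;
          for (size_t b = 0; b < lp.size(); ++b) {
            int j = lp[b];
            if (j == i) continue;
            const int *pj = pbase + (size_t)j * dim;
            int m_other = 0;
            for (int k = 0; k < dim; ++k)
              if (k != axis) m_other += sq[pi[k] - pj[k]];
            int mn = m_other + sq[x - pj[axis]];
            int mo = m_other + sq[oldx - pj[axis]];
            d += ((mn < prr.table_len) ? prr.table[mn] : 0.0) -
                 ((mo < prr.table_len) ? prr.table[mo] : 0.0);
          }
          S.rtot[r] += d;
        }
      }
    } else if (u < S.hop_tot + S.uni_tot) {
      // ---- unimolecular ----
      u -= S.hop_tot;
      int ur = 0;
      for (; ur < (int)S.uni_rate.size() - 1; ++ur) {
        double g = S.uni_rate[ur] * S.counts[S.uni_reactant[ur]];
        if (u < g) break;
        u -= g;
      }
      int sp = S.uni_reactant[ur];
      if (S.counts[sp] == 0) continue;
      int idx = (int)(rng.runif() * S.counts[sp]);
      if (idx >= S.counts[sp]) idx = S.counts[sp] - 1;
      int i = S.by_species[sp][idx];
      uni_events[ur] += 1.0;
      flush_acc(t);
      S.set_species(i, S.uni_product[ur]);
      S.refresh_group_totals();
      S.rebuild_pair_totals();
      rebuild_clock = 0;
    } else {
      // ---- pairwise ----
      u -= S.hop_tot + S.uni_tot;
      int pr = 0;
      for (; pr < nrules - 1; ++pr) {
        if (u < S.rtot[pr]) break;
        u -= S.rtot[pr];
      }
      const PairRule &rule = S.prules[pr];
      // select the pair by scanning in rebuild order
      const std::vector<int> &la = S.by_species[rule.sp_a];
      int ia = -1, ib = -1;
      if (rule.sp_a == rule.sp_b) {
        for (size_t a = 0; a < la.size() && ia < 0; ++a)
          for (size_t b = a + 1; b < la.size(); ++b) {
            u -= S.pair_val(rule, la[a], la[b]);
            if (u < 0) { ia = la[a]; ib = la[b]; break; }
          }
      } else {
        const std::vector<int> &lb = S.by_species[rule.sp_b];
        for (size_t a = 0; a < la.size() && ia < 0; ++a)
          for (size_t b = 0; b < lb.size(); ++b) {
            u -= S.pair_val(rule, la[a], lb[b]);
            if (u < 0) { ia = la[a]; ib = lb[b]; break; }
          }
      }
      if (ia < 0) { // drift sliver: rebuild and skip
        S.rebuild_pair_totals();
        rebuild_clock = 0;
        continue;
      }
      pair_events[pr] += 1.0;
      if (stop_on_first_pair) { flush_acc(t); stop_time = t; status = 1; break; }
      flush_acc(t);
      S.set_species(ia, rule.prod_a);
      S.set_species(ib, rule.prod_b);
      S.refresh_group_totals();
      S.rebuild_pair_totals();
      rebuild_clock = 0;
    }
  }

  IntegerMatrix pos_out(n, dim);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < dim; ++k) pos_out(i, k) = S.pos[(size_t)i * dim + k];

  return List::create(
    _["t_final"] = t,
    _["status"] = status,
    _["stop_time"] = stop_time,
    _["counts"] = counts_out,
    _["acc_full"] = acc_full,
    _["acc_h1"] = acc_h1,
    _["acc_h2"] = acc_h2,
    _["avg_start"] = avg_start,
    _["hop_events"] = hop_events,
    _["uni_events"] = uni_events,
    _["pair_events"] = pair_events,
    _["final_species"] = IntegerVector(S.species.begin(), S.species.end()),
    _["final_pos"] = pos_out,
    _["track"] = track_out,
    _["events"] = events);
}
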