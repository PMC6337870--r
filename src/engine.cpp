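#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

// Portable seedable generator: std::mt19937_64 with explicit 53-bit uniforms
// (uniform_real_distribution is not bit-identical across standard libraries,
// so we build uniforms from raw 64-bit output ourselves).
struct Rng {
  std::mt19937_64 g;
  explicit Rng(uint64_t seed) : g(seed) {}
  // uniform in (0, 1]
  inline double unif_open0() {
    return ((g() >> 11) + 1.0) * (1.0 / 9007199254740992.0);
  }
  // uniform in [0, 1)
  inline double unif() {
    return (g() >> 11) * (1.0 / 9007199254740992.0);
  }
  // uniform integer in [0, n)
  inline int below(int n) { return (int)(unif() * n); }
};

// Weighted draw of a species index proportional to free molecule counts.
static inline int pick_free_species(const std::vector<int>& free_cnt,
                                    long total_free, Rng& rng) {
  double u = rng.unif() * (double)total_free;
  double c = 0.0;
  int S = (int)free_cnt.size();
  for (int s = 0; s < S; ++s) {
    c += free_cnt[s];
    if (u < c) return s;
  }
  // numerical edge: return last species with molecules
  for (int s = S - 1; s >= 0; --s) if (free_cnt[s] > 0) return s;
  return -1;
}

// [[Rcpp::export]]
List cpp_run_ssa(int n_side, double d_per_dir, double k_diss, double t_cat,
                 int n_ribosomes, int n_complexes, IntegerVector trna_total,
                 IntegerVector seq_species, int stop_steps, double max_events,
                 int seed) {
  const int S = trna_total.size();
  const int L = seq_species.size();
  const long n_sites = (long)n_side * n_side * n_side;
  if (n_complexes < 1) stop("stalled system: no ternary complexes");
  if (n_ribosomes < 1) stop("no ribosomes");
  if (L < 1) stop("empty sequence");

  Rng rng((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);

  // free pool
  std::vector<int> free_cnt(S), bound_cnt(S, 0);
  long total_free = 0;
  for (int s = 0; s < S; ++s) {
    if (trna_total[s] < 0) stop("negative tRNA count");
    free_cnt[s] = trna_total[s];
    total_free += trna_total[s];
  }
  if (total_free < n_complexes)
    stop("total tRNA pool smaller than requested complex count");

  // complexes: initial pairing without replacement, uniform over molecules
  std::vector<int> cx(n_complexes), cy(n_complexes), cz(n_complexes);
  std::vector<int> csp(n_complexes);
  for (int i = 0; i < n_complexes; ++i) {
    int s = pick_free_species(free_cnt, total_free, rng);
    free_cnt[s]--; total_free--; bound_cnt[s]++;
    csp[i] = s;
    cx[i] = rng.below(n_side);
    cy[i] = rng.below(n_side);
    cz[i] = rng.below(n_side);
  }

  // ribosomes: fixed uniform-random sites, uniform initial codon index
  std::vector<int> rib_site(n_ribosomes), rib_codon(n_ribosomes);
  std::vector<double> rib_idle(n_ribosomes, 0.0);
  for (int r = 0; r < n_ribosomes; ++r) {
    long site = (long)rng.below(n_side) * n_side * n_side +
                (long)rng.below(n_side) * n_side + rng.below(n_side);
    rib_site[r] = (int)site;
    rib_codon[r] = rng.below(L);
  }
  // site -> ribosome CSR (ribosome sites never move)
  std::vector<int> site_count(n_sites, 0);
  for (int r = 0; r < n_ribosomes; ++r) site_count[rib_site[r]]++;
  std::vector<int> site_off(n_sites + 1, 0);
  for (long s = 0; s < n_sites; ++s) site_off[s + 1] = site_off[s] + site_count[s];
  std::vector<int> site_rib(n_ribosomes);
  {
    std::vector<int> cursor(site_off.begin(), site_off.end() - 1);
    for (int r = 0; r < n_ribosomes; ++r) site_rib[cursor[rib_site[r]]++] = r;
  }

  const double d6 = 6.0 * d_per_dir;
  const double per_mol = d6 + k_diss;
  if (per_mol <= 0) stop("stalled system: zero total propensity");
  const double alpha0 = (double)n_complexes * per_mol;
  const double p_jump = d6 / per_mol;

  std::vector<double> times;
  times.reserve(std::min((long)stop_steps, (long)(1 << 20)));
  double t = 0.0;
  double n_events = 0.0, n_jumps = 0.0, n_diss = 0.0;
  std::vector<double> dir_counts(6, 0.0);
  int step_count = 0;
  bool stalled = false;

  while (step_count < stop_steps) {
    if (n_events >= max_events) { stalled = true; break; }
    n_events += 1.0;
    t += std::log(1.0 / rng.unif_open0()) / alpha0;

    if (rng.unif() < p_jump) {
      // travel channel: uniform molecule, uniform direction
      n_jumps += 1.0;
      int m = rng.below(n_complexes);
      int dir = rng.below(6);
      dir_counts[dir] += 1.0;
      int x = cx[m], y = cy[m], z = cz[m];
      switch (dir) {
        case 0: x = (x + 1 == n_side) ? 0 : x + 1; break;
        case 1: x = (x == 0) ? n_side - 1 : x - 1; break;
        case 2: y = (y + 1 == n_side) ? 0 : y + 1; break;
        case 3: y = (y == 0) ? n_side - 1 : y - 1; break;
        case 4: z = (z + 1 == n_side) ? 0 : z + 1; break;
        default: z = (z == 0) ? n_side - 1 : z - 1; break;
      }
      long site = (long)x * n_side * n_side + (long)y * n_side + z;
      // scan co-located ribosomes for an eligible reaction partner
      int lo = site_off[site], hi = site_off[site + 1];
      int chosen = -1, n_elig = 0;
      for (int k = lo; k < hi; ++k) {
        int r = site_rib[k];
        if (rib_idle[r] <= t && seq_species[rib_codon[r]] == csp[m]) {
          n_elig++;
          // reservoir sampling: uniform among eligible ribosomes
          if (n_elig == 1 || rng.below(n_elig) == 0) chosen = r;
        }
      }
      if (chosen >= 0) {
        // elongation event
        times.push_back(t);
        step_count++;
        rib_codon[chosen] = (rib_codon[chosen] + 1 == L) ? 0 : rib_codon[chosen] + 1;
        rib_idle[chosen] = t + t_cat;
        int sp = csp[m];
        free_cnt[sp]++; total_free++; bound_cnt[sp]--;
        int s2 = pick_free_species(free_cnt, total_free, rng);
        free_cnt[s2]--; total_free--; bound_cnt[s2]++;
        csp[m] = s2;
        cx[m] = rng.below(n_side);
        cy[m] = rng.below(n_side);
        cz[m] = rng.below(n_side);
      } else {
        cx[m] = x; cy[m] = y; cz[m] = z;
      }
    } else {
      // dissociation channel
      n_diss += 1.0;
      int m = rng.below(n_complexes);
      int sp = csp[m];
      free_cnt[sp]++; total_free++; bound_cnt[sp]--;
      int s2 = pick_free_species(free_cnt, total_free, rng);
      free_cnt[s2]--; total_free--; bound_cnt[s2]++;
      csp[m] = s2;
      cx[m] = rng.below(n_side);
      cy[m] = rng.below(n_side);
      cz[m] = rng.below(n_side);
    }
  }

  return List::create(
    _["times"] = NumericVector(times.begin(), times.end()),
    _["n_events"] = n_events,
    _["n_jumps"] = n_jumps,
    _["n_diss"] = n_diss,
    _["dir_counts"] = NumericVector(dir_counts.begin(), dir_counts.end()),
    _["free_final"] = IntegerVector(free_cnt.begin(), free_cnt.end()),
    _["bound_final"] = IntegerVector(bound_cnt.begin(), bound_cnt.end()),
    _["stalled"] = stalled
  );
}

// Non-reacting tracers: collective Gillespie walk, unwrapped displacements.
// Returns squared displacement per tracer in lattice units after time t_end.
// [[Rcpp::export]]
NumericVector cpp_tracer_msd(int n_tracers, double d_per_dir, double t_end,
                             int seed) {
  if (n_tracers < 1) stop("need at least one tracer");
  Rng rng((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 7ULL);
  std::vector<long> dx(n_tracers, 0), dy(n_tracers, 0), dz(n_tracers, 0);
  const double alpha0 = (double)n_tracers * 6.0 * d_per_dir;
  if (alpha0 <= 0) stop("zero jump rate");
  double t = 0.0;
  for (;;) {
    t += std::log(1.0 / rng.unif_open0()) / alpha0;
    if (t > t_end) break;
    int m = rng.below(n_tracers);
    switch (rng.below(6)) {
      case 0: dx[m]++; break;
      case 1: dx[m]--; break;
      case 2: dy[m]++; break;
      case 3: dy[m]--; break;
      case 4: dz[m]++; break;
      default: dz[m]--; break;
    }
  }
  NumericVector out(n_tracers);
  for (int i = 0; i < n_tracers; ++i) {
    out[i] = (double)(dx[i] * dx[i] + dy[i] * dy[i] + dz[i] * dz[i]);
  }
  return out;
}

// Lifetimes of single complexes under the travel + dissociation channels.
// [[Rcpp::export]]
NumericVector cpp_dissociation_times(int n, double d_per_dir, double k_diss,
                                     int seed) {
  if (k_diss <= 0) stop("k_diss must be positive");
  Rng rng((uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 13ULL);
  const double alpha0 = 6.0 * d_per_dir + k_diss;
  const double p_jump = 6.0 * d_per_dir / alpha0;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double t = 0.0;
    for (;;) {
      t += std::log(1.0 / rng.unif_open0()) / alpha0;
      if (rng.unif() >= p_jump) break;  // dissociation fires
    }
    out[i] = t;
  }
  return out;
}
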