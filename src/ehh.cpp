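#include <Rcpp.h>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

// Extended haplotype homozygosity along one side of a core SNP by partition
// refinement.  `haps` is a haplotypes x sites integer matrix with entries
// 0/1/NA; `carriers` indexes (0-based) the haplotype rows that carry the core
// allele class.  Markers are visited outward from `core` (0-based column) in
// steps of `step` (+1 right, -1 left).  A missing allele breaks identity: the
// haplotype is moved to a fresh singleton group and can never rejoin.
//
// Returns EHH at each visited marker.  When `trunc_stop` >= 0 the walk stops
// at (and includes) the first marker whose EHH <= trunc_stop; otherwise the
// whole side is returned.  `max_markers` > 0 bounds the number of markers
// visited regardless of decay.
// [[Rcpp::export]]
NumericVector cpp_ehh_side(const IntegerMatrix& haps, int core,
                           const IntegerVector& carriers, int step,
                           double trunc_stop, int max_markers = -1) {
  const int L = haps.ncol();
  const int nc = carriers.size();
  if (nc < 2) return NumericVector(0);
  const double denom = 0.5 * nc * (nc - 1.0);

  std::vector<int> grp(nc, 0);
  int n_grp = 1;
  std::vector<double> out;
  out.reserve(64);

  for (int m = core + step; m >= 0 && m < L; m += step) {
    // refine: key = old group * 3 + allele (0,1), NA -> fresh singleton
    std::unordered_map<long long, int> remap;
    remap.reserve(2 * n_grp);
    int next_id = 0;
    for (int i = 0; i < nc; ++i) {
      if (grp[i] < 0) continue;  // already a broken singleton
      int a = haps(carriers[i], m);
      if (a == NA_INTEGER) {
        grp[i] = -1;  // permanent singleton
        continue;
      }
      long long key = (long long)grp[i] * 3LL + a;
      std::unordered_map<long long, int>::iterator it = remap.find(key);
      if (it == remap.end()) {
        remap[key] = next_id;
        grp[i] = next_id++;
      } else {
        grp[i] = it->second;
      }
    }
    n_grp = next_id;
    // homozygosity among carriers
    std::vector<int> cnt(n_grp, 0);
    for (int i = 0; i < nc; ++i)
      if (grp[i] >= 0) cnt[grp[i]]++;
    double num = 0.0;
    for (int g = 0; g < n_grp; ++g)
      num += 0.5 * cnt[g] * (cnt[g] - 1.0);
    double ehh = num / denom;
    out.push_back(ehh);
    if (max_markers > 0 && (int)out.size() >= max_markers) break;
    if (trunc_stop >= 0 && ehh <= trunc_stop) break;
    if (ehh == 0.0) {  // cannot increase again; remaining side is all 0
      for (int r = m + step; r >= 0 && r < L; r += step) {
        out.push_back(0.0);
        if (max_markers > 0 && (int)out.size() >= max_markers) break;
      }
      break;
    }
  }
  return wrap(out);
}

// Forward Wright-Fisher evolution of a haplotype panel with recombination,
// mutation, and optional genic selection at one core site.
//
// `haps` is sites x haplotypes (column = one haplotype, so copying a
// haplotype is a contiguous column copy).  Each offspring haplotype is a
// recombinant gamete of two parent haplotypes drawn with probability
// proportional to fitness (1 + s for carriers of the derived core allele).
// Crossover count per gamete is Poisson(rec_rate * span_bp); breakpoints are
// uniform on the physical span.  Mutations toggle random (site, haplotype)
// entries at rate `mut_rate` per site per haplotype per generation; the core
// site is never toggled while under selection.
//
// Evolution stops after `n_gen` generations, or as soon as the derived core
// frequency reaches `target_freq` (when `core` >= 0 and target > 0).  When
// `abort_gen` > 0, a selected run whose core frequency is still below
// `abort_freq` at that generation is abandoned early (the caller restarts);
// this conditions the accepted runs on fast establishment.
// Uses R's RNG; deterministic under set.seed().
// [[Rcpp::export]]
List cpp_wf_evolve(IntegerMatrix haps, const NumericVector& pos_bp,
                   double rec_rate, double mut_rate, int n_gen, int core,
                   double s, double target_freq, int abort_gen = -1,
                   double abort_freq = 0.0) {
  const int L = haps.nrow();
  const int N = haps.ncol();
  const double span = pos_bp[L - 1] - pos_bp[0];
  const double exp_xo = rec_rate * span;

  IntegerMatrix cur = clone(haps);
  IntegerMatrix nxt(L, N);

  bool reached = false;
  int gen_used = 0;

  for (int gen = 0; gen < n_gen; ++gen) {
    // fitness-weighted parent sampling: two classes (derived / ancestral at core)
    int k = 0;
    std::vector<int> der_idx, anc_idx;
    if (core >= 0) {
      der_idx.reserve(N);
      anc_idx.reserve(N);
      for (int j = 0; j < N; ++j) {
        if (cur(core, j) == 1) { der_idx.push_back(j); ++k; }
        else anc_idx.push_back(j);
      }
      if (target_freq > 0 && (double)k / N >= target_freq) { reached = true; break; }
      if (k == 0 && target_freq > 0) break;  // allele lost: caller restarts
      if (abort_gen > 0 && gen >= abort_gen && target_freq > 0 &&
          (double)k / N < abort_freq) break;  // failed to establish in time
    }
    double p_der = 0.0;
    if (core >= 0) {
      double wd = k * (1.0 + s), wa = (double)(N - k);
      p_der = wd / (wd + wa);
    }

    for (int j = 0; j < N; ++j) {
      // pick parent 1
      int p1;
      if (core >= 0) {
        if (unif_rand() < p_der)
          p1 = der_idx[(int)(unif_rand() * k) % k];
        else
          p1 = anc_idx[(int)(unif_rand() * (N - k)) % (N - k)];
      } else {
        p1 = (int)(unif_rand() * N) % N;
      }
      int nxo = (exp_xo > 0) ? (int)R::rpois(exp_xo) : 0;
      if (nxo == 0) {
        std::copy(&cur(0, p1), &cur(0, p1) + L, &nxt(0, j));
      } else {
        int p2;
        if (core >= 0) {
          if (unif_rand() < p_der)
            p2 = der_idx[(int)(unif_rand() * k) % k];
          else
            p2 = anc_idx[(int)(unif_rand() * (N - k)) % (N - k)];
        } else {
          p2 = (int)(unif_rand() * N) % N;
        }
        std::vector<double> bp(nxo);
        for (int x = 0; x < nxo; ++x)
          bp[x] = pos_bp[0] + unif_rand() * span;
        std::sort(bp.begin(), bp.end());
        int seg = 0;  // 0 -> copy from p1, 1 -> from p2
        int x = 0;
        for (int i = 0; i < L; ++i) {
          while (x < nxo && pos_bp[i] > bp[x]) { seg ^= 1; ++x; }
          nxt(i, j) = cur(i, seg ? p2 : p1);
        }
      }
    }

    // mutation: Poisson number of toggles over the whole panel
    if (mut_rate > 0) {
      int nmut = (int)R::rpois(mut_rate * (double)L * (double)N);
      for (int t = 0; t < nmut; ++t) {
        int i = (int)(unif_rand() * L) % L;
        int j = (int)(unif_rand() * N) % N;
        if (core >= 0 && i == core) continue;
        nxt(i, j) = 1 - nxt(i, j);
      }
    }

    std::swap(cur, nxt);
    ++gen_used;
  }

  if (core >= 0 && target_freq > 0 && !reached) {
    int k = 0;
    for (int j = 0; j < N; ++j)
      if (cur(core, j) == 1) ++k;
    if ((double)k / N >= target_freq) reached = true;
  }

  return List::create(_["haps"] = cur, _["generations"] = gen_used,
                      _["reached"] = reached);
}
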