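#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Forward haploid Wright-Fisher simulation with genealogy tracing on the
// 3-population species tree ((p2,p3),p1).  Each individual carries a count
// of deleterious mutations at one non-recombining locus; offspring choose
// parents with probability proportional to (1+s)^count and acquire new
// mutations as a Poisson draw with mean U per offspring (irreversible).
// The pedigree needed to classify the triplet genealogy (which pair of the
// three sampled chromosomes shares its most recent common ancestor) is
// recorded only where coalescence is possible: the ancestral population and
// the internal (p2,p3) branch; tip branches propagate founder indices
// forward instead, which is equivalent and keeps memory at
// O(N * (ancestral + internal generations)).

namespace {

struct Pop {
  int size;
  bool mono;                 // all individuals share one load value
  std::vector<int> load;     // size 1 when mono, else size 'size'

  void init(int n, int base_load) {
    size = n;
    mono = true;
    load.assign(1, base_load);
  }
};

// One generation: offspring population 'cur' of size nc drawn from 'prev'.
// par[i] receives the parent index of offspring i.
void wf_generation(const Pop& prev, Pop& cur, int nc, double s, double U,
                   int* par, std::vector<double>& cw, long generation) {
  const int np = prev.size;
  if (prev.mono) {
    for (int i = 0; i < nc; ++i)
      par[i] = (int)(np * unif_rand());
  } else {
    cw.resize(np);
    double acc = 0.0;
    for (int j = 0; j < np; ++j) {
      acc += std::pow(1.0 + s, prev.load[j]);
      cw[j] = acc;
    }
    if (!(acc > 0.0))
      stop("population mean fitness underflow at generation %d",
           (int)generation);
    for (int i = 0; i < nc; ++i) {
      double u = acc * unif_rand();
      int lo = 0, hi = np - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cw[mid] < u) lo = mid + 1; else hi = mid;
      }
      par[i] = lo;
    }
  }
  // offspring loads
  int nm = (int) R::rpois((double)nc * U);
  if (prev.mono && nm == 0) {
    cur.size = nc; cur.mono = true;
    cur.load.assign(1, prev.load[0]);
    return;
  }
  cur.size = nc; cur.mono = false;
  cur.load.resize(nc);
  if (prev.mono) {
    const int base = prev.load[0];
    for (int i = 0; i < nc; ++i) cur.load[i] = base;
  } else {
    for (int i = 0; i < nc; ++i) cur.load[i] = prev.load[par[i]];
  }
  for (int m = 0; m < nm; ++m)
    cur.load[(int)(nc * unif_rand())]++;
  // collapse back to monomorphic when possible
  int first = cur.load[0];
  bool allsame = true;
  for (int i = 1; i < nc; ++i)
    if (cur.load[i] != first) { allsame = false; break; }
  if (allsame) { cur.mono = true; cur.load.assign(1, first); }
}

} // namespace

// [[Rcpp::export(name = ".wf_triplet_sim")]]
IntegerVector wf_triplet_sim(int n_loci, int N, int N3, int ancestral_gens,
                             int internal_gens, int tip_gens,
                             double s, double U) {
  if (N < 2 || N3 < 1) stop("population sizes too small");
  if (ancestral_gens < 1 || internal_gens < 1 || tip_gens < 1)
    stop("all branch durations must be at least 1 generation");
  IntegerVector out(n_loci);
  std::vector<double> cw;
  std::vector<int> ped_anc((size_t)ancestral_gens * N);
  std::vector<int> ped_p23((size_t)internal_gens * N);
  std::vector<int> par(N), a1(N), a2(N), a3(std::max(N3, 1)), tmp(N),
      tmp3(std::max(N3, 1));
  Pop anc, p1, p23, p2, p3, scratch;

  for (int locus = 0; locus < n_loci; ++locus) {
    long gen = 0;
    // --- ancestral population: founders + ancestral_gens transitions ---
    anc.init(N, 0);
    for (int g = 1; g <= ancestral_gens; ++g) {
      wf_generation(anc, scratch, N, s, U, &ped_anc[(size_t)(g - 1) * N],
                    cw, ++gen);
      std::swap(anc, scratch);
    }
    // --- split 1: p1 and p23 found from the ancestral final generation ---
    // p1: propagate the index of each individual's ancestor in the
    // ancestral final generation; no pedigree stored.
    wf_generation(anc, p1, N, s, U, par.data(), cw, ++gen);
    for (int i = 0; i < N; ++i) a1[i] = par[i];
    wf_generation(anc, p23, N, s, U, &ped_p23[0], cw, gen);
    // --- internal branch: p23 for internal_gens transitions (the first
    //     one above was the founding), pedigree stored; p1 keeps pace ---
    for (int g = 2; g <= internal_gens; ++g) {
      wf_generation(p23, scratch, N, s, U, &ped_p23[(size_t)(g - 1) * N],
                    cw, ++gen);
      std::swap(p23, scratch);
      wf_generation(p1, scratch, N, s, U, par.data(), cw, gen);
      std::swap(p1, scratch);
      for (int i = 0; i < N; ++i) tmp[i] = a1[par[i]];
      std::swap(a1, tmp);
    }
    // --- split 2: p2 (size N) and p3 (size N3) found from p23 final ---
    wf_generation(p23, p2, N, s, U, par.data(), cw, ++gen);
    for (int i = 0; i < N; ++i) a2[i] = par[i];
    wf_generation(p23, p3, N3, s, U, par.data(), cw, gen);
    for (int i = 0; i < N3; ++i) a3[i] = par[i];
    // --- tip branches: tip_gens transitions total per tip population ---
    for (int g = 2; g <= tip_gens; ++g) {
      ++gen;
      wf_generation(p1, scratch, N, s, U, par.data(), cw, gen);
      std::swap(p1, scratch);
      for (int i = 0; i < N; ++i) tmp[i] = a1[par[i]];
      std::swap(a1, tmp);
      wf_generation(p2, scratch, N, s, U, par.data(), cw, gen);
      std::swap(p2, scratch);
      for (int i = 0; i < N; ++i) tmp[i] = a2[par[i]];
      std::swap(a2, tmp);
      wf_generation(p3, scratch, N3, s, U, par.data(), cw, gen);
      std::swap(p3, scratch);
      for (int i = 0; i < N3; ++i) tmp3[i] = a3[par[i]];
      std::swap(a3, tmp3);
    }
    // p1 spans the internal branch plus the tip branch; the loops above
    // gave it internal_gens + tip_gens - 1 transitions, so one remains.
    {
      ++gen;
      wf_generation(p1, scratch, N, s, U, par.data(), cw, gen);
      std::swap(p1, scratch);
      for (int i = 0; i < N; ++i) tmp[i] = a1[par[i]];
      std::swap(a1, tmp);
    }
    // --- sample one chromosome per population and trace backward ---
    int x1 = a1[(int)(N * unif_rand())];        // index into anc final gen
    int x2 = a2[(int)(N * unif_rand())];        // index into p23 final gen
    int x3 = a3[(int)(N3 * unif_rand())];       // index into p23 final gen
    int code = 3;
    // walk the internal branch pedigree: rows internal_gens ... 1
    for (int g = internal_gens; g >= 1; --g) {
      if (x2 == x3) { code = 0; break; }
      x2 = ped_p23[(size_t)(g - 1) * N + x2];
      x3 = ped_p23[(size_t)(g - 1) * N + x3];
    }
    // after row 1 the indices refer to the ancestral final generation
    if (code == 3) {
      for (int g = ancestral_gens; g >= 0; --g) {
        if (x2 == x3) { code = 0; break; }
        if (x1 == x2) { code = 1; break; }
        if (x1 == x3) { code = 2; break; }
        if (g == 0) break;
        x1 = ped_anc[(size_t)(g - 1) * N + x1];
        x2 = ped_anc[(size_t)(g - 1) * N + x2];
        x3 = ped_anc[(size_t)(g - 1) * N + x3];
      }
    }
    out[locus] = code;
  }
  return out;
}
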