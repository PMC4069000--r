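// Hudson coalescent-with-recombination (ancestral recombination graph) for a
// sample of n haploid sequences at one locus, with an optional instantaneous
// bottleneck epoch, infinite-sites mutation, and per-locus summary statistics.
//
// Time scale: units of 4N generations (ms convention).  With k active
// lineages and relative population size size(t), coalescence occurs at rate
// k(k-1)/size(t); mutations fall on a lineage at rate theta_locus * (fraction
// of the unit interval it carries as ancestral material); recombination
// splits a lineage at rate rho_locus * (fraction of the L-1 links spanned by
// its ancestral material).  Under this convention E[S] = theta_locus * a_n
// and E[pi] = theta_locus.
//
// Ancestral material is a sorted set of disjoint segments of [0,1), each
// tagged with the set of sampled sequences descended from it (bitmask,
// n <= 64).  Segments whose descendant set is complete have found their MRCA
// and are discarded, so every mutation is segregating by construction.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Seg {
  double a, b;     // [a, b) subset of [0,1)
  uint64_t d;      // descendant bitmask
};

struct Lineage {
  std::vector<Seg> segs;
  double tot;      // total ancestral length
  double lo, hi;   // span of ancestral material

  void refresh() {
    tot = 0.0;
    for (const Seg &s : segs) tot += s.b - s.a;
    if (segs.empty()) { lo = hi = 0.0; }
    else { lo = segs.front().a; hi = segs.back().b; }
  }
};

// Union of two disjoint-sorted segment lists; overlapping descendant sets are
// OR-ed and complete sets dropped.
std::vector<Seg> merge_segs(const std::vector<Seg> &x, const std::vector<Seg> &y,
                            uint64_t full) {
  std::vector<double> pts;
  pts.reserve(2 * (x.size() + y.size()));
  for (const Seg &s : x) { pts.push_back(s.a); pts.push_back(s.b); }
  for (const Seg &s : y) { pts.push_back(s.a); pts.push_back(s.b); }
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());

  std::vector<Seg> out;
  size_t ix = 0, iy = 0;
  for (size_t i = 0; i + 1 < pts.size(); ++i) {
    double a = pts[i], b = pts[i + 1];
    double m = 0.5 * (a + b);
    uint64_t d = 0;
    while (ix < x.size() && x[ix].b <= m) ++ix;
    if (ix < x.size() && x[ix].a < m) d |= x[ix].d;
    while (iy < y.size() && y[iy].b <= m) ++iy;
    if (iy < y.size() && y[iy].a < m) d |= y[iy].d;
    if (d == 0 || d == full) continue;
    if (!out.empty() && out.back().b == a && out.back().d == d) out.back().b = b;
    else out.push_back(Seg{a, b, d});
  }
  return out;
}

struct Mutation { double pos; uint64_t d; };

// Piecewise-constant relative size: 1 on [0, botEnd), botNe on
// [botEnd, botEnd + botDur), 1 afterwards.  SNM: botNe = 1 (no epochs).
struct Demog {
  bool bottleneck;
  double botEnd, botDur, botNe;
  double size_at(double t) const {
    if (!bottleneck) return 1.0;
    if (t >= botEnd && t < botEnd + botDur) return botNe;
    return 1.0;
  }
  // next epoch boundary strictly after t (R_PosInf if none)
  double next_boundary(double t) const {
    if (!bottleneck) return R_PosInf;
    if (t < botEnd) return botEnd;
    if (t < botEnd + botDur) return botEnd + botDur;
    return R_PosInf;
  }
};

void simulate_locus_core(int n, double theta_locus, double rho_locus,
                         const Demog &dem, std::vector<Mutation> &muts) {
  uint64_t full = (n == 64) ? ~uint64_t(0) : ((uint64_t(1) << n) - 1);
  std::vector<Lineage> lin(n);
  for (int i = 0; i < n; ++i) {
    lin[i].segs.push_back(Seg{0.0, 1.0, uint64_t(1) << i});
    lin[i].refresh();
  }

  double t = 0.0;
  long guard = 0;
  while (lin.size() >= 2) {
    if (++guard > 100000000L) stop("coalescent simulation failed to terminate");
    size_t k = lin.size();
    double sum_tot = 0.0, sum_span = 0.0;
    for (const Lineage &l : lin) { sum_tot += l.tot; sum_span += l.hi - l.lo; }

    double size_now = dem.size_at(t);
    double rate_c = double(k) * double(k - 1) / size_now;
    double rate_r = rho_locus * sum_span;
    double rate_m = theta_locus * sum_tot;
    double R = rate_c + rate_r + rate_m;

    double dt = exp_rand() / R;
    double tb = dem.next_boundary(t);
    if (t + dt >= tb) { t = tb; continue; }  // rates change; redraw
    t += dt;

    double u = unif_rand() * R;
    if (u < rate_c) {
      // coalescence of a uniform pair
      size_t i = (size_t)(unif_rand() * k); if (i >= k) i = k - 1;
      size_t j = (size_t)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      if (i > j) std::swap(i, j);
      std::vector<Seg> merged = merge_segs(lin[i].segs, lin[j].segs, full);
      lin.erase(lin.begin() + j);
      if (merged.empty()) lin.erase(lin.begin() + i);
      else { lin[i].segs = std::move(merged); lin[i].refresh(); }
    } else if (u < rate_c + rate_r) {
      // recombination: lineage chosen proportional to span, breakpoint uniform
      double v = unif_rand() * sum_span;
      size_t i = 0;
      for (; i + 1 < k; ++i) { v -= lin[i].hi - lin[i].lo; if (v <= 0) break; }
      double x = lin[i].lo + unif_rand() * (lin[i].hi - lin[i].lo);
      std::vector<Seg> left, right;
      for (const Seg &s : lin[i].segs) {
        if (s.b <= x) left.push_back(s);
        else if (s.a >= x) right.push_back(s);
        else { left.push_back(Seg{s.a, x, s.d}); right.push_back(Seg{x, s.b, s.d}); }
      }
      if (left.empty() || right.empty()) continue;  // breakpoint outside material
      lin[i].segs = std::move(left); lin[i].refresh();
      Lineage nl; nl.segs = std::move(right); nl.refresh();
      lin.push_back(std::move(nl));
    } else {
      // mutation: lineage proportional to ancestral length, position uniform
      double v = unif_rand() * sum_tot;
      size_t i = 0;
      for (; i + 1 < k; ++i) { v -= lin[i].tot; if (v <= 0) break; }
      double w = unif_rand() * lin[i].tot;
      for (const Seg &s : lin[i].segs) {
        double len = s.b - s.a;
        if (w < len) { muts.push_back(Mutation{s.a + w, s.d}); break; }
        w -= len;
      }
    }
  }
}

List locus_to_R(int n, const std::vector<Mutation> &muts_in) {
  std::vector<Mutation> muts = muts_in;
  std::sort(muts.begin(), muts.end(),
            [](const Mutation &a, const Mutation &b) { return a.pos < b.pos; });
  int S = (int)muts.size();
  NumericVector pos(S);
  IntegerMatrix mat(n, S);
  for (int s = 0; s < S; ++s) {
    pos[s] = muts[s].pos;
    for (int i = 0; i < n; ++i)
      mat(i, s) = (muts[s].d >> i) & 1 ? 1 : 0;
  }
  return List::create(Named("positions") = pos, Named("states") = mat);
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate_dataset(int n, int L, int loci, double theta_bp, double rho_bp,
                          bool bottleneck, double bot_end, double bot_dur,
                          double bot_ne) {
  if (n < 2) stop("n must be >= 2");
  if (n > 64) stop("n must be <= 64");
  if (L < 1) stop("L must be >= 1");
  if (loci < 1) stop("loci must be >= 1");
  if (theta_bp < 0 || rho_bp < 0) stop("rates must be non-negative");
  double theta_locus = theta_bp * L;
  double rho_locus = (L > 1) ? rho_bp * (L - 1) : 0.0;
  Demog dem{bottleneck && bot_ne != 1.0, bot_end, bot_dur, bot_ne};

  RNGScope scope;
  List out(loci);
  for (int l = 0; l < loci; ++l) {
    std::vector<Mutation> muts;
    simulate_locus_core(n, theta_locus, rho_locus, dem, muts);
    out[l] = locus_to_R(n, muts);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Per-locus summary statistics.
// Columns: S, thetaW_bp, pi_bp, thetaH_bp, D, H, He, then folded minor-allele
// counts are binned separately (3 and 5 classes).  D, H and the SFS rows are
// NA when S = 0.

// [[Rcpp::export]]
NumericMatrix cpp_dataset_stats(List dataset, int n, double L) {
  int loci = dataset.size();
  const int NC = 15;  // 7 base stats + 3 + 5 sfs proportions
  NumericMatrix out(loci, NC);
  CharacterVector cn = CharacterVector::create(
      "S", "thetaW", "thetaPi", "thetaH", "D", "H", "He",
      "sfs3_1", "sfs3_2", "sfs3_3",
      "sfs5_1", "sfs5_2", "sfs5_3", "sfs5_4", "sfs5_5");
  colnames(out) = cn;

  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i <= n - 1; ++i) { a1 += 1.0 / i; a2 += 1.0 / (double(i) * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double npairs = n * (n - 1.0) / 2.0;

  for (int l = 0; l < loci; ++l) {
    List locus = dataset[l];
    IntegerMatrix mat = locus["states"];
    if (mat.nrow() != n) stop("locus %d: row count differs from n", l + 1);
    int Sall = mat.ncol();

    int S = 0;
    double pi_loc = 0.0, th_loc = 0.0;
    double sfs3[3] = {0, 0, 0}, sfs5[5] = {0, 0, 0, 0, 0};
    for (int s = 0; s < Sall; ++s) {
      int dc = 0;
      for (int i = 0; i < n; ++i) dc += mat(i, s);
      if (dc < 1 || dc > n - 1) continue;  // not segregating
      ++S;
      pi_loc += dc * double(n - dc) / npairs;          // 2 i (n-i) / (n(n-1))
      th_loc += 2.0 * double(dc) * dc / (n * (n - 1.0));
      double mf = std::min(dc, n - dc) / double(n);    // minor freq in (0, 0.5]
      int b3 = (int)std::ceil(mf * 6.0) - 1;           // equal bins of (0, 0.5]
      if (b3 < 0) b3 = 0; if (b3 > 2) b3 = 2;
      int b5 = (int)std::ceil(mf * 10.0) - 1;
      if (b5 < 0) b5 = 0; if (b5 > 4) b5 = 4;
      sfs3[b3] += 1.0; sfs5[b5] += 1.0;
    }

    // haplotype diversity over distinct row patterns
    double sumsq = 0.0;
    {
      std::vector<int> cnt(n, 0);
      std::vector<int> reps;
      for (int i = 0; i < n; ++i) {
        bool found = false;
        for (size_t r = 0; r < reps.size(); ++r) {
          int j = reps[r];
          bool eq = true;
          for (int s = 0; s < Sall && eq; ++s)
            if (mat(i, s) != mat(j, s)) eq = false;
          if (eq) { cnt[r]++; found = true; break; }
        }
        if (!found) { reps.push_back(i); cnt[reps.size() - 1] = 1; }
      }
      for (size_t r = 0; r < reps.size(); ++r) {
        double p = cnt[r] / double(n);
        sumsq += p * p;
      }
    }
    double He = (n / (n - 1.0)) * (1.0 - sumsq);

    out(l, 0) = S;
    out(l, 1) = S / (a1 * L);
    out(l, 2) = pi_loc / L;
    out(l, 3) = th_loc / L;
    if (S > 0) {
      double thW_loc = S / a1;
      double denom = std::sqrt(e1 * S + e2 * double(S) * (S - 1.0));
      out(l, 4) = (denom > 0) ? (pi_loc - thW_loc) / denom : NA_REAL;
      out(l, 5) = pi_loc - th_loc;
      for (int j = 0; j < 3; ++j) out(l, 7 + j) = sfs3[j] / S;
      for (int j = 0; j < 5; ++j) out(l, 10 + j) = sfs5[j] / S;
    } else {
      out(l, 4) = NA_REAL;
      out(l, 5) = NA_REAL;
      for (int j = 0; j < 8; ++j) out(l, 7 + j) = NA_REAL;
    }
    out(l, 6) = He;
  }
  return out;
}
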