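// Coalescent simulation engines: standard neutral (fixed-S / fixed-theta),
// ancestral recombination graph over [0,1), two-deme isolation-with-migration,
// and the two-locus sampler behind the composite-likelihood rho tables.
// Time units: neutral/ARG/two-locus in 2N generations (pair coalescence rate 1,
// mutations at theta/2 per lineage); IM in mutational units (pair coalescence
// rate 2/theta, mutations at rate 1 per lineage, divergence at t = T*u).
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

typedef std::mt19937_64 RNG;

// ---- descendant-set bitmask ------------------------------------------------
struct Mask {
  std::vector<uint64_t> w;
  Mask() {}
  Mask(int nwords) : w(nwords, 0ULL) {}
  void set(int i) { w[i >> 6] |= (1ULL << (i & 63)); }
  bool get(int i) const { return (w[i >> 6] >> (i & 63)) & 1ULL; }
  void orWith(const Mask& o) { for (size_t j = 0; j < w.size(); ++j) w[j] |= o.w[j]; }
  int count() const {
    int c = 0;
    for (uint64_t x : w) c += __builtin_popcountll(x);
    return c;
  }
  bool equal(const Mask& o) const { return w == o.w; }
};

static inline double rexp1(RNG& g, double rate) {
  std::exponential_distribution<double> d(rate);
  return d(g);
}
static inline double runif1(RNG& g) {
  std::uniform_real_distribution<double> d(0.0, 1.0);
  return d(g);
}
static inline int rint1(RNG& g, int n) { // uniform on 0..n-1
  std::uniform_int_distribution<int> d(0, n - 1);
  return d(g);
}
static inline int rpois1(RNG& g, double lambda) {
  if (lambda <= 0) return 0;
  std::poisson_distribution<int> d(lambda);
  return d(g);
}

// Tajima's D from n, S, mean pairwise differences
static double tajima_d_core(int n, int S, double k) {
  if (S <= 0 || n < 2) return NA_REAL;
  double a1 = 0, a2 = 0;
  for (int i = 1; i < n; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * (n * (double)n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double var = e1 * S + e2 * (double)S * (S - 1.0);
  if (var <= 0) return NA_REAL;
  return (k - S / a1) / std::sqrt(var);
}

// ---- fixed-S standard-neutral null for Tajima's D --------------------------
// Simulates Kingman genealogies for n tips; S mutations fall on branches in
// proportion to length; returns one D value per replicate.
// [[Rcpp::export]]
NumericVector cpp_tajima_null(int n, int S, int reps, int seed) {
  RNG g(seed);
  NumericVector out(reps);
  std::vector<int> sz(n);
  std::vector<double> wt(n); // wt[k] = branch length subtending k tips
  double cn2 = n * (n - 1.0) / 2.0;
  for (int r = 0; r < reps; ++r) {
    int k = n;
    for (int i = 0; i < n; ++i) sz[i] = 1;
    std::fill(wt.begin(), wt.end(), 0.0);
    while (k > 1) {
      double dt = rexp1(g, k * (k - 1.0) / 2.0);
      for (int i = 0; i < k; ++i) wt[sz[i]] += dt;
      int a = rint1(g, k), b = rint1(g, k - 1);
      if (b >= a) ++b;
      sz[a] += sz[b];
      sz[b] = sz[k - 1];
      --k;
    }
    double tot = 0;
    for (int c = 1; c < n; ++c) tot += wt[c];
    // place S mutations
    double pairsum = 0;
    for (int s = 0; s < S; ++s) {
      double u = runif1(g) * tot, acc = 0;
      int cls = n - 1;
      for (int c = 1; c < n; ++c) {
        acc += wt[c];
        if (u <= acc) { cls = c; break; }
      }
      pairsum += (double)cls * (n - cls);
    }
    out[r] = tajima_d_core(n, S, pairsum / cn2);
  }
  return out;
}

// ---- ARG machinery ---------------------------------------------------------
struct Seg { double a, b; Mask m; };
struct Lin { std::vector<Seg> segs; };

static bool mask_full(const Mask& m, int n) { return m.count() == n; }

static double live_len(const Lin& L) {
  double s = 0;
  for (const Seg& sg : L.segs) s += sg.b - sg.a;
  return s;
}
static double span_len(const Lin& L) {
  if (L.segs.empty()) return 0;
  return L.segs.back().b - L.segs.front().a;
}

// overlay-merge two segment lists, unioning masks; drop full (MRCA) segments
static Lin merge_lin(const Lin& A, const Lin& B, int n) {
  std::vector<double> pts;
  for (const Seg& s : A.segs) { pts.push_back(s.a); pts.push_back(s.b); }
  for (const Seg& s : B.segs) { pts.push_back(s.a); pts.push_back(s.b); }
  std::sort(pts.begin(), pts.end());
  pts.erase(std::unique(pts.begin(), pts.end()), pts.end());
  Lin out;
  size_t ia = 0, ib = 0;
  for (size_t p = 0; p + 1 < pts.size(); ++p) {
    double lo = pts[p], hi = pts[p + 1];
    double mid = 0.5 * (lo + hi);
    const Mask* ma = nullptr;
    const Mask* mb = nullptr;
    while (ia < A.segs.size() && A.segs[ia].b <= mid) ++ia;
    if (ia < A.segs.size() && A.segs[ia].a < mid && mid < A.segs[ia].b) ma = &A.segs[ia].m;
    while (ib < B.segs.size() && B.segs[ib].b <= mid) ++ib;
    if (ib < B.segs.size() && B.segs[ib].a < mid && mid < B.segs[ib].b) mb = &B.segs[ib].m;
    if (!ma && !mb) continue;
    Mask m = ma ? *ma : *mb;
    if (ma && mb) m.orWith(*mb);
    if (mask_full(m, n)) continue;
    if (!out.segs.empty() && out.segs.back().b == lo && out.segs.back().m.equal(m)) {
      out.segs.back().b = hi; // coalesce adjacent identical-mask segments
    } else {
      out.segs.push_back(Seg{lo, hi, m});
    }
  }
  return out;
}

// ---- standard-neutral sample (optional recombination) ----------------------
// mode: fixed_S >= 0 requires rho == 0; otherwise theta mode.
// Returns positions in [0,1) and an n x S 0/1 genotype matrix.
// [[Rcpp::export]]
List cpp_sim_neutral(int n, double theta, int fixed_S, double rho, int seed) {
  RNG g(seed);
  int nwords = (n + 63) / 64;
  std::vector<std::pair<double, Mask>> muts; // (position, carriers)

  if (fixed_S >= 0) {
    if (rho != 0) stop("fixed-S conditioning is only supported without recombination");
    // single-segment genealogy with recorded (dt, mask) branch pieces
    std::vector<Mask> mk(n, Mask(nwords));
    for (int i = 0; i < n; ++i) mk[i].set(i);
    std::vector<std::pair<double, int>> rec; // (length, mask index)
    std::vector<Mask> pool = mk;
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    int k = n;
    double tot = 0;
    while (k > 1) {
      double dt = rexp1(g, k * (k - 1.0) / 2.0);
      for (int i = 0; i < k; ++i) { rec.push_back({dt, idx[i]}); tot += dt; }
      int a = rint1(g, k), b = rint1(g, k - 1);
      if (b >= a) ++b;
      Mask m = pool[idx[a]];
      m.orWith(pool[idx[b]]);
      pool.push_back(m);
      idx[a] = (int)pool.size() - 1;
      idx[b] = idx[k - 1];
      --k;
    }
    for (int s = 0; s < fixed_S; ++s) {
      double u = runif1(g) * tot, acc = 0;
      int chosen = rec.back().second;
      for (auto& pr : rec) {
        acc += pr.first;
        if (u <= acc) { chosen = pr.second; break; }
      }
      muts.push_back({runif1(g), pool[chosen]});
    }
  } else {
    // ARG with total recombination rate rho across [0,1)
    std::vector<Lin> lins(n);
    for (int i = 0; i < n; ++i) {
      Mask m(nwords);
      m.set(i);
      lins[i].segs.push_back(Seg{0.0, 1.0, m});
    }
    while (lins.size() > 1) {
      int k = (int)lins.size();
      double crate = k * (k - 1.0) / 2.0;
      double spansum = 0;
      for (const Lin& L : lins) spansum += span_len(L);
      double rrate = 0.5 * rho * spansum;
      double dt = rexp1(g, crate + rrate);
      // mutations during dt
      double llensum = 0;
      for (const Lin& L : lins) llensum += live_len(L);
      int nm = rpois1(g, 0.5 * theta * dt * llensum);
      for (int s = 0; s < nm; ++s) {
        double u = runif1(g) * llensum, acc = 0;
        for (const Lin& L : lins) {
          double ll = live_len(L);
          if (u <= acc + ll) {
            double v = u - acc;
            for (const Seg& sg : L.segs) {
              double sl = sg.b - sg.a;
              if (v <= sl) { muts.push_back({sg.a + v, sg.m}); break; }
              v -= sl;
            }
            break;
          }
          acc += ll;
        }
      }
      if (runif1(g) * (crate + rrate) < crate) { // coalescence
        int a = rint1(g, k), b = rint1(g, k - 1);
        if (b >= a) ++b;
        Lin m = merge_lin(lins[a], lins[b], n);
        lins[a] = m;
        lins[b] = lins[k - 1];
        lins.pop_back();
        // drop lineages with no live material
        for (int i = (int)lins.size() - 1; i >= 0; --i)
          if (lins[i].segs.empty()) { lins[i] = lins.back(); lins.pop_back(); }
      } else { // recombination
        double u = runif1(g) * spansum, acc = 0;
        int pick = k - 1;
        for (int i = 0; i < k; ++i) {
          acc += span_len(lins[i]);
          if (u <= acc) { pick = i; break; }
        }
        const Lin& L = lins[pick];
        double lo = L.segs.front().a, hi = L.segs.back().b;
        double x = lo + runif1(g) * (hi - lo);
        Lin left, right;
        for (const Seg& sg : L.segs) {
          if (sg.b <= x) left.segs.push_back(sg);
          else if (sg.a >= x) right.segs.push_back(sg);
          else {
            left.segs.push_back(Seg{sg.a, x, sg.m});
            right.segs.push_back(Seg{x, sg.b, sg.m});
          }
        }
        if (!left.segs.empty() && !right.segs.empty()) {
          lins[pick] = left;
          lins.push_back(right);
        }
      }
    }
  }
  std::sort(muts.begin(), muts.end(),
            [](const std::pair<double, Mask>& a, const std::pair<double, Mask>& b) {
              return a.first < b.first;
            });
  int S = (int)muts.size();
  NumericVector pos(S);
  IntegerMatrix G(n, S);
  for (int s = 0; s < S; ++s) {
    pos[s] = muts[s].first;
    for (int i = 0; i < n; ++i) G(i, s) = muts[s].second.get(i) ? 1 : 0;
  }
  return List::create(_["positions"] = pos, _["G"] = G);
}

// ---- two-deme IM coalescent ------------------------------------------------
// IMa scaling: theta = 4*N*u per locus, migration rates per mutation event
// (m1: lineages now in deme 1 trace back to deme 2), divergence t in
// mutational units. Mutations fall at rate `scale` per lineage per unit time.
struct IMSample { std::vector<Mask> muts; };

static void sim_im_core(int n1, int n2, double th1, double th2, double thA,
                        double m1, double m2, double tdiv, double scale,
                        RNG& g, IMSample& out) {
  int n = n1 + n2;
  int nwords = (n + 63) / 64;
  std::vector<Mask> mk;
  std::vector<int> deme;
  mk.reserve(2 * n);
  for (int i = 0; i < n; ++i) {
    Mask m(nwords);
    m.set(i);
    mk.push_back(m);
    deme.push_back(i < n1 ? 1 : 2);
  }
  double tau = 0;
  bool ancestral = (tdiv <= 0);
  if (ancestral) for (size_t i = 0; i < deme.size(); ++i) deme[i] = 0;
  while (mk.size() > 1) {
    int k = (int)mk.size();
    double rate;
    int k1 = 0, k2 = 0;
    if (!ancestral) {
      for (int d : deme) { if (d == 1) ++k1; else ++k2; }
      rate = k1 * (k1 - 1.0) / th1 + k2 * (k2 - 1.0) / th2 + k1 * m1 + k2 * m2;
    } else {
      rate = k * (k - 1.0) / thA;
    }
    double dt = (rate > 0) ? rexp1(g, rate) : R_PosInf;
    if (!ancestral && tau + dt > tdiv) { // cross the divergence time
      double step = tdiv - tau;
      int nm = rpois1(g, scale * step * k);
      for (int s = 0; s < nm; ++s) out.muts.push_back(mk[rint1(g, k)]);
      tau = tdiv;
      ancestral = true;
      for (size_t i = 0; i < deme.size(); ++i) deme[i] = 0;
      continue;
    }
    int nm = rpois1(g, scale * dt * k);
    for (int s = 0; s < nm; ++s) out.muts.push_back(mk[rint1(g, k)]);
    tau += dt;
    if (!ancestral) {
      double u = runif1(g) * rate;
      if (u < k1 * (k1 - 1.0) / th1) { // coalescence in deme 1
        int a = rint1(g, k1), b = rint1(g, k1 - 1);
        if (b >= a) ++b;
        // indices of deme-1 lineages
        std::vector<int> id;
        for (int i = 0; i < k; ++i) if (deme[i] == 1) id.push_back(i);
        mk[id[a]].orWith(mk[id[b]]);
        mk[id[b]] = mk[k - 1]; deme[id[b]] = deme[k - 1];
        mk.pop_back(); deme.pop_back();
      } else if (u < k1 * (k1 - 1.0) / th1 + k2 * (k2 - 1.0) / th2) {
        int a = rint1(g, k2), b = rint1(g, k2 - 1);
        if (b >= a) ++b;
        std::vector<int> id;
        for (int i = 0; i < k; ++i) if (deme[i] == 2) id.push_back(i);
        mk[id[a]].orWith(mk[id[b]]);
        mk[id[b]] = mk[k - 1]; deme[id[b]] = deme[k - 1];
        mk.pop_back(); deme.pop_back();
      } else if (u < k1 * (k1 - 1.0) / th1 + k2 * (k2 - 1.0) / th2 + k1 * m1) {
        // a deme-1 lineage jumps (backwards) to deme 2
        int a = rint1(g, k1);
        for (int i = 0, c = 0; i < k; ++i)
          if (deme[i] == 1 && c++ == a) { deme[i] = 2; break; }
      } else {
        int a = rint1(g, k2);
        for (int i = 0, c = 0; i < k; ++i)
          if (deme[i] == 2 && c++ == a) { deme[i] = 1; break; }
      }
    } else {
      int a = rint1(g, k), b = rint1(g, k - 1);
      if (b >= a) ++b;
      mk[a].orWith(mk[b]);
      mk[b] = mk[k - 1];
      mk.pop_back(); deme.pop_back();
    }
  }
}

// [[Rcpp::export]]
List cpp_sim_im(int n1, int n2, double th1, double th2, double thA,
                double m1, double m2, double tdiv, double scale, int seed) {
  RNG g(seed);
  IMSample smp;
  sim_im_core(n1, n2, th1, th2, thA, m1, m2, tdiv, scale, g, smp);
  int n = n1 + n2;
  int S = (int)smp.muts.size();
  NumericVector pos(S);
  for (int s = 0; s < S; ++s) pos[s] = runif1(g);
  IntegerVector ord(S);
  std::vector<int> o(S);
  for (int s = 0; s < S; ++s) o[s] = s;
  std::sort(o.begin(), o.end(), [&](int a, int b) { return pos[a] < pos[b]; });
  NumericVector pos2(S);
  IntegerMatrix G(n, S);
  for (int s = 0; s < S; ++s) {
    pos2[s] = pos[o[s]];
    for (int i = 0; i < n; ++i) G(i, s) = smp.muts[o[s]].get(i) ? 1 : 0;
  }
  IntegerVector dm(n);
  for (int i = 0; i < n; ++i) dm[i] = (i < n1) ? 1 : 2;
  return List::create(_["positions"] = pos2, _["G"] = G, _["deme"] = dm);
}

// ---- per-locus two-group summary statistics --------------------------------
// From derived-allele counts per group; all statistics are invariant to
// ancestral/derived relabelling, so they apply to unpolarized data as well.
// Order: S1 S2 pi1 pi2 D1 D2 pib Da Fst shared fixed priv1 priv2
static const int NSTAT = 13;

static void locus_stats_core(const std::vector<int>& k1, const std::vector<int>& k2,
                             int n1, int n2, double* st) {
  int S = (int)k1.size();
  double c1 = n1 * (n1 - 1.0) / 2.0, c2 = n2 * (n2 - 1.0) / 2.0;
  int S1 = 0, S2 = 0, sh = 0, fx = 0, p1 = 0, p2 = 0;
  double pw1 = 0, pw2 = 0, pwb = 0;
  for (int s = 0; s < S; ++s) {
    int a = k1[s], b = k2[s];
    bool poly1 = a > 0 && a < n1, poly2 = b > 0 && b < n2;
    if (poly1) { ++S1; pw1 += a * (double)(n1 - a); }
    if (poly2) { ++S2; pw2 += b * (double)(n2 - b); }
    pwb += a * (double)(n2 - b) + b * (double)(n1 - a);
    if (poly1 && poly2) ++sh;
    else if ((a == 0 && b == n2) || (a == n1 && b == 0)) ++fx;
    else if (poly1) ++p1;
    else if (poly2) ++p2;
  }
  double pi1 = (c1 > 0) ? pw1 / c1 : NA_REAL;
  double pi2 = (c2 > 0) ? pw2 / c2 : NA_REAL;
  double pib = pwb / ((double)n1 * n2);
  double d1 = tajima_d_core(n1, S1, pi1);
  double d2 = tajima_d_core(n2, S2, pi2);
  double da = pib - 0.5 * (pi1 + pi2);
  double fst = (pib > 0) ? 1.0 - 0.5 * (pi1 + pi2) / pib : NA_REAL;
  st[0] = S1; st[1] = S2; st[2] = pi1; st[3] = pi2; st[4] = d1; st[5] = d2;
  st[6] = pib; st[7] = da; st[8] = fst; st[9] = sh; st[10] = fx;
  st[11] = p1; st[12] = p2;
}

// [[Rcpp::export]]
NumericVector cpp_locus_stats(IntegerVector k1, IntegerVector k2, int n1, int n2) {
  std::vector<int> a(k1.begin(), k1.end()), b(k2.begin(), k2.end());
  NumericVector out(NSTAT);
  locus_stats_core(a, b, n1, n2, REAL(out));
  out.attr("names") = CharacterVector::create(
      "S1", "S2", "pi1", "pi2", "D1", "D2", "pib", "Da", "Fst",
      "shared", "fixed", "priv1", "priv2");
  return out;
}

// Light-weight IM core for summary statistics: lineages carry only their
// group-1 and total descendant counts, so mutations record allele counts
// directly (no bitmasks). Same model and rates as sim_im_core.
static void sim_im_counts(int n1, int n2, double th1, double th2, double thA,
                          double m1, double m2, double tdiv, double scale,
                          RNG& g, std::vector<int>& k1, std::vector<int>& k2) {
  k1.clear(); k2.clear();
  int n = n1 + n2;
  std::vector<int> c1(n), ct(n), deme(n);
  for (int i = 0; i < n; ++i) {
    c1[i] = (i < n1) ? 1 : 0;
    ct[i] = 1;
    deme[i] = (i < n1) ? 1 : 2;
  }
  int k = n;
  int kk1 = n1, kk2 = n2; // deme occupancy, maintained incrementally
  double tau = 0;
  bool ancestral = (tdiv <= 0);
  if (ancestral) for (int i = 0; i < n; ++i) deme[i] = 0;
  while (k > 1) {
    double r1 = 0, r2 = 0, rm1 = 0, rm2 = 0, rate;
    if (!ancestral) {
      r1 = kk1 * (kk1 - 1.0) / th1;
      r2 = kk2 * (kk2 - 1.0) / th2;
      rm1 = kk1 * m1; rm2 = kk2 * m2;
      rate = r1 + r2 + rm1 + rm2;
    } else {
      rate = k * (k - 1.0) / thA;
    }
    double dt = (rate > 0) ? rexp1(g, rate) : R_PosInf;
    double step = dt;
    bool crossing = false;
    if (!ancestral && tau + dt > tdiv) { step = tdiv - tau; crossing = true; }
    int nm = rpois1(g, scale * step * k);
    for (int s = 0; s < nm; ++s) {
      int i = rint1(g, k);
      k1.push_back(c1[i]);
      k2.push_back(ct[i] - c1[i]);
    }
    tau += step;
    if (crossing) {
      ancestral = true;
      for (int i = 0; i < k; ++i) deme[i] = 0;
      continue;
    }
    if (!ancestral) {
      double u = runif1(g) * rate;
      int dcoal = 0, dmig = 0;
      if (u < r1) dcoal = 1;
      else if (u < r1 + r2) dcoal = 2;
      else if (u < r1 + r2 + rm1) dmig = 1;
      else dmig = 2;
      if (dcoal) {
        int kd = (dcoal == 1) ? kk1 : kk2;
        int a = rint1(g, kd), b = rint1(g, kd - 1);
        if (b >= a) ++b;
        int ia = -1, ib = -1;
        for (int i = 0, c = 0; i < k; ++i) {
          if (deme[i] == dcoal) {
            if (c == a) ia = i;
            if (c == b) ib = i;
            ++c;
          }
        }
        c1[ia] += c1[ib]; ct[ia] += ct[ib];
        c1[ib] = c1[k - 1]; ct[ib] = ct[k - 1]; deme[ib] = deme[k - 1];
        --k;
        if (dcoal == 1) --kk1; else --kk2;
      } else {
        int kd = (dmig == 1) ? kk1 : kk2;
        int a = rint1(g, kd);
        for (int i = 0, c = 0; i < k; ++i)
          if (deme[i] == dmig && c++ == a) { deme[i] = (dmig == 1) ? 2 : 1; break; }
        if (dmig == 1) { --kk1; ++kk2; } else { --kk2; ++kk1; }
      }
    } else {
      int a = rint1(g, k), b = rint1(g, k - 1);
      if (b >= a) ++b;
      c1[a] += c1[b]; ct[a] += ct[b];
      c1[b] = c1[k - 1]; ct[b] = ct[k - 1]; deme[b] = deme[k - 1];
      --k;
    }
  }
}

// Simulate `reps` multilocus IM datasets and return, per replicate, the
// across-locus mean of each per-locus statistic followed by its across-locus
// standard deviation (NaN-aware, matching the R-side rule used for the
// observed data). The dispersion block separates migration from shared
// ancestral polymorphism, which the means alone confound.
// [[Rcpp::export]]
NumericMatrix cpp_im_summaries(NumericVector par, int n1, int n2,
                               NumericVector weights, int reps, int seed) {
  RNG g(seed);
  int L = weights.size();
  NumericMatrix out(reps, 2 * NSTAT);
  std::vector<int> k1, k2;
  double st[NSTAT];
  for (int r = 0; r < reps; ++r) {
    double acc[NSTAT] = {0}, acc2[NSTAT] = {0};
    int cnt[NSTAT] = {0};
    for (int l = 0; l < L; ++l) {
      sim_im_counts(n1, n2, par[0], par[1], par[2], par[3], par[4], par[5],
                    weights[l], g, k1, k2);
      locus_stats_core(k1, k2, n1, n2, st);
      for (int j = 0; j < NSTAT; ++j)
        if (!ISNAN(st[j])) {
          acc[j] += st[j];
          acc2[j] += st[j] * st[j];
          ++cnt[j];
        }
    }
    for (int j = 0; j < NSTAT; ++j) {
      double m = cnt[j] > 0 ? acc[j] / cnt[j] : 0.0;
      out(r, j) = m;
      double v = cnt[j] > 1 ? (acc2[j] - cnt[j] * m * m) / (cnt[j] - 1.0) : 0.0;
      out(r, NSTAT + j) = v > 0 ? std::sqrt(v) : 0.0;
    }
  }
  return out;
}

// ---- two-locus sampler for rho likelihood tables ---------------------------
// Two linked loci with recombination rate R (=4Nr) between them; one mutation
// conditioned onto each marginal tree in proportion to branch length.
// Returns reps x 4 matrix of haplotype counts (n11, n10, n01, n00).
// [[Rcpp::export]]
IntegerMatrix cpp_two_locus(int n, double R, int reps, int seed) {
  RNG g(seed);
  int nwords = (n + 63) / 64;
  IntegerMatrix out(reps, 4);
  struct TL { Mask a, b; bool hasA, hasB; };
  for (int r = 0; r < reps; ++r) {
    std::vector<TL> lin(n);
    for (int i = 0; i < n; ++i) {
      lin[i].a = Mask(nwords); lin[i].b = Mask(nwords);
      lin[i].a.set(i); lin[i].b.set(i);
      lin[i].hasA = lin[i].hasB = true;
    }
    bool doneA = false, doneB = false;
    // reservoir sampling of one mutation per locus, weight = branch length
    double WA = 0, WB = 0;
    Mask chosenA, chosenB;
    while (!(doneA && doneB)) {
      int k = (int)lin.size();
      int nboth = 0;
      for (const TL& t : lin) if (t.hasA && t.hasB) ++nboth;
      double crate = k * (k - 1.0) / 2.0;
      double rrate = 0.5 * R * nboth;
      double dt = rexp1(g, crate + rrate);
      for (const TL& t : lin) {
        if (t.hasA && !doneA && !mask_full(t.a, n)) {
          WA += dt;
          if (runif1(g) < dt / WA) chosenA = t.a;
        }
        if (t.hasB && !doneB && !mask_full(t.b, n)) {
          WB += dt;
          if (runif1(g) < dt / WB) chosenB = t.b;
        }
      }
      if (runif1(g) * (crate + rrate) < crate) {
        int a = rint1(g, k), b = rint1(g, k - 1);
        if (b >= a) ++b;
        if (lin[b].hasA) {
          if (lin[a].hasA) lin[a].a.orWith(lin[b].a);
          else lin[a].a = lin[b].a;
          lin[a].hasA = true;
        }
        if (lin[b].hasB) {
          if (lin[a].hasB) lin[a].b.orWith(lin[b].b);
          else lin[a].b = lin[b].b;
          lin[a].hasB = true;
        }
        lin[b] = lin.back();
        lin.pop_back();
      } else {
        int pick = rint1(g, nboth);
        for (size_t i = 0, c = 0; i < lin.size(); ++i) {
          if (lin[i].hasA && lin[i].hasB && (int)c++ == pick) {
            TL nw;
            nw.a = Mask(nwords); nw.b = lin[i].b;
            nw.hasA = false; nw.hasB = true;
            lin[i].hasB = false;
            lin.push_back(nw);
            break;
          }
        }
      }
      // drop finished material
      for (int i = (int)lin.size() - 1; i >= 0; --i) {
        TL& t = lin[i];
        if (t.hasA && mask_full(t.a, n)) t.hasA = false;
        if (t.hasB && mask_full(t.b, n)) t.hasB = false;
        if (!t.hasA && !t.hasB) { lin[i] = lin.back(); lin.pop_back(); }
      }
      // check completion: locus done when a full mask was formed, i.e. no
      // lineage carries live material for it any more
      doneA = true; doneB = true;
      for (const TL& t : lin) {
        if (t.hasA) doneA = false;
        if (t.hasB) doneB = false;
      }
    }
    int n11 = 0, n10 = 0, n01 = 0;
    for (int i = 0; i < n; ++i) {
      bool da = chosenA.get(i), db = chosenB.get(i);
      if (da && db) ++n11;
      else if (da) ++n10;
      else if (db) ++n01;
    }
    out(r, 0) = n11; out(r, 1) = n10; out(r, 2) = n01;
    out(r, 3) = n - n11 - n10 - n01;
  }
  return out;
}
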