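#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels shared by every module.
// Conventions: a gap of length k costs gap_open + k * gap_extend (both
// parameters negative); alignments never end in a gap state (trailing gaps
// cannot improve a score under negative gap costs, and the jump DP relies
// on match-state endpoints). All reported coordinates are 0-based
// half-open. Scores are integers internally.
//
// Endpoint coordinates come from lean score-only forward passes; start
// coordinates are recovered by an anchored extension pass over the
// reversed prefixes, avoiding per-cell origin bookkeeping.

static const int NEG = -1073741824;  // -2^30: safe "minus infinity"

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;  // N and anything else: never matches
  }
}

static std::vector<int> encode(const std::string& s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
  return v;
}

struct Scores { int ma, mi, goe, ge; };

// Local alignment, score + end cell only. Ties: first (smallest i, then j).
static void sw_core(const std::vector<int>& q, const std::vector<int>& r,
                    const Scores& sc, int& best, int& bi, int& bj) {
  const int n = q.size(), m = r.size();
  best = 0; bi = 0; bj = 0;
  if (n == 0 || m == 0) return;
  std::vector<int> M(m + 1, NEG), E(m + 1, NEG), F(m + 1, NEG);
  std::vector<int> Mp(m + 1, NEG), Ep(m + 1, NEG), Fp(m + 1, NEG);
  for (int i = 1; i <= n; ++i) {
    std::swap(M, Mp); std::swap(E, Ep); std::swap(F, Fp);
    M[0] = E[0] = F[0] = NEG;
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      int s = (qi == r[j - 1] && qi != 4) ? sc.ma : sc.mi;
      int pre = Mp[j - 1];
      if (Ep[j - 1] > pre) pre = Ep[j - 1];
      if (Fp[j - 1] > pre) pre = Fp[j - 1];
      if (pre < 0) pre = 0;
      int mm = s + pre;
      M[j] = mm;
      int e = M[j - 1] + sc.goe, e2 = E[j - 1] + sc.ge;
      E[j] = e >= e2 ? e : e2;
      int f = Mp[j] + sc.goe, f2 = Fp[j] + sc.ge;
      F[j] = f >= f2 ? f : f2;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
  }
}

// Extension alignment anchored at (0,0): the first query/ref bases must be
// aligned to each other; no local restart. Reports the best-scoring cell.
// Running this on reversed prefixes ending at a known endpoint recovers the
// start of a local alignment.
static void ext_core(const std::vector<int>& q, const std::vector<int>& r,
                     const Scores& sc, int& best, int& bi, int& bj) {
  const int n = q.size(), m = r.size();
  best = NEG; bi = 0; bj = 0;
  if (n == 0 || m == 0) return;
  std::vector<int> M(m + 1, NEG), E(m + 1, NEG), F(m + 1, NEG);
  std::vector<int> Mp(m + 1, NEG), Ep(m + 1, NEG), Fp(m + 1, NEG);
  // cell (1,1) must align q[0] with r[0]
  for (int i = 1; i <= n; ++i) {
    std::swap(M, Mp); std::swap(E, Ep); std::swap(F, Fp);
    M[0] = E[0] = F[0] = NEG;
    const int qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      int s = (qi == r[j - 1] && qi != 4) ? sc.ma : sc.mi;
      int pre;
      if (i == 1 && j == 1) pre = 0;
      else {
        pre = Mp[j - 1];
        if (Ep[j - 1] > pre) pre = Ep[j - 1];
        if (Fp[j - 1] > pre) pre = Fp[j - 1];
      }
      int mm = pre <= NEG / 2 ? NEG : s + pre;
      M[j] = mm;
      int e = std::max(M[j - 1] + sc.goe, E[j - 1] + sc.ge);
      E[j] = M[j - 1] <= NEG / 2 && E[j - 1] <= NEG / 2 ? NEG : e;
      int f = std::max(Mp[j] + sc.goe, Fp[j] + sc.ge);
      F[j] = Mp[j] <= NEG / 2 && Fp[j] <= NEG / 2 ? NEG : f;
      if (mm > best) { best = mm; bi = i; bj = j; }
    }
  }
}

static std::vector<int> rev_prefix(const std::vector<int>& v, int end) {
  std::vector<int> out(end);
  for (int i = 0; i < end; ++i) out[i] = v[end - 1 - i];
  return out;
}

// [[Rcpp::export]]
List cpp_sw(std::string query, std::string ref,
            double match = 2.0, double mismatch = -4.0,
            double gap_open = -4.0, double gap_extend = -2.0) {
  std::vector<int> q = encode(query), r = encode(ref);
  Scores sc{(int)match, (int)mismatch, (int)(gap_open + gap_extend),
            (int)gap_extend};
  int best, bi, bj;
  sw_core(q, r, sc, best, bi, bj);
  if (best <= 0)
    return List::create(_["score"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["r_start"] = 0, _["r_end"] = 0);
  int b2, si, sj;
  ext_core(rev_prefix(q, bi), rev_prefix(r, bj), sc, b2, si, sj);
  return List::create(_["score"] = (double)best,
                      _["q_start"] = bi - si, _["q_end"] = bi,
                      _["r_start"] = bj - sj, _["r_end"] = bj);
}

// [[Rcpp::export]]
List cpp_sw_score(std::string query, std::string ref,
                  double match = 2.0, double mismatch = -4.0,
                  double gap_open = -4.0, double gap_extend = -2.0) {
  std::vector<int> q = encode(query), r = encode(ref);
  Scores sc{(int)match, (int)mismatch, (int)(gap_open + gap_extend),
            (int)gap_extend};
  int best, bi, bj;
  sw_core(q, r, sc, best, bi, bj);
  return List::create(_["score"] = (double)best, _["q_end"] = bi,
                      _["r_end"] = bj);
}

// ---------------------------------------------------------------------------
// Global / semi-global alignment with optional banding and full traceback.
// free_begin_* make leading unaligned sequence free. The alignment may end
// at the corner, in the last row (when free_end_r) or last column (when
// free_end_q); leftovers on both sequences at the same end are not allowed.
// Used for consensus column voting and monomer fitting.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_nw(std::string query, std::string ref,
            double match = 2.0, double mismatch = -4.0,
            double gap_open = -4.0, double gap_extend = -2.0,
            bool free_begin_q = false, bool free_begin_r = false,
            bool free_end_q = false, bool free_end_r = false,
            int band_offset = 0, int band_width = -1) {
  std::vector<int> q = encode(query), r = encode(ref);
  const int n = q.size(), m = r.size();
  Scores sc{(int)match, (int)mismatch, (int)(gap_open + gap_extend),
            (int)gap_extend};
  if (n == 0 || m == 0) {
    return List::create(_["score"] = 0.0, _["q_aln"] = "", _["r_aln"] = "",
                        _["identity"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["r_start"] = 0, _["r_end"] = 0);
  }
  int w = band_width;
  if (w < 0 || w > m + n) w = m + n;
  const long W = 2L * w + 1;

  std::vector<int> M((n + 1) * W, NEG), E((n + 1) * W, NEG),
      F((n + 1) * W, NEG);
  std::vector<unsigned char> Mt((n + 1) * W, 0), Et((n + 1) * W, 0),
      Ft((n + 1) * W, 0);

  auto idx = [&](int i, int j) -> long {
    return (long)i * W + (j - (i + band_offset - w));
  };
  auto inband = [&](int i, int j) {
    return j >= i + band_offset - w && j <= i + band_offset + w &&
           j >= 0 && j <= m;
  };
  auto lo = [&](int i) { int l = i + band_offset - w; return l < 0 ? 0 : l; };
  auto hi = [&](int i) { int h = i + band_offset + w; return h > m ? m : h; };

  for (int j = lo(0); j <= hi(0); ++j) {
    if (j == 0) { M[idx(0, 0)] = 0; }
    else if (free_begin_r) { M[idx(0, j)] = 0; }
    else { E[idx(0, j)] = sc.goe + (j - 1) * sc.ge; Et[idx(0, j)] = (j == 1) ? 1 : 2; }
  }
  for (int i = 1; i <= n; ++i) {
    const int qi = q[i - 1];
    for (int j = lo(i); j <= hi(i); ++j) {
      long c = idx(i, j);
      if (j == 0) {
        if (free_begin_q) { M[c] = 0; }
        else { F[c] = sc.goe + (i - 1) * sc.ge; Ft[c] = (i == 1) ? 1 : 3; }
        continue;
      }
      if (inband(i - 1, j - 1)) {
        long d = idx(i - 1, j - 1);
        int pre = M[d]; unsigned char t = 1;
        if (E[d] > pre) { pre = E[d]; t = 2; }
        if (F[d] > pre) { pre = F[d]; t = 3; }
        if (pre > NEG / 2) {
          int s = (qi == r[j - 1] && qi != 4) ? sc.ma : sc.mi;
          M[c] = s + pre; Mt[c] = t;
        }
      }
      if (inband(i, j - 1)) {
        long l = idx(i, j - 1);
        int eo = M[l] + sc.goe, ee = E[l] + sc.ge;
        if (eo >= ee) { if (M[l] > NEG / 2) { E[c] = eo; Et[c] = 1; } }
        else          { if (E[l] > NEG / 2) { E[c] = ee; Et[c] = 2; } }
      }
      if (inband(i - 1, j)) {
        long u = idx(i - 1, j);
        int fo = M[u] + sc.goe, fe = F[u] + sc.ge;
        if (fo >= fe) { if (M[u] > NEG / 2) { F[c] = fo; Ft[c] = 1; } }
        else          { if (F[u] > NEG / 2) { F[c] = fe; Ft[c] = 3; } }
      }
    }
  }

  int best = NEG, bi = n, bj = m; unsigned char bstate = 1;
  auto consider = [&](int i, int j) {
    if (!inband(i, j)) return;
    long c = idx(i, j);
    int v = M[c]; unsigned char st = 1;
    if (E[c] > v) { v = E[c]; st = 2; }
    if (F[c] > v) { v = F[c]; st = 3; }
    if (v > best) { best = v; bi = i; bj = j; bstate = st; }
  };
  consider(n, m);
  if (free_end_r) for (int j = 0; j < m; ++j) consider(n, j);
  if (free_end_q) for (int i = 0; i < n; ++i) consider(i, m);

  if (best <= NEG / 2) {
    return List::create(_["score"] = NA_REAL, _["q_aln"] = "", _["r_aln"] = "",
                        _["identity"] = 0.0, _["q_start"] = 0, _["q_end"] = 0,
                        _["r_start"] = 0, _["r_end"] = 0);
  }

  std::string qa, ra;
  int i = bi, j = bj; unsigned char st = bstate;
  int matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    long c = idx(i, j);
    if (st == 1) {
      if (i == 0 || j == 0) break;  // free-begin boundary init cell
      unsigned char t = Mt[c];
      if (t == 0) break;
      qa.push_back(query[i - 1]); ra.push_back(ref[j - 1]);
      ++cols; if (q[i - 1] == r[j - 1] && q[i - 1] != 4) ++matches;
      --i; --j; st = t;
    } else if (st == 2) {
      if (j == 0) break;
      unsigned char t = Et[c];
      qa.push_back('-'); ra.push_back(ref[j - 1]); ++cols;
      --j; st = t;
    } else {
      if (i == 0) break;
      unsigned char t = Ft[c];
      qa.push_back(query[i - 1]); ra.push_back('-'); ++cols;
      --i; st = t;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ra.begin(), ra.end());
  double ident = cols > 0 ? (double)matches / cols : 0.0;
  return List::create(_["score"] = (double)best, _["q_aln"] = qa,
                      _["r_aln"] = ra, _["identity"] = ident,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["r_start"] = j, _["r_end"] = bj);
}

// ---------------------------------------------------------------------------
// Smith-Waterman with a one-time jump between two reference regions.
// Layer 1 is a standard local alignment of the query against ref1. A jump
// carries the best layer-1 prefix (ending in a match state at query row i')
// into layer 2 at any later row i, paying
// jump_penalty + per_inserted_base * (i - i' - 1); the skipped query bases
// form the inserted sequence. Layer 2 extends over ref2 only. The returned
// score also covers the no-jump alternatives, so it is never below a plain
// local alignment against either region alone.
// Tie-breaking favours the latest layer-1 end (maximal micro-homology
// attribution to breakpoint 1) and, within a row, the rightmost ref1
// column.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_jump_align(std::string query, std::string ref1, std::string ref2,
                    double match = 2.0, double mismatch = -4.0,
                    double gap_open = -4.0, double gap_extend = -2.0,
                    double jump_penalty = 0.0, double per_inserted_base = 0.0) {
  std::vector<int> q = encode(query), r1 = encode(ref1), r2 = encode(ref2);
  const int n = q.size(), m1 = r1.size(), m2 = r2.size();
  Scores sc{(int)match, (int)mismatch, (int)(gap_open + gap_extend),
            (int)gap_extend};
  const int jp = (int)jump_penalty, pb = (int)per_inserted_base;

  // ---- layer 1: lean local SW vs ref1, tracking per-row best M cell ----
  std::vector<int> rowbest(n + 1, NEG), rowj(n + 1, 0);
  int best1 = 0, b1i = 0, b1j = 0;
  {
    std::vector<int> M(m1 + 1, NEG), E(m1 + 1, NEG), F(m1 + 1, NEG);
    std::vector<int> Mp(m1 + 1, NEG), Ep(m1 + 1, NEG), Fp(m1 + 1, NEG);
    for (int i = 1; i <= n; ++i) {
      std::swap(M, Mp); std::swap(E, Ep); std::swap(F, Fp);
      M[0] = E[0] = F[0] = NEG;
      const int qi = q[i - 1];
      int rb = NEG, rbj = 0;
      for (int j = 1; j <= m1; ++j) {
        int s = (qi == r1[j - 1] && qi != 4) ? sc.ma : sc.mi;
        int pre = Mp[j - 1];
        if (Ep[j - 1] > pre) pre = Ep[j - 1];
        if (Fp[j - 1] > pre) pre = Fp[j - 1];
        if (pre < 0) pre = 0;
        int mm = s + pre;
        M[j] = mm;
        int e = M[j - 1] + sc.goe, e2 = E[j - 1] + sc.ge;
        E[j] = e >= e2 ? e : e2;
        int f = Mp[j] + sc.goe, f2 = Fp[j] + sc.ge;
        F[j] = f >= f2 ? f : f2;
        if (mm > 0 && mm >= rb) { rb = mm; rbj = j; }  // ties: rightmost j
        if (mm > best1) { best1 = mm; b1i = i; b1j = j; }
      }
      rowbest[i] = rb; rowj[i] = rbj;
    }
  }

  // ---- jump carrier -----------------------------------------------------
  std::vector<int> Jpre(n + 1, NEG), Jsrc(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    int stay = Jpre[i - 1] <= NEG / 2 ? NEG : Jpre[i - 1] + pb;
    int take = rowbest[i] <= NEG / 2 ? NEG : rowbest[i] + jp;
    if (take >= stay) { Jpre[i] = take; Jsrc[i] = i; }  // ties: later i'
    else { Jpre[i] = stay; Jsrc[i] = Jsrc[i - 1]; }
  }

  // ---- layer 2: jump-tagged DP (payload: layer-1 end row, layer-2 start
  // cell encoded as (i-1) * (m2+1) + (j-1)), plus plain local for best2 ----
  int bestJ = NEG, bJi = 0, bJj = 0, bJend1 = 0; long bJstart2 = 0;
  int best2 = 0;
  {
    std::vector<int> Mj(m2 + 1, NEG), Ej(m2 + 1, NEG), Fj(m2 + 1, NEG);
    std::vector<int> Mjp(m2 + 1, NEG), Ejp(m2 + 1, NEG), Fjp(m2 + 1, NEG);
    std::vector<int> Pm1(m2 + 1, 0), Pe1(m2 + 1, 0), Pf1(m2 + 1, 0);
    std::vector<int> Pm1p(m2 + 1, 0), Pe1p(m2 + 1, 0), Pf1p(m2 + 1, 0);
    std::vector<long> Pm2(m2 + 1, 0), Pe2(m2 + 1, 0), Pf2(m2 + 1, 0);
    std::vector<long> Pm2p(m2 + 1, 0), Pe2p(m2 + 1, 0), Pf2p(m2 + 1, 0);
    std::vector<int> M2(m2 + 1, NEG), E2(m2 + 1, NEG), F2(m2 + 1, NEG);
    std::vector<int> M2p(m2 + 1, NEG), E2p(m2 + 1, NEG), F2p(m2 + 1, NEG);
    for (int i = 1; i <= n; ++i) {
      std::swap(Mj, Mjp); std::swap(Ej, Ejp); std::swap(Fj, Fjp);
      std::swap(Pm1, Pm1p); std::swap(Pe1, Pe1p); std::swap(Pf1, Pf1p);
      std::swap(Pm2, Pm2p); std::swap(Pe2, Pe2p); std::swap(Pf2, Pf2p);
      std::swap(M2, M2p); std::swap(E2, E2p); std::swap(F2, F2p);
      Mj[0] = Ej[0] = Fj[0] = NEG;
      M2[0] = E2[0] = F2[0] = NEG;
      const int qi = q[i - 1];
      const int entry = Jpre[i - 1];      // layer 1 must be non-empty
      const int esrc = Jsrc[i - 1];
      for (int j = 1; j <= m2; ++j) {
        int s = (qi == r2[j - 1] && qi != 4) ? sc.ma : sc.mi;
        // jump-tagged M: ties on equal predecessor favour a fresh jump
        // (latest layer-1 end)
        int pre = entry <= NEG / 2 ? NEG : entry;
        int p1 = esrc; long p2 = (long)(i - 1) * (m2 + 1) + (j - 1);
        if (Mjp[j - 1] > pre) { pre = Mjp[j - 1]; p1 = Pm1p[j - 1]; p2 = Pm2p[j - 1]; }
        if (Ejp[j - 1] > pre) { pre = Ejp[j - 1]; p1 = Pe1p[j - 1]; p2 = Pe2p[j - 1]; }
        if (Fjp[j - 1] > pre) { pre = Fjp[j - 1]; p1 = Pf1p[j - 1]; p2 = Pf2p[j - 1]; }
        int mm = pre <= NEG / 2 ? NEG : s + pre;
        Mj[j] = mm; Pm1[j] = p1; Pm2[j] = p2;
        int eo = Mj[j - 1] + sc.goe, ee = Ej[j - 1] + sc.ge;
        if (eo >= ee) { Ej[j] = Mj[j - 1] <= NEG / 2 ? NEG : eo;
                        Pe1[j] = Pm1[j - 1]; Pe2[j] = Pm2[j - 1]; }
        else          { Ej[j] = ee; Pe1[j] = Pe1[j - 1]; Pe2[j] = Pe2[j - 1]; }
        int fo = Mjp[j] + sc.goe, fe = Fjp[j] + sc.ge;
        if (fo >= fe) { Fj[j] = Mjp[j] <= NEG / 2 ? NEG : fo;
                        Pf1[j] = Pm1p[j]; Pf2[j] = Pm2p[j]; }
        else          { Fj[j] = fe; Pf1[j] = Pf1p[j]; Pf2[j] = Pf2p[j]; }
        if (mm > NEG / 2 && mm > bestJ) {
          bestJ = mm; bJi = i; bJj = j; bJend1 = p1; bJstart2 = p2;
        }
        // plain local on ref2
        int pre2 = M2p[j - 1];
        if (E2p[j - 1] > pre2) pre2 = E2p[j - 1];
        if (F2p[j - 1] > pre2) pre2 = F2p[j - 1];
        if (pre2 < 0) pre2 = 0;
        int mm2 = s + pre2;
        M2[j] = mm2;
        int e2o = M2[j - 1] + sc.goe, e2e = E2[j - 1] + sc.ge;
        E2[j] = e2o >= e2e ? e2o : e2e;
        int f2o = M2p[j] + sc.goe, f2e = F2p[j] + sc.ge;
        F2[j] = f2o >= f2e ? f2o : f2e;
        if (mm2 > best2) best2 = mm2;
      }
    }
  }

  int score = std::max(best1, std::max(best2, bestJ));
  bool jumped = bestJ > NEG / 2 && bestJ >= best1 && bestJ >= best2;

  int q_end1 = 0, r1_end = 0, q_start1 = 0, r1_start = 0;
  int q_start2 = 0, r2_start = 0;
  if (bestJ > NEG / 2) {
    q_end1 = bJend1;
    r1_end = rowj[bJend1];
    q_start2 = (int)(bJstart2 / (m2 + 1));
    r2_start = (int)(bJstart2 % (m2 + 1));
    int b, si, sj;
    ext_core(rev_prefix(q, q_end1), rev_prefix(r1, r1_end), sc, b, si, sj);
    q_start1 = q_end1 - si; r1_start = r1_end - sj;
  }
  int b1_qs = 0, b1_rs = 0;
  if (best1 > 0) {
    int b, si, sj;
    ext_core(rev_prefix(q, b1i), rev_prefix(r1, b1j), sc, b, si, sj);
    b1_qs = b1i - si; b1_rs = b1j - sj;
  }

  return List::create(
      _["score"] = (double)score, _["jumped"] = jumped,
      _["jump_score"] = bestJ > NEG / 2 ? (double)bestJ : NA_REAL,
      _["score_ref1_only"] = (double)best1, _["score_ref2_only"] = (double)best2,
      _["q_start1"] = q_start1, _["q_end1"] = q_end1,
      _["r1_start"] = r1_start, _["r1_end"] = r1_end,
      _["q_start2"] = q_start2, _["q_end2"] = bJi,
      _["r2_start"] = r2_start, _["r2_end"] = bJj,
      _["best1_q_start"] = b1_qs, _["best1_q_end"] = b1i,
      _["best1_r_start"] = b1_rs, _["best1_r_end"] = b1j);
}
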