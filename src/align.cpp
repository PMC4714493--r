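#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Shared alignment kernels. Conventions:
//  - amino-acid alphabet order "ACDEFGHIKLMNPQRSTVWY" for profile matrices;
//    'X' (and anything unknown) scores 0 against every profile column.
//  - gap penalties follow the BLAST convention: a gap of length k costs
//    open + k * ext (so the first gapped position costs open + ext).
//  - all reported spans are 1-based inclusive.

static const std::string AA20 = "ACDEFGHIKLMNPQRSTVWY";
static const double NEG_INF = -1e30;

static inline int aa_idx(char c) {
  switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;
    case 'E': return 3;  case 'F': return 4;  case 'G': return 5;
    case 'H': return 6;  case 'I': return 7;  case 'K': return 8;
    case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14;
    case 'S': return 15; case 'T': return 16; case 'V': return 17;
    case 'W': return 18; case 'Y': return 19;
    default: return -1;
  }
}

// ---------------------------------------------------------------------------
// Local profile/sequence Smith-Waterman with affine gaps.
// prof: 20 x L matrix of per-column log-odds (rows in AA20 order).
// Gap columns (deletions) and inserted residues are penalized; matches to
// unknown residues score 0. Returns the best local segment and its span.
// [[Rcpp::export(name = ".cpp_profile_sw")]]
List cpp_profile_sw(NumericMatrix prof, std::string seq,
                    double gap_open, double gap_ext) {
  const int L = prof.ncol();     // profile columns
  const int n = (int) seq.size();
  const double go = gap_open + gap_ext, ge = gap_ext;

  std::vector<double> Mprev(n + 1, NEG_INF), Xprev(n + 1, NEG_INF);
  std::vector<double> Mcur(n + 1), Xcur(n + 1), Ycur(n + 1);
  // origins: column/residue where the local alignment started (1-based)
  std::vector<int> oMpI(n + 1, 0), oMpJ(n + 1, 0), oXpI(n + 1, 0), oXpJ(n + 1, 0);
  std::vector<int> oMcI(n + 1, 0), oMcJ(n + 1, 0), oXcI(n + 1, 0), oXcJ(n + 1, 0);
  std::vector<int> oYcI(n + 1, 0), oYcJ(n + 1, 0);
  std::vector<double> Yprev(n + 1, NEG_INF);
  std::vector<int> oYpI(n + 1, 0), oYpJ(n + 1, 0);

  std::vector<int> sidx(n);
  for (int j = 0; j < n; ++j) sidx[j] = aa_idx(seq[j]);

  double best = 0.0;
  int bi = 0, bj = 0, b0i = 0, b0j = 0;

  for (int i = 1; i <= L; ++i) {
    Mcur[0] = NEG_INF; Xcur[0] = NEG_INF; Ycur[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
      const int ai = sidx[j - 1];
      const double sub = (ai < 0) ? 0.0 : prof(ai, i - 1);
      // M: start fresh (0) or extend from any state at (i-1, j-1)
      double m = 0.0; int oi = i, oj = j;              // fresh start
      if (Mprev[j - 1] > m) { m = Mprev[j - 1]; oi = oMpI[j - 1]; oj = oMpJ[j - 1]; }
      if (Xprev[j - 1] > m) { m = Xprev[j - 1]; oi = oXpI[j - 1]; oj = oXpJ[j - 1]; }
      if (Yprev[j - 1] > m) { m = Yprev[j - 1]; oi = oYpI[j - 1]; oj = oYpJ[j - 1]; }
      Mcur[j] = m + sub; oMcI[j] = oi; oMcJ[j] = oj;
      // X: consume a profile column (gap in the sequence)
      double x = Mprev[j] - go; int xi = oMpI[j], xj = oMpJ[j];
      if (Xprev[j] - ge > x) { x = Xprev[j] - ge; xi = oXpI[j]; xj = oXpJ[j]; }
      Xcur[j] = x; oXcI[j] = xi; oXcJ[j] = xj;
      // Y: consume a residue (gap in the profile)
      double y = Mcur[j - 1] - go; int yi = oMcI[j - 1], yj = oMcJ[j - 1];
      if (Ycur[j - 1] - ge > y) { y = Ycur[j - 1] - ge; yi = oYcI[j - 1]; yj = oYcJ[j - 1]; }
      Ycur[j] = y; oYcI[j] = yi; oYcJ[j] = yj;

      if (Mcur[j] > best) { best = Mcur[j]; bi = i; bj = j; b0i = oMcI[j]; b0j = oMcJ[j]; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    std::swap(oMpI, oMcI); std::swap(oMpJ, oMcJ);
    std::swap(oXpI, oXcI); std::swap(oXpJ, oXcJ);
    std::swap(oYpI, oYcI); std::swap(oYpJ, oYcJ);
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["pstart"] = NA_INTEGER,
                        _["pend"] = NA_INTEGER, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER);
  }
  return List::create(_["score"] = best, _["pstart"] = b0i, _["pend"] = bi,
                      _["qstart"] = b0j, _["qend"] = bj);
}

// ---------------------------------------------------------------------------
// Global pairwise alignment, optionally with free end gaps, affine penalties
// and an arbitrary substitution matrix indexed via `alphabet`.
// Deterministic tie-breaking: diagonal (M) over gap-in-b (X, consumes a)
// over gap-in-a (Y, consumes b); endpoint scan order is fixed (see below).
// [[Rcpp::export(name = ".cpp_pair_align")]]
List cpp_pair_align(std::string a, std::string b, NumericMatrix submat,
                    std::string alphabet, double gap_open, double gap_ext,
                    bool free_ends) {
  const int m = (int) a.size(), n = (int) b.size();
  const double go = gap_open + gap_ext, ge = gap_ext;
  int cidx[256];
  std::fill(cidx, cidx + 256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k)
    cidx[(unsigned char) alphabet[k]] = (int) k;

  std::vector<int> ia(m), ib(n);
  for (int i = 0; i < m; ++i) {
    ia[i] = cidx[(unsigned char) a[i]];
    if (ia[i] < 0) stop("character '%s' not in alignment alphabet",
                        std::string(1, a[i]).c_str());
  }
  for (int j = 0; j < n; ++j) {
    ib[j] = cidx[(unsigned char) b[j]];
    if (ib[j] < 0) stop("character '%s' not in alignment alphabet",
                        std::string(1, b[j]).c_str());
  }

  const size_t sz = (size_t)(m + 1) * (n + 1);
  std::vector<double> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  auto at = [n](int i, int j) { return (size_t) i * (n + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    if (free_ends) M[at(i, 0)] = 0.0;             // free leading gap in b
    else X[at(i, 0)] = -(gap_open + i * ge);
  }
  for (int j = 1; j <= n; ++j) {
    if (free_ends) M[at(0, j)] = 0.0;             // free leading gap in a
    else Y[at(0, j)] = -(gap_open + j * ge);
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const double sub = submat(ia[i - 1], ib[j - 1]);
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)], dY = Y[at(i - 1, j - 1)];
      double dbest = dM;                           // tie-break: M, X, Y
      if (dX > dbest) dbest = dX;
      if (dY > dbest) dbest = dY;
      M[at(i, j)] = dbest + sub;
      double x1 = M[at(i - 1, j)] - go, x2 = X[at(i - 1, j)] - ge;
      X[at(i, j)] = (x1 >= x2) ? x1 : x2;
      double y1 = M[at(i, j - 1)] - go, y2 = Y[at(i, j - 1)] - ge;
      Y[at(i, j)] = (y1 >= y2) ? y1 : y2;
    }
  }

  // endpoint
  int ei = m, ej = n; char estate = 'M';
  double escore;
  auto cellbest = [&](int i, int j, char &st) {
    double v = M[at(i, j)]; st = 'M';
    if (X[at(i, j)] > v) { v = X[at(i, j)]; st = 'X'; }
    if (Y[at(i, j)] > v) { v = Y[at(i, j)]; st = 'Y'; }
    return v;
  };
  if (free_ends) {
    escore = NEG_INF;
    // scan bottom row then last column; among ties prefer the endpoint
    // consuming the most residues (largest i+j), favouring coverage
    const double ttol = 1e-6;
    for (int j = 0; j <= n; ++j) {
      char st; double v = cellbest(m, j, st);
      if (v > escore + ttol ||
          (v > escore - ttol && m + j > ei + ej)) {
        escore = v; ei = m; ej = j; estate = st;
      }
    }
    for (int i = 0; i < m; ++i) {
      char st; double v = cellbest(i, n, st);
      if (v > escore + ttol ||
          (v > escore - ttol && i + n > ei + ej)) {
        escore = v; ei = i; ej = n; estate = st;
      }
    }
  } else {
    escore = cellbest(m, n, estate);
  }

  // traceback from (ei, ej, estate) to a boundary
  std::string ra, rb;
  int i = ei, j = ej; char st = estate;
  const double tol = 1e-6;
  while (i > 0 || j > 0) {
    if (free_ends && (i == 0 || j == 0)) break;
    if (st == 'M') {
      if (i == 0 || j == 0) break;                 // penalized-global boundary
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      double need = M[at(i, j)] - submat(ia[i - 1], ib[j - 1]);
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)], dY = Y[at(i - 1, j - 1)];
      if (std::abs(dM - need) < tol) st = 'M';
      else if (std::abs(dX - need) < tol) st = 'X';
      else st = 'Y';
      --i; --j;
      if (free_ends && (i == 0 || j == 0) && std::abs(M[at(i, j)]) < tol && st == 'M')
        break;                                     // started fresh at boundary
    } else if (st == 'X') {
      ra.push_back(a[i - 1]); rb.push_back('-');
      if (std::abs(M[at(i - 1, j)] - go - X[at(i, j)]) < tol) st = 'M'; else st = 'X';
      --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      if (std::abs(M[at(i, j - 1)] - go - Y[at(i, j)]) < tol) st = 'M'; else st = 'Y';
      --j;
    }
  }
  int astart = i + 1, bstart = j + 1;              // first aligned position
  // pad penalized-global leading gaps
  if (!free_ends) {
    while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
    while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
    astart = 1; bstart = 1;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  // pad trailing end gaps for penalized-global so rows span both sequences
  if (!free_ends) {
    for (int k = ei; k < m; ++k) { ra.push_back(a[k]); rb.push_back('-'); }
    for (int k = ej; k < n; ++k) { ra.push_back('-'); rb.push_back(b[k]); }
    ei = m; ej = n;
  }

  // identity over aligned columns excluding terminal gap runs
  int lead = 0, trail = 0, cols = (int) ra.size();
  while (lead < cols && (ra[lead] == '-' || rb[lead] == '-')) ++lead;
  while (trail < cols - lead &&
         (ra[cols - 1 - trail] == '-' || rb[cols - 1 - trail] == '-')) ++trail;
  int core = cols - lead - trail, matches = 0, acore = 0, bcore = 0;
  for (int k = lead; k < cols - trail; ++k) {
    if (ra[k] != '-') ++acore;
    if (rb[k] != '-') ++bcore;
    if (ra[k] == rb[k] && ra[k] != '-') ++matches;
  }
  double identity = core > 0 ? (double) matches / core : 0.0;
  double cov_a = m > 0 ? (double) acore / m : 0.0;
  double cov_b = n > 0 ? (double) bcore / n : 0.0;

  return List::create(_["score"] = escore, _["aligned_a"] = ra,
                      _["aligned_b"] = rb, _["identity"] = identity,
                      _["coverage_a"] = cov_a, _["coverage_b"] = cov_b,
                      _["matches"] = matches, _["columns"] = core,
                      _["astart"] = astart, _["aend"] = ei,
                      _["bstart"] = bstart, _["bend"] = ej);
}

// ---------------------------------------------------------------------------
// blastn-like ungapped seed-and-extend HSP finder (one orientation).
// Exact word seeds (default 11), X-drop ungapped extension, per-diagonal
// overlap merging. N (or any non-ACGT) never seeds and counts as a mismatch.
// [[Rcpp::export(name = ".cpp_find_hsps")]]
DataFrame cpp_find_hsps(std::string q, std::string s, int word,
                        double match, double mismatch, double xdrop) {
  const int nq = (int) q.size(), ns = (int) s.size();
  std::vector<int> qc(nq), sc(ns);
  auto ntcode = [](char c) {
    switch (c) { case 'A': return 0; case 'C': return 1;
                 case 'G': return 2; case 'T': return 3; default: return -1; }
  };
  for (int i = 0; i < nq; ++i) qc[i] = ntcode(q[i]);
  for (int i = 0; i < ns; ++i) sc[i] = ntcode(s[i]);

  struct Hsp { int qs, qe, ss, se; };              // 0-based half-open
  std::vector<Hsp> raw;

  if (nq >= word && ns >= word) {
    // index subject words (2-bit packed)
    std::unordered_map<uint64_t, std::vector<int> > index;
    index.reserve((size_t) ns);
    uint64_t key = 0; int run = 0;
    const uint64_t mask = (word >= 32) ? ~0ULL : ((1ULL << (2 * word)) - 1);
    for (int i = 0; i < ns; ++i) {
      if (sc[i] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) sc[i]) & mask;
      if (++run >= word) index[key].push_back(i - word + 1);
    }
    // per-diagonal high-water mark of extension end on the query
    std::vector<int> diag_end(nq + ns + 1, -1);
    key = 0; run = 0;
    for (int i = 0; i < nq; ++i) {
      if (qc[i] < 0) { run = 0; key = 0; continue; }
      key = ((key << 2) | (uint64_t) qc[i]) & mask;
      if (++run < word) continue;
      auto it = index.find(key);
      if (it == index.end()) continue;
      const int qpos = i - word + 1;
      for (int spos : it->second) {
        const int d = qpos - spos + ns;            // diagonal id, >= 0
        if (qpos <= diag_end[d]) continue;         // already inside an HSP
        // extend right from seed end
        int qi = qpos + word, si = spos + word;
        double sc_run = word * match, bestsc = sc_run;
        int bqe = qi, bse = si;
        while (qi < nq && si < ns) {
          sc_run += (qc[qi] >= 0 && qc[qi] == sc[si]) ? match : mismatch;
          ++qi; ++si;
          if (sc_run > bestsc) { bestsc = sc_run; bqe = qi; bse = si; }
          else if (bestsc - sc_run > xdrop) break;
        }
        // extend left from seed start
        int qj = qpos, sj = spos;
        sc_run = bestsc; double bestsc2 = bestsc;
        int bqs = qpos, bss = spos;
        while (qj > 0 && sj > 0) {
          --qj; --sj;
          sc_run += (qc[qj] >= 0 && qc[qj] == sc[sj]) ? match : mismatch;
          if (sc_run > bestsc2) { bestsc2 = sc_run; bqs = qj; bss = sj; }
          else if (bestsc2 - sc_run > xdrop) break;
        }
        raw.push_back({bqs, bqe, bss, bse});
        diag_end[d] = bqe - 1;
      }
    }
  }

  // merge overlapping/adjacent HSPs on the same diagonal
  std::sort(raw.begin(), raw.end(), [ns](const Hsp &a, const Hsp &b) {
    int da = a.qs - a.ss, db = b.qs - b.ss;
    if (da != db) return da < db;
    return a.qs < b.qs;
  });
  std::vector<Hsp> merged;
  for (const Hsp &h : raw) {
    if (!merged.empty()) {
      Hsp &c = merged.back();
      if (c.qs - c.ss == h.qs - h.ss && h.qs <= c.qe) {
        if (h.qe > c.qe) { c.qe = h.qe; c.se = h.se; }
        continue;
      }
    }
    merged.push_back(h);
  }

  const int nh = (int) merged.size();
  IntegerVector qstart(nh), qend(nh), sstart(nh), send(nh), length(nh), nmatch(nh);
  NumericVector score(nh), identity(nh);
  for (int k = 0; k < nh; ++k) {
    const Hsp &h = merged[k];
    int len = h.qe - h.qs, mt = 0;
    for (int t = 0; t < len; ++t)
      if (qc[h.qs + t] >= 0 && qc[h.qs + t] == sc[h.ss + t]) ++mt;
    qstart[k] = h.qs + 1; qend[k] = h.qe;
    sstart[k] = h.ss + 1; send[k] = h.se;
    length[k] = len; nmatch[k] = mt;
    identity[k] = len > 0 ? (double) mt / len : 0.0;
    score[k] = mt * match + (len - mt) * mismatch;
  }
  return DataFrame::create(_["qstart"] = qstart, _["qend"] = qend,
                           _["sstart"] = sstart, _["send"] = send,
                           _["length"] = length, _["matches"] = nmatch,
                           _["identity"] = identity, _["score"] = score,
                           _["stringsAsFactors"] = false);
}
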