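// Translated seed-and-extend homology search.
//
// Queries are translated in all six frames (stops rendered '*'); exact
// amino-acid k-mer seeds (default k = 4) against the database are extended
// first ungapped with an X-drop, and subject/frame pairs whose best
// ungapped extension reaches a trigger score get a banded gapped
// Smith-Waterman around the seed diagonal. Raw scores are converted to
// bit scores and Karlin-Altschul E-values on the R side.

#include <Rcpp.h>
#include <unordered_map>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// standard genetic code over ACGT-ordered codon index a*16 + b*4 + c
static const char GENCODE[65] =
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline int nt2i(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}
static inline char ntcmpl(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string translate_frame(const std::string &nt, int frame) {
  std::string s = nt;
  if (frame < 0) {
    s.assign(nt.rbegin(), nt.rend());
    for (auto &c : s) c = ntcmpl(c);
  }
  int off = std::abs(frame) - 1;
  int n = ((int)s.size() - off) / 3;
  std::string aa(std::max(n, 0), 'X');
  for (int i = 0; i < n; i++) {
    int b1 = nt2i(s[off + 3 * i]), b2 = nt2i(s[off + 3 * i + 1]),
        b3 = nt2i(s[off + 3 * i + 2]);
    aa[i] = (b1 < 0 || b2 < 0 || b3 < 0) ? 'X'
                                         : GENCODE[b1 * 16 + b2 * 4 + b3];
  }
  return aa;
}

// [[Rcpp::export]]
CharacterVector cpp_translate(CharacterVector nt, IntegerVector frames) {
  int n = nt.size();
  CharacterVector out(n);
  for (int i = 0; i < n; i++)
    out[i] = translate_frame(as<std::string>(nt[i]),
                             frames[i % frames.size()]);
  return out;
}

// ---------------------------------------------------------------------------

struct SubMat {
  int lut[256];      // char -> matrix row, -1 unknown (scored as X)
  int xrow;          // row index of 'X'
  std::vector<int> m; // nrow x nrow
  int n;
  int score(char a, char b) const {
    int i = lut[(unsigned char)a], j = lut[(unsigned char)b];
    if (i < 0) i = xrow;
    if (j < 0) j = xrow;
    return m[i * n + j];
  }
};

static SubMat make_submat(IntegerMatrix sm) {
  SubMat s;
  s.n = sm.nrow();
  s.m.resize(s.n * s.n);
  for (int i = 0; i < s.n; i++)
    for (int j = 0; j < s.n; j++) s.m[i * s.n + j] = sm(i, j);
  for (int i = 0; i < 256; i++) s.lut[i] = -1;
  CharacterVector rn = rownames(sm);
  s.xrow = 0;
  for (int i = 0; i < s.n; i++) {
    char c = CHAR(STRING_ELT(rn, i))[0];
    s.lut[(unsigned char)c] = i;
    if (c == 'X') s.xrow = i;
  }
  return s;
}

static inline int aa20(char c) {
  static const char *A = "ARNDCQEGHILKMFPSTWYV";
  const char *p = std::strchr(A, c);
  return p ? (int)(p - A) : -1;
}

struct Aln {
  int score = 0, matches = 0, alnlen = 0;
  int qstart = 0, qend = 0, sstart = 0, send = 0;
  bool valid = false;
};

// banded affine local alignment of q vs s, band centred on diagonal d0
// (diagonal d = j - i for q position i, s position j), half-width `band`.
// gap of length k costs gap_open + k * gap_extend.
static Aln banded_sw(const std::string &q, const std::string &s,
                     const SubMat &sub, int gap_open, int gap_extend,
                     int d0, int band) {
  const int NEG = -1000000000;
  int m = (int)q.size(), n = (int)s.size();
  int W = 2 * band + 1;
  // only query rows whose band window intersects the subject are reachable
  int row_lo = std::max(1, 1 - d0 - band), row_hi = std::min(m, n - d0 + band);
  if (row_lo > row_hi) return Aln();
  int R = row_hi - row_lo + 2; // + boundary row row_lo - 1
  auto rix = [&](int i) { return i - (row_lo - 1); };
  std::vector<int> H(R * W, 0), E(R * W, NEG), F(R * W, NEG);
  std::vector<unsigned char> tb(R * W, 0); // 0 stop, 1 diag, 2 up(E), 3 left(F)
  std::vector<unsigned char> tbe(R * W, 0), tbf(R * W, 0);
  auto col = [&](int i, int j) { return j - (i + d0 - band); }; // band slot
  int best = 0, bi = -1, bj = -1;
  for (int i = row_lo; i <= row_hi; i++) {
    int jlo = std::max(1, i + d0 - band), jhi = std::min(n, i + d0 + band);
    for (int j = jlo; j <= jhi; j++) {
      int w = col(i, j);
      int idx = rix(i) * W + w;
      // E: gap in subject direction (consume query) from row i-1, same j
      int wE = col(i - 1, j);
      int e = NEG;
      unsigned char te = 0;
      if (wE >= 0 && wE < W) {
        int up = rix(i - 1) * W + wE;
        int openv = H[up] - gap_open - gap_extend;
        int extv = E[up] - gap_extend;
        if (openv >= extv) { e = openv; te = 0; } else { e = extv; te = 1; }
      }
      E[idx] = e; tbe[idx] = te;
      // F: consume subject, same i, j-1
      int f = NEG;
      unsigned char tf = 0;
      if (w - 1 >= 0) {
        int lf = rix(i) * W + (w - 1);
        int openv = H[lf] - gap_open - gap_extend;
        int extv = F[lf] - gap_extend;
        if (openv >= extv) { f = openv; tf = 0; } else { f = extv; tf = 1; }
      }
      F[idx] = f; tbf[idx] = tf;
      // H
      int dcol = col(i - 1, j - 1);
      int dval = NEG;
      if (dcol >= 0 && dcol < W)
        dval = H[rix(i - 1) * W + dcol] + sub.score(q[i - 1], s[j - 1]);
      int h = 0;
      unsigned char t = 0;
      if (dval > h) { h = dval; t = 1; }
      if (e > h) { h = e; t = 2; }
      if (f > h) { h = f; t = 3; }
      H[idx] = h; tb[idx] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  Aln a;
  if (bi < 0) return a;
  a.valid = true;
  a.score = best;
  a.qend = bi; a.send = bj;
  // traceback
  int i = bi, j = bj, state = 0; // 0 in H, 1 in E, 2 in F
  while (i >= row_lo && j > 0) {
    int w = col(i, j);
    int idx = rix(i) * W + w;
    if (state == 0) {
      unsigned char t = tb[idx];
      if (t == 0) break;
      if (t == 1) {
        a.alnlen++;
        if (q[i - 1] == s[j - 1]) a.matches++;
        i--; j--;
      } else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      a.alnlen++;
      state = tbe[idx] == 0 ? 0 : 1;
      i--;
    } else {
      a.alnlen++;
      state = tbf[idx] == 0 ? 0 : 2;
      j--;
    }
  }
  a.qstart = i; a.sstart = j; // 0-based starts
  return a;
}

// ungapped X-drop extension from an exact k-mer seed
static int ungapped_extend(const std::string &q, const std::string &s,
                           const SubMat &sub, int qpos, int spos, int k,
                           int xdrop) {
  int score = 0;
  for (int j = 0; j < k; j++) score += sub.score(q[qpos + j], s[spos + j]);
  int best = score, run = score;
  // right
  int i = qpos + k, j = spos + k;
  while (i < (int)q.size() && j < (int)s.size()) {
    run += sub.score(q[i], s[j]);
    if (run > best) best = run;
    if (best - run > xdrop) break;
    i++; j++;
  }
  int right_best = best;
  // left
  run = right_best;
  best = right_best;
  i = qpos - 1; j = spos - 1;
  while (i >= 0 && j >= 0) {
    run += sub.score(q[i], s[j]);
    if (run > best) best = run;
    if (best - run > xdrop) break;
    i--; j--;
  }
  return best;
}

struct DbIndex {
  std::vector<std::string> prot;
  std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> seeds;
  int k;
};

static DbIndex build_db_index(CharacterVector db, int k) {
  DbIndex ix;
  ix.k = k;
  int nd = db.size();
  ix.prot.resize(nd);
  for (int d = 0; d < nd; d++) {
    ix.prot[d] = as<std::string>(db[d]);
    const std::string &p = ix.prot[d];
    for (int pos = 0; pos + k <= (int)p.size(); pos++) {
      uint32_t key = 0;
      bool ok = true;
      for (int j = 0; j < k; j++) {
        int a = aa20(p[pos + j]);
        if (a < 0) { ok = false; break; }
        key = key * 20 + a;
      }
      if (ok) ix.seeds[key].push_back({d, pos});
    }
  }
  return ix;
}

// search one peptide (one frame) against the index; results appended
static void search_peptide(const std::string &pep, int qidx, int frame,
                           const DbIndex &ix, const SubMat &sub,
                           int gap_open, int gap_extend, int band, int xdrop,
                           int trigger,
                           std::vector<std::array<int, 10>> &rows) {
  int k = ix.k;
  int m = (int)pep.size();
  if (m < k) return;
  // best ungapped score and its diagonal per subject
  std::unordered_map<int, std::pair<int, int>> cand; // subject -> (score, diag)
  std::unordered_map<long long, int> seen_diag;      // (subject, diag) -> qpos reached
  for (int pos = 0; pos + k <= m; pos++) {
    uint32_t key = 0;
    bool ok = true;
    for (int j = 0; j < k; j++) {
      int a = aa20(pep[pos + j]);
      if (a < 0) { ok = false; break; }
      key = key * 20 + a;
    }
    if (!ok) continue;
    auto hit = ix.seeds.find(key);
    if (hit == ix.seeds.end()) continue;
    for (const auto &se : hit->second) {
      int d = se.first, spos = se.second;
      int diag = spos - pos;
      long long dk = (long long)d * 1000003LL + (diag + 500000);
      auto sd = seen_diag.find(dk);
      if (sd != seen_diag.end() && pos <= sd->second) continue;
      int score = ungapped_extend(pep, ix.prot[d], sub, pos, spos, k, xdrop);
      seen_diag[dk] = pos + k; // skip seeds inside this k-mer span
      auto c = cand.find(d);
      if (c == cand.end() || score > c->second.first)
        cand[d] = {score, diag};
    }
  }
  for (const auto &c : cand) {
    if (c.second.first < trigger) continue;
    int d = c.first;
    Aln a = banded_sw(pep, ix.prot[d], sub, gap_open, gap_extend,
                      c.second.second, band);
    if (!a.valid) continue;
    rows.push_back({qidx, d + 1, frame, a.score, a.matches, a.alnlen,
                    a.qstart, a.qend, a.sstart, a.send});
  }
}

static DataFrame rows_to_df(const std::vector<std::array<int, 10>> &rows) {
  int n = (int)rows.size();
  IntegerVector q(n), s(n), fr(n), sc(n), mt(n), al(n), qs(n), qe(n), ss(n), se(n);
  for (int i = 0; i < n; i++) {
    q[i] = rows[i][0]; s[i] = rows[i][1]; fr[i] = rows[i][2];
    sc[i] = rows[i][3]; mt[i] = rows[i][4]; al[i] = rows[i][5];
    qs[i] = rows[i][6]; qe[i] = rows[i][7]; ss[i] = rows[i][8];
    se[i] = rows[i][9];
  }
  return DataFrame::create(_["query"] = q, _["subject"] = s, _["frame"] = fr,
                           _["score"] = sc, _["matches"] = mt,
                           _["alnlen"] = al, _["qstart"] = qs, _["qend"] = qe,
                           _["sstart"] = ss, _["send"] = se);
}

// [[Rcpp::export]]
DataFrame cpp_translated_search(CharacterVector queries, CharacterVector db,
                                IntegerMatrix submat, int k, int band,
                                int xdrop, int gap_open, int gap_extend,
                                int trigger) {
  SubMat sub = make_submat(submat);
  DbIndex ix = build_db_index(db, k);
  std::vector<std::array<int, 10>> rows;
  static const int FR[6] = {1, 2, 3, -1, -2, -3};
  for (int i = 0; i < queries.size(); i++) {
    std::string nt = as<std::string>(queries[i]);
    if ((int)nt.size() < 3) continue;
    for (int f = 0; f < 6; f++) {
      std::string pep = translate_frame(nt, FR[f]);
      search_peptide(pep, i + 1, FR[f], ix, sub, gap_open, gap_extend,
                     band, xdrop, trigger, rows);
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return rows_to_df(rows);
}

// [[Rcpp::export]]
DataFrame cpp_peptide_search(CharacterVector queries, CharacterVector db,
                             IntegerMatrix submat, int k, int band,
                             int xdrop, int gap_open, int gap_extend,
                             int trigger) {
  SubMat sub = make_submat(submat);
  DbIndex ix = build_db_index(db, k);
  std::vector<std::array<int, 10>> rows;
  for (int i = 0; i < queries.size(); i++) {
    search_peptide(as<std::string>(queries[i]), i + 1, 0, ix, sub, gap_open,
                   gap_extend, band, xdrop, trigger, rows);
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return rows_to_df(rows);
}

// ---------------------------------------------------------------------------
// Global affine (Gotoh) profile-profile alignment for progressive MSA.
// fa, fb: 20 x L column frequency profiles (gaps excluded from
// frequencies); expected column score = fa' S fb. Returns the merge path:
// 1 = align columns, 2 = column from A (gap in B), 3 = column from B.
// [[Rcpp::export]]
IntegerVector cpp_profile_nw(NumericMatrix fa, NumericMatrix fb,
                             NumericMatrix sub20, double gap_open,
                             double gap_extend) {
  int la = fa.ncol(), lb = fb.ncol();
  const double NEG = -1e15;
  // precompute S * fb columns
  std::vector<double> PS(20 * lb, 0.0);
  for (int j = 0; j < lb; j++)
    for (int a = 0; a < 20; a++) {
      double acc = 0;
      for (int b = 0; b < 20; b++) acc += sub20(a, b) * fb(b, j);
      PS[j * 20 + a] = acc;
    }
  auto colscore = [&](int i, int j) {
    double acc = 0;
    for (int a = 0; a < 20; a++) acc += fa(a, i) * PS[j * 20 + a];
    return acc;
  };
  std::vector<double> H((la + 1) * (lb + 1), NEG), E((la + 1) * (lb + 1), NEG),
      F((la + 1) * (lb + 1), NEG);
  std::vector<unsigned char> tb((la + 1) * (lb + 1), 0),
      te((la + 1) * (lb + 1), 0), tf((la + 1) * (lb + 1), 0);
  auto ix = [&](int i, int j) { return i * (lb + 1) + j; };
  H[ix(0, 0)] = 0;
  for (int i = 1; i <= la; i++) {
    E[ix(i, 0)] = -gap_open - (i - 1) * gap_extend;
    H[ix(i, 0)] = E[ix(i, 0)];
    tb[ix(i, 0)] = 2;
    te[ix(i, 0)] = 1;
  }
  for (int j = 1; j <= lb; j++) {
    F[ix(0, j)] = -gap_open - (j - 1) * gap_extend;
    H[ix(0, j)] = F[ix(0, j)];
    tb[ix(0, j)] = 3;
    tf[ix(0, j)] = 1;
  }
  for (int i = 1; i <= la; i++) {
    for (int j = 1; j <= lb; j++) {
      double eo = H[ix(i - 1, j)] - gap_open, ee = E[ix(i - 1, j)] - gap_extend;
      if (eo >= ee) { E[ix(i, j)] = eo; te[ix(i, j)] = 0; }
      else { E[ix(i, j)] = ee; te[ix(i, j)] = 1; }
      double fo = H[ix(i, j - 1)] - gap_open, fe = F[ix(i, j - 1)] - gap_extend;
      if (fo >= fe) { F[ix(i, j)] = fo; tf[ix(i, j)] = 0; }
      else { F[ix(i, j)] = fe; tf[ix(i, j)] = 1; }
      double dg = H[ix(i - 1, j - 1)] + colscore(i - 1, j - 1);
      double h = dg;
      unsigned char t = 1;
      if (E[ix(i, j)] > h) { h = E[ix(i, j)]; t = 2; }
      if (F[ix(i, j)] > h) { h = F[ix(i, j)]; t = 3; }
      H[ix(i, j)] = h;
      tb[ix(i, j)] = t;
    }
  }
  std::vector<int> path;
  int i = la, j = lb, state = 0;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char t = tb[ix(i, j)];
      if (t == 1) { path.push_back(1); i--; j--; }
      else if (t == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      path.push_back(2);
      state = te[ix(i, j)] == 0 ? 0 : 1;
      i--;
    } else {
      path.push_back(3);
      state = tf[ix(i, j)] == 0 ? 0 : 2;
      j--;
    }
  }
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
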