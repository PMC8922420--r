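// Greedy overlap-layout-consensus assembler and ungapped read mapper.
//
// Overlap candidates are found by exact 16-mer seeding: a suffix-prefix
// overlap between two sequences must contain, error-free, the first 16 nt
// of the right-hand sequence; occurrences of that 16-mer inside the
// left-hand sequence propose the overlap, which is then verified base by
// base under the identity threshold. Both orientations of both sequences
// are enumerated, so forward-forward, forward-reverse and reverse-forward
// overlaps are all considered. Merging is greedy: always the longest
// verified overlap, ties broken by the lexicographically smallest id pair.
// Consensus is per-position majority over member bases with quality-sum
// tie-break.

#include <Rcpp.h>
#include <array>
#include <queue>
#include <set>
#include <unordered_map>
#include <cstring>
#include <cmath>
using namespace Rcpp;

static const int KK = 16; // seed k-mer length (nt)

static inline int b2i(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}
static inline char i2b(int i) { return "ACGT"[i]; }
static inline char cmpl(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
  }
  return 'N';
}

static std::string rc(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = cmpl(c);
  return r;
}

// encode 16-mer starting at p; false if it contains a non-ACGT base
static bool kmer_at(const std::string &s, int p, uint64_t &key) {
  if (p + KK > (int)s.size()) return false;
  uint64_t k = 0;
  for (int j = 0; j < KK; j++) {
    int b = b2i(s[p + j]);
    if (b < 0) return false;
    k = (k << 2) | (uint64_t)b;
  }
  key = k;
  return true;
}

struct Item {
  std::string id;
  std::string seq[2];                    // [0] forward, [1] reverse complement
  std::vector<std::array<int, 4>> cnt;   // base counts, forward orientation
  std::vector<std::array<double, 4>> qs; // quality sums, forward orientation
  std::vector<int> members;              // 0-based read indices
  bool alive = true;
};

struct Cand {
  int olen;          // verified overlap length
  std::string lo_id, hi_id; // sorted id pair for tie-break
  int left, right;   // item indices
  int oL, oR;        // orientations (0 fwd, 1 rc)
  int pos;           // offset of right's start inside oriented left
  bool operator<(const Cand &other) const {
    // max-heap: longest overlap first, then lexicographically smallest pair
    if (olen != other.olen) return olen < other.olen;
    if (lo_id != other.lo_id) return lo_id > other.lo_id;
    if (hi_id != other.hi_id) return hi_id > other.hi_id;
    if (oL != other.oL) return oL > other.oL;
    if (oR != other.oR) return oR > other.oR;
    return pos > other.pos;
  }
};

typedef std::unordered_map<uint64_t, std::vector<std::array<int, 3>>> BodyIndex;
// body index value: {item, orient, pos}
typedef std::unordered_map<uint64_t, std::vector<std::array<int, 2>>> PrefIndex;
// prefix index value: {item, orient}

class Assembler {
public:
  std::vector<Item> items;
  BodyIndex body;
  PrefIndex pref;
  std::priority_queue<Cand> heap;
  int min_overlap;
  double min_identity;
  int next_ctg = 1;

  void index_item(int idx) {
    const Item &it = items[idx];
    for (int o = 0; o < 2; o++) {
      uint64_t key;
      const std::string &s = it.seq[o];
      for (int p = 0; p + KK <= (int)s.size(); p++)
        if (kmer_at(s, p, key)) body[key].push_back({idx, o, p});
      if (kmer_at(s, 0, key)) pref[key].push_back({idx, o});
    }
  }

  // verify overlap of oriented left (suffix from pos) against oriented
  // right prefix; push a candidate when it passes the identity threshold
  void try_candidate(int li, int oL, int pos, int ri, int oR) {
    if (li == ri) return;
    const std::string &L = items[li].seq[oL];
    const std::string &R = items[ri].seq[oR];
    int olen = std::min((int)L.size() - pos, (int)R.size());
    if (olen < min_overlap) return;
    int allow = (int)std::floor((1.0 - min_identity) * olen);
    int mm = 0;
    for (int j = 0; j < olen; j++) {
      if (L[pos + j] != R[j]) {
        mm++;
        if (mm > allow) return;
      }
    }
    Cand c;
    c.olen = olen;
    c.left = li; c.right = ri; c.oL = oL; c.oR = oR; c.pos = pos;
    const std::string &a = items[li].id, &b = items[ri].id;
    if (a <= b) { c.lo_id = a; c.hi_id = b; } else { c.lo_id = b; c.hi_id = a; }
    heap.push(c);
  }

  // candidates with item idx on the left: scan its body against prefixes
  void scan_as_left(int idx) {
    const Item &it = items[idx];
    for (int o = 0; o < 2; o++) {
      const std::string &s = it.seq[o];
      uint64_t key;
      for (int p = 0; p + KK <= (int)s.size(); p++) {
        if (!kmer_at(s, p, key)) continue;
        auto hit = pref.find(key);
        if (hit == pref.end()) continue;
        for (const auto &pr : hit->second) {
          if (!items[pr[0]].alive) continue;
          try_candidate(idx, o, p, pr[0], pr[1]);
        }
      }
    }
  }

  // candidates with item idx on the right: find its prefix in other bodies
  void scan_as_right(int idx) {
    const Item &it = items[idx];
    for (int o = 0; o < 2; o++) {
      uint64_t key;
      if (!kmer_at(it.seq[o], 0, key)) continue;
      auto hit = body.find(key);
      if (hit == body.end()) continue;
      for (const auto &bd : hit->second) {
        if (bd[0] == idx || !items[bd[0]].alive) continue;
        try_candidate(bd[0], bd[1], bd[2], idx, o);
      }
    }
  }

  // oriented per-position profile of an item
  static void oriented_profile(const Item &it, int o,
                               std::vector<std::array<int, 4>> &cnt,
                               std::vector<std::array<double, 4>> &qs) {
    cnt = it.cnt; qs = it.qs;
    if (o == 1) {
      std::reverse(cnt.begin(), cnt.end());
      std::reverse(qs.begin(), qs.end());
      for (auto &a : cnt) { std::swap(a[0], a[3]); std::swap(a[1], a[2]); }
      for (auto &a : qs) { std::swap(a[0], a[3]); std::swap(a[1], a[2]); }
    }
  }

  void merge(const Cand &c) {
    Item &L = items[c.left];
    Item &R = items[c.right];
    std::vector<std::array<int, 4>> lc, rcn;
    std::vector<std::array<double, 4>> lq, rq;
    oriented_profile(L, c.oL, lc, lq);
    oriented_profile(R, c.oR, rcn, rq);
    int len = std::max((int)lc.size(), c.pos + (int)rcn.size());
    Item z;
    z.id = "c" + std::to_string(100000 + next_ctg++);
    z.cnt.assign(len, {0, 0, 0, 0});
    z.qs.assign(len, {0, 0, 0, 0});
    for (int p = 0; p < (int)lc.size(); p++) {
      for (int b = 0; b < 4; b++) { z.cnt[p][b] += lc[p][b]; z.qs[p][b] += lq[p][b]; }
    }
    for (int p = 0; p < (int)rcn.size(); p++) {
      for (int b = 0; b < 4; b++) {
        z.cnt[c.pos + p][b] += rcn[p][b];
        z.qs[c.pos + p][b] += rq[p][b];
      }
    }
    std::string s(len, 'N');
    for (int p = 0; p < len; p++) {
      int bb = 0;
      for (int b = 1; b < 4; b++) {
        if (z.cnt[p][b] > z.cnt[p][bb] ||
            (z.cnt[p][b] == z.cnt[p][bb] && z.qs[p][b] > z.qs[p][bb]))
          bb = b;
      }
      s[p] = i2b(bb);
    }
    z.seq[0] = s;
    z.seq[1] = rc(s);
    z.members = L.members;
    z.members.insert(z.members.end(), R.members.begin(), R.members.end());
    L.alive = false;
    R.alive = false;
    items.push_back(z);
    int idx = (int)items.size() - 1;
    index_item(idx);
    scan_as_left(idx);
    scan_as_right(idx);
  }

  void run() {
    for (int i = 0; i < (int)items.size(); i++) scan_as_left(i);
    while (!heap.empty()) {
      Cand c = heap.top();
      heap.pop();
      if (!items[c.left].alive || !items[c.right].alive) continue;
      merge(c);
    }
  }
};

// [[Rcpp::export]]
List cpp_assemble(CharacterVector ids, CharacterVector seqs,
                  CharacterVector quals, int min_overlap,
                  double min_identity) {
  Assembler eng;
  eng.min_overlap = min_overlap;
  eng.min_identity = min_identity;
  int n = seqs.size();
  eng.items.reserve(2 * n + 16);
  for (int i = 0; i < n; i++) {
    Item it;
    it.id = as<std::string>(ids[i]);
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    it.seq[0] = s;
    it.seq[1] = rc(s);
    int L = (int)s.size();
    it.cnt.assign(L, {0, 0, 0, 0});
    it.qs.assign(L, {0, 0, 0, 0});
    for (int p = 0; p < L; p++) {
      int b = b2i(s[p]);
      if (b >= 0) {
        it.cnt[p][b] = 1;
        it.qs[p][b] = (p < (int)q.size()) ? (q[p] - 33) : 30;
      }
    }
    it.members.push_back(i);
    eng.items.push_back(it);
    eng.index_item(i);
  }
  eng.run();

  std::vector<std::string> out_seq;
  std::vector<std::vector<int>> out_members;
  for (const auto &it : eng.items) {
    if (!it.alive) continue;
    std::vector<int> m(it.members);
    for (auto &x : m) x += 1; // 1-based for R
    out_seq.push_back(it.seq[0]);
    out_members.push_back(m);
  }
  List members(out_members.size());
  for (size_t i = 0; i < out_members.size(); i++)
    members[i] = wrap(out_members[i]);
  return List::create(_["seq"] = wrap(out_seq), _["members"] = members);
}

// Ungapped mapping of reads onto contigs (either strand), seeded with
// 16-mers at stride 8. A read maps when the overlapping region with some
// contig spans >= min_aligned bases at >= min_identity. With
// allow_overhang, alignments may run past contig ends (offset can be
// negative); the verified region is the intersection. Returns the best
// placement per read (matches, then aligned length).
// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                        int min_aligned, double min_identity,
                        bool allow_overhang) {
  int nc = contigs.size(), nr = reads.size();
  std::vector<std::string> ctg(nc);
  BodyIndex idx;
  for (int c = 0; c < nc; c++) {
    ctg[c] = as<std::string>(contigs[c]);
    uint64_t key;
    for (int p = 0; p + KK <= (int)ctg[c].size(); p++)
      if (kmer_at(ctg[c], p, key)) idx[key].push_back({c, 0, p});
  }
  std::vector<int> r_read, r_ctg, r_off, r_strand, r_aln, r_match;
  for (int i = 0; i < nr; i++) {
    std::string fwd = as<std::string>(reads[i]);
    int best_match = -1, best_aln = 0, best_c = -1, best_off = 0, best_str = 0;
    for (int o = 0; o < 2; o++) {
      std::string s = (o == 0) ? fwd : rc(fwd);
      int L = (int)s.size();
      if (L < KK) continue;
      std::set<std::pair<int, int>> seen; // (contig, offset)
      for (int p = 0; p + KK <= L; p += 8) {
        uint64_t key;
        if (!kmer_at(s, p, key)) continue;
        auto hit = idx.find(key);
        if (hit == idx.end()) continue;
        for (const auto &h : hit->second) {
          int c = h[0], off = h[2] - p;
          if (!seen.insert({c, off}).second) continue;
          int clen = (int)ctg[c].size();
          if (!allow_overhang && (off < 0 || off + L > clen)) continue;
          int from = std::max(0, -off);          // read coordinate
          int to = std::min(L, clen - off);
          int aln = to - from;
          if (aln < min_aligned) continue;
          int match = 0;
          for (int j = from; j < to; j++)
            if (s[j] == ctg[c][off + j]) match++;
          if ((double)match / aln < min_identity) continue;
          if (match > best_match ||
              (match == best_match && aln > best_aln)) {
            best_match = match; best_aln = aln; best_c = c;
            best_off = off; best_str = o;
          }
        }
      }
    }
    if (best_c >= 0) {
      r_read.push_back(i + 1);
      r_ctg.push_back(best_c + 1);
      r_off.push_back(best_off);
      r_strand.push_back(best_str);
      r_aln.push_back(best_aln);
      r_match.push_back(best_match);
    }
  }
  return DataFrame::create(_["read"] = r_read, _["contig"] = r_ctg,
                           _["offset"] = r_off, _["strand"] = r_strand,
                           _["aligned"] = r_aln, _["matches"] = r_match);
}
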