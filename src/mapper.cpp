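#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>

using namespace Rcpp;

// Canonical amino-acid alphabet, alphabetical order. Index 0..19; -1 = non-canonical.
static const char AA_ALPHABET[21] = "ACDEFGHIKLMNPQRSTVWY";

static inline int aa_index(char c) {
  switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;  case 'E': return 3;
    case 'F': return 4;  case 'G': return 5;  case 'H': return 6;  case 'I': return 7;
    case 'K': return 8;  case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14; case 'S': return 15;
    case 'T': return 16; case 'V': return 17; case 'W': return 18; case 'Y': return 19;
    default:  return -1;
  }
}

static inline int nt_index(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:  return -1; // N or other ambiguity
  }
}

// Standard genetic code indexed by 16*b1 + 4*b2 + b3 (A,C,G,T = 0..3). '*' = stop.
static const char CODON_TABLE[65] =
  "KNKNTTTTRSRSIIMIQHQHPPPPRRRRLLLLEDEDAAAAGGGGVVVV*Y*YSSSS*CWCLFLF";

static inline char translate_codon(int b1, int b2, int b3) {
  if (b1 < 0 || b2 < 0 || b3 < 0) return 'X'; // ambiguous base
  return CODON_TABLE[16 * b1 + 4 * b2 + b3];
}

static inline char complement_nt(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default:  return 'N';
  }
}

struct Fragment {
  std::string seq;
  int frame; // +1,+2,+3 = 1,2,3 ; -1,-2,-3 = -1,-2,-3
};

// Translate one strand of `dna` in frames 1..3, splitting at stops and at X
// (codons containing ambiguous bases). Keeps fragments >= min_orf_len.
static void translate_strand(const std::string& dna, int frame_sign,
                             int min_orf_len, std::vector<Fragment>& out) {
  int n = (int) dna.size();
  for (int off = 0; off < 3; ++off) {
    std::string cur;
    cur.reserve(n / 3 + 1);
    for (int i = off; i + 2 < n; i += 3) {
      char aa = translate_codon(nt_index(dna[i]), nt_index(dna[i + 1]),
                                nt_index(dna[i + 2]));
      if (aa == '*' || aa == 'X') {
        if ((int) cur.size() >= min_orf_len)
          out.push_back({cur, frame_sign * (off + 1)});
        cur.clear();
      } else {
        cur.push_back(aa);
      }
    }
    if ((int) cur.size() >= min_orf_len)
      out.push_back({cur, frame_sign * (off + 1)});
  }
}

static std::vector<Fragment> six_frames(const std::string& read, int min_orf_len) {
  std::vector<Fragment> frags;
  translate_strand(read, +1, min_orf_len, frags);
  std::string rc(read.size(), 'N');
  for (size_t i = 0; i < read.size(); ++i)
    rc[i] = complement_nt(read[read.size() - 1 - i]);
  translate_strand(rc, -1, min_orf_len, frags);
  return frags;
}

// [[Rcpp::export]]
List cpp_translate_six_frames(std::string read, int min_orf_len) {
  std::vector<Fragment> frags = six_frames(read, min_orf_len);
  CharacterVector seqs(frags.size());
  IntegerVector frames(frags.size());
  for (size_t i = 0; i < frags.size(); ++i) {
    seqs[i] = frags[i].seq;
    frames[i] = frags[i].frame;
  }
  return List::create(_["fragment"] = seqs, _["frame"] = frames);
}

// ---------------------------------------------------------------------------
// k-mer index over a peptide catalog
// ---------------------------------------------------------------------------

struct KmerIndex {
  int k;
  std::vector<std::string> ids;
  std::vector<std::string> seqs;
  // key: packed k-mer (base 20); value: (peptide index, offset) postings in
  // catalog order then offset order. For k <= 5 the postings are laid out in
  // a flat CSR structure indexed directly by the packed key (fast path); for
  // larger k a hash map is used.
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> map;
  bool flat = false;
  std::vector<int> head;                      // size 20^k + 1
  std::vector<std::pair<int, int>> postings;  // CSR payload
  size_t n_keys = 0;

  void finalize() {
    n_keys = map.size();
    if (k > 5) return;
    size_t space = 1;
    for (int i = 0; i < k; ++i) space *= 20;
    head.assign(space + 1, 0);
    for (auto& kv : map) head[kv.first + 1] = (int) kv.second.size();
    for (size_t i = 1; i <= space; ++i) head[i] += head[i - 1];
    postings.resize(head[space]);
    for (auto& kv : map) {
      int at = head[kv.first];
      for (auto& p : kv.second) postings[at++] = p;
    }
    map.clear();
    flat = true;
  }
  // returns [begin, end) into a postings array, or nullptr range
  inline const std::pair<int, int>* lookup(uint64_t key, int& n) const {
    if (flat) {
      n = head[key + 1] - head[key];
      return n > 0 ? &postings[head[key]] : nullptr;
    }
    auto it = map.find(key);
    if (it == map.end()) { n = 0; return nullptr; }
    n = (int) it->second.size();
    return it->second.data();
  }
};

static inline bool pack_kmer(const std::string& s, int pos, int k, uint64_t& key) {
  uint64_t v = 0;
  for (int i = 0; i < k; ++i) {
    int a = aa_index(s[pos + i]);
    if (a < 0) return false;
    v = v * 20 + (uint64_t) a;
  }
  key = v;
  return true;
}

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector ids, CharacterVector seqs, int k) {
  KmerIndex* idx = new KmerIndex();
  idx->k = k;
  for (int p = 0; p < ids.size(); ++p) {
    idx->ids.push_back(as<std::string>(ids[p]));
    idx->seqs.push_back(as<std::string>(seqs[p]));
  }
  for (int p = 0; p < (int) idx->seqs.size(); ++p) {
    const std::string& s = idx->seqs[p];
    for (int pos = 0; pos + k <= (int) s.size(); ++pos) {
      uint64_t key;
      if (pack_kmer(s, pos, k, key))
        idx->map[key].push_back({p, pos});
    }
  }
  idx->finalize();
  return XPtr<KmerIndex>(idx, true);
}

static KmerIndex* get_index(SEXP xp) {
  XPtr<KmerIndex> p(xp);
  return p.get();
}

// [[Rcpp::export]]
List cpp_query_index(SEXP xp, std::string kmer) {
  KmerIndex* idx = get_index(xp);
  uint64_t key;
  int np = 0;
  const std::pair<int, int>* post = nullptr;
  if ((int) kmer.size() == idx->k && pack_kmer(kmer, 0, idx->k, key))
    post = idx->lookup(key, np);
  CharacterVector pep(np);
  IntegerVector off(np);
  for (int i = 0; i < np; ++i) {
    pep[i] = idx->ids[post[i].first];
    off[i] = post[i].second; // 0-based
  }
  return List::create(_["peptide"] = pep, _["offset"] = off);
}

// [[Rcpp::export]]
int cpp_index_k(SEXP xp) { return get_index(xp)->k; }

// [[Rcpp::export]]
int cpp_index_size(SEXP xp) { return (int) get_index(xp)->n_keys; }

// ---------------------------------------------------------------------------
// seed-and-extend ungapped mapping
// ---------------------------------------------------------------------------

// Best-scoring contiguous segment (Kadane) on the diagonal overlap between a
// translated fragment and a catalog peptide. Returns best score (substitution
// matrix units), span length, and identical count; requires span>=min_match_len
// and identity >= min_identity to qualify.
struct HitStats { int score; int span; int ident; bool ok; };

// The accepted candidate on a diagonal is the highest-scoring contiguous
// segment that satisfies both constraints (span >= min_match_len, identity
// >= min_identity over the segment). A cheap necessary condition -- every
// qualifying segment contains at least ceil(min_identity * min_match_len)
// identical positions -- rejects almost all spurious seed diagonals in O(L)
// before the exact O(L^2) prefix-sum scan runs.
static HitStats best_diagonal_hit(const std::string& frag, const std::string& pep,
                                  int diag, const IntegerMatrix& sub,
                                  int min_match_len, double min_identity) {
  // diag = pep_offset - frag_offset; overlap region in frag coordinates
  int q0 = std::max(0, -diag);
  int q1 = std::min((int) frag.size(), (int) pep.size() - diag);
  HitStats best = {0, 0, 0, false};
  int L = q1 - q0;
  if (L < min_match_len) return best;
  std::vector<int> cs(L + 1, 0), ci(L + 1, 0);
  for (int t = 0; t < L; ++t) {
    int q = q0 + t;
    int ai = aa_index(frag[q]);
    int bi = aa_index(pep[q + diag]);
    int sc = (ai >= 0 && bi >= 0) ? sub(ai, bi) : -1000000;
    bool id = ai >= 0 && frag[q] == pep[q + diag];
    cs[t + 1] = cs[t] + sc;
    ci[t + 1] = ci[t] + (id ? 1 : 0);
  }
  int need = (int) std::ceil(min_identity * min_match_len - 1e-9);
  if (ci[L] < need) return best;
  int best_score = INT_MIN, b_span = 0, b_ident = 0;
  for (int a = 0; a + min_match_len <= L; ++a) {
    for (int e = a + min_match_len; e <= L; ++e) {
      int span = e - a;
      int ident = ci[e] - ci[a];
      if ((double) ident < min_identity * span - 1e-12) continue;
      int sc = cs[e] - cs[a];
      if (sc > best_score) {
        best_score = sc; b_span = span; b_ident = ident;
      }
    }
  }
  if (best_score == INT_MIN) return best;
  best.score = best_score; best.span = b_span; best.ident = b_ident;
  best.ok = true;
  return best;
}

// Map reads against the indexed catalog. Returns 1-based index of the best-hit
// peptide per read (in index catalog order), or NA if no acceptable hit.
// Ties on score break to the lexicographically smallest peptide id.
// [[Rcpp::export]]
IntegerVector cpp_map_reads(SEXP xp, CharacterVector reads,
                            int min_orf_len, int min_match_len,
                            double min_identity, IntegerMatrix sub) {
  KmerIndex* idx = get_index(xp);
  int k = idx->k;
  int n = reads.size();
  IntegerVector out(n, NA_INTEGER);
  std::unordered_set<int64_t> seen; // (pep, diag) dedup per fragment
  for (int r = 0; r < n; ++r) {
    std::string read = as<std::string>(reads[r]);
    std::vector<Fragment> frags = six_frames(read, min_orf_len);
    int best_score = INT_MIN;
    int best_pep = -1;
    for (const Fragment& f : frags) {
      const std::string& fs = f.seq;
      if ((int) fs.size() < k) continue;
      seen.clear();
      for (int pos = 0; pos + k <= (int) fs.size(); ++pos) {
        uint64_t key;
        if (!pack_kmer(fs, pos, k, key)) continue;
        int np = 0;
        const std::pair<int, int>* post = idx->lookup(key, np);
        for (int pi = 0; pi < np; ++pi) {
          int pep = post[pi].first;
          int diag = post[pi].second - pos;
          int64_t dk = ((int64_t) pep << 24) ^ (int64_t)(diag + 1000000);
          if (!seen.insert(dk).second) continue;
          HitStats h = best_diagonal_hit(fs, idx->seqs[pep], diag, sub,
                                         min_match_len, min_identity);
          if (!h.ok) continue;
          if (h.score > best_score ||
              (h.score == best_score && best_pep >= 0 &&
               idx->ids[pep] < idx->ids[best_pep])) {
            best_score = h.score;
            best_pep = pep;
          }
        }
      }
    }
    if (best_pep >= 0) out[r] = best_pep + 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// affine-gap global alignment (Gotoh three-state, full traceback)
// ---------------------------------------------------------------------------

// Scores are passed in doubled integer units so that half-integer gap-extend
// penalties stay exact. Gap of length L costs open2 + (L-1)*ext2.
// States: 0 = M (diagonal), 1 = X (gap in b, consumes a), 2 = Y (gap in a).
// Traceback preference on ties: M > X > Y (diagonal > up > left).
// [[Rcpp::export]]
List cpp_nw_affine(std::string a, std::string b, IntegerMatrix sub2,
                   int open2, int ext2) {
  const long NEG = -1000000000L;
  int n = (int) a.size(), m = (int) b.size();
  std::vector<int> ai(n), bi(m);
  for (int i = 0; i < n; ++i) {
    ai[i] = aa_index(a[i]);
    if (ai[i] < 0) stop("non-canonical residue '%s' at position %d of first sequence",
                        std::string(1, a[i]).c_str(), i + 1);
  }
  for (int j = 0; j < m; ++j) {
    bi[j] = aa_index(b[j]);
    if (bi[j] < 0) stop("non-canonical residue '%s' at position %d of second sequence",
                        std::string(1, b[j]).c_str(), j + 1);
  }
  size_t sz = (size_t)(n + 1) * (size_t)(m + 1);
  std::vector<long> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  // ptr encodes predecessor state (0,1,2) per state per cell
  std::vector<signed char> pM(sz, -1), pX(sz, -1), pY(sz, -1);
  auto at = [m](int i, int j) { return (size_t) i * (m + 1) + j; };
  M[at(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = -(long) open2 - (long)(i - 1) * ext2;
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = -(long) open2 - (long)(j - 1) * ext2;
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = at(i, j), d = at(i - 1, j - 1), u = at(i - 1, j), l = at(i, j - 1);
      // M: diagonal from best of three states, preference M > X > Y
      long s = (long) sub2(ai[i - 1], bi[j - 1]);
      long vm = M[d], vx = X[d], vy = Y[d];
      long best = vm; signed char p = 0;
      if (vx > best) { best = vx; p = 1; }
      if (vy > best) { best = vy; p = 2; }
      if (best > NEG) { M[c] = best + s; pM[c] = p; }
      // X: gap in b (up). open from M/Y, extend from X.
      long xm = (M[u] > NEG) ? M[u] - open2 : NEG;
      long xx = (X[u] > NEG) ? X[u] - ext2 : NEG;
      long xy = (Y[u] > NEG) ? Y[u] - open2 : NEG;
      best = xm; p = 0;
      if (xx > best) { best = xx; p = 1; }
      if (xy > best) { best = xy; p = 2; }
      if (best > NEG) { X[c] = best; pX[c] = p; }
      // Y: gap in a (left)
      long ym = (M[l] > NEG) ? M[l] - open2 : NEG;
      long yx = (X[l] > NEG) ? X[l] - open2 : NEG;
      long yy = (Y[l] > NEG) ? Y[l] - ext2 : NEG;
      best = ym; p = 0;
      if (yx > best) { best = yx; p = 1; }
      if (yy > best) { best = yy; p = 2; }
      if (best > NEG) { Y[c] = best; pY[c] = p; }
    }
  }
  size_t e = at(n, m);
  long score = M[e]; int state = 0;
  if (X[e] > score) { score = X[e]; state = 1; }
  if (Y[e] > score) { score = Y[e]; state = 2; }
  // traceback
  std::string ga, gb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t c = at(i, j);
    if (state == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      state = pM[c]; --i; --j;
    } else if (state == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      state = pX[c]; --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      state = pY[c]; --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["score2"] = (double) score,
                      _["aligned_a"] = ga, _["aligned_b"] = gb);
}

// ---------------------------------------------------------------------------
// random DNA (uses R's RNG so set.seed() governs reproducibility)
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
CharacterVector cpp_random_dna(int n, int len) {
  static const char NT[5] = "ACGT";
  CharacterVector out(n);
  GetRNGstate();
  std::string buf(len, 'A');
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < len; ++j)
      buf[j] = NT[(int) std::floor(unif_rand() * 4.0) & 3];
    out[i] = buf;
  }
  PutRNGstate();
  return out;
}
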