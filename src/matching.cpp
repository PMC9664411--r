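// Edit-distance-tolerant k-mer search over reads.
//
// A feature matcher is built once from a k-mer table (k-mer, feature id,
// strand) and then streamed over reads.  Search is exact for the configured
// edit distance d: each k-mer is split into d+1 contiguous pieces; if the
// k-mer occurs in a read within d Levenshtein edits, at least one piece
// occurs verbatim (pigeonhole), so seed lookups of piece prefixes followed
// by bit-parallel verification (Myers 1999) of a padded window around each
// seed hit cannot miss a true occurrence.  Patterns are limited to 64 bases
// (one machine word).

#include <Rcpp.h>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

inline int base2bits(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

struct Candidate {
  int kmer;      // k-mer index
  int diag;      // putative start of the k-mer in the text (may be negative)
};

struct Matcher {
  int k;
  int max_dist;
  int q;                       // seed length = floor(k / (d + 1)), capped at 32
  std::vector<std::string> kmers;
  std::vector<int> feature;    // feature id per k-mer (0-based)
  std::vector<int> strand;     // +1 / -1 per k-mer
  std::vector<uint64_t> peq;   // Myers Peq masks, 4 per k-mer
  int n_features;
  // seed -> candidate (k-mer, piece offset) table: direct-indexed for short
  // seeds (the common case), hashed otherwise
  bool direct;
  std::vector<std::vector<Candidate>> seed_arr;
  std::unordered_map<uint64_t, std::vector<Candidate>> seed_map;

  const std::vector<Candidate>* lookup(uint64_t h) const {
    if (direct) {
      const std::vector<Candidate>& v = seed_arr[(size_t)h];
      return v.empty() ? nullptr : &v;
    }
    auto it = seed_map.find(h);
    return (it == seed_map.end()) ? nullptr : &it->second;
  }
};

// Myers bit-parallel approximate search: returns the minimum over all
// substrings of text[from, to) of the edit distance to the pattern, capped
// at limit + 1; records the end position (exclusive, text coords) of the
// leftmost best match.
inline int myers_min_dist(const Matcher& m, int kmer_idx,
                          const char* text, int from, int to,
                          int limit, int& best_end) {
  const uint64_t* peq = &m.peq[4 * (size_t)kmer_idx];
  const int k = m.k;
  const uint64_t high = 1ULL << (k - 1);
  uint64_t pv = ~0ULL, mv = 0ULL;
  int score = k, best = limit + 1;
  best_end = -1;
  for (int j = from; j < to; ++j) {
    int b = base2bits(text[j]);
    uint64_t eq = (b < 0) ? 0ULL : peq[b];
    uint64_t xv = eq | mv;
    uint64_t xh = (((eq & pv) + pv) ^ pv) | eq;
    uint64_t ph = mv | ~(xh | pv);
    uint64_t mh = pv & xh;
    if (ph & high) ++score; else if (mh & high) --score;
    ph <<= 1; mh <<= 1;
    pv = mh | ~(xv | ph);
    mv = ph & xv;
    if (score < best) { best = score; best_end = j + 1; }
  }
  return best;
}

Matcher* as_matcher(SEXP ptr) {
  XPtr<Matcher> xp(ptr);
  return xp.get();
}

} // namespace

// [[Rcpp::export(name = ".matcher_build")]]
SEXP matcher_build(CharacterVector kmers, IntegerVector feature_id,
                   IntegerVector strand, int n_features, int max_dist) {
  if (kmers.size() == 0) stop("empty k-mer table");
  if (max_dist < 0) stop("max_dist must be >= 0");
  Matcher* m = new Matcher();
  m->max_dist = max_dist;
  m->n_features = n_features;
  m->k = LENGTH(STRING_ELT(kmers, 0));
  if (m->k < 1 || m->k > 64) { delete m; stop("k must be in 1..64"); }
  if (max_dist >= m->k) { delete m; stop("max_dist must be < k"); }
  int q = m->k / (max_dist + 1);
  if (q > 32) q = 32;
  if (q < 1) q = 1;
  m->q = q;
  const uint64_t qmask = (q == 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);

  m->direct = (2 * q <= 16);
  if (m->direct) m->seed_arr.resize((size_t)1 << (2 * q));

  int n = kmers.size();
  m->kmers.reserve(n);
  m->feature.reserve(n);
  m->strand.reserve(n);
  m->peq.assign(4 * (size_t)n, 0ULL);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(kmers[i]);
    if ((int)s.size() != m->k) { delete m; stop("k-mers must all have equal length"); }
    for (int j = 0; j < m->k; ++j) {
      int b = base2bits(s[j]);
      if (b < 0) { delete m; stop("k-mers must be ACGT only"); }
      m->peq[4 * (size_t)i + b] |= (1ULL << j);
    }
    m->kmers.push_back(s);
    m->feature.push_back(feature_id[i]);
    m->strand.push_back(strand[i]);
    // seed = first q bases of each of the (max_dist + 1) pieces
    for (int p = 0; p <= max_dist; ++p) {
      int off = p * (m->k / (max_dist + 1));
      if (off + q > m->k) off = m->k - q;
      uint64_t h = 0;
      for (int j = 0; j < q; ++j) h = (h << 2) | (uint64_t)base2bits(s[off + j]);
      h &= qmask;
      if (m->direct) m->seed_arr[(size_t)h].push_back(Candidate{i, -off});
      else m->seed_map[h].push_back(Candidate{i, -off});
    }
  }
  XPtr<Matcher> xp(m, true);
  return xp;
}

// For each read, the best hit per feature.  Returns a list of four
// n_reads x n_features integer matrices: dist (NA if no hit within
// max_dist), start (1-based, approximate within max_dist for inexact hits),
// strand (+1/-1), kmer (1-based index into the k-mer table).
// [[Rcpp::export(name = ".matcher_match")]]
List matcher_match(SEXP ptr, CharacterVector reads) {
  Matcher* m = as_matcher(ptr);
  const int nr = reads.size(), nf = m->n_features;
  const int k = m->k, d = m->max_dist, q = m->q;
  const uint64_t qmask = (q == 32) ? ~0ULL : ((1ULL << (2 * q)) - 1);

  IntegerMatrix dist(nr, nf), start(nr, nf), strnd(nr, nf), kidx(nr, nf);
  std::fill(dist.begin(), dist.end(), NA_INTEGER);
  std::fill(start.begin(), start.end(), NA_INTEGER);
  std::fill(strnd.begin(), strnd.end(), NA_INTEGER);
  std::fill(kidx.begin(), kidx.end(), NA_INTEGER);

  std::vector<int> last_diag(m->kmers.size(), 0);
  std::vector<int> stamp(m->kmers.size(), -1);

  for (int r = 0; r < nr; ++r) {
    SEXP rstr = STRING_ELT(reads, r);
    const char* text = CHAR(rstr);
    const int len = LENGTH(rstr);
    if (len < q) continue;

    uint64_t h = 0;
    int valid = 0; // run length of ACGT bases ending at current position
    for (int j = 0; j < len; ++j) {
      int b = base2bits(text[j]);
      if (b < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)b) & qmask;
      if (++valid < q) continue;
      const std::vector<Candidate>* cand = m->lookup(h);
      if (!cand) continue;
      const int seed_start = j - q + 1;
      for (const Candidate& c : *cand) {
        const int ki = c.kmer;
        const int fi = m->feature[ki];
        // already found a perfect hit for this feature: nothing to improve
        if (dist(r, fi) == 0) continue;
        const int diag = seed_start + c.diag;
        // repeated seed hits implying the identical placement
        if (stamp[ki] == r && last_diag[ki] == diag) continue;
        stamp[ki] = r;
        last_diag[ki] = diag;
        int from = diag - d - 1; if (from < 0) from = 0;
        int to = diag + k + d + 1; if (to > len) to = len;
        int end, dd = myers_min_dist(*m, ki, text, from, to, d, end);
        if (dd > d) continue;
        int st = end - k; if (st < 0) st = 0;
        int cur = dist(r, fi);
        if (cur == NA_INTEGER || dd < cur ||
            (dd == cur && st < start(r, fi) - 1)) {
          dist(r, fi) = dd;
          start(r, fi) = st + 1;
          strnd(r, fi) = m->strand[ki];
          kidx(r, fi) = ki + 1;
        }
      }
    }
  }
  return List::create(_["dist"] = dist, _["start"] = start,
                      _["strand"] = strnd, _["kmer"] = kidx);
}

// [[Rcpp::export(name = ".matcher_valid")]]
bool matcher_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != NULL;
}

// [[Rcpp::export(name = ".matcher_params")]]
List matcher_params(SEXP ptr) {
  Matcher* m = as_matcher(ptr);
  return List::create(_["k"] = m->k, _["max_dist"] = m->max_dist,
                      _["seed_len"] = m->q,
                      _["n_kmers"] = (int)m->kmers.size(),
                      _["n_features"] = m->n_features);
}
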