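// k-mer spectrum counting, the built-in substitution-only corrector, banded
// edit distance, sequencing-error injection, and word tokenization kernels.
// k-mers are packed 2 bits/base into uint64 (k <= 31); windows containing N
// are skipped.  Error injection draws from R's RNG so set.seed() governs it.

#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

typedef std::unordered_map<uint64_t, uint32_t> KmerMap;

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}
static const char BASES[4] = {'A', 'C', 'G', 'T'};

// [[Rcpp::export]]
SEXP cpp_count_kmers(CharacterVector reads, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  XPtr<KmerMap> ptr(new KmerMap(), true);
  const uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
  long total = 0;
  for (int i = 0; i < reads.size(); ++i) {
    const char* s = CHAR(STRING_ELT(reads, i));
    int L = LENGTH(STRING_ELT(reads, i));
    if (L < k) continue;
    uint64_t cur = 0;
    int valid = 0;
    for (int p = 0; p < L; ++p) {
      int c = base_code(s[p]);
      if (c < 0) { valid = 0; cur = 0; continue; }
      cur = ((cur << 2) | (uint64_t)c) & mask;
      if (++valid >= k) { ++(*ptr)[cur]; ++total; }
    }
  }
  ptr.attr("n_kmers_counted") = (double)total;
  return ptr;
}

// [[Rcpp::export]]
double cpp_spectrum_size(SEXP sp) {
  XPtr<KmerMap> ptr(sp);
  return (double)ptr->size();
}

// histogram of k-mer multiplicities: value -> number of distinct k-mers
// [[Rcpp::export]]
DataFrame cpp_spectrum_histogram(SEXP sp) {
  XPtr<KmerMap> ptr(sp);
  std::unordered_map<uint32_t, uint32_t> h;
  for (auto& kv : *ptr) ++h[kv.second];
  std::vector<double> cnt, n;
  for (auto& kv : h) { cnt.push_back(kv.first); n.push_back(kv.second); }
  return DataFrame::create(_["count"] = cnt, _["n_kmers"] = n);
}

static uint64_t encode_kmer(const char* s, int k, bool& ok) {
  uint64_t v = 0;
  ok = true;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { ok = false; return 0; }
    v = (v << 2) | (uint64_t)c;
  }
  return v;
}

// [[Rcpp::export]]
IntegerVector cpp_spectrum_lookup(SEXP sp, CharacterVector kmers, int k) {
  XPtr<KmerMap> ptr(sp);
  IntegerVector out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    const char* s = CHAR(STRING_ELT(kmers, i));
    if (LENGTH(STRING_ELT(kmers, i)) != k) { out[i] = NA_INTEGER; continue; }
    bool ok;
    uint64_t v = encode_kmer(s, k, ok);
    if (!ok) { out[i] = NA_INTEGER; continue; }
    auto it = ptr->find(v);
    out[i] = it == ptr->end() ? 0 : (int)it->second;
  }
  return out;
}

// [[Rcpp::export]]
DataFrame cpp_spectrum_as_df(SEXP sp, int k) {
  XPtr<KmerMap> ptr(sp);
  size_t n = ptr->size();
  if (n > 2000000) stop("spectrum too large to materialize as a data frame");
  CharacterVector kmer(n);
  IntegerVector count(n);
  std::string buf(k, 'A');
  size_t i = 0;
  for (auto& kv : *ptr) {
    uint64_t v = kv.first;
    for (int j = k - 1; j >= 0; --j) { buf[j] = BASES[v & 3ULL]; v >>= 2; }
    kmer[i] = buf;
    count[i] = (int)kv.second;
    ++i;
  }
  return DataFrame::create(_["kmer"] = kmer, _["count"] = count,
                           _["stringsAsFactors"] = false);
}

// Substitution-only greedy corrector.  Scans left to right; at the first
// insolid window, evaluates the 3 alternative bases at each of its k
// positions and commits the substitution maximizing the number of solid
// k-mers covering the changed position (strict improvement required;
// ties -> leftmost position, then lexicographically smallest base).  After
// an attempt (successful or not) scanning resumes k positions on, so there
// is at most one substitution per window and at most ceil(len/k) per read.
// [[Rcpp::export]]
List cpp_toy_correct(CharacterVector reads, int k, SEXP sp, int threshold) {
  XPtr<KmerMap> ptr(sp);
  const uint64_t mask = (k == 31) ? ((1ULL << 62) - 1) : ((1ULL << (2 * k)) - 1);
  auto solid = [&](const std::vector<int>& s, int start) -> int {
    // 1 if window [start, start+k) is solid, 0 if insolid, -1 if has N
    uint64_t v = 0;
    for (int i = start; i < start + k; ++i) {
      if (s[i] < 0) return -1;
      v = ((v << 2) | (uint64_t)s[i]) & mask;
    }
    auto it = ptr->find(v);
    return (it != ptr->end() && (int)it->second >= threshold) ? 1 : 0;
  };
  CharacterVector out(reads.size());
  IntegerVector nsub(reads.size());
  for (int r = 0; r < reads.size(); ++r) {
    const char* cs = CHAR(STRING_ELT(reads, r));
    int L = LENGTH(STRING_ELT(reads, r));
    std::string seq(cs, L);
    if (L < k) { out[r] = seq; nsub[r] = 0; continue; }
    std::vector<int> s(L);
    for (int i = 0; i < L; ++i) s[i] = base_code(seq[i]);
    int cap = (L + k - 1) / k;
    int subs = 0;
    int pos = 0;
    while (pos + k <= L && subs < cap) {
      int st = solid(s, pos);
      if (st != 0) { ++pos; continue; }  // solid or N window: slide on
      // count solid windows covering position q with s[q] temporarily = b
      auto cover_solid = [&](int q) -> int {
        int lo = std::max(0, q - k + 1), hi = std::min(L - k, q);
        int n = 0;
        for (int w = lo; w <= hi; ++w) n += (solid(s, w) == 1);
        return n;
      };
      int best_q = -1, best_b = -1, best_cnt = -1, best_gain = 0;
      for (int q = pos; q < pos + k; ++q) {
        int orig = s[q];
        int cur = cover_solid(q);
        for (int b = 0; b < 4; ++b) {
          if (b == orig) continue;
          s[q] = b;
          int cnt = cover_solid(q);
          s[q] = orig;
          if (cnt > cur && cnt > best_cnt) {
            best_cnt = cnt; best_q = q; best_b = b; best_gain = cnt - cur;
          }
        }
      }
      (void)best_gain;
      if (best_q >= 0) {
        s[best_q] = best_b;
        seq[best_q] = BASES[best_b];
        ++subs;
      }
      pos += k;  // one attempt per non-overlapping window
    }
    out[r] = seq;
    nsub[r] = subs;
  }
  return List::create(_["seq"] = out, _["n_sub"] = nsub);
}

// Banded Levenshtein distance; returns NA if the distance exceeds `band`.
static int banded_edit(const char* a, int la, const char* b, int lb, int band) {
  if (std::abs(la - lb) > band) return -1;
  const int INF = 1 << 28;
  std::vector<int> prev(2 * band + 1, INF), cur(2 * band + 1, INF);
  // column j of row i lives at index j - i + band
  for (int j = 0; j <= std::min(lb, band); ++j) prev[j + band] = j;
  for (int i = 1; i <= la; ++i) {
    std::fill(cur.begin(), cur.end(), INF);
    int jlo = std::max(0, i - band), jhi = std::min(lb, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int idx = j - i + band;  // in [0, 2*band] by construction
      int best;
      if (j == 0) {
        best = i;  // deletions only
      } else {
        best = INF;
        // deletion in a: from D[i-1][j] at prev offset idx+1
        if (idx + 1 <= 2 * band && prev[idx + 1] < INF)
          best = std::min(best, prev[idx + 1] + 1);
        // insertion: from D[i][j-1] at cur offset idx-1
        if (idx - 1 >= 0 && cur[idx - 1] < INF)
          best = std::min(best, cur[idx - 1] + 1);
        // match / mismatch: from D[i-1][j-1] at prev offset idx
        if (prev[idx] < INF)
          best = std::min(best, prev[idx] + (a[i - 1] == b[j - 1] ? 0 : 1));
      }
      cur[idx] = best;
    }
    std::swap(prev, cur);
  }
  int idx = lb - la + band;
  if (idx < 0 || idx > 2 * band || prev[idx] >= INF || prev[idx] > band)
    return -1;
  return prev[idx];
}

// [[Rcpp::export]]
IntegerVector cpp_banded_edit(CharacterVector a, CharacterVector b,
                              IntegerVector band) {
  int n = a.size();
  if (b.size() != n || band.size() != n) stop("length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int d = banded_edit(CHAR(STRING_ELT(a, i)), LENGTH(STRING_ELT(a, i)),
                        CHAR(STRING_ELT(b, i)), LENGTH(STRING_ELT(b, i)),
                        band[i]);
    out[i] = d < 0 ? NA_INTEGER : d;
  }
  return out;
}

// Inject substitution/insertion/deletion errors into oriented templates.
// Per template position exactly one of {del, ins-after, sub, none} is drawn
// (rates must sum to < 1).  Edits are recorded against 1-based template
// coordinates.  Uses R's RNG.
// [[Rcpp::export]]
List cpp_inject_errors(CharacterVector templates, double sub_rate,
                       double ins_rate, double del_rate) {
  int n = templates.size();
  CharacterVector reads(n);
  List edits(n);
  for (int i = 0; i < n; ++i) {
    const char* s = CHAR(STRING_ELT(templates, i));
    int L = LENGTH(STRING_ELT(templates, i));
    std::string out;
    out.reserve(L + 8);
    std::vector<int> pos;
    std::vector<char> op, base;
    for (int p = 0; p < L; ++p) {
      double u = unif_rand();
      if (u < del_rate) {
        pos.push_back(p + 1); op.push_back('D'); base.push_back('-');
      } else if (u < del_rate + ins_rate) {
        out.push_back(s[p]);
        char b = BASES[(int)(unif_rand() * 4) & 3];
        out.push_back(b);
        pos.push_back(p + 1); op.push_back('I'); base.push_back(b);
      } else if (u < del_rate + ins_rate + sub_rate) {
        int orig = base_code(s[p]);
        int shift = 1 + (int)(unif_rand() * 3);
        if (shift > 3) shift = 3;
        char b = BASES[(orig + shift) & 3];
        out.push_back(b);
        pos.push_back(p + 1); op.push_back('S'); base.push_back(b);
      } else {
        out.push_back(s[p]);
      }
    }
    reads[i] = out;
    IntegerVector ep(pos.begin(), pos.end());
    CharacterVector eo(op.size()), eb(base.size());
    for (size_t j = 0; j < op.size(); ++j) {
      eo[j] = std::string(1, op[j]);
      eb[j] = std::string(1, base[j]);
    }
    edits[i] = DataFrame::create(_["pos"] = ep, _["op"] = eo, _["base"] = eb,
                                 _["stringsAsFactors"] = false);
  }
  return List::create(_["seq"] = reads, _["edits"] = edits);
}

// Tokenize chunks into overlapping base-4 word ids (A=0,C=1,G=2,T=3, MSB
// first).  Chunks are assumed N-free; word ids are 0-based.
// [[Rcpp::export]]
List cpp_encode_chunks(CharacterVector chunks, int w, int stride) {
  if (w < 1 || w > 15) stop("word length out of range");
  List out(chunks.size());
  const uint64_t mask = (1ULL << (2 * w)) - 1;
  for (int i = 0; i < chunks.size(); ++i) {
    const char* s = CHAR(STRING_ELT(chunks, i));
    int L = LENGTH(STRING_ELT(chunks, i));
    int nw = L < w ? 0 : (L - w) / stride + 1;
    IntegerVector ids(nw);
    if (nw > 0) {
      for (int j = 0; j < nw; ++j) {
        uint64_t v = 0;
        const char* p = s + j * stride;
        for (int t = 0; t < w; ++t) {
          int c = base_code(p[t]);
          if (c < 0) stop("chunk %d contains a non-ACGT character", i + 1);
          v = (v << 2) | (uint64_t)c;
        }
        ids[j] = (int)(v & mask);
      }
    }
    out[i] = ids;
  }
  return out;
}
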