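// Inverted signature slice list (ISSL) core: 2-bit spacer packing, slice
// table construction, and Hamming-neighbour queries.
//
// A 20-nt spacer packs into 40 bits (A=0, C=1, G=2, T=3, leftmost base most
// significant). The spacer set is partitioned into num_slices fixed-width
// slices; each slice table inverts on the slice signature. With
// num_slices >= max_mm + 1 the pigeonhole principle guarantees that any
// spacer within max_mm mismatches matches at least one slice signature
// exactly, so gathering bucket members and verifying the full Hamming
// distance gives exact recall.
//
// Values cross the R boundary as doubles: 40-bit integers are exact in IEEE
// doubles (< 2^53) but overflow R's 32-bit integers.

#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static inline uint64_t sig_of(uint64_t v, int slice, int width, int spacer_len) {
  int shift = 2 * (spacer_len - (slice + 1) * width);
  uint64_t mask = (width >= 32) ? ~0ULL : ((1ULL << (2 * width)) - 1ULL);
  return (v >> shift) & mask;
}

// Hamming distance over 2-bit base codes.
static inline int hamming40(uint64_t x, uint64_t y) {
  uint64_t t = x ^ y;
  t = (t | (t >> 1)) & 0x5555555555555555ULL;
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(t);
#else
  int n = 0;
  while (t) { t &= t - 1; ++n; }
  return n;
#endif
}

// [[Rcpp::export(name = ".issl_encode_cpp")]]
NumericVector issl_encode_cpp(CharacterVector spacers) {
  R_xlen_t n = spacers.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(spacers, i));
    uint64_t v = 0;
    int len = 0;
    for (const char *p = s; *p; ++p, ++len) {
      int code = base_code(*p);
      if (code < 0) {
        stop("encode_spacer: symbol '%c' is not one of A,C,G,T in '%s'", *p, s);
      }
      v = (v << 2) | (uint64_t)code;
    }
    if (len != 20) {
      stop("encode_spacer: spacer '%s' has length %d, expected 20", s, len);
    }
    out[i] = (double)v;
  }
  return out;
}

// [[Rcpp::export(name = ".issl_decode_cpp")]]
CharacterVector issl_decode_cpp(NumericVector values) {
  static const char bases[] = "ACGT";
  R_xlen_t n = values.size();
  CharacterVector out(n);
  char buf[21];
  buf[20] = '\0';
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t v = (uint64_t)values[i];
    for (int j = 19; j >= 0; --j) {
      buf[j] = bases[v & 3ULL];
      v >>= 2;
    }
    out[i] = buf;
  }
  return out;
}

// Build one slice table over sorted distinct encoded values. Returns
// list(sig, ptr, items): distinct signatures ascending, CSR-style bucket
// boundaries (0-based, length nsig + 1), and 0-based indices into `values`.
// [[Rcpp::export(name = ".issl_build_slice_cpp")]]
List issl_build_slice_cpp(NumericVector values, int slice, int width) {
  R_xlen_t n = values.size();
  std::vector<std::pair<uint64_t, R_xlen_t> > pairs(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    pairs[i] = std::make_pair(sig_of((uint64_t)values[i], slice, width, 20), i);
  }
  std::stable_sort(pairs.begin(), pairs.end());
  std::vector<double> sig;
  std::vector<int> ptr;
  IntegerVector items(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (i == 0 || pairs[i].first != pairs[i - 1].first) {
      sig.push_back((double)pairs[i].first);
      ptr.push_back((int)i);
    }
    items[i] = (int)pairs[i].second;
  }
  ptr.push_back((int)n);
  return List::create(_["sig"] = NumericVector(sig.begin(), sig.end()),
                      _["ptr"] = IntegerVector(ptr.begin(), ptr.end()),
                      _["items"] = items);
}

// Exact Hamming-ball query. values/counts describe the sorted distinct
// spacer set; slices is the list produced by .issl_build_slice_cpp per
// slice. Returns matched values, distances and counts sorted by
// (distance, value).
// [[Rcpp::export(name = ".issl_query_cpp")]]
List issl_query_cpp(NumericVector values, IntegerVector counts, List slices,
                    int width, double query, int max_mm) {
  uint64_t q = (uint64_t)query;
  int num_slices = slices.size();
  std::vector<int> cand;
  for (int s = 0; s < num_slices; ++s) {
    List tab = slices[s];
    NumericVector sig = tab["sig"];
    IntegerVector ptr = tab["ptr"];
    IntegerVector items = tab["items"];
    double qs = (double)sig_of(q, s, width, 20);
    const double *lo = std::lower_bound(sig.begin(), sig.end(), qs);
    if (lo == sig.end() || *lo != qs) continue;
    int b = (int)(lo - sig.begin());
    for (int i = ptr[b]; i < ptr[b + 1]; ++i) {
      cand.push_back(items[i]);
    }
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());

  std::vector<std::pair<int, uint64_t> > hits;   // (distance, value)
  std::vector<int> hit_counts;
  for (size_t i = 0; i < cand.size(); ++i) {
    uint64_t v = (uint64_t)values[cand[i]];
    int d = hamming40(q, v);
    if (d <= max_mm) {
      hits.push_back(std::make_pair(d, v));
      hit_counts.push_back(counts[cand[i]]);
    }
  }
  // sort results by (distance, encoded value) for reproducibility
  std::vector<size_t> ord(hits.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return hits[a] < hits[b];
  });
  R_xlen_t m = (R_xlen_t)hits.size();
  NumericVector out_val(m);
  IntegerVector out_dist(m), out_count(m);
  for (R_xlen_t i = 0; i < m; ++i) {
    out_dist[i] = hits[ord[i]].first;
    out_val[i] = (double)hits[ord[i]].second;
    out_count[i] = hit_counts[ord[i]];
  }
  return List::create(_["value"] = out_val, _["distance"] = out_dist,
                      _["count"] = out_count);
}
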