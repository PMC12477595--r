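#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// 2-bit base encoding; -1 for non-ACGT (resets the rolling window)
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Append all canonical k-mers (lexicographic min of k-mer and its reverse
// complement under the 2-bit encoding) of s[0..n) to out. Windows containing
// non-ACGT characters are skipped. Requires 8 <= k <= 32.
static void canonical_kmers(const char *s, int n, int k,
                            std::vector<uint64_t> &out) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int len = 0;
  for (int i = 0; i < n; i++) {
    int c = base_code(s[i]);
    if (c < 0) { len = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)c) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
    if (++len >= k) out.push_back(fwd < rev ? fwd : rev);
  }
}

//' @noRd
// [[Rcpp::export(name = ".cpp_subset_redundancy")]]
List cpp_subset_redundancy(CharacterVector reads, IntegerVector subset_idx,
                           IntegerVector query_idx, int k, double min_frac) {
  if (k < 8 || k > 32) stop("k must be in [8, 32]");
  std::unordered_map<uint64_t, int32_t> tab;
  tab.reserve(subset_idx.size() * 64);
  std::vector<uint64_t> buf;
  int skipped = 0;

  for (R_xlen_t j = 0; j < subset_idx.size(); j++) {
    SEXP sx = STRING_ELT(reads, subset_idx[j] - 1);
    buf.clear();
    canonical_kmers(CHAR(sx), LENGTH(sx), k, buf);
    if (buf.empty()) { skipped++; continue; }
    for (uint64_t km : buf) tab[km]++;
  }

  // A query read (a member of the subset) is redundant iff at least min_frac
  // of its k-mer positions carry a canonical k-mer that occurs in the subset
  // outside the read itself (total multiplicity > within-read multiplicity).
  int n_query = 0, n_red = 0;
  std::unordered_map<uint64_t, int32_t> local;
  for (R_xlen_t j = 0; j < query_idx.size(); j++) {
    SEXP sx = STRING_ELT(reads, query_idx[j] - 1);
    buf.clear();
    canonical_kmers(CHAR(sx), LENGTH(sx), k, buf);
    if (buf.empty()) continue;
    local.clear();
    for (uint64_t km : buf) local[km]++;
    long hits = 0;
    for (auto &kv : local) {
      auto it = tab.find(kv.first);
      int32_t total = (it == tab.end()) ? 0 : it->second;
      if (total - kv.second > 0) hits += kv.second;
    }
    n_query++;
    if ((double)hits >= min_frac * (double)buf.size()) n_red++;
  }

  return List::create(_["redundant"] = n_red, _["queries"] = n_query,
                      _["skipped_short"] = skipped);
}
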