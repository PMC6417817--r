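// Exact canonical k-mer counting over read sets.
//
// For k <= 32 k-mers are packed 2 bits per base (A=0, C=1, G=2, T=3, first
// base most significant), which preserves the lexicographic order of ACGT
// strings, so min(forward, reverse-complement) of the packed words equals
// the packed canonical k-mer. Longer k falls back to a string hash table.

#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <cstdint>

using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  }
  return -1;
}

// [[Rcpp::export]]
List kmer_scan_cpp(CharacterVector reads, CharacterVector kmers,
                   IntegerVector gene_id, int n_genes, int k) {
  const int n_kmers = kmers.size();
  IntegerVector counts(n_kmers);
  IntegerVector gene_hits(n_genes);
  std::vector<int> last_hit(n_genes, -1);

  if (k <= 32) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    std::unordered_map<uint64_t, int> table;
    table.reserve(n_kmers * 2 + 1);
    for (int i = 0; i < n_kmers; ++i) {
      const char* s = CHAR(STRING_ELT(kmers, i));
      uint64_t key = 0;
      for (int j = 0; j < k; ++j) {
        int b = base2bits(s[j]);
        if (b < 0) stop("index k-mer contains a non-ACGT base");
        key = (key << 2) | (uint64_t)b;
      }
      table[key] = i;
    }
    const int shift = 2 * (k - 1);
    for (int r = 0; r < reads.size(); ++r) {
      const char* s = CHAR(STRING_ELT(reads, r));
      uint64_t fwd = 0, rc = 0;
      int run = 0;
      for (int p = 0; s[p] != '\0'; ++p) {
        int b = base2bits(s[p]);
        if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rc = (rc >> 2) | ((uint64_t)(3 - b) << shift);
        if (++run >= k) {
          uint64_t key = fwd < rc ? fwd : rc;
          auto it = table.find(key);
          if (it != table.end()) {
            counts[it->second]++;
            int g = gene_id[it->second] - 1;
            if (g >= 0 && last_hit[g] != r) { last_hit[g] = r; gene_hits[g]++; }
          }
        }
      }
    }
  } else {
    std::unordered_map<std::string, int> table;
    table.reserve(n_kmers * 2 + 1);
    for (int i = 0; i < n_kmers; ++i)
      table[std::string(CHAR(STRING_ELT(kmers, i)))] = i;
    std::string win, rc;
    win.resize(k); rc.resize(k);
    for (int r = 0; r < reads.size(); ++r) {
      const char* s = CHAR(STRING_ELT(reads, r));
      int len = (int)strlen(s);
      for (int p = 0; p + k <= len; ++p) {
        bool ok = true;
        for (int j = 0; j < k; ++j) {
          char c = s[p + j];
          int b = base2bits(c);
          if (b < 0) { ok = false; break; }
          win[j] = c;
          rc[k - 1 - j] = "TGCA"[b];
        }
        if (!ok) continue;
        const std::string& key = (win < rc) ? win : rc;
        auto it = table.find(key);
        if (it != table.end()) {
          counts[it->second]++;
          int g = gene_id[it->second] - 1;
          if (g >= 0 && last_hit[g] != r) { last_hit[g] = r; gene_hits[g]++; }
        }
      }
    }
  }
  return List::create(_["counts"] = counts, _["gene_hits"] = gene_hits);
}
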