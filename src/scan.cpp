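// Index-free genome scan.
//
// Each chromosome is shifted one base at a time through a single 64-bit
// register, so the last 32 bases seen can be read off in 2-bit format.  All
// primer variants (concrete expansions and their reverse complements,
// truncated to their last 32 bases) are encoded the same way; each variant's
// last N bases (N = length of the shortest primer, <= 32) form a fixed-width
// key in a sorted table.  At every genome position the last N bases are
// looked up by binary search; only on a key hit is the variant's full window
// verified.  Windows touching a non-ACGT base produce no hits.

#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or any other code invalidates the window
  }
}

static inline uint64_t mask_bases(int n) {
  return n >= 32 ? ~uint64_t(0) : ((uint64_t(1) << (2 * n)) - 1);
}

struct Variant {
  uint64_t value;  // last 3' base in the lowest 2 bits
  uint64_t key;    // value & mask_bases(N)
  int len;
  int idx;         // 1-based index into the variant table passed from R
};

static std::vector<Variant> encode_variants(const CharacterVector& seqs,
                                            int n_key) {
  std::vector<Variant> vars;
  vars.reserve(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    const char* s = CHAR(STRING_ELT(seqs, i));
    uint64_t v = 0;
    int len = 0;
    for (const char* p = s; *p; ++p, ++len) {
      int b = base2bit(*p);
      if (b < 0) stop("variant sequences must be ACGT only");
      v = (v << 2) | uint64_t(b);
    }
    if (len > 32) stop("variant longer than 32 bases");
    if (len < n_key) stop("variant shorter than the key length");
    Variant var;
    var.value = v & mask_bases(len);
    var.key = v & mask_bases(n_key);
    var.len = len;
    var.idx = i + 1;
    vars.push_back(var);
  }
  std::sort(vars.begin(), vars.end(),
            [](const Variant& a, const Variant& b) {
              return a.key < b.key || (a.key == b.key && a.idx < b.idx);
            });
  return vars;
}

// [[Rcpp::export]]
List cpp_scan_chromosome(std::string seq, CharacterVector variants,
                         int n_key) {
  if (n_key < 1 || n_key > 32) stop("key length must be in [1, 32]");
  std::vector<Variant> vars = encode_variants(variants, n_key);
  std::vector<int> hit_variant;
  std::vector<double> hit_pos;  // 1-based position of the 3'-most base

  const uint64_t keymask = mask_bases(n_key);
  uint64_t window = 0;
  long long run = 0;  // consecutive ACGT bases ending here
  const size_t n = seq.size();
  for (size_t i = 0; i < n; ++i) {
    int b = base2bit(seq[i]);
    if (b < 0) { run = 0; window = 0; continue; }
    window = (window << 2) | uint64_t(b);
    ++run;
    if (run < n_key) continue;
    uint64_t key = window & keymask;
    // binary search over the sorted fixed-length keys
    Variant probe; probe.key = key; probe.idx = 0;
    auto lo = std::lower_bound(vars.begin(), vars.end(), probe,
                               [](const Variant& a, const Variant& b) {
                                 return a.key < b.key;
                               });
    for (auto it = lo; it != vars.end() && it->key == key; ++it) {
      // full-window verification over the variant's entire length
      if (run >= it->len &&
          (window & mask_bases(it->len)) == it->value) {
        hit_variant.push_back(it->idx);
        hit_pos.push_back(double(i + 1));  // 1-based inclusive
      }
    }
  }
  return List::create(_["variant"] = wrap(hit_variant),
                      _["pos3"] = wrap(hit_pos));
}
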