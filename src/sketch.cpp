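#include <Rcpp.h>
#include <queue>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

// SplitMix64 finalizer: a published 64-bit mixing hash, stable across
// platforms; versioned here as hash "splitmix64/1".
static inline uint64_t splitmix64(uint64_t x) {
  uint64_t z = x + 0x9E3779B97F4A7C15ULL;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1; // N or anything else: k-mers through here are skipped
  }
}

// Bottom-s MinHash sketch of the canonical k-mers of one sequence.
// Canonical k-mer = min(forward, reverse complement) under the 2-bit
// A<C<G<T encoding (equals lexicographic order on ACGT strings).
// Returns the sketch as sorted doubles: hash >> 11, i.e. the top 53 bits,
// exactly representable in an R numeric.
// [[Rcpp::export]]
NumericVector cpp_sketch(std::string seq, int k, int sketch_size) {
  int n = (int) seq.size();
  if (k < 1 || k > 31) stop("k must be in 1..31");
  if (n < k) stop("sequence shorter than k");
  if (sketch_size < 1) stop("sketch_size must be >= 1");

  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift_rc = 2 * (k - 1);

  uint64_t fwd = 0, rc = 0;
  int filled = 0; // valid bases accumulated in current window

  // max-heap over the kept (smallest) hashes + membership set for dedup
  std::priority_queue<uint64_t> heap;
  std::unordered_set<uint64_t> kept;

  for (int i = 0; i < n; ++i) {
    int code = base_code(seq[i]);
    if (code < 0) { filled = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t) code) & mask;
    rc = (rc >> 2) | (((uint64_t) (3 - code)) << shift_rc);
    if (filled < k) ++filled;
    if (filled < k) continue;
    uint64_t canon = fwd < rc ? fwd : rc;
    uint64_t h = splitmix64(canon) >> 11; // 53-bit value
    if (kept.count(h)) continue;
    if ((int) kept.size() < sketch_size) {
      kept.insert(h);
      heap.push(h);
    } else if (h < heap.top()) {
      kept.erase(heap.top());
      heap.pop();
      kept.insert(h);
      heap.push(h);
    }
  }

  NumericVector out(kept.size());
  int i = (int) kept.size() - 1;
  while (!heap.empty()) {
    out[i--] = (double) heap.top();
    heap.pop();
  }
  return out; // ascending
}
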