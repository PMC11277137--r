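#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <vector>

// Pruned depth-first enumeration of circular sequences whose overlapping
// words (read at every circular start offset) cover all required classes
// of a synonymy table.
//
// The key bound: with L words and R required classes, a completed ring has
// exactly L - R "wasted" words (words whose class is unrequired, e.g. STOP,
// or already covered). A partial assignment is abandoned as soon as its
// waste exceeds L - R; this is equivalent to the usual
// "uncovered classes > undetermined words" bound but testable in O(1)
// per extension.
//
// Solutions are deduplicated up to rotation by counting only sequences that
// are the lexicographically minimal rotation of their class; the raw
// (marked-start) count is tracked alongside for audit.

namespace {

struct Search {
  int L, m, w;
  int allowed_waste;
  const int *cls;          // word index -> required-class id, -1 = unrequired
  uint64_t full_mask;
  bool collect;
  std::vector<int> s;
  std::vector<int> pow_m;  // m^(w-1-k)
  long long n_raw = 0, n_canonical = 0, nodes = 0;
  std::vector<std::string> solutions;
  const char *letters;

  bool is_canonical() const {
    for (int r = 1; r < L; ++r) {
      for (int i = 0; i < L; ++i) {
        int a = s[i], b = s[(i + r) % L];
        if (b < a) return false;
        if (b > a) break;
      }
    }
    return true;
  }

  int word_at(int off) const {
    int v = 0;
    for (int k = 0; k < w; ++k) v += s[(off + k) % L] * pow_m[k];
    return v;
  }

  void leaf(uint64_t covered, int waste) {
    // close the w-1 wraparound words
    for (int off = L - w + 1; off < L; ++off) {
      int c = cls[word_at(off)];
      if (c < 0 || ((covered >> c) & 1ULL)) {
        if (++waste > allowed_waste) return;
      } else {
        covered |= 1ULL << c;
      }
    }
    if (covered != full_mask) return;
    ++n_raw;
    if (!is_canonical()) return;
    ++n_canonical;
    if (collect) {
      std::string out(L, 'x');
      for (int i = 0; i < L; ++i) out[i] = letters[s[i]];
      solutions.push_back(out);
    }
  }

  void dfs(int p, uint64_t covered, int waste, int widx) {
    if (p == L) { leaf(covered, waste); return; }
    if ((++nodes & 0xFFFFFF) == 0) Rcpp::checkUserInterrupt();
    for (int c = 0; c < m; ++c) {
      s[p] = c;
      if (p >= w - 1) {
        // widx holds the base-m index of s[p-w+1..p-1]; appending c
        // completes the word starting at p-w+1, and dropping its leading
        // symbol (mod m^(w-1)) yields the next rolling index.
        int word = widx * m + c;
        int cl = cls[word];
        if (cl < 0 || ((covered >> cl) & 1ULL)) {
          if (waste + 1 <= allowed_waste)
            dfs(p + 1, covered, waste + 1, word % pow_m[0]);
        } else {
          dfs(p + 1, covered | (1ULL << cl), waste, word % pow_m[0]);
        }
      } else {
        dfs(p + 1, covered, waste, widx * m + c);
      }
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".ring_search_cpp")]]
Rcpp::List ring_search_cpp(int L, int m, int w,
                           Rcpp::IntegerVector cls, int n_required,
                           std::string alphabet, bool collect) {
  if (n_required > 64) Rcpp::stop("more than 64 required classes unsupported");
  if (L < w) Rcpp::stop("ring length below word length");
  Search sr;
  sr.L = L; sr.m = m; sr.w = w;
  sr.allowed_waste = L - n_required;
  sr.cls = cls.begin();
  sr.full_mask = (n_required == 64) ? ~0ULL : ((1ULL << n_required) - 1);
  sr.collect = collect;
  sr.s.assign(L, 0);
  sr.letters = alphabet.c_str();
  sr.pow_m.assign(w, 1);
  for (int k = w - 2; k >= 0; --k) sr.pow_m[k] = sr.pow_m[k + 1] * m;
  // pow_m[0] = m^(w-1): modulus that drops the leading symbol of the rolling
  // word index.
  if (sr.allowed_waste >= 0) sr.dfs(0, 0ULL, 0, 0);
  return Rcpp::List::create(
      Rcpp::Named("n_raw") = (double)sr.n_raw,
      Rcpp::Named("n_canonical") = (double)sr.n_canonical,
      Rcpp::Named("nodes") = (double)sr.nodes,
      Rcpp::Named("solutions") = Rcpp::wrap(sr.solutions));
}
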