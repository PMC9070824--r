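#include <Rcpp.h>
using namespace Rcpp;

// Pairing predicate for symmetric repeats.  In complement mode (inverted
// repeats) a left-arm base pairs with the Watson-Crick complement of its
// right-arm partner; in mirror mode (H-DNA style mirror repeats) with the
// identical base.  'N' never pairs with anything in either mode.
static inline char wc_complement(char b) {
    switch (b) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 0;   // N or anything else: pairs with nothing
    }
}

static inline bool pair_match(const char *s, int p, int q, bool mirror) {
    char a = s[p], b = s[q];
    if (a == 'N' || b == 'N') return false;
    if (mirror) return a == b;
    char c = wc_complement(b);
    return c != 0 && a == c;
}

// Enumerate all maximal symmetric repeats (arm, gap, arm) in seq.
//
// An occurrence is identified by its innermost arm pair (i, j): i is the last
// base of the left arm, j the first base of the right arm, gap = j - i - 1.
// It is reported iff
//   * the innermost pair matches (it is an arm pair by definition),
//   * the gap cannot be shrunk: gap < 2 or the pair just inside the gap
//     (i+1, j-1) does not match,
//   * outward extension stops at a mismatch / sequence edge, or the arm is
//     capped at max_arm,
//   * min_arm <= arm <= max_arm and gap <= gap_limit.
// Every maximal occurrence has a unique innermost pair, so this enumeration
// is exhaustive and duplicate-free.
// [[Rcpp::export]]
DataFrame symmetric_scan_cpp(std::string seq, int min_arm, int max_arm,
                             int gap_limit, bool mirror) {
    const char *s = seq.c_str();
    const int n = (int) seq.size();
    std::vector<int> left_start, arm_len, gap_len;

    for (int i = 0; i < n - 1; ++i) {
        int jmax = i + 1 + gap_limit;
        if (jmax > n - 1) jmax = n - 1;
        for (int j = i + 1; j <= jmax; ++j) {
            if (!pair_match(s, i, j, mirror)) continue;
            int g = j - i - 1;
            if (g >= 2 && pair_match(s, i + 1, j - 1, mirror)) continue;
            int a = 1;
            while (a < max_arm && i - a >= 0 && j + a < n &&
                   pair_match(s, i - a, j + a, mirror))
                ++a;
            if (a < min_arm) continue;
            left_start.push_back(i - a + 1);
            arm_len.push_back(a);
            gap_len.push_back(g);
        }
    }
    return DataFrame::create(_["left_start"] = left_start,
                             _["arm_len"]   = arm_len,
                             _["gap_len"]   = gap_len);
}
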