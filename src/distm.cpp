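#include <Rcpp.h>
#include <limits>
#include <vector>
#include <string>

using namespace Rcpp;

// Edit distance with unit costs where every maximal run of insertions must
// have length divisible by m, and likewise for deletions (m = 1 gives the
// classical Levenshtein distance). DP layers track the phase of the current
// gap run; a run may only be closed when its phase returns to 0. Pairs whose
// length difference is not 0 mod m are unreachable and yield +Inf.
// [[Rcpp::export]]
double dist_m_cpp(std::string s, std::string t, int m) {
    if (m < 1) stop("m must be >= 1");
    const int ns = s.size(), nt = t.size();
    const int INF = std::numeric_limits<int>::max() / 4;
    // layers: 0 = free (no open run); 1..m-1 insertion phase; m..2m-2 deletion phase
    const int nl = (m == 1) ? 1 : (2 * m - 1);
    std::vector<int> D((ns + 1) * (nt + 1) * nl, INF);
    auto at = [&](int i, int j, int l) -> int& {
        return D[(i * (nt + 1) + j) * nl + l];
    };
    at(0, 0, 0) = 0;
    for (int i = 0; i <= ns; ++i) {
        for (int j = 0; j <= nt; ++j) {
            for (int l = 0; l < nl; ++l) {
                int cur = at(i, j, l);
                if (cur >= INF) continue;
                if (l == 0) {
                    if (i < ns && j < nt) { // substitute / match
                        int c = cur + (s[i] == t[j] ? 0 : 1);
                        if (c < at(i + 1, j + 1, 0)) at(i + 1, j + 1, 0) = c;
                    }
                    if (j < nt) { // open insertion run
                        int l2 = (m == 1) ? 0 : 1;
                        if (cur + 1 < at(i, j + 1, l2)) at(i, j + 1, l2) = cur + 1;
                    }
                    if (i < ns) { // open deletion run
                        int l2 = (m == 1) ? 0 : m;
                        if (cur + 1 < at(i + 1, j, l2)) at(i + 1, j, l2) = cur + 1;
                    }
                } else if (l < m) { // inside insertion run, phase l
                    if (j < nt) {
                        int l2 = (l + 1 == m) ? 0 : l + 1;
                        if (cur + 1 < at(i, j + 1, l2)) at(i, j + 1, l2) = cur + 1;
                    }
                } else { // inside deletion run, phase l - m + 1
                    if (i < ns) {
                        int ph = l - m + 1;
                        int l2 = (ph + 1 == m) ? 0 : m + ph;
                        if (cur + 1 < at(i + 1, j, l2)) at(i + 1, j, l2) = cur + 1;
                    }
                }
            }
        }
    }
    int best = at(ns, nt, 0);
    if (best >= INF) return R_PosInf;
    return (double)best;
}
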