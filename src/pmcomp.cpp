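#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Sankoff-style simultaneous alignment of two base-pairing probability
// matrices (the pmcomp idea): maximize the summed pair-of-pairs bonus
// psi(p,q) = sqrt(p*q) over matched base pairs, plus sigma for every matched
// unpaired position and a linear gap penalty. The DP runs over pairs of
// subsequence intervals (i..j of A, k..l of B) with a diagonal band of width
// `band` on both interval ends; band >= max(nA, nB) is exact.
//
// Candidate pairs are the matrix entries with probability >= pmin. For each
// right-end combination (j, l) the pair-match bonus and its inner-interval
// score are hoisted out of the (i, k) loops.
// [[Rcpp::export]]
double pmcomp_cpp(NumericMatrix PA, NumericMatrix PB, double sigma,
                  double gap, double pmin, int band) {
    const int nA = PA.nrow(), nB = PB.nrow();
    if (PA.ncol() != nA || PB.ncol() != nB)
        stop("probability matrices must be square");
    const double NEG = -std::numeric_limits<double>::infinity();
    const int w = band;
    if (std::abs(nA - nB) > w)
        stop("length difference exceeds band width");

    // candidate pairs indexed by right end (1-based ends)
    std::vector<std::vector<std::pair<int, double> > > candA(nA + 1), candB(nB + 1);
    for (int j = 1; j <= nA; ++j)
        for (int p = 1; p < j; ++p)
            if (PA(p - 1, j - 1) >= pmin)
                candA[j].push_back(std::make_pair(p, PA(p - 1, j - 1)));
    for (int l = 1; l <= nB; ++l)
        for (int q = 1; q < l; ++q)
            if (PB(q - 1, l - 1) >= pmin)
                candB[l].push_back(std::make_pair(q, PB(q - 1, l - 1)));

    // state (i,j,k,l): intervals A[i..j], B[k..l]; i in 1..nA+1, j in i-1..nA,
    // banded offsets dk = k - i, dl = l - j, both in [-w, w]; dl fastest.
    const long W = 2L * w + 1;
    std::vector<long> rowOff(nA + 3, 0);
    {
        long acc = 0;
        for (int i = 1; i <= nA + 1; ++i) {
            rowOff[i] = acc;
            acc += (long)(nA - (i - 1) + 2); // j from i-1 .. nA
        }
        rowOff[nA + 2] = acc;
    }
    const long WW = W * W;
    std::vector<double> S(rowOff[nA + 2] * WW, NEG);
    // base of the (i,j) block
    auto blk = [&](int i, int j) -> double* {
        return &S[(rowOff[i] + (j - (i - 1))) * WW];
    };
    // checked random access
    auto get = [&](int i, int j, int k, int l) -> double {
        if (i < 1 || i > nA + 1 || j < i - 1 || j > nA) return NEG;
        if (k < 1 || k > nB + 1 || l < k - 1 || l > nB) return NEG;
        int dk = k - i, dl = l - j;
        if (dk < -w || dk > w || dl < -w || dl > w) return NEG;
        return blk(i, j)[(dk + w) * W + (dl + w)];
    };

    struct Combo { int p, q; double val; };
    std::vector<Combo> combos;

    for (int j = 0; j <= nA; ++j) {
        int lLo = std::max(0, j - w), lHi = std::min(nB, j + w);
        for (int l = lLo; l <= lHi; ++l) {
            // pair-match combos for right ends (j, l): bonus + inner score
            combos.clear();
            if (j >= 1 && l >= 1 && !candA[j].empty() && !candB[l].empty()) {
                for (size_t a = 0; a < candA[j].size(); ++a) {
                    int p = candA[j][a].first;
                    for (size_t b = 0; b < candB[l].size(); ++b) {
                        int q = candB[l][b].first;
                        if (std::abs(p - q) > w) continue;
                        double inner = get(p + 1, j - 1, q + 1, l - 1);
                        if (inner == NEG) continue;
                        Combo c;
                        c.p = p; c.q = q;
                        c.val = inner +
                            std::sqrt(candA[j][a].second * candB[l][b].second);
                        combos.push_back(c);
                    }
                }
            }
            const int nCombo = (int)combos.size();
            for (int i = j + 1; i >= 1; --i) {
                int dkLo = std::max(1, i - w), dkHi = std::min(nB + 1, i + w);
                double* cur = blk(i, j);
                const double* upJ = (j >= i) ? blk(i, j - 1) : NULL;
                for (int k = dkLo; k <= dkHi; ++k) {
                    if (k > l + 1) continue;
                    const int dk = k - i + w, dl = l - j + w;
                    double best;
                    if (i == j + 1 && k == l + 1) {
                        best = 0.0;
                    } else if (i == j + 1) {
                        best = gap * (l - k + 1);
                    } else if (k == l + 1) {
                        best = gap * (j - i + 1);
                    } else {
                        best = NEG;
                        // A[j] gapped: (i, j-1, k, l) -> dl shifts by +1
                        if (upJ && dl + 1 <= 2 * w) {
                            double v = upJ[dk * W + (dl + 1)];
                            if (v != NEG && v + gap > best) best = v + gap;
                        }
                        // B[l] gapped: (i, j, k, l-1)
                        if (dl - 1 >= 0 && l - 1 >= k - 1) {
                            double v = cur[dk * W + (dl - 1)];
                            if (v != NEG && v + gap > best) best = v + gap;
                        }
                        // unpaired match: (i, j-1, k, l-1)
                        if (upJ) {
                            double v = upJ[dk * W + dl];
                            if (v != NEG && v + sigma > best) best = v + sigma;
                        }
                        // matched base pairs ending at (j, l)
                        for (int c = 0; c < nCombo; ++c) {
                            const Combo& cb = combos[c];
                            if (cb.p < i || cb.q < k) continue;
                            // left part (i, p-1, k, q-1): dk unchanged,
                            // dl = q - p
                            int dql = cb.q - cb.p + w;
                            if (dql < 0 || dql > 2 * w) continue;
                            double left =
                                blk(i, cb.p - 1)[dk * W + dql];
                            if (left == NEG) continue;
                            double sc = left + cb.val;
                            if (sc > best) best = sc;
                        }
                    }
                    cur[dk * W + dl] = best;
                }
            }
        }
    }
    double res = get(1, nA, 1, nB);
    if (res == NEG) stop("banded DP could not reach the full alignment");
    return res;
}
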