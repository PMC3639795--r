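#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>

using namespace Rcpp;

// Affine-gap Smith-Waterman on integer-encoded peptides; a gap of length g
// costs gapOpen + g * gapExt (BLAST convention for open 11 / extend 1).
static int sw_score(const std::vector<int>& a, const std::vector<int>& b,
                    const IntegerMatrix& sm, int gapOpen, int gapExt) {
    const int n = a.size(), m = b.size();
    const int NEG = -1000000;
    std::vector<int> M(m + 1, 0), X(m + 1, NEG), Y(m + 1, NEG);
    int best = 0;
    for (int i = 1; i <= n; ++i) {
        int diagM = 0, diagX = NEG, diagY = NEG; // cell (i-1, 0)
        M[0] = 0; X[0] = NEG;
        for (int j = 1; j <= m; ++j) {
            int s = sm(a[i - 1], b[j - 1]);
            int prevM = M[j], prevX = X[j], prevY = Y[j];
            int h = std::max(diagM, std::max(diagX, diagY));
            int newM = std::max(0, h + s);
            // Y: gap in B (consume a[i])
            int newY = std::max(prevM - gapOpen - gapExt, prevY - gapExt);
            // X: gap in A (consume b[j]) -- uses current row, previous column
            int leftM = (j >= 1) ? M[j - 1] : 0;
            int leftX = (j >= 1) ? X[j - 1] : NEG;
            int newX = std::max(leftM - gapOpen - gapExt, leftX - gapExt);
            diagM = prevM; diagX = prevX; diagY = prevY;
            M[j] = newM; X[j] = newX; Y[j] = newY;
            if (newM > best) best = newM;
        }
    }
    return best;
}

// [[Rcpp::export]]
int sw_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix scoreMat,
                 int gapOpen, int gapExt) {
    std::vector<int> va(a.begin(), a.end()), vb(b.begin(), b.end());
    return sw_score(va, vb, scoreMat, gapOpen, gapExt);
}

// All-vs-all Smith-Waterman over a set of equal-length peptides with a
// shared-word (k-mer) seed prefilter, as a translated-search backend.
// peps: M x L matrix of 0-based amino-acid codes (< 32). Returns pairs
// (1-based indices, i < j) whose SW score is > 0, with the score.
// [[Rcpp::export]]
DataFrame pylis_allpairs_cpp(IntegerMatrix peps, IntegerMatrix scoreMat,
                             int gapOpen, int gapExt, int seedLen) {
    const int M = peps.nrow(), L = peps.ncol();
    std::unordered_map<int64_t, std::vector<int> > words;
    for (int i = 0; i < M; ++i) {
        for (int p = 0; p + seedLen <= L; ++p) {
            int64_t key = 0;
            for (int q = 0; q < seedLen; ++q) key = key * 32 + peps(i, p + q);
            std::vector<int>& v = words[key];
            if (v.empty() || v.back() != i) v.push_back(i);
        }
    }
    std::unordered_set<int64_t> seen;
    std::vector<int> qi, sj;
    std::vector<int> sc;
    for (std::unordered_map<int64_t, std::vector<int> >::iterator it = words.begin();
         it != words.end(); ++it) {
        const std::vector<int>& v = it->second;
        for (size_t x = 0; x < v.size(); ++x) {
            for (size_t y = x + 1; y < v.size(); ++y) {
                int i = v[x], j = v[y];
                int64_t key = (int64_t)i * M + j;
                if (!seen.insert(key).second) continue;
                std::vector<int> a(L), b(L);
                for (int p = 0; p < L; ++p) { a[p] = peps(i, p); b[p] = peps(j, p); }
                int s = sw_score(a, b, scoreMat, gapOpen, gapExt);
                if (s > 0) {
                    qi.push_back(i + 1);
                    sj.push_back(j + 1);
                    sc.push_back(s);
                }
            }
        }
    }
    return DataFrame::create(Named("query") = qi, Named("subject") = sj,
                             Named("score") = sc);
}
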