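#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>

using namespace Rcpp;

// McCaskill-style partition function over nested secondary structures with a
// simplified per-pair energy model (no stacking or loop terms). Returns the
// matrix of base-pairing probabilities P[i][j] (upper triangle, 1-based i<j).
//
// Energies are in the same units as kT; Boltzmann weight of a pair is
// exp(-E/kT). Pairs closer than minHairpin unpaired bases are forbidden.
// [[Rcpp::export]]
NumericMatrix bpp_cpp(std::string seq, double kT, double eGC, double eAU,
                      double eGU, int minHairpin) {
    const int n = seq.size();
    if (n < 1) stop("empty sequence");
    std::string u(seq);
    for (int i = 0; i < n; ++i) {
        char c = toupper(u[i]);
        if (c == 'T') c = 'U';
        u[i] = c;
    }
    auto weight = [&](int i, int j) -> double { // 0-based
        char a = u[i], b = u[j];
        if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G'))
            return std::exp(-eGC / kT);
        if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A'))
            return std::exp(-eAU / kT);
        if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G'))
            return std::exp(-eGU / kT);
        return 0.0;
    };
    const int span = minHairpin + 1; // j - i >= span for a pair (0-based)

    // Q(i,j): partition function of subsequence i..j (0-based, empty -> 1)
    std::vector<std::vector<double> > Q(n, std::vector<double>(n, 1.0));
    std::vector<std::vector<double> > Qb(n, std::vector<double>(n, 0.0));
    auto q = [&](int i, int j) -> double {
        if (i > j) return 1.0;
        return Q[i][j];
    };
    for (int d = 1; d < n; ++d) {
        for (int i = 0; i + d < n; ++i) {
            int j = i + d;
            if (d >= span) {
                double w = weight(i, j);
                if (w > 0) Qb[i][j] = w * q(i + 1, j - 1);
            }
            double s = q(i, j - 1); // j unpaired
            for (int k = i; k <= j - span; ++k) {
                if (Qb[k][j] > 0) s += q(i, k - 1) * Qb[k][j];
            }
            Q[i][j] = s;
        }
    }
    const double Ztot = q(0, n - 1);

    // Outside values Qout(i,j): partition function over the exterior of a
    // closed substructure at (i,j), decomposed by the innermost enclosing pair.
    NumericMatrix P(n, n);
    std::vector<std::vector<double> > Qout(n, std::vector<double>(n, 0.0));
    for (int d = n - 1; d >= span; --d) {
        for (int i = 0; i + d < n; ++i) {
            int j = i + d;
            if (Qb[i][j] <= 0) continue;
            double s = q(0, i - 1) * q(j + 1, n - 1);
            for (int k = 0; k < i; ++k) {
                for (int l = j + 1; l < n; ++l) {
                    if (Qb[k][l] <= 0) continue;
                    double w = weight(k, l);
                    s += w * q(k + 1, i - 1) * q(j + 1, l - 1) * Qout[k][l];
                }
            }
            Qout[i][j] = s;
            P(i, j) = Qb[i][j] * s / Ztot;
        }
    }
    return P;
}
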