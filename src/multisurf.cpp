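#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// MultiSURF* attribute scoring.
//
// Attribute difference: |a - b| / 2 (genotypes are range-2 integers).
// Instance distance: mean attribute difference.
// For each target instance i: threshold T_i = mean distance to all other
// instances, dead band half-width sd_i / 2 (sample standard deviation of
// those distances). Neighbour j is "near" when d(i,j) < T_i - sd_i/2 and
// "far" when d(i,j) > T_i + sd_i/2; the dead band is ignored.
// Score updates per attribute: near miss +diff, near hit -diff,
// far miss -diff, far hit +diff. Final scores are divided by n.
//
// [[Rcpp::export(name = ".multisurfStarCpp")]]
NumericVector multisurf_star_cpp(IntegerMatrix X, IntegerVector y) {
    const int n = X.nrow(), p = X.ncol();
    NumericVector scores(p);
    if (n < 3 || p == 0)
        return scores;

    // pairwise distances (mean attribute diff), stored dense
    std::vector<double> D((size_t)n * n, 0.0);
    const double norm = 2.0 * p;
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double s = 0.0;
            for (int a = 0; a < p; ++a)
                s += std::abs((double)X(i, a) - (double)X(j, a));
            s /= norm;
            D[(size_t)i * n + j] = s;
            D[(size_t)j * n + i] = s;
        }
    }

    for (int i = 0; i < n; ++i) {
        double sum = 0.0, sq = 0.0;
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            double d = D[(size_t)i * n + j];
            sum += d;
            sq += d * d;
        }
        const int m = n - 1;
        double mean = sum / m;
        double var = (sq - m * mean * mean) / (m - 1);
        if (var < 0) var = 0;
        double half = std::sqrt(var) / 2.0;
        double lo = mean - half, hi = mean + half;
        for (int j = 0; j < n; ++j) {
            if (j == i) continue;
            double d = D[(size_t)i * n + j];
            int sgn;
            bool miss = y[i] != y[j];
            if (d < lo)      sgn = miss ? +1 : -1;   // near
            else if (d > hi) sgn = miss ? -1 : +1;   // far
            else continue;                           // dead band
            for (int a = 0; a < p; ++a) {
                double diff =
                    std::abs((double)X(i, a) - (double)X(j, a)) / 2.0;
                scores[a] += sgn * diff;
            }
        }
    }
    for (int a = 0; a < p; ++a)
        scores[a] /= n;
    return scores;
}
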