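#include <Rcpp.h>
using namespace Rcpp;

// Abundance-weighted beta mean nearest taxon distance.
//
// D is the patristic matrix restricted to the regional pool; xi/yi are
// 0-based positions of the taxa present in each community; xw/yw their
// relative abundances (summing to 1 over the support). perm, when
// non-null, maps pool position -> shuffled pool position (the tip-shuffle
// null model: relabelling taxa across the tips of the phylogeny).
static double bmntd_core(const NumericMatrix& D,
                         const IntegerVector& xi, const NumericVector& xw,
                         const IntegerVector& yi, const NumericVector& yw,
                         const int* perm) {
    const int nx = xi.size(), ny = yi.size();
    double s = 0.0;
    for (int a = 0; a < nx; ++a) {
        const int i = perm ? perm[xi[a]] : xi[a];
        double m = R_PosInf;
        for (int b = 0; b < ny; ++b) {
            const int j = perm ? perm[yi[b]] : yi[b];
            const double d = D(i, j);
            if (d < m) m = d;
        }
        s += xw[a] * m;
    }
    for (int b = 0; b < ny; ++b) {
        const int j = perm ? perm[yi[b]] : yi[b];
        double m = R_PosInf;
        for (int a = 0; a < nx; ++a) {
            const int i = perm ? perm[xi[a]] : xi[a];
            const double d = D(i, j);
            if (d < m) m = d;
        }
        s += yw[b] * m;
    }
    return 0.5 * s;
}

// [[Rcpp::export]]
double cpp_bmntd(NumericMatrix D, IntegerVector xi, NumericVector xw,
                 IntegerVector yi, NumericVector yw) {
    return bmntd_core(D, xi, xw, yi, yw, nullptr);
}

// One null beta-MNTD value per column of `perms` (each column a 0-based
// permutation of the pool indices).
// [[Rcpp::export]]
NumericVector cpp_bmntd_null(NumericMatrix D,
                             IntegerVector xi, NumericVector xw,
                             IntegerVector yi, NumericVector yw,
                             IntegerMatrix perms) {
    const int n_null = perms.ncol();
    NumericVector out(n_null);
    std::vector<int> perm(perms.nrow());
    for (int k = 0; k < n_null; ++k) {
        for (int r = 0; r < perms.nrow(); ++r) perm[r] = perms(r, k);
        out[k] = bmntd_core(D, xi, xw, yi, yw, perm.data());
    }
    return out;
}
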