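#include <Rcpp.h>
using namespace Rcpp;

// Run the VAR(p) recursion x_t = sum_r A_r x_{t-r} + e_t.
// coefs: n x n x p array (a[i,j,r] = influence of channel j on channel i
// at lag r); innovations: n x N matrix of pre-drawn noise (drawn in R so
// that determinism follows R's RNG). The first p columns of the output
// equal the innovations (zero initial state).
// [[Rcpp::export]]
NumericMatrix var_recursion(NumericVector coefs, NumericMatrix innovations) {
    IntegerVector dims = coefs.attr("dim");
    const int n = dims[0], p = dims[2], N = innovations.ncol();
    if (dims[1] != n) stop("coefficient array must be square in its first two dimensions");
    if (innovations.nrow() != n) stop("innovation rows must match coefficient dimension");
    NumericMatrix x(n, N);
    double *xp = REAL(x);
    const double *ip = REAL(innovations);
    const double *Ap = REAL(coefs);
    for (int t = 0; t < N; ++t) {
        double *xt = xp + (R_xlen_t)t * n;
        const double *it = ip + (R_xlen_t)t * n;
        for (int i = 0; i < n; ++i) xt[i] = it[i];
        const int rmax = t < p ? t : p;
        for (int r = 1; r <= rmax; ++r) {
            const double *xl = xp + (R_xlen_t)(t - r) * n;
            const double *A = Ap + (R_xlen_t)(r - 1) * n * n;
            for (int j = 0; j < n; ++j) {
                const double xj = xl[j];
                const double *Aj = A + (R_xlen_t)j * n;
                for (int i = 0; i < n; ++i) xt[i] += Aj[i] * xj;
            }
        }
    }
    return x;
}
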