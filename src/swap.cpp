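#include <Rcpp.h>
using namespace Rcpp;

static inline int ri(int n) {
    int k = (int)(unif_rand() * n);
    return (k == n) ? (n - 1) : k;
}

// Reduce a non-negative integer matrix with fixed marginals to a binary one
// by random 2x2 quasi-swap moves: for cells a = m(i,j), b = m(i,jj),
// c = m(ii,j), d = m(ii,jj) the move a--, d--, b++, c++ is applied when
// a > 0, d > 0 and a + d - b - c >= 2, which never increases the excess
// sum(max(m - 1, 0)). Marginals are invariant under every move.
//
// Proposals with a == 0 or d == 0 (or a shared row/column) are no-ops, so
// instead of proposing uniform cell pairs and discarding the overwhelmingly
// zero ones, the pair is drawn uniformly from the nonzero cells: conditional
// on being a non-trivial proposal the two schemes have identical law, so the
// chain (and the sampled matrix distribution) is unchanged while the work
// per accepted move drops by the fill density squared.
// [[Rcpp::export]]
IntegerMatrix cpp_quasiswap(IntegerMatrix m) {
    int nr = m.nrow(), nc = m.ncol();
    R_xlen_t n = (R_xlen_t)nr * nc;
    std::vector<int> nz;
    std::vector<int> where(n, -1);
    nz.reserve(n);
    long excess = 0;
    for (R_xlen_t k = 0; k < n; k++) {
        if (m[k] > 0) { where[k] = (int)nz.size(); nz.push_back((int)k); }
        if (m[k] > 1) excess += m[k] - 1;
    }
    while (excess > 0) {
        int k1 = nz[ri((int)nz.size())];
        int k2 = nz[ri((int)nz.size())];
        int i = k1 % nr, j = k1 / nr;
        int ii = k2 % nr, jj = k2 / nr;
        if (i == ii || j == jj) continue;
        int kb = i + jj * nr, kc = ii + j * nr;
        int a = m[k1], d = m[k2], b = m[kb], c = m[kc];
        if (a + d - b - c < 2) continue;
        m[k1] = a - 1; m[k2] = d - 1; m[kb] = b + 1; m[kc] = c + 1;
        if (a == 1) {  // cell leaves the nonzero set
            int p = where[k1], last = nz.back();
            nz[p] = last; where[last] = p; nz.pop_back(); where[k1] = -1;
        } else excess--;
        if (d == 1) {
            int p = where[k2], last = nz.back();
            nz[p] = last; where[last] = p; nz.pop_back(); where[k2] = -1;
        } else excess--;
        if (b == 0) { where[kb] = (int)nz.size(); nz.push_back(kb); }
        else excess++;
        if (c == 0) { where[kc] = (int)nz.size(); nz.push_back(kc); }
        else excess++;
    }
    return m;
}

// Curveball trades (Strona et al. 2014): pick two distinct rows, pool the
// columns held by exactly one of them, reshuffle the pool and deal the same
// numbers back to each row. Operates on a binary matrix in place.
// [[Rcpp::export]]
IntegerMatrix cpp_curveball(IntegerMatrix m, int n_trades) {
    int nr = m.nrow(), nc = m.ncol();
    if (nr < 2) return m;
    std::vector<int> pool(nc);
    for (int t = 0; t < n_trades; t++) {
        int r1 = ri(nr), r2 = ri(nr - 1);
        if (r2 >= r1) r2++;
        int npool = 0, n1 = 0;
        for (int j = 0; j < nc; j++) {
            int a = m(r1, j), b = m(r2, j);
            if (a != b) {
                pool[npool++] = j;
                if (a) n1++;
            }
        }
        if (npool < 2 || n1 == 0 || n1 == npool) continue;
        // Fisher-Yates shuffle of the pooled columns
        for (int k = npool - 1; k > 0; k--) {
            int s = ri(k + 1);
            int tmp = pool[k]; pool[k] = pool[s]; pool[s] = tmp;
        }
        for (int k = 0; k < npool; k++) {
            int j = pool[k];
            m(r1, j) = (k < n1) ? 1 : 0;
            m(r2, j) = (k < n1) ? 0 : 1;
        }
    }
    return m;
}
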