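#include <Rcpp.h>
using namespace Rcpp;

// Pairwise abundance-weighted beta mean nearest taxon distance.
//
// D    : taxa x taxa patristic distance matrix (zero diagonal, symmetric)
// F    : taxa x samples relative-abundance matrix (columns sum to 1)
// perm : 0-based permutation mapping table rows to tree tips; the identity
//        gives the observed statistic, a random permutation implements the
//        tip-label shuffle null without touching the tree.
//
// bMNTD(a,b) = 0.5 * [ sum_i F(i,a) * min_{j: F(j,b)>0} d(i,j)
//                    + sum_i F(i,b) * min_{j: F(j,a)>0} d(i,j) ]
static void bmntd_fill(const NumericMatrix& D, const NumericMatrix& F,
                       const int* perm, NumericMatrix& out,
                       const std::vector<std::vector<int> >& pres,
                       NumericMatrix& md) {
    const int nt = F.nrow(), ns = F.ncol();
    for (int s = 0; s < ns; ++s) {
        const std::vector<int>& ps = pres[s];
        const int np = (int)ps.size();
        for (int i = 0; i < nt; ++i) {
            const double* drow = &D(0, 0) + (R_xlen_t)perm[i] * D.nrow();
            double mn = R_PosInf;
            for (int k = 0; k < np; ++k) {
                double d = drow[perm[ps[k]]];
                if (d < mn) mn = d;
            }
            md(i, s) = mn;
        }
    }
    for (int a = 0; a < ns - 1; ++a) {
        for (int b = a + 1; b < ns; ++b) {
            double acc = 0.0;
            const std::vector<int>& pa = pres[a];
            const std::vector<int>& pb = pres[b];
            for (size_t k = 0; k < pa.size(); ++k)
                acc += F(pa[k], a) * md(pa[k], b);
            for (size_t k = 0; k < pb.size(); ++k)
                acc += F(pb[k], b) * md(pb[k], a);
            out(a, b) = out(b, a) = 0.5 * acc;
        }
    }
}

static std::vector<std::vector<int> > presence_lists(const NumericMatrix& F) {
    const int nt = F.nrow(), ns = F.ncol();
    std::vector<std::vector<int> > pres(ns);
    for (int s = 0; s < ns; ++s)
        for (int i = 0; i < nt; ++i)
            if (F(i, s) > 0) pres[s].push_back(i);
    return pres;
}

// [[Rcpp::export]]
NumericMatrix bmntd_pairs_cpp(const NumericMatrix& D, const NumericMatrix& F,
                              const IntegerVector& perm) {
    const int nt = F.nrow(), ns = F.ncol();
    if (D.nrow() != nt || D.ncol() != nt)
        stop("distance matrix does not match table");
    std::vector<int> p(nt);
    for (int i = 0; i < nt; ++i) p[i] = perm[i];
    std::vector<std::vector<int> > pres = presence_lists(F);
    for (int s = 0; s < ns; ++s)
        if (pres[s].empty()) stop("sample with no taxa present");
    NumericMatrix out(ns, ns), md(nt, ns);
    bmntd_fill(D, F, p.data(), out, pres, md);
    return out;
}

// Null mean and sd of bMNTD over tip-shuffle permutations.
// perms: taxa x n_null matrix of 0-based permutations (generated in R so
// the RNG stream stays under R's control).
// [[Rcpp::export]]
List bmntd_null_cpp(const NumericMatrix& D, const NumericMatrix& F,
                    const IntegerMatrix& perms) {
    const int nt = F.nrow(), ns = F.ncol(), nn = perms.ncol();
    if (perms.nrow() != nt) stop("permutation matrix does not match table");
    std::vector<std::vector<int> > pres = presence_lists(F);
    for (int s = 0; s < ns; ++s)
        if (pres[s].empty()) stop("sample with no taxa present");
    NumericMatrix sum(ns, ns), sumsq(ns, ns), cur(ns, ns), md(nt, ns);
    std::vector<int> p(nt);
    for (int r = 0; r < nn; ++r) {
        for (int i = 0; i < nt; ++i) p[i] = perms(i, r);
        bmntd_fill(D, F, p.data(), cur, pres, md);
        for (int a = 0; a < ns; ++a)
            for (int b = 0; b < ns; ++b) {
                sum(a, b) += cur(a, b);
                sumsq(a, b) += cur(a, b) * cur(a, b);
            }
        if (r % 64 == 0) checkUserInterrupt();
    }
    NumericMatrix mean(ns, ns), sd(ns, ns);
    for (int a = 0; a < ns; ++a)
        for (int b = 0; b < ns; ++b) {
            double m = sum(a, b) / nn;
            mean(a, b) = m;
            double v = (sumsq(a, b) - nn * m * m) / (nn - 1);
            sd(a, b) = v > 0 ? std::sqrt(v) : 0.0;
        }
    return List::create(_["mean"] = mean, _["sd"] = sd);
}
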