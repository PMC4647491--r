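#include <Rcpp.h>
using namespace Rcpp;

// Pseudo-energy per base pair; T is read as U. Positive return = not pairable.
static inline double pair_score(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
    if ((a == 'A' && (b == 'T' || b == 'U')) ||
        ((a == 'T' || a == 'U') && b == 'A')) return -2.0;
    if ((a == 'G' && (b == 'T' || b == 'U')) ||
        ((a == 'T' || a == 'U') && b == 'G')) return -1.0;
    return 1.0;
}

//' Base-pair maximization pseudo-energy of a nucleotide sequence
//'
//' Nussinov-style dynamic programme minimizing a pairwise pseudo-energy
//' (GC = -3, AU = -2, GU = -1) with a minimum hairpin loop of `min_loop`
//' unpaired bases. Returns a value <= 0.
//'
//' @param seq upper-case nucleotide string over A,C,G,T/U,N
//' @param min_loop minimum number of unpaired bases enclosed by a pair
//' @noRd
// [[Rcpp::export]]
double nussinov_energy(std::string seq, int min_loop = 3) {
    const int n = (int) seq.size();
    if (n == 0) stop("empty sequence");
    if (n == 1) return 0.0;
    std::vector<double> E((size_t) n * n, 0.0);
    #define EN(i, j) E[(size_t)(i) * n + (j)]
    for (int d = 1; d < n; ++d) {
        for (int i = 0; i + d < n; ++i) {
            const int j = i + d;
            double best = std::min(EN(i + 1, j), EN(i, j - 1));
            if (d > min_loop) {
                const double s = pair_score(seq[i], seq[j]);
                if (s < 0) best = std::min(best, EN(i + 1, j - 1) + s);
            }
            for (int k = i + 1; k < j; ++k)
                best = std::min(best, EN(i, k) + EN(k + 1, j));
            EN(i, j) = best;
        }
    }
    #undef EN
    return E[n - 1];
}
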