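#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Greedy one-to-one assignment of query peaks to library peaks.
// Both m/z vectors must be sorted ascending. Candidate pairs are all
// (i, j) with |qmz[i] - lmz[j]| <= tol; they are consumed in order of
// increasing absolute m/z difference, ties broken toward the lower
// library m/z, then the lower query m/z. Each peak is used at most once.
static void greedy_pairs(const double* qmz, int nq,
                         const double* lmz, int nl,
                         double tol,
                         std::vector<int>& out_i,
                         std::vector<int>& out_j) {
    std::vector<int> ci, cj;
    std::vector<double> cd;
    int lo = 0;
    for (int i = 0; i < nq; ++i) {
        while (lo < nl && lmz[lo] < qmz[i] - tol) ++lo;
        for (int j = lo; j < nl && lmz[j] <= qmz[i] + tol; ++j) {
            ci.push_back(i);
            cj.push_back(j);
            cd.push_back(std::fabs(qmz[i] - lmz[j]));
        }
    }
    const int nc = (int)ci.size();
    std::vector<int> ord(nc);
    for (int k = 0; k < nc; ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        if (cd[a] != cd[b]) return cd[a] < cd[b];
        if (cj[a] != cj[b]) return cj[a] < cj[b];
        return ci[a] < ci[b];
    });
    std::vector<char> qused(nq, 0), lused(nl, 0);
    out_i.clear();
    out_j.clear();
    for (int k = 0; k < nc; ++k) {
        int a = ord[k];
        if (qused[ci[a]] || lused[cj[a]]) continue;
        qused[ci[a]] = 1;
        lused[cj[a]] = 1;
        out_i.push_back(ci[a]);
        out_j.push_back(cj[a]);
    }
    // report pairs in ascending query m/z (= ascending query index)
    std::vector<int> ord2(out_i.size());
    for (size_t k = 0; k < ord2.size(); ++k) ord2[k] = (int)k;
    std::sort(ord2.begin(), ord2.end(),
              [&](int a, int b) { return out_i[a] < out_i[b]; });
    std::vector<int> ti(out_i.size()), tj(out_j.size());
    for (size_t k = 0; k < ord2.size(); ++k) {
        ti[k] = out_i[ord2[k]];
        tj[k] = out_j[ord2[k]];
    }
    out_i.swap(ti);
    out_j.swap(tj);
}

// [[Rcpp::export]]
IntegerMatrix cpp_match_greedy(NumericVector qmz, NumericVector lmz, double tol) {
    std::vector<int> oi, oj;
    greedy_pairs(qmz.begin(), qmz.size(), lmz.begin(), lmz.size(), tol, oi, oj);
    IntegerMatrix out((int)oi.size(), 2);
    for (size_t k = 0; k < oi.size(); ++k) {
        out(k, 0) = oi[k] + 1;  // 1-based for R
        out(k, 1) = oj[k] + 1;
    }
    return out;
}

// sqrt-cosine similarity of one scaled query against a block of scaled
// library spectra:
//   S = (sum_matched sqrt(Aq * Al))^2 / (total_q * total_l)
// with totals taken over ALL peaks of each spectrum.
// [[Rcpp::export]]
NumericVector cpp_score_block(NumericVector qmz, NumericVector qa, double qtot,
                              List lib_mz, List lib_a, NumericVector lib_tot,
                              double tol) {
    const int ns = lib_mz.size();
    NumericVector out(ns);
    std::vector<int> oi, oj;
    for (int s = 0; s < ns; ++s) {
        NumericVector lmz = lib_mz[s];
        NumericVector la = lib_a[s];
        greedy_pairs(qmz.begin(), qmz.size(), lmz.begin(), lmz.size(), tol, oi, oj);
        double num = 0.0;
        for (size_t k = 0; k < oi.size(); ++k)
            num += std::sqrt(qa[oi[k]] * la[oj[k]]);
        double sc = (num * num) / (qtot * lib_tot[s]);
        if (sc < 0.0) sc = 0.0;
        if (sc > 1.0) sc = 1.0;  // guard floating-point overshoot of the bound
        out[s] = sc;
    }
    return out;
}
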