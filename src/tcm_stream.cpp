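#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Kahan-compensated accumulator for the metric sums (~1e6 terms per series).
struct KahanSum {
    double s = 0.0, c = 0.0;
    inline void add(double v) {
        double y = v - c;
        double t = s + y;
        c = (t - s) - y;
        s = t;
    }
};

// Average-rank transform (ties get the mean of their ranks).
static void rank_window(const double *x, int w, std::vector<int> &ord,
                        std::vector<double> &out) {
    for (int k = 0; k < w; ++k) ord[k] = k;
    std::sort(ord.begin(), ord.end(),
              [x](int a, int b) { return x[a] < x[b]; });
    int k = 0;
    while (k < w) {
        int j = k;
        while (j + 1 < w && x[ord[j + 1]] == x[ord[k]]) ++j;
        double r = 0.5 * (k + j) + 1.0;
        for (int m = k; m <= j; ++m) out[ord[m]] = r;
        k = j + 1;
    }
}

static inline double pearson_direct(const double *a, const double *b, int w,
                                    bool &ok) {
    long double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
    for (int k = 0; k < w; ++k) {
        sa += a[k]; sb += b[k];
        saa += (long double)a[k] * a[k];
        sbb += (long double)b[k] * b[k];
        sab += (long double)a[k] * b[k];
    }
    long double va = w * saa - sa * sa;
    long double vb = w * sbb - sb * sb;
    if (va <= 1e-12L * w * saa || vb <= 1e-12L * w * sbb) { ok = false; return 0.0; }
    ok = true;
    double cc = (double)((w * sab - sa * sb) / std::sqrt(va * vb));
    if (cc > 1.0) cc = 1.0;
    if (cc < -1.0) cc = -1.0;
    return cc;
}

// Diagonal-streaming computation of the six TCM metrics.
//
// Embedding vector i (0-based) starts at sample i*g and spans w samples.
// Diagonal d is the delay in vector-index units; pairs on it are
// (i, i+d) for i = 0 .. nv-1-d.  Only diagonals
// max(dia_s, 1) <= d < nv - dia_e enter the metric sums; full
// upper-triangle sums (all d >= 1) are accumulated alongside for the
// all-off-diagonal normalization variant.  Pearson sums along a diagonal
// are maintained by rolling window updates in extended precision, so one
// diagonal costs O(nv * g) rather than O(nv * w).
// [[Rcpp::export(name = ".tcm_stream_cpp")]]
List tcm_stream_cpp(NumericVector x, int w, int g, double r,
                    int dia_s, int dia_e, bool spearman) {
    const int n = x.size();
    const int nv = (n - w + 1) / g;
    const int d_lo = dia_s > 1 ? dia_s : 1;
    const int d_hi = nv - dia_e;  // exclusive

    // Center once: Pearson is shift-invariant per window, and removing the
    // global mean avoids catastrophic cancellation in w*Sxy - Sx*Sy.
    std::vector<double> xc(n);
    {
        long double m = 0;
        for (int t = 0; t < n; ++t) m += x[t];
        m /= n;
        for (int t = 0; t < n; ++t) xc[t] = (double)(x[t] - m);
    }

    // Spearman: replace each embedding window by its within-window ranks
    // and correlate those directly (ranks do not roll as the window slides).
    std::vector<double> ranks;
    if (spearman) {
        ranks.resize((size_t)nv * w);
        std::vector<int> ord(w);
        std::vector<double> rw(w);
        for (int i = 0; i < nv; ++i) {
            rank_window(&xc[(size_t)i * g], w, ord, rw);
            std::copy(rw.begin(), rw.end(), ranks.begin() + (size_t)i * w);
        }
    }

    KahanSum sum_pos, sum_neg, sum_pos_all, sum_neg_all;
    double mlp_total = 0.0, mln_total = 0.0;
    long long n_pos = 0, n_neg = 0, n_undef = 0, n_pairs = 0, n_pairs_all = 0;
    long long n_seg_pos = 0, n_seg_neg = 0;

    for (int d = 1; d < nv; ++d) {
        const bool included = (d >= d_lo && d < d_hi);
        const int m = nv - d;            // pairs on this diagonal
        const int lag = d * g;           // sample-unit delay

        // run-detection state (Algorithm-style segment scan)
        int pseg = 0, nseg = 0;          // current run lengths

        long double sa = 0, sb = 0, saa = 0, sbb = 0, sab = 0;
        if (!spearman) {
            const double *a = &xc[0], *b = &xc[lag];
            for (int k = 0; k < w; ++k) {
                sa += a[k]; sb += b[k];
                saa += (long double)a[k] * a[k];
                sbb += (long double)b[k] * b[k];
                sab += (long double)a[k] * b[k];
            }
        }

        for (int i = 0; i < m; ++i) {
            double cc;
            bool ok;
            if (spearman) {
                cc = pearson_direct(&ranks[(size_t)i * w],
                                    &ranks[(size_t)(i + d) * w], w, ok);
            } else {
                long double va = w * saa - sa * sa;
                long double vb = w * sbb - sb * sb;
                if (va <= 1e-12L * w * saa || vb <= 1e-12L * w * sbb) {
                    ok = false; cc = 0.0;
                } else {
                    ok = true;
                    cc = (double)((w * sab - sa * sb) / std::sqrt(va * vb));
                    if (cc > 1.0) cc = 1.0;
                    if (cc < -1.0) cc = -1.0;
                }
                // roll both windows forward by g samples
                if (i + 1 < m) {
                    const int s0 = i * g;
                    for (int k = 0; k < g; ++k) {
                        double a_out = xc[s0 + k],       a_in = xc[s0 + w + k];
                        double b_out = xc[s0 + lag + k], b_in = xc[s0 + lag + w + k];
                        sa += a_in - a_out;
                        sb += b_in - b_out;
                        saa += (long double)a_in * a_in - (long double)a_out * a_out;
                        sbb += (long double)b_in * b_in - (long double)b_out * b_out;
                        sab += (long double)a_in * b_in - (long double)a_out * b_out;
                    }
                }
            }

            ++n_pairs_all;
            if (!ok) { if (included) ++n_undef; }
            if (cc > 0) { sum_pos_all.add(cc); } else if (cc < 0) { sum_neg_all.add(-cc); }

            if (included) {
                ++n_pairs;
                if (cc > 0) { sum_pos.add(cc); ++n_pos; }
                else if (cc < 0) { sum_neg.add(-cc); ++n_neg; }

                // positive-threshold run
                if (cc > r) { ++pseg; }
                else {
                    if (pseg > 1) { mlp_total += pseg; ++n_seg_pos; }
                    pseg = 0;
                }
                // negative-threshold run
                if (cc < -r) { ++nseg; }
                else {
                    if (nseg > 1) { mln_total += nseg; ++n_seg_neg; }
                    nseg = 0;
                }
            }
        }
        // a run reaching the end of the diagonal is closed there
        if (included) {
            if (pseg > 1) { mlp_total += pseg; ++n_seg_pos; }
            if (nseg > 1) { mln_total += nseg; ++n_seg_neg; }
        }
    }

    return List::create(
        _["sum_pos"] = sum_pos.s, _["sum_neg"] = sum_neg.s,
        _["sum_pos_all"] = sum_pos_all.s, _["sum_neg_all"] = sum_neg_all.s,
        _["mlp_total"] = mlp_total, _["mln_total"] = mln_total,
        _["n_pos"] = (double)n_pos, _["n_neg"] = (double)n_neg,
        _["n_undefined"] = (double)n_undef,
        _["n_pairs"] = (double)n_pairs, _["n_pairs_all"] = (double)n_pairs_all,
        _["n_seg_pos"] = (double)n_seg_pos, _["n_seg_neg"] = (double)n_seg_neg,
        _["nv"] = nv);
}
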