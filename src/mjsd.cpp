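#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

static inline int b2i(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
    }
}

// Order-m context counts. A window is attributed to the position x of the
// emitted nucleotide; its context is the m bases immediately preceding x
// (which may lie before `start` but never before the sequence origin).
// This attribution makes profiles exactly additive across adjacent
// intervals: profile([a,b)) + profile([b,c)) == profile([a,c)).
// [[Rcpp::export]]
IntegerMatrix cpp_count_contexts(std::string seq, int m, int start, int end) {
    if (m < 0 || m > 8) stop("context order m must be in 0..8");
    const long n = (long)seq.size();
    if (start < 0 || end > n || end - start < m + 1)
        stop("interval shorter than m+1");
    const int nw = 1 << (2 * m);
    IntegerMatrix counts(nw, 4);
    for (long x = std::max((long)start, (long)m); x < end; ++x) {
        int b = b2i(seq[x]);
        if (b < 0) continue;
        long w = 0;
        bool ok = true;
        for (int j = m; j >= 1; --j) {
            int cb = b2i(seq[x - j]);
            if (cb < 0) { ok = false; break; }
            w = (w << 2) | cb;
        }
        if (!ok) continue;
        counts(w, b) += 1;
    }
    return counts;
}

static inline long double xlog2x(long double v) {
    return (v > 0) ? v * std::log2(v) : 0.0L;
}

// State for one side of a sliding split: exact integer counts plus the two
// running entropy sums S1 = sum c*log2(c) over cells and S2 = sum n_w*log2(n_w)
// over contexts, so that H = (S2 - S1) / N in bits per symbol.
struct SideState {
    std::vector<long> c;   // 4^m x 4, cell (w,x) at 4*w+x
    std::vector<long> nw;  // per-context totals
    long N;
    long double S1, S2;
    explicit SideState(int m)
        : c((size_t)4 << (2 * m), 0), nw((size_t)1 << (2 * m), 0), N(0),
          S1(0.0L), S2(0.0L) {}
    inline void add(long w, int x) {
        long& cc = c[(size_t)(4 * w + x)];
        S1 += xlog2x((long double)(cc + 1)) - xlog2x((long double)cc);
        ++cc;
        long& nn = nw[(size_t)w];
        S2 += xlog2x((long double)(nn + 1)) - xlog2x((long double)nn);
        ++nn;
        ++N;
    }
    inline void remove(long w, int x) {
        long& cc = c[(size_t)(4 * w + x)];
        S1 += xlog2x((long double)(cc - 1)) - xlog2x((long double)cc);
        --cc;
        long& nn = nw[(size_t)w];
        S2 += xlog2x((long double)(nn - 1)) - xlog2x((long double)nn);
        --nn;
        --N;
    }
    inline long double H() const { return N > 0 ? (S2 - S1) / (long double)N : 0.0L; }
};

// Encode the window emitting position x; returns false if any of the m+1
// bases is ambiguous or x < m.
static inline bool window_at(const std::string& seq, int m, long x, long& w,
                             int& b) {
    if (x < m) return false;
    b = b2i(seq[x]);
    if (b < 0) return false;
    w = 0;
    for (int j = m; j >= 1; --j) {
        int cb = b2i(seq[x - j]);
        if (cb < 0) return false;
        w = (w << 2) | cb;
    }
    return true;
}

// Markovian Jensen-Shannon divergence, in bits per symbol, at every
// admissible split s in [lo+min_len, hi-min_len), computed by sliding the
// split one position at a time: exactly one window (the one emitted at the
// position crossing the boundary) moves from the right profile to the left,
// and both entropies are adjusted from the previous values rather than
// recomputed. The whole-interval entropy is constant because the window
// attribution makes left + right == whole at every split.
// [[Rcpp::export]]
List cpp_mjsd_curve(std::string seq, int m, int lo, int hi, int min_len) {
    if (m < 0 || m > 8) stop("context order m must be in 0..8");
    const long n = (long)seq.size();
    if (lo < 0 || hi > n || lo >= hi) stop("bad interval");
    long s0 = lo + min_len, s1 = hi - min_len;  // candidates in [s0, s1)
    if (s1 <= s0)
        return List::create(_["positions"] = IntegerVector(0),
                            _["D"] = NumericVector(0), _["n_total"] = 0,
                            _["n_candidates"] = 0);

    SideState left(m), right(m);
    long w; int b;
    for (long x = lo; x < s0; ++x)
        if (window_at(seq, m, x, w, b)) left.add(w, b);
    for (long x = s0; x < hi; ++x)
        if (window_at(seq, m, x, w, b)) right.add(w, b);

    const long Ntot = left.N + right.N;
    // whole-interval entropy from the pooled profile (computed once)
    long double S1w = 0.0L, S2w = 0.0L;
    {
        const size_t nwctx = (size_t)1 << (2 * m);
        for (size_t i = 0; i < nwctx; ++i) {
            long tot = 0;
            for (int x = 0; x < 4; ++x) {
                long cc = left.c[4 * i + x] + right.c[4 * i + x];
                S1w += xlog2x((long double)cc);
                tot += cc;
            }
            S2w += xlog2x((long double)tot);
        }
    }
    const long double Hw = Ntot > 0 ? (S2w - S1w) / (long double)Ntot : 0.0L;

    const long ncand = s1 - s0;
    IntegerVector positions(ncand);
    NumericVector D(ncand);
    for (long s = s0; s < s1; ++s) {
        if (s > s0 && window_at(seq, m, s - 1, w, b)) {
            right.remove(w, b);
            left.add(w, b);
        }
        long double d = Hw;
        if (Ntot > 0) {
            d -= ((long double)left.N / (long double)Ntot) * left.H();
            d -= ((long double)right.N / (long double)Ntot) * right.H();
        }
        if (d < 0) d = 0;  // guard against rounding at D ~ 0
        positions[s - s0] = (int)s;
        D[s - s0] = (double)d;
    }
    return List::create(_["positions"] = positions, _["D"] = D,
                        _["n_total"] = (double)Ntot,
                        _["n_candidates"] = (double)ncand);
}
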