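#include <Rcpp.h>
#include <cmath>
#include <string>
#include <vector>

using namespace Rcpp;

// 2-bit encoding; anything outside ACGT is ambiguous and breaks context runs.
static inline int base2bit(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default: return -1;
    }
}

static inline char comp(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (char& c : r) c = comp(c);
    return r;
}

// Accumulate k-mer (initial) and (k+1)-mer (transition) counts of one record.
// Contexts never span record boundaries; any window touching an ambiguous
// base contributes nothing.
static void count_record(const std::string& s, int k,
                         std::vector<double>& init_counts,
                         std::vector<double>& trans_counts) {
    const long n = (long)s.size();
    const long mask = (k > 0) ? ((1L << (2 * k)) - 1L) : 0L;
    long ctx = 0;
    long run = 0;  // consecutive unambiguous bases ending just before i
    for (long i = 0; i < n; ++i) {
        int b = base2bit(s[i]);
        if (b < 0) { run = 0; continue; }
        if (run >= k) trans_counts[(size_t)((ctx << 2) | b)] += 1.0;
        ctx = ((ctx << 2) | b) & mask;
        ++run;
        if (run >= k) init_counts[(size_t)ctx] += 1.0;
    }
}

// In-place conversion of pseudocount-seeded count buffers to natural-log
// probabilities (per-context normalisation for transitions, global for the
// initial k-mer distribution).
static void counts_to_logprob(std::vector<double>& init_counts,
                              std::vector<double>& trans_counts, int k) {
    const size_t nk = (size_t)1 << (2 * k);
    double tot = 0.0;
    for (size_t w = 0; w < nk; ++w) tot += init_counts[w];
    for (size_t w = 0; w < nk; ++w)
        init_counts[w] = std::log(init_counts[w] / tot);
    for (size_t w = 0; w < nk; ++w) {
        const size_t o = w << 2;
        double rs = trans_counts[o] + trans_counts[o + 1] +
                    trans_counts[o + 2] + trans_counts[o + 3];
        for (int x = 0; x < 4; ++x)
            trans_counts[o + x] = std::log(trans_counts[o + x] / rs);
    }
}

// Forward-strand log-likelihood of one read under the model tables.
// `scored` reports whether at least one transition window was evaluated,
// i.e. the read holds >= k+1 consecutive unambiguous bases.
static double score_one_strand(const std::string& s, int k,
                               const double* init_log,
                               const double* trans_log, bool& scored) {
    const long n = (long)s.size();
    const long mask = (k > 0) ? ((1L << (2 * k)) - 1L) : 0L;
    long ctx = 0;
    long run = 0;
    double sc = 0.0;
    bool seen_init = false;
    scored = false;
    for (long i = 0; i < n; ++i) {
        int b = base2bit(s[i]);
        if (b < 0) { run = 0; continue; }
        if (run >= k) {
            sc += trans_log[(size_t)((ctx << 2) | b)];
            scored = true;
        }
        ctx = ((ctx << 2) | b) & mask;
        ++run;
        if (run == k && !seen_init) {
            sc += init_log[(size_t)ctx];
            seen_init = true;
        }
    }
    return sc;
}

static double score_both_strands(const std::string& fwd,
                                 const std::string& rev, int k,
                                 const double* init_log,
                                 const double* trans_log) {
    bool a1 = false, a2 = false;
    double f = score_one_strand(fwd, k, init_log, trans_log, a1);
    double r = score_one_strand(rev, k, init_log, trans_log, a2);
    if (!a1 && !a2) return NA_REAL;
    if (!a1) return r;
    if (!a2) return f;
    return f > r ? f : r;
}

// [[Rcpp::export]]
List cpp_build_smm(CharacterVector records, int k, double delta) {
    if (k < 1 || k > 14) stop("model order k must be in 1..14");
    if (delta <= 0) stop("pseudocount delta must be > 0");
    const size_t nk = (size_t)1 << (2 * k);
    std::vector<double> init(nk, delta), trans(nk * 4, delta);
    for (R_xlen_t i = 0; i < records.size(); ++i)
        count_record(as<std::string>(records[i]), k, init, trans);
    counts_to_logprob(init, trans, k);
    return List::create(_["initial_log"] = NumericVector(init.begin(), init.end()),
                        _["transition_log"] = NumericVector(trans.begin(), trans.end()));
}

// [[Rcpp::export]]
double cpp_score_read(NumericVector init_log, NumericVector trans_log, int k,
                      std::string read) {
    return score_both_strands(read, revcomp(read), k,
                              REAL(init_log), REAL(trans_log));
}

// Score every read against every genome. One pair of count buffers is
// allocated up front, reused and reset (refilled with the pseudocount) as
// each genome is modeled, so model memory stays constant in the number of
// genomes. `genomes` is a list of character vectors (records per genome).
// [[Rcpp::export]]
NumericMatrix cpp_score_genomes(CharacterVector reads, List genomes, int k,
                                double delta) {
    if (k < 1 || k > 14) stop("model order k must be in 1..14");
    if (delta <= 0) stop("pseudocount delta must be > 0");
    const size_t nk = (size_t)1 << (2 * k);
    const R_xlen_t nr = reads.size(), ng = genomes.size();

    std::vector<std::string> fwd(nr), rev(nr);
    for (R_xlen_t i = 0; i < nr; ++i) {
        fwd[i] = as<std::string>(reads[i]);
        rev[i] = revcomp(fwd[i]);
    }

    std::vector<double> init(nk), trans(nk * 4);
    NumericMatrix out(nr, ng);
    for (R_xlen_t g = 0; g < ng; ++g) {
        std::fill(init.begin(), init.end(), delta);
        std::fill(trans.begin(), trans.end(), delta);
        CharacterVector recs = genomes[g];
        for (R_xlen_t j = 0; j < recs.size(); ++j)
            count_record(as<std::string>(recs[j]), k, init, trans);
        counts_to_logprob(init, trans, k);
        for (R_xlen_t i = 0; i < nr; ++i)
            out(i, g) = score_both_strands(fwd[i], rev[i], k,
                                           init.data(), trans.data());
        Rcpp::checkUserInterrupt();
    }
    return out;
}
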