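#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state DP.
// Gap of length L costs gapOpen + (L-1) * gapExt (EMBOSS convention).
// States: 0 = M (ref base vs read base), 1 = D (gap in read, consumes ref),
// 2 = I (gap in ref, consumes read). Ties prefer M over D over I so the
// traceback is deterministic; indel placement is normalised downstream by
// left-alignment against the reference.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

struct AlnResult {
    double score;
    std::string cigar;
};

static inline double subScore(char a, char b, double match, double mismatch) {
    return (a == b) ? match : mismatch;
}

// With bandSlack >= 0 the DP is restricted to diagonals
// min(0, n-m) - slack <= i - j <= max(0, n-m) + slack: exact whenever the
// optimal alignment's indel excursion beyond the net length difference stays
// within the slack. bandSlack < 0 computes the full matrix.
static AlnResult nw_one(const std::string& ref, const std::string& read,
                        double match, double mismatch,
                        double gapOpen, double gapExt, int bandSlack) {
    const int n = (int) ref.size();   // rows
    const int m = (int) read.size();  // cols
    const size_t W = (size_t) m + 1;
    int dLo = -m, dHi = n;
    if (bandSlack >= 0) {
        dLo = std::max(dLo, std::min(0, n - m) - bandSlack);
        dHi = std::min(dHi, std::max(0, n - m) + bandSlack);
    }

    std::vector<double> M((n + 1) * W, NEG_INF), D((n + 1) * W, NEG_INF),
        I((n + 1) * W, NEG_INF);
    // ptr: predecessor state for each cell/state, 0/1/2; -1 = boundary
    std::vector<signed char> pM((n + 1) * W, -1), pD((n + 1) * W, -1),
        pI((n + 1) * W, -1);

    M[0] = 0.0;
    for (int i = 1; i <= n && i <= dHi; ++i) {
        D[i * W] = -(gapOpen + (i - 1) * gapExt);
        pD[i * W] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m && -j >= dLo; ++j) {
        I[j] = -(gapOpen + (j - 1) * gapExt);
        pI[j] = (j == 1) ? 0 : 2;
    }

    for (int i = 1; i <= n; ++i) {
        const int jFirst = std::max(1, i - dHi);
        const int jLast = std::min(m, i - dLo);
        for (int j = jFirst; j <= jLast; ++j) {
            const size_t c = i * W + j, up = (i - 1) * W + j,
                lf = i * W + (j - 1), dg = (i - 1) * W + (j - 1);
            // M: diagonal predecessor, prefer M > D > I on ties
            {
                double best = M[dg];
                signed char arg = 0;
                if (D[dg] > best) { best = D[dg]; arg = 1; }
                if (I[dg] > best) { best = I[dg]; arg = 2; }
                if (best > NEG_INF) {
                    M[c] = best + subScore(ref[i - 1], read[j - 1], match, mismatch);
                    pM[c] = arg;
                }
            }
            // D: from above
            {
                double best = (M[up] > NEG_INF) ? M[up] - gapOpen : NEG_INF;
                signed char arg = 0;
                if (D[up] - gapExt > best) { best = D[up] - gapExt; arg = 1; }
                if (I[up] > NEG_INF && I[up] - gapOpen > best) { best = I[up] - gapOpen; arg = 2; }
                D[c] = best; pD[c] = arg;
            }
            // I: from left
            {
                double best = (M[lf] > NEG_INF) ? M[lf] - gapOpen : NEG_INF;
                signed char arg = 0;
                if (D[lf] > NEG_INF && D[lf] - gapOpen > best) { best = D[lf] - gapOpen; arg = 1; }
                if (I[lf] - gapExt > best) { best = I[lf] - gapExt; arg = 2; }
                I[c] = best; pI[c] = arg;
            }
        }
    }

    const size_t end = (size_t) n * W + m;
    double score = M[end];
    signed char state = 0;
    if (D[end] > score) { score = D[end]; state = 1; }
    if (I[end] > score) { score = I[end]; state = 2; }

    // traceback
    std::string ops;
    ops.reserve(n + m);
    int i = n, j = m;
    while (i > 0 || j > 0) {
        signed char prev;
        if (state == 0) {
            prev = pM[i * W + j];
            ops.push_back('M'); --i; --j;
        } else if (state == 1) {
            prev = pD[i * W + j];
            ops.push_back('D'); --i;
        } else {
            prev = pI[i * W + j];
            ops.push_back('I'); --j;
        }
        state = prev;
    }
    // run-length encode reversed ops into a CIGAR
    std::string cigar;
    int run = 0;
    char cur = 0;
    for (int k = (int) ops.size() - 1; k >= 0; --k) {
        if (ops[k] == cur) { ++run; }
        else {
            if (run > 0) { cigar += std::to_string(run); cigar.push_back(cur); }
            cur = ops[k]; run = 1;
        }
    }
    if (run > 0) { cigar += std::to_string(run); cigar.push_back(cur); }

    AlnResult res; res.score = score; res.cigar = cigar;
    return res;
}

// [[Rcpp::export(name = ".nw_align_batch")]]
List nw_align_batch(CharacterVector reads, std::string ref,
                    double match, double mismatch,
                    double gapOpen, double gapExt, int bandSlack) {
    const int N = reads.size();
    NumericVector score(N);
    CharacterVector cigar(N);
    for (int k = 0; k < N; ++k) {
        std::string rd = as<std::string>(reads[k]);
        if (rd.empty() || ref.empty())
            stop("empty sequence");
        AlnResult r = nw_one(ref, rd, match, mismatch, gapOpen, gapExt,
                             bandSlack);
        score[k] = r.score;
        cigar[k] = r.cigar;
    }
    return List::create(_["score"] = score, _["cigar"] = cigar);
}
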