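#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Paired-end merging by maximum-score ungapped overlap, and sliding-window
// quality trimming. Qualities travel as Phred+33 ASCII strings.

static inline char comp(char b) {
    switch (b) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (size_t i = 0; i < r.size(); ++i) r[i] = comp(r[i]);
    return r;
}

// [[Rcpp::export(name = ".merge_pairs_batch")]]
List merge_pairs_batch(CharacterVector seq1, CharacterVector qual1,
                       CharacterVector seq2, CharacterVector qual2,
                       int minOverlap, double maxMismatchFrac) {
    const int N = seq1.size();
    CharacterVector mseq(N), mqual(N);
    IntegerVector overlapLen(N);
    LogicalVector merged(N);

    for (int k = 0; k < N; ++k) {
        std::string s1 = as<std::string>(seq1[k]);
        std::string q1 = as<std::string>(qual1[k]);
        std::string s2 = revcomp(as<std::string>(seq2[k]));
        std::string q2 = as<std::string>(qual2[k]);
        std::reverse(q2.begin(), q2.end());
        const int L1 = (int) s1.size(), L2 = (int) s2.size();
        if (L1 == 0 || L2 == 0) stop("empty read");

        // offset o: position of s2's first base in s1 coordinates.
        // Negative o = s2 overhangs on the left. Overlap must be >= minOverlap.
        int bestO = 0, bestOv = -1;
        double bestScore = -1e18;
        for (int o = -(L2 - minOverlap); o <= L1 - minOverlap; ++o) {
            const int lo = std::max(0, o), hi = std::min(L1, o + L2);
            const int ov = hi - lo;
            if (ov < minOverlap) continue;
            const int allow = (int) (maxMismatchFrac * ov);
            int mism = 0;
            double score = 0.0;
            for (int p = lo; p < hi; ++p) {
                const char a = s1[p], b = s2[p - o];
                if (a == b && a != 'N') score += 1.0;
                else {
                    score -= 1.0;
                    if (++mism > allow) break;  // offset cannot qualify
                }
            }
            if (mism > allow) continue;
            // ties: prefer longer overlap, then smaller |offset|
            if (score > bestScore ||
                (score == bestScore && ov > bestOv)) {
                bestScore = score; bestO = o; bestOv = ov;
            }
        }
        if (bestOv < 0) { merged[k] = false; continue; }

        const int o = bestO;
        const int start = std::min(0, o), end = std::max(L1, o + L2);
        std::string ms, mq;
        ms.reserve(end - start); mq.reserve(end - start);
        for (int p = start; p < end; ++p) {
            const bool in1 = (p >= 0 && p < L1);
            const bool in2 = (p >= o && p < o + L2);
            if (in1 && in2) {
                const char a = s1[p], b = s2[p - o];
                char ca = q1[p], cb = q2[p - o];
                if (a == b) { ms.push_back(a); mq.push_back(ca > cb ? ca : cb); }
                else if (a == 'N') { ms.push_back(b); mq.push_back(cb); }
                else if (b == 'N') { ms.push_back(a); mq.push_back(ca); }
                else if (cb > ca) { ms.push_back(b); mq.push_back(cb); }
                else { ms.push_back(a); mq.push_back(ca); } // tie keeps mate 1
            } else if (in1) { ms.push_back(s1[p]); mq.push_back(q1[p]); }
            else { ms.push_back(s2[p - o]); mq.push_back(q2[p - o]); }
        }
        mseq[k] = ms; mqual[k] = mq;
        overlapLen[k] = bestOv; merged[k] = true;
    }
    return List::create(_["seq"] = mseq, _["qual"] = mqual,
                        _["overlap_len"] = overlapLen, _["merged"] = merged);
}

// Returns surviving length per read (0 = dropped): truncate at the start of
// the first window whose mean quality < minQ, then drop if length < minLen.
// [[Rcpp::export(name = ".sliding_window_keep")]]
IntegerVector sliding_window_keep(CharacterVector qual, int window,
                                  double minQ, int minLen) {
    const int N = qual.size();
    IntegerVector keep(N);
    for (int k = 0; k < N; ++k) {
        std::string q = as<std::string>(qual[k]);
        const int L = (int) q.size();
        int cut = L;
        if (L >= window) {
            double sum = 0.0;
            for (int p = 0; p < window; ++p) sum += q[p] - 33;
            for (int s = 0; ; ++s) {
                if (sum / window < minQ) { cut = s; break; }
                if (s + window >= L) break;
                sum += (q[s + window] - 33) - (q[s] - 33);
            }
        }
        keep[k] = (cut >= minLen) ? cut : 0;
    }
    return keep;
}
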