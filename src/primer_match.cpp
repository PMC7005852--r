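#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Approximate primer occurrence search: semi-global edit-distance DP
// (primer vs read, read gaps free at both ends). For each read, reports the
// number of distinct occurrences with edit distance <= maxErr, and the
// 1-based footprint (start, end) of the best (lowest-distance, leftmost)
// occurrence. End positions within maxErr + 1 of each other are collapsed
// into one occurrence so that the indel slack around a single primer copy
// is not over-counted.

// [[Rcpp::export(name = ".primer_scan")]]
List primer_scan(CharacterVector reads, std::string primer, int maxErr) {
    const int m = (int) primer.size();
    const int N = reads.size();
    IntegerVector count(N), bestStart(N, NA_INTEGER), bestEnd(N, NA_INTEGER);

    std::vector<int> prevD(m + 1), curD(m + 1), prevS(m + 1), curS(m + 1);

    for (int r = 0; r < N; ++r) {
        std::string text = as<std::string>(reads[r]);
        const int n = (int) text.size();
        // column j = 0 (before any text)
        for (int i = 0; i <= m; ++i) { prevD[i] = i; prevS[i] = 1; }
        std::vector<int> endD, endJ, endS;
        for (int j = 1; j <= n; ++j) {
            curD[0] = 0; curS[0] = j + 1; // occurrence may start after j
            for (int i = 1; i <= m; ++i) {
                const int diag = prevD[i - 1] + (primer[i - 1] != text[j - 1]);
                const int up = curD[i - 1] + 1;   // gap in text
                const int left = prevD[i] + 1;    // gap in primer
                int d = diag, s = prevS[i - 1];
                if (up < d) { d = up; s = curS[i - 1]; }
                if (left < d) { d = left; s = prevS[i]; }
                curD[i] = d; curS[i] = s;
            }
            if (curD[m] <= maxErr) {
                endD.push_back(curD[m]); endJ.push_back(j);
                endS.push_back(curS[m]);
            }
            std::swap(prevD, curD); std::swap(prevS, curS);
        }
        // cluster qualifying end positions into occurrences
        int nOcc = 0, bd = maxErr + 1, bj = -1, bs = -1;
        int clusterBd = maxErr + 1, clusterBj = -1, clusterBs = -1;
        for (size_t k = 0; k < endJ.size(); ++k) {
            if (k == 0 || endJ[k] - endJ[k - 1] > maxErr + 1) {
                if (k > 0) { // close previous cluster
                    ++nOcc;
                    if (clusterBd < bd) { bd = clusterBd; bj = clusterBj; bs = clusterBs; }
                }
                clusterBd = maxErr + 1; clusterBj = -1; clusterBs = -1;
            }
            if (endD[k] < clusterBd) {
                clusterBd = endD[k]; clusterBj = endJ[k]; clusterBs = endS[k];
            }
        }
        if (!endJ.empty()) {
            ++nOcc;
            if (clusterBd < bd) { bd = clusterBd; bj = clusterBj; bs = clusterBs; }
        }
        count[r] = nOcc;
        if (nOcc > 0) { bestStart[r] = bs; bestEnd[r] = bj; }
    }
    return List::create(_["count"] = count, _["start"] = bestStart,
                        _["end"] = bestEnd);
}
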