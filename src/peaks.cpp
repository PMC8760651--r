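#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Prominence-filtered peak detection on a depth track.
// A local maximum is a maximal plateau with strictly smaller neighbours on
// both sides (plateaus touching the track boundary are not peaks); its apex
// is the leftmost plateau position. The left/right base is the minimum depth
// between the apex and the nearest position strictly higher than the apex on
// that side (or the track boundary); prominence = apex height - max(bases).
// The region extent is the maximal interval around the apex where
// depth > apex height - prominence.
// Returns 0-based columns: start, end (half-open), apex, height, prominence.
// [[Rcpp::export]]
DataFrame cpp_find_peaks(NumericVector x, double min_prominence) {
    const int n = x.size();
    std::vector<int> starts, ends, apexes;
    std::vector<double> heights, proms;

    int i = 1;
    while (i < n - 1) {
        if (x[i] > x[i - 1]) {
            int j = i;
            while (j + 1 < n && x[j + 1] == x[i]) ++j;
            if (j + 1 < n && x[j + 1] < x[i]) {
                const double h = x[i];
                double lmin = h, rmin = h;
                for (int t = i - 1; t >= 0; --t) {
                    if (x[t] > h) break;
                    if (x[t] < lmin) lmin = x[t];
                }
                for (int t = j + 1; t < n; ++t) {
                    if (x[t] > h) break;
                    if (x[t] < rmin) rmin = x[t];
                }
                const double prom = h - std::max(lmin, rmin);
                if (prom >= min_prominence) {
                    const double thr = h - prom;
                    int s = i, e = j;
                    while (s - 1 >= 0 && x[s - 1] > thr) --s;
                    while (e + 1 < n && x[e + 1] > thr) ++e;
                    starts.push_back(s);
                    ends.push_back(e + 1);
                    apexes.push_back(i);
                    heights.push_back(h);
                    proms.push_back(prom);
                }
            }
            i = j + 1;
        } else {
            ++i;
        }
    }
    return DataFrame::create(_["start"] = starts, _["end"] = ends,
                             _["apex"] = apexes, _["height"] = heights,
                             _["prominence"] = proms);
}
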