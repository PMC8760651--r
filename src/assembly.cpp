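#include <Rcpp.h>
#include <vector>
#include <string>
#include <queue>
#include <algorithm>
using namespace Rcpp;

static std::string revcomp_str(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) {
        switch (c) {
        case 'A': c = 'T'; break; case 'T': c = 'A'; break;
        case 'C': c = 'G'; break; case 'G': c = 'C'; break;
        case 'a': c = 't'; break; case 't': c = 'a'; break;
        case 'c': c = 'g'; break; case 'g': c = 'c'; break;
        default: break;
        }
    }
    return r;
}

// longest prefix of b that is a suffix of a (KMP prefix function on b#a)
static int suffix_prefix_overlap(const std::string &a, const std::string &b) {
    std::string s = b + '\x01' + a;
    const int n = (int)s.size();
    std::vector<int> pi(n, 0);
    for (int i = 1; i < n; ++i) {
        int j = pi[i - 1];
        while (j > 0 && s[i] != s[j]) j = pi[j - 1];
        if (s[i] == s[j]) ++j;
        pi[i] = j;
    }
    return pi[n - 1];
}

struct Merge {
    int ov, i, j, mode; // mode: 0 i->j, 1 j->i, 2 i->rc(j), 3 rc(j)->i
    bool operator<(const Merge &o) const { return ov < o.ov; }
};

// Greedy overlap-layout assembly: repeatedly merge the pair of sequences with
// the longest exact suffix-prefix overlap >= min_overlap, trying both
// orientations of the second sequence; unmerged sequences become their own
// contigs. Contigs are returned in order of decreasing length.
// [[Rcpp::export]]
CharacterVector cpp_greedy_assemble(CharacterVector seqs, int min_overlap) {
    const int n = seqs.size();
    std::vector<std::string> sq(n), rc(n);
    std::vector<bool> alive(n, true);
    for (int i = 0; i < n; ++i) {
        sq[i] = as<std::string>(seqs[i]);
        rc[i] = revcomp_str(sq[i]);
    }

    std::priority_queue<Merge> pq;
    auto push_pair = [&](int i, int j) {
        // four merge layouts; overlap must be >= min_overlap
        int ov0 = suffix_prefix_overlap(sq[i], sq[j]);
        int ov1 = suffix_prefix_overlap(sq[j], sq[i]);
        int ov2 = suffix_prefix_overlap(sq[i], rc[j]);
        int ov3 = suffix_prefix_overlap(rc[j], sq[i]);
        if (ov0 >= min_overlap) pq.push({ov0, i, j, 0});
        if (ov1 >= min_overlap) pq.push({ov1, i, j, 1});
        if (ov2 >= min_overlap) pq.push({ov2, i, j, 2});
        if (ov3 >= min_overlap) pq.push({ov3, i, j, 3});
    };
    for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j) push_pair(i, j);

    auto current_ov = [&](const Merge &m) {
        switch (m.mode) {
        case 0: return suffix_prefix_overlap(sq[m.i], sq[m.j]);
        case 1: return suffix_prefix_overlap(sq[m.j], sq[m.i]);
        case 2: return suffix_prefix_overlap(sq[m.i], rc[m.j]);
        default: return suffix_prefix_overlap(rc[m.j], sq[m.i]);
        }
    };

    while (!pq.empty()) {
        Merge m = pq.top(); pq.pop();
        if (!alive[m.i] || !alive[m.j]) continue;
        // lazy invalidation: sequences may have grown since this entry was pushed
        int ov = current_ov(m);
        if (ov != m.ov) { if (ov >= min_overlap) { m.ov = ov; pq.push(m); } continue; }
        const std::string &left = (m.mode == 0) ? sq[m.i] : (m.mode == 1) ? sq[m.j]
                                  : (m.mode == 2) ? sq[m.i] : rc[m.j];
        const std::string &right = (m.mode == 0) ? sq[m.j] : (m.mode == 1) ? sq[m.i]
                                   : (m.mode == 2) ? rc[m.j] : sq[m.i];
        std::string merged = left + right.substr(std::min<size_t>(ov, right.size()));
        alive[m.j] = false;
        sq[m.i] = merged;
        rc[m.i] = revcomp_str(merged);
        for (int t = 0; t < n; ++t)
            if (alive[t] && t != m.i) push_pair(m.i, t);
    }

    std::vector<int> idx;
    for (int i = 0; i < n; ++i) if (alive[i]) idx.push_back(i);
    std::sort(idx.begin(), idx.end(), [&](int a, int b) {
        if (sq[a].size() != sq[b].size()) return sq[a].size() > sq[b].size();
        return a < b;
    });
    CharacterVector out(idx.size());
    for (size_t i = 0; i < idx.size(); ++i) out[i] = sq[idx[i]];
    return out;
}
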