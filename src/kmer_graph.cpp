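#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit encode; returns false on ambiguous base
static inline bool encode_base(char c, uint64_t &v) {
    switch (c) {
    case 'A': case 'a': v = 0; return true;
    case 'C': case 'c': v = 1; return true;
    case 'G': case 'g': v = 2; return true;
    case 'T': case 't': v = 3; return true;
    default: return false;
    }
}

// Edges of the shared-k-mer read graph: an undirected edge links two reads
// iff they share at least min_shared distinct canonical k-mers.
// Returns a 2-column integer matrix of 1-based read indices.
// [[Rcpp::export]]
IntegerMatrix cpp_kmer_edges(CharacterVector reads, int k, int min_shared) {
    const int n = reads.size();
    if (k < 1 || k > 31) stop("k must be in 1..31");
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

    // distinct canonical k-mers per read
    std::unordered_map<uint64_t, std::vector<int>> buckets;
    buckets.reserve(1 << 20);
    std::vector<uint64_t> kms;
    for (int i = 0; i < n; ++i) {
        const char *s = CHAR(STRING_ELT(reads, i));
        int len = LENGTH(STRING_ELT(reads, i));
        if (len < k) continue;
        kms.clear();
        uint64_t fwd = 0, rev = 0;
        int run = 0;
        for (int p = 0; p < len; ++p) {
            uint64_t b;
            if (!encode_base(s[p], b)) { run = 0; fwd = rev = 0; continue; }
            fwd = ((fwd << 2) | b) & mask;
            rev = (rev >> 2) | ((3ULL - b) << (2 * (k - 1)));
            if (++run >= k) kms.push_back(fwd < rev ? fwd : rev);
        }
        std::sort(kms.begin(), kms.end());
        kms.erase(std::unique(kms.begin(), kms.end()), kms.end());
        for (uint64_t km : kms) buckets[km].push_back(i);
    }

    // count shared k-mers per co-bucketed read pair
    std::unordered_map<uint64_t, int> paircount;
    paircount.reserve(1 << 20);
    for (auto &kv : buckets) {
        const std::vector<int> &v = kv.second;
        const size_t m = v.size();
        if (m < 2) continue;
        for (size_t a = 0; a + 1 < m; ++a)
            for (size_t b = a + 1; b < m; ++b)
                ++paircount[(uint64_t)v[a] * (uint64_t)n + (uint64_t)v[b]];
    }

    std::vector<int> from, to;
    for (auto &kv : paircount) {
        if (kv.second >= min_shared) {
            from.push_back((int)(kv.first / n) + 1);
            to.push_back((int)(kv.first % n) + 1);
        }
    }
    IntegerMatrix out(from.size(), 2);
    for (size_t i = 0; i < from.size(); ++i) {
        out(i, 0) = from[i];
        out(i, 1) = to[i];
    }
    return out;
}

// Shared canonical k-mer count for one read pair (used by test oracles).
// [[Rcpp::export]]
int cpp_shared_kmers(std::string a, std::string b, int k) {
    CharacterVector reads = CharacterVector::create(a, b);
    IntegerMatrix e = cpp_kmer_edges(reads, k, 1);
    if (e.nrow() == 0) return 0;
    // recount precisely
    auto kmset = [&](const std::string &s) {
        std::vector<uint64_t> km;
        const uint64_t mask = (1ULL << (2 * k)) - 1;
        uint64_t fwd = 0, rev = 0; int run = 0;
        for (char c : s) {
            uint64_t v;
            if (!encode_base(c, v)) { run = 0; fwd = rev = 0; continue; }
            fwd = ((fwd << 2) | v) & mask;
            rev = (rev >> 2) | ((3ULL - v) << (2 * (k - 1)));
            if (++run >= k) km.push_back(fwd < rev ? fwd : rev);
        }
        std::sort(km.begin(), km.end());
        km.erase(std::unique(km.begin(), km.end()), km.end());
        return km;
    };
    std::vector<uint64_t> ka = kmset(a), kb = kmset(b), inter;
    std::set_intersection(ka.begin(), ka.end(), kb.begin(), kb.end(),
                          std::back_inserter(inter));
    return (int)inter.size();
}
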