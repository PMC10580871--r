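#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

// 2-bit base encoding; anything outside ACGT (case-insensitive) is invalid
static inline int baseCode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    }
    return -1;
}

// Canonical k-mer codes at every position of s (rolling 2-bit encoding of the
// lexicographically smaller of the k-mer and its reverse complement).
// Positions whose window contains a non-ACGT base are skipped.
// Codes are returned as doubles: 2k <= 52 keeps them exact.
static std::vector<double> canonCodes(const std::string& s, int k) {
    std::vector<double> out;
    const int n = (int) s.size();
    if (n < k) return out;
    out.reserve(n - k + 1);
    const unsigned long long mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    unsigned long long fwd = 0, rev = 0;
    int valid = 0;
    for (int i = 0; i < n; ++i) {
        const int b = baseCode(s[i]);
        if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (unsigned long long) b) & mask;
        rev = (rev >> 2) | (((unsigned long long) (3 - b)) << (2 * (k - 1)));
        if (++valid >= k) out.push_back((double) (fwd < rev ? fwd : rev));
    }
    return out;
}

// [[Rcpp::export(name = ".canonical_codes")]]
List canonical_codes(CharacterVector seqs, int k) {
    const int n = seqs.size();
    List out(n);
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::vector<double> v = canonCodes(s, k);
        out[i] = NumericVector(v.begin(), v.end());
    }
    return out;
}

// Build a flat sorted (code, taxon) table; one entry per distinct canonical
// k-mer per taxon, plus per-taxon distinct-k-mer totals.
// [[Rcpp::export(name = ".build_index_cpp")]]
List build_index_cpp(CharacterVector seqs, IntegerVector taxa, int k) {
    std::vector<std::pair<double, int> > pairs;
    IntegerVector totals(seqs.size());
    for (int i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::vector<double> v = canonCodes(s, k);
        std::sort(v.begin(), v.end());
        v.erase(std::unique(v.begin(), v.end()), v.end());
        totals[i] = (int) v.size();
        for (size_t j = 0; j < v.size(); ++j)
            pairs.push_back(std::make_pair(v[j], taxa[i]));
    }
    std::sort(pairs.begin(), pairs.end());
    pairs.erase(std::unique(pairs.begin(), pairs.end()), pairs.end());
    NumericVector codes(pairs.size());
    IntegerVector ptax(pairs.size());
    for (size_t j = 0; j < pairs.size(); ++j) {
        codes[j] = pairs[j].first;
        ptax[j] = pairs[j].second;
    }
    return List::create(_["codes"] = codes, _["taxa"] = ptax,
                        _["totals"] = totals);
}

// Classify reads against a sorted (code, taxon) table.
// Per read: count, over all k-mer positions, hits to each taxon; the best
// taxon is the argmax of that count (ties -> smallest taxon_id); score is the
// count for the best taxon; n_kmers is the number of valid k-mer positions.
// [[Rcpp::export(name = ".classify_cpp")]]
DataFrame classify_cpp(CharacterVector seqs, NumericVector codes,
                       IntegerVector taxa, int k) {
    const int n = seqs.size();
    IntegerVector best(n), score(n), nk(n);
    const double* lo = codes.begin();
    const double* hi = codes.end();
    for (int i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        std::vector<double> v = canonCodes(s, k);
        nk[i] = (int) v.size();
        std::unordered_map<int, int> counts;
        for (size_t j = 0; j < v.size(); ++j) {
            const double* p = std::lower_bound(lo, hi, v[j]);
            for (; p != hi && *p == v[j]; ++p)
                counts[taxa[p - lo]] += 1;
        }
        int bt = NA_INTEGER, bs = 0;
        for (std::unordered_map<int, int>::const_iterator it = counts.begin();
             it != counts.end(); ++it) {
            if (it->second > bs || (it->second == bs && bs > 0 &&
                                    (bt == NA_INTEGER || it->first < bt))) {
                bs = it->second;
                bt = it->first;
            }
        }
        best[i] = bt;
        score[i] = bs;
    }
    return DataFrame::create(_["taxon_id"] = best, _["score"] = score,
                             _["n_kmers"] = nk);
}
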