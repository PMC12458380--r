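#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

// 2-bit encoding; k <= 31 so a k-mer fits in 62 bits of a uint64_t.

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

static std::string decode_kmer(uint64_t code, int k) {
    static const char *bases = "ACGT";
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = bases[code & 3ULL];
        code >>= 2;
    }
    return s;
}

static uint64_t encode_kmer(const std::string &s) {
    uint64_t code = 0;
    for (size_t i = 0; i < s.size(); ++i) {
        int b = base_code(s[i]);
        if (b < 0) Rcpp::stop("non-ACGT base in k-mer '%s'", s);
        code = (code << 2) | (uint64_t)b;
    }
    return code;
}

// Rolling scan over one sequence calling f(canonical_code, fwd_pos) at every
// position whose k-mer is N-free.
template <typename F>
static void scan_canonical(const std::string &seq, int k, F f) {
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    const int shift = 2 * (k - 1);
    int n = (int)seq.size();
    if (n < k) return;
    uint64_t fwd = 0, rev = 0;
    int valid = 0; // bases accumulated since last invalid char
    for (int i = 0; i < n; ++i) {
        int b = base_code(seq[i]);
        if (b < 0) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)b) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
        if (++valid >= k) {
            uint64_t canon = fwd < rev ? fwd : rev;
            f(canon, i - k + 1);
        }
    }
}

// [[Rcpp::export]]
List cpp_hap_specific_kmers(CharacterVector hap1_seqs, CharacterVector hap2_seqs, int k) {
    if (k < 1 || k > 31) Rcpp::stop("k must be between 1 and 31");
    std::unordered_map<uint64_t, int> c1, c2;
    for (R_xlen_t s = 0; s < hap1_seqs.size(); ++s) {
        std::string seq = as<std::string>(hap1_seqs[s]);
        scan_canonical(seq, k, [&](uint64_t canon, int) { c1[canon]++; });
    }
    for (R_xlen_t s = 0; s < hap2_seqs.size(); ++s) {
        std::string seq = as<std::string>(hap2_seqs[s]);
        scan_canonical(seq, k, [&](uint64_t canon, int) { c2[canon]++; });
    }
    std::vector<uint64_t> m1, m2;
    for (const auto &kv : c1) if (c2.find(kv.first) == c2.end()) m1.push_back(kv.first);
    for (const auto &kv : c2) if (c1.find(kv.first) == c1.end()) m2.push_back(kv.first);
    std::sort(m1.begin(), m1.end());
    std::sort(m2.begin(), m2.end());
    CharacterVector k1(m1.size()), k2(m2.size());
    IntegerVector n1(m1.size()), n2(m2.size());
    for (size_t i = 0; i < m1.size(); ++i) { k1[i] = decode_kmer(m1[i], k); n1[i] = c1[m1[i]]; }
    for (size_t i = 0; i < m2.size(); ++i) { k2[i] = decode_kmer(m2[i], k); n2[i] = c2[m2[i]]; }
    return List::create(_["hap1_markers"] = k1, _["hap1_counts"] = n1,
                        _["hap2_markers"] = k2, _["hap2_counts"] = n2);
}

// [[Rcpp::export]]
List cpp_scan_markers(std::string seq, CharacterVector hap1_markers,
                      CharacterVector hap2_markers, int k) {
    std::unordered_set<uint64_t> s1, s2;
    s1.reserve(hap1_markers.size() * 2 + 1);
    s2.reserve(hap2_markers.size() * 2 + 1);
    for (R_xlen_t i = 0; i < hap1_markers.size(); ++i)
        s1.insert(encode_kmer(as<std::string>(hap1_markers[i])));
    for (R_xlen_t i = 0; i < hap2_markers.size(); ++i)
        s2.insert(encode_kmer(as<std::string>(hap2_markers[i])));
    std::vector<int> pos, src;
    scan_canonical(seq, k, [&](uint64_t canon, int p) {
        if (s1.count(canon)) { pos.push_back(p); src.push_back(1); }
        else if (s2.count(canon)) { pos.push_back(p); src.push_back(2); }
    });
    return List::create(_["pos"] = wrap(pos), _["source"] = wrap(src));
}
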