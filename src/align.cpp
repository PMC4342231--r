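#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
#include <unordered_map>

using namespace Rcpp;

// 2-bit packed representation of a nucleotide string plus a 2-bit "invalid"
// mask (01 at positions holding anything other than A/C/G/T). Mismatch
// counting between a read and a reference window is then XOR + popcount over
// 64-bit words, with any invalid base on either side forced to mismatch.
struct Packed {
    std::vector<uint64_t> code;
    std::vector<uint64_t> bad;
    int len;
};

static inline int baseCode(char c, bool &valid) {
    switch (c) {
    case 'A': case 'a': valid = true; return 0;
    case 'C': case 'c': valid = true; return 1;
    case 'G': case 'g': valid = true; return 2;
    case 'T': case 't': valid = true; return 3;
    default: valid = false; return 0;
    }
}

static Packed pack(const std::string &s) {
    Packed p;
    p.len = (int) s.size();
    int nw = (p.len + 31) / 32;
    p.code.assign(nw + 2, 0);  // padding for shifted window access
    p.bad.assign(nw + 2, 0);
    for (int i = 0; i < p.len; ++i) {
        bool valid;
        uint64_t c = (uint64_t) baseCode(s[i], valid);
        p.code[i >> 5] |= c << (2 * (i & 31));
        if (!valid) p.bad[i >> 5] |= 1ULL << (2 * (i & 31));
    }
    return p;
}

static const uint64_t LOW = 0x5555555555555555ULL;

// A read pre-shifted by s bases (0..31) so that comparing against reference
// words needs no per-window bit shifting: window offset o uses variant
// s = o mod 32 against reference words starting at o div 32. `mask` holds
// the 01-pattern over the read's own positions within each word.
struct ShiftedRead {
    std::vector<uint64_t> code, bad, mask;
    int nWords;
};

static void buildShifted(const Packed &r, std::vector<ShiftedRead> &out) {
    int n = r.len;
    out.resize(32);
    // base (unshifted) valid-position mask
    int nw0 = (n + 31) / 32;
    std::vector<uint64_t> mask0(nw0 + 2, 0);
    for (int i = 0; i < nw0; ++i) mask0[i] = LOW;
    if (n & 31) mask0[nw0 - 1] = LOW & ((1ULL << (2 * (n & 31))) - 1ULL);
    for (int s = 0; s < 32; ++s) {
        ShiftedRead &sr = out[s];
        sr.nWords = (s + n + 31) / 32;
        sr.code.assign(sr.nWords, 0);
        sr.bad.assign(sr.nWords, 0);
        sr.mask.assign(sr.nWords, 0);
        int sh = 2 * s;
        for (int i = 0; i < sr.nWords; ++i) {
            uint64_t lo, hi;
            if (sh == 0) {
                sr.code[i] = (i < nw0) ? r.code[i] : 0;
                sr.bad[i] = (i < nw0) ? r.bad[i] : 0;
                sr.mask[i] = (i < nw0) ? mask0[i] : 0;
            } else {
                lo = (i < nw0) ? r.code[i] : 0;
                hi = (i > 0 && i - 1 < nw0) ? r.code[i - 1] : 0;
                sr.code[i] = (lo << sh) | (i > 0 ? (hi >> (64 - sh)) : 0);
                lo = (i < nw0) ? r.bad[i] : 0;
                hi = (i > 0 && i - 1 < nw0) ? r.bad[i - 1] : 0;
                sr.bad[i] = (lo << sh) | (i > 0 ? (hi >> (64 - sh)) : 0);
                lo = (i < nw0) ? mask0[i] : 0;
                hi = (i > 0 && i - 1 < nw0) ? mask0[i - 1] : 0;
                sr.mask[i] = (lo << sh) | (i > 0 ? (hi >> (64 - sh)) : 0);
            }
        }
    }
}

// Mismatches of the read (as pre-shifted variants) against the reference
// window at 0-based offset o; aborts (returning >= limit) once the running
// count reaches `limit`.
static inline int windowMismatches(const std::vector<ShiftedRead> &sv,
                                   const Packed &ref, int o, int limit) {
    const ShiftedRead &sr = sv[o & 31];
    const uint64_t *rc = ref.code.data() + (o >> 5);
    const uint64_t *rb = ref.bad.data() + (o >> 5);
    int mm = 0;
    for (int i = 0; i < sr.nWords; ++i) {
        uint64_t d = sr.code[i] ^ rc[i];
        uint64_t bits = ((d | (d >> 1)) | sr.bad[i] | rb[i]) & sr.mask[i];
        mm += __builtin_popcountll(bits);
        if (mm >= limit) return mm;
    }
    return mm;
}

static const int SEED_K = 16;

static inline bool kmerAt(const std::string &s, int q, uint32_t &key) {
    key = 0;
    for (int t = 0; t < SEED_K; ++t) {
        bool valid;
        key = (key << 2) | (uint32_t) baseCode(s[q + t], valid);
        if (!valid) return false;
    }
    return true;
}

// Exhaustive ungapped placement of each read against every reference and
// offset. Best placement = fewest mismatches; ties broken by reference
// order then lowest offset. Exact-match k-mer seeds pre-load the
// branch-and-bound threshold so the full scan abandons hopeless windows
// after one or two words; the result is identical to a plain exhaustive
// scan (the full scan still visits every window, accepting an equal-
// mismatch window only when it precedes the current candidate).
// [[Rcpp::export(name = ".alignScan")]]
DataFrame alignScan(CharacterVector reads, CharacterVector refs,
                    double minIdentity) {
    int nReads = reads.size(), nRefs = refs.size();
    if (nRefs == 0) stop("empty reference set");
    std::vector<Packed> prefs(nRefs);
    std::vector<std::string> srefs(nRefs);
    int maxRefLen = 0;
    for (int j = 0; j < nRefs; ++j) {
        srefs[j] = as<std::string>(refs[j]);
        prefs[j] = pack(srefs[j]);
        if (prefs[j].len > maxRefLen) maxRefLen = prefs[j].len;
    }
    std::unordered_map<uint32_t, std::vector<std::pair<int, int>>> index;
    for (int j = 0; j < nRefs; ++j) {
        for (int p = 0; p + SEED_K <= prefs[j].len; ++p) {
            uint32_t key;
            if (kmerAt(srefs[j], p, key))
                index[key].push_back(std::make_pair(j, p));
        }
    }
    IntegerVector refIdx(nReads), start(nReads), mism(nReads);
    LogicalVector mapped(nReads);
    std::vector<ShiftedRead> shifted;
    for (int i = 0; i < nReads; ++i) {
        std::string rs = as<std::string>(reads[i]);
        Packed r = pack(rs);
        if (r.len > maxRefLen)
            stop("read %d is longer than the longest reference", i + 1);
        buildShifted(r, shifted);
        int maxMm = (int) std::floor((1.0 - minIdentity) * r.len + 1e-9);
        int best = maxMm + 1, bestRef = -1, bestOff = -1;
        // seed phase: candidates from exact k-mer hits tighten `best`
        if (r.len >= SEED_K) {
            int probes[4] = {0, r.len / 3, (2 * r.len) / 3, r.len - SEED_K};
            for (int pi = 0; pi < 4; ++pi) {
                int q = probes[pi];
                if (pi > 0 && q == probes[pi - 1]) continue;
                uint32_t key;
                if (!kmerAt(rs, q, key)) continue;
                auto it = index.find(key);
                if (it == index.end()) continue;
                for (size_t h = 0; h < it->second.size(); ++h) {
                    int j = it->second[h].first;
                    int o = it->second[h].second - q;
                    if (o < 0 || o + r.len > prefs[j].len) continue;
                    bool earlier = bestRef >= 0 &&
                        (j < bestRef || (j == bestRef && o < bestOff));
                    int mm = windowMismatches(shifted, prefs[j], o,
                                              earlier ? best + 1 : best);
                    if (mm < best || (earlier && mm == best)) {
                        best = mm;
                        bestRef = j;
                        bestOff = o;
                    }
                }
            }
        }
        for (int j = 0; j < nRefs && best > 0; ++j) {
            int lastOff = prefs[j].len - r.len;
            for (int o = 0; o <= lastOff; ++o) {
                if (j == bestRef && o == bestOff) continue;
                bool earlier = bestRef >= 0 &&
                    (j < bestRef || (j == bestRef && o < bestOff));
                int mm = windowMismatches(shifted, prefs[j], o,
                                          earlier ? best + 1 : best);
                if (mm < best || (earlier && mm == best)) {
                    best = mm;
                    bestRef = j;
                    bestOff = o;
                    if (best == 0) break;
                }
            }
        }
        if (bestRef >= 0) {
            refIdx[i] = bestRef + 1;
            start[i] = bestOff + 1;  // 1-based
            mism[i] = best;
            mapped[i] = true;
        } else {
            refIdx[i] = NA_INTEGER;
            start[i] = NA_INTEGER;
            mism[i] = NA_INTEGER;
            mapped[i] = false;
        }
    }
    return DataFrame::create(_["ref_idx"] = refIdx, _["start"] = start,
                             _["mismatches"] = mism, _["mapped"] = mapped);
}
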