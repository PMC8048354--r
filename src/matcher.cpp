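#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Gapless end-to-end matcher of (paired) read fragments against transcript
// sequences. Transcripts differ only by single-base substitutions, so gapless
// alignment is sufficient. Exactness guarantee: each mate is partitioned into
// (maxMismatch + 1) contiguous pieces; if the mate aligns somewhere with at
// most maxMismatch mismatches, at least one piece is mismatch-free
// (pigeonhole), hence the k-mer at that piece start hits the index and the
// true offset is enumerated. Reads too short to carry informative seeds fall
// back to a full offset scan, so the result equals a brute-force scan in all
// cases. Paired fragments are scored jointly (mismatches summed); mate 2 is
// reverse-complemented and must align downstream of mate 1 on the same
// transcript. Per (fragment, transcript) the single best placement is kept
// (fewest mismatches; ties broken by smallest offsets).

static inline int baseCode(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
    }
}

// mismatches of query aligned at offset; early abort when > budget.
// Non-ACGT characters (N) always count as mismatches.
static inline int countMismatch(const std::string &tx, const std::string &q,
                                int offset, int budget) {
    int mm = 0;
    const int L = (int)q.size();
    for (int i = 0; i < L; ++i) {
        int ca = baseCode(tx[offset + i]), cb = baseCode(q[i]);
        if (ca < 0 || cb < 0 || ca != cb) {
            if (++mm > budget) return mm;
        }
    }
    return mm;
}

static inline std::string revComp(const std::string &s) {
    std::string r(s.rbegin(), s.rend());
    for (auto &c : r) {
        switch (c) {
        case 'A': case 'a': c = 'T'; break;
        case 'C': case 'c': c = 'G'; break;
        case 'G': case 'g': c = 'C'; break;
        case 'T': case 't': c = 'A'; break;
        default: c = 'N';
        }
    }
    return r;
}

typedef std::unordered_map<uint64_t, std::vector<std::pair<int,int> > > KmerIndex;

static bool encodeKmer(const std::string &s, int pos, int k, uint64_t &key) {
    uint64_t v = 0;
    for (int i = 0; i < k; ++i) {
        int c = baseCode(s[pos + i]);
        if (c < 0) return false;
        v = (v << 2) | (uint64_t)c;
    }
    key = v;
    return true;
}

// candidate alignment offsets per transcript for one mate
static void seedCandidates(const std::string &q, int k, int nPieces,
                           const KmerIndex &idx,
                           std::unordered_map<int, std::vector<int> > &cand) {
    const int L = (int)q.size();
    for (int p = 0; p < nPieces; ++p) {
        int start = (int)((long long)p * L / nPieces);
        if (start + k > L) start = L - k;
        if (start < 0) continue;
        uint64_t key;
        if (!encodeKmer(q, start, k, key)) continue;
        KmerIndex::const_iterator it = idx.find(key);
        if (it == idx.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j)
            cand[it->second[j].first].push_back(it->second[j].second - start);
    }
    for (auto &kv : cand) {
        std::sort(kv.second.begin(), kv.second.end());
        kv.second.erase(std::unique(kv.second.begin(), kv.second.end()),
                        kv.second.end());
    }
}

struct Best { int mm, o1, o2; };

static void bestPlacement(const std::string &tx, const std::string &m1,
                          const std::string &m2r, bool paired,
                          const std::vector<int> &off1s,
                          const std::vector<int> &off2s,
                          int maxMismatch, Best &best) {
    const int txLen = (int)tx.size();
    const int L1 = (int)m1.size(), L2 = (int)m2r.size();
    best.mm = maxMismatch + 1; best.o1 = -1; best.o2 = -1;
    for (size_t a = 0; a < off1s.size(); ++a) {
        int o1 = off1s[a];
        if (o1 < 0 || o1 + L1 > txLen) continue;
        int mm1 = countMismatch(tx, m1, o1, maxMismatch);
        if (mm1 > maxMismatch) continue;
        if (!paired) {
            if (mm1 < best.mm) { best.mm = mm1; best.o1 = o1; }
            continue;
        }
        for (size_t b = 0; b < off2s.size(); ++b) {
            int o2 = off2s[b];
            if (o2 < o1 || o2 + L2 > txLen) continue;
            int mm2 = countMismatch(tx, m2r, o2, maxMismatch - mm1);
            int mm = mm1 + mm2;
            if (mm < best.mm) { best.mm = mm; best.o1 = o1; best.o2 = o2; }
        }
    }
}

// [[Rcpp::export(name = ".cpp_build_compat")]]
DataFrame cpp_build_compat(CharacterVector txSeqs, CharacterVector mate1,
                           CharacterVector mate2, int maxMismatch) {
    const int nTx = txSeqs.size();
    const int nFrag = mate1.size();
    const bool paired = mate2.size() > 0;
    if (paired && mate2.size() != nFrag)
        stop("mate1 and mate2 must have equal length");

    std::vector<std::string> tx(nTx);
    for (int t = 0; t < nTx; ++t) tx[t] = as<std::string>(txSeqs[t]);

    // k chosen from the shortest mate so the pigeonhole split stays valid
    int minMate = INT32_MAX;
    for (int f = 0; f < nFrag; ++f) {
        minMate = std::min(minMate, (int)LENGTH(STRING_ELT(mate1, f)));
        if (paired) minMate = std::min(minMate, (int)LENGTH(STRING_ELT(mate2, f)));
    }
    const int nPieces = maxMismatch + 1;
    int k = std::min(16, minMate / nPieces);
    const bool bruteForce = (k < 6) || (nFrag == 0);

    KmerIndex idx;
    if (!bruteForce) {
        for (int t = 0; t < nTx; ++t) {
            const std::string &s = tx[t];
            for (int p = 0; p + k <= (int)s.size(); ++p) {
                uint64_t key;
                if (encodeKmer(s, p, k, key)) idx[key].push_back(std::make_pair(t, p));
            }
        }
    }

    std::vector<int> outFrag, outTx, outMm, outOff1, outOff2;
    Best best;

    for (int f = 0; f < nFrag; ++f) {
        std::string m1 = as<std::string>(mate1[f]);
        std::string m2r;
        if (paired) m2r = revComp(as<std::string>(mate2[f]));

        if (bruteForce) {
            for (int t = 0; t < nTx; ++t) {
                const int txLen = (int)tx[t].size();
                std::vector<int> off1s, off2s;
                for (int o = 0; o + (int)m1.size() <= txLen; ++o) off1s.push_back(o);
                if (paired)
                    for (int o = 0; o + (int)m2r.size() <= txLen; ++o) off2s.push_back(o);
                bestPlacement(tx[t], m1, m2r, paired, off1s, off2s, maxMismatch, best);
                if (best.mm <= maxMismatch) {
                    outFrag.push_back(f + 1); outTx.push_back(t + 1);
                    outMm.push_back(best.mm); outOff1.push_back(best.o1 + 1);
                    outOff2.push_back(paired ? best.o2 + 1 : NA_INTEGER);
                }
            }
        } else {
            std::unordered_map<int, std::vector<int> > c1, c2;
            seedCandidates(m1, k, nPieces, idx, c1);
            if (paired) seedCandidates(m2r, k, nPieces, idx, c2);
            static const std::vector<int> none;
            for (auto &kv : c1) {
                int t = kv.first;
                const std::vector<int> *o2p = &none;
                if (paired) {
                    std::unordered_map<int, std::vector<int> >::iterator it2 = c2.find(t);
                    if (it2 == c2.end()) continue; // both mates must seed
                    o2p = &it2->second;
                }
                bestPlacement(tx[t], m1, m2r, paired, kv.second, *o2p, maxMismatch, best);
                if (best.mm <= maxMismatch) {
                    outFrag.push_back(f + 1); outTx.push_back(t + 1);
                    outMm.push_back(best.mm); outOff1.push_back(best.o1 + 1);
                    outOff2.push_back(paired ? best.o2 + 1 : NA_INTEGER);
                }
            }
        }
    }

    return DataFrame::create(_["fragment"] = outFrag, _["tx"] = outTx,
                             _["mismatch"] = outMm, _["offset1"] = outOff1,
                             _["offset2"] = outOff2);
}
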