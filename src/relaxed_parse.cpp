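#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>

using namespace Rcpp;

// Bounded-event stem alignment used by the relaxed REP parser.
// The left arm is aligned globally against the reverse complement of the
// right arm; a mismatch costs one "interruption" event, a gap run of length
// <= max_bulge costs one event regardless of its length, and longer runs are
// forbidden.  N never pairs with anything.

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

struct AlnRes {
    int events;
    int matches;
};

static AlnRes stem_align(const std::string &A, const std::string &B,
                         int max_ev, int max_bulge) {
    const int la = (int) A.size(), lb = (int) B.size();
    const int INF = INT_MAX / 4;
    // states: 0 = last column was (mis)match; 1..max_bulge = gap-in-A run
    // length; max_bulge+1..2*max_bulge = gap-in-B run length
    const int S = 1 + 2 * max_bulge;
    std::vector<int> ev((size_t)(la + 1) * (lb + 1) * S, INF);
    std::vector<int> mt((size_t)(la + 1) * (lb + 1) * S, -1);
    auto idx = [&](int x, int y, int s) {
        return ((size_t) x * (lb + 1) + y) * S + s;
    };
    ev[idx(0, 0, 0)] = 0;
    mt[idx(0, 0, 0)] = 0;
    for (int x = 0; x <= la; ++x) {
        for (int y = 0; y <= lb; ++y) {
            for (int s = 0; s < S; ++s) {
                const int e = ev[idx(x, y, s)];
                if (e >= INF) continue;
                const int m = mt[idx(x, y, s)];
                if (x < la && y < lb) {  // pair the next two bases
                    const bool match = (A[x] != 'N' && A[x] == B[y]);
                    const int ne = e + (match ? 0 : 1);
                    const int nm = m + (match ? 1 : 0);
                    if (ne <= max_ev) {
                        const size_t id = idx(x + 1, y + 1, 0);
                        if (ne < ev[id] || (ne == ev[id] && nm > mt[id])) {
                            ev[id] = ne; mt[id] = nm;
                        }
                    }
                }
                if (y < lb) {  // bulge: unpaired base on the B side
                    const int run = (s >= 1 && s <= max_bulge) ? s : 0;
                    if (run < max_bulge) {
                        const int ne = e + (run == 0 ? 1 : 0);
                        if (ne <= max_ev) {
                            const size_t id = idx(x, y + 1, run + 1);
                            if (ne < ev[id] || (ne == ev[id] && m > mt[id])) {
                                ev[id] = ne; mt[id] = m;
                            }
                        }
                    }
                }
                if (x < la) {  // bulge: unpaired base on the A side
                    const int run = (s > max_bulge) ? s - max_bulge : 0;
                    if (run < max_bulge) {
                        const int ne = e + (run == 0 ? 1 : 0);
                        if (ne <= max_ev) {
                            const size_t id = idx(x + 1, y, max_bulge + run + 1);
                            if (ne < ev[id] || (ne == ev[id] && m > mt[id])) {
                                ev[id] = ne; mt[id] = m;
                            }
                        }
                    }
                }
            }
        }
    }
    AlnRes best; best.events = INF; best.matches = -1;
    for (int s = 0; s < S; ++s) {
        const size_t id = idx(la, lb, s);
        if (ev[id] < best.events ||
            (ev[id] == best.events && mt[id] > best.matches)) {
            best.events = ev[id];
            best.matches = mt[id];
        }
    }
    return best;
}

// Search all decompositions core = left_arm + loop + right_arm + tail for the
// best imperfect stem.  Ranking: fewest interruption events, then most paired
// matches, then smaller loop, then smaller tail.  Returns
// c(found, left_len, loop_len, right_len, tail_len, events, matches).
// [[Rcpp::export]]
IntegerVector cpp_relaxed_search(std::string core, int min_arm, int max_loop,
                                 int max_tail, int max_interruptions,
                                 int max_bulge) {
    const int n = (int) core.size();
    int best_ev = INT_MAX, best_mt = -1;
    int b_i = -1, b_loop = -1, b_t = -1, b_r = -1;
    for (int i = min_arm; i <= n - min_arm; ++i) {
        const std::string A = core.substr(0, i);
        for (int loop = 0; loop <= max_loop; ++loop) {
            for (int t = 0; t <= max_tail; ++t) {
                const int rlen = n - i - loop - t;
                if (rlen < min_arm) break;
                if (std::abs(i - rlen) > max_interruptions * max_bulge)
                    continue;
                std::string B = core.substr(i + loop, rlen);
                std::reverse(B.begin(), B.end());
                for (size_t q = 0; q < B.size(); ++q) B[q] = comp_base(B[q]);
                AlnRes r = stem_align(A, B, max_interruptions, max_bulge);
                if (r.events > max_interruptions) continue;
                bool better = false;
                if (r.events < best_ev) better = true;
                else if (r.events == best_ev) {
                    if (r.matches > best_mt) better = true;
                    else if (r.matches == best_mt) {
                        if (loop < b_loop) better = true;
                        else if (loop == b_loop && t < b_t) better = true;
                    }
                }
                if (better) {
                    best_ev = r.events; best_mt = r.matches;
                    b_i = i; b_loop = loop; b_t = t; b_r = rlen;
                }
            }
        }
    }
    if (b_i < 0) return IntegerVector::create(0, 0, 0, 0, 0, 0, 0);
    return IntegerVector::create(1, b_i, b_loop, b_r, b_t, best_ev, best_mt);
}
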