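#include <Rcpp.h>
using namespace Rcpp;

// Pair weight for bases a, b (DNA alphabet, T stands for U).
// Watson-Crick = 1, G:U wobble = wobble, otherwise 0 (not pairable).
static inline double pair_weight(char a, char b, double wobble) {
    if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 1.0;
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 1.0;
    if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return wobble;
    return 0.0;
}

// Maximum-weight nested base pairing (Nussinov-style DP).
// Returns 1-based partner vector (0 = unpaired) and the optimal score.
// Traceback is deterministic: the 5'-most base of every subproblem is
// paired with its 3'-most admissible partner whenever pairing achieves
// the optimum, recursing left to right.
// [[Rcpp::export(name = ".fold_nussinov")]]
List fold_nussinov(std::string seq, int min_loop, double wobble_weight) {
    const int n = seq.size();
    const double EPS = 1e-9;
    IntegerVector partner(n, 0);
    if (n == 0)
        return List::create(_["partner"] = partner, _["score"] = 0.0);

    // M[i][j] stored in a flat vector, j >= i; width n
    std::vector<double> M((size_t)n * n, 0.0);
    auto at = [&](int i, int j) -> double {
        if (i > j || i < 0 || j >= n) return 0.0;
        return M[(size_t)i * n + j];
    };

    for (int span = min_loop + 1; span < n; ++span) {
        for (int i = 0; i + span < n; ++i) {
            int j = i + span;
            double best = at(i + 1, j);  // i unpaired
            for (int k = i + min_loop + 1; k <= j; ++k) {
                double w = pair_weight(seq[i], seq[k], wobble_weight);
                if (w > 0.0) {
                    double cand = w + at(i + 1, k - 1) + at(k + 1, j);
                    if (cand > best) best = cand;
                }
            }
            M[(size_t)i * n + j] = best;
        }
    }

    // iterative traceback
    std::vector<std::pair<int, int> > stack;
    stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (i >= j) continue;
        double target = at(i, j);
        if (target < EPS) continue;
        bool paired = false;
        for (int k = j; k >= i + min_loop + 1; --k) {
            double w = pair_weight(seq[i], seq[k], wobble_weight);
            if (w > 0.0 &&
                std::fabs(w + at(i + 1, k - 1) + at(k + 1, j) - target) < EPS) {
                partner[i] = k + 1;  // 1-based
                partner[k] = i + 1;
                stack.push_back(std::make_pair(k + 1, j));
                stack.push_back(std::make_pair(i + 1, k - 1));
                paired = true;
                break;
            }
        }
        if (!paired) stack.push_back(std::make_pair(i + 1, j));
    }

    return List::create(_["partner"] = partner,
                        _["score"] = at(0, n - 1));
}

// Ungapped sliding-alignment distance between two sequences: minimum over
// all offsets of (mismatches in the overlap + unaligned overhang positions
// of both sequences). Overhangs count one per base.
// [[Rcpp::export(name = ".sliding_distance")]]
int sliding_distance(std::string a, std::string b) {
    const int la = a.size(), lb = b.size();
    if (la == 0 || lb == 0) return la + lb;
    int best = la + lb;
    for (int s = -(lb - 1); s <= la - 1; ++s) {
        // a[i] aligned with b[i - s]
        int i0 = std::max(0, s), i1 = std::min(la, lb + s);
        int overlap = i1 - i0;
        if (overlap <= 0) continue;
        int mism = 0;
        for (int i = i0; i < i1; ++i)
            if (a[i] != b[i - s]) ++mism;
        int d = mism + (la - overlap) + (lb - overlap);
        if (d < best) best = d;
    }
    return best;
}

// Distance of each query against each reference; returns for every query the
// best distance and (1-based) index of the best reference, ties broken by
// lowest reference index (callers pre-sort references for id tie-breaks).
// [[Rcpp::export(name = ".best_reference_distance")]]
List best_reference_distance(CharacterVector queries, CharacterVector refs) {
    const int nq = queries.size(), nr = refs.size();
    IntegerVector dist(nq, NA_INTEGER), which(nq, NA_INTEGER);
    std::vector<std::string> rs(nr);
    for (int r = 0; r < nr; ++r) rs[r] = as<std::string>(refs[r]);
    for (int q = 0; q < nq; ++q) {
        std::string qs = as<std::string>(queries[q]);
        int bd = INT_MAX, bw = NA_INTEGER;
        for (int r = 0; r < nr; ++r) {
            int d = sliding_distance(qs, rs[r]);
            if (d < bd) { bd = d; bw = r + 1; }
        }
        if (nr > 0) { dist[q] = bd; which[q] = bw; }
    }
    return List::create(_["distance"] = dist, _["which"] = which);
}

// penalty for one aligned miRNA/target position; positions are 1-based
// from the miRNA 5' end; penalties double within the core region.
static inline double site_penalty(char m, char t, int pos, double wobble_pen,
                                  double mismatch_pen, int core_lo, int core_hi) {
    double p;
    if ((m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
        (m == 'G' && t == 'C') || (m == 'C' && t == 'G'))
        p = 0.0;
    else if ((m == 'G' && t == 'T') || (m == 'T' && t == 'G'))
        p = wobble_pen;
    else
        p = mismatch_pen;
    if (pos >= core_lo && pos <= core_hi) p *= 2.0;
    return p;
}

// Scan one transcript for complementarity sites of one miRNA.
// Site windows are scored ungapped and with single-bulge variants (one
// extra target base, or one unpaired miRNA base). For every start the
// best-scoring variant is kept; hits with score <= cutoff are returned.
// btype: 0 = ungapped, 1 = bulged target base, 2 = bulged miRNA base.
// [[Rcpp::export(name = ".scan_target_sites")]]
DataFrame scan_target_sites(std::string mirna, std::string tx, double cutoff,
                            double gap_pen, double wobble_pen,
                            double mismatch_pen, int core_lo, int core_hi,
                            bool allow_bulge) {
    const int L = mirna.size();
    const int n = tx.size();
    std::vector<int> starts, ends, btypes, bposs;
    std::vector<double> scores;
    if (L == 0 || n < L - 1)
        return DataFrame::create(_["start"] = IntegerVector(0),
                                 _["end"] = IntegerVector(0),
                                 _["score"] = NumericVector(0),
                                 _["btype"] = IntegerVector(0),
                                 _["bpos"] = IntegerVector(0));

    for (int p = 0; p + L - 2 < n; ++p) {
        double best = R_PosInf;
        int bestLen = L, bestType = 0, bestB = 0;

        // ungapped, site length L
        if (p + L <= n) {
            double sc = 0.0;
            for (int i = 1; i <= L && sc <= best; ++i)
                sc += site_penalty(mirna[i - 1], tx[p + L - i], i, wobble_pen,
                                   mismatch_pen, core_lo, core_hi);
            if (sc < best) { best = sc; bestLen = L; bestType = 0; bestB = 0; }
        }

        if (allow_bulge) {
            // bulged target base: site length L + 1, bulge after miRNA pos b
            if (p + L + 1 <= n) {
                for (int b = 1; b <= L - 1; ++b) {
                    double sc = (b + 1 >= core_lo && b + 1 <= core_hi)
                                    ? 2.0 * gap_pen : gap_pen;
                    for (int i = 1; i <= L && sc < best; ++i) {
                        int sidx = (i <= b) ? (p + L + 1 - i) : (p + L - i);
                        sc += site_penalty(mirna[i - 1], tx[sidx], i, wobble_pen,
                                           mismatch_pen, core_lo, core_hi);
                    }
                    if (sc < best) { best = sc; bestLen = L + 1; bestType = 1; bestB = b; }
                }
            }
            // bulged miRNA base at pos b: site length L - 1
            if (p + L - 1 <= n) {
                for (int b = 2; b <= L - 1; ++b) {
                    double sc = (b >= core_lo && b <= core_hi)
                                    ? 2.0 * gap_pen : gap_pen;
                    for (int i = 1; i <= L && sc < best; ++i) {
                        if (i == b) continue;
                        int sidx = (i < b) ? (p + L - 1 - i) : (p + L - i);
                        sc += site_penalty(mirna[i - 1], tx[sidx], i, wobble_pen,
                                           mismatch_pen, core_lo, core_hi);
                    }
                    if (sc < best) { best = sc; bestLen = L - 1; bestType = 2; bestB = b; }
                }
            }
        }

        if (best <= cutoff) {
            starts.push_back(p);            // 0-based
            ends.push_back(p + bestLen);    // half-open
            scores.push_back(best);
            btypes.push_back(bestType);
            bposs.push_back(bestB);
        }
    }

    return DataFrame::create(_["start"] = wrap(starts), _["end"] = wrap(ends),
                             _["score"] = wrap(scores), _["btype"] = wrap(btypes),
                             _["bpos"] = wrap(bposs));
}
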