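#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Stacking-weighted Nussinov-style maximum-score folding.
//
// Pair scores: GC/CG = 3, AU/UA = 2, GU/UG = 1; +1 stacking bonus each time
// a pair sits directly inside another pair.  Minimum hairpin loop = 3
// unpaired bases.  Traceback is deterministic: at every cell a pairing
// decomposition is preferred over leaving the 5'-most base unpaired, and
// among tied partners the 3'-most (largest j) wins.

static const int NEG = INT_MIN / 4;
static const int MIN_LOOP = 3;
static const int STACK_BONUS = 1;

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default: return -1;
    }
}

static inline int pair_score(int a, int b) {
    // A=0 C=1 G=2 U=3
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3; // GC
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2; // AU
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1; // GU
    return NEG;
}

class Folder {
public:
    explicit Folder(const std::string &seq) : n((int)seq.size()) {
        code.resize(n);
        for (int i = 0; i < n; ++i) {
            code[i] = base_code(seq[i]);
            if (code[i] < 0) stop("invalid base '%s' (RNA alphabet A/C/G/U required)",
                                  std::string(1, seq[i]));
        }
        M.assign((size_t)n * n, 0);
        P.assign((size_t)n * n, NEG);
        db.assign(n, '.');
        fill();
    }

    std::string dotbracket() { traceM(0, n - 1); return std::string(db.begin(), db.end()); }
    int score() const { return n ? M[idx(0, n - 1)] : 0; }

private:
    int n;
    std::vector<int> code;
    std::vector<int> M, P;
    std::vector<char> db;

    inline size_t idx(int i, int j) const { return (size_t)i * n + j; }
    inline int m_at(int i, int j) const { return (i > j) ? 0 : M[idx(i, j)]; }

    // best score of [i,j] given that (i,j) pair; NEG if they cannot
    void fillP(int i, int j) {
        int w = pair_score(code[i], code[j]);
        if (w == NEG || j - i - 1 < MIN_LOOP) { P[idx(i, j)] = NEG; return; }
        int best = m_at(i + 1, j - 1);
        if (j - 1 - (i + 1) - 1 >= MIN_LOOP && P[idx(i + 1, j - 1)] > NEG) {
            int stacked = P[idx(i + 1, j - 1)] + STACK_BONUS;
            if (stacked > best) best = stacked;
        }
        P[idx(i, j)] = w + best;
    }

    void fill() {
        for (int len = MIN_LOOP + 2; len <= n; ++len) {
            for (int i = 0; i + len - 1 < n; ++i) {
                int j = i + len - 1;
                fillP(i, j);
                int best = m_at(i + 1, j);
                for (int k = i + MIN_LOOP + 1; k <= j; ++k) {
                    if (P[idx(i, k)] == NEG) continue;
                    int cand = P[idx(i, k)] + m_at(k + 1, j);
                    if (cand > best) best = cand;
                }
                M[idx(i, j)] = best;
            }
        }
    }

    void traceM(int i, int j) {
        while (i <= j) {
            if (j - i < MIN_LOOP + 1) return;
            int target = M[idx(i, j)];
            int chosen = -1;
            for (int k = j; k >= i + MIN_LOOP + 1; --k) { // largest partner wins ties
                if (P[idx(i, k)] == NEG) continue;
                if (P[idx(i, k)] + m_at(k + 1, j) == target) { chosen = k; break; }
            }
            if (chosen < 0) { ++i; continue; } // i unpaired
            traceP(i, chosen);
            i = chosen + 1;
        }
    }

    void traceP(int i, int j) {
        while (true) {
            db[i] = '('; db[j] = ')';
            int inner_best = P[idx(i, j)] - pair_score(code[i], code[j]);
            bool stack_ok = (j - 1 - (i + 1) - 1 >= MIN_LOOP) && P[idx(i + 1, j - 1)] > NEG &&
                            (P[idx(i + 1, j - 1)] + STACK_BONUS == inner_best);
            if (stack_ok) { ++i; --j; continue; } // prefer extending the helix
            traceM(i + 1, j - 1);
            return;
        }
    }
};

// [[Rcpp::export(name = ".fold_nussinov")]]
List fold_nussinov(CharacterVector sequences) {
    int m = sequences.size();
    CharacterVector structures(m);
    IntegerVector scores(m);
    for (int s = 0; s < m; ++s) {
        std::string seq = as<std::string>(sequences[s]);
        if (seq.empty()) stop("cannot fold an empty sequence");
        Folder f(seq);
        structures[s] = f.dotbracket();
        scores[s] = f.score();
        if (s % 256 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["dotbracket"] = structures, _["score"] = scores);
}
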