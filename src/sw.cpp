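#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

// Residue encoding: characters are mapped to matrix row indices via the
// matrix alphabet; anything not in the alphabet falls back to 'X'.
static std::vector<int> make_lookup(const std::string &alphabet) {
    std::vector<int> lut(256, -1);
    for (size_t i = 0; i < alphabet.size(); ++i)
        lut[(unsigned char)alphabet[i]] = (int)i;
    int xi = lut[(unsigned char)'X'];
    for (int i = 0; i < 256; ++i)
        if (lut[i] < 0) lut[i] = xi;
    return lut;
}

static std::vector<int> encode(const std::string &s, const std::vector<int> &lut) {
    std::vector<int> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) v[i] = lut[(unsigned char)s[i]];
    return v;
}

// Flatten the R substitution matrix into row-major int storage so the
// DP inner loop runs on raw pointers.
static std::vector<int> flatten(const IntegerMatrix &mat) {
    const int A = mat.nrow();
    std::vector<int> M((size_t)A * A);
    for (int i = 0; i < A; ++i)
        for (int j = 0; j < A; ++j)
            M[(size_t)i * A + j] = mat(i, j);
    return M;
}

// Score-only affine-gap Smith-Waterman (Gotoh), two rolling rows.
// A gap of length k costs gap_open + k * gap_ext.
static int sw_score_flat(const std::vector<int> &a, const std::vector<int> &b,
                         const std::vector<int> &M, int A, int go, int ge) {
    const int m = (int)a.size(), n = (int)b.size();
    if (m == 0 || n == 0) return 0;
    const int NEG = INT_MIN / 4;
    const int goe = go + ge;
    std::vector<int> H(n + 1, 0);   // previous row H, overwritten in place
    std::vector<int> E(n + 1, NEG); // vertical gap state (consumes a)
    int best = 0;
    for (int i = 1; i <= m; ++i) {
        const int *row = &M[(size_t)a[i - 1] * A];
        int Fgap = NEG;   // horizontal gap state (consumes b)
        int diag = 0;     // H[i-1][j-1]
        int *Hp = H.data();
        int *Ep = E.data();
        for (int j = 1; j <= n; ++j) {
            const int up = Hp[j];                    // H[i-1][j]
            const int e = (up - goe > Ep[j] - ge) ? up - goe : Ep[j] - ge;
            Ep[j] = e;
            const int left = Hp[j - 1];              // already row i
            const int f = (left - goe > Fgap - ge) ? left - goe : Fgap - ge;
            Fgap = f;
            int h = diag + row[b[j - 1]];
            if (e > h) h = e;
            if (f > h) h = f;
            if (h < 0) h = 0;
            diag = up;
            Hp[j] = h;
            if (h > best) best = h;
        }
    }
    return best;
}

static int sw_score_full(const std::vector<int> &a, const std::vector<int> &b,
                         const IntegerMatrix &mat, int go, int ge) {
    std::vector<int> M = flatten(mat);
    return sw_score_flat(a, b, M, mat.nrow(), go, ge);
}

// [[Rcpp::export]]
int cpp_sw_score(std::string a, std::string b, IntegerMatrix mat,
                 std::string alphabet, int gap_open, int gap_ext) {
    std::vector<int> lut = make_lookup(alphabet);
    std::vector<int> ea = encode(a, lut), eb = encode(b, lut);
    return sw_score_full(ea, eb, mat, gap_open, gap_ext);
}

// Full Smith-Waterman with traceback: returns score, 1-based inclusive
// coordinates of one optimal local alignment, identity count and number of
// alignment columns. End cell = maximal H scanning i then j (first strict
// maximum, i.e. smallest end coordinates); traceback prefers diagonal,
// then horizontal gap, then vertical gap.
// [[Rcpp::export]]
List cpp_sw_align(std::string a, std::string b, IntegerMatrix mat,
                  std::string alphabet, int gap_open, int gap_ext) {
    std::vector<int> lut = make_lookup(alphabet);
    std::vector<int> ea = encode(a, lut), eb = encode(b, lut);
    const int m = (int)ea.size(), n = (int)eb.size();
    if (m == 0 || n == 0)
        return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                            _["s_start"] = 0, _["s_end"] = 0,
                            _["n_identical"] = 0, _["aln_len"] = 0,
                            _["n_gap_opens"] = 0);
    const int NEG = INT_MIN / 4;
    const int nr = mat.nrow();
    std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
        F((m + 1) * (n + 1), NEG);
    auto idx = [n](int i, int j) { return (size_t)i * (n + 1) + j; };
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            // E: gap in query a (consumes b[j-1], horizontal)
            E[idx(i, j)] = std::max(H[idx(i, j - 1)] - gap_open - gap_ext,
                                    E[idx(i, j - 1)] - gap_ext);
            // F: gap in subject b (consumes a[i-1], vertical)
            F[idx(i, j)] = std::max(H[idx(i - 1, j)] - gap_open - gap_ext,
                                    F[idx(i - 1, j)] - gap_ext);
            int s = mat[(size_t)eb[j - 1] * nr + ea[i - 1]];
            int h = H[idx(i - 1, j - 1)] + s;
            if (E[idx(i, j)] > h) h = E[idx(i, j)];
            if (F[idx(i, j)] > h) h = F[idx(i, j)];
            if (h < 0) h = 0;
            H[idx(i, j)] = h;
            if (h > best) { best = h; bi = i; bj = j; }
        }
    }
    if (best == 0)
        return List::create(_["score"] = 0, _["q_start"] = 0, _["q_end"] = 0,
                            _["s_start"] = 0, _["s_end"] = 0,
                            _["n_identical"] = 0, _["aln_len"] = 0,
                            _["n_gap_opens"] = 0);
    // traceback
    int i = bi, j = bj, n_id = 0, cols = 0, gap_opens = 0;
    int state = 0; // 0 = H, 1 = E (horizontal), 2 = F (vertical)
    while (true) {
        if (state == 0) {
            if (H[idx(i, j)] == 0) break;
            int s = mat[(size_t)eb[j - 1] * nr + ea[i - 1]];
            if (i > 0 && j > 0 && H[idx(i, j)] == H[idx(i - 1, j - 1)] + s) {
                if (ea[i - 1] == eb[j - 1]) ++n_id;
                ++cols; --i; --j;
            } else if (H[idx(i, j)] == E[idx(i, j)]) {
                state = 1; ++gap_opens;
            } else {
                state = 2; ++gap_opens;
            }
        } else if (state == 1) {
            ++cols;
            if (E[idx(i, j)] == H[idx(i, j - 1)] - gap_open - gap_ext) {
                --j; state = 0;
            } else {
                --j; state = 1;
            }
        } else {
            ++cols;
            if (F[idx(i, j)] == H[idx(i - 1, j)] - gap_open - gap_ext) {
                --i; state = 0;
            } else {
                --i; state = 2;
            }
        }
    }
    return List::create(_["score"] = best, _["q_start"] = i + 1,
                        _["q_end"] = bi, _["s_start"] = j + 1,
                        _["s_end"] = bj, _["n_identical"] = n_id,
                        _["aln_len"] = cols, _["n_gap_opens"] = gap_opens);
}

// One query against many subjects, score only, with an optional exact
// shared-k-mer prescreen (a subject is aligned only if it shares at least
// min_shared exact k-mers with the query). Screened-out subjects report
// score 0 and screened = TRUE.
// [[Rcpp::export]]
List cpp_sw_score_multi(std::string query, CharacterVector subjects,
                        IntegerMatrix mat, std::string alphabet,
                        int gap_open, int gap_ext, int kmer_k, int min_shared) {
    std::vector<int> lut = make_lookup(alphabet);
    std::vector<int> eq = encode(query, lut);
    const int A = (int)alphabet.size();
    std::vector<int> M = flatten(mat);
    std::unordered_set<long long> qk;
    if (kmer_k > 0 && (int)eq.size() >= kmer_k) {
        for (size_t i = 0; i + kmer_k <= eq.size(); ++i) {
            long long code = 0;
            for (int t = 0; t < kmer_k; ++t) code = code * A + eq[i + t];
            qk.insert(code);
        }
    }
    int N = subjects.size();
    IntegerVector scores(N);
    LogicalVector screened(N);
    for (int s = 0; s < N; ++s) {
        std::string sub = as<std::string>(subjects[s]);
        std::vector<int> es = encode(sub, lut);
        if (kmer_k > 0 && (int)eq.size() >= kmer_k && (int)es.size() >= kmer_k) {
            int shared = 0;
            for (size_t i = 0; i + kmer_k <= es.size() && shared < min_shared; ++i) {
                long long code = 0;
                for (int t = 0; t < kmer_k; ++t) code = code * A + es[i + t];
                if (qk.count(code)) ++shared;
            }
            if (shared < min_shared) {
                scores[s] = 0;
                screened[s] = true;
                continue;
            }
        }
        scores[s] = sw_score_flat(eq, es, M, A, gap_open, gap_ext);
        screened[s] = false;
    }
    return List::create(_["score"] = scores, _["screened"] = screened);
}
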