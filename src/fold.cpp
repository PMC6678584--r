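// Minimum-free-energy folding of a single RNA sequence over nested
// (pseudoknot-free) structures, with a nearest-neighbor stacking model:
// stacking energies for the 16 pair steps (Watson-Crick + G.U wobble),
// length-dependent hairpin/bulge/interior loop penalties with an asymmetry
// term, and an affine multibranch-loop penalty.  Energies are integer
// centi-kcal/mol throughout so that the dynamic program agrees exactly with
// an exhaustive enumeration of structures under the same parameters.
//
// Ties in energy are broken toward the structure with more base pairs; the
// traceback re-derives decisions in the same evaluation order as the fill,
// so the returned structure is deterministic.

#include <Rcpp.h>
#include <vector>
#include <cstdlib>
using namespace Rcpp;

static const int INF_E = 100000000;

// base coding: 1=A 2=C 3=G 4=U ; pair types 1=AU 2=UA 3=CG 4=GC 5=GU 6=UG
static inline int pairtype(int a, int b) {
    if (a == 1 && b == 4) return 1;
    if (a == 4 && b == 1) return 2;
    if (a == 2 && b == 3) return 3;
    if (a == 3 && b == 2) return 4;
    if (a == 3 && b == 4) return 5;
    if (a == 4 && b == 3) return 6;
    return 0;
}

struct FoldTables {
    int stack[7][7];
    std::vector<int> hp;        // hp[size], size = unpaired nt in hairpin loop
    std::vector<int> bulge;     // bulge[size], size >= 1
    std::vector<int> interior;  // interior[size], size >= 2 (both sides summed)
    int asym_per, asym_max;     // interior-loop asymmetry: min(asym_max, asym_per*|n1-n2|)
    int ml_a, ml_b;             // multiloop closing penalty, per-branch penalty
    int min_hp;                 // minimum hairpin loop size (unpaired nt)
    int max_int;                // maximum total bulge/interior loop size
};

static inline bool better(int e1, int n1, int e2, int n2) {
    return (e1 < e2) || (e1 == e2 && n1 > n2);
}

// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seqcode, List par) {
    const int n = seqcode.size();
    FoldTables T;
    IntegerMatrix st = par["stack"];
    for (int a = 0; a < 7; ++a)
        for (int b = 0; b < 7; ++b)
            T.stack[a][b] = (a >= 1 && b >= 1) ? st(a - 1, b - 1) : INF_E;
    IntegerVector hpv = par["hairpin"], bgv = par["bulge"], inv = par["interior"];
    T.hp.assign(hpv.begin(), hpv.end());
    T.bulge.assign(bgv.begin(), bgv.end());
    T.interior.assign(inv.begin(), inv.end());
    T.asym_per = as<int>(par["asym_per"]);
    T.asym_max = as<int>(par["asym_max"]);
    T.ml_a = as<int>(par["ml_a"]);
    T.ml_b = as<int>(par["ml_b"]);
    T.min_hp = as<int>(par["min_hp"]);
    T.max_int = as<int>(par["max_interior"]);

    std::vector<int> s(n);
    for (int i = 0; i < n; ++i) s[i] = seqcode[i];

    // hairpin penalty lookup padded to any size occurring here
    std::vector<int> hp(n > 0 ? n : 1, INF_E);
    for (int sz = 0; sz < (int)hp.size(); ++sz)
        hp[sz] = (sz < (int)T.hp.size()) ? T.hp[sz] : T.hp.back();

    std::vector<std::vector<int> > V(n, std::vector<int>(n, INF_E)),
        VN(n, std::vector<int>(n, 0)),
        WM(n, std::vector<int>(n, INF_E)), WMN(n, std::vector<int>(n, 0)),
        WM2(n, std::vector<int>(n, INF_E)), WM2N(n, std::vector<int>(n, 0));

    for (int d = 4; d < n; ++d) {
        for (int i = 0; i + d < n; ++i) {
            const int j = i + d;
            // ---- V(i,j): best structure closed by pair (i,j)
            int bestE = INF_E, bestN = 0;
            const int pt = pairtype(s[i], s[j]);
            if (pt) {
                const int ls = j - i - 1;
                if (ls >= T.min_hp && hp[ls] < INF_E) { bestE = hp[ls]; bestN = 1; }
                const int kmax = std::min(i + 1 + T.max_int, j - 5);
                for (int k = i + 1; k <= kmax; ++k) {
                    const int n1 = k - i - 1;
                    for (int l = j - 1; l >= k + 4; --l) {
                        const int n2 = j - l - 1;
                        if (n1 + n2 > T.max_int) break;
                        if (!pairtype(s[k], s[l]) || V[k][l] >= INF_E) continue;
                        int le;
                        if (n1 == 0 && n2 == 0)
                            le = T.stack[pt][pairtype(s[k], s[l])];
                        else if (n1 == 0 || n2 == 0)
                            le = T.bulge[n1 + n2];
                        else
                            le = T.interior[n1 + n2] +
                                 std::min(T.asym_max, T.asym_per * std::abs(n1 - n2));
                        const int e = le + V[k][l], np = VN[k][l] + 1;
                        if (better(e, np, bestE, bestN)) { bestE = e; bestN = np; }
                    }
                }
                if (j - 1 >= i + 1 && WM2[i + 1][j - 1] < INF_E) {
                    const int e = T.ml_a + T.ml_b + WM2[i + 1][j - 1];
                    const int np = WM2N[i + 1][j - 1] + 1;
                    if (better(e, np, bestE, bestN)) { bestE = e; bestN = np; }
                }
            }
            V[i][j] = bestE; VN[i][j] = bestN;

            // ---- WM(i,j): >= 1 branch inside a multiloop (unpaired free)
            bestE = INF_E; bestN = 0;
            if (i + 1 <= j && WM[i + 1][j] < INF_E &&
                better(WM[i + 1][j], WMN[i + 1][j], bestE, bestN)) {
                bestE = WM[i + 1][j]; bestN = WMN[i + 1][j];
            }
            if (j - 1 >= i && WM[i][j - 1] < INF_E &&
                better(WM[i][j - 1], WMN[i][j - 1], bestE, bestN)) {
                bestE = WM[i][j - 1]; bestN = WMN[i][j - 1];
            }
            if (V[i][j] < INF_E &&
                better(V[i][j] + T.ml_b, VN[i][j], bestE, bestN)) {
                bestE = V[i][j] + T.ml_b; bestN = VN[i][j];
            }
            for (int k = i + 1; k <= j - 4; ++k) {
                if (WM[i][k - 1] >= INF_E || V[k][j] >= INF_E) continue;
                const int e = WM[i][k - 1] + V[k][j] + T.ml_b;
                const int np = WMN[i][k - 1] + VN[k][j];
                if (better(e, np, bestE, bestN)) { bestE = e; bestN = np; }
            }
            WM[i][j] = bestE; WMN[i][j] = bestN;

            // ---- WM2(i,j): >= 2 branches
            bestE = INF_E; bestN = 0;
            if (j - 1 >= i && WM2[i][j - 1] < INF_E &&
                better(WM2[i][j - 1], WM2N[i][j - 1], bestE, bestN)) {
                bestE = WM2[i][j - 1]; bestN = WM2N[i][j - 1];
            }
            for (int k = i + 1; k <= j - 4; ++k) {
                if (WM[i][k - 1] >= INF_E || V[k][j] >= INF_E) continue;
                const int e = WM[i][k - 1] + V[k][j] + T.ml_b;
                const int np = WMN[i][k - 1] + VN[k][j];
                if (better(e, np, bestE, bestN)) { bestE = e; bestN = np; }
            }
            WM2[i][j] = bestE; WM2N[i][j] = bestN;
        }
    }

    // ---- external loop (unpaired bases free, branches unpenalized)
    std::vector<int> W(n, 0), WN(n, 0);
    for (int j = 0; j < n; ++j) {
        int bestE = (j > 0) ? W[j - 1] : 0;
        int bestN = (j > 0) ? WN[j - 1] : 0;
        for (int i = 0; i <= j - 4; ++i) {
            if (V[i][j] >= INF_E) continue;
            const int pre = (i > 0) ? W[i - 1] : 0;
            const int preN = (i > 0) ? WN[i - 1] : 0;
            const int e = pre + V[i][j], np = preN + VN[i][j];
            if (better(e, np, bestE, bestN)) { bestE = e; bestN = np; }
        }
        W[j] = bestE; WN[j] = bestN;
    }

    // ---- traceback (first candidate matching (E, N) in fill order)
    std::vector<std::pair<int,int> > pairs;
    enum { ST_V, ST_WM, ST_WM2 };
    std::vector<std::vector<int> > work;  // (i, j, state)

    // external
    {
        int j = n - 1;
        while (j >= 0) {
            const int prevE = (j > 0) ? W[j - 1] : 0;
            const int prevN = (j > 0) ? WN[j - 1] : 0;
            if (W[j] == prevE && WN[j] == prevN) { --j; continue; }
            bool found = false;
            for (int i = 0; i <= j - 4 && !found; ++i) {
                if (V[i][j] >= INF_E) continue;
                const int pre = (i > 0) ? W[i - 1] : 0;
                const int preN = (i > 0) ? WN[i - 1] : 0;
                if (pre + V[i][j] == W[j] && preN + VN[i][j] == WN[j]) {
                    std::vector<int> t(3); t[0] = i; t[1] = j; t[2] = ST_V;
                    work.push_back(t);
                    j = i - 1; found = true;
                }
            }
            if (!found) break;  // defensive; cannot happen
        }
    }

    while (!work.empty()) {
        const int i = work.back()[0], j = work.back()[1], stt = work.back()[2];
        work.pop_back();
        if (stt == ST_V) {
            pairs.push_back(std::make_pair(i, j));
            const int pt = pairtype(s[i], s[j]);
            const int ls = j - i - 1;
            if (ls >= T.min_hp && hp[ls] == V[i][j] && VN[i][j] == 1) continue;
            bool found = false;
            const int kmax = std::min(i + 1 + T.max_int, j - 5);
            for (int k = i + 1; k <= kmax && !found; ++k) {
                const int n1 = k - i - 1;
                for (int l = j - 1; l >= k + 4; --l) {
                    const int n2 = j - l - 1;
                    if (n1 + n2 > T.max_int) break;
                    if (!pairtype(s[k], s[l]) || V[k][l] >= INF_E) continue;
                    int le;
                    if (n1 == 0 && n2 == 0)
                        le = T.stack[pt][pairtype(s[k], s[l])];
                    else if (n1 == 0 || n2 == 0)
                        le = T.bulge[n1 + n2];
                    else
                        le = T.interior[n1 + n2] +
                             std::min(T.asym_max, T.asym_per * std::abs(n1 - n2));
                    if (le + V[k][l] == V[i][j] && VN[k][l] + 1 == VN[i][j]) {
                        std::vector<int> t(3); t[0] = k; t[1] = l; t[2] = ST_V;
                        work.push_back(t);
                        found = true; break;
                    }
                }
            }
            if (found) continue;
            if (j - 1 >= i + 1 && WM2[i + 1][j - 1] < INF_E &&
                T.ml_a + T.ml_b + WM2[i + 1][j - 1] == V[i][j] &&
                WM2N[i + 1][j - 1] + 1 == VN[i][j]) {
                std::vector<int> t(3); t[0] = i + 1; t[1] = j - 1; t[2] = ST_WM2;
                work.push_back(t);
            }
        } else if (stt == ST_WM) {
            if (i + 1 <= j && WM[i + 1][j] == WM[i][j] && WMN[i + 1][j] == WMN[i][j]) {
                std::vector<int> t(3); t[0] = i + 1; t[1] = j; t[2] = ST_WM;
                work.push_back(t); continue;
            }
            if (j - 1 >= i && WM[i][j - 1] == WM[i][j] && WMN[i][j - 1] == WMN[i][j]) {
                std::vector<int> t(3); t[0] = i; t[1] = j - 1; t[2] = ST_WM;
                work.push_back(t); continue;
            }
            if (V[i][j] < INF_E && V[i][j] + T.ml_b == WM[i][j] && VN[i][j] == WMN[i][j]) {
                std::vector<int> t(3); t[0] = i; t[1] = j; t[2] = ST_V;
                work.push_back(t); continue;
            }
            for (int k = i + 1; k <= j - 4; ++k) {
                if (WM[i][k - 1] >= INF_E || V[k][j] >= INF_E) continue;
                if (WM[i][k - 1] + V[k][j] + T.ml_b == WM[i][j] &&
                    WMN[i][k - 1] + VN[k][j] == WMN[i][j]) {
                    std::vector<int> t1(3); t1[0] = i; t1[1] = k - 1; t1[2] = ST_WM;
                    std::vector<int> t2(3); t2[0] = k; t2[1] = j; t2[2] = ST_V;
                    work.push_back(t1); work.push_back(t2);
                    break;
                }
            }
        } else {  // ST_WM2
            if (j - 1 >= i && WM2[i][j - 1] == WM2[i][j] && WM2N[i][j - 1] == WM2N[i][j]) {
                std::vector<int> t(3); t[0] = i; t[1] = j - 1; t[2] = ST_WM2;
                work.push_back(t); continue;
            }
            for (int k = i + 1; k <= j - 4; ++k) {
                if (WM[i][k - 1] >= INF_E || V[k][j] >= INF_E) continue;
                if (WM[i][k - 1] + V[k][j] + T.ml_b == WM2[i][j] &&
                    WMN[i][k - 1] + VN[k][j] == WM2N[i][j]) {
                    std::vector<int> t1(3); t1[0] = i; t1[1] = k - 1; t1[2] = ST_WM;
                    std::vector<int> t2(3); t2[0] = k; t2[1] = j; t2[2] = ST_V;
                    work.push_back(t1); work.push_back(t2);
                    break;
                }
            }
        }
    }

    IntegerMatrix pm(pairs.size(), 2);
    for (int r = 0; r < (int)pairs.size(); ++r) {
        pm(r, 0) = pairs[r].first + 1;
        pm(r, 1) = pairs[r].second + 1;
    }
    const double energy = (n > 0 ? W[n - 1] : 0) / 100.0;
    return List::create(_["energy"] = energy, _["pairs"] = pm,
                        _["n_pairs"] = (n > 0 ? WN[n - 1] : 0));
}
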