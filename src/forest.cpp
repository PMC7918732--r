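#include <Rcpp.h>
#include <algorithm>
#include <cstdint>
#include <random>
#include <string>
#include <vector>

// Regression-forest variance-importance for a single target gene.
//
// Importance of predictor j = sum over all trees and all splits on j of the
// node sum-of-squares reduction, divided by (n * ntrees); on a unit-variance
// target the importances of a fully grown tree sum to ~1 per tree. Split
// search is exhaustive over thresholds (midpoints between distinct sorted
// values), with ties broken toward the first candidate feature / smallest
// threshold, so results are a pure function of (X, y, seed, target_id).
//
// The per-target RNG stream is derived from the target id (FNV-1a) mixed with
// the user seed: results do not depend on the order targets are processed in,
// nor on any parallel scheduling.

static inline uint64_t fnv1a(const std::string& s) {
    uint64_t h = 14695981039346656037ULL;
    for (unsigned char c : s) { h ^= c; h *= 1099511628211ULL; }
    return h;
}

static inline uint32_t bounded(std::mt19937_64& rng, uint32_t m) {
    // multiply-shift bounded draw; deterministic across platforms
    return (uint32_t)(((rng() >> 32) * (uint64_t)m) >> 32);
}

// [[Rcpp::export(name = ".forestImportance")]]
Rcpp::NumericVector forestImportance(const Rcpp::NumericMatrix& X,
                                     const Rcpp::NumericVector& y,
                                     int ntrees, int k, int maxdepth,
                                     bool bootstrap, int minleaf, int seed,
                                     const std::string& target_id) {
    const int n = X.nrow(), p = X.ncol();
    if (n < 2) Rcpp::stop("need at least 2 samples");
    if (p < 1) Rcpp::stop("need at least 1 predictor");
    if (k < 1) k = 1;
    if (k > p) k = p;
    if (minleaf < 1) minleaf = 1;

    uint64_t h = fnv1a(target_id);
    h ^= (uint64_t)(uint32_t)seed + 0x9E3779B97F4A7C15ULL + (h << 6) + (h >> 2);
    std::mt19937_64 rng(h);

    std::vector<double> imp(p, 0.0);
    std::vector<double> yb(n);
    std::vector<int> ord((size_t)n * p);     // per-feature slot order, sorted by value
    std::vector<double> xs((size_t)n * p);   // x values in ord order
    std::vector<double> ys((size_t)n * p);   // y values in ord order
    std::vector<int> tmp(n);
    std::vector<double> tmpx(n), tmpy(n);
    std::vector<char> goLeft(n);
    std::vector<int> feat(p);
    std::vector<int> orig(n), counts(n), start(n);
    std::vector<double> Xr((size_t)n * p);   // row-major copy for fast gathers
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < p; ++j) Xr[(size_t)i * p + j] = X(i, j);

    // sort every predictor column over the original samples once; per-tree
    // sorted orders are then derived from the bootstrap multiset in O(n)
    std::vector<int> gsort((size_t)n * p);
    for (int j = 0; j < p; ++j) {
        int* gj = &gsort[(size_t)j * n];
        const double* xj = &X[(size_t)j * n];
        for (int i = 0; i < n; ++i) gj[i] = i;
        std::stable_sort(gj, gj + n,
                         [xj](int a, int b) { return xj[a] < xj[b]; });
    }

    struct Node { int lo, hi, depth; };
    std::vector<Node> stack;

    for (int t = 0; t < ntrees; ++t) {
        // bootstrap multiset as multiplicity counts; slots are laid out
        // grouped by original sample so duplicate draws sit adjacently
        std::fill(counts.begin(), counts.end(), 0);
        if (bootstrap) {
            for (int i = 0; i < n; ++i) ++counts[bounded(rng, (uint32_t)n)];
        } else {
            std::fill(counts.begin(), counts.end(), 1);
        }
        int c0 = 0;
        for (int v = 0; v < n; ++v) {
            start[v] = c0;
            for (int c = 0; c < counts[v]; ++c) orig[c0++] = v;
        }
        for (int j = 0; j < p; ++j) {
            int* oj = &ord[(size_t)j * n];
            double* xj = &xs[(size_t)j * n];
            double* yj = &ys[(size_t)j * n];
            const int* gj = &gsort[(size_t)j * n];
            const double* xcol = &X[(size_t)j * n];
            int k2 = 0;
            for (int i = 0; i < n; ++i) {
                const int v = gj[i];
                const int m = counts[v];
                if (!m) continue;
                const double xv = xcol[v], yv = y[v];
                const int st = start[v];
                for (int c = 0; c < m; ++c) {
                    oj[k2] = st + c; xj[k2] = xv; yj[k2] = yv; ++k2;
                }
            }
        }
        stack.clear();
        stack.push_back({0, n, 0});
        while (!stack.empty()) {
            Node nd = stack.back(); stack.pop_back();
            const int lo = nd.lo, hi = nd.hi, nt = hi - lo;
            if (nt < 2 * minleaf || nt < 2) continue;
            double S = 0.0;
            for (int i = lo; i < hi; ++i) S += ys[i];

            int ncand = p;
            if (k < p) {
                for (int j = 0; j < p; ++j) feat[j] = j;
                for (int i = 0; i < k; ++i) {
                    int r = i + (int)bounded(rng, (uint32_t)(p - i));
                    std::swap(feat[i], feat[r]);
                }
                ncand = k;
            }
            const double base = S * S / nt;
            double bestImp = 0.0, bestCut = 0.0;
            int bestJ = -1;
            for (int c = 0; c < ncand; ++c) {
                const int j = (k < p) ? feat[c] : c;
                const double* xj = &xs[(size_t)j * n];
                const double* yj = &ys[(size_t)j * n];
                double cs = 0.0;
                for (int i = lo; i < hi - 1; ++i) {
                    cs += yj[i];
                    const int nl = i - lo + 1, nr = nt - nl;
                    if (nl < minleaf || nr < minleaf) continue;
                    if (xj[i + 1] <= xj[i]) continue;  // tie in x
                    const double d = cs * cs / nl +
                        (S - cs) * (S - cs) / nr - base;
                    if (d > bestImp) {
                        bestImp = d; bestJ = j; bestCut = xj[i];
                    }
                }
            }
            if (bestJ < 0 || bestImp <= 0.0) continue;
            imp[bestJ] += bestImp / n;
            int nl = 0;
            {
                const int* oj = &ord[(size_t)bestJ * n];
                const double* xrow = &Xr[0];
                for (int i = lo; i < hi; ++i) {
                    int s = oj[i];
                    // left = values <= cut (cut is a realised value, so consistent)
                    goLeft[s] = (char)(xrow[(size_t)orig[s] * p + bestJ] <= bestCut);
                    nl += goLeft[s];
                }
            }
            for (int j = 0; j < p; ++j) {  // stable partition, keeps sort order
                int* oj = &ord[(size_t)j * n];
                double* xj = &xs[(size_t)j * n];
                double* yj = &ys[(size_t)j * n];
                int a = lo, b = 0;
                for (int i = lo; i < hi; ++i) {
                    const int s = oj[i];
                    if (goLeft[s]) {
                        oj[a] = s; xj[a] = xj[i]; yj[a] = yj[i]; ++a;
                    } else {
                        tmp[b] = s; tmpx[b] = xj[i]; tmpy[b] = yj[i]; ++b;
                    }
                }
                std::copy(tmp.begin(), tmp.begin() + b, oj + a);
                std::copy(tmpx.begin(), tmpx.begin() + b, xj + a);
                std::copy(tmpy.begin(), tmpy.begin() + b, yj + a);
            }
            if (maxdepth > 0 && nd.depth + 1 >= maxdepth) continue;
            stack.push_back({lo, lo + nl, nd.depth + 1});
            stack.push_back({lo + nl, hi, nd.depth + 1});
        }
    }
    Rcpp::NumericVector out(p);
    for (int j = 0; j < p; ++j) out[j] = imp[j] / ntrees;
    return out;
}
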