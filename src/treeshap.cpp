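// Exact path-dependent TreeSHAP over flattened regression forests, plus
// node-cover computation and leaf routing. Trees are stored as parallel
// arrays across the whole forest: childLeft/childRight hold absolute node
// indices (-1 for leaves), feature holds 0-based predictor indices (-1 for
// leaves), value holds leaf predictions. Numeric splits send
// x[feature] <= threshold to the left child (the backing forest library's
// convention, asserted in the test suite by comparing routed predictions
// with the library's own).

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export(name = ".cppTreeCovers")]]
NumericVector cppTreeCovers(IntegerVector treeStart, IntegerVector childLeft,
                            IntegerVector childRight, IntegerVector feature,
                            NumericVector threshold, NumericMatrix X) {
    const int nNodes = childLeft.size();
    const int nTree = treeStart.size();
    const int n = X.nrow();
    NumericVector covers(nNodes);
    for (int t = 0; t < nTree; ++t) {
        const int root = treeStart[t];
        for (int i = 0; i < n; ++i) {
            int node = root;
            for (;;) {
                covers[node] += 1.0;
                if (feature[node] < 0) break;
                node = (X(i, feature[node]) <= threshold[node])
                           ? childLeft[node] : childRight[node];
            }
        }
    }
    return covers;
}

// [[Rcpp::export(name = ".cppForestPredict")]]
NumericVector cppForestPredict(IntegerVector treeStart,
                               IntegerVector childLeft,
                               IntegerVector childRight,
                               IntegerVector feature,
                               NumericVector threshold, NumericVector value,
                               NumericMatrix X) {
    const int nTree = treeStart.size();
    const int n = X.nrow();
    NumericVector out(n);
    for (int i = 0; i < n; ++i) {
        double acc = 0;
        for (int t = 0; t < nTree; ++t) {
            int node = treeStart[t];
            while (feature[node] >= 0)
                node = (X(i, feature[node]) <= threshold[node])
                           ? childLeft[node] : childRight[node];
            acc += value[node];
        }
        out[i] = acc / nTree;
    }
    return out;
}

// ---------------------------------------------------------------------------
// TreeSHAP (path-dependent): Shapley values of the game v(S) = E[f(x) | x_S]
// where the conditional expectation descends the tree, following x on
// features in S and cover-weighted averaging on features outside S.
// ---------------------------------------------------------------------------

struct PathElem {
    int d;        // feature index (-1 for the dummy root element)
    double z;     // fraction of zero (cover-flow) paths
    double o;     // fraction of one (x-following) paths
    double w;     // permutation weight
};

static inline void extendPath(PathElem *path, int depth, double pz,
                              double po, int pi) {
    path[depth].d = pi;
    path[depth].z = pz;
    path[depth].o = po;
    path[depth].w = (depth == 0) ? 1.0 : 0.0;
    for (int i = depth - 1; i >= 0; --i) {
        path[i + 1].w += po * path[i].w * (i + 1.0) / (depth + 1.0);
        path[i].w = pz * path[i].w * (depth - i) / (depth + 1.0);
    }
}

static inline void unwindPath(PathElem *path, int depth, int idx) {
    const double po = path[idx].o;
    const double pz = path[idx].z;
    double nxt = path[depth].w;
    for (int i = depth - 1; i >= 0; --i) {
        if (po != 0) {
            const double tmp = path[i].w;
            path[i].w = nxt * (depth + 1.0) / ((i + 1.0) * po);
            nxt = tmp - path[i].w * pz * (depth - i) / (depth + 1.0);
        } else {
            path[i].w = path[i].w * (depth + 1.0) / (pz * (depth - i));
        }
    }
    for (int i = idx; i < depth; ++i) {
        path[i].d = path[i + 1].d;
        path[i].z = path[i + 1].z;
        path[i].o = path[i + 1].o;
    }
}

static inline double unwoundPathSum(const PathElem *path, int depth,
                                    int idx) {
    const double po = path[idx].o;
    const double pz = path[idx].z;
    double total = 0, nxt = path[depth].w;
    if (po != 0) {
        for (int i = depth - 1; i >= 0; --i) {
            const double tmp = nxt / ((i + 1.0) * po);
            total += tmp;
            nxt = path[i].w - tmp * pz * (depth - i);
        }
    } else {
        for (int i = depth - 1; i >= 0; --i)
            total += path[i].w / (pz * (depth - i));
    }
    return total * (depth + 1.0);
}

struct TreeView {
    const int *childLeft, *childRight, *feature;
    const double *threshold, *value, *cover;
};

static void shapRecurse(const TreeView &tr, const double *x, double *phi,
                        int node, PathElem *parentPath, int depth,
                        double pz, double po, int pi) {
    PathElem *path = parentPath + depth + 1;
    std::copy(parentPath, parentPath + depth + 1, path);
    extendPath(path, depth, pz, po, pi);

    const int f = tr.feature[node];
    if (f < 0) {
        for (int i = 1; i <= depth; ++i) {
            const double w = unwoundPathSum(path, depth, i);
            phi[path[i].d] += w * (path[i].o - path[i].z) * tr.value[node];
        }
        return;
    }
    const int left = tr.childLeft[node], right = tr.childRight[node];
    const bool goLeft = x[f] <= tr.threshold[node];
    const int hot = goLeft ? left : right;
    const int cold = goLeft ? right : left;
    const double w = tr.cover[node];
    const double hotZ = tr.cover[hot] / w;
    const double coldZ = tr.cover[cold] / w;

    double iz = 1.0, io = 1.0;
    int k = 0;
    for (; k <= depth; ++k)
        if (path[k].d == f) break;
    if (k != depth + 1) {
        iz = path[k].z;
        io = path[k].o;
        unwindPath(path, depth, k);
        depth -= 1;
    }
    shapRecurse(tr, x, phi, hot, path, depth + 1, hotZ * iz, io, f);
    shapRecurse(tr, x, phi, cold, path, depth + 1, coldZ * iz, 0.0, f);
}

static int treeMaxDepth(const TreeView &tr, int node) {
    if (tr.feature[node] < 0) return 0;
    const int dl = treeMaxDepth(tr, tr.childLeft[node]);
    const int dr = treeMaxDepth(tr, tr.childRight[node]);
    return 1 + (dl > dr ? dl : dr);
}

// Returns an n x M matrix of SHAP values (forest-averaged) with the
// cover-weighted expected prediction as attribute "baseValue".
// [[Rcpp::export(name = ".cppTreeShap")]]
NumericMatrix cppTreeShap(IntegerVector treeStart, IntegerVector childLeft,
                          IntegerVector childRight, IntegerVector feature,
                          NumericVector threshold, NumericVector value,
                          NumericVector covers, NumericMatrix X) {
    const int nTree = treeStart.size();
    const int n = X.nrow();
    const int M = X.ncol();
    NumericMatrix phi(n, M);
    double base = 0;

    std::vector<double> xrow(M);
    for (int t = 0; t < nTree; ++t) {
        TreeView tr = {childLeft.begin(), childRight.begin(),
                       feature.begin(), threshold.begin(), value.begin(),
                       covers.begin()};
        const int root = treeStart[t];
        // base value: cover-weighted mean over leaves == E[f]
        // accumulate by traversing once
        std::vector<int> stack;
        stack.push_back(root);
        double tbase = 0;
        while (!stack.empty()) {
            const int node = stack.back();
            stack.pop_back();
            if (tr.feature[node] < 0)
                tbase += tr.cover[node] / tr.cover[root] * tr.value[node];
            else {
                stack.push_back(tr.childLeft[node]);
                stack.push_back(tr.childRight[node]);
            }
        }
        base += tbase;

        const int md = treeMaxDepth(tr, root);
        std::vector<PathElem> buf(((md + 2) * (md + 3)) / 2);
        for (int i = 0; i < n; ++i) {
            for (int j = 0; j < M; ++j) xrow[j] = X(i, j);
            std::vector<double> phir(M, 0.0);
            shapRecurse(tr, xrow.data(), phir.data(), root, buf.data(), 0,
                        1.0, 1.0, -1);
            for (int j = 0; j < M; ++j) phi(i, j) += phir[j];
        }
        Rcpp::checkUserInterrupt();
    }
    for (int i = 0; i < n; ++i)
        for (int j = 0; j < M; ++j) phi(i, j) /= nTree;
    phi.attr("baseValue") = base / nTree;
    return phi;
}
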