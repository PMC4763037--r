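// Simulated-annealing search for the maximum-likelihood dendrogram, and a
// fast full-recompute log-likelihood used by the exhaustive-search oracle.
//
// Node ids are 1-based: leaves 1..N, internal nodes N+1..2N-1. Child
// vectors passed from R have length N-1 and are indexed by (id - N).
// All randomness comes from R's RNG (unif_rand), so set.seed() on the R
// side makes runs reproducible.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

// likelihood contribution of one internal node: E edges among M = Ng*L*R
// slots at the closed-form MLE theta = E/M, with 0 log 0 := 0
inline double nodeContrib(double E, double M) {
    if (M <= 0.0) return 0.0;
    double th = E / M;
    double out = 0.0;
    if (E > 0.0) out += E * std::log(th);
    if (M - E > 0.0) out += (M - E) * std::log1p(-th);
    return out;
}

struct TreeState {
    int N;                    // number of leaves
    int Ng;                   // number of networks
    std::vector<int> c1, c2;  // children, indexed by node id (0 for leaves)
    std::vector<int> par;     // parent, 0 at root
    int root;
    std::vector<double> E;    // aggregated edge count per internal node
    std::vector<int> nl;      // leaf count per node
    std::vector<double> f;    // likelihood contribution per internal node
    double obj;               // sum of f over internal nodes
};

void collectLeaves(const TreeState& S, int node, std::vector<int>& out) {
    out.clear();
    std::vector<int> stack{node};
    while (!stack.empty()) {
        int x = stack.back();
        stack.pop_back();
        if (x <= S.N) {
            out.push_back(x);
        } else {
            stack.push_back(S.c1[x]);
            stack.push_back(S.c2[x]);
        }
    }
}

double crossWeight(const std::vector<int>& a, const std::vector<int>& b,
                   const NumericMatrix& W) {
    double s = 0.0;
    for (int u : a)
        for (int v : b) s += W(u - 1, v - 1);
    return s;
}

// recompute nl, E, f and obj from the structure alone
void fullStats(TreeState& S, const NumericMatrix& W) {
    int M = 2 * S.N - 1;
    std::vector<std::vector<int>> leaves(M + 1);
    for (int i = 1; i <= S.N; ++i) leaves[i] = {i};
    // post-order: DFS order then reverse
    std::vector<int> order;
    order.reserve(S.N - 1);
    std::vector<int> stack{S.root};
    while (!stack.empty()) {
        int x = stack.back();
        stack.pop_back();
        order.push_back(x);
        if (S.c1[x] > S.N) stack.push_back(S.c1[x]);
        if (S.c2[x] > S.N) stack.push_back(S.c2[x]);
    }
    S.obj = 0.0;
    for (auto it = order.rbegin(); it != order.rend(); ++it) {
        int x = *it;
        const std::vector<int>& L = leaves[S.c1[x]];
        const std::vector<int>& R = leaves[S.c2[x]];
        S.E[x] = crossWeight(L, R, W);
        S.nl[x] = (int)(L.size() + R.size());
        S.f[x] = nodeContrib(S.E[x], (double)S.Ng * L.size() * R.size());
        S.obj += S.f[x];
        leaves[x].reserve(L.size() + R.size());
        leaves[x].insert(leaves[x].end(), L.begin(), L.end());
        leaves[x].insert(leaves[x].end(), R.begin(), R.end());
    }
}

TreeState makeState(const IntegerVector& leftChild,
                    const IntegerVector& rightChild, int root, int Ng,
                    const NumericMatrix& W) {
    TreeState S;
    S.N = leftChild.size() + 1;
    S.Ng = Ng;
    int M = 2 * S.N - 1;
    S.c1.assign(M + 1, 0);
    S.c2.assign(M + 1, 0);
    S.par.assign(M + 1, 0);
    S.root = root;
    S.E.assign(M + 1, 0.0);
    S.nl.assign(M + 1, 1);
    S.f.assign(M + 1, 0.0);
    for (int i = 0; i < S.N - 1; ++i) {
        int node = S.N + 1 + i;
        S.c1[node] = leftChild[i];
        S.c2[node] = rightChild[i];
        S.par[leftChild[i]] = node;
        S.par[rightChild[i]] = node;
    }
    S.par[root] = 0;
    fullStats(S, W);
    return S;
}

}  // namespace

// [[Rcpp::export(name = ".hrgLogLikCpp")]]
double hrgLogLikCpp(IntegerVector leftChild, IntegerVector rightChild,
                    int root, NumericMatrix W, int Ng) {
    TreeState S = makeState(leftChild, rightChild, root, Ng, W);
    return S.obj;
}

// [[Rcpp::export(name = ".annealCpp")]]
List annealCpp(NumericMatrix W, int Ng, IntegerVector leftChild,
               IntegerVector rightChild, int root, double tStart, double tEnd,
               int nMax, double gamma, bool restartFromBest) {
    TreeState S = makeState(leftChild, rightChild, root, Ng, W);
    int N = S.N;
    int M = 2 * N - 1;

    // best tree copy
    std::vector<int> bc1 = S.c1, bc2 = S.c2;
    int broot = S.root;
    double objBest = S.obj;
    double objC = S.obj;

    int maxEpochs =
        (int)std::ceil(std::log(tEnd / tStart) / std::log(gamma)) + 2;
    NumericMatrix trace(maxEpochs, 6);
    int epoch = 0;

    std::vector<int> leavesA, leavesP;

    double T = tStart;
    for (;;) {
        if (restartFromBest) {
            S.c1 = bc1;
            S.c2 = bc2;
            S.root = broot;
            for (int x = 1; x <= M; ++x) S.par[x] = 0;
            for (int x = N + 1; x <= M; ++x) {
                S.par[S.c1[x]] = x;
                S.par[S.c2[x]] = x;
            }
            fullStats(S, W);
            objC = S.obj;
        }
        int counter = 0, accepted = 0, noop = 0;
        while (counter < nMax) {
            ++counter;
            // select an internal node uniformly
            int s = N + 1 + (int)(unif_rand() * (N - 1));
            if (s > M) s = M;
            int cA = S.c1[s], cB = S.c2[s];
            bool i1 = cA > N, i2 = cB > N;
            if (!i1 && !i2) {
                ++noop;  // two leaf children: the proposal is a no-op
                continue;
            }
            int t, A;
            if (i1 && i2) {
                if (unif_rand() < 0.5) { t = cA; A = cB; }
                else { t = cB; A = cA; }
            } else if (i1) { t = cA; A = cB; }
            else { t = cB; A = cA; }
            int B = S.c1[t], C = S.c2[t];

            // Exchange swaps A with a grandchild; Rotate regroups
            // (A,(B,C)) into ((A,B),C) or ((A,C),B). Either way the local
            // shape is determined by which grandchild stays paired with A.
            bool exchange = unif_rand() < 0.5;
            bool pickFirst = unif_rand() < 0.5;
            int partner, other;
            if (exchange) {
                // swap A with B => t holds {A, C}; swap A with C => {A, B}
                if (pickFirst) { partner = C; other = B; }
                else { partner = B; other = C; }
            } else {
                // rotate to ((A,B),C) or ((A,C),B)
                if (pickFirst) { partner = B; other = C; }
                else { partner = C; other = B; }
            }

            collectLeaves(S, A, leavesA);
            collectLeaves(S, partner, leavesP);
            double newEt = crossWeight(leavesA, leavesP, W);
            double newEs = S.E[s] + S.E[t] - newEt;
            double Mt = (double)Ng * S.nl[A] * S.nl[partner];
            double Ms = (double)Ng * S.nl[other] * (S.nl[A] + S.nl[partner]);
            double newft = nodeContrib(newEt, Mt);
            double newfs = nodeContrib(newEs, Ms);
            double objT = objC + newfs + newft - S.f[s] - S.f[t];

            // apply the move (cheap to undo)
            int oc1s = S.c1[s], oc2s = S.c2[s], oc1t = S.c1[t], oc2t = S.c2[t];
            int onlt = S.nl[t];
            double oEs = S.E[s], oEt = S.E[t], ofs = S.f[s], oft = S.f[t];
            S.c1[t] = A; S.c2[t] = partner;
            S.c1[s] = t; S.c2[s] = other;
            S.par[A] = t; S.par[partner] = t; S.par[other] = s;
            S.nl[t] = S.nl[A] + S.nl[partner];
            S.E[s] = newEs; S.E[t] = newEt;
            S.f[s] = newfs; S.f[t] = newft;

            if (objT > objBest) {  // strict improvement replaces the best
                bc1 = S.c1;
                bc2 = S.c2;
                broot = S.root;
                objBest = objT;
            }
            double p = (objT >= objC) ? 1.0 : std::exp((objT - objC) / T);
            if (unif_rand() < p) {
                objC = objT;
                ++accepted;
            } else {  // undo
                S.c1[s] = oc1s; S.c2[s] = oc2s;
                S.c1[t] = oc1t; S.c2[t] = oc2t;
                S.par[oc1s] = s; S.par[oc2s] = s;
                S.par[oc1t] = t; S.par[oc2t] = t;
                S.nl[t] = onlt;
                S.E[s] = oEs; S.E[t] = oEt;
                S.f[s] = ofs; S.f[t] = oft;
            }
        }
        trace(epoch, 0) = epoch + 1;
        trace(epoch, 1) = T;
        trace(epoch, 2) = objC;
        trace(epoch, 3) = objBest;
        trace(epoch, 4) = accepted;
        trace(epoch, 5) = noop;
        ++epoch;
        T *= gamma;
        if (!(T > tEnd)) break;
        if (epoch >= maxEpochs) break;  // defensive; cannot trigger
    }

    IntegerVector outL(N - 1), outR(N - 1);
    for (int i = 0; i < N - 1; ++i) {
        outL[i] = bc1[N + 1 + i];
        outR[i] = bc2[N + 1 + i];
    }
    return List::create(Named("leftChild") = outL, Named("rightChild") = outR,
                        Named("root") = broot, Named("objBest") = objBest,
                        Named("trace") = trace(Range(0, epoch - 1), _));
}
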