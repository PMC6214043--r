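#include <Rcpp.h>
#include <complex>
#include <algorithm>
#include <numeric>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// CVFNT evaluation
//
// A tree is passed as parallel prefix-order arrays: kind (0 terminal,
// 1 function), arity, input (0-based terminal index), plus a complex
// parameter vector holding, per function node in prefix order, the child
// weights w1..wn followed by the threshold w0, and real vectors a, r (one
// entry per function node, same order). Each neuron computes
// elliot(w0 + sum w_j z_j) with elliot(net) = net / (a + |net|/r), evaluated
// simultaneously over all time columns of the complex input matrix.
// ---------------------------------------------------------------------------

namespace {

struct TreeEval {
    const int *kind, *arity, *input;
    const std::complex<double>* par;
    const double *a, *r;
    const std::complex<double>* z;  // L x T, column-major
    int L, T;
    int cursor = 0, fcursor = 0, pcursor = 0;

    void eval(std::vector<std::complex<double>>& out) {
        const int node = cursor++;
        if (kind[node] == 0) {
            const int idx = input[node];
            for (int t = 0; t < T; ++t)
                out[t] = z[idx + static_cast<size_t>(t) * L];
            return;
        }
        const int n = arity[node];
        const int f = fcursor++;
        const int p = pcursor;
        pcursor += n + 1;
        std::vector<std::complex<double>> acc(T, par[p + n]);  // w0
        std::vector<std::complex<double>> child(T);
        for (int c = 0; c < n; ++c) {
            eval(child);
            const std::complex<double> w = par[p + c];
            for (int t = 0; t < T; ++t) acc[t] += w * child[t];
        }
        const double aa = a[f], rr = r[f];
        for (int t = 0; t < T; ++t)
            out[t] = acc[t] / (aa + std::abs(acc[t]) / rr);
    }
};

std::vector<std::complex<double>> asStd(const ComplexVector& v) {
    std::vector<std::complex<double>> out(v.size());
    for (R_xlen_t i = 0; i < v.size(); ++i)
        out[i] = std::complex<double>(v[i].r, v[i].i);
    return out;
}

std::vector<std::complex<double>> evalRoot(
        const IntegerVector& kind, const IntegerVector& arity,
        const IntegerVector& input, const ComplexVector& par,
        const NumericVector& a, const NumericVector& r,
        const ComplexMatrix& z) {
    std::vector<std::complex<double>> pars = asStd(par);
    std::vector<std::complex<double>> zz(z.nrow() * (size_t)z.ncol());
    for (R_xlen_t i = 0; i < z.nrow() * (R_xlen_t)z.ncol(); ++i)
        zz[i] = std::complex<double>(z[i].r, z[i].i);
    TreeEval ev;
    ev.kind = kind.begin(); ev.arity = arity.begin(); ev.input = input.begin();
    ev.par = pars.data(); ev.a = a.begin(); ev.r = r.begin();
    ev.z = zz.data(); ev.L = z.nrow(); ev.T = z.ncol();
    std::vector<std::complex<double>> out(ev.T);
    ev.eval(out);
    return out;
}

}  // namespace

// [[Rcpp::export]]
ComplexVector cvfntEvalCpp(IntegerVector kind, IntegerVector arity,
                           IntegerVector input, ComplexVector par,
                           NumericVector a, NumericVector r,
                           ComplexMatrix z) {
    std::vector<std::complex<double>> out =
        evalRoot(kind, arity, input, par, a, r, z);
    ComplexVector res(out.size());
    for (size_t t = 0; t < out.size(); ++t) {
        res[t].r = out[t].real();
        res[t].i = out[t].imag();
    }
    return res;
}

// RMSE between the real-valued readout of the tree output (real part, or
// modulus when useReal is false) and the target vector.
// [[Rcpp::export]]
double cvfntRmseCpp(IntegerVector kind, IntegerVector arity,
                    IntegerVector input, ComplexVector par,
                    NumericVector a, NumericVector r,
                    ComplexMatrix z, NumericVector target, bool useReal) {
    std::vector<std::complex<double>> out =
        evalRoot(kind, arity, input, par, a, r, z);
    double ss = 0.0;
    const int T = out.size();
    for (int t = 0; t < T; ++t) {
        const double pred = useReal ? out[t].real() : std::abs(out[t]);
        const double d = pred - target[t];
        ss += d * d;
    }
    return std::sqrt(ss / T);
}

// ---------------------------------------------------------------------------
// MIC grid search
//
// For grids with nx * ny <= B cells (nx, ny >= 2): one axis is partitioned
// into equal-frequency bins (ties share a bin), the other axis's cut points
// are optimised exactly by dynamic programming (minimising the weighted
// conditional entropy, which is additive over bins); the normalised score
// I / log(min(nx, ny)) is maximised over grid sizes and both orientations.
// Natural logarithms throughout; the ratio is unit-free.
// ---------------------------------------------------------------------------

namespace {

const double INF = std::numeric_limits<double>::infinity();

double nlogn(double n) { return n > 0 ? n * std::log(n) : 0.0; }

// Best normalised score with y equal-frequency partitioned, x DP-optimised.
double micOriented(const std::vector<double>& x, const std::vector<double>& y,
                   int B) {
    const int N = x.size();
    std::vector<int> xord(N), yord(N);
    std::iota(xord.begin(), xord.end(), 0);
    std::iota(yord.begin(), yord.end(), 0);
    std::sort(xord.begin(), xord.end(),
              [&](int i, int j) { return x[i] < x[j]; });
    std::sort(yord.begin(), yord.end(),
              [&](int i, int j) { return y[i] < y[j]; });

    // valid cut boundaries in x-order (cannot split tied x values)
    std::vector<bool> canCut(N + 1, false);
    canCut[0] = canCut[N] = true;
    for (int j = 1; j < N; ++j)
        canCut[j] = x[xord[j]] != x[xord[j - 1]];

    double best = 0.0;
    for (int ny = 2; 2 * ny <= B; ++ny) {
        // equal-frequency labels on y, ties share the earlier label
        std::vector<int> lab(N);
        for (int rnk = 0; rnk < N; ++rnk) {
            int b = (int)(((long long)rnk * ny) / N);
            if (rnk > 0 && y[yord[rnk]] == y[yord[rnk - 1]])
                b = lab[yord[rnk - 1]];
            lab[yord[rnk]] = b;
        }
        // relabel contiguously
        std::vector<int> map(ny, -1);
        int K = 0;
        for (int rnk = 0; rnk < N; ++rnk) {
            int& m = map[lab[yord[rnk]]];
            if (m < 0) m = K++;
        }
        for (int i = 0; i < N; ++i) lab[i] = map[lab[i]];
        if (K < 2) continue;

        // class counts over x-sorted prefixes
        std::vector<int> cum((N + 1) * K, 0);
        for (int j = 1; j <= N; ++j) {
            for (int c = 0; c < K; ++c) cum[j * K + c] = cum[(j - 1) * K + c];
            ++cum[j * K + lab[xord[j - 1]]];
        }
        double HQ = 0.0;
        for (int c = 0; c < K; ++c) {
            const double p = (double)cum[N * K + c] / N;
            if (p > 0) HQ -= p * std::log(p);
        }
        // seg(i, j): (j-i) * H(Q | bin spanning x-sorted points i..j-1)
        auto seg = [&](int i, int j) {
            double s = nlogn(j - i);
            for (int c = 0; c < K; ++c)
                s -= nlogn(cum[j * K + c] - cum[i * K + c]);
            return s;
        };
        const int nxMax = B / ny;
        if (nxMax < 2) continue;
        // F[k][j]: minimal cost of covering the first j points with k bins
        std::vector<std::vector<double>> F(nxMax + 1,
                                           std::vector<double>(N + 1, INF));
        for (int j = 1; j <= N; ++j)
            if (canCut[j]) F[1][j] = seg(0, j);
        for (int k = 2; k <= nxMax; ++k)
            for (int j = k; j <= N; ++j) {
                if (!canCut[j]) continue;
                double m = INF;
                for (int i = k - 1; i < j; ++i) {
                    if (F[k - 1][i] == INF) continue;
                    const double cand = F[k - 1][i] + seg(i, j);
                    if (cand < m) m = cand;
                }
                F[k][j] = m;
            }
        for (int nx = 2; nx <= nxMax; ++nx) {
            if (F[nx][N] == INF) continue;
            const double I = HQ - F[nx][N] / N;
            const double score = I / std::log((double)std::min(nx, ny));
            if (score > best) best = score;
        }
    }
    return std::min(best, 1.0);
}

}  // namespace

// [[Rcpp::export]]
double micCpp(NumericVector x, NumericVector y, int B) {
    std::vector<double> xv(x.begin(), x.end()), yv(y.begin(), y.end());
    const double a = micOriented(xv, yv, B);
    const double b = micOriented(yv, xv, B);
    return std::max(a, b);
}
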