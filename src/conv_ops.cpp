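#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Valid (no padding) stride-1 2-D convolution over batched H x W x C x N
// arrays, implemented as one im2col + GEMM per batch.  Arrays are
// column-major with H fastest, matching R's layout.  Weights are
// K x K x Cin x F; the im2col column ordering (ki fastest, then kj, then
// channel) matches the flattening of the weight array's first three
// dimensions.  Patch rows are ordered (oi fastest, oj, then sample), so
// rows P*n .. P*n+P-1 belong to sample n.

static inline void get_dims4(const NumericVector& x, int d[4]) {
    IntegerVector dim = x.attr("dim");
    if (dim.size() != 4) stop("expected a 4-d array");
    for (int i = 0; i < 4; ++i) d[i] = dim[i];
}

static void im2col_batch(const double* x, int H, int W, int C, int N,
                         int K, arma::mat& M) {
    const int oh = H - K + 1, ow = W - K + 1, P = oh * ow;
    const R_xlen_t sampleStride = (R_xlen_t)H * W * C;
    for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < K; ++kj) {
            for (int ki = 0; ki < K; ++ki) {
                const int col = ki + K * (kj + K * c);
                double* mcol = M.colptr(col);
                for (int n = 0; n < N; ++n) {
                    const double* xn = x + n * sampleStride;
                    double* dstn = mcol + (R_xlen_t)P * n;
                    for (int oj = 0; oj < ow; ++oj) {
                        const double* src = xn + ki + H * ((oj + kj) + W * c);
                        double* dst = dstn + oh * oj;
                        for (int oi = 0; oi < oh; ++oi) dst[oi] = src[oi];
                    }
                }
            }
        }
    }
}

// [[Rcpp::export(name = ".conv2d_forward")]]
NumericVector conv2d_forward(NumericVector x, NumericVector w,
                             NumericVector b) {
    int xd[4], wd[4];
    get_dims4(x, xd);
    get_dims4(w, wd);
    const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
    const int K = wd[0], F = wd[3];
    if (wd[1] != K || wd[2] != C) stop("weight dims do not match input");
    const int oh = H - K + 1, ow = W - K + 1, P = oh * ow, KK = K * K * C;

    arma::mat M((R_xlen_t)P * N, KK);
    im2col_batch(x.begin(), H, W, C, N, K, M);
    arma::mat Wm(w.begin(), KK, F, false, true);
    arma::mat Y = M * Wm;                       // (P*N) x F

    NumericVector y((R_xlen_t)P * F * N);
    y.attr("dim") = IntegerVector::create(oh, ow, F, N);
    // permute (p, n, f) -> (p, f, n), adding the bias
    for (int n = 0; n < N; ++n) {
        for (int f = 0; f < F; ++f) {
            const double* src = Y.colptr(f) + (R_xlen_t)P * n;
            double* dst = y.begin() + (R_xlen_t)P * (f + (R_xlen_t)F * n);
            const double bf = b[f];
            for (int p = 0; p < P; ++p) dst[p] = src[p] + bf;
        }
    }
    return y;
}

// [[Rcpp::export(name = ".conv2d_backward")]]
List conv2d_backward(NumericVector x, NumericVector w, NumericVector dy) {
    int xd[4], wd[4];
    get_dims4(x, xd);
    get_dims4(w, wd);
    const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
    const int K = wd[0], F = wd[3];
    const int oh = H - K + 1, ow = W - K + 1, P = oh * ow, KK = K * K * C;
    const R_xlen_t sampleStride = (R_xlen_t)H * W * C;

    arma::mat M((R_xlen_t)P * N, KK);
    im2col_batch(x.begin(), H, W, C, N, K, M);

    // gather dy (p, f, n) into G (p + P*n, f)
    arma::mat G((R_xlen_t)P * N, F);
    for (int n = 0; n < N; ++n)
        for (int f = 0; f < F; ++f)
            std::copy(dy.begin() + (R_xlen_t)P * (f + (R_xlen_t)F * n),
                      dy.begin() + (R_xlen_t)P * (f + (R_xlen_t)F * n) + P,
                      G.colptr(f) + (R_xlen_t)P * n);

    NumericVector dw(w.size()), db(F), dx(x.size());
    dw.attr("dim") = w.attr("dim");
    dx.attr("dim") = x.attr("dim");
    arma::mat dWm(dw.begin(), KK, F, false, true);
    dWm = M.t() * G;
    for (int f = 0; f < F; ++f)
        db[f] = arma::accu(G.col(f));
    arma::mat dM = G * arma::mat(w.begin(), KK, F, false, true).t();

    // col2im scatter-add
    for (int c = 0; c < C; ++c) {
        for (int kj = 0; kj < K; ++kj) {
            for (int ki = 0; ki < K; ++ki) {
                const int col = ki + K * (kj + K * c);
                const double* mcol = dM.colptr(col);
                for (int n = 0; n < N; ++n) {
                    double* dxn = dx.begin() + n * sampleStride;
                    const double* srcn = mcol + (R_xlen_t)P * n;
                    for (int oj = 0; oj < ow; ++oj) {
                        double* dst = dxn + ki + H * ((oj + kj) + W * c);
                        const double* src = srcn + oh * oj;
                        for (int oi = 0; oi < oh; ++oi) dst[oi] += src[oi];
                    }
                }
            }
        }
    }
    return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pooling, stride 2, floor semantics (trailing odd row/col
// dropped).  Returns pooled values and 0-based linear indices into x.
// [[Rcpp::export(name = ".maxpool2_forward")]]
List maxpool2_forward(NumericVector x) {
    int xd[4];
    get_dims4(x, xd);
    const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
    const int oh = H / 2, ow = W / 2;
    NumericVector y((R_xlen_t)oh * ow * C * N);
    NumericVector idx(y.size());
    IntegerVector od = IntegerVector::create(oh, ow, C, N);
    y.attr("dim") = od;
    idx.attr("dim") = od;
    const double* xp = x.begin();
    R_xlen_t o = 0;
    for (int n = 0; n < N; ++n) {
        for (int c = 0; c < C; ++c) {
            const R_xlen_t base = (R_xlen_t)H * W * (c + (R_xlen_t)C * n);
            for (int oj = 0; oj < ow; ++oj) {
                for (int oi = 0; oi < oh; ++oi) {
                    R_xlen_t best = base + (2 * oi) + (R_xlen_t)H * (2 * oj);
                    double bv = xp[best];
                    const R_xlen_t cand[3] = {best + 1, best + H,
                                              best + H + 1};
                    for (int t = 0; t < 3; ++t)
                        if (xp[cand[t]] > bv) { bv = xp[cand[t]];
                                                best = cand[t]; }
                    y[o] = bv;
                    idx[o] = (double)best;
                    ++o;
                }
            }
        }
    }
    return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_backward")]]
NumericVector maxpool2_backward(NumericVector idx, NumericVector dy,
                                IntegerVector xdim) {
    if (xdim.size() != 4) stop("xdim must have length 4");
    R_xlen_t n = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
    NumericVector dx(n);
    dx.attr("dim") = xdim;
    for (R_xlen_t i = 0; i < dy.size(); ++i) dx[(R_xlen_t)idx[i]] += dy[i];
    return dx;
}

// Elementwise activations on large arrays (dims preserved), fused in C++
// to avoid repeated R-level allocations in the training loop.
// [[Rcpp::export(name = ".act_forward")]]
NumericVector act_forward(NumericVector z, int kind) {
    NumericVector a(z.size());
    a.attr("dim") = z.attr("dim");
    const double* zp = z.begin();
    double* ap = a.begin();
    const R_xlen_t n = z.size();
    switch (kind) {
    case 1: for (R_xlen_t i = 0; i < n; ++i)
                ap[i] = zp[i] > 0 ? zp[i] : 0;               break;
    case 2: for (R_xlen_t i = 0; i < n; ++i)
                ap[i] = std::tanh(zp[i]);                    break;
    case 3: for (R_xlen_t i = 0; i < n; ++i)
                ap[i] = 1.0 / (1.0 + std::exp(-zp[i]));      break;
    default: stop("unknown activation kind");
    }
    return a;
}

// gradient wrt pre-activation: da * act'(z), using a = act(z)
// [[Rcpp::export(name = ".act_backward")]]
NumericVector act_backward(NumericVector da, NumericVector z,
                           NumericVector a, int kind) {
    NumericVector dz(da.size());
    dz.attr("dim") = da.attr("dim");
    const double* dap = da.begin();
    const double* zp = z.begin();
    const double* ap = a.begin();
    double* dzp = dz.begin();
    const R_xlen_t n = da.size();
    switch (kind) {
    case 1: for (R_xlen_t i = 0; i < n; ++i)
                dzp[i] = zp[i] > 0 ? dap[i] : 0;             break;
    case 2: for (R_xlen_t i = 0; i < n; ++i)
                dzp[i] = dap[i] * (1.0 - ap[i] * ap[i]);     break;
    case 3: for (R_xlen_t i = 0; i < n; ++i)
                dzp[i] = dap[i] * ap[i] * (1.0 - ap[i]);     break;
    default: stop("unknown activation kind");
    }
    return dz;
}
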