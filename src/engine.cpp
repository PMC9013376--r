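// Minimal CPU engine for densely connected convolutional networks.
//
// The network is described as a flat list of layers over a tensor graph:
// tensor 0 is the input image, layer l produces tensor l+1, and each layer
// consumes the channel-wise concatenation of an arbitrary set of earlier
// tensors.  That representation covers dense blocks, inter-block skip
// connections and the bottleneck without special cases.
//
// Batched evaluation: a tensor holding N samples of an H x W x C feature
// map is stored as one (N*H*W) x C float matrix (sample-major rows, each
// sample's channel column in R/Armadillo column-major image order).  All
// convolutions then become one im2col + one sgemm per layer across the
// whole batch, which keeps BLAS matrix shapes large.  The stride-2
// transpose convolution is the adjoint of a stride-2 convolution and
// reuses the same im2col/col2im geometry.  im2col blocks are cached per
// tensor, so dense-block layers, which share the 3x3 stride-1 geometry,
// extract each tensor's patches only once per pass.
//
// The engine is deterministic: it contains no RNG and no threading of its
// own; all randomness lives on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;

namespace {

struct Layer {
  int type;   // 0 = conv (stride 1, same padding), 1 = transpose conv
  int k;
  int stride;
  int pb;     // leading pad (conv) / leading crop (transpose conv)
  bool relu;
  std::vector<int> inputs;  // tensor ids
  std::vector<int> in_ch;   // channels of each input tensor
  int cin;
  int cout;
  int wi;     // index into params list
  int bi;     // index into params list, -1 when the layer has no bias
};

std::vector<Layer> parse_spec(const List& spec) {
  std::vector<Layer> layers(spec.size());
  for (int l = 0; l < spec.size(); ++l) {
    List ls = spec[l];
    Layer& L = layers[l];
    L.type = as<int>(ls["type"]);
    L.k = as<int>(ls["k"]);
    L.stride = as<int>(ls["stride"]);
    L.pb = as<int>(ls["pb"]);
    L.relu = as<bool>(ls["relu"]);
    IntegerVector in = ls["inputs"];
    IntegerVector ich = ls["in_ch"];
    L.inputs.assign(in.begin(), in.end());
    L.in_ch.assign(ich.begin(), ich.end());
    L.cin = as<int>(ls["cin"]);
    L.cout = as<int>(ls["cout"]);
    L.wi = as<int>(ls["wi"]);
    L.bi = as<int>(ls["bi"]);
  }
  return layers;
}

// Extract sliding-window patches for all N samples.  Output pixel (oi, oj)
// reads input pixel (oi*stride + di - pb, oj*stride + dj - pb);
// out-of-range reads are zero.  Column order: ((c*k + dj)*k + di).
fmat im2col(const fmat& T, int H, int W, int N, int k, int stride, int pb,
            int oh, int ow) {
  const int C = T.n_cols;
  fmat cols(static_cast<size_t>(N) * oh * ow, k * k * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const float* tc = T.colptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        float* dst = cols.colptr((c * k + dj) * k + di);
        for (int s = 0; s < N; ++s) {
          const float* img = tc + static_cast<size_t>(s) * H * W;
          float* out = dst + static_cast<size_t>(s) * oh * ow;
          for (int oj = 0; oj < ow; ++oj) {
            const int jj = oj * stride + dj - pb;
            if (jj < 0 || jj >= W) continue;
            const float* src = img + static_cast<size_t>(jj) * H;
            float* d = out + static_cast<size_t>(oj) * oh;
            for (int oi = 0; oi < oh; ++oi) {
              const int ii = oi * stride + di - pb;
              if (ii >= 0 && ii < H) d[oi] = src[ii];
            }
          }
        }
      }
    }
  }
  return cols;
}

// Adjoint of im2col: scatter-add patch columns back onto the image grid.
void col2im_add(fmat& acc, int H, int W, int N, const fmat& cols, int k,
                int stride, int pb, int oh, int ow, int col_off, int C) {
  for (int c = 0; c < C; ++c) {
    float* tc = acc.colptr(c);
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const float* src0 = cols.colptr(col_off + (c * k + dj) * k + di);
        for (int s = 0; s < N; ++s) {
          float* img = tc + static_cast<size_t>(s) * H * W;
          const float* out = src0 + static_cast<size_t>(s) * oh * ow;
          for (int oj = 0; oj < ow; ++oj) {
            const int jj = oj * stride + dj - pb;
            if (jj < 0 || jj >= W) continue;
            float* dst = img + static_cast<size_t>(jj) * H;
            const float* sp = out + static_cast<size_t>(oj) * oh;
            for (int oi = 0; oi < oh; ++oi) {
              const int ii = oi * stride + di - pb;
              if (ii >= 0 && ii < H) dst[ii] += sp[oi];
            }
          }
        }
      }
    }
  }
}

struct Workspace {
  int N;
  std::vector<fmat> tensors;        // (N*H*W) x C per tensor id
  std::vector<int> th, tw;          // spatial size per tensor id
  std::vector<fmat> col3;           // im2col cache (3x3 stride-1 geometry)
  std::vector<bool> col3_ok;
};

const fmat& col3_of(Workspace& ws, int id, int k, int pb) {
  if (!ws.col3_ok[id]) {
    ws.col3[id] = im2col(ws.tensors[id], ws.th[id], ws.tw[id], ws.N, k, 1,
                         pb, ws.th[id], ws.tw[id]);
    ws.col3_ok[id] = true;
  }
  return ws.col3[id];
}

void forward_pass(const std::vector<Layer>& layers,
                  const std::vector<fmat>& params, Workspace& ws) {
  for (size_t l = 0; l < layers.size(); ++l) {
    const Layer& L = layers[l];
    const fmat& Wt = params[L.wi];
    const int id0 = L.inputs[0];
    const int h = ws.th[id0], w = ws.tw[id0];
    fmat Y;
    if (L.type == 0) {
      Y.zeros(static_cast<size_t>(ws.N) * h * w, L.cout);
      int roff = 0;
      for (size_t b = 0; b < L.inputs.size(); ++b) {
        const int id = L.inputs[b];
        const int nrow = L.k * L.k * L.in_ch[b];
        if (L.k == 1) {
          Y += ws.tensors[id] * Wt.rows(roff, roff + nrow - 1);
        } else {
          Y += col3_of(ws, id, L.k, L.pb) * Wt.rows(roff, roff + nrow - 1);
        }
        roff += nrow;
      }
      ws.th[l + 1] = h;
      ws.tw[l + 1] = w;
    } else {
      const int OH = h * L.stride, OW = w * L.stride;
      fmat cols = ws.tensors[id0] * Wt;  // (N*h*w) x (k^2 * cout)
      Y.zeros(static_cast<size_t>(ws.N) * OH * OW, L.cout);
      col2im_add(Y, OH, OW, ws.N, cols, L.k, L.stride, L.pb, h, w, 0,
                 L.cout);
      ws.th[l + 1] = OH;
      ws.tw[l + 1] = OW;
    }
    if (L.bi >= 0) Y.each_row() += params[L.bi].row(0);
    if (L.relu) Y.clamp(0.0f, arma::Datum<float>::inf);
    ws.tensors[l + 1] = std::move(Y);
    ws.col3_ok[l + 1] = false;
  }
}

void backward_pass(const std::vector<Layer>& layers,
                   const std::vector<fmat>& params, Workspace& ws,
                   fmat&& dout, std::vector<fmat>& gparams) {
  const int nt = (int)layers.size() + 1;
  std::vector<fmat> gt(nt);
  gt[nt - 1] = std::move(dout);
  for (int l = (int)layers.size() - 1; l >= 0; --l) {
    const Layer& L = layers[l];
    if (gt[l + 1].is_empty()) continue;
    fmat g = std::move(gt[l + 1]);
    if (L.relu) {
      const fmat& out = ws.tensors[l + 1];
      float* gp = g.memptr();
      const float* op = out.memptr();
      const size_t n = g.n_elem;
      for (size_t i = 0; i < n; ++i)
        if (op[i] <= 0.0f) gp[i] = 0.0f;
    }
    if (L.bi >= 0) gparams[L.bi].row(0) += arma::sum(g, 0);
    const fmat& Wt = params[L.wi];
    const int id0 = L.inputs[0];
    if (L.type == 0) {
      const int h = ws.th[id0], w = ws.tw[id0];
      int roff = 0;
      for (size_t b = 0; b < L.inputs.size(); ++b) {
        const int id = L.inputs[b];
        const int nc = L.in_ch[b];
        const int nrow = L.k * L.k * nc;
        if (gt[id].is_empty() && id > 0)
          gt[id].zeros(ws.tensors[id].n_rows, ws.tensors[id].n_cols);
        if (L.k == 1) {
          gparams[L.wi].rows(roff, roff + nrow - 1) +=
              ws.tensors[id].t() * g;
          if (id > 0) gt[id] += g * Wt.rows(roff, roff + nrow - 1).t();
        } else {
          gparams[L.wi].rows(roff, roff + nrow - 1) +=
              col3_of(ws, id, L.k, L.pb).t() * g;
          if (id > 0) {
            fmat dcols = g * Wt.rows(roff, roff + nrow - 1).t();
            col2im_add(gt[id], ws.th[id], ws.tw[id], ws.N, dcols, L.k, 1,
                       L.pb, h, w, 0, nc);
          }
        }
        roff += nrow;
      }
    } else {
      const int h = ws.th[id0], w = ws.tw[id0];
      fmat dcols = im2col(g, ws.th[l + 1], ws.tw[l + 1], ws.N, L.k,
                          L.stride, L.pb, h, w);
      gparams[L.wi] += ws.tensors[id0].t() * dcols;
      if (id0 > 0) {
        if (gt[id0].is_empty())
          gt[id0].zeros(ws.tensors[id0].n_rows, ws.tensors[id0].n_cols);
        gt[id0] += dcols * Wt.t();
      }
    }
  }
}

std::vector<fmat> params_to_f(const List& params) {
  std::vector<fmat> out(params.size());
  for (int i = 0; i < params.size(); ++i) {
    NumericMatrix m = params[i];
    out[i] = arma::conv_to<fmat>::from(
        arma::mat(m.begin(), m.nrow(), m.ncol(), false));
  }
  return out;
}

// stack N equally sized input images into the batched tensor-0 matrix
void init_workspace(Workspace& ws, const List& inputs, int n_tensors) {
  const int N = inputs.size();
  NumericMatrix x0 = inputs[0];
  const int H = x0.nrow(), W = x0.ncol();
  fmat T0(static_cast<size_t>(N) * H * W, 1);
  for (int s = 0; s < N; ++s) {
    NumericMatrix xs = inputs[s];
    if (xs.nrow() != H || xs.ncol() != W)
      stop("all batch images must share one size");
    float* dst = T0.colptr(0) + static_cast<size_t>(s) * H * W;
    const double* src = xs.begin();
    for (int i = 0; i < H * W; ++i) dst[i] = (float)src[i];
  }
  ws.N = N;
  ws.tensors.assign(n_tensors, fmat());
  ws.th.assign(n_tensors, 0);
  ws.tw.assign(n_tensors, 0);
  ws.col3.assign(n_tensors, fmat());
  ws.col3_ok.assign(n_tensors, false);
  ws.tensors[0] = std::move(T0);
  ws.th[0] = H;
  ws.tw[0] = W;
}

NumericMatrix sample_to_matrix(const fmat& T, int H, int W, int s) {
  NumericMatrix out(H, W);
  const float* src = T.colptr(0) + static_cast<size_t>(s) * H * W;
  double* dst = out.begin();
  for (int i = 0; i < H * W; ++i) dst[i] = (double)src[i];
  return out;
}

}  // namespace

// [[Rcpp::export(name = "cpp_net_forward")]]
NumericMatrix cpp_net_forward(List params, List spec, NumericMatrix input) {
  std::vector<Layer> layers = parse_spec(spec);
  std::vector<fmat> P = params_to_f(params);
  Workspace ws;
  init_workspace(ws, List::create(input), (int)layers.size() + 1);
  forward_pass(layers, P, ws);
  const int last = (int)layers.size();
  return sample_to_matrix(ws.tensors[last], ws.th[last], ws.tw[last], 0);
}

// All intermediate feature maps of a single-sample forward pass, as
// H x W x C arrays (tensor 0 is the input).
// [[Rcpp::export(name = "cpp_net_tensors")]]
List cpp_net_tensors(List params, List spec, NumericMatrix input) {
  std::vector<Layer> layers = parse_spec(spec);
  std::vector<fmat> P = params_to_f(params);
  Workspace ws;
  init_workspace(ws, List::create(input), (int)layers.size() + 1);
  forward_pass(layers, P, ws);
  List out(ws.tensors.size());
  for (size_t i = 0; i < ws.tensors.size(); ++i) {
    const fmat& T = ws.tensors[i];
    const int H = ws.th[i], W = ws.tw[i], C = T.n_cols;
    NumericVector a(Dimension(H, W, C));
    double* dst = a.begin();
    for (int c = 0; c < C; ++c) {
      const float* src = T.colptr(c);
      for (int j = 0; j < H * W; ++j) dst[(size_t)c * H * W + j] = src[j];
    }
    out[i] = a;
  }
  return out;
}

// Forward + backward over a batch with the loss evaluated internally.
// loss 0 = mean squared error, 1 = mean absolute error, both averaged over
// all pixels and all batch members.
// [[Rcpp::export(name = "cpp_net_grad_batch")]]
List cpp_net_grad_batch(List params, List spec, List inputs, List targets,
                        int loss) {
  std::vector<Layer> layers = parse_spec(spec);
  std::vector<fmat> P = params_to_f(params);
  std::vector<fmat> G(P.size());
  for (size_t i = 0; i < P.size(); ++i)
    G[i].zeros(P[i].n_rows, P[i].n_cols);
  Workspace ws;
  init_workspace(ws, inputs, (int)layers.size() + 1);
  forward_pass(layers, P, ws);
  const int last = (int)layers.size();
  const fmat& pred = ws.tensors[last];
  const int M = ws.th[last] * ws.tw[last];
  const int N = ws.N;
  fmat d(pred.n_rows, 1);
  double total = 0.0;
  const double sc = 1.0 / (static_cast<double>(M) * N);
  const float* pp = pred.colptr(0);
  float* dp = d.colptr(0);
  for (int s = 0; s < N; ++s) {
    NumericMatrix tgt = targets[s];
    if (tgt.nrow() * tgt.ncol() != M) stop("target size mismatch");
    const double* tp = tgt.begin();
    const size_t off = static_cast<size_t>(s) * M;
    for (int i = 0; i < M; ++i) {
      const double r = (double)pp[off + i] - tp[i];
      if (loss == 0) {
        total += r * r;
        dp[off + i] = (float)(2.0 * r * sc);
      } else {
        total += std::fabs(r);
        dp[off + i] = (float)((r > 0 ? 1.0 : (r < 0 ? -1.0 : 0.0)) * sc);
      }
    }
  }
  backward_pass(layers, P, ws, std::move(d), G);
  List gout(G.size());
  for (size_t i = 0; i < G.size(); ++i)
    gout[i] = wrap(arma::conv_to<arma::mat>::from(G[i]));
  return List::create(_["loss"] = total * sc, _["grads"] = gout);
}

// Backward pass with externally supplied output gradients (one matrix per
// batch member), for losses evaluated on the R side.
// [[Rcpp::export(name = "cpp_net_backward_batch")]]
List cpp_net_backward_batch(List params, List spec, List inputs,
                            List dpreds) {
  std::vector<Layer> layers = parse_spec(spec);
  std::vector<fmat> P = params_to_f(params);
  std::vector<fmat> G(P.size());
  for (size_t i = 0; i < P.size(); ++i)
    G[i].zeros(P[i].n_rows, P[i].n_cols);
  Workspace ws;
  init_workspace(ws, inputs, (int)layers.size() + 1);
  forward_pass(layers, P, ws);
  const int last = (int)layers.size();
  const int M = ws.th[last] * ws.tw[last];
  fmat d(ws.tensors[last].n_rows, 1);
  float* dp = d.colptr(0);
  for (int s = 0; s < ws.N; ++s) {
    NumericMatrix dm = dpreds[s];
    if (dm.nrow() * dm.ncol() != M) stop("gradient size mismatch");
    const double* sp = dm.begin();
    const size_t off = static_cast<size_t>(s) * M;
    for (int i = 0; i < M; ++i) dp[off + i] = (float)sp[i];
  }
  backward_pass(layers, P, ws, std::move(d), G);
  List gout(G.size());
  for (size_t i = 0; i < G.size(); ++i)
    gout[i] = wrap(arma::conv_to<arma::mat>::from(G[i]));
  return gout;
}
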