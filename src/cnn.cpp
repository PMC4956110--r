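// Convolutional network forward/backward.
//
// Feature maps are stored as (positions x channels) matrices, positions
// column-major over the (H x W) spatial grid (row index fastest), so each
// channel column is a contiguous H*W image. Convolutions are valid (no
// padding inside the stack) via im2col + gemm; the im2col gather then
// reduces to contiguous column-block copies. Max-pooling is 2x2 stride 2
// with the floor convention (odd trailing rows/columns dropped).
//
// The implementation is templated on the scalar type: single precision is
// the default compute path (the workload is memory-bandwidth and gemm
// bound), double precision is available for numerical checks such as
// finite-difference gradient validation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::uword;

struct LayerDef {
  std::string kind;      // "conv" or "maxpool" (cccp/softmax are 1x1 convs)
  int h, w, c_out;
  std::string act;       // "relu", "softmax", "none"
};

static std::vector<LayerDef> parse_arch(const List& arch) {
  std::vector<LayerDef> out;
  for (R_xlen_t i = 0; i < arch.size(); ++i) {
    List l = arch[i];
    LayerDef d;
    if (!l.containsElementNamed("kind")) stop("layer without kind");
    d.kind = as<std::string>(l["kind"]);
    if (d.kind == "maxpool") {
      d.h = 2; d.w = 2; d.c_out = 0; d.act = "none";
    } else {
      d.h = as<int>(l["h"]); d.w = as<int>(l["w"]);
      d.c_out = as<int>(l["c_out"]);
      d.act = as<std::string>(l["activation"]);
    }
    out.push_back(d);
  }
  return out;
}

// Reusable byte-buffer pool for the large transient matrices. First-touch
// page faults on fresh ~100 MB allocations dominate the run time otherwise;
// training calls this code thousands of times with identically shaped
// buffers.
namespace {
struct BufferPool {
  std::multimap<size_t, char*> free_list;
  std::map<char*, std::unique_ptr<char[]>> owned;
  size_t total = 0;
  static const size_t kMaxBytes = size_t(3) << 30;  // stop pooling past 3 GB

  std::pair<char*, size_t> get(size_t bytes) {
    auto it = free_list.lower_bound(bytes);
    if (it != free_list.end() && it->first <= 4 * bytes + 4096) {
      auto pr = std::make_pair(it->second, it->first);
      free_list.erase(it);
      return pr;
    }
    char* p = new char[bytes];
    if (total < kMaxBytes) {
      owned[p].reset(p);
      total += bytes;
      return {p, bytes};
    }
    return {p, 0};  // unpooled: PoolBuf deletes it on release
  }
  void put(char* p, size_t cap) {
    if (cap) free_list.emplace(cap, p);
  }
};
BufferPool g_pool;

template <typename T>
struct PoolBuf {
  char* p = nullptr; size_t cap = 0; size_t n = 0;
  PoolBuf() {}
  explicit PoolBuf(size_t n_) { acquire(n_); }
  void acquire(size_t n_) {
    release();
    n = n_;
    auto pr = g_pool.get(n_ * sizeof(T));
    p = pr.first; cap = pr.second;
  }
  arma::Mat<T> make(uword r, uword c) {
    if ((size_t)r * c > n) stop("pool buffer too small");
    return arma::Mat<T>(reinterpret_cast<T*>(p), r, c, false, true);
  }
  void release() {
    if (p) { if (cap) g_pool.put(p, cap); else delete[] p; }
    p = nullptr; cap = 0; n = 0;
  }
  ~PoolBuf() { release(); }
  PoolBuf(const PoolBuf&) = delete;
  PoolBuf& operator=(const PoolBuf&) = delete;
};
}  // namespace

// im2col, transposed: K (Ho*Wo x C*fh*fw); column ((c*fh)+fi)*fw + fj holds
// input cell (io+fi, jo+fj) of channel c for every output position (io, jo).
template <typename T>
static void im2col_t(arma::Mat<T>& K, const arma::Mat<T>& A, int H, int W,
                     int fh, int fw) {
  const int C = A.n_cols;
  const int Ho = H - fh + 1, Wo = W - fw + 1;
  for (int c = 0; c < C; ++c) {
    const T* img = A.colptr(c);
    for (int fi = 0; fi < fh; ++fi)
      for (int fj = 0; fj < fw; ++fj) {
        T* kcol = K.colptr((uword)((c * fh) + fi) * fw + fj);
        for (int jo = 0; jo < Wo; ++jo)
          std::memcpy(kcol + (uword)jo * Ho,
                      img + (uword)(jo + fj) * H + fi,
                      sizeof(T) * Ho);
      }
  }
}

// Scatter-add of dK back into dA (inverse of im2col_t).
template <typename T>
static void col2im_add_t(arma::Mat<T>& dA, const arma::Mat<T>& dK, int H,
                         int W, int fh, int fw) {
  const int C = dA.n_cols;
  const int Ho = H - fh + 1, Wo = W - fw + 1;
  for (int c = 0; c < C; ++c) {
    T* img = dA.colptr(c);
    for (int fi = 0; fi < fh; ++fi)
      for (int fj = 0; fj < fw; ++fj) {
        const T* kcol = dK.colptr((uword)((c * fh) + fi) * fw + fj);
        for (int jo = 0; jo < Wo; ++jo) {
          T* dst = img + (uword)(jo + fj) * H + fi;
          const T* src = kcol + (uword)jo * Ho;
          for (int io = 0; io < Ho; ++io) dst[io] += src[io];
        }
      }
  }
}

template <typename T>
struct ForwardState {
  std::vector<arma::Mat<T>> act;  // post-activation map per layer (+input)
  std::vector<int> Hs, Ws;        // spatial dims per stored map
  std::vector<arma::umat> pool_arg;  // argmax (position index) per pool
  // pooled im2col matrices kept for the backward pass (keep_cols = true)
  std::vector<std::unique_ptr<PoolBuf<T>>> kbufs;
  std::vector<std::pair<uword, uword>> kdims;
};

// Row-wise (per-position) softmax over channels.
template <typename T>
static void softmax_rows(arma::Mat<T>& Y) {
  arma::Col<T> m = arma::max(Y, 1);
  Y.each_col() -= m;
  Y = arma::exp(Y);
  arma::Col<T> s = arma::sum(Y, 1);
  Y.each_col() /= s;
}

template <typename T>
static ForwardState<T> run_forward(const std::vector<LayerDef>& defs,
                                   const std::vector<arma::Mat<T>>& weights,
                                   const std::vector<arma::Col<T>>& biases,
                                   const arma::Mat<T>& input, int H0, int W0,
                                   bool keep_cols = false) {
  ForwardState<T> st;
  st.act.push_back(input); st.Hs.push_back(H0); st.Ws.push_back(W0);
  st.kbufs.resize(defs.size());
  st.kdims.resize(defs.size());
  for (size_t li = 0; li < defs.size(); ++li) {
    const LayerDef& d = defs[li];
    const arma::Mat<T>& A = st.act.back();
    int H = st.Hs.back(), W = st.Ws.back();
    if (d.kind == "maxpool") {
      int Ho = H / 2, Wo = W / 2;
      const int C = A.n_cols;
      arma::Mat<T> Y((uword)Ho * Wo, C);
      arma::umat arg((uword)Ho * Wo, C);
      for (int c = 0; c < C; ++c) {
        const T* img = A.colptr(c);
        T* out = Y.colptr(c);
        uword* am = arg.colptr(c);
        for (int jo = 0; jo < Wo; ++jo)
          for (int io = 0; io < Ho; ++io) {
            uword cand[4] = {(uword)(2 * jo) * H + 2 * io,
                             (uword)(2 * jo) * H + 2 * io + 1,
                             (uword)(2 * jo + 1) * H + 2 * io,
                             (uword)(2 * jo + 1) * H + 2 * io + 1};
            T best = img[cand[0]]; uword bi = cand[0];
            for (int k = 1; k < 4; ++k)
              if (img[cand[k]] > best) { best = img[cand[k]]; bi = cand[k]; }
            out[(uword)jo * Ho + io] = best;
            am[(uword)jo * Ho + io] = bi;
          }
      }
      st.pool_arg.push_back(arg);
      st.act.push_back(Y); st.Hs.push_back(Ho); st.Ws.push_back(Wo);
    } else {
      int Ho = H - d.h + 1, Wo = W - d.w + 1;
      arma::Mat<T> Y;
      if (d.h == 1 && d.w == 1) {
        Y = A * weights[li];
      } else {
        uword kr = (uword)Ho * Wo, kc = A.n_cols * (uword)d.h * d.w;
        std::unique_ptr<PoolBuf<T>> kb(new PoolBuf<T>(kr * kc));
        arma::Mat<T> K = kb->make(kr, kc);
        im2col_t(K, A, H, W, d.h, d.w);
        Y = K * weights[li];
        if (keep_cols) {
          st.kbufs[li] = std::move(kb);
          st.kdims[li] = std::make_pair(kr, kc);
        }
      }
      Y.each_row() += biases[li].t();
      if (d.act == "relu")
        Y.transform([](T v) { return v > 0 ? v : T(0); });
      else if (d.act == "softmax") softmax_rows(Y);
      st.act.push_back(Y); st.Hs.push_back(Ho); st.Ws.push_back(Wo);
    }
  }
  return st;
}

// Parameters come from R as W (c_out x fan_in), b (c_out); internally the
// transposed weight (fan_in x c_out) is used.
template <typename T>
static void unpack_params(const List& params,
                          const std::vector<LayerDef>& defs,
                          std::vector<arma::Mat<T>>& weights,
                          std::vector<arma::Col<T>>& biases) {
  weights.resize(defs.size());
  biases.resize(defs.size());
  for (size_t li = 0; li < defs.size(); ++li) {
    if (defs[li].kind == "maxpool") continue;
    List pl = params[li];
    weights[li] = arma::conv_to<arma::Mat<T>>::from(as<arma::mat>(pl["W"]).t());
    biases[li] = arma::conv_to<arma::Col<T>>::from(as<arma::vec>(pl["b"]));
  }
}

template <typename T>
static List cnn_forward_impl(List arch, List params, const arma::mat& input) {
  std::vector<LayerDef> defs = parse_arch(arch);
  std::vector<arma::Mat<T>> weights; std::vector<arma::Col<T>> biases;
  unpack_params(params, defs, weights, biases);
  arma::Mat<T> in = arma::conv_to<arma::Mat<T>>::from(input);
  int H0 = in.n_rows, W0 = in.n_cols;
  in.reshape((uword)H0 * W0, 1);  // column-major flatten: 1 channel
  ForwardState<T> st = run_forward(defs, weights, biases, in, H0, W0);
  return List::create(
      _["out"] = arma::conv_to<arma::mat>::from(st.act.back().t()),
      _["H"] = st.Hs.back(), _["W"] = st.Ws.back());
}

template <typename T>
static List cnn_grad_impl(List arch, List params, const arma::mat& input,
                          const IntegerVector& labels) {
  std::vector<LayerDef> defs = parse_arch(arch);
  std::vector<arma::Mat<T>> weights; std::vector<arma::Col<T>> biases;
  unpack_params(params, defs, weights, biases);
  arma::Mat<T> in = arma::conv_to<arma::Mat<T>>::from(input);
  int H0 = in.n_rows, W0 = in.n_cols;
  in.reshape((uword)H0 * W0, 1);
  ForwardState<T> st = run_forward(defs, weights, biases, in, H0, W0, true);

  const arma::Mat<T>& P = st.act.back();
  if ((R_xlen_t)P.n_rows != labels.size())
    stop("label length does not match network output positions");
  double loss = 0; int n_lab = 0;

  // two ping-pong pooled buffers carry the backpropagated gradient map;
  // a fresh mat view over the active buffer is made in each iteration
  PoolBuf<T> gbuf[2];
  int cur = 0;
  uword gr = P.n_rows, gc = P.n_cols;
  gbuf[cur].acquire(gr * gc);
  {
    arma::Mat<T> dY = gbuf[cur].make(gr, gc);
    dY.zeros();
    for (uword p = 0; p < P.n_rows; ++p) {
      int lb = labels[p];
      if (lb <= 0) continue;
      ++n_lab;
      loss -= std::log(std::max((double)P(p, lb - 1), 1e-300));
      dY.row(p) = P.row(p);
      dY(p, lb - 1) -= T(1);
    }
  }

  List grads(defs.size());
  int pool_i = (int)st.pool_arg.size() - 1;
  // the gradient buffer holds d(loss)/d(logits) of the last layer on entry
  for (int li = (int)defs.size() - 1; li >= 0; --li) {
    const LayerDef& d = defs[li];
    const arma::Mat<T>& A = st.act[li];
    int H = st.Hs[li], W = st.Ws[li];
    arma::Mat<T> dY = gbuf[cur].make(gr, gc);
    if (d.kind == "maxpool") {
      const arma::umat& arg = st.pool_arg[pool_i--];
      const int C = A.n_cols;
      gbuf[1 - cur].acquire(A.n_elem);
      arma::Mat<T> dA = gbuf[1 - cur].make((uword)H * W, C);
      dA.zeros();
      for (int c = 0; c < C; ++c) {
        T* img = dA.colptr(c);
        const uword* am = arg.colptr(c);
        const T* g = dY.colptr(c);
        for (uword po = 0; po < dY.n_rows; ++po) img[am[po]] += g[po];
      }
      cur = 1 - cur; gr = (uword)H * W; gc = C;
      grads[li] = R_NilValue;
      continue;
    }
    if (d.act == "relu") {
      const arma::Mat<T>& Y = st.act[li + 1];
      const T* y = Y.memptr();
      T* g = dY.memptr();
      for (uword k = 0; k < Y.n_elem; ++k)
        if (y[k] <= 0) g[k] = 0;
    }
    arma::Mat<T> dWt;
    arma::Col<T> db = arma::sum(dY, 0).t();
    if (d.h == 1 && d.w == 1) {
      dWt = A.t() * dY;
      if (li > 0) {
        gbuf[1 - cur].acquire(A.n_elem);
        arma::Mat<T> dA = gbuf[1 - cur].make(A.n_rows, A.n_cols);
        dA = dY * weights[li].t();
        cur = 1 - cur; gr = A.n_rows; gc = A.n_cols;
      }
    } else {
      arma::Mat<T> K = st.kbufs[li]->make(st.kdims[li].first,
                                          st.kdims[li].second);
      dWt = K.t() * dY;
      if (li > 0) {
        PoolBuf<T> dkb(K.n_elem);
        arma::Mat<T> dK = dkb.make(K.n_rows, K.n_cols);
        dK = dY * weights[li].t();
        gbuf[1 - cur].acquire(A.n_elem);
        arma::Mat<T> dA = gbuf[1 - cur].make(A.n_rows, A.n_cols);
        dA.zeros();
        col2im_add_t(dA, dK, H, W, d.h, d.w);
        cur = 1 - cur; gr = A.n_rows; gc = A.n_cols;
      }
    }
    grads[li] = List::create(
        _["dW"] = arma::conv_to<arma::mat>::from(dWt.t()),
        _["db"] = arma::conv_to<arma::vec>::from(db));
  }
  return List::create(_["loss"] = loss, _["n"] = n_lab, _["grads"] = grads);
}

// [[Rcpp::export]]
List cpp_cnn_forward(List arch, List params, arma::mat input,
                     bool double_precision = false) {
  if (double_precision) return cnn_forward_impl<double>(arch, params, input);
  return cnn_forward_impl<float>(arch, params, input);
}

// Cross-entropy loss and parameter gradients for one sequence.
// labels: one entry per output position (Ho*Wo of the last layer, row index
// fastest), values in 1..c_out or 0 for positions excluded from the loss.
// [[Rcpp::export]]
List cpp_cnn_grad(List arch, List params, arma::mat input,
                  IntegerVector labels, bool double_precision = false) {
  if (double_precision) return cnn_grad_impl<double>(arch, params, input, labels);
  return cnn_grad_impl<float>(arch, params, input, labels);
}
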