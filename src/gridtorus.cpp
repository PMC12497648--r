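// Compiled numerics: spatial autocorrelation, component labelling,
// grid-model loss/gradient, and the LSTM decoder (forward + BPTT + Adam).
// Everything here is deterministic given its inputs; all randomness
// (weight init, batch order, shuffles) lives on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Spatial autocorrelation: Pearson r of the map with itself at every integer
// bin displacement, using only bins valid in both copies. Lags with fewer
// than min_overlap overlapping bins are NA.
// [[Rcpp::export]]
arma::mat cpp_spatial_autocorr(const arma::mat& m, const arma::umat& valid,
                               int min_overlap) {
  const int nr = m.n_rows, nc = m.n_cols;
  arma::mat ac(2 * nr - 1, 2 * nc - 1);
  ac.fill(NA_REAL);
  for (int dr = -(nr - 1); dr <= nr - 1; ++dr) {
    for (int dc = -(nc - 1); dc <= nc - 1; ++dc) {
      double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
      int n = 0;
      const int r0 = std::max(0, -dr), r1 = std::min(nr, nr - dr);
      const int c0 = std::max(0, -dc), c1 = std::min(nc, nc - dc);
      for (int r = r0; r < r1; ++r) {
        for (int c = c0; c < c1; ++c) {
          if (valid(r, c) && valid(r + dr, c + dc)) {
            const double a = m(r, c), b = m(r + dr, c + dc);
            sx += a; sy += b; sxx += a * a; syy += b * b; sxy += a * b;
            ++n;
          }
        }
      }
      if (n >= min_overlap) {
        const double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
        if (vx > 1e-12 && vy > 1e-12) {
          ac(dr + nr - 1, dc + nc - 1) = (sxy - sx * sy / n) / std::sqrt(vx * vy);
        }
      }
    }
  }
  return ac;
}

// ---------------------------------------------------------------------------
// 4-connected component labelling of a logical matrix (0 = background).
// [[Rcpp::export]]
arma::imat cpp_label_components(const arma::umat& mask) {
  const int nr = mask.n_rows, nc = mask.n_cols;
  arma::imat lab(nr, nc, arma::fill::zeros);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) && lab(r, c) == 0) {
        ++next;
        stack.push_back({r, c});
        lab(r, c) = next;
        while (!stack.empty()) {
          auto [cr, cc] = stack.back();
          stack.pop_back();
          const int dr[4] = {-1, 1, 0, 0}, dc[4] = {0, 0, -1, 1};
          for (int k = 0; k < 4; ++k) {
            const int r2 = cr + dr[k], c2 = cc + dc[k];
            if (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc &&
                mask(r2, c2) && lab(r2, c2) == 0) {
              lab(r2, c2) = next;
              stack.push_back({r2, c2});
            }
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Grid-model loss and gradient. The model rate at position (x, y) is
//   relu((cos(a0-o0) + cos(a1-o1) + cos(a2-o2) + 1.5) / 4.5 * pr),
// a_i = (x cos th_i + y sin th_i) / p_i * 2 pi.
// Parameter vector layout:
//   stage 1 (constrained): c(theta, p, o0, o1, o2, pr)      [axes theta + k*60deg]
//   stage 2 (free):        c(th0, th1, th2, p0, p1, p2, o0, o1, o2, pr)
// Returns list(loss, grad) for loss = mean((model - target)^2).
// [[Rcpp::export]]
List cpp_grid_loss_grad(const arma::vec& x, const arma::vec& y,
                        const arma::vec& target, const arma::vec& par,
                        bool constrained) {
  const int n = x.n_elem;
  arma::vec th(3), p(3), o(3);
  double pr;
  if (constrained) {
    for (int i = 0; i < 3; ++i) {
      th(i) = par(0) + i * M_PI / 3.0;
      p(i) = par(1);
      o(i) = par(2 + i);
    }
    pr = par(5);
  } else {
    for (int i = 0; i < 3; ++i) { th(i) = par(i); p(i) = par(3 + i); o(i) = par(6 + i); }
    pr = par(9);
  }
  arma::vec grad(par.n_elem, arma::fill::zeros);
  double loss = 0.0;
  // per-axis accumulators for gradient
  arma::vec g_th(3, arma::fill::zeros), g_p(3, arma::fill::zeros),
            g_o(3, arma::fill::zeros);
  double g_pr = 0.0;
  for (int j = 0; j < n; ++j) {
    double csum = 0.0;
    double a[3], s[3], d[3];
    for (int i = 0; i < 3; ++i) {
      d[i] = x(j) * std::cos(th(i)) + y(j) * std::sin(th(i));
      a[i] = d[i] / p(i) * 2.0 * M_PI;
      csum += std::cos(a[i] - o(i));
      s[i] = std::sin(a[i] - o(i));
    }
    const double pre = (csum + 1.5) / 4.5 * pr;
    const double m = pre > 0 ? pre : 0.0;
    const double e = m - target(j);
    loss += e * e;
    if (pre > 0) {
      const double w = 2.0 * e * pr / 4.5;  // d loss / d csum (per sample)
      for (int i = 0; i < 3; ++i) {
        const double da_dth = (-x(j) * std::sin(th(i)) + y(j) * std::cos(th(i))) / p(i) * 2.0 * M_PI;
        const double da_dp = -d[i] / (p(i) * p(i)) * 2.0 * M_PI;
        g_th(i) += w * (-s[i]) * da_dth;
        g_p(i)  += w * (-s[i]) * da_dp;
        g_o(i)  += w * s[i];
      }
      g_pr += 2.0 * e * (csum + 1.5) / 4.5;
    }
  }
  loss /= n;
  g_th /= n; g_p /= n; g_o /= n; g_pr /= n;
  if (constrained) {
    grad(0) = arma::accu(g_th);
    grad(1) = arma::accu(g_p);
    for (int i = 0; i < 3; ++i) grad(2 + i) = g_o(i);
    grad(5) = g_pr;
  } else {
    for (int i = 0; i < 3; ++i) { grad(i) = g_th(i); grad(3 + i) = g_p(i); grad(6 + i) = g_o(i); }
    grad(9) = g_pr;
  }
  return List::create(_["loss"] = loss, _["grad"] = grad);
}

// Model rates only (used for prediction / targets).
// [[Rcpp::export]]
arma::vec cpp_grid_rate(const arma::vec& x, const arma::vec& y,
                        const arma::vec& th, const arma::vec& p,
                        const arma::vec& o, double pr) {
  const int n = x.n_elem;
  arma::vec out(n);
  for (int j = 0; j < n; ++j) {
    double csum = 0.0;
    for (int i = 0; i < 3; ++i) {
      const double d = x(j) * std::cos(th(i)) + y(j) * std::sin(th(i));
      csum += std::cos(d / p(i) * 2.0 * M_PI - o(i));
    }
    const double pre = (csum + 1.5) / 4.5 * pr;
    out(j) = pre > 0 ? pre : 0.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// LSTM decoder. Two stacked LSTM layers + linear read-out of the last hidden
// state. Batch matrices are (features x batch). Parameters travel as a list
// of matrices so R owns initialization and the Adam state.

struct LstmLayer {
  arma::mat W, U;   // (4H x n_in), (4H x H)
  arma::vec b;      // 4H
};

static LstmLayer layer_from_list(const List& par, const std::string& pre) {
  LstmLayer L;
  L.W = as<arma::mat>(par[pre + "W"]);
  L.U = as<arma::mat>(par[pre + "U"]);
  L.b = as<arma::vec>(par[pre + "b"]);
  return L;
}

static inline arma::mat sigm(const arma::mat& z) { return 1.0 / (1.0 + arma::exp(-z)); }

struct LayerCache {
  std::vector<arma::mat> i, f, g, o, c, tc, h, x;  // per timestep
};

// forward one layer over T steps; x_t supplied via cache.x
static void lstm_layer_forward(const LstmLayer& L, LayerCache& cc, int T, int N) {
  const int H = L.U.n_cols;
  arma::mat h(H, N, arma::fill::zeros), c(H, N, arma::fill::zeros);
  cc.i.resize(T); cc.f.resize(T); cc.g.resize(T); cc.o.resize(T);
  cc.c.resize(T); cc.tc.resize(T); cc.h.resize(T);
  for (int t = 0; t < T; ++t) {
    arma::mat z = L.W * cc.x[t] + L.U * h;
    z.each_col() += L.b;
    arma::mat zi = z.rows(0, H - 1), zf = z.rows(H, 2 * H - 1),
              zg = z.rows(2 * H, 3 * H - 1), zo = z.rows(3 * H, 4 * H - 1);
    cc.i[t] = sigm(zi); cc.f[t] = sigm(zf);
    cc.g[t] = arma::tanh(zg); cc.o[t] = sigm(zo);
    c = cc.f[t] % c + cc.i[t] % cc.g[t];
    cc.c[t] = c;
    cc.tc[t] = arma::tanh(c);
    h = cc.o[t] % cc.tc[t];
    cc.h[t] = h;
  }
}

// backward one layer; dh_t = external gradient on h_t (vector over t).
// Fills dW,dU,db and dx per timestep.
static void lstm_layer_backward(const LstmLayer& L, const LayerCache& cc,
                                const std::vector<arma::mat>& dh_ext,
                                int T, int N,
                                arma::mat& dW, arma::mat& dU, arma::vec& db,
                                std::vector<arma::mat>& dx) {
  const int H = L.U.n_cols;
  dW.zeros(L.W.n_rows, L.W.n_cols);
  dU.zeros(L.U.n_rows, L.U.n_cols);
  db.zeros(L.b.n_elem);
  dx.resize(T);
  arma::mat dh(H, N, arma::fill::zeros), dc(H, N, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    dh += dh_ext[t];
    arma::mat do_ = dh % cc.tc[t];
    dc += dh % cc.o[t] % (1.0 - arma::square(cc.tc[t]));
    arma::mat cprev = (t > 0) ? cc.c[t - 1] : arma::mat(H, N, arma::fill::zeros);
    arma::mat di = dc % cc.g[t];
    arma::mat dg = dc % cc.i[t];
    arma::mat df = dc % cprev;
    arma::mat dc_prev = dc % cc.f[t];
    arma::mat dz(4 * H, N);
    dz.rows(0, H - 1)         = di % cc.i[t] % (1.0 - cc.i[t]);
    dz.rows(H, 2 * H - 1)     = df % cc.f[t] % (1.0 - cc.f[t]);
    dz.rows(2 * H, 3 * H - 1) = dg % (1.0 - arma::square(cc.g[t]));
    dz.rows(3 * H, 4 * H - 1) = do_ % cc.o[t] % (1.0 - cc.o[t]);
    dW += dz * cc.x[t].t();
    arma::mat hprev = (t > 0) ? cc.h[t - 1] : arma::mat(H, N, arma::fill::zeros);
    dU += dz * hprev.t();
    db += arma::sum(dz, 1);
    dx[t] = L.W.t() * dz;
    dh = L.U.t() * dz;
    dc = dc_prev;
  }
}

// Gather a batch: X cube of (n_cells x N) slices over T timesteps.
// rates: (n_bins x n_cells); idx: 1-based bin index of the window END for
// each sample; window: number of timesteps.
static std::vector<arma::mat> gather_batch(const arma::mat& rates,
                                           const arma::uvec& idx, int window) {
  const int N = idx.n_elem;
  const int n_cells = rates.n_cols;
  std::vector<arma::mat> x(window);
  for (int t = 0; t < window; ++t) x[t].set_size(n_cells, N);
  for (int j = 0; j < N; ++j) {
    const int end = idx(j) - 1;  // 0-based
    for (int t = 0; t < window; ++t) {
      for (int k = 0; k < n_cells; ++k) {
        x[t](k, j) = rates(end - window + 1 + t, k);
      }
    }
  }
  return x;
}

// Forward pass to predictions for a set of samples.
// [[Rcpp::export]]
arma::mat cpp_lstm_predict(const arma::mat& rates, const arma::uvec& idx,
                           int window, const List& par) {
  LstmLayer L1 = layer_from_list(par, "l1_");
  LstmLayer L2 = layer_from_list(par, "l2_");
  arma::mat Wy = as<arma::mat>(par["out_W"]);
  arma::vec by = as<arma::vec>(par["out_b"]);
  const int N = idx.n_elem;
  LayerCache c1, c2;
  c1.x = gather_batch(rates, idx, window);
  lstm_layer_forward(L1, c1, window, N);
  c2.x = c1.h;
  lstm_layer_forward(L2, c2, window, N);
  arma::mat yhat = Wy * c2.h[window - 1];
  yhat.each_col() += by;
  return yhat.t();  // N x 4
}

// Loss + full gradient for one batch (used by training and gradient checks).
static double lstm_batch_grad(const arma::mat& rates, const arma::uvec& idx,
                              const arma::mat& Y, int window, const List& par,
                              List& grads) {
  LstmLayer L1 = layer_from_list(par, "l1_");
  LstmLayer L2 = layer_from_list(par, "l2_");
  arma::mat Wy = as<arma::mat>(par["out_W"]);
  arma::vec by = as<arma::vec>(par["out_b"]);
  const int N = idx.n_elem, T = window;
  LayerCache c1, c2;
  c1.x = gather_batch(rates, idx, window);
  lstm_layer_forward(L1, c1, T, N);
  c2.x = c1.h;
  lstm_layer_forward(L2, c2, T, N);
  arma::mat yhat = Wy * c2.h[T - 1];
  yhat.each_col() += by;
  arma::mat err = yhat - Y.t();             // 4 x N
  const double loss = arma::accu(arma::square(err)) / (4.0 * N);
  arma::mat dy = 2.0 * err / (4.0 * N);
  arma::mat dWy = dy * c2.h[T - 1].t();
  arma::vec dby = arma::sum(dy, 1);
  const int H2 = L2.U.n_cols;
  std::vector<arma::mat> dh2(T);
  for (int t = 0; t < T; ++t) dh2[t].zeros(H2, N);
  dh2[T - 1] = Wy.t() * dy;
  arma::mat dW2, dU2; arma::vec db2;
  std::vector<arma::mat> dx2;
  lstm_layer_backward(L2, c2, dh2, T, N, dW2, dU2, db2, dx2);
  arma::mat dW1, dU1; arma::vec db1;
  std::vector<arma::mat> dx1;
  lstm_layer_backward(L1, c1, dx2, T, N, dW1, dU1, db1, dx1);
  grads = List::create(
    _["l1_W"] = dW1, _["l1_U"] = dU1, _["l1_b"] = db1,
    _["l2_W"] = dW2, _["l2_U"] = dU2, _["l2_b"] = db2,
    _["out_W"] = dWy, _["out_b"] = dby);
  return loss;
}

// [[Rcpp::export]]
List cpp_lstm_loss_grad(const arma::mat& rates, const arma::uvec& idx,
                        const arma::mat& Y, int window, const List& par) {
  List grads;
  const double loss = lstm_batch_grad(rates, idx, Y, window, par, grads);
  return List::create(_["loss"] = loss, _["grad"] = grads);
}

// One training epoch with Adam over batches defined by `order` (1-based into
// idx/Y rows). Parameters and Adam moments are updated in place (clones
// returned). `state` carries m, v (same shapes) and step count.
// [[Rcpp::export]]
List cpp_lstm_train_epoch(const arma::mat& rates, const arma::uvec& idx,
                          const arma::mat& Y, int window, List par, List state,
                          const arma::uvec& order, int batch_size, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const int n = order.n_elem;
  List m = state["m"], v = state["v"];
  int step = as<int>(state["step"]);
  CharacterVector nm = par.names();
  std::vector<double> losses;
  for (int start = 0; start < n; start += batch_size) {
    const int stop = std::min(start + batch_size, n);
    arma::uvec sel(stop - start);
    for (int j = start; j < stop; ++j) sel(j - start) = order(j);
    arma::uvec bidx(sel.n_elem);
    arma::mat bY(sel.n_elem, Y.n_cols);
    for (unsigned j = 0; j < sel.n_elem; ++j) {
      bidx(j) = idx(sel(j) - 1);
      bY.row(j) = Y.row(sel(j) - 1);
    }
    List grads;
    losses.push_back(lstm_batch_grad(rates, bidx, bY, window, par, grads));
    ++step;
    const double bc1 = 1.0 - std::pow(b1, step), bc2 = 1.0 - std::pow(b2, step);
    for (int k = 0; k < nm.size(); ++k) {
      std::string key = as<std::string>(nm[k]);
      arma::mat P = as<arma::mat>(par[key]);
      arma::mat G = as<arma::mat>(grads[key]);
      arma::mat M = as<arma::mat>(m[key]);
      arma::mat V = as<arma::mat>(v[key]);
      M = b1 * M + (1.0 - b1) * G;
      V = b2 * V + (1.0 - b2) * arma::square(G);
      P -= lr * (M / bc1) / (arma::sqrt(V / bc2) + eps);
      par[key] = P; m[key] = M; v[key] = V;
    }
    Rcpp::checkUserInterrupt();
  }
  state["m"] = m; state["v"] = v; state["step"] = step;
  return List::create(_["par"] = par, _["state"] = state,
                      _["losses"] = wrap(losses));
}
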