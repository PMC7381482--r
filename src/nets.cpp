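// Training loops for the two recurrent networks.
//
// hub_train_cpp: recurrent auto-associator (visible <-> hidden with
// hidden recurrence), trained by backpropagation through time over the
// unrolled 2-clamped + 5-free settling cycles, targets applied to the
// visible units on the final cycles, online weight updates with
// multiplicative weight decay.  Bias input is a fixed -2.0 to every unit
// and is never updated.
//
// srn_train_cpp: simple recurrent (Elman) network trained by BPTT over
// whole action sequences plus one-step background items, softmax output,
// online updates with momentum.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline rowvec sigm(const rowvec& x) { return 1.0 / (1.0 + exp(-x)); }

// [[Rcpp::export]]
Rcpp::List hub_train_cpp(arma::mat W_vh, arma::mat W_hh, arma::mat W_hv,
                         const arma::mat& patterns,
                         const Rcpp::List& clamp_masks,
                         int epochs, double lr, double decay, double bias,
                         int cycles_clamped, int cycles_free,
                         int target_cycles, std::string loss) {
  const int n_vis = W_vh.n_rows, n_hid = W_vh.n_cols;
  const int n_pat = patterns.n_rows;
  const int C = cycles_clamped + cycles_free;
  const bool use_ce = (loss == "ce");
  const int n_clamp = clamp_masks.size();

  std::vector<uvec> masks(n_clamp);
  for (int m = 0; m < n_clamp; ++m)
    masks[m] = Rcpp::as<uvec>(clamp_masks[m]); // 0-based visible indices

  mat V(C + 1, n_vis), H(C + 1, n_hid);       // per-cycle activations
  mat DPH(C + 1, n_hid, fill::zeros), DPV(C + 1, n_vis, fill::zeros);
  vec loss_trace(epochs, fill::zeros);

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_err = 0.0;
    for (int p = 0; p < n_pat; ++p) {
      rowvec target = patterns.row(p);
      for (int m = 0; m < n_clamp; ++m) {
        const uvec& ci = masks[m];
        // forward
        rowvec v(n_vis, fill::zeros), h(n_hid, fill::zeros);
        for (uword j = 0; j < ci.n_elem; ++j) v(ci(j)) = target(ci(j));
        V.row(0) = v; H.row(0) = h;
        for (int t = 1; t <= C; ++t) {
          rowvec hn = sigm(bias + v * W_vh + h * W_hh);
          rowvec vn = sigm(bias + h * W_hv);
          if (t <= cycles_clamped)
            for (uword j = 0; j < ci.n_elem; ++j) vn(ci(j)) = target(ci(j));
          v = vn; h = hn;
          V.row(t) = v; H.row(t) = h;
        }
        ep_err += accu(square(V.row(C) - target));
        // backward through the unrolled cycles
        DPH.zeros(); DPV.zeros();
        for (int t = C; t >= 1; --t) {
          rowvec gh(n_hid, fill::zeros), gv(n_vis, fill::zeros);
          if (t < C) {
            gh = DPH.row(t + 1) * W_hh.t() + DPV.row(t + 1) * W_hv.t();
            gv = DPH.row(t + 1) * W_vh.t();
          }
          rowvec vt = V.row(t), ht = H.row(t);
          rowvec dpv = gv % (vt % (1.0 - vt));
          if (t > C - target_cycles) {
            rowvec err = vt - target;
            if (use_ce) dpv += err;                    // CE through sigmoid
            else dpv += 2.0 * err % (vt % (1.0 - vt)); // SSE
          }
          if (t <= cycles_clamped)
            for (uword j = 0; j < ci.n_elem; ++j) dpv(ci(j)) = 0.0;
          DPV.row(t) = dpv;
          DPH.row(t) = gh % (ht % (1.0 - ht));
        }
        mat gW_vh = V.rows(0, C - 1).t() * DPH.rows(1, C);
        mat gW_hh = H.rows(0, C - 1).t() * DPH.rows(1, C);
        mat gW_hv = H.rows(0, C - 1).t() * DPV.rows(1, C);
        // PDPTool-style decay: added to the gradient, scaled by lr
        W_vh -= lr * (gW_vh + decay * W_vh);
        W_hh -= lr * (gW_hh + decay * W_hh);
        W_hv -= lr * (gW_hv + decay * W_hv);
      }
    }
    loss_trace(ep) = ep_err;
    if (!W_vh.is_finite()) Rcpp::stop("hub training diverged (non-finite weights) at epoch %d", ep + 1);
    if (ep % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("W_vh") = W_vh,
                            Rcpp::Named("W_hh") = W_hh,
                            Rcpp::Named("W_hv") = W_hv,
                            Rcpp::Named("loss_trace") = loss_trace);
}

// Batched settling used by naming/lesion sweeps: rows of `vis_input` are
// clamped onto the visual units for `cycles_clamped` cycles, then the
// network runs free.  Returns final visible and hidden activations.
// [[Rcpp::export]]
Rcpp::List hub_settle_cpp(const arma::mat& W_vh, const arma::mat& W_hh,
                          const arma::mat& W_hv, const arma::mat& clamp_values,
                          const arma::uvec& clamp_idx, double bias,
                          int cycles_clamped, int cycles_free) {
  const int n_vis = W_vh.n_rows, n_hid = W_vh.n_cols;
  const int n = clamp_values.n_rows;
  const int C = cycles_clamped + cycles_free;
  mat v(n, n_vis, fill::zeros), h(n, n_hid, fill::zeros);
  for (uword j = 0; j < clamp_idx.n_elem; ++j)
    v.col(clamp_idx(j)) = clamp_values.col(j);
  for (int t = 1; t <= C; ++t) {
    mat hn = 1.0 / (1.0 + exp(-(bias + v * W_vh + h * W_hh)));
    mat vn = 1.0 / (1.0 + exp(-(bias + h * W_hv)));
    if (t <= cycles_clamped)
      for (uword j = 0; j < clamp_idx.n_elem; ++j)
        vn.col(clamp_idx(j)) = clamp_values.col(j);
    v = vn; h = hn;
  }
  return Rcpp::List::create(Rcpp::Named("visible") = v,
                            Rcpp::Named("hidden") = h);
}

// [[Rcpp::export]]
Rcpp::List srn_train_cpp(arma::mat W_ih, arma::mat W_ch, arma::mat W_ho,
                         arma::rowvec b_h, arma::rowvec b_o,
                         const Rcpp::List& seq_inputs,
                         const Rcpp::List& seq_targets,
                         const arma::mat& bg_inputs,
                         const arma::ivec& bg_targets,
                         int epochs, double lr, double momentum,
                         double context_init, double bg_weight,
                         double train_noise_sd) {
  const int n_hid = W_ih.n_cols, n_out = W_ho.n_cols;
  const int n_seq = seq_inputs.size();
  const int n_bg = bg_inputs.n_rows;

  mat V_ih(size(W_ih), fill::zeros), V_ch(size(W_ch), fill::zeros),
      V_ho(size(W_ho), fill::zeros);
  rowvec v_bh(size(b_h), fill::zeros), v_bo(size(b_o), fill::zeros);

  std::vector<mat> X(n_seq);
  std::vector<ivec> Y(n_seq);
  for (int s = 0; s < n_seq; ++s) {
    X[s] = Rcpp::as<mat>(seq_inputs[s]);
    Y[s] = Rcpp::as<ivec>(seq_targets[s]); // 0-based action ids
  }
  vec loss_trace(epochs, fill::zeros);

  auto update = [&](const mat& gih, const mat& gch, const mat& gho,
                    const rowvec& gbh, const rowvec& gbo) {
    V_ih = momentum * V_ih - lr * gih; W_ih += V_ih;
    V_ch = momentum * V_ch - lr * gch; W_ch += V_ch;
    V_ho = momentum * V_ho - lr * gho; W_ho += V_ho;
    v_bh = momentum * v_bh - lr * gbh; b_h += v_bh;
    v_bo = momentum * v_bo - lr * gbo; b_o += v_bo;
  };

  for (int ep = 0; ep < epochs; ++ep) {
    double ep_loss = 0.0;
    for (int s = 0; s < n_seq; ++s) {
      const mat& x = X[s];
      const ivec& y = Y[s];
      const int T = x.n_rows;
      // C holds the context actually fed forward: the previous hidden
      // state plus (optional) training noise that makes the sequence
      // paths attracting; H holds the clean hidden states for backprop
      mat H(T + 1, n_hid), C(T + 1, n_hid);
      C.row(0).fill(context_init);
      mat DPO(T, n_out);
      for (int t = 0; t < T; ++t) {
        rowvec h = sigm(b_h + x.row(t) * W_ih + C.row(t) * W_ch);
        H.row(t + 1) = h;
        C.row(t + 1) = h;
        if (train_noise_sd > 0) {
          for (int j = 0; j < n_hid; ++j)
            C(t + 1, j) += R::rnorm(0.0, train_noise_sd);
        }
        rowvec po = b_o + h * W_ho;
        po -= po.max();
        rowvec o = exp(po); o /= accu(o);
        ep_loss -= std::log(std::max(o(y(t)), 1e-12));
        o(y(t)) -= 1.0;
        DPO.row(t) = o;
      }
      mat gih(size(W_ih), fill::zeros), gch(size(W_ch), fill::zeros);
      mat DPH(T, n_hid);
      rowvec carry(n_hid, fill::zeros);
      for (int t = T - 1; t >= 0; --t) {
        rowvec h = H.row(t + 1);
        rowvec gh = DPO.row(t) * W_ho.t() + carry;
        rowvec dph = gh % (h % (1.0 - h));
        DPH.row(t) = dph;
        carry = dph * W_ch.t();
      }
      gih = x.t() * DPH;
      gch = C.rows(0, T - 1).t() * DPH;
      mat gho = H.rows(1, T).t() * DPO;
      rowvec gbh = sum(DPH, 0), gbo = sum(DPO, 0);
      update(gih, gch, gho, gbh, gbo);
    }
    // one-step background items, presented online with neutral context
    rowvec c0(n_hid); c0.fill(context_init);
    for (int b = 0; b < n_bg; ++b) {
      rowvec x = bg_inputs.row(b);
      rowvec h = sigm(b_h + x * W_ih + c0 * W_ch);
      rowvec po = b_o + h * W_ho;
      po -= po.max();
      rowvec o = exp(po); o /= accu(o);
      ep_loss -= std::log(std::max(o(bg_targets(b)), 1e-12));
      o(bg_targets(b)) -= 1.0;
      o *= bg_weight;
      rowvec dph = (o * W_ho.t()) % (h % (1.0 - h));
      update(x.t() * dph, c0.t() * dph, h.t() * o, dph, o);
    }
    loss_trace(ep) = ep_loss;
    if (!W_ih.is_finite() || !std::isfinite(ep_loss))
      Rcpp::stop("SRN training diverged (non-finite loss) at epoch %d", ep + 1);
    if (ep % 200 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(Rcpp::Named("W_ih") = W_ih,
                            Rcpp::Named("W_ch") = W_ch,
                            Rcpp::Named("W_ho") = W_ho,
                            Rcpp::Named("b_h") = b_h,
                            Rcpp::Named("b_o") = b_o,
                            Rcpp::Named("loss_trace") = loss_trace);
}
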