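// S-CTRNNPB core: forward dynamics, Gaussian NLL, exact BPTT gradients,
// and full-batch adaptive-moment training loops.
//
// Conventions (shared with the R wrappers):
//  * X is a T x D sequence matrix; the network predicts row t+1 from row t,
//    so predictions exist for steps 1..T-1.
//  * Lower-level internal state starts at zero (so the initial lower-level
//    activity tanh(0) is zero).
//  * The parametric bias (PB) internal state q is constant over time within
//    a sequence; its reported activity is tanh(q).
//  * Masks are applied multiplicatively to inter-level weights before use,
//    and gradients of masked-out entries are forced to zero.
//  * The variance pre-activation is capped above at `vcap` before
//    exponentiation; the cap blocks the gradient when active.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Net {
  mat Wxl, Wll, Wpl, Wlm, Wlv;  // effective (already masked) weights
  vec a_low, a_m, a_v;
  double tau, vfloor, vcap;
};

Net unpack(const Rcpp::List& params, double tau, double vfloor, double vcap) {
  Net n;
  n.Wxl = Rcpp::as<mat>(params["W_xl"]) % Rcpp::as<mat>(params["M_xl"]);
  n.Wll = Rcpp::as<mat>(params["W_ll"]);
  n.Wpl = Rcpp::as<mat>(params["W_pl"]) % Rcpp::as<mat>(params["M_pl"]);
  n.Wlm = Rcpp::as<mat>(params["W_lm"]) % Rcpp::as<mat>(params["M_lm"]);
  n.Wlv = Rcpp::as<mat>(params["W_lv"]) % Rcpp::as<mat>(params["M_lv"]);
  n.a_low = Rcpp::as<vec>(params["a_lower"]);
  n.a_m = Rcpp::as<vec>(params["a_mean"]);
  n.a_v = Rcpp::as<vec>(params["a_var"]);
  n.tau = tau; n.vfloor = vfloor; n.vcap = vcap;
  return n;
}

struct Fwd {
  mat U, L, Y, V, S, Lmat;  // columns are time steps 1..T-1
  double nll, mse;
};

// closed = false: x_t = X[t,]; closed = true: x_1 = X[1,], x_t = y_{t-1} after.
Fwd forward(const Net& net, const mat& X, const vec& q, bool closed) {
  const uword T = X.n_rows, D = X.n_cols, H = net.Wll.n_rows;
  Fwd f;
  f.U.set_size(H, T - 1); f.L.set_size(H, T - 1);
  f.Y.set_size(D, T - 1); f.V.set_size(D, T - 1);
  f.S.set_size(D, T - 1); f.Lmat.set_size(D, T - 1);
  const vec p = tanh(q);
  const double it = 1.0 / net.tau;
  vec u(H, fill::zeros), l(H, fill::zeros), x;
  for (uword t = 0; t + 1 < T; ++t) {
    x = (closed && t > 0) ? vec(f.Y.col(t - 1)) : vec(X.row(t).t());
    u = it * (net.Wxl * x + net.Wll * l + net.Wpl * p + net.a_low) +
        (1.0 - it) * u;
    l = tanh(u);
    vec m = net.Wlm * l + net.a_m;
    vec s = net.Wlv * l + net.a_v;
    s.elem(find(s > net.vcap)).fill(net.vcap);
    vec y = tanh(m);
    vec v = exp(s) + net.vfloor;
    vec e = X.row(t + 1).t() - y;
    f.U.col(t) = u; f.L.col(t) = l; f.Y.col(t) = y;
    f.V.col(t) = v; f.S.col(t) = s;
    f.Lmat.col(t) = 0.5 * log(2.0 * datum::pi * v) + square(e) / (2.0 * v);
  }
  f.nll = accu(f.Lmat);
  f.mse = accu(square(X.rows(1, T - 1).t() - f.Y)) /
          static_cast<double>((T - 1) * D);
  return f;
}

struct Grads {
  mat gWxl, gWll, gWpl, gWlm, gWlv;
  vec ga_m, ga_v, gq;
};

// Exact BPTT for the open-loop loss. Mask projection happens in the caller.
Grads backward(const Net& net, const mat& X, const vec& q, const Fwd& f) {
  const uword T = X.n_rows, D = X.n_cols, H = net.Wll.n_rows;
  const uword P = net.Wpl.n_cols;
  const double it = 1.0 / net.tau;
  const vec p = tanh(q);
  Grads g;
  g.gWxl.zeros(H, net.Wxl.n_cols); g.gWll.zeros(H, H);
  g.gWpl.zeros(H, P);
  g.gWlm.zeros(D, H); g.gWlv.zeros(D, H);
  g.ga_m.zeros(D); g.ga_v.zeros(D);
  vec du_next(H, fill::zeros), carry_l(H, fill::zeros), du_sum(H, fill::zeros);
  for (uword ti = T - 1; ti-- > 0; ) {  // ti = T-2 .. 0
    const vec y = f.Y.col(ti), v = f.V.col(ti), s = f.S.col(ti);
    const vec e = X.row(ti + 1).t() - y;
    vec dy = -e / v;
    vec dm = dy % (1.0 - square(y));
    vec dv = 0.5 / v - square(e) / (2.0 * square(v));
    vec ds = dv % (v - net.vfloor);            // d v / d s = exp(s)
    ds.elem(find(s >= net.vcap)).zeros();      // cap blocks the gradient
    const vec l = f.L.col(ti);
    g.ga_m += dm; g.ga_v += ds;
    g.gWlm += dm * l.t(); g.gWlv += ds * l.t();
    vec dl = net.Wlm.t() * dm + net.Wlv.t() * ds + carry_l;
    vec du = dl % (1.0 - square(l)) + (1.0 - it) * du_next;
    const vec lprev = (ti == 0) ? vec(H, fill::zeros) : vec(f.L.col(ti - 1));
    g.gWxl += it * du * X.row(ti);             // x_t row
    g.gWll += it * du * lprev.t();
    g.gWpl += it * du * p.t();
    du_sum += du;
    carry_l = it * net.Wll.t() * du;
    du_next = du;
  }
  g.gq = (it * net.Wpl.t() * du_sum) % (1.0 - square(p));
  return g;
}

// One Adam update in place; m/v are moment buffers, step is 1-based.
void adam(mat& w, const mat& grad, mat& m1, mat& m2, double lr,
          double b1, double b2, int step) {
  const double eps = 1e-8;
  m1 = b1 * m1 + (1.0 - b1) * grad;
  m2 = b2 * m2 + (1.0 - b2) * square(grad);
  const double c1 = 1.0 - std::pow(b1, step), c2 = 1.0 - std::pow(b2, step);
  w -= lr * (m1 / c1) / (sqrt(m2 / c2) + eps);
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_run_sequence(Rcpp::List params, double tau, double vfloor,
                            double vcap, arma::mat X, arma::vec pb_q,
                            bool closed_loop) {
  if (!X.is_finite()) Rcpp::stop("non-finite values in input sequence");
  Net net = unpack(params, tau, vfloor, vcap);
  Fwd f = forward(net, X, pb_q, closed_loop);
  return Rcpp::List::create(
      Rcpp::Named("y") = f.Y.t(), Rcpp::Named("v") = f.V.t(),
      Rcpp::Named("u_lower") = f.U.t(), Rcpp::Named("l") = f.L.t(),
      Rcpp::Named("per_step_per_dim") = f.Lmat.t(),
      Rcpp::Named("nll") = f.nll, Rcpp::Named("mse") = f.mse,
      Rcpp::Named("pb_activity") = tanh(pb_q));
}

// [[Rcpp::export]]
Rcpp::List cpp_gradients(Rcpp::List params, double tau, double vfloor,
                         double vcap, arma::mat X, arma::vec pb_q) {
  Net net = unpack(params, tau, vfloor, vcap);
  Fwd f = forward(net, X, pb_q, false);
  Grads g = backward(net, X, pb_q, f);
  // gradients of masked-out entries are identically zero by the mask contract
  g.gWxl %= Rcpp::as<mat>(params["M_xl"]);
  g.gWpl %= Rcpp::as<mat>(params["M_pl"]);
  g.gWlm %= Rcpp::as<mat>(params["M_lm"]);
  g.gWlv %= Rcpp::as<mat>(params["M_lv"]);
  return Rcpp::List::create(
      Rcpp::Named("W_xl") = g.gWxl, Rcpp::Named("W_ll") = g.gWll,
      Rcpp::Named("W_pl") = g.gWpl, Rcpp::Named("W_lm") = g.gWlm,
      Rcpp::Named("W_lv") = g.gWlv, Rcpp::Named("a_mean") = g.ga_m,
      Rcpp::Named("a_var") = g.ga_v, Rcpp::Named("pb") = g.gq,
      Rcpp::Named("nll") = f.nll);
}

// Full-batch training: network structure (masked weights, output biases) and
// one PB internal-state vector per sequence are optimized jointly against the
// summed NLL; lower-level thresholds a_lower stay fixed.
// [[Rcpp::export]]
Rcpp::List cpp_train(Rcpp::List params, double tau, double vfloor, double vcap,
                     Rcpp::List X_list, arma::mat PBq, int epochs, double lr,
                     double b1, double b2) {
  const int S = X_list.size();
  mat Mxl = Rcpp::as<mat>(params["M_xl"]), Mpl = Rcpp::as<mat>(params["M_pl"]),
      Mlm = Rcpp::as<mat>(params["M_lm"]), Mlv = Rcpp::as<mat>(params["M_lv"]);
  mat Wxl = Rcpp::as<mat>(params["W_xl"]) % Mxl;
  mat Wll = Rcpp::as<mat>(params["W_ll"]);
  mat Wpl = Rcpp::as<mat>(params["W_pl"]) % Mpl;
  mat Wlm = Rcpp::as<mat>(params["W_lm"]) % Mlm;
  mat Wlv = Rcpp::as<mat>(params["W_lv"]) % Mlv;
  vec a_low = Rcpp::as<vec>(params["a_lower"]);
  mat a_m = Rcpp::as<vec>(params["a_mean"]);  // as mat for the adam helper
  mat a_v = Rcpp::as<vec>(params["a_var"]);

  std::vector<mat> Xs(S);
  for (int s = 0; s < S; ++s) Xs[s] = Rcpp::as<mat>(X_list[s]);

  // Adam moment buffers
  mat mWxl(size(Wxl), fill::zeros), vWxl = mWxl;
  mat mWll(size(Wll), fill::zeros), vWll = mWll;
  mat mWpl(size(Wpl), fill::zeros), vWpl = mWpl;
  mat mWlm(size(Wlm), fill::zeros), vWlm = mWlm;
  mat mWlv(size(Wlv), fill::zeros), vWlv = mWlv;
  mat mam(size(a_m), fill::zeros), vam = mam;
  mat mav(size(a_v), fill::zeros), vav = mav;
  mat mPB(size(PBq), fill::zeros), vPB = mPB;

  vec curve_mse(epochs > 0 ? epochs : 1, fill::zeros);
  vec curve_nll = curve_mse;

  Net net;
  net.tau = tau; net.vfloor = vfloor; net.vcap = vcap;
  net.a_low = a_low;

  for (int ep = 0; ep < epochs; ++ep) {
    net.Wxl = Wxl; net.Wll = Wll; net.Wpl = Wpl;
    net.Wlm = Wlm; net.Wlv = Wlv;
    net.a_m = a_m.col(0); net.a_v = a_v.col(0);
    mat gWxl(size(Wxl), fill::zeros), gWll(size(Wll), fill::zeros),
        gWpl(size(Wpl), fill::zeros), gWlm(size(Wlm), fill::zeros),
        gWlv(size(Wlv), fill::zeros);
    vec ga_m(a_m.n_rows, fill::zeros), ga_v(a_v.n_rows, fill::zeros);
    mat gPB(size(PBq), fill::zeros);
    double mse_sum = 0.0, nll_sum = 0.0;
    for (int s = 0; s < S; ++s) {
      vec q = PBq.row(s).t();
      Fwd f = forward(net, Xs[s], q, false);
      Grads g = backward(net, Xs[s], q, f);
      gWxl += g.gWxl; gWll += g.gWll; gWpl += g.gWpl;
      gWlm += g.gWlm; gWlv += g.gWlv;
      ga_m += g.ga_m; ga_v += g.ga_v;
      gPB.row(s) = g.gq.t();
      mse_sum += f.mse; nll_sum += f.nll;
    }
    if (!std::isfinite(nll_sum))
      Rcpp::stop("training diverged (non-finite loss) at epoch %d", ep + 1);
    curve_mse(ep) = mse_sum / S;
    curve_nll(ep) = nll_sum / S;
    gWxl %= Mxl; gWpl %= Mpl; gWlm %= Mlm; gWlv %= Mlv;
    const int step = ep + 1;
    adam(Wxl, gWxl, mWxl, vWxl, lr, b1, b2, step);
    adam(Wll, gWll, mWll, vWll, lr, b1, b2, step);
    adam(Wpl, gWpl, mWpl, vWpl, lr, b1, b2, step);
    adam(Wlm, gWlm, mWlm, vWlm, lr, b1, b2, step);
    adam(Wlv, gWlv, mWlv, vWlv, lr, b1, b2, step);
    adam(a_m, ga_m, mam, vam, lr, b1, b2, step);
    adam(a_v, ga_v, mav, vav, lr, b1, b2, step);
    adam(PBq, gPB, mPB, vPB, lr, b1, b2, step);
    Wxl %= Mxl; Wpl %= Mpl; Wlm %= Mlm; Wlv %= Mlv;  // keep masked entries 0
    if (ep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  // final per-sequence fit with the trained parameters
  net.Wxl = Wxl; net.Wll = Wll; net.Wpl = Wpl; net.Wlm = Wlm; net.Wlv = Wlv;
  net.a_m = a_m.col(0); net.a_v = a_v.col(0);
  vec final_mse(S), final_nll(S);
  for (int s = 0; s < S; ++s) {
    Fwd f = forward(net, Xs[s], vec(PBq.row(s).t()), false);
    final_mse(s) = f.mse; final_nll(s) = f.nll;
  }

  Rcpp::List out_params = Rcpp::clone(params);
  out_params["W_xl"] = Wxl; out_params["W_ll"] = Wll; out_params["W_pl"] = Wpl;
  out_params["W_lm"] = Wlm; out_params["W_lv"] = Wlv;
  out_params["a_mean"] = vec(a_m.col(0)); out_params["a_var"] = vec(a_v.col(0));
  return Rcpp::List::create(
      Rcpp::Named("params") = out_params, Rcpp::Named("pb_internal") = PBq,
      Rcpp::Named("curve_mse") = curve_mse, Rcpp::Named("curve_nll") = curve_nll,
      Rcpp::Named("final_mse") = final_mse, Rcpp::Named("final_nll") = final_nll);
}

// Recognition: optimize only one sequence's PB internal state; the network
// structure is read but never written.
// [[Rcpp::export]]
Rcpp::List cpp_infer_pb(Rcpp::List params, double tau, double vfloor,
                        double vcap, arma::mat X, arma::vec q0, int epochs,
                        double lr, double b1, double b2) {
  Net net = unpack(params, tau, vfloor, vcap);
  vec q = q0;
  mat m1(size(q), fill::zeros), m2 = m1;
  vec curve(epochs > 0 ? epochs : 1, fill::zeros);
  for (int ep = 0; ep < epochs; ++ep) {
    Fwd f = forward(net, X, q, false);
    if (!std::isfinite(f.nll))
      Rcpp::stop("PB inference diverged (non-finite loss) at epoch %d", ep + 1);
    curve(ep) = f.mse;
    Grads g = backward(net, X, q, f);
    mat qm(q), gm(g.gq);
    adam(qm, gm, m1, m2, lr, b1, b2, ep + 1);
    q = qm.col(0);
  }
  Fwd f = forward(net, X, q, false);
  if (epochs <= 0) curve(0) = f.mse;
  return Rcpp::List::create(
      Rcpp::Named("pb_internal") = q, Rcpp::Named("pb_activity") = tanh(q),
      Rcpp::Named("mse") = f.mse, Rcpp::Named("nll") = f.nll,
      Rcpp::Named("curve_mse") = curve);
}
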