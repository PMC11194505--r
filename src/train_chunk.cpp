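// Fused inner training loop: explicit Euler integration of the E-I rate
// dynamics, Hebbian weight increments from the post-step rates, optional
// autapse exclusion, synapse-type-specific divisive normalization, the
// classic (unnormalized) inhibitory rule, and restoration of statically
// tuned rows.  One call advances a chunk of stimulus presentations; all
// bookkeeping (snapshots, convergence checks, histories) stays in R.
//
// The operation order matches the exported R reference operations
// euler_step() and competitive_plasticity_step() exactly.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// a * max(0, u - b)^n, elementwise; a and b are per-neuron vectors
static arma::vec rate_fun(const arma::vec& u, const arma::vec& a,
                          const arma::vec& b, double n) {
  arma::vec v = u - b;
  v.for_each([](arma::vec::elem_type& x) { if (x < 0) x = 0; });
  if (n == 1.0) return a % v;
  if (n == 2.0) return a % (v % v);
  return a % arma::pow(v, n);
}

static bool bad(const arma::vec& u) {
  return !u.is_finite() || (u.n_elem > 0 && arma::abs(u).max() > 1e6);
}

// [[Rcpp::export(name = ".train_chunk_cpp")]]
List train_chunk_cpp(List Wlist, const arma::mat& rF_chunk,
                     int steps_per_stim, List par) {
  arma::mat W_EE = as<arma::mat>(Wlist["W_EE"]);
  arma::mat W_EI = as<arma::mat>(Wlist["W_EI"]);
  arma::mat W_EF = as<arma::mat>(Wlist["W_EF"]);
  arma::mat W_IE = as<arma::mat>(Wlist["W_IE"]);
  arma::mat W_II = as<arma::mat>(Wlist["W_II"]);
  arma::mat W_IF = as<arma::mat>(Wlist["W_IF"]);

  arma::vec uE = as<arma::vec>(par["uE"]);
  arma::vec uI = as<arma::vec>(par["uI"]);
  arma::vec rE = as<arma::vec>(par["rE"]);
  arma::vec rI = as<arma::vec>(par["rI"]);

  const arma::vec aE = as<arma::vec>(par["aE"]);
  const arma::vec bE = as<arma::vec>(par["bE"]);
  const double nE = as<double>(par["nE"]);
  const arma::vec aI = as<arma::vec>(par["aI"]);
  const arma::vec bI = as<arma::vec>(par["bI"]);
  const double nI = as<double>(par["nI"]);
  const double kE = as<double>(par["kE"]);
  const double kI = as<double>(par["kI"]);

  const double eEE = as<double>(par["eEE"]), eEI = as<double>(par["eEI"]),
               eEF = as<double>(par["eEF"]), eIE = as<double>(par["eIE"]),
               eII = as<double>(par["eII"]), eIF = as<double>(par["eIF"]);
  const bool pEE = eEE > 0, pEI = eEI > 0, pEF = eEF > 0,
             pIE = eIE > 0, pII = eII > 0, pIF = eIF > 0;
  const bool clamp = as<bool>(par["clamp"]);
  const bool exaut = as<bool>(par["exclude_autapses"]);
  const bool NIpos = W_II.n_rows > 0;

  // norms < 0 encode "no normalization for this pool"
  const double nrmE = as<double>(par["nEE"]), nrmI = as<double>(par["nIE"]),
               nrmEI = as<double>(par["nEI"]), nrmII = as<double>(par["nII"]);
  const bool normE = nrmE > 0 && (pEE || pEF);
  const bool normI = NIpos && nrmI > 0 && (pIE || pIF);
  const bool normEI = pEI && nrmEI > 0;
  const bool normII = NIpos && pII && nrmII > 0;

  const bool classic = as<bool>(par["classic"]);
  const double ceps = as<double>(par["classic_eps_dt"]);
  const double r0 = as<double>(par["r0"]);

  const arma::uvec staticE = as<arma::uvec>(par["static_E"]);  // 0-based
  const arma::uvec staticI = as<arma::uvec>(par["static_I"]);
  arma::mat W_EF_static, W_IF_static;
  if (staticE.n_elem > 0) W_EF_static = as<arma::mat>(par["W_EF_static"]);
  if (staticI.n_elem > 0) W_IF_static = as<arma::mat>(par["W_IF_static"]);

  const int n_stim = rF_chunk.n_rows;
  int div_stim = 0, div_step = 0;
  bool diverged = false;
  double mean_rE_acc = 0.0;

  for (int s = 0; s < n_stim && !diverged; ++s) {
    const arma::vec rF = rF_chunk.row(s).t();
    for (int k = 0; k < steps_per_stim; ++k) {
      const arma::vec& rId = clamp ? rF : rI;
      arma::vec uE_new = uE + kE * (W_EF * rF + W_EE * rE - W_EI * rId - uE);
      if (!clamp && NIpos)
        uI = uI + kI * (W_IF * rF + W_IE * rE - W_II * rI - uI);
      uE = uE_new;
      rE = rate_fun(uE, aE, bE, nE);
      if (clamp) rI = rF;
      else if (NIpos) rI = rate_fun(uI, aI, bI, nI);
      if (bad(uE) || (NIpos && !clamp && bad(uI))) {
        diverged = true; div_stim = s + 1; div_step = k + 1;
        break;
      }
      if (pEE) W_EE += eEE * (rE * rE.t());
      if (pEI) W_EI += eEI * (rE * rId.t());
      if (pEF) W_EF += eEF * (rE * rF.t());
      if (NIpos) {
        if (pIE) W_IE += eIE * (rI * rE.t());
        if (pII) W_II += eII * (rI * rI.t());
        if (pIF) W_IF += eIF * (rI * rF.t());
      }
      if (exaut) {
        if (pEE) W_EE.diag().zeros();
        if (pII) W_II.diag().zeros();
      }
      if (normE) {
        arma::vec pooled = arma::sum(W_EE, 1);
        if (pEF) pooled += arma::sum(W_EF, 1);
        arma::vec sc = nrmE / pooled;
        sc.elem(arma::find(pooled <= 0)).ones();
        W_EE.each_col() %= sc;
        if (pEF) W_EF.each_col() %= sc;
      }
      if (normI) {
        arma::vec pooled = arma::sum(W_IE, 1);
        if (pIF) pooled += arma::sum(W_IF, 1);
        arma::vec sc = nrmI / pooled;
        sc.elem(arma::find(pooled <= 0)).ones();
        W_IE.each_col() %= sc;
        if (pIF) W_IF.each_col() %= sc;
      }
      if (normEI) {
        arma::vec rs = arma::sum(W_EI, 1);
        arma::vec sc = nrmEI / rs;
        sc.elem(arma::find(rs <= 0)).ones();
        W_EI.each_col() %= sc;
      }
      if (normII) {
        arma::vec rs = arma::sum(W_II, 1);
        arma::vec sc = nrmII / rs;
        sc.elem(arma::find(rs <= 0)).ones();
        W_II.each_col() %= sc;
      }
      if (classic) {
        W_EI += ceps * ((rE - r0) * rId.t());
        W_EI.for_each([](arma::mat::elem_type& x) { if (x < 0) x = 0; });
      }
      if (staticE.n_elem > 0) {
        W_EF.rows(staticE) = W_EF_static;
        W_EE.rows(staticE).zeros();
        if (NIpos) W_EI.rows(staticE).zeros();
      }
      if (staticI.n_elem > 0) {
        W_IF.rows(staticI) = W_IF_static;
        if (W_IE.n_cols > 0) W_IE.rows(staticI).zeros();
        W_II.rows(staticI).zeros();
      }
    }
    if (!diverged && rE.n_elem > 0) mean_rE_acc += arma::mean(rE);
  }

  return List::create(
    _["W_EE"] = W_EE, _["W_EI"] = W_EI, _["W_EF"] = W_EF,
    _["W_IE"] = W_IE, _["W_II"] = W_II, _["W_IF"] = W_IF,
    _["uE"] = uE, _["uI"] = uI, _["rE"] = rE, _["rI"] = rI,
    _["diverged"] = diverged, _["div_stim"] = div_stim,
    _["div_step"] = div_step, _["mean_rE_acc"] = mean_rE_acc,
    _["n_done"] = diverged ? div_stim : n_stim);
}
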