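#' Hebbian weight increment
#'
#' The plain Hebbian rate rule `dW_AB/dt = eps_AB * r_A r_B^T`, discretized
#' with the Euler factor `dt`: `delta = dt * eps * outer(r_post, r_pre)`.
#' The increment is a non-negative rank-<=1 matrix.
#'
#' @param r_post,r_pre Non-negative rate vectors of the post- and
#'   presynaptic populations.
#' @param eps Scalar learning rate (1/ms).
#' @param dt Integration step (ms).
#' @return Matrix of weight increments (`length(r_post) x length(r_pre)`).
#' @export
#' @examples
#' hebbian_delta(1, c(2, 3), eps = 0.1, dt = 1) # 0.2 0.3
hebbian_delta <- function(r_post, r_pre, eps, dt) {
  (dt * eps) * tcrossprod(r_post, r_pre)
}

#' Divisive normalization of the pooled excitatory inputs
#'
#' Rescales each postsynaptic neuron's excitatory inputs so that the sum of
#' its recurrent excitatory row and its plastic feedforward row equals the
#' excitatory resource norm, leaving relative proportions within the row
#' unchanged:
#' `w_AB(ij) <- W_AE * w_AB(ij) / (sum_j w_AE(ij) + sum_k w_AF(ik))`.
#' A row whose pooled sum is zero carries no resource to redistribute and is
#' left unchanged (with a warning unless `warn = FALSE`).
#'
#' @param W_AE Recurrent excitatory block (rows = postsynaptic neurons).
#' @param W_AF Plastic feedforward block sharing the pool, or `NULL` if the
#'   pool consists of the recurrent block alone.
#' @param norm Positive pooled norm.
#' @param warn Emit a warning for all-zero rows (default `TRUE`).
#' @return List with the rescaled `W_AE` and `W_AF`.
#' @export
normalize_excitatory_pool <- function(W_AE, W_AF = NULL, norm, warn = TRUE) {
  if (nrow(W_AE) == 0) return(list(W_AE = W_AE, W_AF = W_AF))
  pooled <- rowSums(W_AE)
  if (!is.null(W_AF)) pooled <- pooled + rowSums(W_AF)
  zero <- pooled <= 0
  if (any(zero) && warn)
    warning(sprintf("%d row(s) with zero pooled excitatory weight left unchanged",
                    sum(zero)), call. = FALSE)
  scale <- norm / pooled
  scale[zero] <- 1
  list(W_AE = W_AE * scale, W_AF = if (is.null(W_AF)) NULL else W_AF * scale)
}

#' Divisive normalization of inhibitory inputs
#'
#' Rescales each postsynaptic neuron's inhibitory row to the inhibitory
#' resource norm: `w_AI(ij) <- W_AI * w_AI(ij) / sum_j w_AI(ij)`.
#' Inhibitory synapses draw on their own pool, separate from the excitatory
#' one.  Zero rows are left unchanged (with a warning unless `warn = FALSE`).
#'
#' @param W_AI Inhibitory block (rows = postsynaptic neurons).
#' @param norm Positive norm.
#' @param warn Emit a warning for all-zero rows (default `TRUE`).
#' @return The rescaled matrix.
#' @export
normalize_inhibitory <- function(W_AI, norm, warn = TRUE) {
  if (nrow(W_AI) == 0 || ncol(W_AI) == 0) return(W_AI)
  rs <- rowSums(W_AI)
  zero <- rs <= 0
  if (any(zero) && warn)
    warning(sprintf("%d row(s) with zero inhibitory weight left unchanged",
                    sum(zero)), call. = FALSE)
  scale <- norm / rs
  scale[zero] <- 1
  W_AI * scale
}

#' One synapse-type-specific competitive plasticity step
#'
#' Applies, to every plastic block, the Hebbian increment computed from the
#' current rates, re-zeroes the autapse diagonals, and then renormalizes:
#' the pooled excitatory inputs of each population to their excitatory norm
#' and the inhibitory inputs to their inhibitory norm.  Blocks with a zero
#' learning rate are static and untouched; a static feedforward block is
#' additionally excluded from the excitatory pool.
#'
#' @param s A [network_state()] holding the post-update rates.
#' @param rF Feedforward rate vector.
#' @param w A [weight_set()].
#' @param rates A [learning_rates()] object (0 = static block).
#' @param norms A [weight_norms()] object.
#' @param dt Integration step (ms).
#' @param exclude_autapses Re-zero diagonals of `W_EE`, `W_II` before
#'   normalizing (default `TRUE`).
#' @param warn Warn on zero pooled rows (default `FALSE`: during training,
#'   rows that have not yet received any Hebbian mass are silently skipped).
#' @return The updated [weight_set()].
#' @export
competitive_plasticity_step <- function(s, rF, w, rates, norms, dt,
                                        exclude_autapses = TRUE, warn = FALSE) {
  NE <- nrow(w$W_EE); NI <- nrow(w$W_II)
  ff_plastic_E <- rates$eps_EF > 0
  ff_plastic_I <- rates$eps_IF > 0
  if (rates$eps_EE > 0) w$W_EE <- w$W_EE + hebbian_delta(s$rE, s$rE, rates$eps_EE, dt)
  if (rates$eps_EI > 0) w$W_EI <- w$W_EI + hebbian_delta(s$rE, s$rI, rates$eps_EI, dt)
  if (ff_plastic_E)     w$W_EF <- w$W_EF + hebbian_delta(s$rE, rF, rates$eps_EF, dt)
  if (NI > 0) {
    if (rates$eps_IE > 0) w$W_IE <- w$W_IE + hebbian_delta(s$rI, s$rE, rates$eps_IE, dt)
    if (rates$eps_II > 0) w$W_II <- w$W_II + hebbian_delta(s$rI, s$rI, rates$eps_II, dt)
    if (ff_plastic_I)     w$W_IF <- w$W_IF + hebbian_delta(s$rI, rF, rates$eps_IF, dt)
  }
  if (exclude_autapses) {
    if (NE > 0) diag(w$W_EE) <- 0
    if (NI > 0) diag(w$W_II) <- 0
  }
  if (!is.null(norms$W_EE) && (rates$eps_EE > 0 || ff_plastic_E)) {
    r <- normalize_excitatory_pool(w$W_EE, if (ff_plastic_E) w$W_EF else NULL,
                                   norms$W_EE, warn = warn)
    w$W_EE <- r$W_AE
    if (ff_plastic_E) w$W_EF <- r$W_AF
  }
  if (NI > 0 && !is.null(norms$W_IE) && (rates$eps_IE > 0 || ff_plastic_I)) {
    r <- normalize_excitatory_pool(w$W_IE, if (ff_plastic_I) w$W_IF else NULL,
                                   norms$W_IE, warn = warn)
    w$W_IE <- r$W_AE
    if (ff_plastic_I) w$W_IF <- r$W_AF
  }
  if (rates$eps_EI > 0 && !is.null(norms$W_EI))
    w$W_EI <- normalize_inhibitory(w$W_EI, norms$W_EI, warn = warn)
  if (NI > 0 && rates$eps_II > 0 && !is.null(norms$W_II))
    w$W_II <- normalize_inhibitory(w$W_II, norms$W_II, warn = warn)
  w
}

#' Classic homeostatic inhibitory plasticity step
#'
#' The target-rate rule `dw_EI/dt = eps_EI * (r_E - r0) * r_I`, discretized
#' with the Euler factor and *not* normalized: inhibitory growth under this
#' rule is bounded only by its self-limiting effect on the postsynaptic
#' rate.  Entries driven below zero are clipped at zero (Dale's law).
#'
#' @param rE,rI Rate vectors of the postsynaptic excitatory and presynaptic
#'   inhibitory populations.
#' @param W_EI Current inhibitory-to-excitatory block.
#' @param p A [classic_inhib_params()] object.
#' @param dt Integration step (ms).
#' @return The updated `W_EI` matrix.
#' @export
classic_inhibitory_step <- function(rE, rI, W_EI, p, dt) {
  pmax(W_EI + (dt * p$eps_EI) * tcrossprod(rE - p$r0, rI), 0)
}

#' Parameters of the classic inhibitory plasticity rule
#'
#' @param r0 Target postsynaptic firing rate, `>= 0`.
#' @param eps_EI Learning rate (1/ms), `>= 0`.
#' @return An object of class `"classic_inhib_params"`.
#' @export
classic_inhib_params <- function(r0, eps_EI) {
  if (r0 < 0) stop("target rate r0 must be >= 0", call. = FALSE)
  if (eps_EI < 0) stop("eps_EI must be >= 0", call. = FALSE)
  structure(list(r0 = r0, eps_EI = eps_EI), class = "classic_inhib_params")
}
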