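#' Network dimensions
#'
#' Sizes of the three neural populations: `NE` recurrent excitatory neurons,
#' `NI` recurrent inhibitory neurons and `NF` feedforward input neurons.
#' `NI = 0` yields a purely feedforward excitatory circuit; `NE = 0` an
#' inhibition-only circuit.
#'
#' @param NE,NI,NF Non-negative integer counts. `NE + NI >= 1`, `NF >= 1`.
#' @return An object of class `"network_dims"`.
#' @export
#' @examples
#' network_dims(NE = 10, NI = 10, NF = 40)
network_dims <- function(NE, NI, NF) {
  for (v in list(NE, NI, NF)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop("NE, NI, NF must be single non-negative integers", call. = FALSE)
  }
  if (NE + NI < 1L) stop("need at least one recurrent neuron (NE + NI >= 1)", call. = FALSE)
  if (NF < 1L) stop("need at least one input neuron (NF >= 1)", call. = FALSE)
  structure(list(NE = as.integer(NE), NI = as.integer(NI), NF = as.integer(NF)),
            class = "network_dims")
}

#' Rectified power-law activation parameters
#'
#' Parameters of the rate function `f(u) = a * max(0, u - b)^n`: gain `a`,
#' threshold `b` (potential units) and exponent `n`. `n = 1, b = 0` gives a
#' rectified-linear unit, which on non-negative drive behaves linearly.
#' `a` and `b` may be vectors (one entry per neuron) to give individual
#' neurons different gains or thresholds.
#'
#' @param a Gain, `> 0` (scalar or per-neuron vector).
#' @param b Threshold (scalar or per-neuron vector).
#' @param n Exponent, `> 0`.
#' @return An object of class `"activation_params"`.
#' @export
activation_params <- function(a = 1, b = 0, n = 1) {
  if (any(a <= 0)) stop("gain a must be > 0", call. = FALSE)
  if (n <= 0) stop("exponent n must be > 0", call. = FALSE)
  structure(list(a = a, b = b, n = n), class = "activation_params")
}

#' Rate-dynamics parameters
#'
#' Membrane time constants of the excitatory (`tau_E`) and inhibitory
#' (`tau_I`) populations and the Euler integration step `dt`, all in
#' milliseconds.
#'
#' @param tau_E,tau_I,dt Positive scalars (ms).
#' @return An object of class `"dynamics_params"`.
#' @export
dynamics_params <- function(tau_E, tau_I = tau_E, dt) {
  if (tau_E <= 0 || tau_I <= 0 || dt <= 0)
    stop("tau_E, tau_I and dt must all be > 0", call. = FALSE)
  structure(list(tau_E = tau_E, tau_I = tau_I, dt = dt), class = "dynamics_params")
}

#' Weight initialization specification
#'
#' Initial synaptic weights are drawn from a normal distribution with mean
#' `mu_W` and standard deviation `sigma_W`; negative draws are replaced by
#' their absolute value so all weights start non-negative.  By default all
#' weights of recurrent excitatory origin (both the E-to-E and the E-to-I
#' block) are then zeroed before the one-shot setup normalization, so the
#' untrained network is dominated by feedforward input; `zero_recurrent_E`
#' can restrict this to the E-to-E block or disable it.  Autapses (diagonals
#' of the E-to-E and I-to-I blocks) are excluded (held at zero) by default.
#'
#' @param mu_W Mean of the initial draw. The presets use `mu_W = 2 * sigma_W`.
#' @param sigma_W Standard deviation of the draw, `>= 0`.
#' @param zero_recurrent_E One of `"both"` (zero E-to-E and E-to-I recurrent
#'   blocks, the default), `"EE_only"`, or `"none"`.
#' @param exclude_autapses Keep self-connections at zero (default `TRUE`).
#' @return An object of class `"init_spec"`.
#' @export
init_spec <- function(mu_W, sigma_W, zero_recurrent_E = c("both", "EE_only", "none"),
                      exclude_autapses = TRUE) {
  zero_recurrent_E <- match.arg(zero_recurrent_E)
  if (sigma_W < 0) stop("sigma_W must be >= 0", call. = FALSE)
  structure(list(mu_W = mu_W, sigma_W = sigma_W,
                 zero_recurrent_E = zero_recurrent_E,
                 exclude_autapses = isTRUE(exclude_autapses)),
            class = "init_spec")
}

#' Hebbian learning rates
#'
#' One scalar learning rate per synapse-type block, in 1/ms.  A rate of 0
#' freezes the block (it is treated as static and receives no Hebbian
#' updates).  Block names follow the postsynaptic-first convention:
#' `eps_EI` is the rate of inhibitory-to-excitatory synapses.
#'
#' @param eps_EE,eps_IE,eps_EI,eps_II,eps_EF,eps_IF Non-negative scalars (1/ms).
#' @return An object of class `"learning_rates"`.
#' @export
learning_rates <- function(eps_EE = 0, eps_IE = 0, eps_EI = 0, eps_II = 0,
                           eps_EF = 0, eps_IF = 0) {
  r <- list(eps_EE = eps_EE, eps_IE = eps_IE, eps_EI = eps_EI,
            eps_II = eps_II, eps_EF = eps_EF, eps_IF = eps_IF)
  if (any(unlist(r) < 0)) stop("learning rates must be >= 0", call. = FALSE)
  structure(r, class = "learning_rates")
}

#' Synaptic resource pools (weight norms)
#'
#' Total synaptic weight maintained per postsynaptic neuron, one pool per
#' synapse type.  `W_EE` / `W_IE` are the *pooled excitatory* norms of
#' excitatory / inhibitory neurons: they cover the recurrent excitatory
#' inputs together with the plastic feedforward inputs of that neuron, which
#' jointly compete for the same resource.  `W_EI` / `W_II` are the inhibitory
#' norms.  `W_EF` / `W_IF` are only used for feedforward blocks that are
#' static: such blocks are normalized once per row at setup and are excluded
#' from the pooled excitatory normalization thereafter.
#'
#' @param W_EE,W_IE Pooled excitatory norms (per postsynaptic E / I neuron).
#' @param W_EI,W_II Inhibitory norms.
#' @param W_EF,W_IF Norms for static feedforward rows (or `NULL`).
#' @return An object of class `"weight_norms"`.
#' @export
weight_norms <- function(W_EE = NULL, W_IE = NULL, W_EI = NULL, W_II = NULL,
                         W_EF = NULL, W_IF = NULL) {
  n <- list(W_EE = W_EE, W_IE = W_IE, W_EI = W_EI, W_II = W_II,
            W_EF = W_EF, W_IF = W_IF)
  for (nm in names(n)) {
    if (!is.null(n[[nm]]) && n[[nm]] <= 0)
      stop(sprintf("norm %s must be > 0 (or NULL if unused)", nm), call. = FALSE)
  }
  structure(n, class = "weight_norms")
}

#' Orientation tuning of the feedforward input population
#'
#' Input neurons are tuned to orientations `theta_F`, by default evenly
#' spaced on `[0, 180)` degrees, with Gaussian tuning width `sigma_F`
#' (degrees) and maximum firing rate `A_F` at 100% contrast.
#'
#' @param NF Number of input neurons (ignored if `theta_F` is given).
#' @param sigma_F Tuning width in degrees, `> 0`.
#' @param A_F Maximum firing rate, `> 0`.
#' @param theta_F Optional explicit vector of preferred orientations (degrees).
#' @return An object of class `"input_tuning"`.
#' @export
#' @examples
#' input_tuning(NF = 10, sigma_F = 20, A_F = 1)
input_tuning <- function(NF, sigma_F, A_F, theta_F = NULL) {
  if (is.null(theta_F)) theta_F <- seq(0, 180, length.out = NF + 1L)[seq_len(NF)]
  if (sigma_F <= 0) stop("sigma_F must be > 0", call. = FALSE)
  if (A_F <= 0) stop("A_F must be > 0", call. = FALSE)
  structure(list(theta_F = theta_F, sigma_F = sigma_F, A_F = A_F),
            class = "input_tuning")
}

#' Training protocol
#'
#' Describes the stimulus stream used during training.  For
#' `kind = "gratings"` single oriented gratings with orientations sampled
#' uniformly on `[0, 180)` degrees are each presented for
#' `stimulus_duration` ms at contrast `contrast`.  `kind = "ensemble"`
#' presents the rows of a user-supplied pattern matrix (one input-rate
#' pattern per row) in order, recycling if necessary.
#' `kind = "center_surround"` draws per-region gratings according to a
#' [center_surround_layout()].
#'
#' @param n_stimuli Number of stimulus presentations (hard cap when
#'   convergence-monitored stopping is enabled).
#' @param stimulus_duration Presentation time per stimulus in ms (default 200).
#' @param contrast Stimulus contrast used during training.
#' @param kind One of `"gratings"`, `"ensemble"`, `"center_surround"`.
#' @param patterns For `kind = "ensemble"`: numeric matrix, one pattern per row.
#' @return An object of class `"training_protocol"`.
#' @export
training_protocol <- function(n_stimuli, stimulus_duration = 200, contrast = 1,
                              kind = c("gratings", "ensemble", "center_surround"),
                              patterns = NULL) {
  kind <- match.arg(kind)
  if (n_stimuli < 0) stop("n_stimuli must be >= 0", call. = FALSE)
  if (stimulus_duration <= 0) stop("stimulus_duration must be > 0", call. = FALSE)
  if (contrast < 0) stop("contrast must be >= 0", call. = FALSE)
  if (kind == "ensemble") {
    if (is.null(patterns)) stop("kind = 'ensemble' requires a pattern matrix", call. = FALSE)
    patterns <- as.matrix(patterns)
  }
  structure(list(n_stimuli = as.integer(n_stimuli),
                 stimulus_duration = stimulus_duration,
                 contrast = contrast, kind = kind, patterns = patterns),
            class = "training_protocol")
}

#' Center/surround input layout
#'
#' Splits the input channels and the recurrent neurons into two disjoint
#' regions ("center" and "surround"), each with its own copy of the input
#' tuning.  During training the two regions are stimulated either with the
#' same orientation on every trial (`mode = "correlated"`) or one region is
#' chosen uniformly at random and stimulated while the other receives zero
#' input (`mode = "independent"`).
#'
#' @param mode `"correlated"` or `"independent"`.
#' @param NF_region Input channels per region (total `NF = 2 * NF_region`).
#' @param NE_region,NI_region Recurrent neurons per region.
#' @return An object of class `"center_surround_layout"`.
#' @export
center_surround_layout <- function(mode = c("correlated", "independent"),
                                   NF_region, NE_region, NI_region) {
  mode <- match.arg(mode)
  structure(list(mode = mode, NF_region = as.integer(NF_region),
                 NE_region = as.integer(NE_region), NI_region = as.integer(NI_region)),
            class = "center_surround_layout")
}

#' @export
print.network_dims <- function(x, ...) {
  cat(sprintf("network dimensions: NE = %d, NI = %d, NF = %d\n", x$NE, x$NI, x$NF))
  invisible(x)
}
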