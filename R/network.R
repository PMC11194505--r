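#' Rectified power-law rate function
#'
#' Maps membrane potentials to firing rates via
#' `f(u) = a * max(0, u - b)^n`.  Total function: any real input is valid
#' and the output is always non-negative.
#'
#' @param u Numeric vector of membrane potentials.
#' @param act An [activation_params()] object.
#' @return Numeric vector of firing rates, `>= 0`.
#' @export
#' @examples
#' rectified_power_activation(5, activation_params(a = 0.04, b = 0, n = 2)) # 1
rectified_power_activation <- function(u, act) {
  act$a * pmax(0, u - act$b)^act$n
}

#' Construct a network state
#'
#' Membrane potentials and firing rates of the excitatory and inhibitory
#' populations at one time step.  Rates are recomputed from the potentials
#' so the invariant `r = f(u)` holds by construction.
#'
#' @param uE,uI Numeric potential vectors (lengths `NE`, `NI`).
#' @param act_E,act_I [activation_params()] for the two populations.
#' @param rI_clamp Optional: clamp the inhibitory rates to this vector
#'   instead of computing them from `uI` (used when the inhibitory units are
#'   input-mirroring units whose activity is set equal to the feedforward
#'   rates).
#' @return An object of class `"network_state"` with fields `uE, uI, rE, rI`.
#' @export
network_state <- function(uE, uI, act_E, act_I, rI_clamp = NULL) {
  rI <- if (is.null(rI_clamp)) rectified_power_activation(uI, act_I) else rI_clamp
  structure(list(uE = uE, uI = uI,
                 rE = rectified_power_activation(uE, act_E), rI = rI),
            class = "network_state")
}

#' Zero initial state
#'
#' Potentials start at zero; rates follow from the activation function.
#'
#' @param dims A [network_dims()] object.
#' @inheritParams network_state
#' @return A `"network_state"`.
#' @export
zero_state <- function(dims, act_E, act_I) {
  network_state(numeric(dims$NE), numeric(dims$NI), act_E, act_I)
}

empty_weight_block <- function(nr, nc) matrix(0, nr, nc)

#' Construct a weight set
#'
#' The six synaptic weight matrices `W_AB` between postsynaptic population
#' `A` and presynaptic population `B`, with `A` in `{E, I}` and `B` in
#' `{E, I, F}`.  All entries are non-negative (Dale's law by construction:
#' inhibition enters the dynamics with an explicit minus sign).
#'
#' @param W_EE,W_EI,W_EF,W_IE,W_II,W_IF Non-negative matrices with shapes
#'   consistent with `dims` (`W_EE` is `NE x NE`, `W_EI` is `NE x NI`, ...).
#'   Missing blocks default to zero matrices.
#' @param dims A [network_dims()] object.
#' @return An object of class `"weight_set"`: a named list of the six
#'   matrices with the dimensions stored as an attribute.
#' @export
weight_set <- function(dims, W_EE = NULL, W_EI = NULL, W_EF = NULL,
                       W_IE = NULL, W_II = NULL, W_IF = NULL) {
  shp <- list(W_EE = c(dims$NE, dims$NE), W_EI = c(dims$NE, dims$NI),
              W_EF = c(dims$NE, dims$NF), W_IE = c(dims$NI, dims$NE),
              W_II = c(dims$NI, dims$NI), W_IF = c(dims$NI, dims$NF))
  given <- list(W_EE = W_EE, W_EI = W_EI, W_EF = W_EF,
                W_IE = W_IE, W_II = W_II, W_IF = W_IF)
  w <- lapply(names(shp), function(nm) {
    m <- given[[nm]]
    if (is.null(m)) return(empty_weight_block(shp[[nm]][1], shp[[nm]][2]))
    m <- as.matrix(m)
    if (!all(dim(m) == shp[[nm]]))
      stop(sprintf("%s must be %d x %d, got %d x %d", nm,
                   shp[[nm]][1], shp[[nm]][2], nrow(m), ncol(m)), call. = FALSE)
    if (any(m < 0)) stop(sprintf("%s has negative entries", nm), call. = FALSE)
    m
  })
  names(w) <- names(shp)
  structure(w, dims = dims, class = "weight_set")
}

#' Draw and normalize initial weights
#'
#' Entries are drawn `N(mu_W, sigma_W)` with negatives replaced by their
#' absolute value, recurrent excitatory-origin blocks optionally zeroed,
#' autapse diagonals zeroed, and the synapse-type-specific one-shot
#' normalization applied: each postsynaptic neuron's pooled excitatory row
#' (recurrent E plus plastic feedforward) is scaled to its excitatory norm
#' and each inhibitory row to its inhibitory norm.  Deterministic given the
#' R random seed in effect.
#'
#' Draw order is fixed (`W_EE, W_EI, W_EF, W_IE, W_II, W_IF`, column-major
#' within each block) so runs are reproducible.
#'
#' @param dims A [network_dims()] object.
#' @param spec An [init_spec()] object.
#' @param norms A [weight_norms()] object.
#' @param ff_static_E,ff_static_I Logical: treat the feedforward block onto
#'   E (resp. I) as static, i.e. exclude it from the pooled excitatory
#'   normalization and instead normalize its rows once to `W_EF` / `W_IF`.
#' @return A [weight_set()].
#' @export
initialize_weights <- function(dims, spec, norms,
                               ff_static_E = FALSE, ff_static_I = FALSE) {
  draw <- function(nr, nc) {
    if (nr == 0 || nc == 0) return(empty_weight_block(nr, nc))
    abs(matrix(stats::rnorm(nr * nc, spec$mu_W, spec$sigma_W), nr, nc))
  }
  W_EE <- draw(dims$NE, dims$NE); W_EI <- draw(dims$NE, dims$NI)
  W_EF <- draw(dims$NE, dims$NF); W_IE <- draw(dims$NI, dims$NE)
  W_II <- draw(dims$NI, dims$NI); W_IF <- draw(dims$NI, dims$NF)
  if (spec$zero_recurrent_E %in% c("both", "EE_only")) W_EE[] <- 0
  if (spec$zero_recurrent_E == "both") W_IE[] <- 0
  if (spec$exclude_autapses) {
    if (dims$NE > 0) diag(W_EE) <- 0
    if (dims$NI > 0) diag(W_II) <- 0
  }
  # one-shot setup normalization, mirroring the per-step rule
  if (!is.null(norms$W_EE)) {
    r <- normalize_excitatory_pool(W_EE, if (ff_static_E) NULL else W_EF,
                                   norms$W_EE, warn = FALSE)
    W_EE <- r$W_AE
    if (!ff_static_E) W_EF <- r$W_AF
  }
  if (!is.null(norms$W_IE) && dims$NI > 0) {
    r <- normalize_excitatory_pool(W_IE, if (ff_static_I) NULL else W_IF,
                                   norms$W_IE, warn = FALSE)
    W_IE <- r$W_AE
    if (!ff_static_I) W_IF <- r$W_AF
  }
  if (!is.null(norms$W_EI) && dims$NI > 0)
    W_EI <- normalize_inhibitory(W_EI, norms$W_EI, warn = FALSE)
  if (!is.null(norms$W_II) && dims$NI > 0)
    W_II <- normalize_inhibitory(W_II, norms$W_II, warn = FALSE)
  if (ff_static_E && !is.null(norms$W_EF))
    W_EF <- normalize_inhibitory(W_EF, norms$W_EF, warn = FALSE)
  if (ff_static_I && !is.null(norms$W_IF) && dims$NI > 0)
    W_IF <- normalize_inhibitory(W_IF, norms$W_IF, warn = FALSE)
  weight_set(dims, W_EE = W_EE, W_EI = W_EI, W_EF = W_EF,
             W_IE = W_IE, W_II = W_II, W_IF = W_IF)
}

#' One explicit Euler step of the rate dynamics
#'
#' Integrates `tau_A du_A/dt = -u_A + W_AF rF + W_AE rE - W_AI rI` for both
#' populations with the explicit scheme: the drive is evaluated at the
#' incoming state's rates, then rates are recomputed from the new
#' potentials.  With `dt = tau` a step replaces each potential by its drive.
#'
#' @param s A [network_state()].
#' @param w A [weight_set()].
#' @param rF Feedforward rate vector (length `NF`, `>= 0`).
#' @param dyn A [dynamics_params()] object.
#' @param act_E,act_I [activation_params()] for the two populations.
#' @param clamp_I If `TRUE`, the inhibitory units mirror the input: their
#'   rates equal the current `rF` (requires `NI == NF`), both in the drive
#'   and in the returned state, and their potentials are not integrated.
#' @return The new `"network_state"`.
#' @export
euler_step <- function(s, w, rF, dyn, act_E, act_I, clamp_I = FALSE) {
  if (length(rF) != ncol(w$W_EF))
    stop(sprintf("rF has length %d, expected %d", length(rF), ncol(w$W_EF)),
         call. = FALSE)
  rI_drive <- if (clamp_I) rF else s$rI
  driveE <- drop(w$W_EF %*% rF) + drop(w$W_EE %*% s$rE) - drop(w$W_EI %*% rI_drive)
  uE <- s$uE + (dyn$dt / dyn$tau_E) * (driveE - s$uE)
  if (clamp_I) {
    network_state(uE, s$uI, act_E, act_I, rI_clamp = rF)
  } else {
    uI <- s$uI
    if (length(uI) > 0) {
      driveI <- drop(w$W_IF %*% rF) + drop(w$W_IE %*% s$rE) - drop(w$W_II %*% s$rI)
      uI <- uI + (dyn$dt / dyn$tau_I) * (driveI - uI)
    }
    network_state(uE, uI, act_E, act_I)
  }
}

#' Integrate the dynamics for a fixed duration
#'
#' Repeats [euler_step()] for `floor(duration / dt)` steps under a constant
#' input vector, optionally recording the per-step rates.  Aborts with an
#' error naming the step if any potential becomes non-finite or exceeds
#' `1e6` in magnitude (runaway recurrent excitation).
#'
#' @inheritParams euler_step
#' @param duration Integration time in ms, `>= dt`.
#' @param record If `TRUE`, also return matrices `rE_trace`, `rI_trace`
#'   (steps x neurons).
#' @return The final `"network_state"`; if `record = TRUE`, a list with
#'   fields `state`, `rE_trace`, `rI_trace`.
#' @export
run_to_steady_state <- function(s, w, rF, dyn, act_E, act_I, duration,
                                clamp_I = FALSE, record = FALSE) {
  n_steps <- floor(duration / dyn$dt)
  if (n_steps < 1) stop("duration must be >= dt", call. = FALSE)
  if (record) {
    trE <- matrix(NA_real_, n_steps, length(s$uE))
    trI <- matrix(NA_real_, n_steps, length(s$rI))
  }
  for (k in seq_len(n_steps)) {
    s <- euler_step(s, w, rF, dyn, act_E, act_I, clamp_I = clamp_I)
    if (any(!is.finite(s$uE)) || any(!is.finite(s$uI)) ||
        any(abs(s$uE) > 1e6) || any(abs(s$uI) > 1e6))
      stop(sprintf("dynamics diverged at step %d (|u| > 1e6 or non-finite)", k),
           call. = FALSE)
    if (record) { trE[k, ] <- s$rE; trI[k, ] <- s$rI }
  }
  if (record) list(state = s, rE_trace = trE, rI_trace = trI) else s
}

#' Steady state of the linearized network by direct solve
#'
#' For a linear rate function `r = u` the fixed point of the dynamics
#' solves `(I - M) u = h` where `M` stacks the recurrent blocks with signs
#' `[W_EE, -W_EI; W_IE, -W_II]` and `h = [W_EF; W_IF] rF`.  Used as an
#' independent oracle for the simulated steady state.
#'
#' @inheritParams euler_step
#' @return List with potential vectors `uE`, `uI`.
#' @export
linear_steady_state <- function(w, rF) {
  NE <- nrow(w$W_EE); NI <- nrow(w$W_II)
  M <- rbind(cbind(w$W_EE, -w$W_EI), cbind(w$W_IE, -w$W_II))
  h <- c(drop(w$W_EF %*% rF), if (NI > 0) drop(w$W_IF %*% rF) else numeric(0))
  u <- solve(diag(NE + NI) - M, h)
  list(uE = u[seq_len(NE)], uI = if (NI > 0) u[NE + seq_len(NI)] else numeric(0))
}
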