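#' Uncentered second-moment matrix of a pattern ensemble
#'
#' `C = <y y^T>`, the temporal average of the outer products of the input
#' patterns, taken *uncentered* exactly as the linear theory defines it.
#' Callers wanting centered statistics must center the ensemble first.
#'
#' @param ensemble Numeric matrix, one pattern per row (`patterns x channels`).
#' @return Symmetric positive semidefinite `channels x channels` matrix.
#' @export
second_moment <- function(ensemble) {
  ensemble <- as.matrix(ensemble)
  if (nrow(ensemble) < 2) stop("need at least 2 patterns", call. = FALSE)
  crossprod(ensemble) / nrow(ensemble)
}

#' Modified covariance matrix of a paired E/I input ensemble
#'
#' The block matrix governing the joint drift of excitatory and inhibitory
#' weight vectors under synapse-type-specific competitive Hebbian learning
#' with a linear rate function:
#' `Cbar = [[<yE yE^T>, -<yE yI^T>], [<yI yE^T>, -<yI yI^T>]]`.
#' The sign structure reflects that inhibitory input enters the postsynaptic
#' drive with a minus sign while Hebbian growth of both synapse types is
#' driven by the same postsynaptic rate.
#'
#' @param ensemble_E Excitatory input patterns (`patterns x nE` matrix).
#' @param ensemble_I Inhibitory input patterns (`patterns x nI` matrix) with
#'   the same number of rows; if `NULL`, the inhibitory stream is clamped to
#'   the excitatory one (`yI = yE`).
#' @return An object of class `"modified_covariance"`: list with the full
#'   block matrix `Cbar`, the blocks `C_EE, C_EI, C_IE, C_II` (unsigned
#'   moments), and the block sizes `nE`, `nI`.
#' @export
modified_covariance <- function(ensemble_E, ensemble_I = NULL) {
  YE <- as.matrix(ensemble_E)
  YI <- if (is.null(ensemble_I)) YE else as.matrix(ensemble_I)
  if (nrow(YE) != nrow(YI))
    stop("ensemble_E and ensemble_I must have the same number of patterns",
         call. = FALSE)
  if (nrow(YE) < 2) stop("need at least 2 patterns", call. = FALSE)
  n <- nrow(YE)
  C_EE <- crossprod(YE) / n
  C_EI <- crossprod(YE, YI) / n
  C_IE <- crossprod(YI, YE) / n
  C_II <- crossprod(YI) / n
  Cbar <- rbind(cbind(C_EE, -C_EI), cbind(C_IE, -C_II))
  structure(list(Cbar = Cbar, C_EE = C_EE, C_EI = C_EI, C_IE = C_IE,
                 C_II = C_II, nE = ncol(YE), nI = ncol(YI)),
            class = "modified_covariance")
}

#' Expected weight drift under the linearized competitive dynamics
#'
#' Evaluates `<d wbar/dt> \propto Cbar wbar - (gamma * wE; rho * wI)` for a
#' stacked weight configuration `wbar = (wE; wI)`.  The normalization
#' multipliers `gamma` and `rho` are the block-wise mean Hebbian drive
#' divided by the block's total weight, the unique scalars for which the
#' drift sums to zero within each block, i.e. for which the L1 norms of the
#' two synapse types are preserved under the flow.
#'
#' @param wE,wI Excitatory and inhibitory weight vectors.
#' @param mc A [modified_covariance()] object.
#' @return List with fields `drift_E`, `drift_I`, `drift` (stacked),
#'   `gamma`, `rho`.
#' @export
expected_drift <- function(wE, wI, mc) {
  if (length(wE) != mc$nE || length(wI) != mc$nI)
    stop("weight vector lengths do not match the covariance blocks", call. = FALSE)
  v <- drop(mc$Cbar %*% c(wE, wI))
  vE <- v[seq_len(mc$nE)]
  vI <- v[mc$nE + seq_len(mc$nI)]
  gamma <- if (sum(wE) != 0) sum(vE) / sum(wE) else 0
  rho <- if (sum(wI) != 0) sum(vI) / sum(wI) else 0
  dE <- vE - gamma * wE
  dI <- vI - rho * wI
  list(drift_E = dE, drift_I = dI, drift = c(dE, dI), gamma = gamma, rho = rho)
}

#' Effective attraction of an input mode
#'
#' An input mode's effective attraction is its feedforward attraction plus
#' the eigencircuit attraction contributed by the recurrently connected
#' neurons tuned to it: excitatory rate variances add, inhibitory rate
#' variances subtract:
#' `lambda_eff = lambda_ff + sum(var_E) - sum(var_I)`.
#' With unit rate variances this reduces to `lambda_eig = nE - nI`.
#'
#' @param lambda_ff Feedforward attraction of the mode.
#' @param var_E,var_I Vectors of rate variances of the excitatory and
#'   inhibitory neurons in the eigencircuit (possibly empty).
#' @return An object of class `"eigencircuit_summary"`: list with
#'   `lambda_ff`, `var_E`, `var_I`, `lambda_eig`, `lambda_eff`.
#' @export
#' @examples
#' effective_attraction(1, var_E = c(0.3, 0.2), var_I = 0.4)$lambda_eff # 1.1
effective_attraction <- function(lambda_ff, var_E = numeric(0), var_I = numeric(0)) {
  if (any(var_E < 0) || any(var_I < 0))
    stop("rate variances must be >= 0", call. = FALSE)
  lambda_eig <- sum(var_E) - sum(var_I)
  structure(list(lambda_ff = lambda_ff, var_E = var_E, var_I = var_I,
                 lambda_eig = lambda_eig, lambda_eff = lambda_ff + lambda_eig),
            class = "eigencircuit_summary")
}

#' Tuning-collapse condition
#'
#' In the linear theory, the collapse of all tuning curves onto a single
#' input mode is prevented when the population-level inhibitory rate
#' variance outweighs the excitatory one:
#' `NE * mean_var_E < NI * mean_var_I` (strict inequality; the equality
#' case counts as not prevented).
#'
#' @param NE,NI Neuron counts, `>= 0`.
#' @param mean_var_E,mean_var_I Average rate variances, `>= 0`.
#' @return List with logical fields `collapse_prevented` and
#'   `collapse_predicted` (its negation).
#' @export
collapse_predicted <- function(NE, NI, mean_var_E, mean_var_I) {
  if (NE < 0 || NI < 0 || mean_var_E < 0 || mean_var_I < 0)
    stop("counts and variances must be >= 0", call. = FALSE)
  prevented <- (NE * mean_var_E) < (NI * mean_var_I)
  list(collapse_prevented = prevented, collapse_predicted = !prevented)
}

#' Principal eigenvector of a symmetric matrix
#'
#' Unit-norm eigenvector of the largest eigenvalue, with the sign fixed so
#' that the largest-magnitude component is positive.  A degenerate
#' (repeated, within relative tolerance) leading eigenvalue is reported via
#' the `degenerate` attribute rather than silently resolved.
#'
#' @param M Symmetric numeric matrix.
#' @param tol Relative tolerance for degeneracy detection.
#' @return Unit-norm numeric vector with attribute `degenerate` (logical).
#' @export
principal_eigenvector <- function(M, tol = 1e-10) {
  M <- as.matrix(M)
  if (!isSymmetric(M, tol = 1e-8))
    stop("matrix must be symmetric", call. = FALSE)
  e <- eigen(M, symmetric = TRUE)
  v <- e$vectors[, 1]
  i <- which.max(abs(v))
  if (v[i] < 0) v <- -v
  scale <- max(abs(e$values), 1)
  degenerate <- nrow(M) > 1 && (e$values[1] - e$values[2]) <= tol * scale
  attr(v, "degenerate") <- degenerate
  v
}

#' Steady-state rate statistics over a stimulus ensemble
#'
#' Presents each stimulus (a row of `rF_matrix`) to a fixed network, runs
#' the dynamics to steady state, and returns the per-neuron mean and
#' variance of the steady-state rates across stimuli.  These rate variances
#' are the quantities entering [effective_attraction()] and
#' [collapse_predicted()].
#'
#' @param w A [weight_set()].
#' @param rF_matrix Stimulus matrix, one input-rate pattern per row.
#' @param dyn,act_E,act_I Dynamics and activation parameters.
#' @param settle Settling time in ms (default `20 * tau_E`).
#' @param clamp_I Mirror the input in the inhibitory units (see
#'   [euler_step()]).
#' @return List with `rE` (stimuli x NE rate matrix), `rI`, `mean_E`,
#'   `mean_I`, `var_E`, `var_I` (population variances, denominator `n`).
#' @export
rate_statistics <- function(w, rF_matrix, dyn, act_E, act_I,
                            settle = 20 * dyn$tau_E, clamp_I = FALSE) {
  rF_matrix <- as.matrix(rF_matrix)
  dims <- attr(w, "dims")
  n <- nrow(rF_matrix)
  RE <- matrix(NA_real_, n, dims$NE)
  RI <- matrix(NA_real_, n, if (clamp_I) dims$NF else dims$NI)
  for (k in seq_len(n)) {
    s <- zero_state(dims, act_E, act_I)
    s <- run_to_steady_state(s, w, rF_matrix[k, ], dyn, act_E, act_I,
                             duration = settle, clamp_I = clamp_I)
    RE[k, ] <- s$rE
    if (ncol(RI) > 0) RI[k, ] <- s$rI
  }
  pvar <- function(X) if (ncol(X) == 0) numeric(0) else
    colMeans(X^2) - colMeans(X)^2
  list(rE = RE, rI = RI, mean_E = colMeans(RE),
       mean_I = if (ncol(RI) > 0) colMeans(RI) else numeric(0),
       var_E = pvar(RE), var_I = pvar(RI))
}
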