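#' Circular orientation distance
#'
#' Shortest distance between two orientations around a circle of
#' circumference 180 degrees.  Inputs are reduced modulo 180; the result
#' lies in `[0, 90]`.
#'
#' @param t1,t2 Orientations in degrees (vectors recycle).
#' @return Distance in degrees.
#' @export
#' @examples
#' circular_distance(10, 170) # 20
circular_distance <- function(t1, t2) {
  d <- abs(t1 - t2) %% 180
  pmin(d, 180 - d)
}

#' Population response to an oriented grating
#'
#' Input neurons respond to a grating of orientation `theta` and contrast
#' `c` with a Gaussian profile of the circular distance to their preferred
#' orientation: `rF_j = c * A_F * exp(-|theta, theta_F_j|^2 / (2 sigma_F^2))`.
#'
#' @param theta Grating orientation in degrees.
#' @param contrast Grating contrast, `>= 0`.
#' @param tuning An [input_tuning()] object.
#' @return Rate vector of length `NF`.
#' @export
#' @examples
#' tun <- input_tuning(NF = 10, sigma_F = 20, A_F = 1)
#' grating_response(30, 1, tun)
grating_response <- function(theta, contrast, tuning) {
  d <- circular_distance(theta, tuning$theta_F)
  contrast * tuning$A_F * exp(-d^2 / (2 * tuning$sigma_F^2))
}

#' Superpose several gratings at the input stage
#'
#' The input-population response to a compound stimulus (e.g. a plaid of a
#' test and a mask grating) is the sum of the individual grating responses.
#' Any sublinearity in the *network* response to the compound stimulus is
#' then attributable to the recurrent dynamics, not to the input model.
#'
#' @param stims List of stimuli, each a list with fields `theta`, `contrast`.
#' @param tuning An [input_tuning()] object.
#' @return Rate vector of length `NF`.
#' @export
compose_stimuli <- function(stims, tuning) {
  if (length(stims) < 1) stop("need at least one stimulus", call. = FALSE)
  Reduce(`+`, lapply(stims, function(s) grating_response(s$theta, s$contrast, tuning)))
}

#' Sample a training stream of oriented gratings
#'
#' Orientations are drawn i.i.d. uniform on `[0, 180)` degrees; each
#' stimulus is held for the protocol's `stimulus_duration`.  Reproducible
#' under the R random seed in effect.
#'
#' @param protocol A [training_protocol()] object.
#' @return Data frame with columns `trial`, `theta`, `contrast`.
#' @export
sample_training_stream <- function(protocol) {
  n <- protocol$n_stimuli
  data.frame(trial = seq_len(n),
             theta = if (n > 0) stats::runif(n, 0, 180) else numeric(0),
             contrast = rep(protocol$contrast, n))
}

#' Sample a center/surround training stream
#'
#' In `"correlated"` mode both regions receive the same orientation on
#' every trial.  In `"independent"` mode one region is chosen uniformly at
#' random and stimulated while the other receives zero input (`NA`
#' orientation, zero contrast).
#'
#' @param layout A [center_surround_layout()] object.
#' @param protocol A [training_protocol()] object.
#' @return Data frame with columns `trial`, `theta_center`,
#'   `contrast_center`, `theta_surround`, `contrast_surround`.
#' @export
center_surround_stream <- function(layout, protocol) {
  n <- protocol$n_stimuli
  theta <- if (n > 0) stats::runif(n, 0, 180) else numeric(0)
  cc <- rep(protocol$contrast, n)
  if (layout$mode == "correlated") {
    data.frame(trial = seq_len(n), theta_center = theta, contrast_center = cc,
               theta_surround = theta, contrast_surround = cc)
  } else {
    pick_center <- if (n > 0) stats::runif(n) < 0.5 else logical(0)
    data.frame(trial = seq_len(n),
               theta_center = ifelse(pick_center, theta, NA_real_),
               contrast_center = ifelse(pick_center, cc, 0),
               theta_surround = ifelse(pick_center, NA_real_, theta),
               contrast_surround = ifelse(pick_center, 0, cc))
  }
}

#' Static Gaussian feedforward weights from assigned preferred orientations
#'
#' Builds feedforward weight rows `W_AF(ij) = exp(-|theta_hat_i, theta_F_j|^2
#' / (2 sigma_theta^2))`, then scales each row to sum to `norm`.  Used when
#' the feedforward tuning of recurrent neurons is fixed rather than learned.
#'
#' @param theta_hat Assigned preferred orientations of the postsynaptic
#'   neurons (degrees).
#' @param tuning An [input_tuning()] object (supplies `theta_F`).
#' @param sigma_theta Width of the Gaussian connectivity profile (degrees).
#' @param norm Row-sum norm (or `NULL` to skip normalization).
#' @return Matrix `length(theta_hat) x NF`.
#' @export
static_feedforward_weights <- function(theta_hat, tuning, sigma_theta, norm = NULL) {
  D <- outer(theta_hat, tuning$theta_F, circular_distance)
  W <- exp(-D^2 / (2 * sigma_theta^2))
  if (!is.null(norm)) W <- W * (norm / rowSums(W))
  W
}

#' Evenly spaced preferred orientations
#'
#' `n` orientations evenly distributed on `[0, 180)` degrees, the standard
#' assignment for both input channels and statically tuned neurons.
#'
#' @param n Number of orientations.
#' @return Numeric vector of length `n`.
#' @export
even_orientations <- function(n) seq(0, 180, length.out = n + 1L)[seq_len(n)]
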