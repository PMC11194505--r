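#' Tuning uniformity of a feedforward weight matrix
#'
#' Measures how evenly a population's total feedforward weight is spread
#' across the input neurons.  With `p_j` the share of input neuron `j` in
#' the total weight (`p_j = sum_i w(ij) / sum_ij w(ij)`), the uniformity is
#' the normalized Shannon entropy `U = -sum_j p_j log p_j / log(NF)`:
#' 1 when every input neuron carries the same total weight, 0 when all
#' weight is concentrated on a single input neuron.  `0 * log 0` is taken
#' as 0.
#'
#' @param W_AF Non-negative feedforward weight matrix (rows = postsynaptic
#'   neurons, columns = input neurons, `NF >= 2`) with positive total.
#' @return Scalar in `[0, 1]`.
#' @export
#' @examples
#' tuning_uniformity(matrix(1, 4, 10)) # 1
tuning_uniformity <- function(W_AF) {
  W_AF <- as.matrix(W_AF)
  if (any(W_AF < 0)) stop("weights must be non-negative", call. = FALSE)
  total <- sum(W_AF)
  if (total <= 0) stop("tuning uniformity undefined for an all-zero matrix",
                       call. = FALSE)
  NF <- ncol(W_AF)
  if (NF < 2) stop("need at least 2 input neurons", call. = FALSE)
  p <- colSums(W_AF) / total
  p <- p[p > 0]
  -sum(p * log(p)) / log(NF)
}

#' Column-mass shares of a feedforward weight matrix
#'
#' The normalized total synaptic output weight of each input neuron onto
#' the postsynaptic population (the distribution whose entropy
#' [tuning_uniformity()] normalizes).
#'
#' @inheritParams tuning_uniformity
#' @return Non-negative vector of length `NF` summing to 1.
#' @export
output_weight_share <- function(W_AF) {
  total <- sum(W_AF)
  if (total <= 0) stop("undefined for an all-zero matrix", call. = FALSE)
  colSums(as.matrix(W_AF)) / total
}

#' Preferred orientations by peak steady-state response
#'
#' Probes the network with single gratings on an orientation grid, runs the
#' dynamics to steady state for each, and assigns every neuron the grid
#' orientation of its peak response.  Ties (e.g. a perfectly flat response
#' of an untrained neuron) are broken toward the smallest angle.
#'
#' @param w A [weight_set()].
#' @param tuning An [input_tuning()] object.
#' @param dyn,act_E,act_I Dynamics and activation parameters.
#' @param grid Probe orientations in degrees (default 1-degree resolution).
#' @param contrast Probe contrast (default 1).
#' @param settle Settling time in ms (default `20 * tau_E`).
#' @param clamp_I Mirror the input in the inhibitory units.
#' @return List of class `"preferred_orientations"` with fields `E`, `I`
#'   (degree vectors), `responses_E`, `responses_I` (grid x neuron rate
#'   matrices), `grid`, `contrast`.
#' @export
preferred_orientations.weight_set <- function(w, tuning, dyn, act_E, act_I,
                                   grid = seq(0, 179, by = 1), contrast = 1,
                                   settle = 20 * dyn$tau_E, clamp_I = FALSE) {
  rF <- t(vapply(grid, function(th) grating_response(th, contrast, tuning),
                 numeric(length(tuning$theta_F))))
  st <- rate_statistics(w, rF, dyn, act_E, act_I, settle = settle,
                        clamp_I = clamp_I)
  argmax <- function(R) {
    if (ncol(R) == 0) return(numeric(0))
    grid[apply(R, 2, which.max)]  # which.max returns the first (smallest-angle) tie
  }
  structure(list(E = argmax(st$rE), I = argmax(st$rI),
                 responses_E = st$rE, responses_I = st$rI,
                 grid = grid, contrast = contrast),
            class = "preferred_orientations")
}

#' Connectivity as a function of preferred-orientation difference
#'
#' Averages the weights of a recurrent block within bins of the signed
#' circular difference `delta = theta_hat_post - theta_hat_pre` (mapped to
#' `[-90, 90)`), normalized by the block's largest weight.  Autapse
#' diagonal entries are excluded when pre- and postsynaptic populations are
#' the same size and `exclude_diagonal = TRUE`.  Empty bins are recorded as
#' `NA`, not zero.
#'
#' @param W Weight block (rows = postsynaptic, columns = presynaptic).
#' @param theta_hat_pre,theta_hat_post Preferred orientations (degrees).
#' @param n_bins Number of equal bins partitioning `[-90, 90)` (default 18).
#' @param exclude_diagonal Drop self-connections for square blocks.
#' @return Data frame with columns `bin_center`, `mean_weight`
#'   (normalized), `n_pairs`.
#' @export
connectivity_vs_delta_theta <- function(W, theta_hat_pre, theta_hat_post,
                                        n_bins = 18, exclude_diagonal = TRUE) {
  W <- as.matrix(W)
  wmax <- max(W)
  delta <- outer(theta_hat_post, theta_hat_pre,
                 function(a, b) ((a - b + 90) %% 180) - 90)
  keep <- matrix(TRUE, nrow(W), ncol(W))
  if (exclude_diagonal && nrow(W) == ncol(W)) diag(keep) <- FALSE
  breaks <- seq(-90, 90, length.out = n_bins + 1L)
  idx <- findInterval(delta[keep], breaks, rightmost.closed = FALSE,
                      all.inside = FALSE)
  idx[idx > n_bins] <- n_bins  # delta = 90 cannot occur; guard rounding
  wn <- if (wmax > 0) W[keep] / wmax else W[keep]
  mw <- vapply(seq_len(n_bins), function(b) {
    v <- wn[idx == b]
    if (length(v) == 0) NA_real_ else mean(v)
  }, numeric(1))
  np <- vapply(seq_len(n_bins), function(b) sum(idx == b), numeric(1))
  data.frame(bin_center = (breaks[-1] + breaks[-(n_bins + 1L)]) / 2,
             mean_weight = mw, n_pairs = np)
}

#' Excitatory/inhibitory input decomposition
#'
#' Splits the drive onto each excitatory neuron at a given network state
#' into its total excitatory part (feedforward plus recurrent, reported
#' separately as well) and its inhibitory part.  At a steady state of the
#' dynamics the difference of the two equals the membrane potential.
#'
#' @param s A [network_state()].
#' @param w A [weight_set()].
#' @param rF Feedforward rate vector.
#' @return Data frame with one row per excitatory neuron and columns
#'   `exc_ffwd`, `exc_rec`, `exc_total`, `inh`.
#' @export
ei_input_decomposition <- function(s, w, rF) {
  ff <- drop(w$W_EF %*% rF)
  rec <- drop(w$W_EE %*% s$rE)
  inh <- drop(w$W_EI %*% s$rI)
  data.frame(exc_ffwd = ff, exc_rec = rec, exc_total = ff + rec, inh = inh)
}

#' Count local maxima of a circular profile
#'
#' A value is a local maximum if it is strictly greater than its circular
#' neighbours; flat plateaus count once.  Used to check unimodality of
#' learned tuning curves over the ring of input preferences.
#'
#' @param x Numeric vector interpreted as samples around a circle.
#' @return Integer count of local maxima.
#' @export
count_circular_peaks <- function(x) {
  n <- length(x)
  if (n < 3) return(as.integer(n > 0))
  # collapse exact plateaus so each counts as one candidate
  r <- rle(x)
  v <- r$values
  m <- length(v)
  if (m == 1) return(1L)
  left <- v[c(m, seq_len(m - 1))]
  right <- v[c(seq_len(m - 1) + 1, 1)]
  sum(v > left & v > right)
}
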