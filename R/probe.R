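# Build the input-rate vector for one probe stimulus description.
probe_input <- function(fit, row) {
  cfg <- fit$config
  if (!is.null(cfg$layout)) {
    m <- cfg$layout$NF_region
    tun <- input_tuning(m, cfg$sigma_F, cfg$A_F, theta_F = even_orientations(m))
    part <- function(theta, contrast) {
      if (is.na(contrast) || contrast <= 0 || is.na(theta)) numeric(m)
      else grating_response(theta, contrast, tun)
    }
    c(part(row$theta_center, row$contrast_center),
      part(row$theta_surround, row$contrast_surround))
  } else {
    stims <- list(list(theta = row$theta, contrast = row$contrast))
    if (!is.null(row$mask_theta) && !is.na(row$mask_theta) &&
        !is.null(row$mask_contrast) && row$mask_contrast > 0)
      stims <- c(stims, list(list(theta = row$mask_theta,
                                  contrast = row$mask_contrast)))
    compose_stimuli(stims, fit$tuning)
  }
}

#' Steady-state response of a trained network to a raw input vector
#'
#' Integrates the (frozen-weight) dynamics from rest under a constant
#' input-rate vector and returns the settled state.
#'
#' @param fit A fitted [hebbnet()] object.
#' @param rF Input-rate vector of length `NF`.
#' @param settle Settling time in ms (default `20 * tau_E`).
#' @return A [network_state()].
#' @export
probe_response <- function(fit, rF, settle = 20 * fit$dyn$tau_E) {
  s <- zero_state(fit$dims, fit$act_E, fit$act_I)
  run_to_steady_state(s, fit$weights, rF, fit$dyn, fit$act_E, fit$act_I,
                      duration = settle, clamp_I = fit$config$clamp_I)
}

#' Predict steady-state responses to probe stimuli
#'
#' Runs the trained network (weights frozen) to steady state for each probe
#' stimulus and returns the firing rates.
#'
#' For standard fits `newdata` has columns `theta` and `contrast`, plus
#' optional `mask_theta` / `mask_contrast` for a superimposed plaid mask.
#' For center/surround fits it has columns `theta_center`,
#' `contrast_center`, `theta_surround`, `contrast_surround` (use `NA` / `0`
#' to leave a region unstimulated).
#'
#' @param object A fitted [hebbnet()] object.
#' @param newdata Data frame of probe stimuli (one per row).
#' @param population `"E"` or `"I"`: which population's rates to return.
#' @param settle Settling time in ms (default `20 * tau_E`).
#' @param ... Unused.
#' @return Matrix of steady-state rates, `nrow(newdata) x N`.
#' @export
predict.hebbnet <- function(object, newdata, population = c("E", "I"),
                            settle = 20 * object$dyn$tau_E, ...) {
  population <- match.arg(population)
  n <- nrow(newdata)
  N <- if (population == "E") object$dims$NE else
    if (object$config$clamp_I) object$dims$NF else object$dims$NI
  out <- matrix(NA_real_, n, N)
  for (i in seq_len(n)) {
    s <- probe_response(object, probe_input(object, newdata[i, , drop = FALSE]),
                        settle = settle)
    out[i, ] <- if (population == "E") s$rE else s$rI
  }
  out
}

#' Surround suppression curves
#'
#' Probes a center/surround-trained network with a center grating of fixed
#' (by default 100%) contrast and a surround grating of increasing
#' contrast, either iso-oriented or cross-oriented (orthogonal) to the
#' center stimulus, and reports the mean steady-state rate of the
#' center-tuned excitatory population.
#'
#' @param fit A fitted [hebbnet()] with a center/surround layout.
#' @param surround_contrasts Increasing non-negative contrast grid.
#' @param condition `"iso"`, `"cross"`, or both.
#' @param center_theta Center grating orientation (degrees).
#' @param center_contrast Center grating contrast (default 1 = 100%).
#' @param settle Settling time in ms.
#' @return Data frame with columns `condition`, `surround_contrast`,
#'   `response` (mean center-population excitatory rate).
#' @export
suppression_curves <- function(fit, surround_contrasts = seq(0, 1, by = 0.25),
                               condition = c("iso", "cross"),
                               center_theta = 90, center_contrast = 1,
                               settle = 20 * fit$dyn$tau_E) {
  if (is.null(fit$config$layout))
    stop("suppression_curves requires a center/surround fit", call. = FALSE)
  condition <- match.arg(condition, several.ok = TRUE)
  ne <- fit$config$layout$NE_region
  center_idx <- seq_len(ne)
  out <- list()
  for (cond in condition) {
    th_s <- if (cond == "iso") center_theta else (center_theta + 90) %% 180
    resp <- vapply(surround_contrasts, function(cs) {
      nd <- data.frame(theta_center = center_theta,
                       contrast_center = center_contrast,
                       theta_surround = th_s, contrast_surround = cs)
      mean(predict(fit, nd, settle = settle)[1, center_idx])
    }, numeric(1))
    out[[cond]] <- data.frame(condition = cond,
                              surround_contrast = surround_contrasts,
                              response = resp)
  }
  do.call(rbind, out)
}

#' Contrast-response curves under a superimposed mask
#'
#' Steady-state response of one excitatory neuron to a test grating of
#' increasing contrast, with a cross-oriented mask grating superimposed at
#' each of several fixed mask contrasts.  By default the probed neuron is
#' the one whose preferred orientation (assigned or measured) is closest to
#' the test orientation.
#'
#' @param fit A fitted [hebbnet()] object (standard, non-region layout).
#' @param test_theta,mask_theta Orientations of test and mask gratings.
#' @param test_contrasts Increasing test-contrast grid.
#' @param mask_contrasts Mask contrast levels (0 = no mask).
#' @param neuron Index of the probed excitatory neuron, or `NULL` to pick
#'   the neuron tuned closest to `test_theta`.
#' @param settle Settling time in ms.
#' @return Data frame with columns `test_contrast`, `mask_contrast`,
#'   `response`, plus the probed `neuron` as an attribute.
#' @export
contrast_response <- function(fit, test_theta = 45, mask_theta = 135,
                              test_contrasts = seq(0, 1, by = 0.125),
                              mask_contrasts = c(0, 0.25, 0.5),
                              neuron = NULL, settle = 20 * fit$dyn$tau_E) {
  if (is.null(neuron)) {
    th <- fit$theta_hat_E
    neuron <- which.min(circular_distance(th, test_theta))
  }
  grid <- expand.grid(test_contrast = test_contrasts,
                      mask_contrast = mask_contrasts)
  resp <- vapply(seq_len(nrow(grid)), function(i) {
    nd <- data.frame(theta = test_theta, contrast = grid$test_contrast[i],
                     mask_theta = mask_theta,
                     mask_contrast = grid$mask_contrast[i])
    predict(fit, nd, settle = settle)[1, neuron]
  }, numeric(1))
  out <- data.frame(grid, response = resp)
  attr(out, "neuron") <- neuron
  out
}

#' Semi-saturation contrast of a contrast-response curve
#'
#' The contrast at which the response first reaches half of the curve's
#' maximum, linearly interpolated between grid points.  A rightward shift
#' of this value under increasing mask contrast is the signature of
#' divisive normalization.
#'
#' @param contrast Increasing contrast grid.
#' @param response Responses at those contrasts.
#' @return Interpolated semi-saturation contrast (scalar), or `NA` if the
#'   curve never reaches half its maximum above the starting response.
#' @export
semi_saturation_contrast <- function(contrast, response) {
  half <- max(response) / 2
  if (response[1] >= half) return(contrast[1])
  above <- which(response >= half)
  if (length(above) == 0) return(NA_real_)
  i <- above[1]
  c0 <- contrast[i - 1]; c1 <- contrast[i]
  r0 <- response[i - 1]; r1 <- response[i]
  if (r1 == r0) return(c1)
  c0 + (half - r0) / (r1 - r0) * (c1 - c0)
}

#' Check conservation of the synaptic resource pools
#'
#' Computes, for every postsynaptic neuron with plastic inputs, the pooled
#' excitatory row sum and the inhibitory row sum, and returns the largest
#' relative deviation from the configured norms.
#'
#' @param w A [weight_set()].
#' @param norms A [weight_norms()] object.
#' @param ff_in_pool_E,ff_in_pool_I Whether the feedforward block is part
#'   of the pooled excitatory norm (i.e. plastic).
#' @param exclude_E,exclude_I Row indices of static neurons to skip.
#' @param check_EI Include the inhibitory-onto-E pool (set `FALSE` under
#'   the classic unnormalized rule).
#' @return Largest relative deviation (scalar, `>= 0`).
#' @export
norm_conservation <- function(w, norms, ff_in_pool_E = TRUE, ff_in_pool_I = TRUE,
                              exclude_E = integer(0), exclude_I = integer(0),
                              check_EI = TRUE) {
  dev <- 0
  rows <- function(n, excl) setdiff(seq_len(n), excl)
  rE <- rows(nrow(w$W_EE), exclude_E)
  rI <- rows(nrow(w$W_II), exclude_I)
  if (!is.null(norms$W_EE) && length(rE)) {
    pooled <- rowSums(w$W_EE)[rE]
    if (ff_in_pool_E) pooled <- pooled + rowSums(w$W_EF)[rE]
    dev <- max(dev, abs(pooled - norms$W_EE) / norms$W_EE)
  }
  if (!is.null(norms$W_IE) && length(rI)) {
    pooled <- rowSums(w$W_IE)[rI]
    if (ff_in_pool_I) pooled <- pooled + rowSums(w$W_IF)[rI]
    dev <- max(dev, abs(pooled - norms$W_IE) / norms$W_IE)
  }
  if (check_EI && !is.null(norms$W_EI) && length(rE) && ncol(w$W_EI) > 0)
    dev <- max(dev, abs(rowSums(w$W_EI)[rE] - norms$W_EI) / norms$W_EI)
  if (!is.null(norms$W_II) && length(rI) && ncol(w$W_II) > 0)
    dev <- max(dev, abs(rowSums(w$W_II)[rI] - norms$W_II) / norms$W_II)
  dev
}
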