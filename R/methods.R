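#' @export
print.hebbnet <- function(x, ...) {
  cat(sprintf("Trained competitive Hebbian E-I network ('%s')\n", x$config$name))
  cat(sprintf("  populations: NE = %d, NI = %d, NF = %d\n",
              x$dims$NE, x$dims$NI, x$dims$NF))
  cat(sprintf("  rule: %s; %d stimuli presented%s\n", x$config$rule,
              x$n_presented, if (x$converged) " (converged early)" else ""))
  invisible(x)
}

#' Summarize a trained network
#'
#' Reports the feedforward tuning uniformity of both populations, the
#' resource-pool conservation residual, the mean training rate and the
#' convergence status.
#'
#' @param object A fitted [hebbnet()] object.
#' @param ... Unused.
#' @return An object of class `"summary.hebbnet"`.
#' @export
summary.hebbnet <- function(object, ...) {
  cfg <- object$config
  w <- object$weights
  U_E <- if (object$dims$NE > 0 && object$dims$NF >= 2 && sum(w$W_EF) > 0)
    tuning_uniformity(w$W_EF) else NA_real_
  U_I <- if (object$dims$NI > 0 && object$dims$NF >= 2 && sum(w$W_IF) > 0)
    tuning_uniformity(w$W_IF) else NA_real_
  res <- norm_conservation(w, cfg$norms,
                           ff_in_pool_E = cfg$eps$eps_EF > 0,
                           ff_in_pool_I = cfg$eps$eps_IF > 0,
                           exclude_E = cfg$static_E, exclude_I = cfg$static_I,
                           check_EI = cfg$rule != "classic_inhibitory")
  structure(list(name = cfg$name, dims = object$dims, rule = cfg$rule,
                 n_presented = object$n_presented, converged = object$converged,
                 U_E = U_E, U_I = U_I, norm_residual = res,
                 mean_rate_E = object$mean_rate_E),
            class = "summary.hebbnet")
}

#' @export
print.summary.hebbnet <- function(x, ...) {
  cat(sprintf("Trained competitive Hebbian E-I network ('%s')\n", x$name))
  cat(sprintf("  populations: NE = %d, NI = %d, NF = %d\n",
              x$dims$NE, x$dims$NI, x$dims$NF))
  cat(sprintf("  plasticity rule: %s\n", x$rule))
  cat(sprintf("  stimuli presented: %d%s\n", x$n_presented,
              if (x$converged) " (stopped at convergence)" else ""))
  cat(sprintf("  feedforward tuning uniformity: U_E = %s, U_I = %s\n",
              format(x$U_E, digits = 4), format(x$U_I, digits = 4)))
  cat(sprintf("  resource-pool conservation residual: %.2e\n", x$norm_residual))
  cat(sprintf("  mean excitatory training rate: %.4g\n", x$mean_rate_E))
  invisible(x)
}

#' Extract the learned synaptic weights
#'
#' @param object A fitted [hebbnet()] object.
#' @param block Optional block name (`"W_EF"`, `"W_EE"`, ...); if omitted
#'   the full [weight_set()] is returned.
#' @param ... Unused.
#' @return A [weight_set()] or a single weight matrix.
#' @export
coef.hebbnet <- function(object, block = NULL, ...) {
  if (is.null(block)) object$weights else object$weights[[block]]
}

#' Plot learned tuning
#'
#' For networks with plastic feedforward weights, plots each excitatory
#' neuron's feedforward weight profile against the input preferred
#' orientations (the learned tuning curves).  For networks with static
#' feedforward tuning, plots the recurrent excitatory connectivity profile
#' against the difference in preferred orientation instead.
#'
#' @param x A fitted [hebbnet()] object.
#' @param population `"E"` or `"I"`.
#' @param ... Passed to [graphics::matplot()] / [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.hebbnet <- function(x, population = c("E", "I"), ...) {
  population <- match.arg(population)
  W <- if (population == "E") x$weights$W_EF else x$weights$W_IF
  plastic_ff <- if (population == "E") x$config$eps$eps_EF > 0 else
    x$config$eps$eps_IF > 0
  if (plastic_ff && nrow(W) > 0) {
    ord <- order(x$tuning$theta_F)
    graphics::matplot(x$tuning$theta_F[ord], t(W[, ord, drop = FALSE]),
                      type = "l", lty = 1,
                      xlab = "input preferred orientation (deg)",
                      ylab = "feedforward weight",
                      main = sprintf("learned feedforward tuning (%s)", population),
                      ...)
  } else {
    th <- if (population == "E") x$theta_hat_E else x$theta_hat_I
    Wr <- if (population == "E") x$weights$W_EE else x$weights$W_II
    prof <- connectivity_vs_delta_theta(Wr, th, th)
    graphics::plot(prof$bin_center, prof$mean_weight, type = "b",
                   xlab = expression(Delta * hat(theta) ~ "(deg)"),
                   ylab = "normalized weight",
                   main = sprintf("recurrent connectivity profile (%s)", population),
                   ...)
  }
  invisible(x)
}

#' Draw new training stimulus streams from the fitted protocol
#'
#' @param object A fitted [hebbnet()] object.
#' @param nsim Number of streams to draw.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return A list of `nsim` stimulus-stream data frames.
#' @export
simulate.hebbnet <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- object$config
  model <- list(tuning = object$tuning)
  replicate(nsim, build_stream(cfg, model), simplify = FALSE)
}

#' Preferred orientations (generic)
#'
#' See [preferred_orientations.weight_set()] for the full interface; the
#' `hebbnet` method probes a fitted network with its own tuning, dynamics
#' and activation parameters.
#'
#' @param w A [weight_set()] or fitted [hebbnet()] object.
#' @param ... Method arguments.
#' @export
preferred_orientations <- function(w, ...) UseMethod("preferred_orientations")

#' @rdname preferred_orientations
#' @export
preferred_orientations.hebbnet <- function(w, ...) {
  preferred_orientations(w$weights, w$tuning, w$dyn, w$act_E, w$act_I,
                         clamp_I = w$config$clamp_I, ...)
}

#' @export
print.weight_set <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("weight set (NE = %d, NI = %d, NF = %d); block row-sum ranges:\n",
              d$NE, d$NI, d$NF))
  for (nm in names(x)) {
    if (nrow(x[[nm]]) == 0 || ncol(x[[nm]]) == 0) next
    rs <- rowSums(x[[nm]])
    cat(sprintf("  %s: [%.4g, %.4g]\n", nm, min(rs), max(rs)))
  }
  invisible(x)
}
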