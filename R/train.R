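gcd_int <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  while (b > 0L) { t <- a %% b; a <- b; b <- t }
  a
}

# Build the derived model objects (dimensions, activation vectors, tuning,
# initial weights, static masks) from a validated configuration.
build_model <- function(cfg) {
  dims <- network_dims(cfg$NE, cfg$NI, cfg$NF)
  aE <- rep(cfg$a_E, max(dims$NE, 1L))
  aI <- rep(cfg$a_I, max(dims$NI, 1L))
  if (length(cfg$static_E) && !is.null(cfg$static_gain_E))
    aE[cfg$static_E] <- cfg$static_gain_E
  if (length(cfg$static_I) && !is.null(cfg$static_gain_I))
    aI[cfg$static_I] <- cfg$static_gain_I
  act_E <- activation_params(a = if (dims$NE > 0) aE[seq_len(dims$NE)] else cfg$a_E,
                             b = cfg$b_E, n = cfg$n_E)
  act_I <- activation_params(a = if (dims$NI > 0) aI[seq_len(dims$NI)] else cfg$a_I,
                             b = cfg$b_I, n = cfg$n_I)
  dyn <- dynamics_params(cfg$tau_E, cfg$tau_I, cfg$dt)
  theta_F <- if (is.null(cfg$layout)) even_orientations(dims$NF) else
    rep(even_orientations(cfg$layout$NF_region), 2L)
  tuning <- input_tuning(dims$NF, cfg$sigma_F, cfg$A_F, theta_F = theta_F)
  theta_hat <- function(n, n_region = NULL) {
    if (is.null(cfg$layout)) even_orientations(n) else
      rep(even_orientations(n_region), 2L)
  }
  list(dims = dims, act_E = act_E, act_I = act_I, dyn = dyn, tuning = tuning,
       theta_hat_E = if (dims$NE > 0) theta_hat(dims$NE, cfg$layout$NE_region) else numeric(0),
       theta_hat_I = if (dims$NI > 0) theta_hat(dims$NI, cfg$layout$NI_region) else numeric(0))
}

# Tuned feedforward block; block-diagonal by region under a
# center/surround layout (no cross-region feedforward connections).
tuned_ff_block <- function(theta_hat, cfg, model, norm) {
  if (is.null(cfg$layout)) {
    static_feedforward_weights(theta_hat, model$tuning, cfg$sigma_theta, norm)
  } else {
    m <- cfg$layout$NF_region
    n_half <- length(theta_hat) / 2L
    tun_r <- input_tuning(m, cfg$sigma_F, cfg$A_F,
                          theta_F = even_orientations(m))
    G <- static_feedforward_weights(theta_hat[seq_len(n_half)], tun_r,
                                    cfg$sigma_theta, norm)
    W <- matrix(0, 2L * n_half, 2L * m)
    W[seq_len(n_half), seq_len(m)] <- G
    W[n_half + seq_len(n_half), m + seq_len(m)] <- G
    W
  }
}

build_weights <- function(cfg, model) {
  spec <- init_spec(cfg$mu_W, cfg$sigma_W, cfg$zero_recurrent_E,
                    cfg$exclude_autapses)
  w <- initialize_weights(model$dims, spec, cfg$norms,
                          ff_static_E = cfg$ff_static_E,
                          ff_static_I = cfg$ff_static_I)
  if (cfg$ff_init == "tuned") {
    if (model$dims$NE > 0) {
      w$W_EF <- tuned_ff_block(model$theta_hat_E, cfg, model,
                               if (cfg$ff_static_E) cfg$norms$W_EF else NULL)
      if (!cfg$ff_static_E) {
        r <- normalize_excitatory_pool(w$W_EE, w$W_EF, cfg$norms$W_EE, warn = FALSE)
        w$W_EE <- r$W_AE; w$W_EF <- r$W_AF
      }
    }
    if (model$dims$NI > 0) {
      w$W_IF <- tuned_ff_block(model$theta_hat_I, cfg, model,
                               if (cfg$ff_static_I) cfg$norms$W_IF else NULL)
      if (!cfg$ff_static_I) {
        r <- normalize_excitatory_pool(w$W_IE, w$W_IF, cfg$norms$W_IE, warn = FALSE)
        w$W_IE <- r$W_AE; w$W_IF <- r$W_AF
      }
    }
  }
  # individually static neurons: fixed tuned feedforward row, no plastic
  # recurrent inputs
  if (length(cfg$static_E)) {
    th <- cfg$static_theta_hat_E
    if (is.null(th)) th <- even_orientations(length(cfg$static_E))
    w$W_EF[cfg$static_E, ] <- static_feedforward_weights(
      th, model$tuning, cfg$static_sigma_theta, cfg$norms$W_EF)
    w$W_EE[cfg$static_E, ] <- 0
    if (model$dims$NI > 0) w$W_EI[cfg$static_E, ] <- 0
  }
  if (length(cfg$static_I)) {
    th <- cfg$static_theta_hat_I
    if (is.null(th)) th <- even_orientations(length(cfg$static_I))
    if (!is.null(cfg$static_sigma_theta))
      w$W_IF[cfg$static_I, ] <- static_feedforward_weights(
        th, model$tuning, cfg$static_sigma_theta, cfg$norms$W_IF)
    if (model$dims$NE > 0) w$W_IE[cfg$static_I, ] <- 0
    w$W_II[cfg$static_I, ] <- 0
  }
  w
}

# Sample the stimulus stream as a data frame; the per-stimulus input-rate
# vectors are reconstructed on the fly during training.
build_stream <- function(cfg, model) {
  proto <- training_protocol(cfg$n_stimuli, cfg$stimulus_duration, cfg$contrast,
                             kind = cfg$protocol_kind, patterns = cfg$patterns)
  switch(cfg$protocol_kind,
    gratings = sample_training_stream(proto),
    ensemble = data.frame(trial = seq_len(cfg$n_stimuli),
                          row = ((seq_len(cfg$n_stimuli) - 1L) %%
                                   nrow(proto$patterns)) + 1L),
    center_surround = center_surround_stream(cfg$layout, proto))
}

stream_input <- function(cfg, model, stream, i) {
  switch(cfg$protocol_kind,
    gratings = grating_response(stream$theta[i], stream$contrast[i], model$tuning),
    ensemble = as.numeric(cfg$patterns[stream$row[i], ]),
    center_surround = {
      m <- cfg$layout$NF_region
      tun <- input_tuning(m, cfg$sigma_F, cfg$A_F, theta_F = even_orientations(m))
      ctr <- if (stream$contrast_center[i] > 0)
        grating_response(stream$theta_center[i], stream$contrast_center[i], tun)
      else numeric(m)
      srd <- if (stream$contrast_surround[i] > 0)
        grating_response(stream$theta_surround[i], stream$contrast_surround[i], tun)
      else numeric(m)
      c(ctr, srd)
    })
}

#' Train a competitive Hebbian E-I network
#'
#' The package's fitting function: builds the network described by a
#' configuration, samples the training stimulus stream, and iterates
#' stimulus presentation, Euler integration of the rate dynamics, Hebbian
#' weight updates and synapse-type-specific divisive normalization, in sync
#' at every integration step.  The run is fully reproducible from the seed:
#' initial weights are drawn first, then the stimulus stream, from a single
#' seeded generator.
#'
#' The inner loop is a compiled implementation of exactly one
#' [euler_step()] followed by one [competitive_plasticity_step()] (plus
#' [classic_inhibitory_step()] under the classic rule) per integration
#' step; the exported R operations are the reference semantics, and the
#' test suite asserts the two paths agree.
#'
#' Training stops at `n_stimuli` presentations, or earlier once the largest
#' relative weight change per `check_every` stimuli falls below
#' `tol_convergence` (set `tol_convergence = 0` to disable early stopping).
#'
#' @param config A [hebbnet_config()] (or a preset name, passed through).
#' @param seed Optional seed overriding `config$seed`.
#' @param init_weights Optional [weight_set()] to start from (warm start /
#'   snapshot resume) instead of freshly initialized weights.  The random
#'   draws of the initializer are still consumed, so the stimulus stream of
#'   a resumed run matches the stream a fresh run would see.
#' @param init_state Optional [network_state()] to start from.
#' @param skip_stimuli Skip the first `skip_stimuli` presentations of the
#'   stream (used together with `init_weights` / `init_state` to resume a
#'   run from a snapshot: the resumed trajectory reproduces the remainder
#'   of the original run exactly).
#' @param ... Overrides forwarded to [hebbnet_config()] when `config` is a
#'   preset name.
#' @return An object of class `"hebbnet"`: a list with the resolved
#'   `config`, the derived model objects (`dims`, `act_E`, `act_I`, `dyn`,
#'   `tuning`, `theta_hat_E`, `theta_hat_I`), the initial and final
#'   [weight_set()]s (`weights_init`, `weights`), the final
#'   [network_state()] (`state`), the stimulus `stream`, a `history` data
#'   frame (uniformity and mean rates at the snapshot cadence), optional
#'   weight `snapshots`, `n_presented` and `converged`.
#' @seealso [predict.hebbnet()], [summary.hebbnet()], [suppression_curves()],
#'   [contrast_response()]
#' @export
#' @examples
#' fit <- hebbnet("single_neuron", n_stimuli = 200, seed = 1)
#' summary(fit)
hebbnet <- function(config, seed = NULL, init_weights = NULL,
                    init_state = NULL, skip_stimuli = 0L, ...) {
  cfg <- if (is.character(config)) hebbnet_config(config, ...) else config
  if (!inherits(cfg, "hebbnet_config")) cfg <- validate_config(cfg)
  if (!is.null(seed)) cfg$seed <- seed
  set.seed(cfg$seed)
  model <- build_model(cfg)
  w <- build_weights(cfg, model)
  stream <- build_stream(cfg, model)
  if (!is.null(init_weights)) w <- init_weights
  w0 <- w

  dims <- model$dims; dyn <- model$dyn
  act_E <- model$act_E; act_I <- model$act_I
  steps_per_stim <- max(1L, floor(cfg$stimulus_duration / cfg$dt))

  rates <- cfg$eps
  classic <- cfg$rule == "classic_inhibitory"
  if (classic) {
    classic_p <- classic_inhib_params(cfg$r0, rates$eps_EI)
    rates$eps_EI <- 0
  }

  # --- chunked compiled inner loop ---------------------------------------
  W_EE <- w$W_EE; W_EI <- w$W_EI; W_EF <- w$W_EF
  W_IE <- w$W_IE; W_II <- w$W_II; W_IF <- w$W_IF
  clamp <- cfg$clamp_I
  uE <- if (is.null(init_state)) numeric(dims$NE) else init_state$uE
  uI <- if (is.null(init_state)) numeric(dims$NI) else init_state$uI
  rE <- rectified_power_activation(uE, act_E)
  rI <- if (clamp) numeric(dims$NF) else rectified_power_activation(uI, act_I)
  pEF <- rates$eps_EF > 0; pIF <- rates$eps_IF > 0
  sE <- as.integer(cfg$static_E); sI <- as.integer(cfg$static_I)

  par <- list(
    aE = rep_len(as.numeric(act_E$a), max(dims$NE, 1))[seq_len(dims$NE)],
    bE = rep_len(as.numeric(act_E$b), max(dims$NE, 1))[seq_len(dims$NE)],
    nE = as.numeric(act_E$n),
    aI = rep_len(as.numeric(act_I$a), max(dims$NI, 1))[seq_len(dims$NI)],
    bI = rep_len(as.numeric(act_I$b), max(dims$NI, 1))[seq_len(dims$NI)],
    nI = as.numeric(act_I$n),
    kE = dyn$dt / dyn$tau_E, kI = dyn$dt / dyn$tau_I,
    eEE = dyn$dt * rates$eps_EE, eEI = dyn$dt * rates$eps_EI,
    eEF = dyn$dt * rates$eps_EF, eIE = dyn$dt * rates$eps_IE,
    eII = dyn$dt * rates$eps_II, eIF = dyn$dt * rates$eps_IF,
    clamp = clamp, exclude_autapses = cfg$exclude_autapses,
    nEE = if (is.null(cfg$norms$W_EE)) -1 else cfg$norms$W_EE,
    nIE = if (is.null(cfg$norms$W_IE)) -1 else cfg$norms$W_IE,
    nEI = if (is.null(cfg$norms$W_EI)) -1 else cfg$norms$W_EI,
    nII = if (is.null(cfg$norms$W_II)) -1 else cfg$norms$W_II,
    classic = classic,
    classic_eps_dt = if (classic) dyn$dt * classic_p$eps_EI else 0,
    r0 = if (classic) classic_p$r0 else 0,
    static_E = sE - 1L, static_I = sI - 1L,
    W_EF_static = if (length(sE)) W_EF[sE, , drop = FALSE],
    W_IF_static = if (length(sI)) W_IF[sI, , drop = FALSE])

  plastic_blocks <- c("W_EE", "W_EI", "W_EF", "W_IE", "W_II", "W_IF")[
    c(rates$eps_EE > 0, rates$eps_EI > 0 || classic, pEF,
      rates$eps_IE > 0, rates$eps_II > 0, pIF)]
  block_norm <- list(W_EE = cfg$norms$W_EE, W_EF = cfg$norms$W_EE,
                     W_EI = cfg$norms$W_EI, W_IE = cfg$norms$W_IE,
                     W_IF = cfg$norms$W_IE, W_II = cfg$norms$W_II)
  sync_w <- function() {
    w$W_EE <- W_EE; w$W_EI <- W_EI; w$W_EF <- W_EF
    w$W_IE <- W_IE; w$W_II <- W_II; w$W_IF <- W_IF
    w
  }

  n <- cfg$n_stimuli
  snap_every <- cfg$snapshot_every
  check_every <- if (cfg$tol_convergence > 0) cfg$check_every else 0L
  events <- c(if (snap_every > 0) snap_every, if (check_every > 0) check_every)
  chunk <- if (length(events)) Reduce(gcd_int, events) else 1000L
  chunk <- max(1L, min(chunk, 1000L))
  # chunk must divide every event cadence so boundaries line up
  if (length(events) && any(events %% chunk != 0L))
    chunk <- Reduce(gcd_int, c(events, chunk))

  hist_rows <- list()
  snapshots <- if (cfg$keep_snapshots) list() else NULL
  record <- function(i) {
    uni <- function(W, plastic, npost) {
      if (plastic && npost > 0 && dims$NF >= 2 && sum(W) > 0)
        tuning_uniformity(W) else NA_real_
    }
    data.frame(stimulus = i,
               U_E = uni(W_EF, pEF, dims$NE), U_I = uni(W_IF, pIF, dims$NI),
               mean_rE = if (dims$NE > 0) mean(rE) else NA_real_,
               mean_rI = if (dims$NI > 0 || clamp) mean(rI) else NA_real_)
  }
  hist_rows[[1]] <- record(0L)

  w_check <- sync_w()
  converged <- FALSE
  mean_rE_acc <- 0
  i <- as.integer(skip_stimuli)
  n_presented <- 0L
  while (i < n) {
    m <- min(chunk, n - i)
    idx <- i + seq_len(m)
    rFm <- t(vapply(idx, function(j) stream_input(cfg, model, stream, j),
                    numeric(dims$NF)))
    par$uE <- uE; par$uI <- uI; par$rE <- rE; par$rI <- rI
    res <- .train_chunk_cpp(list(W_EE = W_EE, W_EI = W_EI, W_EF = W_EF,
                                 W_IE = W_IE, W_II = W_II, W_IF = W_IF),
                            rFm, steps_per_stim, par)
    W_EE <- res$W_EE; W_EI <- res$W_EI; W_EF <- res$W_EF
    W_IE <- res$W_IE; W_II <- res$W_II; W_IF <- res$W_IF
    uE <- drop(res$uE); uI <- drop(res$uI)
    rE <- drop(res$rE); rI <- drop(res$rI)
    mean_rE_acc <- mean_rE_acc + res$mean_rE_acc
    if (res$diverged)
      stop(errorCondition(
        sprintf("dynamics diverged at stimulus %d, step %d",
                i + res$div_stim, res$div_step),
        class = c("hebbnet_divergence", "error"),
        stimulus = i + res$div_stim, step = res$div_step))
    i <- i + m
    n_presented <- n_presented + m
    if (snap_every > 0 && i %% snap_every == 0L) {
      hist_rows[[length(hist_rows) + 1L]] <- record(i)
      if (cfg$keep_snapshots) snapshots[[length(snapshots) + 1L]] <- sync_w()
    }
    if (check_every > 0 && i %% check_every == 0L) {
      wn <- sync_w()
      delta <- 0
      for (b in plastic_blocks) {
        bn <- block_norm[[b]]
        if (is.null(bn)) bn <- max(abs(w_check[[b]]), 1)
        d <- max(abs(wn[[b]] - w_check[[b]])) / bn
        if (d > delta) delta <- d
      }
      w_check <- wn
      if (delta < cfg$tol_convergence) { converged <- TRUE; break }
    }
  }
  w <- sync_w()
  s <- network_state(uE, uI, act_E, act_I,
                     rI_clamp = if (clamp) rI else NULL)
  history <- do.call(rbind, hist_rows)
  structure(list(config = cfg, dims = dims, act_E = act_E, act_I = act_I,
                 dyn = dyn, tuning = model$tuning,
                 theta_hat_E = model$theta_hat_E, theta_hat_I = model$theta_hat_I,
                 weights_init = w0, weights = w, state = s, stream = stream,
                 history = history, snapshots = snapshots,
                 n_presented = n_presented, converged = converged,
                 mean_rate_E = mean_rE_acc / max(n_presented, 1L),
                 steps_per_stimulus = steps_per_stim),
            class = "hebbnet")
}
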