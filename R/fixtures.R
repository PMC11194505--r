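#' Miniature analytically tractable experiment fixtures
#'
#' Builds seconds-scale configurations with known structure, used for
#' validating the simulator against the linear theory:
#' \describe{
#'   \item{`two_channel_pca`}{A single linear neuron with two plastic
#'     excitatory input channels driven by an anisotropic (4:1 variance
#'     ratio) non-negative Gaussian ensemble whose uncentered principal
#'     axis is known by construction; competitive Hebbian learning should
#'     align the weight vector with that axis.}
#'   \item{`paired_ei_pca`}{The same ensemble feeding one excitatory and
#'     one mirrored inhibitory input stream (`yI = yE`); both weight
#'     vectors should align with the principal axis and with each other
#'     (the balanced fixed point).}
#'   \item{`toy_recurrent`}{A small fully plastic recurrent grating network
#'     (4E/4I/8F) for smoke and conservation tests.}
#'   \item{`tiny_center_surround`}{A scaled-down center/surround network.}
#' }
#'
#' @param kind Fixture name.
#' @param seed Seed stored in the configuration (and used for the
#'   ensemble draw where applicable).
#' @param n_patterns Ensemble size for the PCA fixtures.
#' @param axis_deg Principal-axis angle (degrees from the first channel
#'   axis) for the PCA fixtures.
#' @param mode Center/surround training statistics for
#'   `tiny_center_surround`.
#' @return A list with fields `config` (a [hebbnet_config()]) and, for the
#'   PCA fixtures, `ensemble` (the pattern matrix) and `axis` (the
#'   construction axis as a unit vector).
#' @export
#' @examples
#' fx <- make_fixture("two_channel_pca", seed = 1)
#' principal_eigenvector(second_moment(fx$ensemble))
make_fixture <- function(kind = c("two_channel_pca", "paired_ei_pca",
                                  "toy_recurrent", "tiny_center_surround"),
                         seed = 1, n_patterns = 5000, axis_deg = 30,
                         mode = c("correlated", "independent")) {
  kind <- match.arg(kind)
  switch(kind,
    two_channel_pca = {
      ens <- two_channel_ensemble(n_patterns, axis_deg, seed)
      cfg <- hebbnet_config(
        NE = 1L, NI = 0L, NF = 2L,
        a_E = 1, b_E = 0, n_E = 1, a_I = 1, b_I = 0, n_I = 1,
        tau_E = 1, tau_I = 1, dt = 1, stimulus_duration = 1,
        mu_W = 0.5, sigma_W = 0.25,
        eps = learning_rates(eps_EF = 0.002),
        norms = weight_norms(W_EE = 1),
        protocol_kind = "ensemble", patterns = ens$Y,
        n_stimuli = n_patterns, tol_convergence = 0,
        snapshot_every = 500L, seed = seed, name = "two_channel_pca")
      list(config = cfg, ensemble = ens$Y, axis = ens$axis)
    },
    paired_ei_pca = {
      ens <- two_channel_ensemble(n_patterns, axis_deg, seed)
      cfg <- hebbnet_config(
        NE = 1L, NI = 2L, NF = 2L,
        a_E = 1, b_E = 0, n_E = 1, a_I = 1, b_I = 0, n_I = 1,
        tau_E = 1, tau_I = 1, dt = 1, stimulus_duration = 1,
        mu_W = 0.5, sigma_W = 0.25,
        eps = learning_rates(eps_EF = 0.002, eps_EI = 0.002),
        norms = weight_norms(W_EE = 1, W_EI = 0.5),
        protocol_kind = "ensemble", patterns = ens$Y,
        n_stimuli = n_patterns, clamp_I = TRUE, tol_convergence = 0,
        snapshot_every = 500L, seed = seed, name = "paired_ei_pca")
      list(config = cfg, ensemble = ens$Y, axis = ens$axis)
    },
    toy_recurrent = {
      cfg <- hebbnet_config("recurrent_small",
        NE = 4L, NI = 4L, NF = 8L, sigma_F = 25, n_stimuli = 500L,
        seed = seed, name = "toy_recurrent")
      list(config = cfg)
    },
    tiny_center_surround = {
      mode <- match.arg(mode)
      preset <- paste0("center_surround_", mode)
      cfg <- hebbnet_config(preset,
        NF_region = 20L, NE_region = 16L, NI_region = 4L,
        n_stimuli = 1500L, seed = seed)
      list(config = cfg)
    })
}

# Non-negative 2-channel Gaussian ensemble with mean along the
# construction axis, so the axis is the exact principal eigenvector of the
# uncentered population second moment; sample moments approach it as
# n grows.  Variance along the axis is 4x the orthogonal variance.
two_channel_ensemble <- function(n, axis_deg, seed, mean_len = 2,
                                 sd_major = 0.5) {
  set.seed(seed)
  phi <- axis_deg * pi / 180
  v <- c(cos(phi), sin(phi))
  vp <- c(-sin(phi), cos(phi))
  z1 <- stats::rnorm(n, 0, sd_major)
  z2 <- stats::rnorm(n, 0, sd_major / 2)
  Y <- (mean_len + z1) %o% v + z2 %o% vp
  Y[Y < 0] <- 0
  list(Y = Y, axis = v)
}

#' Linear toy configurations for the tuning-collapse condition
#'
#' Builds small fully plastic linear-activation networks driven by
#' near-one-hot input patterns over `NF = 6` channels (so the input modes
#' are essentially the channels themselves, with slightly unequal
#' amplitudes making one mode the most attractive), in two regimes of the
#' collapse condition.  In the `"collapse"` regime the network has no
#' inhibition, so the excitatory rate variance necessarily dominates and
#' all excitatory tunings are expected to converge onto the most
#' attractive mode.  In the `"prevented"` regime a twice-larger population
#' of inhibitory neurons contributes more pooled rate variance than the
#' excitatory one, which repels excitatory neurons from occupied modes and
#' keeps their tunings distributed.
#'
#' A small common baseline keeps every channel weakly co-active on every
#' pattern: with strictly one-hot patterns a fully committed weight vector
#' would be an absorbing state (a zeroed channel that never fires together
#' with the postsynaptic neuron can receive no Hebbian input again), a
#' degeneracy that the overlap of realistic tuning curves rules out.  The
#' E-to-I coupling is strong and the I-to-I suppression weak, so that the
#' inhibitory population repels committed excitatory neurons without
#' silencing them (overwhelming inhibition would freeze learning in a
#' quenched collapsed state).
#'
#' @param regime `"collapse"` or `"prevented"`.
#' @param seed Configuration seed.
#' @param n_stimuli Training length.
#' @return A list with `config`, the pattern `amplitudes` and the pattern
#'   matrix `patterns`.
#' @export
collapse_regime_config <- function(regime = c("collapse", "prevented"),
                                   seed = 1, n_stimuli = 12000) {
  regime <- match.arg(regime)
  NF <- 6L
  amplitudes <- seq(1.2, 0.8, length.out = NF)
  set.seed(seed + 1000L)
  k <- sample.int(NF, n_stimuli, replace = TRUE)
  Y <- matrix(0.05, n_stimuli, NF)
  Y[cbind(seq_len(n_stimuli), k)] <- amplitudes[k]
  common <- list(
    NF = NF,
    a_E = 1, b_E = 0, n_E = 1, a_I = 1, b_I = 0, n_I = 1,
    tau_E = 1, tau_I = 1, dt = 1, stimulus_duration = 1,
    mu_W = 0.5, sigma_W = 0.25,
    protocol_kind = "ensemble", patterns = Y,
    n_stimuli = n_stimuli, tol_convergence = 0,
    snapshot_every = 500L, seed = seed)
  if (regime == "collapse") {
    args <- c(common, list(
      NE = 6L, NI = 0L,
      eps = learning_rates(eps_EF = 0.002, eps_EE = 0.002),
      norms = weight_norms(W_EE = 1),
      name = "collapse_regime"))
  } else {
    args <- c(common, list(
      NE = 6L, NI = 12L,
      eps = learning_rates(eps_EF = 0.002, eps_EE = 0.002, eps_IE = 0.003,
                           eps_IF = 0.003, eps_EI = 0.004, eps_II = 0.005),
      norms = weight_norms(W_EE = 1, W_IE = 1, W_EI = 1.0, W_II = 0.2),
      name = "prevented_regime"))
  }
  list(config = do.call(hebbnet_config, args), amplitudes = amplitudes,
       patterns = Y)
}
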