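test_that("tuning uniformity attains its entropy bounds and known values", {
  expect_equal(tuning_uniformity(matrix(1, 4, 10)), 1, tolerance = 1e-12)
  onehot <- matrix(0, 4, 10); onehot[, 3] <- 2
  expect_equal(tuning_uniformity(onehot), 0, tolerance = 1e-12)
  # NF = 2 with shares (0.25, 0.75)
  W <- matrix(c(0.25, 0.75), 1, 2)
  expect_equal(tuning_uniformity(W),
               -(0.25 * log(0.25) + 0.75 * log(0.75)) / log(2),
               tolerance = 1e-12)
  expect_error(tuning_uniformity(matrix(0, 2, 3)), "all-zero")
  expect_error(tuning_uniformity(matrix(-1, 2, 3)), "non-negative")
})

test_that("tuning uniformity is bounded and invariant to column permutation and rescaling", {
  set.seed(14)
  for (k in 1:20) {
    W <- matrix(rexp(5 * 8), 5, 8)
    u <- tuning_uniformity(W)
    expect_gte(u, 0); expect_lte(u, 1)
    expect_equal(tuning_uniformity(W[, sample(8)]), u)
    expect_equal(tuning_uniformity(W * 37.5), u)
  }
  expect_equal(sum(output_weight_share(matrix(runif(12), 3))), 1)
})

test_that("preferred orientations recover feedforward tuning and tie-break to zero", {
  dims <- network_dims(3, 0, 24)
  tun <- input_tuning(24, sigma_F = 12, A_F = 1)
  th_hat <- c(60, 105, 0)
  W <- weight_set(dims, W_EF = static_feedforward_weights(th_hat, tun, 15, 1))
  dyn <- dynamics_params(10, 10, 1)
  po <- preferred_orientations(W, tun, dyn, linear_act, linear_act,
                               grid = seq(0, 179, by = 1), settle = 100)
  expect_equal(po$E, th_hat)
  # identity feedforward recovers the input channels' own preferences
  # exactly on a probe grid containing them
  dimsF <- network_dims(24, 0, 24)
  WI <- weight_set(dimsF, W_EF = diag(24))
  poI <- preferred_orientations(WI, tun, dyn, linear_act, linear_act,
                                grid = tun$theta_F, settle = 100)
  expect_equal(poI$E, tun$theta_F)
  # untrained flat weights: flat response over the channel grid, tie-break
  # returns the smallest angle
  Wf <- weight_set(dims, W_EF = matrix(1, 3, 24))
  pof <- preferred_orientations(Wf, tun, dyn, linear_act, linear_act,
                                grid = tun$theta_F, settle = 50)
  expect_equal(pof$E, c(0, 0, 0))
})

test_that("rotating feedforward weights by one channel shifts preferred orientations equally", {
  dims <- network_dims(4, 0, 18)
  tun <- input_tuning(18, sigma_F = 15, A_F = 1)
  W0 <- static_feedforward_weights(c(20, 70, 120, 160), tun, 18, 1)
  rot <- c(18, 1:17)  # shift columns by one channel (10 degrees)
  dyn <- dynamics_params(10, 10, 1)
  po0 <- preferred_orientations(weight_set(dims, W_EF = W0), tun, dyn,
                                linear_act, linear_act, settle = 50)
  po1 <- preferred_orientations(weight_set(dims, W_EF = W0[, rot]), tun, dyn,
                                linear_act, linear_act, settle = 50)
  expect_equal((po0$E + 10) %% 180, po1$E)
})

test_that("connectivity profiles bin by signed orientation difference with block-max normalization", {
  # duplicated orientations so equal-tuning pairs exist off the diagonal
  th <- rep(even_orientations(6), 2)
  # strongest weights between equally tuned neurons
  W <- exp(-outer(th, th, circular_distance)^2 / (2 * 20^2))
  prof <- connectivity_vs_delta_theta(W, th, th, n_bins = 18)
  expect_equal(nrow(prof), 18)
  imax <- which.max(prof$mean_weight)
  expect_lte(abs(prof$bin_center[imax]), 5)
  expect_true(all(prof$mean_weight <= 1 + 1e-12, na.rm = TRUE))
  # all-equal weights: flat profile at 1
  proff <- connectivity_vs_delta_theta(matrix(2, 12, 12), th, th, n_bins = 18)
  expect_true(all(abs(proff$mean_weight[!is.na(proff$mean_weight)] - 1) < 1e-12))
  # empty bins recorded as NA, not zero
  prof2 <- connectivity_vs_delta_theta(matrix(1, 2, 2), c(0, 10), c(0, 10),
                                       n_bins = 18)
  expect_true(any(is.na(prof2$mean_weight)))
  expect_equal(sum(prof2$n_pairs), 2)
})

test_that("E/I input decomposition is consistent with the steady-state potential", {
  w <- tiny_stable_weights(seed = 31)
  dims <- attr(w, "dims")
  act <- activation_params(a = 0.5, b = 0, n = 2)
  dyn <- dynamics_params(10, 8, 0.5)
  rF <- c(1.2, 0.4, 0.9, 1.6)
  s <- run_to_steady_state(zero_state(dims, act, act), w, rF, dyn, act, act,
                           duration = 400)
  dec <- ei_input_decomposition(s, w, rF)
  expect_true(all(dec >= 0))
  expect_equal(dec$exc_total, dec$exc_ffwd + dec$exc_rec)
  # at the fixed point u = total excitation - total inhibition
  expect_equal(dec$exc_total - dec$inh, s$uE, tolerance = 1e-6)
  z <- ei_input_decomposition(zero_state(dims, act, act), w, numeric(4))
  expect_true(all(z == 0))
})

test_that("circular peak counting and semi-saturation interpolation behave as documented", {
  expect_equal(count_circular_peaks(c(0, 1, 3, 2, 1, 0)), 1L)
  expect_equal(count_circular_peaks(c(0, 2, 0, 3, 0, 1)), 3L)
  expect_equal(count_circular_peaks(rep(1, 6)), 1L)
  # half-max of a saturating curve, linearly interpolated
  cc <- c(0, 0.25, 0.5, 1)
  resp <- c(0, 2, 8, 8)
  expect_equal(semi_saturation_contrast(cc, resp), 0.25 + (4 - 2) / 6 * 0.25)
  # a curve already at half-max at the origin reports the first contrast
  expect_equal(semi_saturation_contrast(cc, c(5, 6, 8, 8)), 0)
})
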