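test_that("rectified power-law activation matches hand evaluation", {
  act <- activation_params(a = 0.04, b = 0, n = 2)
  expect_equal(rectified_power_activation(-1, act), 0)
  expect_equal(rectified_power_activation(5, act), 1.0)
  # the threshold point gives exactly zero for any gain/exponent
  for (p in list(activation_params(2, 0.7, 1), activation_params(0.5, -1, 3)))
    expect_equal(rectified_power_activation(p$b, p), 0)
  # vectorized, non-negative, monotone above threshold
  u <- seq(-2, 2, by = 0.25)
  r <- rectified_power_activation(u, act)
  expect_true(all(r >= 0))
  expect_true(all(diff(r[u >= 0]) >= 0))
})

test_that("euler_step holds the trivial fixed point and dt = tau replaces u by its drive", {
  dims <- network_dims(2, 2, 3)
  act <- linear_act
  w0 <- weight_set(dims)  # all-zero weights
  dyn <- dynamics_params(tau_E = 10, tau_I = 10, dt = 1)
  s <- zero_state(dims, act, act)
  s1 <- euler_step(s, w0, numeric(3), dyn, act, act)
  expect_equal(s1$uE, c(0, 0))
  expect_equal(s1$rI, c(0, 0))

  # dt = tau with no recurrence: one step writes W_EF rF into uE
  w <- weight_set(dims, W_EF = matrix(1:6 / 10, 2, 3))
  dyn2 <- dynamics_params(tau_E = 200, tau_I = 200, dt = 200)
  rF <- c(1, 0.5, 2)
  s2 <- euler_step(zero_state(dims, act, act), w, rF, dyn2, act, act)
  expect_equal(s2$uE, drop(w$W_EF %*% rF))

  expect_error(euler_step(s, w0, numeric(5), dyn, act, act), "length")
})

test_that("iterated Euler integration converges to the closed-form exponential relaxation", {
  # single linear E neuron, constant drive d: u(t) = d (1 - exp(-t / tau))
  dims <- network_dims(1, 0, 1)
  w <- weight_set(dims, W_EF = matrix(1, 1, 1))
  d <- 2.5
  tau <- 20; dt <- 0.1
  dyn <- dynamics_params(tau_E = tau, tau_I = tau, dt = dt)
  s <- zero_state(dims, linear_act, linear_act)
  for (t_end in c(10, 40)) {
    out <- run_to_steady_state(zero_state(dims, linear_act, linear_act), w, d,
                               dyn, linear_act, linear_act, duration = t_end)
    exact <- d * (1 - exp(-t_end / tau))
    # explicit Euler error is O(dt/tau) relative
    expect_lt(abs(out$uE - exact), 2 * d * dt / tau)
  }
})

test_that("simulated steady state matches the direct linear solve", {
  w <- tiny_stable_weights()
  dims <- attr(w, "dims")
  dyn <- dynamics_params(tau_E = 10, tau_I = 8, dt = 0.5)
  rF <- c(1, 0.2, 0.7, 1.5)
  s <- run_to_steady_state(zero_state(dims, linear_act, linear_act), w, rF,
                           dyn, linear_act, linear_act, duration = 20 * 10)
  ref <- linear_steady_state(w, rF)
  expect_true(all(ref$uE > 0) && all(ref$uI > 0))  # linear regime applies
  expect_lt(max(abs(s$uE - ref$uE)) / max(abs(ref$uE)), 1e-6)
  expect_lt(max(abs(s$uI - ref$uI)) / max(abs(ref$uI)), 1e-6)

  # duration = dt is exactly one euler step
  one <- euler_step(zero_state(dims, linear_act, linear_act), w, rF, dyn,
                    linear_act, linear_act)
  viaRun <- run_to_steady_state(zero_state(dims, linear_act, linear_act), w,
                                rF, dyn, linear_act, linear_act, duration = dyn$dt)
  expect_identical(one$uE, viaRun$uE)

  # zero input: rates decay toward f(0)
  s0 <- run_to_steady_state(s, w, numeric(4), dyn, linear_act, linear_act,
                            duration = 400)
  expect_lt(max(abs(s0$rE)), 1e-6)
})

test_that("runaway recurrent excitation raises a divergence error naming the step", {
  dims <- network_dims(1, 0, 1)
  w <- weight_set(dims, W_EE = matrix(0, 1, 1), W_EF = matrix(1, 1, 1))
  w$W_EE[1, 1] <- 3  # self-excitation gain > 1: unstable
  dyn <- dynamics_params(tau_E = 1, tau_I = 1, dt = 1)
  expect_error(
    run_to_steady_state(zero_state(dims, linear_act, linear_act), w, 5, dyn,
                        linear_act, linear_act, duration = 200),
    "diverged at step")
})

test_that("weight initialization is deterministic, non-negative and exactly normalized", {
  dims <- network_dims(6, 4, 12)
  norms <- weight_norms(W_EE = 2, W_IE = 1.5, W_EI = 0.8, W_II = 0.5)
  spec <- init_spec(mu_W = 0.2, sigma_W = 0.1)
  set.seed(11); w1 <- initialize_weights(dims, spec, norms)
  set.seed(11); w2 <- initialize_weights(dims, spec, norms)
  expect_identical(w1, w2)
  for (nm in names(w1)) expect_true(all(w1[[nm]] >= 0))
  expect_equal(diag(w1$W_EE), numeric(6))
  expect_equal(diag(w1$W_II), numeric(4))
  # recurrent excitatory-origin blocks zeroed by default
  expect_true(all(w1$W_EE == 0) && all(w1$W_IE == 0))
  # pooled and inhibitory row sums hit the norms to 1e-12 relative
  expect_equal(rowSums(w1$W_EE) + rowSums(w1$W_EF), rep(2, 6), tolerance = 1e-12)
  expect_equal(rowSums(w1$W_IE) + rowSums(w1$W_IF), rep(1.5, 4), tolerance = 1e-12)
  expect_equal(rowSums(w1$W_EI), rep(0.8, 6), tolerance = 1e-12)
  expect_equal(rowSums(w1$W_II), rep(0.5, 4), tolerance = 1e-12)

  # sigma_W = 0: every drawn entry is exactly mu_W before normalization
  set.seed(1)
  w3 <- initialize_weights(dims, init_spec(0.3, 0, zero_recurrent_E = "none"),
                           weight_norms())
  off <- w3$W_EE[row(w3$W_EE) != col(w3$W_EE)]
  expect_true(all(off == 0.3))
  expect_true(all(w3$W_EF == 0.3))
})

test_that("permuting input-channel labels permutes learned feedforward columns (end-to-end)", {
  # uniform init (sigma_W = 0) makes the setup permutation-symmetric
  set.seed(5)
  Y <- matrix(abs(rnorm(200 * 4, 1, 0.5)), 200, 4)
  Y[, 3] <- Y[, 3] * 2
  perm <- c(3, 1, 4, 2)
  base <- list(NE = 1L, NI = 0L, NF = 4L, a_E = 1, b_E = 0, n_E = 1,
               tau_E = 1, tau_I = 1, dt = 1, stimulus_duration = 1,
               mu_W = 0.25, sigma_W = 0,
               eps = learning_rates(eps_EF = 0.005),
               norms = weight_norms(W_EE = 1),
               protocol_kind = "ensemble", n_stimuli = 200L,
               tol_convergence = 0, seed = 3)
  f1 <- hebbnet(do.call(hebbnet_config, c(base, list(patterns = Y))))
  f2 <- hebbnet(do.call(hebbnet_config, c(base, list(patterns = Y[, perm]))))
  expect_equal(drop(f2$weights$W_EF), drop(f1$weights$W_EF)[perm],
               tolerance = 1e-12)
})

test_that("rates and weights remain non-negative along a training run", {
  fx <- make_fixture("toy_recurrent", seed = 2)
  fx$config$n_stimuli <- 60L
  fit <- hebbnet(fx$config)
  for (nm in names(fit$weights)) expect_true(all(fit$weights[[nm]] >= 0))
  expect_true(all(fit$state$rE >= 0) && all(fit$state$rI >= 0))
  expect_true(all(fit$history$mean_rE >= 0))
})
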