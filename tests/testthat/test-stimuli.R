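test_that("circular orientation distance wraps on a 180-degree ring", {
  expect_equal(circular_distance(30, 30), 0)
  expect_equal(circular_distance(10, 170), 20)
  expect_equal(circular_distance(0, 90), 90)
  set.seed(3)
  a <- runif(100, -360, 360); b <- runif(100, -360, 360)
  d <- circular_distance(a, b)
  expect_equal(d, circular_distance(b, a))
  expect_true(all(d >= 0 & d <= 90))
  # periodicity
  expect_equal(circular_distance(a + 180, b), d)
})

test_that("grating responses are Gaussian in circular distance with peak c * A_F", {
  tun <- input_tuning(NF = 10, sigma_F = 20, A_F = 1)
  expect_equal(grating_response(77, 0, tun), rep(0, 10))
  # channel at its preferred orientation responds at exactly c * A_F
  r <- grating_response(tun$theta_F[4], 0.7, tun)
  expect_equal(r[4], 0.7)
  expect_true(all(r <= r[4] + 1e-12))
  # direct evaluation at 20 degrees offset with sigma_F = 20
  tun1 <- input_tuning(NF = 1, sigma_F = 20, A_F = 1, theta_F = 50)
  expect_equal(grating_response(70, 1, tun1), exp(-0.5), tolerance = 1e-12)
  # invariance under theta + 180 and shift equivariance
  expect_equal(grating_response(30, 1, tun), grating_response(210, 1, tun))
  tun_shift <- input_tuning(NF = 10, sigma_F = 20, A_F = 1,
                            theta_F = tun$theta_F + 13)
  expect_equal(grating_response(30 + 13, 1, tun_shift),
               grating_response(30, 1, tun))
})

test_that("stimulus composition is additive and symmetric for orthogonal pairs", {
  tun <- input_tuning(NF = 18, sigma_F = 15, A_F = 2)
  one <- compose_stimuli(list(list(theta = 40, contrast = 0.5)), tun)
  expect_equal(one, grating_response(40, 0.5, tun))
  two <- compose_stimuli(list(list(theta = 40, contrast = 0.5),
                              list(theta = 40, contrast = 0.5)), tun)
  expect_equal(two, grating_response(40, 1, tun))
  # test 45 / mask 135 at equal contrast: profile symmetric about 90
  plaid <- compose_stimuli(list(list(theta = 45, contrast = 1),
                                list(theta = 135, contrast = 1)), tun)
  sym <- sapply(tun$theta_F, function(th) {
    mirrored <- (180 - th) %% 180
    j <- which(abs(circular_distance(tun$theta_F, mirrored)) < 1e-9)
    plaid[j]
  })
  expect_equal(plaid, sym)
  expect_error(compose_stimuli(list(), tun), "at least one")
})

test_that("grating training streams are reproducible and orientation-uniform", {
  p <- training_protocol(n_stimuli = 10000, contrast = 1)
  set.seed(123); s1 <- sample_training_stream(p)
  set.seed(123); s2 <- sample_training_stream(p)
  expect_identical(s1, s2)
  expect_true(all(s1$theta >= 0 & s1$theta < 180))
  ct <- table(cut(s1$theta, breaks = seq(0, 180, by = 10)))
  expect_gt(chisq.test(ct)$p.value, 0.01)
  expect_equal(nrow(sample_training_stream(training_protocol(0))), 0)
})

test_that("static feedforward weights are tuned Gaussians with exact row norms", {
  tun <- input_tuning(NF = 24, sigma_F = 12, A_F = 1)
  th_hat <- even_orientations(6)
  W <- static_feedforward_weights(th_hat, tun, sigma_theta = 15, norm = 1.4)
  expect_equal(rowSums(W), rep(1.4, 6), tolerance = 1e-12)
  for (i in seq_len(6)) {
    j <- which.max(W[i, ])
    expect_lte(circular_distance(tun$theta_F[j], th_hat[i]),
               circular_distance(tun$theta_F[which.min(W[i, ])], th_hat[i]))
    expect_equal(tun$theta_F[j], th_hat[i])
  }
  # very broad profile: rows tend to uniform norm / NF
  Wb <- static_feedforward_weights(th_hat, tun, sigma_theta = 1e5, norm = 2.4)
  expect_equal(Wb, matrix(2.4 / 24, 6, 24), tolerance = 1e-4)
})

test_that("center/surround streams implement correlated and independent statistics", {
  lay_c <- center_surround_layout("correlated", 20, 16, 4)
  lay_i <- center_surround_layout("independent", 20, 16, 4)
  p <- training_protocol(n_stimuli = 10000, contrast = 0.5)
  set.seed(7); sc <- center_surround_stream(lay_c, p)
  expect_identical(sc$theta_center, sc$theta_surround)
  expect_true(all(sc$contrast_center == 0.5 & sc$contrast_surround == 0.5))

  set.seed(7); si <- center_surround_stream(lay_i, p)
  n_center <- sum(si$contrast_center > 0)
  # each region stimulated about half the time (binomial 99.9% interval)
  expect_lt(abs(n_center / 10000 - 0.5), 3.3 * 0.5 / sqrt(10000))
  expect_true(all((si$contrast_center > 0) != (si$contrast_surround > 0)))

  # input correlation across trials: matched channels perfectly correlated
  # under correlated statistics, near zero (never positive) when independent
  tun <- input_tuning(20, sigma_F = 15, A_F = 80)
  inp <- function(stream, i) {
    ctr <- if (stream$contrast_center[i] > 0)
      grating_response(stream$theta_center[i], stream$contrast_center[i], tun)
    else numeric(20)
    srd <- if (stream$contrast_surround[i] > 0)
      grating_response(stream$theta_surround[i], stream$contrast_surround[i], tun)
    else numeric(20)
    c(ctr, srd)
  }
  Xc <- t(sapply(1:400, function(i) inp(sc, i)))
  Xi <- t(sapply(1:400, function(i) inp(si, i)))
  cc <- diag(cor(Xc[, 1:20], Xc[, 21:40]))
  ci <- diag(cor(Xi[, 1:20], Xi[, 21:40]))
  expect_equal(cc, rep(1, 20), tolerance = 1e-12)
  expect_true(all(ci < 0.05))
  expect_lt(mean(abs(ci)), 0.25)
})
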