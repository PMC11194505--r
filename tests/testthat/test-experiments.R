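test_that("presets carry the reference parameter sets and validation catches bad fields", {
  cfg <- hebbnet_config("single_neuron")
  expect_equal(cfg$NE, 1L)
  expect_equal(cfg$NI, 10L)
  expect_equal(cfg$NF, 10L)
  expect_equal(cfg$dt, 200)
  expect_equal(cfg$tau_E, 200)
  expect_equal(cfg$eps$eps_EF, 1e-4)
  expect_equal(cfg$eps$eps_EI, 2e-4)
  expect_equal(cfg$norms$W_EE, 10)
  expect_equal(cfg$norms$W_EI, 5)
  expect_equal(cfg$sigma_F, 20)
  expect_true(cfg$clamp_I)

  small <- hebbnet_config("recurrent_small")
  expect_equal(c(small$NE, small$NI, small$NF), c(10L, 10L, 40L))
  expect_equal(small$eps$eps_EE, 2e-9)
  expect_equal(small$norms$W_EE, 2)
  expect_equal(small$A_F, 35)

  expect_error(hebbnet_config("single_neuron", dt = 0), "dt")
  expect_error(hebbnet_config("single_neuron", bogus_field = 1), "unknown")
  expect_error(hebbnet_config(NE = 0L, NI = 0L, NF = 4L), "at least one")
  for (p in preset_names()) expect_s3_class(hebbnet_config(p), "hebbnet_config")
})

test_that("configurations round-trip through the YAML file format", {
  cfg <- hebbnet_config("recurrent_small", n_stimuli = 123L, seed = 9L)
  f <- tempfile(fileext = ".yaml")
  save_config(cfg, f)
  back <- load_config(f)
  for (nm in names(cfg)) {
    if (is.null(cfg[[nm]])) next
    expect_equal(back[[nm]], cfg[[nm]], info = nm, ignore_attr = TRUE)
  }
  # unknown keys are rejected with the key named
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("preset: single_neuron", "not_a_field: 3"), bad)
  expect_error(load_config(bad), "not_a_field")
  expect_error(load_config(tempfile()), "no such file")
})

test_that("training runs are deterministic given config and seed", {
  f1 <- hebbnet("single_neuron", n_stimuli = 150L, seed = 7)
  f2 <- hebbnet("single_neuron", n_stimuli = 150L, seed = 7)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$stream, f2$stream)
  expect_identical(f1$history, f2$history)
  f3 <- hebbnet("single_neuron", n_stimuli = 150L, seed = 8)
  expect_false(identical(f3$weights$W_EF, f1$weights$W_EF))
})

test_that("with all learning rates zero the final weights equal the initial weights", {
  cfg <- hebbnet_config("recurrent_small", n_stimuli = 30L,
                        eps = learning_rates(), seed = 2)
  fit <- hebbnet(cfg)
  expect_identical(fit$weights, fit$weights_init)
})

test_that("the compiled training loop reproduces the exported per-step operations", {
  cfg <- hebbnet_config("recurrent_small", n_stimuli = 10L,
                        tol_convergence = 0, seed = 13)
  fit <- hebbnet(cfg)
  set.seed(cfg$seed)
  model <- hebbnet:::build_model(cfg)
  w <- hebbnet:::build_weights(cfg, model)
  stream <- hebbnet:::build_stream(cfg, model)
  s <- zero_state(model$dims, model$act_E, model$act_I)
  for (i in seq_len(10)) {
    rF <- hebbnet:::stream_input(cfg, model, stream, i)
    for (k in seq_len(fit$steps_per_stimulus)) {
      s <- euler_step(s, w, rF, model$dyn, model$act_E, model$act_I)
      w <- competitive_plasticity_step(s, rF, w, cfg$eps, cfg$norms, cfg$dt,
                                       exclude_autapses = cfg$exclude_autapses)
    }
  }
  for (b in names(w))
    expect_equal(fit$weights[[b]], w[[b]], tolerance = 1e-12, info = b)
  expect_equal(fit$state$uE, s$uE, tolerance = 1e-12)
})

test_that("resuming from a snapshot with the same stream reproduces the remainder of a run", {
  cfg <- hebbnet_config("recurrent_small", n_stimuli = 40L,
                        snapshot_every = 20L, keep_snapshots = TRUE,
                        tol_convergence = 0, seed = 5)
  full <- hebbnet(cfg)
  half <- hebbnet(hebbnet_config("recurrent_small", n_stimuli = 20L,
                                 tol_convergence = 0, seed = 5))
  # same stream prefix, same state at 20 stimuli
  expect_identical(half$weights, full$snapshots[[1]])
  # resume: warm start from the half state and replay only the second half
  # of the stream (the initializer draws are consumed identically, so the
  # resumed stream matches the full run's)
  cfg2 <- hebbnet_config("recurrent_small", n_stimuli = 40L,
                         tol_convergence = 0, seed = 5)
  res <- hebbnet(cfg2, init_weights = half$weights, init_state = half$state,
                 skip_stimuli = 20L)
  expect_identical(res$stream, full$stream)
  expect_identical(res$weights, full$weights)
  expect_identical(res$state$uE, full$state$uE)
})

test_that("fixtures construct what they promise", {
  fx <- make_fixture("two_channel_pca", seed = 3, n_patterns = 4000)
  ev <- principal_eigenvector(second_moment(fx$ensemble))
  ang <- acos(abs(cosine(ev, fx$axis))) * 180 / pi
  expect_lt(ang, 2)
  expect_true(all(fx$ensemble >= 0))

  fx2 <- make_fixture("paired_ei_pca", seed = 3)
  expect_true(fx2$config$clamp_I)  # inhibitory stream mirrors the excitatory one
  expect_equal(fx2$config$NI, 2L)

  fx3 <- make_fixture("toy_recurrent", seed = 1)
  expect_s3_class(validate_config(fx3$config), "hebbnet_config")

  fx4 <- make_fixture("tiny_center_surround", seed = 1, mode = "independent")
  expect_equal(fx4$config$layout$mode, "independent")
  expect_equal(fx4$config$NF, 2L * fx4$config$layout$NF_region)
})

test_that("every preset trains end-to-end at desk scale with non-negative weights", {
  for (p in preset_names()) {
    fit <- hebbnet(p, n_stimuli = 30L, seed = 4, snapshot_every = 10L,
                   tol_convergence = 0)
    expect_equal(fit$n_presented, 30L, info = p)
    for (nm in names(fit$weights))
      expect_true(all(fit$weights[[nm]] >= 0), info = paste(p, nm))
    expect_gte(nrow(fit$history), 2L)
  }
})

test_that("statically tuned lateral neurons keep their assigned tuning during training", {
  fit <- hebbnet("microcircuit_lateral_E", n_stimuli = 100L, seed = 2)
  # the static neuron's feedforward row is unchanged from initialization
  expect_identical(fit$weights$W_EF[2, ], fit$weights_init$W_EF[2, ])
  expect_true(all(fit$weights$W_EE[2, ] == 0))
  # the plastic neuron's pooled excitatory inputs stay on the norm
  pooled <- sum(fit$weights$W_EE[1, ]) + sum(fit$weights$W_EF[1, ])
  expect_equal(pooled, fit$config$norms$W_EE, tolerance = 1e-10)
})

test_that("a divergent configuration reports the stimulus and step and inherits the error class", {
  # recurrent excitation with no inhibition and a large norm blows up
  cfg <- hebbnet_config(NE = 3L, NI = 0L, NF = 3L,
                        a_E = 1, b_E = 0, n_E = 2,
                        tau_E = 10, tau_I = 10, dt = 5, stimulus_duration = 200,
                        mu_W = 0.2, sigma_W = 0.1, zero_recurrent_E = "none",
                        eps = learning_rates(eps_EE = 1e-4, eps_EF = 1e-4),
                        norms = weight_norms(W_EE = 50),
                        A_F = 10, sigma_F = 30, n_stimuli = 50L, seed = 1)
  err <- tryCatch(hebbnet(cfg), error = function(e) e)
  expect_s3_class(err, "hebbnet_divergence")
  expect_match(conditionMessage(err), "stimulus \\d+, step \\d+")
})

test_that("runs serialize to flat files and read back consistently", {
  fit <- cached_fit("single_short", function()
    hebbnet("single_neuron", n_stimuli = 100L, seed = 3))
  dir <- file.path(tempdir(), "runout")
  write_run(fit, dir)
  expect_true(file.exists(file.path(dir, "config.yaml")))
  expect_true(file.exists(file.path(dir, "final_W_EF.csv")))
  expect_true(file.exists(file.path(dir, "summary.json")))
  back <- read_weight_set(dir, fit$dims, prefix = "final_")
  expect_equal(back$W_EF, fit$weights$W_EF, ignore_attr = TRUE)
  side <- jsonlite::read_json(file.path(dir, "summary.json"))
  expect_equal(side$n_presented, fit$n_presented)
  # ensemble CSV reader
  f <- tempfile(fileext = ".csv")
  X <- matrix(rnorm(20), 5)
  write.table(X, f, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_equal(read_ensemble_csv(f), X, tolerance = 1e-12)
})

test_that("fit methods expose the model components", {
  fit <- cached_fit("single_short", function()
    hebbnet("single_neuron", n_stimuli = 100L, seed = 3))
  expect_s3_class(coef(fit), "weight_set")
  expect_equal(dim(coef(fit, "W_EF")), c(1L, 10L))
  s <- summary(fit)
  expect_lt(s$norm_residual, 1e-10)
  expect_output(print(s), "uniformity")
  streams <- simulate(fit, nsim = 2, seed = 1)
  expect_length(streams, 2)
  expect_equal(nrow(streams[[1]]), fit$config$n_stimuli)
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  # predict returns one row per probe stimulus
  pr <- predict(fit, data.frame(theta = c(0, 45, 90), contrast = 1))
  expect_equal(dim(pr), c(3L, 1L))
  expect_true(all(pr >= 0))
})
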