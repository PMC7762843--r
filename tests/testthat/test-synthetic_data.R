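test_that("identical configs produce bit-identical datasets", {
  cfg <- tiny_config(rng_seed = 42)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_dataset(tiny_config(rng_seed = 43))
  expect_false(identical(d1$epochs, d3$epochs))
})

test_that("effect specs are validated against the config", {
  expect_error(effect_spec("pattern_rotation", "r1", c(100, 200), 120), "90")
  expect_error(effect_spec("power_gain", "r1", c(100, 200), -1.5), "-1")
  expect_error(
    sim_config(regions = "r1",
               effects = list(effect_spec("power_gain", "elsewhere",
                                          c(100, 200), 0.5))),
    "not in cfg regions")
})

test_that("condition-mean signal scales linearly with amplitude in the noise-free limit", {
  # very high snr ~ noise-free; compare region RMS of condition means under
  # a power gain: post amplitude = (1+beta) * pre inside the window
  beta <- 0.7
  cfg <- sim_config(n_subjects = 1, regions = "r1", n_vertices = 20,
                    n_trials = 50, snr = 1e4, rng_seed = 5, effect_sd = 0,
                    effects = list(effect_spec("power_gain", "r1",
                                               c(100, 200), beta)))
  ds <- simulate_dataset(cfg)
  win <- ds$time_ms >= 100 & ds$time_ms <= 200
  pre <- apply(ds$epochs[[1]]$r1$O1_pre, c(1, 2), mean)
  post <- apply(ds$epochs[[1]]$r1$O1_post, c(1, 2), mean)
  rms <- function(m) sqrt(mean(m^2))
  expect_equal(rms(post[, win]) / rms(pre[, win]), 1 + beta, tolerance = 1e-3)
  # pattern untouched: condition-mean maps collinear inside the window
  ip <- sum(pre[, win] * post[, win]) /
    sqrt(sum(pre[, win]^2) * sum(post[, win]^2))
  expect_equal(ip, 1, tolerance = 1e-6)
})

test_that("a 90-degree rotation makes pre/post condition-mean maps orthogonal at high snr", {
  cfg <- sim_config(n_subjects = 1, regions = "r1", n_vertices = 30,
                    n_trials = 50, snr = 1e4, rng_seed = 6,
                    effects = list(effect_spec("pattern_rotation", "r1",
                                               c(100, 200), 90)))
  ds <- simulate_dataset(cfg)
  win <- ds$time_ms >= 100 & ds$time_ms <= 200
  pre <- rowMeans(apply(ds$epochs[[1]]$r1$O1_pre[, win, ], c(1, 2), mean))
  post <- rowMeans(apply(ds$epochs[[1]]$r1$O1_post[, win, ], c(1, 2), mean))
  cosang <- sum(pre * post) / sqrt(sum(pre^2) * sum(post^2))
  expect_lt(abs(cosang), 1e-3)
  # rotation preserves signal power
  expect_equal(sqrt(sum(post^2)) / sqrt(sum(pre^2)), 1, tolerance = 1e-3)
})

test_that("rotation by theta produces exactly theta between condition-mean maps at high snr", {
  for (theta in c(30, 60)) {
    cfg <- sim_config(n_subjects = 1, regions = "r1", n_vertices = 30,
                      n_trials = 50, snr = 1e4, rng_seed = 8,
                      effects = list(effect_spec("pattern_rotation", "r1",
                                                 c(100, 200), theta)))
    ds <- simulate_dataset(cfg)
    win <- ds$time_ms >= 100 & ds$time_ms <= 200
    pre <- rowMeans(apply(ds$epochs[[1]]$r1$O1_pre[, win, ], c(1, 2), mean))
    post <- rowMeans(apply(ds$epochs[[1]]$r1$O1_post[, win, ], c(1, 2), mean))
    expect_equal(pattern_angle(pre, post), theta, tolerance = 0.1)
  }
})

test_that("null datasets leave same-stimulus pairs at chance while distinct stimuli decode", {
  cfg <- sim_config(n_subjects = 4, regions = "r1", n_vertices = 30,
                    n_trials = 50, rng_seed = 9)
  ds <- null_dataset(cfg)
  rd <- compute_empirical_rdms(ds, pipeline_config(analysis_window_ms = c(60, 200),
                                                   rng_seed = 9))
  sru <- mean(rd$acc[, , rd$pairs$component == "sRU", ])
  sna <- mean(rd$acc[, , rd$pairs$component == "sNa", ])
  un <- mean(rd$acc[, , rd$pairs$component == "UN", ])
  # same pattern pre/post and across sessions: chance
  expect_lt(abs(sru - 0.5), 0.05)
  expect_lt(abs(sna - 0.5), 0.05)
  # sNa and sRU are exchangeable by construction
  expect_lt(abs(sru - sna), 0.06)
  # distinct stimuli are decodable in the evoked window
  expect_gt(un, 0.55)
})

test_that("delayed shared pattern appears in pre-state at W and post-state at W+dt", {
  dt <- 100
  cfg <- sim_config(n_subjects = 1, regions = "r1", n_vertices = 30,
                    n_trials = 50, snr = 1e4, rng_seed = 10,
                    effects = list(effect_spec("delayed_shared_pattern", "r1",
                                               c(140, 180), dt)))
  ds <- simulate_dataset(cfg)
  t1 <- ds$time_ms >= 140 & ds$time_ms <= 180
  t2 <- ds$time_ms >= 140 + dt & ds$time_ms <= 180 + dt
  m_pre <- apply(ds$epochs[[1]]$r1$O1_pre, c(1, 2), mean)
  m_post <- apply(ds$epochs[[1]]$r1$O2_post, c(1, 2), mean)
  # the shared component: pre-state in W vs post-state in W+dt correlate
  # once the stimulus-specific envelope part is projected out is hard to
  # isolate exactly; instead check the injected bump raises power in the
  # right windows relative to a no-effect control
  ctrl <- simulate_dataset(sim_config(n_subjects = 1, regions = "r1",
                                      n_vertices = 30, n_trials = 50,
                                      snr = 1e4, rng_seed = 10))
  c_pre <- apply(ctrl$epochs[[1]]$r1$O1_pre, c(1, 2), mean)
  c_post <- apply(ctrl$epochs[[1]]$r1$O2_post, c(1, 2), mean)
  gain_pre_W <- sum(m_pre[, t1]^2) - sum(c_pre[, t1]^2)
  gain_post_W2 <- sum(m_post[, t2]^2) - sum(c_post[, t2]^2)
  gain_pre_W2 <- sum(m_pre[, t2]^2) - sum(c_pre[, t2]^2)
  expect_gt(gain_pre_W, 0)
  expect_gt(gain_post_W2, 0)
  expect_lt(abs(gain_pre_W2), gain_post_W2 / 2)
})
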