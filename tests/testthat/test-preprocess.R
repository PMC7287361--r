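test_that("block-mean downsampling reduces 32 Hz to 8 Hz exactly 4:1", {
  tr <- eda_trace(seq_len(320), 32)
  out <- downsample(tr, 8)
  expect_equal(out$sample_rate, 8)
  expect_length(out$values, 80)
  ## each output sample is the mean of its 4-sample block
  expect_equal(out$values[1], mean(1:4))
  expect_equal(out$values[80], mean(317:320))
})

test_that("downsampling a ramp yields block midpoints and keeps constants", {
  ramp <- eda_trace(seq(0, 1, length.out = 32), 32)
  out <- downsample(ramp, 8)
  blocks <- matrix(ramp$values, nrow = 4)
  expect_equal(out$values, colMeans(blocks))
  const <- downsample(eda_trace(rep(2.5, 64), 32), 8)
  expect_true(all(const$values == 2.5))
  expect_error(downsample(eda_trace(1:10, 8), 32), "exceeds")
})

test_that("z-scoring normalises, is idempotent, and rejects flat traces", {
  tr <- eda_trace(c(1, 2, 3), 8)
  z <- zscore(tr)
  expect_equal(mean(z$values), 0, tolerance = 1e-10)
  expect_equal(stats::sd(z$values), 1, tolerance = 1e-10)
  z2 <- zscore(z)
  expect_equal(z2$values, z$values, tolerance = 1e-10)
  expect_error(zscore(eda_trace(rep(1, 10), 8)), "degenerate")
})

test_that("downsample + zscore pipeline is normalised for random traces", {
  set.seed(21)
  for (i in 1:50) {
    tr <- eda_trace(stats::rnorm(32 * stats::rpois(1, 40) + 64), 32)
    z <- prepare_crqa_series(tr)
    expect_lt(abs(mean(z$values)), 1e-8)
    expect_lt(abs(stats::sd(z$values) - 1), 1e-8)
  }
})

test_that("SCR scoring recovers an embedded unit response and floors at zero", {
  fs <- 32
  tt <- (0:(30 * fs - 1)) / fs
  k <- scr_kernel(amplitude = 1)
  onset <- 10
  tr <- eda_trace(scr_kernel_eval(k, tt - onset), fs)
  amp <- score_scr(tr, onset)
  expect_equal(amp, 1, tolerance = 0.02)
  ## flat trace scores zero
  expect_equal(score_scr(eda_trace(rep(0.3, 30 * fs), fs), onset), 0)
  ## a response ending before onset never yields a negative amplitude
  pre <- eda_trace(scr_kernel_eval(k, tt - 2), fs)
  expect_equal(score_scr(pre, 15), 0)
  expect_error(score_scr(tr, 29), "exceeds")
})

test_that("score_phase yields one deviation-coded row per CS presentation", {
  d <- tiny_dataset(n_dyads = 2)
  bl <- d$dyads[[1]]$blocks[[1]]
  test_rows <- score_phase(bl$obs_testing, bl$schedule)
  expect_equal(nrow(test_rows), 14)
  expect_equal(sum(test_rows$cs_code == 0.5), 7)
  expect_equal(sum(test_rows$cs_code == -0.5), 7)
  learn_rows <- score_phase(bl$obs_learning, bl$schedule)
  expect_equal(nrow(learn_rows), 6)  # 3 per CS in the reduced design
  expect_true(all(learn_rows$amplitude_raw >= 0))
  none <- score_phase(bl$obs_testing, bl$schedule,
                      preprocess_config(transform = "none"))
  expect_equal(none$amplitude_tx, none$amplitude_raw)
  lg <- score_phase(bl$obs_testing, bl$schedule)
  expect_equal(lg$amplitude_tx, log1p(lg$amplitude_raw))
})

test_that("full-design testing phase scores 14 rows and learning 12", {
  set.seed(31)
  des <- design_config(sample_rate = 8)
  sched <- make_schedule(des)
  cp <- coupling_config()
  demo <- synth_demonstrator_trace(sched, "testing", default_kernels(),
                                   cp, 8)
  obs <- synth_observer_trace(attr(demo, "events"), sched, "testing", cp,
                              default_kernels(), 8)
  expect_equal(nrow(score_phase(obs, sched)), 14)
  demo_l <- synth_demonstrator_trace(sched, "learning", default_kernels(),
                                     cp, 8)
  obs_l <- synth_observer_trace(attr(demo_l, "events"), sched, "learning",
                                cp, default_kernels(), 8)
  expect_equal(nrow(score_phase(obs_l, sched)), 12)
})

test_that("UCS responses score one amplitude per shock, anchored at delivery", {
  d <- generate_dataset(design_config(n_dyads = 2, n_blocks = 1,
                                      sample_rate = 8), seed = 3)
  bl <- d$dyads[[1]]$blocks[[1]]
  u <- ucs_responses(bl$obs_learning, bl$schedule)
  expect_length(u$amplitudes, 4)
  expect_equal(u$mean, mean(u$amplitudes))
  ## flat observer trace gives zero mean
  flat <- eda_trace(rep(0, length(bl$obs_learning$values)), 8,
                    phase = "learning")
  expect_equal(ucs_responses(flat, bl$schedule)$mean, 0)
  ## no shocks -> error
  sched_noshock <- bl$schedule
  sched_noshock$shock[sched_noshock$phase == "learning"] <- FALSE
  expect_error(ucs_responses(bl$obs_learning, sched_noshock), "no shock")
})

test_that("doubling embedded shock responses doubles the scored UCS mean", {
  set.seed(12)
  des <- design_config(n_cs_each_learning = 3, n_shocked_csplus = 2,
                       sample_rate = 32)
  sched <- make_schedule(des)
  cp <- coupling_config(kappa = 0, spontaneous_rate = 0, noise_sd = 0,
                        amp_jitter_sdlog = 0, arousal_mod = 0,
                        arousal_drive = 0, micro_drive = 0,
                        latency_jitter_sd = 0, vicarious_gain = 1)
  ## CS responses are silenced so the scored UCS amplitude is a pure
  ## (linear) function of the shock kernel
  kern1 <- list(shock = scr_kernel(amplitude = 1),
                cs_plus = scr_kernel(amplitude = 0),
                cs_minus = scr_kernel(amplitude = 0))
  kern2 <- kern1
  kern2$shock <- scr_kernel(amplitude = 2)
  demo1 <- synth_demonstrator_trace(sched, "learning", kern1, cp, 32)
  obs1 <- synth_observer_trace(attr(demo1, "events"), sched, "learning",
                               cp, kern1, 32)
  demo2 <- synth_demonstrator_trace(sched, "learning", kern2, cp, 32)
  obs2 <- synth_observer_trace(attr(demo2, "events"), sched, "learning",
                               cp, kern2, 32)
  u1 <- ucs_responses(obs1, sched)
  u2 <- ucs_responses(obs2, sched)
  expect_equal(u2$mean, 2 * u1$mean, tolerance = 0.05)
})

test_that("testing-phase CS+ responses exceed CS- when learning gain is active", {
  cp <- coupling_config(learning_gain = 0.8, noise_sd = 0,
                        spontaneous_rate = 0, amp_jitter_sdlog = 0)
  d <- generate_dataset(design_config(n_dyads = 10, n_blocks = 1,
                                      sample_rate = 8), cp,
                        kappa_sampler = function(n) rep(0.8, n), seed = 14)
  tr <- assemble_trials(d)
  expect_gt(mean(tr$amplitude_raw[tr$cs == "plus"]),
            mean(tr$amplitude_raw[tr$cs == "minus"]))
})
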