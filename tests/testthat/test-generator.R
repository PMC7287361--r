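test_that("SCR kernel is causal, zero at onset, and peak-normalised", {
  k <- scr_kernel(amplitude = 1, tau_rise = 0.75, tau_decay = 2.5,
                  latency = 1)
  expect_equal(scr_kernel_eval(k, c(-1, 0, 0.5, 1)), rep(0, 4))
  ## dense grid search confirms the closed-form peak normalisation
  tt <- seq(0, 30, by = 1e-4)
  v <- scr_kernel_eval(k, tt)
  expect_equal(max(v), 1, tolerance = 1e-6)
  expect_equal(tt[which.max(v)], scr_kernel_peak_time(k), tolerance = 1e-3)
  expect_error(scr_kernel(tau_rise = 3, tau_decay = 2), "smaller")
})

test_that("kernel peak scales linearly with amplitude", {
  k2 <- scr_kernel(amplitude = 2.5)
  tt <- seq(0, 20, by = 0.001)
  expect_equal(max(scr_kernel_eval(k2, tt)), 2.5, tolerance = 1e-5)
})

silent_coupling <- function(...) {
  coupling_config(spontaneous_rate = 0, noise_sd = 0, amp_jitter_sdlog = 0,
                  arousal_mod = 0, arousal_drive = 0, micro_drive = 0, ...)
}

test_that("silent generator produces an identically zero trace", {
  set.seed(2)
  des <- design_config(n_cs_each_learning = 3, n_shocked_csplus = 2)
  sched <- make_schedule(des)
  kern0 <- list(shock = scr_kernel(amplitude = 0),
                cs_plus = scr_kernel(amplitude = 0),
                cs_minus = scr_kernel(amplitude = 0))
  tr <- synth_demonstrator_trace(sched, "learning", kern0,
                                 silent_coupling(), 32)
  expect_true(all(tr$values == 0))
})

test_that("a lone shock response peaks at the analytic kernel peak time", {
  set.seed(3)
  des <- design_config(n_cs_each_learning = 1, n_shocked_csplus = 1)
  sched <- make_schedule(des)
  kern <- list(shock = scr_kernel(amplitude = 1),
               cs_plus = scr_kernel(amplitude = 0),
               cs_minus = scr_kernel(amplitude = 0))
  tr <- synth_demonstrator_trace(sched, "learning", kern,
                                 silent_coupling(), 32)
  shock_t <- sched$shock_time_s[which(sched$shock & sched$phase == "learning")]
  peak_t <- trace_times(tr)[which.max(tr$values)]
  expect_equal(peak_t, shock_t + scr_kernel_peak_time(kern$shock),
               tolerance = 1 / 32 + 1e-9)
})

test_that("traces are reproducible under a fixed seed", {
  d1 <- generate_dataset(design_config(n_dyads = 2, n_blocks = 1,
                                       sample_rate = 8), seed = 17)
  d2 <- generate_dataset(design_config(n_dyads = 2, n_blocks = 1,
                                       sample_rate = 8), seed = 17)
  expect_identical(d1$dyads[[1]]$blocks[[1]]$obs_learning$values,
                   d2$dyads[[1]]$blocks[[1]]$obs_learning$values)
  expect_identical(d1$ground_truth, d2$ground_truth)
})

test_that("kappa = 1 observer copies the demonstrator pointwise", {
  set.seed(4)
  des <- design_config(n_cs_each_learning = 3, n_shocked_csplus = 2)
  sched <- make_schedule(des)
  kern <- default_kernels()
  cp <- silent_coupling(kappa = 1, lag = 0, vicarious_gain = 1)
  demo <- synth_demonstrator_trace(sched, "learning", kern, cp, 32)
  obs <- synth_observer_trace(attr(demo, "events"), sched, "learning",
                              cp, kern, 32)
  expect_equal(obs$values, demo$values, tolerance = 1e-12)
})

test_that("kappa = 0 dyads show near-zero lag-0 correlation on average", {
  set.seed(6)
  des <- design_config(n_dyads = 30, n_blocks = 1, sample_rate = 8)
  d <- generate_dataset(des, kappa_sampler = function(n) rep(0, n),
                        seed = 8)
  r0 <- vapply(d$dyads, function(dy) {
    x <- prepare_crqa_series(dy$blocks[[1]]$demo_learning)$values
    y <- prepare_crqa_series(dy$blocks[[1]]$obs_learning)$values
    n <- min(length(x), length(y))
    stats::cor(x[seq_len(n)], y[seq_len(n)])
  }, 0)
  expect_lt(mean(abs(r0)), 0.2)
})

test_that("lag-0 correlation increases monotonically with kappa", {
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  means <- vapply(seq_along(grid), function(i) {
    d <- generate_dataset(
      design_config(n_dyads = 25, n_blocks = 1, sample_rate = 8),
      kappa_sampler = function(n) rep(grid[i], n), seed = 30 + i)
    mean(vapply(d$dyads, function(dy) {
      x <- prepare_crqa_series(dy$blocks[[1]]$demo_learning)$values
      y <- prepare_crqa_series(dy$blocks[[1]]$obs_learning)$values
      n <- min(length(x), length(y))
      stats::cor(x[seq_len(n)], y[seq_len(n)])
    }, 0))
  }, 0)
  expect_true(all(diff(means) > 0))
  expect_gt(suppressWarnings(cor(grid, means, method = "spearman")), 0.9)
})

test_that("with a flat learning model the testing phases show no CS difference", {
  ## learning_gain = 0, no baseline CS effect, extinction off: CS+ and CS-
  ## testing amplitudes are exchangeable by construction
  cp <- coupling_config(learning_gain = 0, beta_cs_base = 0,
                        extinction_rate = 0)
  d <- generate_dataset(design_config(n_dyads = 25, n_blocks = 1,
                                      sample_rate = 8), cp, seed = 9)
  tr <- assemble_trials(d)
  diff_cs <- mean(tr$amplitude_raw[tr$cs == "plus"]) -
    mean(tr$amplitude_raw[tr$cs == "minus"])
  expect_lt(abs(diff_cs), 0.03)
})

test_that("testing-phase CS differentiation regressed on kappa recovers the gain", {
  ## beta0 is raised so the zero floor on amplitudes never binds, and
  ## nonspecific SCRs are off: spontaneous activity overlapping the
  ## scoring window biases trough-to-peak amplitudes by a few percent
  ## (true of real SCR scoring too), while this contract concerns the
  ## generative response model itself
  cp <- coupling_config(learning_gain = 0.5, extinction_rate = 0,
                        amp_jitter_sdlog = 0.2, beta0 = 0.8,
                        spontaneous_rate = 0)
  d <- generate_dataset(design_config(n_dyads = 69, n_blocks = 1,
                                      sample_rate = 8), cp, seed = 10)
  per_dyad <- vapply(d$dyads, function(dy) {
    bl <- dy$blocks[[1]]
    tt <- score_phase(bl$obs_testing, bl$schedule,
                      preprocess_config(transform = "none"))
    mean(tt$amplitude_raw[tt$cs == "plus"]) -
      mean(tt$amplitude_raw[tt$cs == "minus"])
  }, 0)
  fit <- stats::lm(per_dyad ~ d$ground_truth$kappa)
  est <- summary(fit)$coefficients[2, ]
  expect_lt(abs(est["Estimate"] - 0.5), 2 * est["Std. Error"])
})

test_that("dataset shape matches the experimental design", {
  d <- tiny_dataset(n_dyads = 3, n_blocks = 4)
  expect_length(d$dyads, 3)
  expect_length(d$dyads[[1]]$blocks, 4)
  ## 3 dyads x 4 blocks learning phases
  n_phases <- sum(vapply(d$dyads, function(dy)
    sum(vapply(dy$blocks, function(b)
      !is.null(b$demo_learning), TRUE)), 0L))
  expect_equal(n_phases, 12)
  ## role reversal halfway: observer ids differ between halves
  b <- d$dyads[[1]]$blocks
  expect_true(b[[1]]$role_first && b[[2]]$role_first)
  expect_false(b[[3]]$role_first || b[[4]]$role_first)
  expect_equal(b[[1]]$observer_id, b[[2]]$observer_id)
  expect_false(b[[1]]$observer_id == b[[3]]$observer_id)
})

test_that("degenerate kappa sampler propagates to ground truth", {
  d <- generate_dataset(design_config(n_dyads = 3, n_blocks = 1,
                                      sample_rate = 8),
                        kappa_sampler = function(n) rep(0.5, n), seed = 2)
  expect_equal(d$ground_truth$kappa, rep(0.5, 3))
  expect_error(generate_dataset(design_config(n_dyads = 1), seed = 1),
               "at least 2")
})

test_that("every generated trace covers its schedule span", {
  d <- tiny_dataset(n_dyads = 2, n_blocks = 2)
  for (dy in d$dyads) for (bl in dy$blocks) {
    for (ph in c("learning", "testing")) {
      s <- bl$schedule[bl$schedule$phase == ph, ]
      tr <- bl[[paste0("obs_", ph)]]
      expect_gte(max(trace_times(tr)), max(s$onset_s + s$duration_s))
    }
  }
})
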