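test_that("time-delay embedding matches direct index arithmetic", {
  expect_equal(embed_series(1:5, 1, 2),
               rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5)))
  expect_equal(embed_series(1:7, 2, 3),
               rbind(c(1, 3, 5), c(2, 4, 6), c(3, 5, 7)))
  x <- rnorm(10)
  expect_equal(embed_series(x, 3, 1), matrix(x, ncol = 1))
  expect_error(embed_series(1:5, 3, 3), "too short")
  set.seed(41)
  for (i in 1:20) {
    x <- rnorm(sample(20:60, 1))
    d <- sample(1:4, 1); m <- sample(1:4, 1)
    if (length(x) < (m - 1) * d + 1) next
    expect_equal(embed_series(x, d, m), oracle_embed(x, d, m))
  }
})

test_that("cross-recurrence limits: infinite, zero, and self radius", {
  set.seed(42)
  xe <- embed_series(rnorm(30), 1, 2)
  ye <- embed_series(rnorm(30), 1, 2)
  expect_true(all(cross_recurrence(xe, ye, Inf) == 1))
  expect_true(all(cross_recurrence(xe, ye, 1e-12) == 0))
  Rs <- cross_recurrence(xe, xe, 1e-12)
  expect_true(all(diag(Rs) == 1))
  expect_error(cross_recurrence(xe, embed_series(rnorm(30), 1, 3), 1),
               "dimensions differ")
})

test_that("line counting and metrics match the worked 5x5 example", {
  R <- matrix(0L, 5, 5)
  R[cbind(c(1, 2, 3, 1, 4), c(1, 2, 3, 4, 1))] <- 1L
  d <- sort(diagonal_lines(R, 1))
  expect_equal(d, c(1, 1, 3))
  expect_length(vertical_lines(R, 2), 0)
  m <- compute_metrics(R)
  expect_equal(m$rr, 5 / 25)
  expect_equal(m$det, 3 / 5)
  expect_equal(m$lam, 0)
  expect_equal(m$maxl, 3L)
  expect_equal(m$rentr, 0)
})

test_that("degenerate matrices give the documented limits", {
  ones <- matrix(1L, 4, 4)
  m1 <- compute_metrics(ones)
  ## the two corner cells are diagonals of length 1, below lmin = 2
  expect_equal(m1$rr, 1); expect_equal(m1$det, 14 / 16)
  expect_equal(m1$lam, 1); expect_equal(m1$maxl, 4L)
  expect_equal(sort(vertical_lines(ones, 1)), rep(4L, 4))
  expect_equal(max(diagonal_lines(diag(1L, 6), 1)), 6L)
  m0 <- compute_metrics(matrix(0L, 4, 4))
  expect_true(m0$degenerate)
  expect_equal(c(m0$rr, m0$det, m0$lam, m0$maxl, m0$rentr), rep(0, 5))
})

test_that("metrics equal brute-force enumeration on 200 random matrices", {
  set.seed(77)
  for (i in 1:200) {
    nr <- sample(2:12, 1); nc <- sample(2:12, 1)
    R <- matrix(rbinom(nr * nc, 1, runif(1, 0.1, 0.7)), nr, nc)
    m <- compute_metrics(R)
    o <- oracle_metrics(R)
    expect_equal(m$rr, o$rr)
    expect_equal(m$det, o$det)
    expect_equal(m$lam, o$lam)
    expect_equal(m$maxl, as.integer(o$maxl))
    expect_equal(m$entr, o$entr)
    expect_equal(m$rentr, o$rentr)
  }
})

test_that("AMI delay selection finds the quarter period of a sine wave", {
  ## a little noise keeps the histogram AMI estimator off its degenerate
  ## noiseless-deterministic artifacts
  set.seed(3)
  t <- 0:1599
  x <- sin(2 * pi * t / 32) + rnorm(1600, sd = 0.05)
  d <- select_delay(x, 20)
  expect_gte(d, 6); expect_lte(d, 10)
  expect_error(select_delay(x, 1), "at least 2")
})

test_that("delay selection on iid noise returns a lag in range", {
  set.seed(8)
  d <- select_delay(rnorm(500), 20)
  expect_gte(d, 1); expect_lte(d, 20)
})

test_that("FNN dimension: low for a sinusoid, high for white noise", {
  t <- 0:599
  x <- sin(2 * pi * t / 40)
  expect_lte(select_dim(x, delay = 10), 3)
  set.seed(9)
  expect_gte(select_dim(rnorm(400), delay = 1, max_dim = 8), 3)
  expect_error(select_dim(rep(1, 100), 2), "degenerate")
})

test_that("radius calibration reaches the 2-4% band and is monotone", {
  set.seed(10)
  x <- prepare_crqa_series(eda_trace(cumsum(rnorm(600)), 8))
  y <- prepare_crqa_series(eda_trace(cumsum(rnorm(600)), 8))
  xe <- embed_series(x$values, 2, 3); ye <- embed_series(y$values, 2, 3)
  cal <- calibrate_radius(xe, ye)
  expect_gte(cal$rr, 0.02); expect_lte(cal$rr, 0.04)
  ## recurrence rate never decreases as the radius grows
  radii <- sort(runif(20, 0, 3))
  rrs <- vapply(radii, function(r)
    mean(cross_recurrence(xe, ye, r) == 1), 0)
  expect_true(all(diff(rrs) >= 0))
  ## constant series: RR jumps 0 -> 1, band unattainable
  ce <- embed_series(rep(1, 50), 1, 2)
  expect_error(calibrate_radius(ce, ce), "unattainable")
})

test_that("identical inputs give the full main diagonal and determinism", {
  set.seed(11)
  tr <- prepare_crqa_series(
    eda_trace(cumsum(rnorm(2400)) + rnorm(2400), 32))
  m1 <- run_crqa(tr, tr)
  n_emb <- m1$params$n_samples - (m1$params$dim - 1) * m1$params$delay
  expect_equal(m1$maxl, n_emb)
  m2 <- run_crqa(tr, tr)
  expect_identical(m1[c("rr", "det", "lam", "maxl", "entr")],
                   m2[c("rr", "det", "lam", "maxl", "entr")])
})

test_that("swapping the dyad members transposes the recurrence structure", {
  set.seed(12)
  x <- prepare_crqa_series(eda_trace(cumsum(rnorm(500)), 8))
  y <- prepare_crqa_series(eda_trace(cumsum(rnorm(500)), 8))
  xe <- embed_series(x$values, 2, 3); ye <- embed_series(y$values, 2, 3)
  cal <- calibrate_radius(xe, ye)
  Rxy <- cross_recurrence(xe, ye, cal$radius)
  Ryx <- cross_recurrence(ye, xe, cal$radius)
  expect_equal(unclass(t(Rxy)), unclass(Ryx), ignore_attr = TRUE)
  mxy <- compute_metrics(Rxy); myx <- compute_metrics(Ryx)
  expect_equal(mxy$rr, myx$rr)
  expect_equal(mxy$det, myx$det)
  expect_equal(mxy$maxl, myx$maxl)
  ## vertical lines of the transpose are horizontal runs of the original
  expect_equal(sort(vertical_lines(Ryx, 2)),
               sort(oracle_vertical_runs(t(unclass(Rxy)))[
                 oracle_vertical_runs(t(unclass(Rxy))) >= 2]))
})

test_that("coupled dyads sustain far longer diagonal lines than uncoupled ones", {
  ## the longest-line statistic is the robust carrier of coupling in this
  ## signal family; the line-ratio metrics (DET/LAM) are intensive
  ## process properties and stay near their smooth-signal ceiling
  met <- lapply(c(0, 1), function(k) {
    d <- generate_dataset(desk_design(n_dyads = 12, seed = 1),
                          kappa_sampler = function(n) rep(k, n), seed = 50 + k)
    crqa_dataset(d)
  })
  expect_gt(mean(met[[2]]$maxl), 2 * mean(met[[1]]$maxl))
})

test_that("the longest-line statistic rises with coupling across the kappa grid", {
  d <- generate_dataset(desk_design(n_dyads = 60, seed = 2), seed = 60)
  met <- crqa_dataset(d)
  m <- merge(met, d$ground_truth, by = "dyad_id")
  ct <- stats::cor.test(m$maxl, m$kappa, method = "spearman",
                        exact = FALSE, alternative = "greater")
  expect_lt(ct$p.value, 0.01)
})

test_that("all dyad-block metrics stay inside their theoretical ranges", {
  d <- generate_dataset(desk_design(n_dyads = 8, seed = 3), seed = 70)
  met <- crqa_dataset(d)
  expect_true(all(met$rr >= 0.02 & met$rr <= 0.04))
  expect_true(all(met$det >= 0 & met$det <= 1))
  expect_true(all(met$lam >= 0 & met$lam <= 1))
  expect_true(all(met$rentr >= 0 & met$rentr <= 1))
  expect_true(all(met$maxl >= 0 &
                    met$maxl <= met$n_samples))
})
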