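# Synthetic homogeneity traces and the analyses that run on them:
# period extraction, damping summary, effusion-time recovery.

test_that("noiseless instantaneous trace is the binary phase signal", {
  sim <- default_sim_short()
  tr <- synthesize_trace(sim, sample_dt = 0.1, noise_sd = 0,
                         response_time = 0, jitter_frac = 0, seed = 1)
  expect_true(all(tr$h %in% c(0, 1)))
  sig <- approx(sim$states$t, sim$states$sigma, xout = tr$t, rule = 2,
                ties = "ordered")$y
  expect_equal(tr$h, as.numeric(sig < sim$phase_params$sigma_phase))
})

test_that("traces are deterministic in the seed", {
  sim <- default_sim_short()
  t1 <- synthesize_trace(sim, noise_sd = 0.1, seed = 7)
  t2 <- synthesize_trace(sim, noise_sd = 0.1, seed = 7)
  t3 <- synthesize_trace(sim, noise_sd = 0.1, seed = 8)
  expect_identical(t1$h, t2$h)
  expect_identical(t1$t, t2$t)
  expect_false(identical(t1$h, t3$h))
  # synthesize_trace must not disturb the caller's RNG stream
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(synthesize_trace(sim, seed = 1)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("period extraction on clean fixtures", {
  t <- seq(0, 200, 0.1)
  sq <- data.frame(t = t, h = as.numeric(t %% 20 < 5))
  p <- extract_cycle_periods(sq)
  expect_equal(as.numeric(p), rep(20, length(p)), tolerance = 1e-10)
  expect_warning(p0 <- extract_cycle_periods(data.frame(t = t, h = 1)),
                 "fewer than 2")
  expect_length(p0, 0)
  expect_error(extract_cycle_periods(sq, threshold = 1.2), "in \\(0, 1\\)")
})

test_that("noisy round trip recovers the engine cycle periods", {
  sim <- default_sim_short()
  sample_dt <- 0.1
  tr <- synthesize_trace(sim, sample_dt = sample_dt, noise_sd = 0.1, seed = 1)
  p <- extract_cycle_periods(tr)
  truth <- sim$cycles$period
  expect_gte(length(p), length(truth) - 1)
  n <- min(length(p), length(truth))
  expect_true(all(abs(p[1:n] - truth[1:n]) <= 2 * sample_dt))
})

test_that("period estimates are threshold-invariant at low noise", {
  sim <- default_sim_short()
  tr <- synthesize_trace(sim, sample_dt = 0.1, noise_sd = 0.05, seed = 2)
  p_ref <- extract_cycle_periods(tr, threshold = 0.5)
  for (thr in c(0.3, 0.4, 0.6, 0.7)) {
    p <- extract_cycle_periods(tr, threshold = thr)
    n <- min(length(p), length(p_ref))
    expect_true(all(abs(p[1:n] - p_ref[1:n]) <= 2 * 0.1),
                label = paste("threshold", thr))
  }
})

test_that("damping summary condenses periods and flags quiescence", {
  d <- damping_summary(c(10, 20, 30))
  expect_equal(d$n_cycles, 3)
  expect_equal(d$fold_increase, 3)
  expect_equal(damping_summary(15)$fold_increase, 1)
  expect_equal(damping_summary(numeric(0))$n_cycles, 0)
  # trailing crossing-free window marks quiescence at the last crossing
  p <- c(10, 10)
  attr(p, "crossings") <- c(10, 20, 30)
  trace <- data.frame(t = seq(0, 100, 0.5), h = 0)
  d2 <- damping_summary(p, trace)
  expect_equal(d2$t_quiescent, 30)
  d3 <- damping_summary(p, trace, trailing_window = 1000)
  expect_true(is.na(d3$t_quiescent))
})

test_that("effusion-time recovery is exact without noise and robust with it", {
  tau <- 0.533
  t <- seq(0, 2, length.out = 50)
  fit <- recover_effusion_time(t, 200 * exp(-t / tau))
  expect_equal(coef(fit)[["tau"]], tau, tolerance = 1e-10)
  expect_equal(coef(fit)[["c0"]], 200, tolerance = 1e-8)
  expect_equal(length(residuals(fit)), 50)
  expect_equal(predict(fit, time = 0), 200, tolerance = 1e-8)
  # 5% multiplicative noise, 50 samples: within 10% of truth
  set.seed(11)
  cn <- 200 * exp(-t / tau) * (1 + rnorm(50, 0, 0.05))
  fit2 <- recover_effusion_time(t, cn)
  expect_lt(abs(fit2$tau - tau) / tau, 0.10)
  expect_gt(fit2$se_tau, 0)
})

test_that("effusion-time recovery is unbiased over replicates at 5% noise", {
  tau <- 0.533
  t <- seq(0, 2, length.out = 50)
  set.seed(99)
  taus <- replicate(200, {
    cn <- 200 * exp(-t / tau) * (1 + rnorm(50, 0, 0.05))
    suppressWarnings(recover_effusion_time(t, cn)$tau)
  })
  mcse <- sd(taus) / sqrt(length(taus))
  expect_lt(abs(mean(taus) - tau), 3 * mcse + 1e-12)
})

test_that("effusion-time recovery fails gracefully on degenerate input", {
  t <- seq(0, 2, length.out = 50)
  expect_error(recover_effusion_time(t, rep(5, 50)), "do not decay")
  expect_error(recover_effusion_time(t[1:4], rep(1, 4)), "at least 5")
  expect_warning(
    fit <- recover_effusion_time(seq(0, 5, 0.1),
                                 c(200 * exp(-seq(0, 4.9, 0.1) / 0.5), -1)),
    "non-positive")
  expect_equal(fit$n_used, 50)
})
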