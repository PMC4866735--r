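test_that("EMG preprocessing removes offset, clips at 5 SD, normalizes", {
  set.seed(1)
  raw <- rnorm(2000, mean = 3, sd = 1)
  out <- preprocess_emg(raw)
  expect_true(all(out >= 0))
  expect_equal(max(out), 1)
  # a huge spike is clipped to 5 SD before normalization, so after
  # normalization it sits exactly at 1 and the rest scale by 5 SD
  raw2 <- rnorm(5000, 0, 1)
  s <- sd(raw2 - mean(raw2))
  raw2[100] <- mean(raw2) + 10 * s
  out2 <- preprocess_emg(raw2)
  expect_equal(max(out2), 1)
  expect_equal(out2[100], 1)   # the clipped spike is the maximum
  # clean samples are scaled by the 5-SD clip value
  x <- raw2 - mean(raw2)
  s2 <- sd(x)
  expect_equal(out2[200], abs(pmin(pmax(x[200], -5 * s2), 5 * s2)) /
                 (5 * s2), tolerance = 1e-12)
  expect_error(preprocess_emg(rep(2, 1500)), "zero variance")
  expect_error(preprocess_emg(rnorm(100)), NULL)  # under 1 s
})

test_that("generated EMG follows the exponential observation law", {
  n <- 1e5
  emg <- gen_emg(rep(0.5, n), seed = 11)
  expect_gt(mean(emg), 0.49)
  expect_lt(mean(emg), 0.51)
  # distributional check against the exponential with mean 0.5
  ks <- suppressWarnings(ks.test(emg, "pexp", rate = 2))
  expect_gt(ks$p.value, 0.01)
  # degenerate floor at zero drive
  expect_identical(gen_emg(rep(0, 100), seed = 1), rep(0, 100))
  expect_error(gen_emg(c(0.5, 1.2)), "outside")
  # determinism given seed
  expect_identical(gen_emg(rep(0.3, 50), seed = 4),
                   gen_emg(rep(0.3, 50), seed = 4))
})

test_that("drive filter recovers planted constant and piecewise drives", {
  n <- 2000
  emg <- gen_emg(rep(0.5, n), seed = 21)
  xh <- estimate_drive(emg)
  expect_gt(median(xh[500:n]), 0.4)
  expect_lt(median(xh[500:n]), 0.6)
  # zero input decays to the grid floor
  xf <- estimate_drive(rep(0, 1000))
  expect_equal(tail(xf, 1), sanger_config()$floor_epsilon)
  # piecewise-constant plateaus recovered within 0.1 median error
  drive <- c(rep(0.2, 1500), rep(0.7, 1500), rep(0.4, 1500))
  emg2 <- gen_emg(drive, seed = 22)
  xh2 <- estimate_drive(emg2)
  expect_lt(abs(median(xh2[500:1500]) - 0.2), 0.1)
  expect_lt(abs(median(xh2[2000:3000]) - 0.7), 0.1)
  expect_lt(abs(median(xh2[3500:4500]) - 0.4), 0.1)
  expect_error(estimate_drive(c(0.1, NA)), "non-finite")
})

test_that("drive filter step response lags by under 60 ms", {
  lags <- vapply(1:3, function(s) {
    drive <- c(rep(0.05, 1000), rep(0.8, 1000))
    emg <- gen_emg(drive, seed = 30 + s)
    xh <- estimate_drive(emg)
    which(xh > 0.4)[1] - 1001
  }, numeric(1))
  expect_true(all(lags >= 0))
  expect_true(all(lags < 60))   # samples at 1000 Hz = ms
})

test_that("refining the latent grid barely changes the estimate", {
  emg <- gen_emg(c(rep(0.3, 1000), rep(0.6, 1000)), seed = 41)
  x64 <- estimate_drive(emg, sanger_config(grid_size = 64))
  x256 <- estimate_drive(emg, sanger_config(grid_size = 256))
  expect_lt(sqrt(mean((x64 - x256)^2)), 0.02)
})

test_that("MVC normalization divides, renormalizes and enforces bursts", {
  fs <- 1000
  mvc <- rep(0.8, 2 * fs)
  drive <- c(rep(0.1, fs), rep(0.4, fs))
  out <- mvc_normalize(drive, mvc, fs = fs)
  expect_equal(max(out$drive), 0.5, tolerance = 1e-12)
  expect_equal(out$mvc_value, 0.8)
  expect_false(out$renormalized)
  # walking drive exceeding the MVC value renormalizes to max exactly 1
  out2 <- mvc_normalize(c(rep(0.2, fs), rep(0.9, fs)), mvc, fs = fs)
  expect_equal(max(out2$drive), 1)
  expect_true(out2$renormalized)
  # short bursts do not qualify
  short <- rep(c(rep(0.8, 500), rep(0, 500)), 3)
  expect_error(mvc_normalize(drive, short, fs = fs), "burst")
})

test_that("activation dynamics matches its closed-form step responses", {
  fs <- 1000
  time <- seq(0, 0.2, by = 1 / fs)
  # fixed point: constant drive equal to the initial activation
  a_const <- activation_dynamics(rep(0.4, length(time)), time,
                                 threshold = 0)
  expect_equal(a_const, rep(0.4, length(time)), tolerance = 1e-12)
  # step up with x = 1: a(t) = 1 - exp(-t/tau_act)
  tau_act <- 0.015
  x_up <- c(0, rep(1, length(time) - 1))
  a_up <- activation_dynamics(x_up, time, tau_act = tau_act,
                              tau_deact = 0.05, threshold = 0)
  expect_equal(a_up[-1], 1 - exp(-time[-1] / tau_act), tolerance = 1e-6)
  expect_equal(a_up[time == 0.015], 1 - exp(-1), tolerance = 1e-3)
  # step down with x = 0: a(t) = exp(-t/tau_deact)
  tau_deact <- 0.05
  x_dn <- c(1, rep(0, length(time) - 1))
  a_dn <- activation_dynamics(x_dn, time, tau_act = 0.015,
                              tau_deact = tau_deact, threshold = 0,
                              a0 = 1)
  expect_equal(a_dn[-1], exp(-time[-1] / tau_deact), tolerance = 1e-6)
  # rise is faster than decay for matched step size
  t_rise <- time[which(a_up > 0.5)[1]]
  t_fall <- time[which(a_dn < 0.5)[1]]
  expect_lt(t_rise, t_fall)
  expect_error(activation_dynamics(c(0.1, 0.2), c(1, 1)), "non-monotone")
})

test_that("cycle averaging discards only the planted outlier", {
  fs <- 100
  n_cyc <- 21
  T <- 1
  time <- seq(0, n_cyc * T, by = 1 / fs)
  base <- sin(2 * pi * (time %% T))^2
  value <- base
  # scale one full cycle by 5
  idx <- time >= 7 & time < 8
  value[idx] <- 5 * value[idx]
  hs <- seq(0, n_cyc * T, by = T)
  avg <- segment_and_average(value, time, hs)
  expect_identical(avg$discarded, 8L)
  expect_equal(length(avg$kept), n_cyc - 1)
  # identical cycles: zero SD, none discarded
  avg2 <- segment_and_average(base, time, hs)
  expect_identical(avg2$discarded, integer(0))
  expect_lt(max(avg2$sd), 1e-9)
  # mean equals the per-point arithmetic mean of kept cycles
  expect_equal(avg$mean, colMeans(avg$cycles), tolerance = 1e-12)
  expect_error(segment_and_average(base, time, c(0, 1, 2)), "3 complete")
  expect_error(segment_and_average(base, time, c(0, 1, 2, 50)), "span")
})
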