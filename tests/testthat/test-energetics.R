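test_that("metabolic rate components obey their identities", {
  p <- fix_params()
  mass <- muscle_mass(p)
  # resting muscle: every component zero
  r0 <- umberger_rate(0, 0, p$l_opt, 0, 0, mass, p)
  expect_true(all(unlist(r0) == 0))
  # isometric: no shortening heat, no work
  ri <- umberger_rate(0.5, 0.5, p$l_opt, 0, 500, mass, p)
  expect_identical(ri$h_SL, 0)
  expect_identical(ri$w_CE, 0)
  expect_gt(ri$h_A + ri$h_M, 0)
  # work-rate identity: F = 100 N shortening at 0.1 m/s, 0.5 kg muscle
  rw <- umberger_rate(0.5, 0.5, p$l_opt, -0.1, 100, 0.5, p)
  expect_equal(rw$w_CE, 20)
  # negative (lengthening) work is excluded from the work term
  rl <- umberger_rate(0.5, 0.5, p$l_opt, +0.1, 100, 0.5, p)
  expect_identical(rl$w_CE, 0)
  expect_gt(rl$h_SL, 0)
  # all heats nonnegative over a random state sweep
  set.seed(2)
  for (i in 1:50) {
    r <- umberger_rate(runif(1), runif(1), runif(1, 0.07, 0.14),
                       runif(1, -1, 1) * p$v_max, runif(1, 0, 1000),
                       mass, p)
    expect_true(all(r$h_A >= 0, r$h_M >= 0, r$h_SL >= 0, r$w_CE >= 0))
    expect_gte(r$total, r$w_CE)
  }
})

test_that("muscle mass follows density times strength-length over tension", {
  p <- mtu_params(F_max = 1000, l_opt = 0.10, l_sl = 0.2)
  expect_equal(muscle_mass(p), 0.42388, tolerance = 1e-5)
  p2 <- mtu_params(F_max = 2000, l_opt = 0.10, l_sl = 0.2)
  expect_equal(muscle_mass(p2), 2 * muscle_mass(p), tolerance = 1e-12)
})

test_that("whole-body cost reduces to the basal closed form when silent", {
  sc <- subject_scalars(body_mass = 70, walking_speed = 1.25,
                        basal_rate = 1.5)
  masses <- c(SOL = 0.8, TA = 0.3)
  silent <- c(SOL = 0, TA = 0)
  # with no modeled muscle, the whole body is billed at the basal rate
  out0 <- whole_body_cost(numeric(0), numeric(0), sc, T = 1.1)
  expect_equal(out0$C_met, 70 * 1.5 * 1.1, tolerance = 1e-12)
  expect_equal(out0$mcot, 1.5 / (9.81 * 1.25), tolerance = 1e-12)
  # a massive but silent muscle shifts mass out of basal billing only
  out <- whole_body_cost(silent, masses, sc, T = 1.1)
  out2 <- whole_body_cost(c(silent, X = 0), c(masses, X = 1), sc, T = 1.1)
  expect_equal(out$C_met - out2$C_met, 2 * 1 * 1.5 * 1.1,
               tolerance = 1e-12)
  # doubling the window doubles the cost for stationary rates
  out3 <- whole_body_cost(2 * c(SOL = 10, TA = 4), masses, sc, T = 2.2)
  ref <- whole_body_cost(c(SOL = 10, TA = 4), masses, sc, T = 1.1)
  expect_equal(out3$C_met, 2 * ref$C_met, tolerance = 1e-12)
  # additive over muscles and order-invariant
  sh <- whole_body_cost(c(TA = 4, SOL = 10), masses[c("TA", "SOL")],
                        sc, T = 1.1)
  expect_equal(sh$C_met, ref$C_met, tolerance = 1e-12)
  expect_error(whole_body_cost(silent, c(SOL = 40, TA = 40), sc, 1.1),
               "exceeds body mass")
})

test_that("phase fractions integrate rates over the gait partitions", {
  T <- 1
  time <- seq(0, T, length.out = 1001)
  ev <- gait_events(heel_strike = c(0, T), toe_off = 0.6 * T,
                    contra_heel_strike = 0.5 * T, contra_toe_off = 0.1 * T)
  # uniform rate: fractions equal phase-duration fractions
  pf <- phase_fractions(rep(5, length(time)), time, ev)
  expect_equal(sum(pf), 1, tolerance = 1e-9)
  expect_equal(unname(pf), c(0.2, 0.4, 0.4), tolerance = 1e-3)
  # rate concentrated in swing
  r_sw <- ifelse(time > 0.6 * T, 1, 0)
  pf2 <- phase_fractions(r_sw, time, ev)
  expect_equal(unname(pf2), c(0, 0, 1), tolerance = 1e-2)
  # push-off work concentrated in second double support inflates the
  # double-support fraction above its duration share
  r_po <- ifelse(time >= 0.5 & time <= 0.6, 10, 1)
  pf3 <- phase_fractions(r_po, time, ev)
  expect_gt(pf3[["double_support"]], 0.2)
  bad <- gait_events(c(0, T), 0.4 * T, 0.5 * T, 0.1 * T)
  expect_error(phase_fractions(rep(1, length(time)), time, bad), "tile")
})

test_that("positive-work efficiency matches its ratio identity", {
  p <- fix_params()
  n <- 101
  time <- seq(0, 1, length.out = n)
  # synthetic steady shortening trace with constant rate
  tr <- data.frame(time = time, F_CE = rep(100, n), v_CE = rep(-0.1, n))
  mass <- 0.5
  w_rate <- 20                         # = 100 * 0.1 / 0.5 W/kg
  rates <- list(M = data.frame(total = rep(4 * w_rate, n)))
  eff <- positive_work_efficiency(list(M = tr), rates, c(M = mass))
  expect_equal(eff, 0.25, tolerance = 1e-9)
  # all isometric: zero efficiency
  tr0 <- transform(tr, v_CE = 0)
  eff0 <- positive_work_efficiency(list(M = tr0),
                                   list(M = data.frame(total = rep(10, n))),
                                   c(M = mass))
  expect_equal(eff0, 0)
})

test_that("steady-shortening efficiency peaks at intermediate speed", {
  p <- fix_params()
  mass <- muscle_mass(p)
  eff_at <- function(frac) {
    v <- -frac * p$v_max
    F <- p$F_max * force_velocity(v, p)
    r <- umberger_rate(1, 1, p$l_opt, v, F, mass, p)
    r$w_CE / r$total
  }
  e_slow <- eff_at(0.02)
  e_mid <- eff_at(0.17)
  e_fast <- eff_at(0.90)
  expect_gt(e_mid, e_slow)
  expect_gt(e_mid, e_fast)
})
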