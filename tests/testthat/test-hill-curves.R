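test_that("tendon force-strain law is normalized, slack-safe and monotone", {
  for (row in fix_tendon_rows()) {
    p <- mtu_params(F_max = row$F_max, l_opt = 0.1, l_sl = 0.25,
                    K_sh = row$K_sh, lambda_ref = row$lambda_ref)
    # at the reference strain the tendon carries exactly F_max,
    # independent of the shape factor
    expect_equal(tendon_force(row$lambda_ref, p), row$F_max,
                 tolerance = 1e-12)
    expect_identical(tendon_force(0, p), 0)
    expect_identical(tendon_force(-0.01, p), 0)
    lam <- seq(1e-4, row$lambda_ref * 1.5, length.out = 200)
    expect_true(all(diff(tendon_force(lam, p)) > 0))
    # continuity at the slack point
    expect_lt(tendon_force(1e-10, p), 1e-4 * row$F_max)
  }
})

test_that("tendon force matches hand evaluation of the exponential law", {
  p <- mtu_params(F_max = 1000, l_opt = 0.1, l_sl = 0.25, K_sh = 3,
                  lambda_ref = 0.05)
  # F = 1000 (e^{1.5} - 1) / (e^3 - 1) at half the reference strain
  expect_equal(tendon_force(0.025, p),
               1000 * (exp(1.5) - 1) / (exp(3) - 1), tolerance = 1e-12)
  expect_equal(tendon_force(0.025, p), 182.4258, tolerance = 1e-4)
})

test_that("pennation preserves muscle width and handles edge geometry", {
  p <- fix_params()
  expect_equal(pennation_angle(p$l_opt, p), p$theta0, tolerance = 1e-12)
  # constant width along a length sweep
  l <- seq(0.06, 0.15, length.out = 50)
  th <- pennation_angle(l, p)
  expect_equal(l * sin(th), rep(p$l_opt * sin(p$theta0), 50),
               tolerance = 1e-12)
  # zero pennation stays zero
  p0 <- mtu_params(F_max = 100, l_opt = 0.1, l_sl = 0.2, theta0 = 0)
  expect_identical(pennation_angle(c(0.05, 0.2), p0), c(0, 0))
  # arcsin(1) at half the optimal length with 30 deg resting pennation
  p30 <- mtu_params(F_max = 100, l_opt = 0.10, l_sl = 0.2,
                    theta0 = 30 * pi / 180)
  expect_equal(pennation_angle(0.05, p30), pi / 2, tolerance = 1e-6)
  expect_warning(pennation_angle(0.049, p30), "clamped")
})

test_that("contractile element force obeys its normalization corners", {
  p <- fix_params()
  # inactive muscle produces no active force anywhere
  f <- ce_force(0, 0.8 * p$l_opt, -0.3 * p$v_max, p)
  expect_identical(f$F_CE, 0)
  # isometric at optimal length and full activation gives exactly F_max
  expect_equal(ce_force(1, p$l_opt, 0, p)$F_CE, p$F_max,
               tolerance = 1e-12)
  # Hill curve zero at maximal shortening
  expect_equal(ce_force(1, p$l_opt, -p$v_max, p)$F_CE, 0,
               tolerance = 1e-12)
  # parallel element engages only above optimal length
  expect_identical(parallel_elastic_force(p$l_opt * 0.99, p), 0)
  expect_gt(parallel_elastic_force(p$l_opt * 1.2, p), 0)
  expect_equal(parallel_elastic_force(p$l_opt * (1 + p$w), p), p$F_max,
               tolerance = 1e-12)
})

test_that("analytic force-velocity inversion matches dense bisection", {
  set.seed(7)
  p <- fix_params()
  fv_reach <- force_velocity(p$v_max, p)   # largest value attainable
  for (i in 1:100) {
    fv <- runif(1, 0.001, fv_reach - 1e-6)
    v_analytic <- force_velocity_inverse(fv, p)
    v_oracle <- fix_fv_bisect(fv, p)
    expect_lt(abs(v_analytic - v_oracle), 1e-6 * p$v_max)
  }
  # branch caps
  expect_equal(force_velocity_inverse(0, p), -p$v_max)
  expect_equal(force_velocity_inverse(1, p), 0, tolerance = 1e-12)
})

test_that("velocity solve returns equilibrium sign structure", {
  p <- fix_params()
  l_CE <- p$l_opt
  th <- p$theta0
  # choose l_MTC so the tendon carries exactly the isometric fiber force
  a <- 0.6
  F_iso <- (a * p$F_max * force_length(l_CE, p) +
              parallel_elastic_force(l_CE, p)) * cos(pennation_angle(l_CE, p))
  lam <- p$lambda_ref * log(1 + F_iso / p$F_max * (exp(p$K_sh) - 1)) / p$K_sh
  l_MTC <- p$l_sl * (1 + lam) + l_CE * cos(pennation_angle(l_CE, p))
  s <- solve_ce_velocity(a, l_CE, l_MTC, p)
  expect_equal(s$v_CE, 0, tolerance = 1e-9)
  # lower tendon force -> shortening; higher -> lengthening
  expect_lt(solve_ce_velocity(a, l_CE, l_MTC - 0.002, p)$v_CE, 0)
  expect_gt(solve_ce_velocity(a, l_CE, l_MTC + 0.002, p)$v_CE, 0)
})

test_that("power-optimal shortening speed matches the closed form", {
  for (K in c(4, 4.5, 5)) {
    p <- mtu_params(F_max = 1000, l_opt = 0.1, l_sl = 0.2, K_hill = K)
    s <- seq(0, p$v_max, length.out = 20001)
    power <- s * force_velocity(-s, p)
    v_opt <- s[which.max(power)] / p$v_max
    closed <- (sqrt(1 + K) - 1) / K
    expect_equal(v_opt, closed, tolerance = 1e-3)
    # consistent with peak muscle power output near 0.30 v_max
    expect_gte(closed, 0.28)
    expect_lte(closed, 0.32)
  }
})

test_that("hip ligament engages only past its engagement angle", {
  h <- hfl_params(K_HFL = 193, theta0_HFL = 0.04)
  expect_identical(hfl_torque(0.04, h), 0)
  expect_identical(hfl_torque(0.24, h), 0)     # flexed: disengaged
  # 0.1 rad of extension past engagement -> +19.3 N m of flexion torque
  expect_equal(hfl_torque(0.04 - 0.1, h), 19.3, tolerance = 1e-12)
  th <- seq(-0.3, 0.3, length.out = 100)
  expect_true(all(hfl_torque(th, h) >= 0))
})
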