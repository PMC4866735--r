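test_that("kinetic cost mirrors the coefficient of determination", {
  set.seed(3)
  time <- seq(0, 1, length.out = 100)
  tau_exp <- data.frame(ankle = sin(2 * pi * time) * 50,
                        knee = cos(2 * pi * time) * 30,
                        hip = sin(4 * pi * time) * 40)
  # perfect fit
  k0 <- kinetic_cost(tau_exp, tau_exp)
  expect_equal(k0$C_kin, 0, tolerance = 1e-12)
  # per-joint mean prediction scores exactly zero
  tau_mean <- as.data.frame(lapply(tau_exp, function(v)
    rep(mean(v), length(v))))
  k1 <- kinetic_cost(tau_mean, tau_exp)
  expect_equal(unname(k1$R2), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(k1$C_kin, 1, tolerance = 1e-12)
  # additive noise at a known residual/total ratio
  tau_noisy <- tau_exp
  for (j in names(tau_noisy)) {
    e <- tau_exp[[j]] - mean(tau_exp[[j]])
    noise <- rnorm(length(e))
    noise <- noise * sqrt(0.1 * sum(e^2) / sum(noise^2))
    tau_noisy[[j]] <- tau_exp[[j]] + noise
  }
  k2 <- kinetic_cost(tau_noisy, tau_exp)
  expect_equal(k2$C_kin, 0.1, tolerance = 1e-9)
  expect_error(kinetic_cost(tau_exp, transform(tau_exp, ankle = 1)),
               "zero-variance")
})

test_that("stance torque error normalizes by the experimental range", {
  time <- seq(0, 1.1, length.out = 138)
  ev <- gait_events(c(0, 1.1), 0.66, 0.55, 0.11)
  tau_exp <- 20 * sin(2 * pi * time / 1.1)   # range 40 over stance
  expect_equal(fmae(tau_exp, tau_exp, time, ev), 0)
  # constant offset d over range R gives exactly d/R
  stance <- time >= 0 & time <= 0.66
  r <- diff(range(tau_exp[stance]))
  expect_equal(fmae(tau_exp + 2, tau_exp, time, ev), 2 / r,
               tolerance = 1e-12)
  expect_equal(fmae(tau_exp + 0.05 * r, tau_exp, time, ev), 0.05,
               tolerance = 1e-12)
  expect_error(fmae(tau_exp, rep(1, length(time)), time, ev), "range")
})

test_that("bounds carry the printed tendon windows and ligament formulas", {
  partial <- gen_kinematics_geometry(seed = 1)
  b <- build_bounds(partial)
  for (m in b$muscles) {
    expect_equal(b$lower[[paste0(m, ".K_sh")]], 2)
    expect_equal(b$upper[[paste0(m, ".K_sh")]], 5)
    expect_equal(b$lower[[paste0(m, ".lambda_ref")]], 0.02)
    expect_equal(b$upper[[paste0(m, ".lambda_ref")]], 0.09)
    ref <- b$meta$reference_F_max[[m]]
    expect_equal(b$lower[[paste0(m, ".F_max")]], 0.5 * ref)
    expect_equal(b$upper[[paste0(m, ".F_max")]], 3.0 * ref)
  }
  # ligament box: engagement angle in [-pi/18, |min hip|], spring in
  # [0, 2 max(tau_hip)/|min hip|]
  tau_hip <- 30 * sin(2 * pi * partial$time / partial$period)
  tau_hip[10] <- 60                       # exact known peak
  partial$joint_moments <- data.frame(hip = tau_hip)
  partial$joint_angles$hip <- partial$joint_angles$hip -
    min(partial$joint_angles$hip) - 0.3   # |min| = 0.3 exactly
  b2 <- build_bounds(partial)
  expect_equal(unname(b2$lower[["theta0_HFL"]]), -pi / 18)
  expect_equal(unname(b2$upper[["theta0_HFL"]]), 0.3, tolerance = 1e-12)
  expect_equal(unname(b2$upper[["K_HFL"]]), 2 * 60 / 0.3,
               tolerance = 1e-6)
  # widening the force-length band widens the feasible scale interval
  widen <- function(w_mult) {
    tab <- default_muscle_table()
    m <- "SOL"; row <- tab[tab$muscle == m, ]
    lm <- partial$mtu_lengths[[m]]; ct <- cos(row$theta0)
    w <- row$w * w_mult
    c(max(lm) / (row$l_sl_ref + row$l_opt_ref * (1 + w) * ct),
      min(lm) / (row$l_sl_ref + row$l_opt_ref * (1 - w) * ct))
  }
  iv1 <- widen(1); iv2 <- widen(1.2)
  expect_lt(iv2[1], iv1[1])
  expect_gt(iv2[2], iv1[2])
})

test_that("candidate evaluation is deterministic and penalizes failure", {
  ds <- toy_problem(seed = 2)
  r1 <- evaluate_candidate(ds$truth$morphology, ds)
  r2 <- evaluate_candidate(ds$truth$morphology, ds)
  expect_identical(r1$C_met, r2$C_met)
  expect_identical(r1$C_kin, r2$C_kin)
  expect_false(r1$failed)
  # ground truth on its own noiseless dataset fits nearly perfectly
  expect_lt(r1$C_kin, 1e-3)
  # weakest-possible muscles: cheaper but worse fit (lower-left corner)
  weak <- ds$truth$morphology
  for (m in names(weak$F_max))
    weak$F_max[[m]] <- ds$bounds$lower[[paste0(m, ".F_max")]]
  rw <- evaluate_candidate(weak, ds)
  expect_lt(rw$C_met, r1$C_met)
  expect_gt(rw$C_kin, r1$C_kin)
})

test_that("small searches produce valid, reproducible fronts", {
  ds <- toy_problem(seed = 3)
  ga <- ga_config(pop_size = 24, generations = 6)
  f1 <- run_identification(ds, ds$bounds, ga = ga, seed = 5)
  f2 <- run_identification(ds, ds$bounds, ga = ga, seed = 5)
  # determinism contract
  expect_identical(f1$objectives, f2$objectives)
  expect_identical(f1$solutions[[1]]$vector, f2$solutions[[1]]$vector)
  # every returned solution nondominated by brute force
  expect_true(all(nondominated(f1$objectives)))
  # monotone trade-off: sorted by C_kin, C_met must decrease
  expect_true(all(diff(f1$objectives[, 1]) <= 1e-9))
  # hypervolume never decreases under elitist survival
  ref <- c(max(f1$history$best_C_met) * 10, 2)
  expect_true(all(diff(f1$history$best_C_kin) <= 1e-12))
  # all solutions within bounds
  for (s in f1$solutions)
    expect_true(all(s$vector >= ds$bounds$lower &
                      s$vector <= ds$bounds$upper))
})

test_that("paper-scale and desk-scale presets carry their settings", {
  desk <- ga_config("desk")
  expect_equal(desk$pop_size, 64)
  expect_equal(desk$generations, 20)
  paper <- ga_config("paper")
  expect_equal(paper$pop_size, 1000)
  expect_equal(paper$generations, 100)
  expect_equal(paper$crossover_fraction, 0.8)
})

test_that("morphology pack/unpack round-trips with fixed ordering", {
  partial <- gen_kinematics_geometry(seed = 1)
  b <- build_bounds(partial)
  m <- gen_truth_params(b, seed = 12)
  x <- pack_morphology(m)
  expect_length(x, 50)          # 12 muscles x 4 + 2 ligament
  m2 <- unpack_morphology(x, b$muscles, b$has_hfl)
  expect_equal(m2$F_max, m$F_max)
  expect_equal(m2$lambda_ref, m$lambda_ref)
  expect_equal(m2$K_HFL, m$K_HFL)
})

test_that("strength is compensable by compliance when all parameters are free", {
  # documents the identifiability limit: inflate one muscle's strength by
  # 40 percent, re-fit only that muscle's length multiplier and tendon
  # constants, and the kinetic cost falls orders of magnitude below any
  # acceptance threshold -- maximal force is not observable from joint
  # moments alone on this problem
  ds <- toy_problem(seed = 2, free = "all")
  b <- ds$bounds
  x0 <- pack_morphology(ds$truth$morphology)
  ck <- function(x) evaluate_candidate(x, ds, bounds = b)$C_kin
  x <- x0
  x[9] <- x0[9] * 1.2                      # GAS strength +20 percent
  idx <- 10:12                             # its scale, K_sh, lambda_ref
  o <- optim(x0[idx], function(p) {
    y <- x
    y[idx] <- pmin(pmax(p, b$lower[idx]), b$upper[idx])
    ck(y)
  }, method = "Nelder-Mead", control = list(maxit = 400, reltol = 1e-12))
  expect_lt(o$value, 1e-4)
})
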