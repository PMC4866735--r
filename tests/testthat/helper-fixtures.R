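# Shared fixtures, built in code at test time.

# a plain mid-size muscle used across unit tests
fix_params <- function(...) {
  mtu_params(F_max = 1000, l_opt = 0.10, l_sl = 0.25, K_sh = 3,
             lambda_ref = 0.05, theta0 = 10 * pi / 180, w = 0.56,
             FT = 0.5, ...)
}

# participant tendon parameter triplets used by the tendon tests
# (F_max N, K_sh, lambda_ref), one row per (participant, muscle) sample
fix_tendon_rows <- function() {
  p1 <- participant_params(1)
  p3 <- participant_params(3)
  list(
    list(F_max = p1$F_max[["TA"]], K_sh = p1$K_sh[["TA"]],
         lambda_ref = p1$lambda_ref[["TA"]]),
    list(F_max = p1$F_max[["SOL"]], K_sh = p1$K_sh[["SOL"]],
         lambda_ref = p1$lambda_ref[["SOL"]]),
    list(F_max = p3$F_max[["VAS"]], K_sh = p3$K_sh[["VAS"]],
         lambda_ref = p3$lambda_ref[["VAS"]]),
    list(F_max = p3$F_max[["HAM"]], K_sh = p3$K_sh[["HAM"]],
         lambda_ref = p3$lambda_ref[["HAM"]])
  )
}

# brute-force force-velocity inversion by dense bisection (oracle)
fix_fv_bisect <- function(fv_target, params, tol = 1e-12) {
  f <- function(v) force_velocity(v, params) - fv_target
  lo <- -params$v_max
  hi <- params$v_max
  if (f(lo) > 0 || f(hi) < 0) return(NA_real_)
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# single-MTU constant-input simulation fixture
fix_constant_sim <- function(params = fix_params(), a = 0.5,
                             l_MTC = NULL, n = 60, T = 1.2) {
  if (is.null(l_MTC))
    l_MTC <- params$l_sl + params$l_opt * cos(params$theta0) * 1.0
  time <- seq(0, T, length.out = n)
  simulate_mtu(rep(l_MTC, n), rep(a, n), time, params, n_cycles = 4)
}
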