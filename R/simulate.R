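#' Simulate one muscle-tendon unit over prescribed kinematics
#'
#' Integrates the Hill-type contraction dynamics for one MTU over a
#' prescribed total-length trajectory \code{l_MTC(t)} and activation
#' \code{a(t)}. The fascicle length is the state; its velocity at every
#' instant solves the series force balance (tendon force equals fiber force
#' projected through the pennation angle). Stepping is backward Euler with
#' sub-steps, stable for near-rigid tendons. Following the two-cycle
#' protocol, the input cycle is repeated \code{n_cycles} times from a
#' quasi-static initial equilibrium and only the last cycle is returned, so
#' initial transients are flushed.
#'
#' @param l_MTC numeric vector, total MTU length over one cycle, m.
#' @param a numeric vector, activation in [0,1], same grid.
#' @param time numeric vector, s, strictly increasing, same length. The
#'   cycle period is taken as \code{diff(range(time)) + dt}.
#' @param params \code{mtu_params}.
#' @param n_cycles cycles simulated before reporting (default 2).
#' @param n_sub backward-Euler sub-steps per grid interval (default 4).
#' @param l_CE0 optional initial fascicle length, m; default solves the
#'   static equilibrium at the first sample.
#' @return data.frame of class \code{mtu_trace} with columns \code{time},
#'   \code{l_CE}, \code{v_CE} (positive = lengthening), \code{theta},
#'   \code{lambda}, \code{F_SE}, \code{F_PE}, \code{F_CE}, \code{F_MTC},
#'   \code{a}, \code{clamped}; attribute \code{n_clamped} counts samples
#'   where a force demand fell outside the Hill curve's range.
#' @export
simulate_mtu <- function(l_MTC, a, time, params, n_cycles = 2, n_sub = 4,
                         l_CE0 = NA_real_) {
  n <- length(time)
  stopifnot(length(l_MTC) == n, length(a) == n, n >= 2,
            all(diff(time) > 0), all(a >= 0), all(a <= 1),
            all(l_MTC > 0), inherits(params, "mtu_params"))
  dt <- time[2] - time[1]
  period <- time[n] - time[1] + dt
  # tile the cycle n_cycles times on a continuous clock
  idx <- rep(seq_len(n), n_cycles)
  tt <- time[1] + (seq_len(n * n_cycles) - 1) * dt
  if (max(abs(diff(time) - dt)) > 1e-9 * dt) {
    # non-uniform grid: tile by shifting the original clock
    tt <- as.vector(vapply(seq_len(n_cycles) - 1L,
                           function(k) time + k * period, numeric(n)))
  }
  res <- .mtu_simulate_cpp(tt, l_MTC[idx], a[idx], unclass(params),
                           n_sub = as.integer(n_sub), l_CE0 = l_CE0)
  keep <- seq.int(n * (n_cycles - 1) + 1L, n * n_cycles)
  out <- data.frame(time = time,
                    l_CE = res$l_CE[keep], v_CE = res$v_CE[keep],
                    theta = res$theta[keep], lambda = res$lambda[keep],
                    F_SE = res$F_SE[keep], F_PE = res$F_PE[keep],
                    F_CE = res$F_CE[keep], a = a)
  out$F_MTC <- out$F_SE
  out$clamped <- res$clamped[keep]
  attr(out, "n_clamped") <- sum(res$clamped[keep])
  attr(out, "params") <- params
  class(out) <- c("mtu_trace", "data.frame")
  out
}

#' Assemble modeled joint moments from MTU traces
#'
#' Sums muscle-tendon forces times their (possibly time-varying, signed)
#' moment arms at each joint; biarticular muscles contribute at every joint
#' they span. The hip flexor ligament torque is added at the hip when its
#' parameters and the hip angle trajectory are supplied.
#'
#' @param traces named list of \code{mtu_trace} (names = muscles).
#' @param moment_arms named list: \code{moment_arms[[joint]][[muscle]]} is a
#'   numeric vector (moment arm over the cycle, m, signed so that positive
#'   force times positive arm gives a positive joint moment).
#' @param hfl optional \code{hfl_params}.
#' @param theta_hip hip angle trajectory, rad (required with \code{hfl}).
#' @return data.frame: \code{time} plus one torque column per joint, N m.
#' @export
joint_moments <- function(traces, moment_arms, hfl = NULL,
                          theta_hip = NULL) {
  stopifnot(length(traces) > 0)
  time <- traces[[1]]$time
  out <- data.frame(time = time)
  for (joint in names(moment_arms)) {
    tau <- numeric(length(time))
    for (m in names(moment_arms[[joint]])) {
      if (!m %in% names(traces))
        stop(sprintf("no trace for muscle '%s' wired at joint '%s'", m, joint))
      r <- moment_arms[[joint]][[m]]
      tau <- tau + traces[[m]]$F_MTC * r
    }
    if (joint == "hip" && !is.null(hfl)) {
      if (is.null(theta_hip)) stop("theta_hip required for the hip ligament")
      tau <- tau + hfl_torque(theta_hip, hfl)
    }
    out[[joint]] <- tau
  }
  out
}
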