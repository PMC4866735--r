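# Synthetic gait datasets with known ground truth.
#
# The generator emulates the per-subject inputs of the identification
# pipeline: smooth periodic sagittal joint angles, geometry-consistent MTU
# lengths and moment arms, EMG sampled from the jump-diffusion/exponential
# observation model, and joint moments forward-simulated from a known
# morphology. Every downstream stage can therefore be tested by parameter
# recovery without any experimental recordings.

#' Subject scalars
#'
#' @param body_mass kg. @param height m. @param walking_speed m/s.
#' @param basal_rate standing basal metabolic rate, W/kg (typical measured
#'   range 1.38-1.63).
#' @param gait_cycle_duration s.
#' @return list of class \code{subject_scalars}.
#' @export
subject_scalars <- function(body_mass = 70.4, height = 1.77,
                            walking_speed = 1.25, basal_rate = 1.5,
                            gait_cycle_duration = 1.1) {
  stopifnot(body_mass > 0, height > 0, walking_speed > 0,
            basal_rate >= 1.0, basal_rate <= 2.0, gait_cycle_duration > 0)
  structure(list(body_mass = body_mass, height = height,
                 walking_speed = walking_speed, basal_rate = basal_rate,
                 gait_cycle_duration = gait_cycle_duration),
            class = "subject_scalars")
}

# Signed moment-arm coefficients r(theta) = c0 + c1 * theta (m, m/rad).
# Conventions: ankle dorsiflexion, knee flexion and hip flexion positive;
# an arm is positive when muscle force produces a positive joint moment.
.moment_arm_table <- function() {
  list(
    ankle = list(TA  = c(0.040, 0),  SOL = c(-0.050, 0),
                 GAS = c(-0.045, 0)),
    knee  = list(GAS = c(0.012, 0),  VAS = c(-0.042, -0.004),
                 BFSH = c(0.025, 0), RF  = c(-0.040, 0),
                 HAM = c(0.025, 0)),
    hip   = list(RF  = c(0.035, 0),  HAM = c(-0.050, 0),
                 ILL = c(0.040, 0),  GMAX = c(-0.060, 0),
                 GMED = c(-0.020, 0), ADDL = c(0.020, 0),
                 ADDM = c(-0.030, 0))
  )
}

# Smooth periodic bump in percent-gait-cycle phase (wrapped Gaussian).
.gc_bump <- function(phi, center, width, amp) {
  d <- (phi - center) %% 1
  d <- pmin(d, 1 - d)
  amp * exp(-0.5 * (d / width)^2)
}

# Ground-truth neural drive templates: qualitative walking on/off timing
# (plantarflexors mid-to-late stance, dorsiflexor swing, knee extensors
# around heel strike, hip flexors around toe-off).
.drive_templates <- function() {
  list(
    TA   = list(c(0.03, 0.05, 0.30), c(0.80, 0.12, 0.20)),
    SOL  = list(c(0.35, 0.13, 0.50)),
    GAS  = list(c(0.45, 0.10, 0.45)),
    VAS  = list(c(0.05, 0.06, 0.18), c(0.95, 0.05, 0.12)),
    BFSH = list(c(0.65, 0.07, 0.15)),
    RF   = list(c(0.60, 0.07, 0.12), c(0.05, 0.05, 0.08)),
    HAM  = list(c(0.95, 0.07, 0.25), c(0.05, 0.06, 0.18)),
    ILL  = list(c(0.62, 0.08, 0.25)),
    GMAX = list(c(0.08, 0.08, 0.18)),
    GMED = list(c(0.20, 0.12, 0.15)),
    ADDL = list(c(0.63, 0.08, 0.15)),
    ADDM = list(c(0.95, 0.08, 0.15))
  )
}

#' Synthetic drive trajectories on a time grid
#'
#' Smooth periodic bump templates with walking-like on/off timing, one
#' trace per muscle, values in [0, 1].
#'
#' @param time time grid over one cycle, s.
#' @param period gait-cycle duration, s.
#' @param muscles subset of muscle names (default all 12).
#' @return named list of numeric vectors.
#' @export
synthetic_drives <- function(time, period,
                             muscles = default_muscle_table()$muscle) {
  phi <- ((time - time[1]) / period) %% 1
  tmpl <- .drive_templates()
  out <- lapply(muscles, function(m) {
    v <- numeric(length(phi))
    for (b in tmpl[[m]]) v <- v + .gc_bump(phi, b[1], b[2], b[3])
    pmin(v, 1)
  })
  names(out) <- muscles
  out
}

#' Generate synthetic gait kinematics and muscle-tendon geometry
#'
#' Joint angles are truncated Fourier series (up to 5 harmonics)
#' qualitatively matching level walking: the hip extends through stance and
#' passes vertical (angle < 0, flexion positive) before toe-off so the hip
#' ligament can engage; the knee shows a small stance flexion wave and a
#' large swing flexion wave; the ankle dorsiflexes through mid-stance and
#' plantarflexes at push-off. Moment arms are low-order polynomials in
#' joint angle with anatomically signed conventions, and MTU lengths follow
#' from exact integration of \eqn{\dot l_{MTC} = -\sum_j r_{ij}
#' \dot\theta_j}, so the geometry is self-consistent by construction.
#'
#' @param scalars \code{subject_scalars}.
#' @param seed RNG seed (small per-subject jitter of angle amplitudes).
#' @param grid_rate mechanics sampling rate, Hz (default 125).
#' @param muscles muscle subset (default all 12).
#' @param joints joint subset; restricting it (e.g. \code{"ankle"}) yields
#'   a reduced single- or two-joint problem for testing.
#' @param amplitude_jitter relative SD of per-subject amplitude jitter.
#' @return list (partial gait dataset): \code{time}, \code{period},
#'   \code{joint_angles} (data.frame ankle/knee/hip, rad),
#'   \code{moment_arms} (list joint -> muscle -> numeric vector, m),
#'   \code{mtu_lengths} (data.frame, m), \code{events}
#'   (\code{gait_events}), \code{scalars}, \code{muscles}.
#' @export
gen_kinematics_geometry <- function(scalars = subject_scalars(), seed = 1,
                                    grid_rate = 125,
                                    muscles = default_muscle_table()$muscle,
                                    joints = c("ankle", "knee", "hip"),
                                    amplitude_jitter = 0.05) {
  if (scalars$gait_cycle_duration <= 0 || grid_rate <= 0)
    stop("cycle duration and grid rate must be positive")
  set.seed(seed)
  T <- scalars$gait_cycle_duration
  n <- round(grid_rate * T)
  time <- seq(0, by = 1 / grid_rate, length.out = n)
  phi <- time / T
  j <- function() 1 + stats::rnorm(1, 0, amplitude_jitter)
  w <- 2 * pi * phi
  # hip: flexed ~0.5 rad at heel strike, extends past vertical (~-0.2 rad)
  # in late stance, re-flexes for swing
  hip <- 0.15 * j() + 0.35 * j() * cos(w) + 0.06 * j() * sin(w) +
    0.02 * j() * cos(2 * w)
  # knee: small stance wave + large swing flexion peak near 70% GC
  knee <- 0.42 * j() - 0.11 * j() * cos(w) - 0.38 * j() * sin(w) -
    0.12 * j() * cos(2 * w) + 0.10 * j() * sin(2 * w) -
    0.015 * j() * cos(3 * w) - 0.03 * j() * sin(3 * w)
  knee <- pmax(knee, 0.02)
  # ankle: early plantarflex bump, mid-stance dorsiflexion, push-off
  ankle <- 0.02 * j() - 0.03 * j() * cos(w) + 0.10 * j() * sin(w) -
    0.09 * j() * cos(2 * w) - 0.06 * j() * sin(2 * w) +
    0.02 * j() * cos(3 * w)
  angles <- data.frame(ankle = ankle, knee = knee, hip = hip)[joints]
  arms_tab <- .moment_arm_table()[joints]
  tab <- default_muscle_table()
  moment_arms <- list()
  excursion <- stats::setNames(
    rep(list(numeric(n)), length(muscles)), muscles)
  for (joint in names(arms_tab)) {
    th <- angles[[joint]]
    for (m in intersect(names(arms_tab[[joint]]), muscles)) {
      cc <- arms_tab[[joint]][[m]]
      moment_arms[[joint]][[m]] <- cc[1] + cc[2] * th
      # l_MTC excursion: minus the antiderivative of r(theta) d theta
      excursion[[m]] <- excursion[[m]] - (cc[1] * th + cc[2] * th^2 / 2)
    }
  }
  mtu_lengths <- as.data.frame(lapply(muscles, function(m) {
    row <- tab[tab$muscle == m, ]
    L_ref <- row$l_sl_ref + row$l_opt_ref * cos(row$theta0) -
      mean(excursion[[m]])
    L_ref + excursion[[m]]
  }))
  names(mtu_lengths) <- muscles
  events <- gait_events(heel_strike = c(0, T),
                        toe_off = 0.60 * T,
                        contra_heel_strike = 0.50 * T,
                        contra_toe_off = 0.10 * T)
  list(time = time, period = T, joint_angles = angles,
       moment_arms = moment_arms, mtu_lengths = mtu_lengths,
       events = events, scalars = scalars, muscles = muscles)
}

#' Sample raw EMG from a drive trajectory
#'
#' Each sample is drawn from the exponential observation law with mean
#' equal to the instantaneous drive \code{x(t)}; at zero drive the sample
#' is exactly zero (degenerate floor). Optionally a random sign emulates
#' unrectified EMG.
#'
#' @param drive numeric vector in [0,1] already sampled at \code{fs}.
#' @param fs sampling rate, Hz (metadata only).
#' @param seed RNG seed.
#' @param signed emit signed (unrectified-looking) samples.
#' @return numeric vector of EMG samples.
#' @export
gen_emg <- function(drive, fs = 1000, seed = 1, signed = FALSE) {
  if (any(drive < 0 | drive > 1)) stop("drive outside [0,1]")
  set.seed(seed)
  n <- length(drive)
  out <- numeric(n)
  pos <- drive > 0
  out[pos] <- stats::rexp(sum(pos), rate = 1 / drive[pos])
  if (signed) out <- out * sample(c(-1, 1), n, replace = TRUE)
  out
}

#' Simulate the jump-diffusion drive process
#'
#' Latent drive evolving by Brownian increments at rate \code{alpha} with
#' jumps to a uniform level at rate \code{beta} events per second, clipped
#' to [0,1].
#'
#' @param n samples. @param fs rate, Hz. @param alpha diffusion rate.
#' @param beta jump rate, events/s. @param x0 initial level.
#' @param seed RNG seed.
#' @return numeric vector in [0,1].
#' @export
gen_drive_process <- function(n, fs = 1000, alpha = 0.05, beta = 1,
                              x0 = 0.2, seed = 1) {
  set.seed(seed)
  dt <- 1 / fs
  x <- numeric(n); x[1] <- x0
  dW <- stats::rnorm(n, 0, sqrt(alpha * dt))
  jump <- stats::runif(n) < beta * dt
  U <- stats::runif(n)
  for (i in 2:n) {
    x[i] <- if (jump[i]) U[i] else x[i - 1] + dW[i]
    x[i] <- min(max(x[i], 0), 1)
  }
  x
}

#' Draw ground-truth morphology parameters within bounds
#'
#' Uniform draw strictly inside the identification bounds; when a dataset
#' is supplied, draws whose rigid-tendon fascicle sweep leaves the active
#' force-length band are rejected and redrawn.
#'
#' @param bounds \code{bounds} object (see \code{\link{build_bounds}}).
#' @param seed RNG seed.
#' @param dataset optional partial dataset for the feasibility check.
#' @param max_reject rejection budget (default 1e4).
#' @return \code{morphology} object.
#' @export
gen_truth_params <- function(bounds, seed = 1, dataset = NULL,
                             max_reject = 1e4) {
  stopifnot(inherits(bounds, "mt_bounds"))
  set.seed(seed)
  for (i in seq_len(max_reject)) {
    x <- bounds$lower + stats::runif(length(bounds$lower)) *
      (bounds$upper - bounds$lower)
    morph <- unpack_morphology(x, bounds$muscles, bounds$has_hfl)
    if (is.null(dataset) ||
        all(.scale_feasible(morph, dataset))) return(morph)
  }
  stop("no feasible morphology after ", max_reject, " rejections")
}

# TRUE per muscle when the rigid-tendon fascicle sweep stays within the
# force-length band [l_opt (1-w), l_opt (1+w)]
.scale_feasible <- function(morph, dataset) {
  tab <- default_muscle_table()
  vapply(names(morph$F_max), function(m) {
    row <- tab[tab$muscle == m, ]
    s <- morph$length_scale[[m]]
    l_opt <- row$l_opt_ref * s; l_sl <- row$l_sl_ref * s
    lm <- (dataset$mtu_lengths[[m]] - l_sl) / cos(row$theta0)
    all(lm > l_opt * (1 - row$w)) && all(lm < l_opt * (1 + row$w))
  }, logical(1))
}

#' Forward-generate a complete dataset from known ground truth
#'
#' Closes the loop: activations are obtained from the drive templates via
#' the activation dynamics, all MTUs are simulated over two cycles with the
#' ground-truth morphology, joint moments get additive Gaussian noise
#' (stated fraction of each joint's range), EMG is sampled from the drives
#' at \code{emg_rate}, and ground-truth metabolics are recorded.
#'
#' @param truth \code{morphology} object (ground-truth parameters).
#' @param partial output of \code{\link{gen_kinematics_geometry}}.
#' @param drives named list of drive series on the mechanics grid; default
#'   the packaged templates.
#' @param noise_sd_frac moment noise SD as fraction of per-joint range
#'   (default 0.02).
#' @param emg_rate EMG sampling rate, Hz.
#' @param seed RNG seed.
#' @return list of class \code{gait_dataset}: the fields of \code{partial}
#'   plus \code{joint_moments} (noisy, N m), \code{joint_moments_clean},
#'   \code{emg}, \code{emg_time}, and \code{truth} (morphology, drives,
#'   activations, traces, C_met, mcot).
#' @export
forward_generate <- function(truth, partial, drives = NULL,
                             noise_sd_frac = 0.02, emg_rate = 1000,
                             seed = 1) {
  muscles <- partial$muscles
  if (is.null(drives))
    drives <- synthetic_drives(partial$time, partial$period, muscles)
  stopifnot(all(vapply(drives, function(d)
    all(d >= 0 & d <= 1), logical(1))))
  tab <- default_muscle_table()
  params <- morphology_to_params(truth, tab)
  acts <- lapply(muscles, function(m) {
    row <- tab[tab$muscle == m, ]
    activation_dynamics(drives[[m]], partial$time,
                        tau_act = row$tau_act, tau_deact = row$tau_deact,
                        threshold = 0)
  })
  names(acts) <- muscles
  traces <- lapply(muscles, function(m)
    simulate_mtu(partial$mtu_lengths[[m]], acts[[m]], partial$time,
                 params[[m]]))
  names(traces) <- muscles
  hfl <- if (!is.null(truth$K_HFL))
    hfl_params(truth$K_HFL, truth$theta0_HFL) else NULL
  tau <- joint_moments(traces, partial$moment_arms, hfl = hfl,
                       theta_hip = partial$joint_angles$hip)
  set.seed(seed)
  tau_noisy <- tau
  for (joint in setdiff(names(tau), "time")) {
    rng <- diff(range(tau[[joint]]))
    tau_noisy[[joint]] <- tau[[joint]] +
      stats::rnorm(nrow(tau), 0, noise_sd_frac * max(rng, 1e-9))
  }
  # EMG on its own (faster) clock, sampled from the drive signals
  emg_time <- seq(0, partial$period - 1 / emg_rate, by = 1 / emg_rate)
  emg <- lapply(seq_along(muscles), function(i) {
    d <- stats::approx(partial$time, drives[[muscles[i]]],
                       xout = emg_time, rule = 2)$y
    gen_emg(pmin(pmax(d, 0), 1), fs = emg_rate, seed = seed + i)
  })
  names(emg) <- muscles
  rep_en <- energetics_report(traces, drives, params, partial$scalars,
                              partial$events)
  out <- c(partial,
           list(joint_moments = tau_noisy[setdiff(names(tau), "time")],
                joint_moments_clean = tau[setdiff(names(tau), "time")],
                emg = as.data.frame(emg), emg_time = emg_time,
                truth = list(morphology = truth, drives = drives,
                             activations = acts, traces = traces,
                             C_met = rep_en$C_met, mcot = rep_en$mcot)))
  class(out) <- "gait_dataset"
  out
}

#' Physiological truth window inside the search bounds
#'
#' The identification searches a deliberately wide box (strength up to
#' three times reference); a realistic subject sits near the reference
#' morphology. Ground truths are therefore drawn from a narrower window:
#' maximal force within [0.85, 1.25] of reference, length multiplier in
#' the central half of its feasible interval, tendon constants in the
#' mid-range typical of identified optima (K_sh 2.2-3.5, lambda_ref
#' 0.04-0.08), ligament in the central half of its box.
#'
#' @param bounds full search \code{mt_bounds}.
#' @param f_window relative F_max window around reference.
#' @return narrowed \code{mt_bounds}.
#' @export
truth_window <- function(bounds, f_window = c(0.85, 1.25)) {
  lower <- bounds$lower; upper <- bounds$upper
  ref <- bounds$meta$reference_F_max
  for (m in bounds$muscles) {
    i <- which(names(lower) == paste0(m, ".F_max"))
    lower[i] <- max(lower[i], f_window[1] * ref[[m]])
    upper[i] <- min(upper[i], f_window[2] * ref[[m]])
    j <- which(names(lower) == paste0(m, ".scale"))
    mid <- (lower[j] + upper[j]) / 2; half <- (upper[j] - lower[j]) / 4
    lower[j] <- mid - half; upper[j] <- mid + half
    k <- which(names(lower) == paste0(m, ".K_sh"))
    lower[k] <- 2.2; upper[k] <- 3.5
    l <- which(names(lower) == paste0(m, ".lambda_ref"))
    lower[l] <- 0.04; upper[l] <- 0.08
  }
  if (bounds$has_hfl) {
    n <- length(lower)
    for (i in c(n - 1, n)) {
      mid <- (lower[i] + upper[i]) / 2; half <- (upper[i] - lower[i]) / 4
      lower[i] <- mid - half; upper[i] <- mid + half
    }
  }
  structure(list(lower = lower, upper = upper, muscles = bounds$muscles,
                 has_hfl = bounds$has_hfl, meta = bounds$meta),
            class = "mt_bounds")
}

#' One-call synthetic subject
#'
#' Generates geometry, builds the full search bounds, draws a ground-truth
#' morphology from the physiological \code{\link{truth_window}} and
#' forward-simulates the complete dataset.
#'
#' @param seed RNG seed.
#' @param scalars \code{subject_scalars}.
#' @param muscles muscle subset.
#' @param noise_sd_frac moment noise level.
#' @param ... passed to \code{gen_kinematics_geometry}.
#' @return \code{gait_dataset} with \code{$truth} and \code{$bounds} (the
#'   full search bounds).
#' @export
synthetic_subject <- function(seed = 1, scalars = subject_scalars(),
                              muscles = default_muscle_table()$muscle,
                              noise_sd_frac = 0.02, ...) {
  partial <- gen_kinematics_geometry(scalars, seed = seed,
                                     muscles = muscles, ...)
  bounds <- build_bounds(partial)
  truth <- gen_truth_params(truth_window(bounds), seed = seed + 1000,
                            dataset = partial)
  ds <- forward_generate(truth, partial, seed = seed + 2000,
                         noise_sd_frac = noise_sd_frac)
  ds$bounds <- bounds
  ds
}

#' Reduced single-joint identification experiment
#'
#' A 3-muscle (TA, SOL, GAS), ankle-only identification problem with
#' boosted excitation: the drive templates are scaled by \code{drive_gain}
#' (capped at 1) so the muscles operate near force saturation during their
#' bursts, the informative regime for strength identification (a weakly
#' excited muscle's maximal force trades off against tendon compliance
#' and is not observable from joint moments). Noiseless by default.
#'
#' By default the benchmark frees only the three maximal forces and pins
#' each muscle's length multiplier and tendon constants at their true
#' values (strength recovery under known muscle-tendon geometry and
#' tendon material properties). This isolates what the search machinery
#' can be held to: with the tendon and length parameters also free, a
#' strength error of tens of percent can be compensated by the muscle's
#' own compliance parameters to a kinetic-cost floor around 1e-5, so
#' maximal force is not identifiable from joint moments alone -- the
#' under-determination that motivates selecting solutions by metabolic
#' plausibility rather than kinetic fit.
#'
#' @param seed RNG seed.
#' @param drive_gain excitation gain on the drive templates (default 1.6).
#' @param noise_sd_frac moment noise level (default 0, noiseless).
#' @param free which parameters the returned bounds leave free:
#'   \code{"F_max"} (default) or \code{"all"}.
#' @return \code{gait_dataset} with \code{$truth} and \code{$bounds}.
#' @export
toy_problem <- function(seed = 1, drive_gain = 1.6, noise_sd_frac = 0,
                        free = c("F_max", "all")) {
  free <- match.arg(free)
  muscles <- c("TA", "SOL", "GAS")
  partial <- gen_kinematics_geometry(seed = seed, muscles = muscles,
                                     joints = "ankle")
  bounds <- build_bounds(partial, include_hfl = FALSE)
  truth <- gen_truth_params(truth_window(bounds), seed = seed + 1000,
                            dataset = partial)
  # temporally separated bursts: an identification experiment needs each
  # actuator excited on its own so strength is observable (SOL mid-stance,
  # GAS a narrow late-stance power burst, TA around heel strike and swing)
  phi <- ((partial$time - partial$time[1]) / partial$period) %% 1
  g <- function(...) pmin(drive_gain * Reduce(`+`, lapply(
    list(...), function(b) .gc_bump(phi, b[1], b[2], b[3]))), 1)
  drives <- list(TA = g(c(0.03, 0.05, 0.30), c(0.80, 0.12, 0.20)),
                 SOL = g(c(0.30, 0.10, 0.50)),
                 GAS = g(c(0.52, 0.06, 0.45)))
  ds <- forward_generate(truth, partial, drives = drives,
                         seed = seed + 2000,
                         noise_sd_frac = noise_sd_frac)
  if (free == "F_max") {
    # pin everything except strength at the true values
    x <- pack_morphology(truth)
    pin <- !grepl("F_max", names(bounds$lower))
    bounds$lower[pin] <- x[pin]
    bounds$upper[pin] <- x[pin]
  }
  ds$bounds <- bounds
  ds
}
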