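# Dual-objective identification of muscle-tendon morphology: the
# 50-element parameter vector (4 per muscle + 2 ligament), bounds,
# kinetic/metabolic cost functions and candidate evaluation.

#' Pack a morphology into the flat optimization vector
#'
#' Fixed ordering, versioned with the package: for each muscle in the
#' given order the quadruple (F_max, length_scale, K_sh, lambda_ref), then
#' (K_HFL, theta0_HFL) when the ligament is present. Twelve muscles plus
#' the ligament give 50 scalars.
#'
#' @param morph \code{morphology} object.
#' @return numeric vector.
#' @export
pack_morphology <- function(morph) {
  muscles <- names(morph$F_max)
  x <- as.vector(vapply(muscles, function(m)
    c(morph$F_max[[m]], morph$length_scale[[m]],
      morph$K_sh[[m]], morph$lambda_ref[[m]]), numeric(4)))
  if (!is.null(morph$K_HFL)) x <- c(x, morph$K_HFL, morph$theta0_HFL)
  unname(x)
}

#' Unpack the flat optimization vector into a morphology
#'
#' @param x numeric vector (4 per muscle, plus 2 if \code{has_hfl}).
#' @param muscles muscle names in packing order.
#' @param has_hfl whether the last two elements are the ligament.
#' @return object of class \code{morphology}.
#' @export
unpack_morphology <- function(x, muscles, has_hfl = TRUE) {
  n <- length(muscles)
  stopifnot(length(x) == 4 * n + if (has_hfl) 2 else 0)
  m <- matrix(x[seq_len(4 * n)], nrow = 4)
  out <- list(
    F_max = stats::setNames(m[1, ], muscles),
    length_scale = stats::setNames(m[2, ], muscles),
    K_sh = stats::setNames(m[3, ], muscles),
    lambda_ref = stats::setNames(m[4, ], muscles),
    K_HFL = if (has_hfl) unname(x[4 * n + 1]) else NULL,
    theta0_HFL = if (has_hfl) unname(x[4 * n + 2]) else NULL)
  class(out) <- "morphology"
  out
}

#' Expand a morphology into per-muscle MTU parameter sets
#'
#' @param morph \code{morphology}.
#' @param table muscle table supplying the reference lengths and fixed
#'   Hill constants.
#' @return named list of \code{mtu_params}.
#' @export
morphology_to_params <- function(morph, table = default_muscle_table()) {
  build_mtu_set(morph$F_max, morph$length_scale, morph$K_sh,
                morph$lambda_ref, table = table)
}

#' Construct identification bounds from a dataset
#'
#' Maximal forces are bounded to [0.5, 3.0] times the reference value;
#' tendon constants to K_sh in [2, 5] and lambda_ref in [0.02, 0.09]. The
#' per-muscle length multiplier interval is computed so that the
#' rigid-tendon fascicle sweep over the cycle stays strictly inside the
#' active force-length band [l_opt(1-w), l_opt(1+w)]. Ligament bounds:
#' engagement angle in [-pi/18, |min hip angle|]; spring constant in
#' [0, 2 max(hip torque)/|min hip angle|] (when the dataset carries no
#' torque yet, the torque scale defaults to 1 N m per kg body mass).
#'
#' @param dataset (partial) gait dataset with \code{mtu_lengths},
#'   \code{joint_angles}, optionally \code{joint_moments}.
#' @param reference_F_max named vector of reference forces, N (default the
#'   muscle table).
#' @param include_hfl include the ligament parameters (default: TRUE when
#'   the hip is present).
#' @return object of class \code{mt_bounds}: \code{lower}, \code{upper},
#'   \code{muscles}, \code{has_hfl}, \code{meta}.
#' @export
build_bounds <- function(dataset, reference_F_max = NULL,
                         include_hfl = NULL) {
  tab <- default_muscle_table()
  muscles <- dataset$muscles
  if (is.null(reference_F_max))
    reference_F_max <- stats::setNames(
      tab$F_max_ref[match(muscles, tab$muscle)], muscles)
  if (is.null(include_hfl))
    include_hfl <- "hip" %in% names(dataset$joint_angles) &&
      any(muscles %in% names(.moment_arm_table()$hip))
  lower <- c(); upper <- c()
  for (m in muscles) {
    row <- tab[tab$muscle == m, ]
    lm <- dataset$mtu_lengths[[m]]
    ct <- cos(row$theta0)
    s_lo <- max(lm) / (row$l_sl_ref + row$l_opt_ref * (1 + row$w) * ct)
    s_hi <- min(lm) / (row$l_sl_ref + row$l_opt_ref * (1 - row$w) * ct)
    s_lo <- s_lo * 1.002; s_hi <- s_hi * 0.998
    if (s_lo >= s_hi)
      stop(sprintf("no feasible length-scale interval for muscle %s", m))
    lower <- c(lower, 0.5 * reference_F_max[[m]], s_lo, 2, 0.02)
    upper <- c(upper, 3.0 * reference_F_max[[m]], s_hi, 5, 0.09)
  }
  if (include_hfl) {
    th_min <- abs(min(dataset$joint_angles$hip))
    tau_max <- if (!is.null(dataset$joint_moments))
      max(dataset$joint_moments$hip) else dataset$scalars$body_mass * 1.0
    lower <- c(lower, 0, -pi / 18)
    upper <- c(upper, 2 * tau_max / th_min, th_min)
  }
  nm <- c(as.vector(outer(c("F_max", "scale", "K_sh", "lambda_ref"),
                          muscles, function(a, b) paste(b, a, sep = "."))),
          if (include_hfl) c("K_HFL", "theta0_HFL"))
  structure(list(lower = stats::setNames(lower, nm),
                 upper = stats::setNames(upper, nm),
                 muscles = muscles, has_hfl = include_hfl,
                 meta = list(reference_F_max = reference_F_max)),
            class = "mt_bounds")
}

#' Kinetic cost: one minus the mean coefficient of determination
#'
#' Per joint, \eqn{R^2 = 1 - SS_{res}/SS_{tot}} between modeled and
#' experimental torque (negative for fits worse than the mean);
#' \eqn{C_{kin} = 1 - \overline{R^2}}.
#'
#' @param tau_mod data.frame of modeled torques (one column per joint).
#' @param tau_exp data.frame of experimental torques, same joints.
#' @return list: \code{C_kin}, \code{mean_R2}, \code{R2} (named per joint).
#' @export
kinetic_cost <- function(tau_mod, tau_exp) {
  joints <- setdiff(names(tau_exp), "time")
  r2 <- vapply(joints, function(j) {
    e <- tau_exp[[j]]
    ss_tot <- sum((e - mean(e))^2)
    if (ss_tot == 0) stop("zero-variance experimental torque at ", j)
    1 - sum((e - tau_mod[[j]])^2) / ss_tot
  }, numeric(1))
  list(C_kin = 1 - mean(r2), mean_R2 = mean(r2), R2 = r2)
}

#' Fractional mean absolute error of a joint moment over stance
#'
#' Mean absolute modeled-vs-experimental difference over the stance window
#' divided by the experimental torque range over the same window.
#'
#' @param tau_mod,tau_exp numeric vectors, one joint's torque.
#' @param time time base, s.
#' @param events \code{gait_events} (stance = heel strike to toe-off), or
#'   \code{stance} may be given directly.
#' @param stance optional logical index vector selecting stance samples.
#' @return dimensionless FMAE.
#' @export
fmae <- function(tau_mod, tau_exp, time = NULL, events = NULL,
                 stance = NULL) {
  if (is.null(stance)) {
    stopifnot(!is.null(time), !is.null(events))
    stance <- time >= events$heel_strike[1] & time <= events$toe_off[1]
  }
  e <- tau_exp[stance]; m <- tau_mod[stance]
  r <- diff(range(e))
  if (r == 0) stop("zero experimental torque range over stance")
  mean(abs(e - m)) / r
}

#' Evaluate one candidate morphology on a dataset
#'
#' Simulates every muscle for two gait cycles (second scored), assembles
#' joint moments including the ligament, and returns the metabolic cost
#' (gross, both legs, basal included) and kinetic cost. A failed
#' simulation returns worst-case penalty costs with a diagnostic flag
#' rather than raising, so an optimizer loop never dies on one candidate.
#'
#' @param morph \code{morphology} or packed numeric vector.
#' @param dataset \code{gait_dataset}.
#' @param activations named list of activation series (mechanics grid);
#'   defaults to the dataset's ground-truth activations.
#' @param drives named list of drive series (for the metabolic
#'   excitation factor); defaults to the dataset's ground truth.
#' @param bounds needed only to unpack a numeric \code{morph}.
#' @return list: \code{C_met}, \code{mcot}, \code{C_kin}, \code{mean_R2},
#'   \code{R2}, \code{fractions} (per-muscle metabolic fractions, both
#'   legs, basal included), \code{failed}, \code{n_clamped}.
#' @export
evaluate_candidate <- function(morph, dataset, activations = NULL,
                               drives = NULL, bounds = NULL) {
  if (is.numeric(morph)) {
    stopifnot(!is.null(bounds))
    morph <- unpack_morphology(morph, bounds$muscles, bounds$has_hfl)
  }
  if (is.null(activations)) activations <- dataset$truth$activations
  if (is.null(drives)) drives <- dataset$truth$drives
  muscles <- names(morph$F_max)
  scalars <- dataset$scalars
  T <- dataset$period
  penalty <- function(why) {
    basal <- scalars$body_mass * scalars$basal_rate * T
    list(C_met = 10 * basal,
         mcot = 10 * basal / (scalars$body_mass * 9.81 *
                                scalars$walking_speed * T),
         C_kin = 2, mean_R2 = -1,
         R2 = NULL, fractions = NULL, failed = TRUE, why = why,
         n_clamped = NA_integer_)
  }
  res <- tryCatch({
    params <- morphology_to_params(morph)
    traces <- lapply(muscles, function(m)
      simulate_mtu(dataset$mtu_lengths[[m]], activations[[m]],
                   dataset$time, params[[m]]))
    names(traces) <- muscles
    hfl <- if (!is.null(morph$K_HFL))
      hfl_params(morph$K_HFL, morph$theta0_HFL) else NULL
    tau <- joint_moments(traces, dataset$moment_arms, hfl = hfl,
                         theta_hip = dataset$joint_angles$hip)
    kin <- kinetic_cost(tau, dataset$joint_moments)
    masses <- vapply(params, muscle_mass, numeric(1))
    energies <- vapply(muscles, function(m) {
      tr <- traces[[m]]
      r <- umberger_rate(drives[[m]], tr$a, tr$l_CE, tr$v_CE, tr$F_CE,
                         masses[[m]], params[[m]])
      dt <- diff(tr$time)
      sum(dt * (r$total[-1] + r$total[-nrow(r)]) / 2) * masses[[m]]
    }, numeric(1))
    cost <- whole_body_cost(energies, masses, scalars, T)
    list(C_met = cost$C_met, mcot = cost$mcot,
         C_kin = kin$C_kin, mean_R2 = kin$mean_R2, R2 = kin$R2,
         fractions = 2 * energies / cost$C_met,
         failed = FALSE, why = NULL,
         n_clamped = sum(vapply(traces, function(tr)
           attr(tr, "n_clamped"), numeric(1))))
  }, error = function(e) penalty(conditionMessage(e)))
  res
}

#' Genetic-algorithm settings
#'
#' Two presets: \code{"desk"} (population 64, 20 generations) sized for
#' interactive use and testing, and \code{"paper"} (population 1000, 100
#' generations, elite fraction from 25/1000) matching a full-scale
#' identification run.
#'
#' @param preset \code{"desk"} or \code{"paper"}; individual fields
#'   override the preset.
#' @param pop_size,generations,crossover_fraction,mutation_sd_frac,
#'   mutation_prob optional overrides.
#' @return list of class \code{ga_config}.
#' @export
ga_config <- function(preset = c("desk", "paper"), pop_size = NULL,
                      generations = NULL, crossover_fraction = 0.8,
                      mutation_sd_frac = 0.02, mutation_prob = 0.2) {
  preset <- match.arg(preset)
  def <- switch(preset,
                desk  = list(pop_size = 64, generations = 20),
                paper = list(pop_size = 1000, generations = 100))
  structure(list(pop_size = if (is.null(pop_size)) def$pop_size
                 else pop_size,
                 generations = if (is.null(generations)) def$generations
                 else generations,
                 crossover_fraction = crossover_fraction,
                 mutation_sd_frac = mutation_sd_frac,
                 mutation_prob = mutation_prob,
                 preset = preset),
            class = "ga_config")
}

# Lean evaluation path used inside the optimizer loop: identical math to
# evaluate_candidate but no data.frame assembly. Returns c(C_met, C_kin)
# plus details when asked.
.eval_core <- function(x, dataset, activations, drives, bounds,
                       details = FALSE) {
  morph <- unpack_morphology(x, bounds$muscles, bounds$has_hfl)
  muscles <- bounds$muscles
  scalars <- dataset$scalars
  T <- dataset$period
  tab <- default_muscle_table()
  time <- dataset$time
  n <- length(time)
  dt <- time[2] - time[1]
  idx <- rep(seq_len(n), 2)
  tt <- time[1] + (seq_len(2 * n) - 1) * dt
  keep <- seq.int(n + 1L, 2L * n)
  out <- tryCatch({
    joints <- names(dataset$moment_arms)
    tau <- lapply(joints, function(j) numeric(n))
    names(tau) <- joints
    C_mus <- 0; m_mus <- 0
    energies <- numeric(length(muscles)); names(energies) <- muscles
    masses <- numeric(length(muscles)); names(masses) <- muscles
    for (m in muscles) {
      row <- tab[tab$muscle == m, ]
      p <- mtu_params(F_max = morph$F_max[[m]],
                      l_opt = row$l_opt_ref * morph$length_scale[[m]],
                      l_sl = row$l_sl_ref * morph$length_scale[[m]],
                      K_sh = morph$K_sh[[m]],
                      lambda_ref = morph$lambda_ref[[m]],
                      theta0 = row$theta0, w = row$w, FT = row$FT,
                      muscle = m)
      a <- activations[[m]]
      res <- .mtu_simulate_cpp(tt, dataset$mtu_lengths[[m]][idx], a[idx],
                               unclass(p), n_sub = 4L, l_CE0 = NA_real_)
      F_SE <- res$F_SE[keep]
      for (j in joints) {
        r <- dataset$moment_arms[[j]][[m]]
        if (!is.null(r)) tau[[j]] <- tau[[j]] + F_SE * r
      }
      mass <- muscle_mass(p)
      r_tot <- umberger_rate(drives[[m]], a, res$l_CE[keep],
                             res$v_CE[keep], res$F_CE[keep],
                             mass, p)$total
      energies[[m]] <- sum(diff(time) *
                             (r_tot[-1] + r_tot[-n]) / 2) * mass
      masses[[m]] <- mass
    }
    if (bounds$has_hfl && "hip" %in% joints) {
      hfl <- hfl_params(morph$K_HFL, morph$theta0_HFL)
      tau$hip <- tau$hip + hfl_torque(dataset$joint_angles$hip, hfl)
    }
    kin <- kinetic_cost(as.data.frame(tau), dataset$joint_moments)
    cost <- whole_body_cost(energies, masses, scalars, T)
    if (details)
      list(obj = c(cost$C_met, kin$C_kin),
           res = list(C_met = cost$C_met, mcot = cost$mcot,
                      C_kin = kin$C_kin, mean_R2 = kin$mean_R2,
                      R2 = kin$R2, fractions = 2 * energies / cost$C_met,
                      failed = FALSE))
    else c(cost$C_met, kin$C_kin)
  }, error = function(e) {
    basal <- scalars$body_mass * scalars$basal_rate * T
    pen <- list(C_met = 10 * basal,
                mcot = 10 * basal / (scalars$body_mass * 9.81 *
                                       scalars$walking_speed * T),
                C_kin = 2, mean_R2 = -1, R2 = NULL, fractions = NULL,
                failed = TRUE, why = conditionMessage(e))
    if (details) list(obj = c(pen$C_met, pen$C_kin), res = pen)
    else c(pen$C_met, pen$C_kin)
  })
  out
}
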