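#' Default lumped muscle table for the sagittal-plane leg model
#'
#' Twelve lumped actuators spanning ankle, knee and hip, plus a passive hip
#' flexor ligament handled separately. Per-muscle columns give the reference
#' morphology that the identification's dimensionless length multiplier acts
#' on, the Hill-curve constants, fiber composition and activation time
#' constants.
#'
#' Columns:
#' \describe{
#'   \item{muscle}{abbreviation (TA, SOL, GAS, VAS, BFSH, RF, HAM, ILL,
#'     GMAX, GMED, ADDL, ADDM)}
#'   \item{F_max_ref}{reference maximal isometric force, N}
#'   \item{l_opt_ref}{reference optimal fascicle length, m}
#'   \item{l_sl_ref}{reference tendon slack length, m}
#'   \item{theta0}{pennation angle at \code{l_CE = l_opt}, rad}
#'   \item{w}{active force-length width, dimensionless}
#'   \item{FT}{fast-twitch fiber fraction in [0,1]}
#'   \item{tau_act, tau_deact}{activation/deactivation time constants, s}
#' }
#'
#' Reference forces and lengths are literature-typical values for an adult
#' male; they only anchor the synthetic generator and the identification
#' bounds (the identification itself rescales them).
#'
#' @return data.frame, one row per muscle, in canonical order.
#' @export
default_muscle_table <- function() {
  tab <- data.frame(
    muscle    = c("TA",  "SOL", "GAS", "VAS", "BFSH", "RF",  "HAM", "ILL",
                  "GMAX", "GMED", "ADDL", "ADDM"),
    F_max_ref = c(800,  3600, 1600, 6000, 350,  850,  2600, 1400,
                  1800, 1600, 450,  1000),
    l_opt_ref = c(0.070, 0.055, 0.060, 0.090, 0.120, 0.080, 0.100, 0.100,
                  0.150, 0.070, 0.110, 0.120),
    l_sl_ref  = c(0.240, 0.260, 0.380, 0.160, 0.100, 0.350, 0.330, 0.090,
                  0.110, 0.050, 0.110, 0.120),
    theta0    = c(5, 25, 17, 5, 12, 5, 7, 8, 3, 8, 6, 5) * pi / 180,
    w         = c(0.45, 0.56, 0.56, 0.56, 0.50, 0.50, 0.50, 0.50,
                  0.50, 0.50, 0.50, 0.50),
    FT        = c(0.30, 0.20, 0.50, 0.50, 0.50, 0.55, 0.45, 0.50,
                  0.45, 0.45, 0.50, 0.55),
    stringsAsFactors = FALSE
  )
  # SOL is slow-dominant: slower activation dynamics
  tab$tau_act <- ifelse(tab$muscle == "SOL", 0.018, 0.012)
  tab$tau_deact <- 4 * tab$tau_act
  tab
}

#' Muscle-to-joint wiring of the leg model
#'
#' Which muscles span which sagittal-plane joints. Biarticular muscles (GAS,
#' RF, HAM) appear at two joints. The hip flexor ligament acts at the hip
#' only and is not listed here.
#'
#' @return named list of character vectors, one per joint
#'   (ankle, knee, hip).
#' @export
muscle_wiring <- function() {
  list(
    ankle = c("TA", "SOL", "GAS"),
    knee  = c("GAS", "VAS", "BFSH", "RF", "HAM"),
    hip   = c("RF", "HAM", "ILL", "GMAX", "GMED", "ADDL", "ADDM")
  )
}

#' Construct a validated MTU parameter set
#'
#' Bundles one muscle's morphology and Hill-curve constants. \code{l_opt}
#' and \code{l_sl} are the actual lengths used by the simulation (the
#' identification varies a joint multiplier on a reference pair and passes
#' the products here).
#'
#' @param F_max maximal isometric force, N.
#' @param l_opt optimal fascicle length, m.
#' @param l_sl tendon slack length, m.
#' @param K_sh tendon shape factor, dimensionless, in [2, 5].
#' @param lambda_ref tendon reference strain (strain where the tendon
#'   carries \code{F_max}), in [0.02, 0.09].
#' @param theta0 pennation angle at optimal length, rad.
#' @param w active force-length width, dimensionless.
#' @param FT fast-twitch fraction in [0,1].
#' @param v_max maximal shortening velocity, m/s. Default
#'   \code{(6 + 6*FT) * l_opt} per second (fiber-composition scaling).
#' @param K_hill Hill force-velocity curvature constant (default 5).
#' @param N_ecc eccentric force saturation as multiple of F_max
#'   (default 1.5).
#' @param tau_act,tau_deact activation time constants, s.
#' @param muscle optional name tag.
#' @return object of class \code{mtu_params} (a named list).
#' @export
mtu_params <- function(F_max, l_opt, l_sl, K_sh = 3, lambda_ref = 0.05,
                       theta0 = 0, w = 0.56, FT = 0.5,
                       v_max = (6 + 6 * FT) * l_opt,
                       K_hill = 5, N_ecc = 1.5,
                       tau_act = 0.012, tau_deact = 0.048,
                       muscle = NA_character_) {
  stopifnot(F_max > 0, l_opt > 0, l_sl > 0,
            lambda_ref > 0, K_sh > 0, w > 0, w < 1,
            v_max > 0, FT >= 0, FT <= 1,
            theta0 >= 0, theta0 < pi / 2)
  structure(list(F_max = F_max, l_opt = l_opt, l_sl = l_sl,
                 K_sh = K_sh, lambda_ref = lambda_ref, theta0 = theta0,
                 w = w, FT = FT, v_max = v_max, K_hill = K_hill,
                 N_ecc = N_ecc, tau_act = tau_act, tau_deact = tau_deact,
                 muscle = muscle),
            class = "mtu_params")
}

#' @export
print.mtu_params <- function(x, ...) {
  cat(sprintf("MTU parameters%s\n",
              if (is.na(x$muscle)) "" else paste0(" [", x$muscle, "]")))
  cat(sprintf("  F_max %.4g N | l_opt %.4g m | l_sl %.4g m\n",
              x$F_max, x$l_opt, x$l_sl))
  cat(sprintf("  K_sh %.3g | lambda_ref %.3g | theta0 %.3g rad | w %.2g\n",
              x$K_sh, x$lambda_ref, x$theta0, x$w))
  cat(sprintf("  FT %.2g | v_max %.3g m/s | tau %.3g/%.3g s\n",
              x$FT, x$v_max, x$tau_act, x$tau_deact))
  invisible(x)
}

#' Hip flexor ligament parameters
#'
#' Lumped iliofemoral/ischiofemoral/pubofemoral ligament modeled as a linear
#' rotary spring that engages when the hip extends beyond its engagement
#' angle (flexion positive).
#'
#' @param K_HFL spring constant, N m / rad, non-negative.
#' @param theta0_HFL engagement angle, rad.
#' @return object of class \code{hfl_params}.
#' @export
hfl_params <- function(K_HFL, theta0_HFL) {
  stopifnot(K_HFL >= 0, is.finite(theta0_HFL))
  structure(list(K_HFL = K_HFL, theta0_HFL = theta0_HFL),
            class = "hfl_params")
}

#' Build MTU parameter sets from a morphology assignment
#'
#' Expands the muscle table into per-muscle \code{mtu_params}, applying a
#' per-muscle maximal force and the dimensionless length multiplier that
#' jointly scales (l_sl, l_opt).
#'
#' @param F_max named numeric vector of maximal forces, N.
#' @param length_scale named numeric vector of length multipliers.
#' @param K_sh,lambda_ref named numeric vectors of tendon constants.
#' @param table muscle table (default \code{default_muscle_table()}).
#' @return named list of \code{mtu_params}.
#' @export
build_mtu_set <- function(F_max, length_scale, K_sh, lambda_ref,
                          table = default_muscle_table()) {
  muscles <- names(F_max)
  stopifnot(!is.null(muscles), all(muscles %in% table$muscle))
  out <- lapply(muscles, function(m) {
    row <- table[table$muscle == m, ]
    mtu_params(F_max = F_max[[m]],
               l_opt = row$l_opt_ref * length_scale[[m]],
               l_sl = row$l_sl_ref * length_scale[[m]],
               K_sh = K_sh[[m]], lambda_ref = lambda_ref[[m]],
               theta0 = row$theta0, w = row$w, FT = row$FT,
               tau_act = row$tau_act, tau_deact = row$tau_deact,
               muscle = m)
  })
  names(out) <- muscles
  out
}
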