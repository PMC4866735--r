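#' Series-elastic (tendon) force from strain
#'
#' Exponential toe-region force-strain law. The tendon is slack (zero force)
#' at non-positive strain, and carries exactly \code{F_max} at the reference
#' strain \code{lambda_ref} regardless of the shape factor:
#' \deqn{F(\lambda) = F_{max} \frac{e^{K_{sh}\lambda/\lambda_{ref}} - 1}
#'                                 {e^{K_{sh}} - 1}, \quad \lambda > 0.}
#'
#' @param lambda tendon strain beyond slack length,
#'   \eqn{(l_{SE} - l_{sl})/l_{sl}} (vectorized).
#' @param params \code{mtu_params}.
#' @return force, N (same length as \code{lambda}).
#' @export
tendon_force <- function(lambda, params) {
  out <- numeric(length(lambda))
  pos <- lambda > 0
  out[pos] <- params$F_max *
    (exp(params$K_sh * lambda[pos] / params$lambda_ref) - 1) /
    (exp(params$K_sh) - 1)
  out
}

#' Pennation angle at a given fascicle length
#'
#' Constant-muscle-width model: \eqn{l_{CE}\sin\theta = l_{opt}\sin\theta_0}.
#' Below the geometric minimum length the angle is clamped just under 90
#' degrees and a warning is raised, so violations are visible but do not
#' abort a simulation.
#'
#' @param l_CE fascicle length, m (vectorized).
#' @param params \code{mtu_params}.
#' @return pennation angle, rad.
#' @export
pennation_angle <- function(l_CE, params) {
  if (params$theta0 == 0) return(numeric(length(l_CE)))
  s <- params$l_opt * sin(params$theta0) / l_CE
  if (any(s > 1)) {
    warning("l_CE below geometric minimum width; pennation clamped at 89.9 deg")
    s <- pmin(s, sin(89.9 * pi / 180))
  }
  asin(s)
}

#' Active force-length factor
#'
#' Bell curve equal to 1 at \code{l_opt} and 0.05 at the width boundaries
#' \code{l_opt (1 +/- w)}:
#' \deqn{f_l = \exp\left(\ln(0.05)\,
#'   \left|\frac{l_{CE}-l_{opt}}{l_{opt} w}\right|^3\right).}
#'
#' @param l_CE fascicle length, m (vectorized).
#' @param params \code{mtu_params}.
#' @return dimensionless factor in (0, 1].
#' @export
force_length <- function(l_CE, params) {
  exp(log(0.05) * abs((l_CE - params$l_opt) / (params$l_opt * params$w))^3)
}

#' Force-velocity factor
#'
#' Hill hyperbola on the concentric branch (shortening, \code{v < 0} in this
#' package's lengthening-positive convention) with curvature \code{K_hill},
#' and a saturating eccentric branch reaching \code{N_ecc} at large
#' lengthening rates:
#' \deqn{f_v(v<0) = \frac{v_{max} - |v|}{v_{max} + K |v|},\qquad
#'       f_v(v\ge 0) = N - (N-1)\frac{v_{max} + v}{7.56 K v + v_{max}}.}
#'
#' @param v_CE fascicle velocity, m/s, positive = lengthening (vectorized).
#' @param params \code{mtu_params}.
#' @return dimensionless factor in [0, \code{N_ecc}).
#' @export
force_velocity <- function(v_CE, params) {
  K <- params$K_hill; N <- params$N_ecc; vm <- params$v_max
  out <- numeric(length(v_CE))
  con <- v_CE < 0
  s <- pmin(abs(v_CE[con]), vm)
  out[con] <- (vm - s) / (vm + K * s)
  v <- v_CE[!con]
  out[!con] <- N - (N - 1) * (vm + v) / (7.56 * K * v + vm)
  out
}

#' Invert the force-velocity factor
#'
#' Returns the unique velocity with \code{force_velocity(v) == fv}. The
#' concentric and eccentric branches both invert in closed form; demands at
#' or beyond the curve's range are clamped to the branch caps
#' (\code{-v_max} for \code{fv <= 0}; the eccentric cap for demands at or
#' above the saturation level).
#'
#' @param fv demanded force-velocity factor (vectorized).
#' @param params \code{mtu_params}.
#' @return velocity, m/s, positive = lengthening.
#' @export
force_velocity_inverse <- function(fv, params) {
  K <- params$K_hill; N <- params$N_ecc; vm <- params$v_max
  fv_sat <- N - (N - 1) / (7.56 * K)    # supremum of the eccentric branch
  v_ecc_cap <- vm                        # eccentric velocity cap
  out <- numeric(length(fv))
  lo <- fv <= 0
  out[lo] <- -vm
  con <- !lo & fv < 1
  out[con] <- -vm * (1 - fv[con]) / (1 + K * fv[con])
  ecc <- fv >= 1 & fv < fv_sat
  out[ecc] <- vm * (fv[ecc] - 1) / (7.56 * K * (N - fv[ecc]) - (N - 1))
  sat <- fv >= fv_sat
  out[sat] <- v_ecc_cap
  pmin(out, v_ecc_cap)
}

#' Parallel-elastic force
#'
#' Engages only above optimal fascicle length; quadratic, reaching
#' \code{F_max} at \code{l_opt (1 + w)}.
#'
#' @param l_CE fascicle length, m (vectorized).
#' @param params \code{mtu_params}.
#' @return force, N.
#' @export
parallel_elastic_force <- function(l_CE, params) {
  e <- pmax(0, (l_CE - params$l_opt) / (params$l_opt * params$w))
  params$F_max * e^2
}

#' Contractile and parallel-elastic forces at a state
#'
#' \eqn{F_{CE} = a\,F_{max} f_l(l_{CE}) f_v(v_{CE})}; the parallel element
#' depends on length only.
#'
#' @param a activation in [0,1].
#' @param l_CE fascicle length, m.
#' @param v_CE fascicle velocity, m/s, positive = lengthening.
#' @param params \code{mtu_params}.
#' @return list with \code{F_CE} and \code{F_PE}, N.
#' @export
ce_force <- function(a, l_CE, v_CE, params) {
  stopifnot(all(a >= 0), all(a <= 1))
  list(F_CE = a * params$F_max * force_length(l_CE, params) *
         force_velocity(v_CE, params),
       F_PE = parallel_elastic_force(l_CE, params))
}

#' Solve the series force balance for fascicle velocity
#'
#' Given activation, fascicle length and total MTU length, finds the
#' velocity at which the fiber force (CE + PE, projected through the
#' pennation angle) equals the series-elastic force:
#' \deqn{F_{SE}(\lambda) = (F_{CE}(a,l_{CE},v_{CE}) + F_{PE}(l_{CE}))
#'       \cos\theta.}
#' The Hill curve is inverted analytically on each branch; demands outside
#' the curve's range are clamped to the velocity caps and flagged.
#'
#' @param a activation in [0,1].
#' @param l_CE fascicle length, m.
#' @param l_MTC total muscle-tendon length, m.
#' @param params \code{mtu_params}.
#' @return list: \code{v_CE} (m/s), \code{clamped} (logical), plus the
#'   forces \code{F_SE}, \code{F_PE} and angle \code{theta} at the state.
#' @export
solve_ce_velocity <- function(a, l_CE, l_MTC, params) {
  theta <- as.numeric(pennation_angle(l_CE, params))
  l_SE <- l_MTC - l_CE * cos(theta)
  lambda <- (l_SE - params$l_sl) / params$l_sl
  F_SE <- tendon_force(lambda, params)
  F_PE <- parallel_elastic_force(l_CE, params)
  F_fiber <- F_SE / cos(theta)           # fiber-direction demand
  denom <- a * params$F_max * force_length(l_CE, params)
  clamped <- FALSE
  if (denom <= 0) {
    # inactive fiber: any net demand must be passive; shorten/lengthen at cap
    v <- if (F_fiber > F_PE) params$v_max else -params$v_max
    clamped <- TRUE
    if (abs(F_fiber - F_PE) < 1e-12 * params$F_max) { v <- 0; clamped <- FALSE }
  } else {
    fv <- (F_fiber - F_PE) / denom
    v <- force_velocity_inverse(fv, params)
    fv_sat <- params$N_ecc - (params$N_ecc - 1) / (7.56 * params$K_hill)
    clamped <- fv <= 0 || fv >= fv_sat
  }
  list(v_CE = v, clamped = clamped, F_SE = F_SE, F_PE = F_PE,
       theta = theta, lambda = lambda)
}

#' Hip flexor ligament torque
#'
#' Linear rotary spring engaging when the hip extends beyond the engagement
#' angle (flexion positive): \eqn{\tau = -K(\theta - \theta_0)} for
#' \eqn{\theta < \theta_0}, else 0. When engaged the torque is a pure
#' flexion (positive) moment.
#'
#' @param theta_hip hip angle, rad, flexion positive (vectorized).
#' @param params \code{hfl_params}.
#' @return torque, N m.
#' @export
hfl_torque <- function(theta_hip, params) {
  ifelse(theta_hip < params$theta0_HFL,
         -params$K_HFL * (theta_hip - params$theta0_HFL), 0)
}
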