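# Muscle energetics: per-muscle metabolic rate (activation, maintenance,
# shortening/lengthening heats plus mechanical work of the contractile
# element), muscle masses, whole-body cost, cost of transport and phase
# breakdown.

# Named constants of the heat-rate model (W/kg and normalized-velocity
# units; fiber-type blending per Umberger's formulation, 2010 revision).
.umberger_constants <- function() {
  vbar_max_ft <- 12          # max shortening velocity, fast fibers, l_opt/s
  vbar_max_st <- vbar_max_ft / 2.5
  list(
    vbar_max_ft = vbar_max_ft,
    vbar_max_st = vbar_max_st,
    h_am_coef   = c(per_ft = 128, base = 25),  # activation+maintenance W/kg
    alpha_s_st  = 100 / vbar_max_st,  # shortening heat coeff, slow fibers
    alpha_s_ft  = 153 / vbar_max_ft,  # shortening heat coeff, fast fibers
    alpha_l_factor = 4                # lengthening coeff = 4 x alpha_s_st
  )
}

#' Per-muscle metabolic rate components
#'
#' Metabolic power per unit muscle mass as the sum of activation heat,
#' maintenance heat, shortening/lengthening heat and positive mechanical
#' work of the contractile element. Heats follow the fiber-type-blended
#' formulation with the composite excitation/activation factor
#' \code{A = u} when \code{u > a}, else \code{(u+a)/2}; an aerobic scaling
#' \code{S} multiplies the heat terms. Negative CE work is excluded (the
#' work-rate term is floored at zero). At \code{u = a = 0} every component
#' is identically zero; resting metabolism is billed at the whole-body
#' stage instead.
#'
#' @param u neural excitation (drive) in [0,1] (vectorized).
#' @param a activation in [0,1].
#' @param l_CE fascicle length, m.
#' @param v_CE fascicle velocity, m/s, positive = lengthening.
#' @param F_CE contractile-element force, N.
#' @param mass muscle mass, kg (see \code{\link{muscle_mass}}).
#' @param params \code{mtu_params}.
#' @param S aerobic scaling factor (default 1.5, walking).
#' @return data.frame with columns \code{h_A}, \code{h_M}, \code{h_SL},
#'   \code{w_CE} and \code{total}, all W/kg.
#' @export
umberger_rate <- function(u, a, l_CE, v_CE, F_CE, mass, params, S = 1.5) {
  stopifnot(all(u >= 0), all(u <= 1), all(a >= 0), all(a <= 1), mass > 0)
  k <- .umberger_constants()
  A <- ifelse(u > a, u, (u + a) / 2)
  fl <- force_length(l_CE, params)
  ft <- params$FT
  h_am_full <- (k$h_am_coef[["per_ft"]] * ft + k$h_am_coef[["base"]])
  # length dependence above optimal length: 40% length-independent,
  # 60% scaled by the isometric force-length factor
  len_fac <- ifelse(l_CE > params$l_opt, 0.4 + 0.6 * fl, 1)
  h_am <- h_am_full * len_fac * A^0.6 * S
  # split for reporting: activation heat ~ the fiber-type-independent floor
  h_A <- (k$h_am_coef[["base"]] / h_am_full) * h_am
  h_M <- h_am - h_A
  vbar <- v_CE / params$l_opt           # l_opt per second
  shortening <- vbar < 0
  alpha_s <- k$alpha_s_st * (1 - ft) + k$alpha_s_ft * ft
  alpha_l <- k$alpha_l_factor * k$alpha_s_st
  h_SL <- ifelse(shortening,
                 alpha_s * (-vbar) * A^2,
                 alpha_l * vbar * fl * A) * S
  h_SL <- h_SL * ifelse(l_CE > params$l_opt, fl, 1)
  w_CE <- pmax(0, -F_CE * v_CE) / mass
  zero <- (u == 0) & (a == 0)
  h_A[zero] <- 0; h_M[zero] <- 0; h_SL[zero] <- 0
  data.frame(h_A = h_A, h_M = h_M, h_SL = h_SL, w_CE = w_CE,
             total = h_A + h_M + h_SL + w_CE)
}

#' Muscle mass from strength and optimal length
#'
#' \eqn{M_i = \rho F_{max} l_{opt} / \sigma} with density
#' \eqn{\rho = 1059.7} kg/m^3 and specific tension \eqn{\sigma = 0.25} MPa.
#'
#' @param params \code{mtu_params}.
#' @return mass, kg.
#' @export
muscle_mass <- function(params) {
  rho <- 1059.7          # kg m^-3
  sigma <- 0.25e6        # Pa
  rho * params$F_max * params$l_opt / sigma
}

#' Whole-body metabolic cost and cost of transport
#'
#' Integrated muscle energies (one leg's muscles) are doubled for bilateral
#' symmetry; the remaining body mass is billed at the basal rate. The
#' metabolic cost of transport is gross cost normalized by body weight
#' times distance:
#' \deqn{C_{met} = 2\sum_i M_i E_i + (M - 2\sum_i M_i)\,\dot E_{bas} T,
#'   \qquad MCOT = \frac{C_{met}}{M g v T}.}
#'
#' @param muscle_energies named numeric vector, J per muscle over the
#'   window (one leg).
#' @param muscle_masses named numeric vector, kg per muscle (one leg).
#' @param scalars list with \code{body_mass} (kg), \code{walking_speed}
#'   (m/s) and \code{basal_rate} (W/kg).
#' @param T time window, s (one gait cycle).
#' @param gross logical; \code{FALSE} subtracts the basal-only cost
#'   (net cost of transport). Default \code{TRUE}.
#' @return list with \code{C_met} (J) and \code{mcot} (dimensionless).
#' @export
whole_body_cost <- function(muscle_energies, muscle_masses, scalars, T,
                            gross = TRUE) {
  g <- 9.81
  stopifnot(T > 0, length(muscle_energies) == length(muscle_masses))
  m_mus <- 2 * sum(muscle_masses)      # both legs
  if (m_mus >= scalars$body_mass)
    stop("summed muscle mass exceeds body mass")
  C <- 2 * sum(muscle_energies) +
    (scalars$body_mass - m_mus) * scalars$basal_rate * T
  if (!gross) C <- C - scalars$body_mass * scalars$basal_rate * T
  list(C_met = C,
       mcot = C / (scalars$body_mass * g * scalars$walking_speed * T))
}

#' Gait events constructor
#'
#' Times of ipsilateral and contralateral heel strikes and toe-offs; the
#' ipsilateral heel strikes bound the cycle. Within one cycle the phases
#' tile it as: first double support (heel strike to contralateral toe-off),
#' single support (to contralateral heel strike), second double support
#' (to ipsilateral toe-off), swing (to the next heel strike).
#'
#' @param heel_strike ipsilateral heel-strike times, s (>= 2, increasing).
#' @param toe_off ipsilateral toe-off times, s.
#' @param contra_heel_strike,contra_toe_off contralateral event times, s.
#' @return object of class \code{gait_events}.
#' @export
gait_events <- function(heel_strike, toe_off, contra_heel_strike,
                        contra_toe_off) {
  stopifnot(length(heel_strike) >= 2, all(diff(heel_strike) > 0),
            all(diff(toe_off) > 0))
  structure(list(heel_strike = heel_strike, toe_off = toe_off,
                 contra_heel_strike = contra_heel_strike,
                 contra_toe_off = contra_toe_off),
            class = "gait_events")
}

#' Metabolic phase fractions over the gait cycle
#'
#' Integrates a summed metabolic rate series over the double-support,
#' single-support and swing portions of one cycle (as viewed from one leg;
#' both double-support windows pool into one fraction) and normalizes by
#' the cycle total.
#'
#' @param rate total metabolic rate series, W (vectorized over time).
#' @param time time base, s, spanning one cycle.
#' @param events \code{gait_events} whose first cycle covers \code{time}.
#' @return named numeric vector \code{c(double_support, single_support,
#'   swing)} summing to 1.
#' @export
phase_fractions <- function(rate, time, events) {
  hs1 <- events$heel_strike[1]; hs2 <- events$heel_strike[2]
  cto <- events$contra_toe_off[events$contra_toe_off > hs1 &
                                 events$contra_toe_off < hs2][1]
  chs <- events$contra_heel_strike[events$contra_heel_strike > hs1 &
                                     events$contra_heel_strike < hs2][1]
  ito <- events$toe_off[events$toe_off > hs1 & events$toe_off < hs2][1]
  if (any(is.na(c(cto, chs, ito))) || !(hs1 < cto && cto < chs &&
                                        chs < ito && ito < hs2))
    stop("gait events do not tile the cycle")
  seg_int <- function(lo, hi) {
    keep <- time >= lo & time <= hi
    if (sum(keep) < 2) return(0)
    sum(diff(time[keep]) * (rate[keep][-1] + rate[keep][-sum(keep)]) / 2)
  }
  ds <- seg_int(hs1, cto) + seg_int(chs, ito)
  ss <- seg_int(cto, chs)
  sw <- seg_int(ito, hs2)
  tot <- ds + ss + sw
  if (tot <= 0) stop("zero total metabolic rate over the cycle")
  c(double_support = ds / tot, single_support = ss / tot, swing = sw / tot)
}

#' Efficiency of positive muscle work
#'
#' Total positive contractile-element work over the cycle divided by the
#' total muscle metabolic energy (muscle-only denominator; basal metabolism
#' of non-muscle tissue is excluded).
#'
#' @param traces named list of \code{mtu_trace}.
#' @param rates named list of per-muscle rate data.frames from
#'   \code{\link{umberger_rate}} on the same grids.
#' @param masses named numeric vector, kg.
#' @return dimensionless efficiency in [0, 1].
#' @export
positive_work_efficiency <- function(traces, rates, masses) {
  wpos <- 0; etot <- 0
  for (m in names(traces)) {
    tr <- traces[[m]]
    dt <- diff(tr$time)
    p <- pmax(0, -tr$F_CE * tr$v_CE)
    wpos <- wpos + sum(dt * (p[-1] + p[-length(p)]) / 2)
    r <- rates[[m]]$total * masses[[m]]
    etot <- etot + sum(dt * (r[-1] + r[-length(r)]) / 2)
  }
  if (etot <= 0) stop("zero metabolic energy over the cycle")
  wpos / etot
}

#' Full energetics report for a simulated cycle
#'
#' Convenience wrapper: per-muscle masses, rate components, cycle energies,
#' whole-body cost, MCOT, phase fractions and positive-work efficiency.
#'
#' @param traces named list of \code{mtu_trace}.
#' @param drives named list of drive series (u) on the trace grid.
#' @param param_set named list of \code{mtu_params}.
#' @param scalars subject scalars (list: body_mass, walking_speed,
#'   basal_rate).
#' @param events \code{gait_events}.
#' @param S aerobic scaling factor.
#' @return list of class \code{energetics_report}.
#' @export
energetics_report <- function(traces, drives, param_set, scalars, events,
                              S = 1.5) {
  muscles <- names(traces)
  masses <- vapply(param_set[muscles], muscle_mass, numeric(1))
  rates <- list(); energies <- numeric(length(muscles))
  names(energies) <- muscles
  total_rate <- NULL
  for (m in muscles) {
    tr <- traces[[m]]
    r <- umberger_rate(drives[[m]], tr$a, tr$l_CE, tr$v_CE, tr$F_CE,
                       masses[[m]], param_set[[m]], S = S)
    rates[[m]] <- r
    dt <- diff(tr$time)
    energies[[m]] <- sum(dt * (r$total[-1] + r$total[-nrow(r)]) / 2) *
      masses[[m]]
    w <- r$total * masses[[m]]
    total_rate <- if (is.null(total_rate)) w else total_rate + w
  }
  T <- diff(range(traces[[1]]$time)) +
    traces[[1]]$time[2] - traces[[1]]$time[1]
  cost <- whole_body_cost(energies, masses, scalars, T)
  if (all(total_rate == 0)) {
    # fully silent muscle set: phase split and efficiency are undefined
    pf <- c(double_support = NA_real_, single_support = NA_real_,
            swing = NA_real_)
    eff <- NA_real_
  } else {
    pf <- phase_fractions(total_rate, traces[[1]]$time, events)
    eff <- positive_work_efficiency(traces, rates, masses)
  }
  structure(list(masses = masses, rates = rates, energies = energies,
                 C_met = cost$C_met, mcot = cost$mcot,
                 phase_fractions = pf, positive_work_efficiency = eff,
                 T = T),
            class = "energetics_report")
}

#' @export
print.energetics_report <- function(x, ...) {
  cat(sprintf("Energetics over T = %.3f s: C_met = %.1f J, MCOT = %.3f\n",
              x$T, x$C_met, x$mcot))
  cat(sprintf("  phases (ds/ss/sw): %.2f / %.2f / %.2f | efficiency %.3f\n",
              x$phase_fractions[1], x$phase_fractions[2],
              x$phase_fractions[3], x$positive_work_efficiency))
  invisible(x)
}
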