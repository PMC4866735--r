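# Choosing one solution from the Pareto front via the per-muscle
# metabolic budget: polynomial budget curves, the normalized vastus budget
# shift, and the cutoff selection rule.

#' Fit per-muscle metabolic-budget curves along the front
#'
#' For each muscle, least-squares fit of a fifth-order polynomial to its
#' fractional metabolic cost (both legs, basal included) as a function of
#' the mean kinetic coefficient of determination along the front. With
#' fewer than 12 solutions the degree is reduced (with a warning) to keep
#' the fit determined.
#'
#' @param front \code{pareto_front} or list of solutions each carrying
#'   \code{mean_R2} and \code{fractions}.
#' @param degree polynomial degree (default 5).
#' @return named list of \code{budget_curve} objects: \code{muscle},
#'   \code{coef} (raw polynomial, increasing powers), \code{domain}
#'   (observed R2 span), \code{degree}.
#' @export
budget_curves_fit <- function(front, degree = 5) {
  sols <- if (inherits(front, "pareto_front")) front$solutions else front
  sols <- Filter(function(s) !is.null(s$fractions), sols)
  r2 <- vapply(sols, `[[`, numeric(1), "mean_R2")
  if (length(unique(r2)) < 2) stop("fewer than 2 distinct R2 values")
  if (length(sols) < degree + 7 && length(sols) < 12) {
    degree <- max(1, min(degree, length(unique(r2)) - 1))
    warning("small front: polynomial degree reduced to ", degree)
  }
  muscles <- names(sols[[1]]$fractions)
  lapply(stats::setNames(muscles, muscles), function(m) {
    f <- vapply(sols, function(s) s$fractions[[m]], numeric(1))
    fit <- stats::lm(f ~ stats::poly(r2, degree, raw = TRUE))
    co <- stats::coef(fit)
    co[is.na(co)] <- 0
    structure(list(muscle = m, coef = unname(co),
                   domain = range(r2), degree = degree),
              class = "budget_curve")
  })
}

#' Evaluate a budget curve
#'
#' @param curve \code{budget_curve}.
#' @param r2 mean R2 values (vectorized).
#' @return fitted fractional metabolic cost.
#' @export
budget_curve_eval <- function(curve, r2) {
  drop(outer(r2, seq_along(curve$coef) - 1, `^`) %*% curve$coef)
}

#' Normalized vastus budget shift along the front
#'
#' Relative change of the fitted vastus fraction between the front's worst
#' and best kinetic fits:
#' \deqn{\Delta_{VAS}(R^2) = \frac{F_{VAS}(R^2) - F_{VAS}(R^2_{min})}
#'   {F_{VAS}(R^2_{max}) - F_{VAS}(R^2_{min})}.}
#' Evaluated on the fitted polynomial, not the raw fractions.
#'
#' @param curve \code{budget_curve} for the vastus group.
#' @param r2 mean R2 at which to evaluate (within the fitting domain).
#' @return dimensionless shift (0 at the domain minimum, 1 at the
#'   maximum).
#' @export
delta_vas <- function(curve, r2) {
  if (any(r2 < curve$domain[1] - 1e-9 | r2 > curve$domain[2] + 1e-9))
    stop("R2 outside the fitting domain")
  f_lo <- budget_curve_eval(curve, curve$domain[1])
  f_hi <- budget_curve_eval(curve, curve$domain[2])
  if (abs(f_hi - f_lo) < .Machine$double.eps * 100)
    stop("flat vastus budget (zero denominator)")
  (budget_curve_eval(curve, r2) - f_lo) / (f_hi - f_lo)
}

#' Choose the optimal solution from the front
#'
#' Returns the maximum-mean-R2 solution whose vastus budget shift is
#' strictly below the cutoff; among equals, lower metabolic cost wins.
#' The cutoff excludes the overfit tail of the front where one large
#' muscle group absorbs disproportionate metabolic energy for marginal
#' kinetic gains.
#'
#' @param front \code{pareto_front} or list of solutions.
#' @param curves output of \code{\link{budget_curves_fit}}; must contain a
#'   \code{VAS} curve.
#' @param cutoff the budget-shift cutoff (default 0.63).
#' @return the chosen solution (list) with \code{delta_vas} attached.
#' @export
choose_solution <- function(front, curves, cutoff = 0.63) {
  sols <- if (inherits(front, "pareto_front")) front$solutions else front
  sols <- Filter(function(s) !is.null(s$fractions), sols)
  if (length(sols) == 0) stop("empty front")
  if (!"VAS" %in% names(curves)) stop("no vastus budget curve")
  r2 <- vapply(sols, `[[`, numeric(1), "mean_R2")
  dv <- delta_vas(curves$VAS, r2)
  ok <- dv < cutoff
  if (!any(ok)) stop("no solution satisfies the budget cutoff")
  cand <- which(ok)
  best <- cand[order(-r2[cand],
                     vapply(sols[cand], `[[`, numeric(1), "C_met"))][1]
  out <- sols[[best]]
  out$delta_vas <- dv[best]
  out
}
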