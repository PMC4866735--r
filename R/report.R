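# End-to-end pipeline driver and the solution report: joint-moment
# agreement (R2, FMAE), energetics (MCOT, phase fractions, efficiency)
# and normalized muscle-state summaries.

#' Report a morphology's performance on a dataset
#'
#' Simulates the morphology over the dataset (two cycles, second scored)
#' and assembles moments, fit statistics, full energetics and normalized
#' muscle-state traces (\code{l_CE/l_opt}, \code{v_CE/v_max}).
#'
#' @param morph \code{morphology}.
#' @param dataset \code{gait_dataset}.
#' @param activations,drives activation-stage output (default: dataset
#'   ground truth).
#' @return list of class \code{solution_report}: \code{tau_mod},
#'   \code{R2}, \code{mean_R2}, \code{C_kin}, \code{fmae} (per joint over
#'   stance), \code{energetics} (an \code{energetics_report}),
#'   \code{muscle_state} (data.frame per muscle: normalized length and
#'   velocity).
#' @export
report_solution <- function(morph, dataset, activations = NULL,
                            drives = NULL) {
  if (is.null(activations)) activations <- dataset$truth$activations
  if (is.null(drives)) drives <- dataset$truth$drives
  muscles <- names(morph$F_max)
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
  fm <- vapply(setdiff(names(dataset$joint_moments), "time"),
               function(j) fmae(tau[[j]], dataset$joint_moments[[j]],
                                dataset$time, dataset$events),
               numeric(1))
  en <- energetics_report(traces, drives, params, dataset$scalars,
                          dataset$events)
  state <- do.call(rbind, lapply(muscles, function(m) {
    tr <- traces[[m]]
    data.frame(muscle = m, time = tr$time,
               l_norm = tr$l_CE / params[[m]]$l_opt,
               v_norm = tr$v_CE / params[[m]]$v_max)
  }))
  structure(list(tau_mod = tau, R2 = kin$R2, mean_R2 = kin$mean_R2,
                 C_kin = kin$C_kin, fmae = fm, energetics = en,
                 muscle_state = state, traces = traces),
            class = "solution_report")
}

#' @export
print.solution_report <- function(x, ...) {
  cat(sprintf("Joint-moment fit: mean R2 = %.3f (C_kin = %.4f)\n",
              x$mean_R2, x$C_kin))
  for (j in names(x$R2))
    cat(sprintf("  %-6s R2 = %.3f | stance FMAE = %.3f\n",
                j, x$R2[[j]], x$fmae[[j]]))
  print(x$energetics)
  invisible(x)
}

#' Run the full identification pipeline on a synthetic subject
#'
#' Chains the stages: synthetic dataset generation, (optionally) EMG drive
#' re-estimation, dual-objective identification, budget-curve fitting and
#' cutoff selection, and the final report of the chosen solution.
#'
#' @param seed master RNG seed.
#' @param ga \code{ga_config}.
#' @param muscles muscle subset (default all 12).
#' @param cutoff vastus budget-shift cutoff.
#' @param reestimate_drive re-run the Bayesian EMG stage on the synthetic
#'   EMG instead of using the true drives (slower; default FALSE).
#' @param verbose print search progress.
#' @return list: \code{dataset}, \code{front}, \code{curves},
#'   \code{chosen}, \code{report}.
#' @export
run_pipeline <- function(seed = 1, ga = ga_config("desk"),
                         muscles = default_muscle_table()$muscle,
                         cutoff = 0.63, reestimate_drive = FALSE,
                         verbose = FALSE) {
  ds <- synthetic_subject(seed = seed, muscles = muscles)
  activations <- ds$truth$activations
  drives <- ds$truth$drives
  if (reestimate_drive) {
    tab <- default_muscle_table()
    drives <- lapply(muscles, function(m) {
      d <- estimate_drive(pmin(ds$emg[[m]] / max(ds$emg[[m]]), 1))
      stats::approx(ds$emg_time, d, xout = ds$time, rule = 2)$y
    })
    names(drives) <- muscles
    activations <- lapply(muscles, function(m) {
      row <- tab[tab$muscle == m, ]
      activation_dynamics(drives[[m]], ds$time, tau_act = row$tau_act,
                          tau_deact = row$tau_deact)
    })
    names(activations) <- muscles
  }
  front <- run_identification(ds, ds$bounds, activations = activations,
                              drives = drives, ga = ga, seed = seed,
                              verbose = verbose)
  curves <- budget_curves_fit(front)
  chosen <- tryCatch(choose_solution(front, curves, cutoff = cutoff),
                     error = function(e) front$solutions[[1]])
  rep <- report_solution(chosen$morphology, ds,
                         activations = activations, drives = drives)
  list(dataset = ds, front = front, curves = curves, chosen = chosen,
       report = rep)
}
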