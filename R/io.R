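# Dataset-directory and parameter-file readers/writers. Time series go to
# CSV (portable, diffable), events/scalars/parameters to JSON; all units
# SI. The layout round-trips losslessly through write/read.

#' Write a gait dataset to a directory
#'
#' Layout: \code{timeseries.csv} (wide; time, joint angles \code{ang_*},
#' MTU lengths \code{lmtc_*}, moment arms \code{arm_<joint>_<muscle>},
#' torques \code{tau_*}), \code{emg.csv} (its own 1000 Hz clock),
#' \code{events.json}, \code{subject.json} and, when ground truth is
#' attached, \code{truth_params.json}.
#'
#' @param dataset \code{gait_dataset}.
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_gait_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts <- data.frame(time = dataset$time)
  for (j in names(dataset$joint_angles))
    ts[[paste0("ang_", j)]] <- dataset$joint_angles[[j]]
  for (m in names(dataset$mtu_lengths))
    ts[[paste0("lmtc_", m)]] <- dataset$mtu_lengths[[m]]
  for (j in names(dataset$moment_arms))
    for (m in names(dataset$moment_arms[[j]]))
      ts[[paste0("arm_", j, "_", m)]] <- dataset$moment_arms[[j]][[m]]
  if (!is.null(dataset$joint_moments))
    for (j in names(dataset$joint_moments))
      ts[[paste0("tau_", j)]] <- dataset$joint_moments[[j]]
  utils::write.csv(ts, file.path(dir, "timeseries.csv"),
                   row.names = FALSE)
  if (!is.null(dataset$emg)) {
    emg <- cbind(data.frame(time = dataset$emg_time), dataset$emg)
    utils::write.csv(emg, file.path(dir, "emg.csv"), row.names = FALSE)
  }
  ev <- dataset$events
  jsonlite::write_json(list(heel_strike = ev$heel_strike,
                            toe_off = ev$toe_off,
                            contra_heel_strike = ev$contra_heel_strike,
                            contra_toe_off = ev$contra_toe_off),
                       file.path(dir, "events.json"), digits = NA)
  jsonlite::write_json(unclass(dataset$scalars),
                       file.path(dir, "subject.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(dataset$truth))
    write_params(dataset$truth$morphology,
                 file.path(dir, "truth_params.json"))
  invisible(dir)
}

#' Read a gait dataset directory
#'
#' Validates the channel inventory (every muscle needs an MTU length and
#' every wired moment arm must be present) and reconstructs the dataset on
#' its two declared clocks (mechanics and EMG).
#'
#' @param dir dataset directory written by \code{\link{write_gait_dataset}}.
#' @return \code{gait_dataset} (without simulated ground-truth traces; the
#'   stored true morphology is reattached when present).
#' @export
read_gait_dataset <- function(dir) {
  ts <- utils::read.csv(file.path(dir, "timeseries.csv"))
  if (any(diff(ts$time) <= 0)) stop("non-monotone time in timeseries.csv")
  cols <- names(ts)
  joints <- sub("^ang_", "", grep("^ang_", cols, value = TRUE))
  muscles <- sub("^lmtc_", "", grep("^lmtc_", cols, value = TRUE))
  ja <- as.data.frame(ts[paste0("ang_", joints)])
  names(ja) <- joints
  ml <- as.data.frame(ts[paste0("lmtc_", muscles)])
  names(ml) <- muscles
  if (any(as.matrix(ml) <= 0)) stop("non-positive MTU length")
  arms <- list()
  wiring <- muscle_wiring()
  for (j in joints) {
    for (m in intersect(wiring[[j]], muscles)) {
      cn <- paste0("arm_", j, "_", m)
      if (!cn %in% cols)
        stop(sprintf("missing moment-arm channel %s", cn))
      arms[[j]][[m]] <- ts[[cn]]
    }
  }
  moments <- NULL
  tau_cols <- grep("^tau_", cols, value = TRUE)
  if (length(tau_cols)) {
    moments <- as.data.frame(ts[tau_cols])
    names(moments) <- sub("^tau_", "", tau_cols)
  }
  ev <- jsonlite::read_json(file.path(dir, "events.json"),
                            simplifyVector = TRUE)
  sc <- jsonlite::read_json(file.path(dir, "subject.json"),
                            simplifyVector = TRUE)
  scalars <- subject_scalars(body_mass = sc$body_mass, height = sc$height,
                             walking_speed = sc$walking_speed,
                             basal_rate = sc$basal_rate,
                             gait_cycle_duration = sc$gait_cycle_duration)
  out <- list(time = ts$time,
              period = scalars$gait_cycle_duration,
              joint_angles = ja, moment_arms = arms, mtu_lengths = ml,
              joint_moments = moments,
              events = gait_events(ev$heel_strike, ev$toe_off,
                                   ev$contra_heel_strike,
                                   ev$contra_toe_off),
              scalars = scalars, muscles = muscles)
  emg_path <- file.path(dir, "emg.csv")
  if (file.exists(emg_path)) {
    emg <- utils::read.csv(emg_path)
    out$emg_time <- emg$time
    out$emg <- emg[setdiff(names(emg), "time")]
  }
  tp <- file.path(dir, "truth_params.json")
  if (file.exists(tp)) out$truth <- list(morphology = read_params(tp))
  class(out) <- "gait_dataset"
  out
}

#' Write a morphology to JSON
#'
#' Per-muscle blocks (F_max, length scale, tendon constants) plus a
#' ligament block; lossless numeric round-trip.
#'
#' @param morph \code{morphology}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(morph, path) {
  muscles <- names(morph$F_max)
  blocks <- lapply(stats::setNames(muscles, muscles), function(m)
    list(F_max = morph$F_max[[m]], scale = morph$length_scale[[m]],
         K_sh = morph$K_sh[[m]], lambda_ref = morph$lambda_ref[[m]]))
  obj <- list(muscles = blocks)
  if (!is.null(morph$K_HFL))
    obj$hfl <- list(K_HFL = morph$K_HFL, theta0_HFL = morph$theta0_HFL)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a morphology from JSON
#'
#' Validates tendon constants against their physical ranges (K_sh in
#' [2, 5], lambda_ref in [0.02, 0.09]) and names the offending field on
#' failure.
#'
#' @param path JSON file from \code{\link{write_params}} (or a packaged
#'   participant fixture).
#' @param validate check tendon-constant ranges (default TRUE).
#' @return \code{morphology}.
#' @export
read_params <- function(path, validate = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- obj$muscles
  muscles <- names(blocks)
  get <- function(f) vapply(muscles, function(m)
    as.numeric(blocks[[m]][[f]]), numeric(1))
  out <- list(F_max = get("F_max"), length_scale = get("scale"),
              K_sh = get("K_sh"), lambda_ref = get("lambda_ref"),
              K_HFL = if (!is.null(obj$hfl)) obj$hfl$K_HFL else NULL,
              theta0_HFL = if (!is.null(obj$hfl)) obj$hfl$theta0_HFL
              else NULL)
  class(out) <- "morphology"
  if (validate) {
    for (m in muscles) {
      if (out$K_sh[[m]] < 2 || out$K_sh[[m]] > 5)
        stop(sprintf("K_sh out of range [2,5] for muscle %s", m))
      if (out$lambda_ref[[m]] < 0.02 || out$lambda_ref[[m]] > 0.09)
        stop(sprintf("lambda_ref out of range [0.02,0.09] for muscle %s",
                     m))
      if (out$F_max[[m]] <= 0)
        stop(sprintf("non-positive F_max for muscle %s", m))
    }
  }
  out
}

#' Load a packaged participant parameter fixture
#'
#' Chosen-optimal morphologies for five participants ship with the
#' package as JSON fixtures (the printed \code{l_sl, l_opt} scaling column
#' is stored verbatim in the \code{scale} slot).
#'
#' @param participant integer 1..5.
#' @return \code{morphology}.
#' @export
participant_params <- function(participant = 1) {
  stopifnot(participant %in% 1:5)
  path <- system.file("extdata",
                      sprintf("participant%d_params.json", participant),
                      package = "mtident")
  if (path == "") stop("fixture not found")
  read_params(path)
}
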