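# EMG processing: preprocessing, Bayesian drive (neural excitation)
# estimation, MVC normalization, first-order activation dynamics and
# gait-cycle segmentation/averaging.

#' Preprocess a raw EMG channel
#'
#' Removes the DC offset, clips the zero-mean signal beyond 5 standard
#' deviations (rare extreme values are usually artifacts and cannot be
#' modeled reliably), normalizes to the resulting maximum absolute value
#' and rectifies.
#'
#' @param raw numeric vector, signed raw EMG samples.
#' @param fs sampling rate, Hz (used only to enforce a minimum duration).
#' @return rectified series in [0, 1] with max exactly 1.
#' @export
preprocess_emg <- function(raw, fs = 1000) {
  stopifnot(length(raw) >= fs)  # at least 1 s
  if (any(!is.finite(raw))) stop("non-finite EMG samples")
  x <- raw - mean(raw)
  s <- stats::sd(x)
  if (s == 0) stop("constant EMG channel (zero variance after DC removal)")
  x <- pmin(pmax(x, -5 * s), 5 * s)
  x <- x / max(abs(x))
  abs(x)
}

#' Configuration of the Bayesian drive filter
#'
#' The latent drive lives on a uniform grid of levels in
#' [\code{floor_epsilon}, 1]. Per sample the prior is propagated by a
#' three-point diffusion kernel with per-side neighbor weight
#' \code{alpha / 2} (the discrete analogue of Brownian drift at rate
#' \code{alpha}) plus an additive uniform jump mass \code{beta}; the
#' additive mass also prevents absorbing states. The measurement update
#' multiplies by the exponential observation likelihood
#' \eqn{P(emg|x) = e^{-emg/x}/x}.
#'
#' @param alpha diffusion rate per sample (default 0.5).
#' @param beta jump/floor mass per sample (default 5e-31).
#' @param grid_size number of latent levels (default 100, >= 32).
#' @param floor_epsilon smallest latent level (default 1e-3).
#' @return list of class \code{sanger_config}.
#' @export
sanger_config <- function(alpha = 0.5, beta = 5e-31, grid_size = 100,
                          floor_epsilon = 1e-3) {
  stopifnot(alpha >= 0, beta >= 0, grid_size >= 32,
            floor_epsilon > 0, floor_epsilon < 1)
  structure(list(alpha = alpha, beta = beta, grid_size = grid_size,
                 floor_epsilon = floor_epsilon),
            class = "sanger_config")
}

#' Estimate the neural drive from rectified EMG
#'
#' Recursive Bayesian (grid) filter for the jump-diffusion drive model with
#' exponential observation law; returns the maximum a posteriori drive per
#' sample. Compared with bandpass envelopes the estimate turns on/off more
#' sharply and lags by a few tens of milliseconds, which is the behavior
#' that lets downstream muscle force build up consistently with observed
#' joint torques.
#'
#' @param emg_rect rectified, normalized EMG (values >= 0).
#' @param cfg \code{sanger_config}.
#' @return numeric vector of MAP drive estimates in
#'   [\code{floor_epsilon}, 1].
#' @export
estimate_drive <- function(emg_rect, cfg = sanger_config()) {
  if (any(!is.finite(emg_rect))) stop("non-finite samples")
  stopifnot(all(emg_rect >= 0))
  G <- cfg$grid_size
  grid <- seq(cfg$floor_epsilon, 1, length.out = G)
  p <- rep(1 / G, G)
  # grid-consistent diffusion: the per-sample variance in drive units is
  # alpha/(100^2) regardless of grid size, applied as one or more
  # three-point convolution passes (reference grid = 100 levels)
  v_cells <- cfg$alpha * (G / 100)^2
  npass <- max(1L, ceiling(v_cells / 0.5))
  wside <- v_cells / npass / 2
  wkeep <- 1 - 2 * wside
  out <- numeric(length(emg_rect))
  inv_grid <- 1 / grid
  for (t in seq_along(emg_rect)) {
    # diffusion (reflecting boundaries) + additive jump mass
    for (pass in seq_len(npass))
      p <- wkeep * p +
        wside * c(p[1], p[-G]) +
        wside * c(p[-1], p[G])
    p <- p + cfg$beta / G + 1e-300
    # measurement update: exponential likelihood
    p <- p * exp(-emg_rect[t] * inv_grid) * inv_grid
    p <- p / sum(p)
    out[t] <- grid[which.max(p)]
  }
  out
}

#' Normalize a drive trace by its maximal-voluntary-contraction value
#'
#' The MVC value is the mean drive over the largest contiguous
#' suprathreshold burst of duration at least \code{min_burst} seconds in
#' the MVC trial. If the normalized walking drive then exceeds 1 anywhere,
#' it is renormalized by its own maximum so the output never exceeds 1.
#'
#' @param drive drive trace from a walking trial.
#' @param mvc_drive drive trace from the MVC trial.
#' @param fs sampling rate of both traces, Hz.
#' @param threshold burst detection threshold on the MVC drive.
#' @param min_burst minimal qualifying burst duration, s (default 1).
#' @return list: \code{drive} (normalized, max <= 1), \code{mvc_value},
#'   \code{renormalized} (logical).
#' @export
mvc_normalize <- function(drive, mvc_drive, fs = 1000, threshold = 0.1,
                          min_burst = 1) {
  above <- mvc_drive > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= min_burst * fs
  if (!any(ok)) stop("no suprathreshold burst of at least 1 s in MVC trial")
  # largest burst by mean magnitude
  vals <- vapply(which(ok), function(i)
    mean(mvc_drive[starts[i]:ends[i]]), numeric(1))
  mvc_value <- max(vals)
  out <- drive / mvc_value
  renorm <- FALSE
  if (max(out) > 1) { out <- out / max(out); renorm <- TRUE }
  list(drive = out, mvc_value = mvc_value, renormalized = renorm)
}

#' First-order activation dynamics
#'
#' Maps neural drive to muscle activation with asymmetric rise/decay:
#' \deqn{\dot a = (x-a)\,(x/\tau_{act} + (1-x)/\tau_{deact}) \ (x \ge a),
#'   \qquad \dot a = (x-a)/\tau_{deact} \ (x < a).}
#' Drive values below \code{threshold} are zeroed before integration (noise
#' floor). Integration is an exponential (exact for piecewise-constant
#' drive) update, unconditionally stable for any time constants.
#'
#' @param drive numeric vector in [0,1].
#' @param time time base, s, strictly increasing.
#' @param tau_act,tau_deact activation/deactivation time constants, s,
#'   with \code{tau_act <= tau_deact}.
#' @param threshold noise-floor cutoff on the drive (default 0.05).
#' @param a0 initial activation; default the (thresholded) initial drive.
#' @return activation vector in [0,1] on the same time base.
#' @export
activation_dynamics <- function(drive, time, tau_act = 0.012,
                                tau_deact = 0.048, threshold = 0.05,
                                a0 = NULL) {
  stopifnot(all(drive >= 0), all(drive <= 1), tau_act > 0,
            tau_act <= tau_deact, length(drive) == length(time))
  if (any(diff(time) <= 0)) stop("non-monotone time base")
  x <- ifelse(drive < threshold, 0, drive)
  a <- numeric(length(x))
  a[1] <- if (is.null(a0)) x[1] else a0
  for (i in 2:length(x)) {
    dt <- time[i] - time[i - 1]
    xi <- x[i]
    k <- if (xi >= a[i - 1]) xi / tau_act + (1 - xi) / tau_deact
         else 1 / tau_deact
    a[i] <- xi + (a[i - 1] - xi) * exp(-k * dt)
  }
  pmin(pmax(a, 0), 1)
}

#' Segment a trace into gait cycles and average
#'
#' Splits a trace at ipsilateral heel strikes, resamples each cycle to a
#' common percent-gait-cycle grid, discards outlier cycles by a robust
#' median-distance rule, and averages the rest. The outlier rule flags a
#' cycle when its RMS distance to the pointwise median cycle exceeds
#' \code{k_mad} times the median absolute deviation (scaled) of all cycles'
#' distances, which discards on the order of 5-10 percent of cycles on
#' noisy input.
#'
#' @param value numeric trace.
#' @param time time base, s.
#' @param heel_strikes ipsilateral heel-strike times bounding the cycles
#'   (>= 4 values for >= 3 cycles).
#' @param n_points points of the percent-GC grid (default 101).
#' @param k_mad robust rejection multiplier (default 3.5).
#' @return list: \code{pct} (0..100), \code{mean}, \code{sd},
#'   \code{cycles} (matrix, kept cycles in rows), \code{kept},
#'   \code{discarded} (integer indices).
#' @export
segment_and_average <- function(value, time, heel_strikes, n_points = 101,
                                k_mad = 3.5) {
  hs <- sort(heel_strikes)
  if (length(hs) < 4) stop("need at least 3 complete cycles")
  if (hs[1] < time[1] || hs[length(hs)] > time[length(time)] + 1e-9)
    stop("events outside trace span")
  pct <- seq(0, 100, length.out = n_points)
  n_cyc <- length(hs) - 1
  cyc <- matrix(NA_real_, n_cyc, n_points)
  for (i in seq_len(n_cyc)) {
    tt <- seq(hs[i], hs[i + 1], length.out = n_points)
    cyc[i, ] <- stats::approx(time, value, xout = tt, rule = 2)$y
  }
  med <- apply(cyc, 2, stats::median)
  d <- sqrt(rowMeans((cyc - matrix(med, n_cyc, n_points, byrow = TRUE))^2))
  mad_d <- stats::mad(d)
  # absolute floor guards the degenerate identical-cycles case against
  # interpolation round-off
  thr <- stats::median(d) + k_mad * mad_d +
    1e-9 * max(diff(range(cyc)), 1)
  keep <- d <= thr
  if (!any(keep)) keep <- rep(TRUE, n_cyc)
  kept <- cyc[keep, , drop = FALSE]
  list(pct = pct,
       mean = colMeans(kept),
       sd = apply(kept, 2, stats::sd),
       cycles = kept,
       kept = which(keep),
       discarded = which(!keep))
}
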