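# Controlled elitist nondominated-sorting genetic search (NSGA-II style)
# for the dual-objective (metabolic, kinetic) identification, plus the
# dominance utilities used to validate its output.

#' Pareto dominance between objective rows
#'
#' Row i dominates row j when it is no worse in both objectives and
#' strictly better in at least one (minimization).
#'
#' @param obj numeric matrix, one row per solution, columns = objectives.
#' @return logical vector: TRUE for rows not dominated by any other row.
#' @export
nondominated <- function(obj) {
  n <- nrow(obj)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && all(obj[j, ] <= obj[i, ]) && any(obj[j, ] < obj[i, ])) {
        keep[i] <- FALSE
        break
      }
    }
  }
  keep
}

# fast-enough nondominated sorting into ranks (2 objectives, small pops)
.nds_ranks <- function(obj) {
  n <- nrow(obj)
  rank <- rep(NA_integer_, n)
  remaining <- seq_len(n)
  r <- 0L
  while (length(remaining) > 0) {
    r <- r + 1L
    nd <- nondominated(obj[remaining, , drop = FALSE])
    rank[remaining[nd]] <- r
    remaining <- remaining[!nd]
  }
  rank
}

.crowding <- function(obj) {
  n <- nrow(obj)
  d <- numeric(n)
  for (k in seq_len(ncol(obj))) {
    o <- order(obj[, k])
    rng <- obj[o[n], k] - obj[o[1], k]
    d[o[c(1, n)]] <- Inf
    if (n > 2 && rng > 0)
      d[o[2:(n - 1)]] <- d[o[2:(n - 1)]] +
        (obj[o[3:n], k] - obj[o[1:(n - 2)], k]) / rng
  }
  d
}

# simulated binary crossover (SBX), eta = 15
.sbx <- function(p1, p2, lower, upper, eta = 15) {
  u <- stats::runif(length(p1))
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  list(pmin(pmax(c1, lower), upper), pmin(pmax(c2, lower), upper))
}

# bounded Gaussian mutation: per-gene probability, sd = frac of range,
# resampled into bounds by reflection
.mutate <- function(x, lower, upper, prob, sd_frac) {
  hit <- stats::runif(length(x)) < prob
  if (any(hit)) {
    rng <- upper - lower
    x[hit] <- x[hit] + stats::rnorm(sum(hit), 0, sd_frac * rng[hit])
    over <- x > upper; x[over] <- upper[over] - (x[over] - upper[over]) %% rng[over]
    under <- x < lower; x[under] <- lower[under] + (lower[under] - x[under]) %% rng[under]
    x <- pmin(pmax(x, lower), upper)
  }
  x
}

#' Dual-objective morphology identification
#'
#' Searches the bounded morphology space for the Pareto front of
#' (metabolic cost, kinetic cost) with an elitist NSGA-II-style genetic
#' algorithm: full-space uniform initialization (no seeding), binary
#' tournament selection on (rank, crowding distance), simulated binary
#' crossover, bounded Gaussian mutation (sd = 2 percent of each
#' parameter's range by default), and (mu + lambda) survival by
#' nondominated sorting. Fully reproducible given \code{seed}.
#'
#' @param dataset \code{gait_dataset}.
#' @param bounds \code{mt_bounds}.
#' @param activations,drives frozen activation-stage output (default: the
#'   dataset's ground truth; the activation stage is computed once per
#'   dataset and not revisited inside the search).
#' @param ga \code{ga_config}.
#' @param seed integer RNG seed.
#' @param verbose print per-generation front statistics.
#' @return list of class \code{pareto_front}: \code{solutions} (list of
#'   pareto solutions sorted by increasing \code{C_kin}; each carries
#'   \code{vector}, \code{morphology}, \code{C_met}, \code{mcot},
#'   \code{C_kin}, \code{mean_R2}, \code{R2}, \code{fractions}),
#'   \code{objectives} (matrix), \code{history} (per-generation summary),
#'   \code{ga}, \code{seed}.
#' @export
run_identification <- function(dataset, bounds, activations = NULL,
                               drives = NULL, ga = ga_config("desk"),
                               seed = 1, verbose = FALSE) {
  set.seed(seed)
  if (is.null(activations)) activations <- dataset$truth$activations
  if (is.null(drives)) drives <- dataset$truth$drives
  lower <- bounds$lower; upper <- bounds$upper
  npar <- length(lower)
  if (any(lower > upper)) stop("empty feasible region")
  N <- ga$pop_size
  evalf <- function(x) .eval_core(x, dataset, activations, drives,
                                  bounds, details = TRUE)
  pop <- matrix(stats::runif(N * npar, rep(lower, each = N),
                             rep(upper, each = N)), nrow = N)
  evals <- apply(pop, 1, evalf)
  obj <- t(vapply(evals, function(e) e$obj, numeric(2)))
  history <- data.frame()
  for (gen in seq_len(ga$generations)) {
    rank <- .nds_ranks(obj)
    crowd <- numeric(N)
    for (r in unique(rank)) {
      idx <- which(rank == r)
      crowd[idx] <- .crowding(obj[idx, , drop = FALSE])
    }
    tournament <- function() {
      i <- sample.int(N, 2)
      if (rank[i[1]] < rank[i[2]]) i[1]
      else if (rank[i[2]] < rank[i[1]]) i[2]
      else if (crowd[i[1]] >= crowd[i[2]]) i[1] else i[2]
    }
    children <- matrix(NA_real_, N, npar)
    k <- 1
    while (k <= N) {
      p1 <- pop[tournament(), ]; p2 <- pop[tournament(), ]
      if (stats::runif(1) < ga$crossover_fraction) {
        cc <- .sbx(p1, p2, lower, upper)
      } else cc <- list(p1, p2)
      children[k, ] <- .mutate(cc[[1]], lower, upper,
                               ga$mutation_prob, ga$mutation_sd_frac)
      if (k + 1 <= N)
        children[k + 1, ] <- .mutate(cc[[2]], lower, upper,
                                     ga$mutation_prob, ga$mutation_sd_frac)
      k <- k + 2
    }
    cevals <- apply(children, 1, evalf)
    cobj <- t(vapply(cevals, function(e) e$obj, numeric(2)))
    allpop <- rbind(pop, children)
    allobj <- rbind(obj, cobj)
    allev <- c(evals, cevals)
    arank <- .nds_ranks(allobj)
    sel <- integer(0)
    for (r in sort(unique(arank))) {
      idx <- which(arank == r)
      if (length(sel) + length(idx) <= N) {
        sel <- c(sel, idx)
      } else {
        cd <- .crowding(allobj[idx, , drop = FALSE])
        sel <- c(sel, idx[order(cd, decreasing = TRUE)][
          seq_len(N - length(sel))])
        break
      }
    }
    pop <- allpop[sel, , drop = FALSE]
    obj <- allobj[sel, , drop = FALSE]
    evals <- allev[sel]
    if (verbose)
      message(sprintf("gen %3d | best C_kin %.4f | best C_met %.1f J | front %d",
                      gen, min(obj[, 2]), min(obj[, 1]),
                      sum(nondominated(obj))))
    history <- rbind(history,
                     data.frame(generation = gen,
                                best_C_kin = min(obj[, 2]),
                                best_C_met = min(obj[, 1]),
                                front_size = sum(nondominated(obj))))
  }
  nd <- which(nondominated(obj))
  # deduplicate identical objective pairs
  nd <- nd[!duplicated(round(obj[nd, , drop = FALSE], 12))]
  ord <- nd[order(obj[nd, 2])]
  solutions <- lapply(ord, function(i) {
    r <- evals[[i]]$res
    list(vector = pop[i, ],
         morphology = unpack_morphology(pop[i, ], bounds$muscles,
                                        bounds$has_hfl),
         C_met = r$C_met, mcot = r$mcot, C_kin = r$C_kin,
         mean_R2 = r$mean_R2, R2 = r$R2, fractions = r$fractions,
         failed = r$failed)
  })
  structure(list(solutions = solutions,
                 objectives = obj[ord, , drop = FALSE],
                 history = history, ga = ga, seed = seed,
                 bounds = bounds),
            class = "pareto_front")
}

#' @export
print.pareto_front <- function(x, ...) {
  n <- length(x$solutions)
  ck <- vapply(x$solutions, `[[`, numeric(1), "C_kin")
  cm <- vapply(x$solutions, `[[`, numeric(1), "C_met")
  cat(sprintf("Pareto front: %d solutions | C_kin %.4f..%.4f | C_met %.1f..%.1f J\n",
              n, min(ck), max(ck), min(cm), max(cm)))
  invisible(x)
}

#' Hypervolume of a 2-objective front
#'
#' Area dominated by the front relative to a reference point
#' (minimization both objectives). Used as a search-progress diagnostic.
#'
#' @param obj matrix of objective rows.
#' @param ref reference point (both coordinates above the front).
#' @return scalar area.
#' @export
hypervolume2d <- function(obj, ref) {
  nd <- obj[nondominated(obj), , drop = FALSE]
  nd <- nd[nd[, 1] <= ref[1] & nd[, 2] <= ref[2], , drop = FALSE]
  if (nrow(nd) == 0) return(0)
  nd <- nd[order(nd[, 1]), , drop = FALSE]
  hv <- 0
  prev_y <- ref[2]
  for (i in seq_len(nrow(nd))) {
    hv <- hv + (ref[1] - nd[i, 1]) * (prev_y - nd[i, 2])
    prev_y <- nd[i, 2]
  }
  hv
}
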