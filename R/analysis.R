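# Trajectory metrics, regime classification, ensemble statistics, phase
# diagrams, and the analytic-oracle validation suite.

#' Fraction of recorded time the two carboxysomes are within the
#' self-association range
#'
#' @param traj an `mcd_trajectory` with exactly two carboxysomes.
#' @param params a valid `mcd_params` object (supplies `self_range`).
#' @return Fraction in `[0, 1]` of samples with center-center distance at or
#'   below `springs.self_range`.
#' @export
clustered_fraction <- function(traj, params) {
  if (traj$n_carboxysomes != 2)
    stop(sprintf("clustered_fraction requires exactly 2 carboxysomes (got %d)",
                 traj$n_carboxysomes), call. = FALSE)
  if (length(traj$time) < 2) stop("trajectory needs at least 2 samples", call. = FALSE)
  d_um <- sqrt((traj$x[, 1] - traj$x[, 2])^2 + (traj$y[, 1] - traj$y[, 2])^2)
  mean(d_um * 1000 <= params$springs$self_range)
}

.diameter_brute <- function(xy) {
  n <- nrow(xy)
  if (n < 2) return(0)
  max(stats::dist(xy))
}

.diameter_hull <- function(xy) {
  n <- nrow(xy)
  if (n < 4) return(.diameter_brute(xy))
  h <- tryCatch(grDevices::chull(xy[, 1], xy[, 2]), error = function(e) NULL)
  if (is.null(h) || length(h) < 2) return(.diameter_brute(xy))
  .diameter_brute(xy[h, , drop = FALSE])
}

#' Movement range of a trajectory
#'
#' The movement range of one carboxysome is the maximum Euclidean distance
#' between any two recorded points of its path; the trajectory's range is
#' the maximum over carboxysomes. The default fast path takes the diameter
#' of the convex hull of the samples (the diameter of a point set is
#' attained on its hull), which agrees exactly with the `O(n^2)` brute-force
#' reference.
#'
#' @param traj an `mcd_trajectory`.
#' @param method `"hull"` (fast path, default) or `"brute"` (all-pairs
#'   reference).
#' @param per_carboxysome return the per-carboxysome vector instead of the
#'   maximum?
#' @return Movement range in um.
#' @export
movement_range <- function(traj, method = c("hull", "brute"),
                           per_carboxysome = FALSE) {
  method <- match.arg(method)
  if (length(traj$time) < 1) stop("empty trajectory", call. = FALSE)
  fn <- if (method == "hull") .diameter_hull else .diameter_brute
  rng <- vapply(seq_len(traj$n_carboxysomes), function(c) {
    fn(cbind(traj$x[, c], traj$y[, c]))
  }, numeric(1))
  if (per_carboxysome) rng else max(rng)
}

.regime_levels <- c("clustered_diffuse", "clustered_positioned",
                    "partitioned_positioned", "partitioned_diffuse")
.regime3_levels <- c("clustered_diffuse", "clustered_positioned",
                     "partitioned_positioned")

#' Classify a trajectory into a mobility regime
#'
#' A pair of carboxysomes is *clustered* if it spends more than
#' `clustered_time_fraction` (default 90%) of recorded time within the
#' self-association range, and *positioned* if its movement range is below
#' `positioned_range_fraction` (default 0.25) times the nucleoid length.
#' The four logical combinations map to regimes `clustered_diffuse`,
#' `clustered_positioned`, `partitioned_positioned`, and
#' `partitioned_diffuse`; for the three-regime phase map
#' (`regime3`), the rare partitioned-but-wandering cell is folded into
#' `partitioned_positioned`, preserving the raw four-way label alongside.
#'
#' @param traj an `mcd_trajectory` with two carboxysomes.
#' @param params a valid `mcd_params` object.
#' @return An `mcd_classification`: list with `clustered_fraction`,
#'   `movement_range_um`, logicals `clustered` and `positioned`, `regime`
#'   (four-way) and `regime3` (three-regime fold).
#' @export
classify_trajectory <- function(traj, params) {
  cf <- clustered_fraction(traj, params)
  mr <- movement_range(traj)
  clustered <- cf > params$classify$clustered_time_fraction
  positioned <- mr < params$classify$positioned_range_fraction *
    params$geometry$nucleoid_length
  regime <- if (clustered && positioned) "clustered_positioned"
  else if (clustered) "clustered_diffuse"
  else if (positioned) "partitioned_positioned"
  else "partitioned_diffuse"
  regime3 <- if (regime == "partitioned_diffuse") "partitioned_positioned" else regime
  structure(list(clustered_fraction = cf, movement_range_um = mr,
                 clustered = clustered, positioned = positioned,
                 regime = regime, regime3 = regime3),
            class = "mcd_classification")
}

#' @export
print.mcd_classification <- function(x, ...) {
  cat(sprintf("regime %s (clustered fraction %.3f, movement range %.3f um)\n",
              x$regime, x$clustered_fraction, x$movement_range_um))
  invisible(x)
}

.majority_regime <- function(votes3) {
  mx <- max(votes3)
  # ties resolved toward the more-clustered regime (documented tie-break)
  for (lab in .regime3_levels) if (votes3[[lab]] == mx) return(lab)
  .regime3_levels[1]
}

#' Run and classify an ensemble of trajectories
#'
#' Runs `n` trajectories with seeds `base_seed .. base_seed + n - 1` and
#' aggregates clustered fractions, movement ranges, and regime votes. The
#' ensemble regime is the plurality vote over the three-regime labels, ties
#' resolved toward the more-clustered regime.
#'
#' @param params a valid `mcd_params` object.
#' @param base_seed first seed of the ensemble.
#' @param n number of trajectories (default `run.n_trajectories`).
#' @param verbose log one line per trajectory?
#' @return An `mcd_ensemble`: list with per-trajectory vectors
#'   (`clustered_fractions`, `movement_ranges_um`, `regimes`), ensemble
#'   means, `regime_votes` (four-way), `regime3_votes`, and
#'   `majority_regime`.
#' @export
run_ensemble <- function(params, base_seed = params$run$seed,
                         n = params$run$n_trajectories, verbose = FALSE) {
  validate_params(params)
  seeds <- base_seed + seq_len(n) - 1
  cfs <- numeric(n); mrs <- numeric(n); regimes <- character(n)
  for (i in seq_len(n)) {
    traj <- run_trajectory(params, seed = seeds[i])
    cls <- classify_trajectory(traj, params)
    cfs[i] <- cls$clustered_fraction
    mrs[i] <- cls$movement_range_um
    regimes[i] <- cls$regime
    if (verbose)
      message(sprintf("seed %d: %s (fraction %.3f, range %.3f um)",
                      seeds[i], cls$regime, cfs[i], mrs[i]))
  }
  votes4 <- setNames(vapply(.regime_levels, function(l) sum(regimes == l),
                            integer(1)), .regime_levels)
  regimes3 <- ifelse(regimes == "partitioned_diffuse",
                     "partitioned_positioned", regimes)
  votes3 <- setNames(vapply(.regime3_levels, function(l) sum(regimes3 == l),
                            integer(1)), .regime3_levels)
  structure(list(
    n = n, seeds = seeds,
    clustered_fractions = cfs, movement_ranges_um = mrs, regimes = regimes,
    mean_clustered_fraction = mean(cfs),
    mean_movement_range_um = mean(mrs),
    regime_votes = votes4, regime3_votes = votes3,
    majority_regime = .majority_regime(votes3)
  ), class = "mcd_ensemble")
}

#' @export
print.mcd_ensemble <- function(x, ...) {
  cat(sprintf("mcdratchet ensemble (n = %d): majority %s\n", x$n, x$majority_regime))
  cat(sprintf("  mean clustered fraction %.3f, mean movement range %.3f um\n",
              x$mean_clustered_fraction, x$mean_movement_range_um))
  v <- x$regime_votes[x$regime_votes > 0]
  cat("  votes:", paste(sprintf("%s=%d", names(v), v), collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the (k_self, k_AB) phase diagram
#'
#' Runs one classified ensemble per grid cell. The seed schedule is
#' deterministic in the cell index (`base_seed + cell_index * n`), so a
#' sweep is reproducible cell by cell regardless of evaluation order.
#'
#' @param params a valid `mcd_params` object (all non-swept parameters).
#' @param k_self_values,k_AB_values stiffness grids in pN/nm (nonempty).
#' @param n trajectories per cell.
#' @param base_seed base of the seed schedule.
#' @param verbose log per-cell progress?
#' @return An `mcd_phase_diagram`: list with the grids, the cell ensembles,
#'   and a tidy `grid` data frame (one row per cell with means, majority
#'   regime, and vote counts).
#' @export
sweep_phase_diagram <- function(params, k_self_values, k_AB_values,
                                n = params$run$n_trajectories,
                                base_seed = params$run$seed, verbose = FALSE) {
  if (length(k_self_values) < 1 || length(k_AB_values) < 1)
    stop("stiffness grids must be nonempty", call. = FALSE)
  cells <- vector("list", length(k_self_values) * length(k_AB_values))
  rows <- list()
  for (i in seq_along(k_self_values)) {
    for (j in seq_along(k_AB_values)) {
      idx <- (i - 1) * length(k_AB_values) + (j - 1)
      p <- params
      p$springs$k_self <- k_self_values[i]
      p$springs$k_AB <- k_AB_values[j]
      ens <- run_ensemble(p, base_seed = base_seed + idx * n, n = n)
      cells[[idx + 1]] <- ens
      rows[[idx + 1]] <- data.frame(
        k_self = k_self_values[i], k_AB = k_AB_values[j], n = n,
        mean_clustered_fraction = ens$mean_clustered_fraction,
        mean_movement_range_um = ens$mean_movement_range_um,
        majority_regime = ens$majority_regime,
        votes_clustered_diffuse = ens$regime_votes[["clustered_diffuse"]],
        votes_clustered_positioned = ens$regime_votes[["clustered_positioned"]],
        votes_partitioned_positioned = ens$regime_votes[["partitioned_positioned"]],
        votes_partitioned_diffuse = ens$regime_votes[["partitioned_diffuse"]],
        stringsAsFactors = FALSE
      )
      if (verbose)
        message(sprintf("k_self=%.3g k_AB=%.3g -> %s", k_self_values[i],
                        k_AB_values[j], ens$majority_regime))
    }
  }
  grid <- do.call(rbind, rows)
  rownames(grid) <- NULL
  structure(list(k_self_grid = k_self_values, k_AB_grid = k_AB_values,
                 cells = cells, grid = grid),
            class = "mcd_phase_diagram")
}

#' @export
print.mcd_phase_diagram <- function(x, ...) {
  cat(sprintf("mcdratchet phase diagram: %d x %d cells\n",
              length(x$k_self_grid), length(x$k_AB_grid)))
  print(x$grid)
  invisible(x)
}

#' Mean clustered fraction as a function of bond stiffness
#'
#' Computes the ensemble-mean clustered fraction for each `k_AB` at the
#' fixed `k_self` of `params` - the cross-section of the phase diagram along
#' which clustering decays as the McdA-McdB interaction strengthens.
#'
#' @param params a valid `mcd_params` object (fixes `k_self` etc.).
#' @param k_AB_values bond stiffnesses in pN/nm, sorted ascending.
#' @param n trajectories per stiffness.
#' @param base_seed base of the seed schedule (`base_seed + (i-1) * n` per
#'   point).
#' @param verbose log per-point progress?
#' @return Data frame with `k_AB`, `mean_clustered_fraction`,
#'   `se_clustered_fraction`, `mean_movement_range_um`, `n`.
#' @export
clustered_fraction_curve <- function(params, k_AB_values,
                                     n = params$run$n_trajectories,
                                     base_seed = params$run$seed,
                                     verbose = FALSE) {
  if (is.unsorted(k_AB_values))
    stop("k_AB_values must be sorted ascending", call. = FALSE)
  rows <- lapply(seq_along(k_AB_values), function(i) {
    p <- params
    p$springs$k_AB <- k_AB_values[i]
    ens <- run_ensemble(p, base_seed = base_seed + (i - 1) * n, n = n)
    if (verbose)
      message(sprintf("k_AB=%.3g: mean clustered fraction %.3f",
                      k_AB_values[i], ens$mean_clustered_fraction))
    data.frame(k_AB = k_AB_values[i],
               mean_clustered_fraction = ens$mean_clustered_fraction,
               se_clustered_fraction = stats::sd(ens$clustered_fractions) / sqrt(ens$n),
               mean_movement_range_um = ens$mean_movement_range_um,
               n = ens$n)
  })
  do.call(rbind, rows)
}
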