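# System state and time stepping.
#
# A state is a plain list (class "mcd_state"): carboxysome centers (nm),
# fixed McdB offsets in the body frame, the McdA lattice occupancy, and the
# live-bond tables. All stochastic updates draw from R's RNG, so set.seed()
# (or the seed arguments below) makes everything reproducible.

#' Initialize the system state
#'
#' Places `n_carboxysomes` disks in a row about the domain center at
#' center-center spacing `rest_length_self` (touching, within the
#' self-association range), scatters each carboxysome's McdB sites uniformly
#' over its footprint, and puts McdA on uniformly random distinct lattice
#' sites at the two-state steady-state bound fraction
#' `k_rebind / (k_rebind + k_off_intrinsic)` (all on the nucleoid if both
#' rates are zero), remainder in the cytoplasm. No bonds; time 0.
#'
#' @param params a valid `mcd_params` object.
#' @param seed integer seed (defaults to `params$run$seed`).
#' @return An `mcd_state` object.
#' @export
init_state <- function(params, seed = params$run$seed) {
  validate_params(params)
  set.seed(seed)
  cpp_init_state(params)
}

#' Advance the state by one time step
#'
#' Applies, in fixed order: (1) McdA lattice hops; (2) cytoplasm-to-nucleoid
#' rebinding; (3) intrinsic unbinding of unbonded McdA; (4) bond formation;
#' (5) force evaluation (bond tethers + self-association springs); (6)
#' overdamped carboxysome displacement with thermal noise, hard-core
#' exclusion, and boundary reflection; (7) bond breaking with stimulated
#' ejection of McdA to the cytoplasm. McdA count is conserved.
#'
#' @param state an `mcd_state` object.
#' @param params a valid `mcd_params` object.
#' @return The updated `mcd_state`, with `time` advanced by `dt`.
#' @export
step <- function(state, params) {
  cpp_step(state, params)
}

#' Advance the state by many steps, optionally recording samples
#'
#' Low-level driver used by [run_trajectory()] and [validate_model()].
#'
#' @param state an `mcd_state` object.
#' @param params a valid `mcd_params` object.
#' @param n_steps number of `dt` steps to take.
#' @param record_every record a sample every this many steps (0 = none).
#' @param track_annulus if `TRUE`, at each sample count nucleoid McdA in the
#'   half-annuli (inner/outer radius `r_in`/`r_out`, nm) ahead of and behind
#'   the first carboxysome's displacement since the previous sample.
#' @param r_in,r_out annulus radii in nm.
#' @return A list with `state`, a `records` matrix (columns: `time_s`,
#'   `n_mcdA_nucleoid`, then `x_nm`, `y_nm`, `n_bonds` per carboxysome), and
#'   `annulus_lead`/`annulus_trail` counts when tracking.
#' @export
advance_state <- function(state, params, n_steps, record_every = 0L,
                          track_annulus = FALSE, r_in = 0, r_out = 0) {
  cpp_advance(state, params, as.integer(n_steps), as.integer(record_every),
              track_annulus, r_in, r_out)
}

#' Check internal consistency of a state
#'
#' Verifies that the occupancy map, McdA site assignments, and bond tables
#' cross-reference each other exactly.
#'
#' @inheritParams step
#' @return Character vector of violations; empty when consistent.
#' @export
check_state <- function(state, params) {
  cpp_check_state(state, params)
}

.record_row0 <- function(state, params) {
  nc <- params$run$n_carboxysomes
  row <- numeric(2 + 3 * nc)
  row[1] <- state$time
  row[2] <- sum(state$mcda_site > 0)
  nb <- colSums(state$bond_mcda > 0)
  for (c in seq_len(nc)) {
    row[2 + 3 * (c - 1) + 1] <- state$carb[c, 1]
    row[2 + 3 * (c - 1) + 2] <- state$carb[c, 2]
    row[2 + 3 * (c - 1) + 3] <- nb[c]
  }
  row
}

#' Run one full trajectory
#'
#' Initializes the state and iterates [step()] for `duration/dt` steps,
#' recording carboxysome centers and live-bond counts every
#' `record_interval` (the sample at time 0 included), so a 300 s run recorded
#' every 0.1 s yields 3001 samples per carboxysome.
#'
#' @param params a valid `mcd_params` object.
#' @param seed integer seed (defaults to `params$run$seed`). Identical
#'   `(params, seed)` give bit-identical trajectories.
#' @param verbose if `TRUE`, log progress roughly every 10 simulated seconds.
#' @return An `mcd_trajectory`: list with `time` (s), `x`, `y` (um matrices,
#'   samples x carboxysomes), `n_bonds`, `n_mcdA_nucleoid`, plus the
#'   generating `params` and `seed`.
#' @export
run_trajectory <- function(params, seed = params$run$seed, verbose = FALSE) {
  validate_params(params)
  set.seed(seed)
  state <- cpp_init_state(params)
  dt <- params$run$dt
  every <- as.integer(round(params$run$record_interval / dt))
  n_steps <- as.integer(round(params$run$duration / dt))
  chunk <- every * max(1L, as.integer(ceiling(10 / params$run$record_interval)))
  rows <- list(.record_row0(state, params))
  done <- 0L
  while (done < n_steps) {
    nb <- min(chunk, n_steps - done)
    res <- cpp_advance(state, params, nb, every, FALSE, 0, 0)
    state <- res$state
    rows[[length(rows) + 1L]] <- res$records
    done <- done + nb
    if (verbose)
      message(sprintf("t = %.1f / %.1f s, bonds = %s", state$time,
                      params$run$duration,
                      paste(colSums(state$bond_mcda > 0), collapse = "+")))
  }
  rec <- do.call(rbind, rows)
  nc <- params$run$n_carboxysomes
  idx <- 2 + 3 * (seq_len(nc) - 1)
  traj <- list(
    time = rec[, 1],
    x = rec[, idx + 1, drop = FALSE] / 1000,
    y = rec[, idx + 2, drop = FALSE] / 1000,
    n_bonds = rec[, idx + 3, drop = FALSE],
    n_mcdA_nucleoid = rec[, 2],
    n_carboxysomes = nc,
    params = params,
    seed = seed
  )
  class(traj) <- "mcd_trajectory"
  traj
}

#' @export
print.mcd_trajectory <- function(x, ...) {
  cat(sprintf("mcdratchet trajectory: %d carboxysome(s), %d samples over %.4g s\n",
              x$n_carboxysomes, length(x$time), max(x$time)))
  if (!is.null(x$seed)) cat(sprintf("  seed %s\n", format(x$seed)))
  invisible(x)
}

#' @export
print.mcd_state <- function(x, ...) {
  cat(sprintf("mcdratchet state at t = %.4g s: %d carboxysome(s), %d/%d McdA on nucleoid, %d bond(s)\n",
              x$time, nrow(x$carb), sum(x$mcda_site > 0), length(x$mcda_site),
              sum(x$bond_mcda > 0)))
  invisible(x)
}
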