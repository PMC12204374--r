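# Shared fixtures: small parameter sets and hand-built states with known
# geometry, so kinetic and mechanical operations can be checked against
# closed forms.

# Default parameters with a short run, for fast end-to-end tests.
fast_params <- function(duration = 2) {
  p <- default_params()
  p$run$duration <- duration
  p
}

# Small lattice (1.0 x 0.5 um, 40 x 20 sites) with all stochastic channels
# off; individual tests switch on what they need.
quiet_params <- function(n_mcdA = 1, n_mcdB = 2, n_carb = 1) {
  p <- default_params()
  p$geometry$nucleoid_length <- 1.0
  p$geometry$nucleoid_width <- 0.5
  p$kinetics$n_mcdA <- n_mcdA
  p$kinetics$n_mcdB_per_carb <- n_mcdB
  p$kinetics$k_off_intrinsic <- 0
  p$kinetics$k_rebind <- 0
  p$kinetics$k_bond_on <- 0
  p$kinetics$k_bond_off <- 0
  p$kinetics$D_mcdA_nucleoid <- 0
  p$kinetics$D_carb <- 0
  p$springs$k_self <- 0
  p$run$n_carboxysomes <- n_carb
  p
}

lattice_dims <- function(params) {
  a <- params$geometry$lattice_spacing
  c(nx = round(params$geometry$nucleoid_length * 1000 / a),
    ny = round(params$geometry$nucleoid_width * 1000 / a))
}

# 1-based lattice index of the site with center nearest (x, y) in nm.
site_at <- function(params, x, y) {
  a <- params$geometry$lattice_spacing
  d <- lattice_dims(params)
  ix <- min(max(floor(x / a), 0), d["nx"] - 1)
  iy <- min(max(floor(y / a), 0), d["ny"] - 1)
  as.integer(iy * d["nx"] + ix + 1)
}

site_pos <- function(params, s) {
  a <- params$geometry$lattice_spacing
  d <- lattice_dims(params)
  ix <- (s - 1) %% d[["nx"]]
  iy <- (s - 1) %/% d[["nx"]]
  c((ix + 0.5) * a, (iy + 0.5) * a)
}

# Put McdA particle i on lattice site s (1-based), keeping occupancy in sync.
place_mcda <- function(state, i, s) {
  old <- state$mcda_site[i]
  if (old > 0) state$occupancy[old] <- 0L
  state$mcda_site[i] <- as.integer(s)
  if (s > 0) state$occupancy[s] <- as.integer(i)
  state
}

# Install a live bond between McdA i (already on a site) and McdB site j of
# carboxysome c.
install_bond <- function(state, i, carb, j) {
  stopifnot(state$mcda_site[i] > 0)
  state$bond_mcda[j, carb] <- as.integer(i)
  state$mcda_bond_carb[i] <- as.integer(carb)
  state$mcda_bond_site[i] <- as.integer(j)
  state
}

# Set a McdB offset (nm, body frame) on carboxysome c.
set_offset <- function(state, carb, j, off) {
  state$offsets[[carb]][j, ] <- off
  state
}

# Synthetic trajectory object from coordinate matrices (um).
make_traj <- function(time, x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  structure(list(time = time, x = x, y = y,
                 n_bonds = matrix(0L, nrow(x), ncol(x)),
                 n_mcdA_nucleoid = rep(NA_real_, nrow(x)),
                 n_carboxysomes = ncol(x), params = NULL, seed = NA),
            class = "mcd_trajectory")
}
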