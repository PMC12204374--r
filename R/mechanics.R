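# Deterministic mechanics: elastic forces, overdamped displacement,
# hard-core exclusion, boundary reflection. Forces are evaluated from
# positions at the start of the step (explicit Euler-Maruyama).

#' Elastic McdA-McdB bond forces per carboxysome
#'
#' Each bond is a Hookean tether of stiffness `k_AB` (zero rest length by
#' default) between the McdB site position (carboxysome center + fixed
#' offset) and the anchoring McdA lattice position. The force on the
#' carboxysome is `-k_AB * extension`, summed over its live bonds.
#'
#' @param state an `mcd_state` object.
#' @param params a valid `mcd_params` object.
#' @return A numeric matrix (`n_carboxysomes` x 2, columns `fx`, `fy`, pN).
#' @export
bond_forces <- function(state, params) {
  f <- cpp_bond_forces(state, params)
  colnames(f) <- c("fx", "fy")
  f
}

#' Carboxysome self-association spring forces
#'
#' For each pair of carboxysomes with center distance `r <= self_range`, a
#' Hookean spring of stiffness `k_self` and rest length `rest_length_self`
#' (contact) acts along the center line: attractive for `r` above rest
#' length, equal and opposite on the two members, zero beyond the cutoff.
#' Overlap below contact is handled by the hard core, not the spring.
#'
#' @inheritParams bond_forces
#' @return A numeric matrix (`n_carboxysomes` x 2, columns `fx`, `fy`, pN).
#' @export
self_association_forces <- function(state, params) {
  f <- cpp_self_forces(state, params)
  colnames(f) <- c("fx", "fy")
  f
}

#' Overdamped carboxysome displacement
#'
#' Moves each center by `(F / gamma) * dt + sqrt(2 * D_carb * dt) * eta`
#' with `eta` standard normal per axis and drag `gamma = kBT / D_carb`; then
#' resolves pairwise overlaps symmetrically to contact distance, then
#' reflects centers specularly into the nucleoid rectangle. With
#' `D_carb = 0` there is neither noise nor drift (infinite drag); use
#' `noise = FALSE` to study deterministic relaxation at finite drag.
#'
#' @inheritParams bond_forces
#' @param forces numeric matrix (`n_carboxysomes` x 2) of net forces in pN.
#' @param noise draw thermal displacements? (default `TRUE`).
#' @return The updated state.
#' @export
displace_carboxysomes <- function(state, forces, params, noise = TRUE) {
  cpp_displace(state, forces, params, noise)
}

#' Newton's-third-law check for the self-association forces
#'
#' Verifies that the self-association force table sums to zero (action =
#' reaction over every pair) within `tol`.
#'
#' @inheritParams bond_forces
#' @param forces optional force table to check (default: computed from
#'   `state`); pass a corrupted table as a negative control.
#' @param tol tolerance in pN.
#' @return `TRUE` or `FALSE`.
#' @export
newton_third_law_check <- function(state, params, forces = NULL, tol = 1e-9) {
  ref <- cpp_self_forces(state, params)
  if (is.null(forces)) forces <- ref
  if (!is.matrix(forces) || !all(dim(forces) == dim(ref))) return(FALSE)
  all(abs(colSums(forces)) <= tol) && all(abs(forces - ref) <= tol)
}
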