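# Stochastic McdA state transitions. Each operation applies one kinetic
# channel of the fixed update ordering in step(); all transition
# probabilities have the tau-leap form 1 - exp(-rate * dt). These wrappers
# exist so each channel can be exercised and validated in isolation; they
# consume R's RNG stream (use set.seed() for reproducibility).

#' McdA surface diffusion (lattice hops)
#'
#' Each unbonded nucleoid McdA attempts a hop to one of its 4 nearest
#' neighbor sites with total probability `4 * D_mcdA_nucleoid / a^2 * dt`
#' (direction uniform); hops off the lattice edge or into occupied sites are
#' rejected, implementing hard volumetric exclusion.
#'
#' @param state an `mcd_state` object.
#' @param params a valid `mcd_params` object.
#' @return The updated state.
#' @export
hop_mcdA <- function(state, params) {
  cpp_hop(state, params)
}

#' Cytoplasm-to-nucleoid rebinding of McdA
#'
#' Each cytoplasmic McdA binds with probability `1 - exp(-k_rebind * dt)` to
#' a uniformly random empty lattice site. If no empty site exists the
#' particle stays cytoplasmic. The slowness of this channel relative to
#' stimulated release is what maintains the McdA depletion zone behind a
#' moving carboxysome.
#'
#' @inheritParams hop_mcdA
#' @return The updated state.
#' @export
rebind_mcdA <- function(state, params) {
  cpp_rebind(state, params)
}

#' Intrinsic dissociation of unbonded McdA from the nucleoid
#'
#' Each unbonded nucleoid McdA is ejected to the cytoplasm with probability
#' `1 - exp(-k_off_intrinsic * dt)`. Bonded McdA never leaves through this
#' channel.
#'
#' @inheritParams hop_mcdA
#' @return The updated state.
#' @export
unbind_mcdA_intrinsic <- function(state, params) {
  cpp_unbind(state, params)
}

#' McdA-McdB bond formation
#'
#' Free McdB sites pair with the nearest free, unbonded nucleoid McdA within
#' `capture_radius`; competition for the same McdA is resolved by smallest
#' distance, then lowest site index, then lowest McdA id (greedy matching).
#' Each matched pair then forms a bond with probability
#' `1 - exp(-k_bond_on * dt)`. A bond anchors the McdA at its lattice
#' position; one bond per site and per McdA.
#'
#' @inheritParams hop_mcdA
#' @return The updated state.
#' @export
form_bonds <- function(state, params) {
  cpp_form_bonds(state, params)
}

#' McdA-McdB bond breaking with stimulated release
#'
#' Each live bond breaks with probability `1 - exp(-k_bond_off * dt)`, and
#' unconditionally if its extension exceeds `max_extension_AB` (numerical
#' guard). On break the McdA is ejected to the cytoplasmic pool immediately
#' (McdB-stimulated release, idealized as instantaneous) and its lattice
#' site is vacated.
#'
#' @inheritParams hop_mcdA
#' @return The updated state.
#' @export
break_bonds <- function(state, params) {
  cpp_break_bonds(state, params)
}
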