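# mcdratchet

Agent-based stochastic simulation of carboxysome positioning and
partitioning on the bacterial nucleoid by the McdAB system.

Carboxysomes — ~150 nm protein microcompartments — are distributed over the
nucleoid by a ParA/MinD-family Brownian ratchet: McdA binds the nucleoid,
McdB decorates the carboxysome surface, and transient McdA–McdB elastic
tethers plus McdB-stimulated release of McdA rectify the cargo's thermal
motion along a self-generated McdA depletion gradient. Carboxysomes also
self-associate. `mcdratchet` models both tendencies and maps how their
competition sets the cargo's fate.

**For whom:** modelers of ParA/MinD-type positioning systems who want a
reproducible, tested reference implementation of the ratchet-with-adhesion
model; experimentalists who want to classify tracked-focus trajectories with
the same thresholds the model uses.

## The model in brief

Two hard disks (diameter 150 nm) move on a 2.0 × 0.5 µm nucleoid by
overdamped Langevin dynamics, `dx = (F/γ) dt + √(2 D dt) η` with
`γ = k_BT / D`. McdA particles occupy a 25 nm exclusion lattice, exchange
with a well-mixed cytoplasmic pool (slow rebinding), and form
zero-rest-length Hookean tethers of stiffness `k_AB` with McdB sites fixed
on each disk; bond breakage ejects the McdA (stimulated release), and bonded
anchors hop with Metropolis acceptance `exp(−ΔE/k_BT)` on the elastic
energy, so soft tethers relay along the nucleoid while stiff tethers freeze.
An attractive contact spring of stiffness `k_self` (rest length 150 nm,
engagement cutoff 167 nm) models self-association.

Per 300 s trajectory the package computes the **clustered fraction** (share
of 0.1 s samples with the centers within the self-association range;
clustered if > 90%) and the **movement range** (maximum distance between any
two points of a carboxysome's path; positioned if < 0.25 × nucleoid length),
then classifies ensembles by plurality into *clustered & diffuse*,
*clustered & positioned*, or *partitioned & positioned* — the three regimes
that appear, at fixed `k_self = 0.6 pN/nm`, at McdA–McdB stiffnesses of
0.1, 0.3, and 0.8 pN/nm respectively.

## Worked example

```r
library(mcdratchet)

p <- default_params()          # calibrated reference parameters
p$springs$k_AB <- 0.3          # intermediate bond stiffness
ens <- run_ensemble(p, base_seed = 1, n = 16)
ens
#> mcdratchet ensemble (n = 16): majority clustered_positioned
#>   mean clustered fraction 1.000, mean movement range 0.408 um
#>   votes: clustered_positioned=16
```

The two carboxysomes stay within self-association range 100% of recorded
time (mean clustered fraction 1.000 > 0.90: a cluster) while the cluster's
movement range, 0.408 µm, stays below a quarter of the 2 µm nucleoid
(0.408/2 = 0.204 < 0.25: positioned near mid-nucleoid). At `k_AB = 0.1` the
same ensemble is clustered but diffusive (mean range 0.63 µm), and at 0.8
the pair separates (mean clustered fraction 0.077) — the three regimes of
the phase diagram.

Single trajectories, phase-diagram sweeps, and the analytic-oracle
validation suite (free-diffusion MSD, tether equipartition, two-state
occupancy, depletion-zone asymmetry, conservation, τ-leap consistency):

```r
traj <- run_trajectory(p, seed = 1)
classify_trajectory(traj, p)
pd <- sweep_phase_diagram(p, k_self_values = 0.6,
                          k_AB_values = c(0.1, 0.3, 0.8), n = 16)
validate_model()
```

The same drivers are available from the shell via `exec/mcdratchet`
(`run`, `sweep`, `classify`, `validate`); every output directory includes a
manifest (parameters + seed schedule) that reproduces it byte-identically.

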