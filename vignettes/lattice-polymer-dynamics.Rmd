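---
title: "Dynamics of lattice polymers at adsorbing surfaces: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamics of lattice polymers at adsorbing surfaces: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polylat)
```

## The model

`polylat` simulates a single coarse-grained linear polymer of `N` monomers
on the simple cubic lattice.  Each monomer occupies one lattice site; no two
monomers may share a site.  Consecutive monomers are joined by fluctuating
bonds whose length may be 1, sqrt(2) or sqrt(3) (in lattice units), and no
two bonds may geometrically intersect — together these constraints prevent
the chain from ever crossing itself during local moves.  The configurational
energy is

    E = - n_PP * E_PP - n_PS * E_PS      (units of kT, kT = 1)

where `n_PP` counts *non-bonded* monomer pairs on nearest-neighbour sites
(the short-range intra-polymer attraction that drives the coil–globule
collapse) and `n_PS` counts monomers in the lattice layer adjacent to the
surface.  Three boundary modes represent the three physical situations of
interest:

* **`bulk3d`** — a desorbed chain in dilute solution; periodic boundaries in
  x, y, z; `E_PS` does not act.
* **`slab`** — a chain near an impenetrable, homogeneous, attractive wall at
  z = 0; periodic in x and y; monomer sites start at z = 1, where each
  monomer gains `-E_PS`; a reflecting top closes the box.
* **`plane2d`** — a fully adsorbed chain, idealised as a strictly
  two-dimensional polymer on one z-plane; the bond set shrinks to
  {1, sqrt(2)} and the surface term is a constant (`n_PS = N`), which
  cancels from all Metropolis ratios and is therefore ignored.

## Dynamics

Chain dynamics are generated by single-monomer Metropolis moves: a monomer
is picked uniformly at random and a displacement by one lattice spacing is
drawn uniformly from the six axis directions (four in `plane2d`).  The move
is allowed if the target site is empty, both affected bonds stay within the
allowed length set, neither displaced bond intersects any other bond, and
the wall constraints hold; an allowed move is accepted with probability
`min(1, exp(-dE))`.  One Monte Carlo step (MCS) consists of `N` attempted
moves — rejected attempts consume time, which is what makes the Metropolis
chain a model of dynamics and not just a sampler.  All energy changes are
computed from local neighbourhoods and verified (in testing) against
from-scratch recounts.

Bond crossing is decided by an exact integer-arithmetic segment–segment
intersection test (closed segments; coplanarity via the scalar triple
product, then rational barycentric parameters).  Two consecutive bonds
sharing a monomer are exempt.  Distances across periodic boundaries use the
minimum-image convention.

### Adsorption protocol (slab mode)

Each slab run follows three phases before production: (1) the chain is
equilibrated between a *virtual repulsive wall* at z = L_z/4 and the top of
the box, so its conformation decorrelates from initialisation without
touching the surface (the virtual wall is implemented as a hard constraint;
equilibration statistics are insensitive to its softness); (2) the virtual
wall is removed and the unbiased dynamics run until the first surface
contact (`n_PS > 0`), with a configurable cap that raises an error if the
chain never adsorbs; (3) the chain settles for `settle_mcs` before
production begins.  If the chain fully desorbs during production the frames
are kept and a run-level desorbed-fraction diagnostic is reported, so the
averages are not silently biased while the always-adsorbed assumption
remains checkable.

### Time scales and defaults

Pilot measurements with this engine give rotational relaxation times of
roughly `1.0 N^2.35` MCS in bulk, `(0.35 + 0.30 max(E_PS, 1)) N^2.6` in slab
geometry and `2.1 N^2.7` strictly in-plane (athermal chains, N = 8..64).
These calibrated guides size the defaults: equilibration is the larger of
`ceil(N^(1+2 nu))` (nu = 0.6 in 3D, 0.75 in-plane) and two relaxation
times — the bare `N^(1+2 nu)` alone is several times shorter than the
measured relaxation of this move set and would start production from a
not-yet-equilibrated state — and production covers about twelve relaxation
times with ~2000 recorded frames.  All of these are per-run overridable
through `run_protocol()`.

Box defaults: the lateral edge is `max(64, ceil(4 N^0.75))`, large enough
that a chain never interacts with its own periodic image.  The slab height
is `max(6, ceil(1.5 N^0.588))`: several times the vertical extent of the
desorbed coil (whose per-axis radius of gyration is only ~0.4 N^0.588), so
the pre-adsorption equilibration is effectively unconfined, while keeping
the diffusive search for the surface short and the chain firmly in the
adsorbed regime that is being studied — in tall boxes short chains at
E_PS = 1 spend a substantial fraction of time desorbed, which is not the
physical situation of interest here.

### Random numbers

Every run owns a private xoshiro256++ stream seeded (via splitmix64) from an
integer recorded in the run configuration; identical seed and configuration
give a bit-identical trajectory, and replicas use consecutive recorded
seeds.  The scrambled seeding makes nearby integer seeds statistically
independent streams.

## Observables

**Translational diffusion.**  The centre-of-mass mean-square displacement
is averaged over all time origins of a trajectory at ~60 logarithmically
spaced lags.  For the adsorbed chain, motion normal to the wall is bounded,
so the parallel component is the meaningful one; `D_xy` is the fitted slope
of the in-plane MSD over the last decade of lags divided by 4 (the
long-time limit of `<dr^2>_xy / 4t`), with an R^2 linearity diagnostic.  In
bulk the same xy-component estimator is used — by isotropy it estimates the
same `D` as any other pair of components.

**Rotational relaxation.**  The end-to-end vector autocorrelation
`rho(t) = <R(t0 + t) . R(t0)> / <R . R>` uses all time origins and
normalises by the time-averaged `<R . R>` (the equilibrium estimator; equal
to the single-origin definition in expectation, with lower variance).
`tau_R` comes from a log-linear fit restricted to the window
`0.06 < rho < 0.30`, where a clean single-exponential regime is found (the
local decay time is flat across this window in long-run checks).  The fit
is weighted by `rho^2`: the averaged ACF carries a roughly lag-independent
absolute noise floor of order `sqrt(2 tau_R / (T R))` for `R` replicas of
length `T`, so unweighted log-fits are tilted by the noisiest points just
above the lower window edge when ensembles are small; `rho^2` weighting is
the standard variance-stabilising choice and is identical on an exact
exponential.

At the replica-aggregation level (`run_point`), one further small-sample
correction is applied before the window fit: each finite trajectory carries
a spurious correlation offset of order `|mean_t R|^2 / <R.R>` — zero-mean
across replicas but constant across lags within a replica — which can
masquerade as a slow tail of the averaged ACF and occasionally inflate
`tau_R` severely.  The offset is estimated as the mean of the averaged
curve over the last quarter of the lag range (where the true correlation
has decayed to below ~2%) and subtracted; the corrected fit is accepted
only if it is self-consistent, i.e. the tail region used lies beyond four
corrected relaxation times, and otherwise the uncorrected fit stands.  In
deliberately under-powered trials this reduced the spread of `tau_R`
estimates several-fold without shifting well-resolved values.

**Scaling exponents.**  `alpha` (`D_xy ~ N^-alpha`) and `beta`
(`tau_R ~ N^beta`) are ordinary least squares on log-log axes, with the
sign convention that both are reported positive.  The reproduction studies
fit over N = 8, 16, 32, 64; analyses with more chain lengths may restrict
to the long-chain regime (e.g. N >= 32) via `n_min_fit`.

**Coil–globule locator.**  `<R_G^2>` is swept over an `E_PP` grid at fixed
N; the transition is reported as the grid point of steepest descent
(central finite differences), with the grid spacing as the resolution.  The
steepest point must be a strict interior extremum of the slope — an
essentially linear decrease is refused rather than assigned an arbitrary
location.

## Exact enumeration oracle

For chains of up to four monomers every configuration can be enumerated
(depth-first growth over the 26 allowed bond vectors — 8 in-plane — with
self-avoidance and non-crossing checks).  The oracle is written in plain R
and shares no code with the C++ engine, including an independent
segment-intersection routine.  It yields exact Boltzmann averages and
per-configuration probabilities against which the sampler is tested:
configuration frequencies of the trimer at `E_PP = 1` (chi-squared), dimer
and trimer moments in bulk and slab boxes, and monotonicity of `<n_PP>` in
`E_PP` and `<n_PS>` in `E_PS`.  Slab enumeration runs at absolute heights
`1 <= z <= z_max` with a reflecting top, and the matching engine box
(`L_z = z_max + 1`) makes the two ensembles identical rather than
approximately so.

## Reproduction studies and their scale

The package's headline numbers are the scaling exponents of the athermal
chain, recomputed at desk scale by `scripts/acceptance.R` (seeded, from
scratch).  The study conditions are: chain lengths N = 8, 16, 32, 64;
~100 replicas per point for the shorter chains, graded down to ~16-40 for
the longest (a long-chain trajectory spans ~12 tau_R and contributes
correspondingly many time origins, so per-point statistics stay
comparable); the full published ensembles (5000 replicas, N up to 128) are
reachable with the same code via the replica arguments or the CLI's
`--paper-scale` flag.  At this reduced scale the fitted exponents carry
bootstrap uncertainties of a few hundredths (diffusion) to ~0.1
(relaxation).

## What the simulations do and do not emulate

The model captures excluded volume, chain connectivity without crossing,
short-range intra-chain cohesion and a homogeneous short-range adsorbing
wall, with purely local stochastic dynamics — the ingredients behind Rouse
scaling, its 2D analogue, and the partially adsorbed chain's behaviour
between them.  It does not include hydrodynamic interactions (experimental
diffusion exponents can differ for this reason), surface heterogeneity,
explicit solvent, bending stiffness, or off-lattice geometry.  Passing the
acceptance checks therefore validates the lattice model and its estimators,
not quantitative agreement with any particular experiment.

## Known limitations

* The ACF noise floor makes `tau_R` for the slowest point (2D, N = 64) the
  least certain quantity at desk scale; its bootstrap error is honest but
  large (~10-20%), which the exponent fit's leverage damps to a few
  hundredths on `beta`.
* At N <= 64 the slab chain is still crossing over between 3D-like and
  2D-like dynamics, so fitted slab exponents at desk scale sit slightly
  below their long-chain values.
* Short chains (N = 8) at E_PS = 1 desorb intermittently even in the short
  default box (~15% of frames); the desorbed-fraction diagnostic reports
  this, and it vanishes for E_PS = 2 or N >= 16.
* Enumeration is exhaustive and guarded to N <= 4.

## A minimal session

```{r example, eval = FALSE}
# one adsorbed-chain point at reduced scale
pt <- run_point(32, "slab", e_ps = 1, replicas = 8, seed = 1)
pt$d_xy; pt$tau_r; pt$desorbed_fraction

# a small athermal sweep and its exponents
sw <- run_sweep(sweep_config(c(8, 16, 32, 64), "bulk3d", replicas = 8,
                             seed = 1))
sw$exponents

# exact dimer ensemble: <R^2> = 27/13
exact_average(enumerate_chains(2, "bulk3d"), "r_sq")
```
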