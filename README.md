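# polylat

Dynamic Monte Carlo simulation of a single coarse-grained polymer on the
simple cubic lattice, for studying how an attractive, homogeneous surface
changes the chain's translational diffusion and rotational relaxation.

## The problem and the model

A flexible polymer physisorbed on a flat attractive wall diffuses along the
surface and reorients much more slowly than the same chain free in dilute
solution; a chain pinned flat on the surface (the strong-adsorption limit)
is slower still.  `polylat` implements the standard lattice model for this
problem: a self-avoiding chain of `N` monomers on the cubic lattice whose
bond lengths fluctuate among 1, √2, √3 (a fluctuating-bond chain), with
energy

```
E = − n_PP·E_PP − n_PS·E_PS        (kT = 1)
```

where `n_PP` counts non-bonded nearest-neighbour monomer pairs (intra-chain
cohesion; drives the coil–globule collapse as `E_PP` grows) and `n_PS`
counts monomers in the lattice layer next to the impenetrable wall at
z = 0.  Dynamics are single-monomer Metropolis moves — one lattice spacing
in a random axis direction, accepted with probability `min(1, e^−ΔE)`
provided the target site is empty, bond lengths stay allowed and no two
bonds cross.  One Monte Carlo step (MCS) = `N` attempted moves.  Three
boundary modes cover the desorbed chain (`bulk3d`), the partially adsorbed
chain near the wall (`slab`, with the equilibrate–adsorb–settle protocol),
and the fully adsorbed chain (`plane2d`, a strictly 2D polymer).

From recorded trajectories the package estimates

* `D_xy` — parallel diffusion coefficient, the long-time slope of the
  in-plane centre-of-mass mean-square displacement divided by 4;
* `τ_R` — rotational relaxation time, from the exponential decay of the
  end-to-end vector autocorrelation ρ(t), fitted where 0.06 < ρ < 0.30;
* scaling exponents `α` and `β` in `D_xy ~ N^−α` and `τ_R ~ N^β`
  (log–log least squares);
* the coil–globule transition location, as the steepest drop of `⟨R_G²⟩`
  over an `E_PP` grid.

An exact enumeration oracle (chains of up to 4 monomers, pure R,
independent of the C++ engine) validates geometry, energetics and
equilibrium sampling.  See the vignette
(`vignettes/lattice-polymer-dynamics.Rmd`) for the model's assumptions,
default time scales and design choices.

## A worked example

```r
library(polylat)

# exact dimer ensemble: 26 bond vectors, <R^2> = 27/13
ens <- enumerate_chains(2, "bulk3d")
nrow(ens)                     #> 26
exact_average(ens, "r_sq")    #> 2.076923

# a partially adsorbed chain, reduced ensemble
pt <- run_point(32, "slab", e_ps = 1, replicas = 8, seed = 42)
print(pt)
#> polylat_point slab_n032_epp0_eps1 (8 replicas)
#>   D_xy = 0.001486 +/- 0.00025, tau_R = 4503 +/- 1.4e+04 MCS
#>   <R_G^2> = 15.19, <n_PS> = 14.7, acceptance 0.272, desorbed 0.0019
```

`D_xy` is in lattice units² per MCS, `τ_R` in MCS; `<n_PS>` says about half
of the 32 monomers touch the wall layer at `E_PS = 1`, and the chain was
desorbed in only 0.2% of recorded frames.  A small sweep fits the
chain-length scaling (at 24 replicas the relaxation exponent still carries
a bootstrap error of ~0.4 — the reproduction runs below use ~100):

```r
sw <- run_sweep(sweep_config(c(8, 16, 32), "bulk3d", replicas = 24, seed = 7))
sw$exponents
#>     mode e_pp e_ps    alpha   alpha_se     beta   beta_se  n_used
#> 1 bulk3d    0    0 1.234447 0.05207311 3.245912 0.4087968 8,16,32
```

A command-line front end with `simulate`, `sweep`, `fit` and `oracle`
subcommands is installed at `inst/cli/polylat.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/polylat.R", package="polylat"))')" \
    sweep --n 8,16,32,64 --mode slab --eps 1 --replicas 100 --seed 1 --out results/
```

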