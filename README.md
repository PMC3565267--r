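# polypack

Monte Carlo simulation and local-order analysis of athermal polymer
packings: freely-jointed chains of tangent hard spheres of uniform diameter
σ in periodic boxes.  In such systems every allowed configuration has the
same (zero) energy, so any ordering transition is driven purely by entropy.
Above a critical packing fraction (between the hard-sphere melting point
φ_M = 0.545 and the maximally random jammed density), dense chain packings
spontaneously crystallize into randomly stacked hexagonal close packed
(rhcp) morphologies; the package provides both the simulation engine that
produces such trajectories and the structural descriptors that detect and
characterize the transition.

The package is aimed at researchers studying entropy-driven ordering in
hard-particle and coarse-grained polymer systems, and at anyone needing
robust per-site crystal classification (hcp / fcc / fivefold) or Voronoi
shape analysis for dense packings.

## What it computes

**Engine** — a seven-move Monte Carlo mix (reptation, end rotation,
configurational-bias regrowth, inter-chain reptation, internal libration,
and the simplified end-bridging pair sEB/sIEB that re-forms bonds between
nearly tangent spheres to equilibrate chain lengths), with multiple-trial
(Rosenbluth) acceptance, chain-length chemical potentials for uniform or
Flory length distributions, an isotropic compression protocol with rigid
affine chain repositioning, and a monomer mode for bond-free reference
systems.

**Descriptors** —

* exact periodic Voronoi tessellation; per-cell inertia-tensor shape
  measures: asphericity *b* = ½(I₁+I₂) − I₃, acylindricity *c* = I₁ − I₂,
  relative shape anisotropy
  k² = 4(1 − 3(I₁I₂+I₂I₃+I₃I₁)/(I₁+I₂+I₃)²), semiaxes
  L₁ = √{(5/2)(I₂+I₃−I₁)} (and cyclic), local density = 1/V_cell;
* the characteristic-crystallographic-element (CCE) norm ε_j^X: a per-site
  scalar that is zero exactly for a perfect X-type first shell (X = hcp,
  fcc, fivefold), rigid-motion invariant, and strongly discriminating
  between structures; sites with ε^X < ε_thres = 0.245 count toward the
  order parameter S^X, and the crystallinity is τ^c = S^hcp + S^fcc;
* the pair correlation g(r) with a contact-value extrapolation (the
  hard-sphere compressibility factor follows as Z = 1 + 4φ g(σ⁺));
* the flipper statistic: the fraction of interior spheres that can rotate
  ±dφ about the axis through their bonded neighbours without overlap — a
  proxy for local translational entropy.

## Worked example

Generate a dilute 20-chain system with uniform chain lengths, compress it
above the melting point, run the engine, and classify the final frame:

```r
library(polypack)

ens <- ensemble_spec("uniform", N_av = 12, Delta = 0.5)
sys <- make_dilute_chains(20, ens, phi = 0.05, seed = 3)
sys
#> chain_system: 240 spheres in 20 chains (lengths 6..16), phi = 0.0500

dense <- compress_system(sys, 0.56, run_spec(1, seed = 4, ensemble = ens),
                         relax_steps = 1200, max_cycles = 1e5)
res <- run_mc(dense, run_spec(2e5, record_every = 5e4, seed = 5,
                              ensemble = ens))
res$stats[, 1:3]
#>                   move attempted accepted
#> 1            reptation     19828        0
#> 2         end_rotation     19811      364
#> 3          config_bias     40105      237
#> 4 interchain_reptation     50090       12
#> 5   internal_libration     69737    19175
#> 6                  sEB       208       12
#> 7                 sIEB       221        0
#> 8         displacement         0        0

cl <- classify_frame(res$system)
unlist(cl$order[c("S_hcp", "S_fcc", "tau_c")])
#>       S_hcp       S_fcc       tau_c
#> 0.008333333 0.012500000 0.020833333
```

The acceptance table shows the expected density behaviour at
φ = 0.56: insertion-type moves (reptation, configurational-bias regrowth)
are nearly frozen, internal libration carries the local relaxation, and
the connectivity-altering sEB move accepts at a *higher* rate (5.8%) than
the local insertion moves — densification favours bond-swapping over
displacement, which is exactly why the simplified end-bridging pair is in
the mix.  The classification reports ~2% of sites with hcp- or fcc-like
first shells, the amorphous baseline level; over ~10¹⁰ steps at φ = 0.61
such systems order to τ^c ≈ 0.8 (see `scripts/long_run.R` for that
cluster-scale protocol).

On a perfect crystal the classifier saturates:

```r
classify_frame(make_hcp(6, 3, 2))$order$tau_c
#> [1] 1
```

A command-line wrapper for the generate / compress / simulate / analyze
pipeline is installed at `inst/cli/polypack`.

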