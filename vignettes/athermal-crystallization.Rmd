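---
title: "Simulating and detecting crystallization in athermal hard-sphere polymer packings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and detecting crystallization in athermal hard-sphere polymer packings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(polypack)
```

## The model

`polypack` simulates freely-jointed linear chains of tangent hard spheres of
uniform diameter $\sigma$ in a periodic cubic box.  The model is athermal:
the only interaction is the hard core, so every allowed configuration has
the same energy, temperature is irrelevant, and any phase transition must be
driven by entropy alone.  Tangency means every bond length $l$ satisfies
$\sigma \le l \le \sigma + \epsilon_{\mathrm{tol}}$; the default tolerance
is $10^{-8}\sigma$ (runs with $10^{-4}$ and $10^{-8}$ behave identically,
but acceptance rates of bond-forming moves depend on it, so it is
configurable).  There are no bending or torsion potentials: conformations
are restricted only by excluded volume and the bond constraints.  The
packing fraction is $\phi = n_{at}\,(\pi/6)\sigma^3/V$.  All internal
lengths use $\sigma = 1$; file I/O records $\sigma$ explicitly and rescales
on read.

Dense monodisperse hard spheres freeze at $\phi_F = 0.494$ and melt at
$\phi_M = 0.545$; the interesting chain physics happens between the melting
point and the maximally random jammed (MRJ) density, which is why the
compression targets in the examples are $\phi = 0.56\ldots0.61$.

## The Monte Carlo engine

One MC step is one attempted move, drawn from a seven-move mix with attempt
probabilities (reptation 10%, end rotation 10%, configurational-bias end
regrowth 20%, inter-chain reptation 25%, internal libration 34.98%,
simplified end-bridging sEB 0.1%, simplified intramolecular end-bridging
sIEB 0.1%).  The printed percentages sum to 100.18; `move_mix()` keeps the
printed relative weights and normalizes the total to exactly 1.  Local
moves use the multiple-trial (Rosenbluth) pattern: $k$ trial positions per
displaced site, chosen uniformly among the feasible ones and accepted with
the ratio of new to old Rosenbluth weights.  `cb_schedule()` raises $k$
with density (10 below $\phi = 0.45$, 30 below $0.58$, 50 above), because
open volume becomes exponentially harder to hit.

The connectivity-altering moves exchange monomers between chains without
displacing trimers: an end sphere "attacks" a nearly tangent interior
sphere of another chain (sEB) or of its own chain (sIEB), one bond adjacent
to the attacked sphere is deleted, the new end-interior bond is formed, and
the attacked sphere is regrown on the exact circle tangent to both of its
new neighbours with $k$ trials.  Because exactly tangent acceptor pairs
essentially never exist at a $10^{-8}$ tolerance, candidates are collected
from a search shell `r_search` (default $10^{-2}\sigma$) beyond tangency.
The forward/reverse proposal probabilities of the candidate and side
selection are not included in the acceptance; with the Rosenbluth ratio of
the circle regrowth and the chemical-potential weight this is an
approximation to detailed balance that we verify empirically through the
stationarity of the length distribution (below).  The exact
superdetailed-balance bookkeeping of the original end-bridging literature
is a known, documented refinement point.

Chains of length one are driven by displacement moves plus multi-trial
box-wide reinsertion; this monomer mode samples the same equilibrium
ensemble as event-driven molecular dynamics for every static observable
used here, which is what the package needs from it.  Displacement and
libration amplitudes auto-tune to a 30-50% acceptance window.

### Chain-length ensembles and chemical potentials

Simulations conserve $n_{at}$, $n_{ch}$ and $V$, so the mean chain length
is pinned at $n_{at}/n_{ch}$ and polydispersity is controlled by relative
chemical potentials $\mu^*_N$ entering the acceptance of the
length-changing moves.  Two targets are provided: uniform on
$[N_{av}(1-\Delta), N_{av}(1+\Delta)]$ and a most-probable (Flory)
distribution $P(N) \propto p^{N-N_{min}}$ with $p$ solved from the mean.
For an ideal dilute system the configurational weight of a length
composition is independent of the composition, so the analytic profiles
(flat for uniform; $\mu^*_N = (N-N_{min})\ln p$ for Flory) already give the
right stationary shape up to $O(1/n_{ch})$ composition-constraint
corrections: both tails slightly suppressed, the mean slightly enhanced.
For the uniform target (symmetric, narrow) these corrections are
negligible; for the geometric Flory shape they are detectable with $10^4$
samples, and `calibrate_mu()` removes them by a short stochastic iteration
$\mu_N \mathrel{+}= \eta \log(\mathrm{target}_N/\mathrm{observed}_N)$,
after which the profile is frozen.  Generation with `make_dilute_chains()`
conditions the drawn composition on $\sum N = n_{ch} N_{av}$ so the pinned
mean coincides with the target mean.

### Compression

`compress_system()` alternates MC relaxation with isotropic shrink
attempts.  A shrink by factor $f$ rescales the box and repositions every
chain rigidly: the first sphere moves affinely with the box
($\mathbf{r} \to f\mathbf{r}$) and the rest of the chain translates with
it, leaving all intra-chain geometry untouched.  Any resulting overlap
rejects the attempt, which is retried after further relaxation.  The
shrink amplitude adapts (up 25% on acceptance, down 30% on rejection,
capped at 5%), so the protocol automatically takes the largest overlap-free
step the instantaneous minimum gap admits; near the target this makes the
compression rate track the collision rate of the closest pair, the same
limiting behaviour as event-driven compaction schemes.  The
generation-protocol independence check of the source methodology is
available as `split_chains()`: splitting every chain of an $N_{av}=24$
configuration in half yields an $N_{av}=12$ configuration whose
observables must match freshly generated ones.

## Local-structure descriptors

### Voronoi cell shape

`tessellate()` computes exact periodic Voronoi cells by sequential
half-space clipping, starting from the Wigner-Seitz cube of the site's own
periodic images and cutting with bisector planes of neighbouring images,
nearest first, until no image can reach the farthest vertex.  Cells tile
the box to $10^{-8}$ relative volume, which also pins each frame's mean
local density $n_{at}/\sum_i V_{cell,i}$ (the harmonic mean of the per-site
inverse cell volumes) at $n_{at}/V$.

Each cell is summarized by the inertia tensor of its vertices, treated as
equivalent unit point masses about their centroid,
$\mathbf{I} = \frac{1}{n_{ver}}\sum_i (r_i^2\,\boldsymbol\delta -
\mathbf{r}_i\mathbf{r}_i)$, with eigenvalues $I_1 \ge I_2 \ge I_3$.  From
these, semiaxes $L_1 = \sqrt{\tfrac52(I_2+I_3-I_1)}$ (and cyclic),
asphericity $b = \tfrac12(I_1+I_2) - I_3$, acylindricity $c = I_1 - I_2$,
and relative shape anisotropy
$k^2 = 4\bigl(1 - 3\,(I_1I_2+I_2I_3+I_3I_1)/(I_1+I_2+I_3)^2\bigr)$.
Because vertex coordinates are kept in $\sigma$ units (not normalized by
cell size), $b$ and $c$ carry units of $\sigma^2$; this is the convention
under which amorphous cells show $b \approx 2\ldots3$ and well-ordered
cells $b \lesssim 1$, and it is isolated in one place so a different
normalization is a one-line change.  All three measures shrink toward zero
as the local environment becomes more symmetric; for point sets obeying
the triangle condition $I_1 \le I_2 + I_3$ the anisotropy satisfies
$0 \le k^2 \le 1$, with 1 attained only by collinear vertex sets.

A fact worth stating explicitly because it is easy to guess wrong: the
*ideal* trapezo-rhombic dodecahedron (the hcp Voronoi cell) has an exactly
isotropic vertex inertia tensor, just like the rhombic dodecahedron (the
fcc cell) — its upper half has $C_{3v}$ symmetry, so its quadrupole is
transversely isotropic, and the mirrored lower half then contributes the
same tensor as the inverted one.  Both ideal cells therefore have
$b = c = k^2 = 0$, and the shape measures distinguish hcp from fcc
environments only through their *noisy* cells (where the hcp cell's
threefold axis still forces $c \to 0$ faster than $b$).  Site-resolved
crystal identification is the job of the CCE norm, not of $b$, $c$, $k^2$.

### The characteristic-crystallographic-element (CCE) norm

For a site with first-shell vectors $\mathbf{u}_i$ (the 12 nearest
minimum-image neighbours, directions scaled by $d_i/\bar d$ so the norm
sees both orientational and radial deviations) and a reference structure
$X$ with ideal shell $\{\mathbf{s}_i\}$ and distinguishing point-symmetry
operations $\{g_k\}$:

$$\varepsilon^X = \min_R \sqrt{\frac{C(\mathbf{u}, R\mathbf{s}) +
\sum_k C(R g_k R^\top \mathbf{u}, \mathbf{u})}{12\,(1+m)}}$$

where $C(\cdot,\cdot)$ is the optimal-assignment (Hungarian) sum of squared
differences.  The first term anchors the shell to the template; the second
measures how well the shell maps onto *itself* under the structure's
characteristic symmetry elements — the basal mirror and $\bar 6$ axis for
hcp, a fourfold axis for fcc, the fivefold rotation and $S_{10}$
rotoreflection for the icosahedral motif.  The rotation is minimized by
iterative closest point (assignment + Kabsch) from a deterministic
low-discrepancy set of starting orientations, refined by Nelder-Mead on
the full objective; the minimizer is deterministic, so norms are exactly
reproducible.  $\varepsilon^X = 0$ exactly for a perfect $X$ site, the
norm is invariant to rigid motion and uniform dilation, and the perfect
cross-structure values are 0.31-0.40, comfortably above the threshold.

A site is labelled by its smallest norm when that norm is below
$\varepsilon^{\mathrm{thres}} = 0.245$; the order parameter $S^X$ is the
fraction of sites with $\varepsilon^X$ below threshold (the mass of the
norm distribution $P(\varepsilon^X)$ below the cut), and the crystallinity
is $\tau^c = S^{hcp} + S^{fcc}$.  The reference formulation of the norm
lives in a lineage of prior methodology papers; this package's
operationalization keeps its defining properties (perfect-site zero,
strong hcp/fcc/fivefold discrimination, rigid-motion invariance) but the
numerical scale of intermediate values is its own, so the printed
threshold should be read as calibrated against this implementation's
perfect-crystal cross values (distorted crystals cross 0.245 at shell
noise of roughly $0.12\sigma$), not as transferable digit-for-digit from
other codes.

### Mobility: flippers

An interior sphere is a *flipper* at amplitude $d\varphi$ if rotating it
about the axis through its two bonded neighbours by $+d\varphi$ and
$-d\varphi$ is overlap-free both ways.  The test is feasibility-only — no
move is applied — and proxies the local translational freedom, hence the
translational entropy, of the packing.  End spheres have no two-neighbour
axis and are excluded from the denominator (the reported `eligible` count
makes the convention auditable); an optional mode probes ends about a
random perpendicular axis for sensitivity analysis.  Fractions are
monotone non-increasing in $d\varphi$ by construction.

## What the generators emulate

The fixture generators stand in for the original initial-structure
pipeline: `make_dilute_chains()` grows tangent random walks at
$\phi \le 0.10$ (in place of atomistic-template seeds), and
`make_stacking()` builds exact close-packed layer sequences over A/B/C —
`ABAB` is hcp, `ABCABC` is fcc, random sequences are rhcp — in
orthorhombic-commensurate boxes so interior sites have mathematically
perfect shells (the general simulation box is cubic; the orthorhombic
option exists only because no cubic box is commensurate with a hexagonal
stacking).  `stacking_ground_truth()` labels each interior layer hcp or
fcc by whether its flanking layers repeat, which is the combinatorial
ground truth the classifier is tested against.  The icosahedral cluster
fixture provides the fivefold-symmetric environment that competes with
crystallization in dense packings.  What these fixtures do *not* emulate:
thermal disorder, crystallite boundaries, twinning, and finite
crystallites embedded in fluid — so passing the fixture suites shows
correctness of the descriptors, not that any particular simulated packing
will crystallize.

The amorphous baseline (`amorphous_baseline()`) provides random packings
at a target density by rapid compression.  Two routes exist: the default
follows the source protocol for monomer reference states — compress a
*chain* system (connectivity frustrates ordering during densification),
then delete all bonds and briefly relax — while `route = "monomer"`
compresses bond-free spheres directly.  The acceptance suite runs the
direct monomer route at $\phi = 0.61$ and finds $\tau^c \approx
0.10\ldots0.13$ across seeds: an acceptance-limited MC compression
necessarily spends on the order of $10^4$ sweeps above the melting point,
enough to anneal some local order into a monomer packing of this size.
That number should be read as the floor of this protocol, not as the
crystallinity of an ideally random packing; the chain route exists
precisely because connectivity suppresses this annealing, at roughly ten
times the computational cost of the monomer route.

## Numerical choices

* Overlap slack $10^{-12}\sigma$ in validation absorbs round-off after
  affine rescaling; the engine itself places bonds at
  $\sigma + \epsilon_{\mathrm{tol}}/2$ so round-off cannot push them out of
  the legal interval.
* Voronoi clipping classifies vertices within $10^{-9} L$ of a cutting
  plane as on-plane; a plane through existing vertices (ubiquitous in
  perfect lattices) then cuts nothing, which is what keeps the fcc cell at
  exactly 12 faces and 14 vertices.  A jitter-and-retry fallback
  ($10^{-10}\sigma$) exists for adversarially degenerate inputs.
* Eigenvalues are sorted descending with stable ties, so $c = I_1 - I_2$
  vanishes identically under symmetry-forced ties.
* The CCE rotation search uses 40 deterministic starts and 4 Nelder-Mead
  refinements; against 400-restart exhaustive searches the default agrees
  to $10^{-6}$ on distorted shells.
* Seeds: every stochastic routine takes an explicit integer seed; the
  engine RNG (Mersenne twister, 64-bit) is seeded directly, R-level
  generation uses a save/restore wrapper, and runs are bit-reproducible
  for a fixed seed and build.

## Problem sizes used by the test suite

The routine suites run at desk scale, chosen so the full suite finishes in
roughly twenty minutes on one CPU: equation-of-state checks use 256
monomers and $4\times10^6$ samples per density ($\phi = 0.1, 0.2, 0.3$;
contact values agree with the Carnahan-Starling closed form to well under
3%); length-ensemble checks use 100 chains of mean length 12 over
$3\times10^6$ steps; stacking-classifier checks use twenty random
8-layer sequences with 96 sites per layer pair; the amorphous baseline
uses the full 1200-sphere composition of the source systems across five
seeds.  The headline experiment — spontaneous crystallization of
1200-sphere chain systems at $\phi = 0.61$ over more than $10^{10}$ steps,
with $\tau^c$ rising from 0.05 to 0.83, fivefold sites vanishing, and the
asphericity / crystallinity / flipper curves transitioning in the same
step window — is orders of magnitude beyond a desk run; the script
`scripts/long_run.R` reproduces that protocol end-to-end for cluster use,
and `trajectory_report()` performs the co-location analysis on any
trajectory it produces.

## Known limitations

* sEB/sIEB acceptance omits the forward/reverse candidate-count ratio
  (documented above); length-distribution control is verified empirically
  and holds at the tested conditions.
* The CCE norm's intermediate scale is implementation-specific (see
  above); only its zeros, invariances and discrimination gaps are
  portable.
* Monomer mode uses stochastic MC dynamics; nothing dynamical (diffusion
  constants, collision kinetics) should be read from step counts.
* Boxes are cubic (orthorhombic only for stacking fixtures); no walls,
  no chain stiffness, no polydisperse diameters.
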