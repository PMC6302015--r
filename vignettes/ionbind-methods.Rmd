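---
title: "Methods: geometric zinc-site prediction and cation-binding thermodynamics"
author: "ionbind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometric zinc-site prediction and cation-binding thermodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionbind)
```

ionbind packages the computational layer of a transition-metal binding study
of an EF-hand calcium sensor protein: where in a structure a Zn²⁺ ion could
geometrically sit, what a calorimeter would measure while that ion binds,
how many ions a dialysis experiment says are bound, and how binding changes
the protein's thermal stability. This vignette records the models, the
defaults and the design decisions, so that a maintainer can see *why* the
code does what it does.

## 1. Geometric zinc-site prediction

### Model

Zinc in proteins is chelated by a small vocabulary of atoms: the side-chain
S/N/O atoms `SG, ND1, NE2, OD1, OD2, OE1, OE2, OG, OG1, OH` and the backbone
carbonyl oxygen `O`. The search treats a structure purely geometrically:

1. **Coordinator selection** — atoms with those names; `"O"` is accepted
   only from standard amino-acid residues, so ligand and water oxygens
   never masquerade as backbone carbonyls.
2. **Clique detection** — an isolated pair of oxygens cannot hold a
   divalent cation, so candidate neighbourhoods are *maximal cliques* of at
   least 3 coordinators, every pair closer than 6 Å (via
   `igraph::max_cliques`). The alternative reading — all ≥3-subsets rather
   than maximal cliques — yields the same voxel counts because counting is
   done over the union of clique members; maximal cliques are simply the
   cheaper enumeration.
3. **Density grid** — a cubic lattice (default step 0.1 Å) over the
   clique members' bounding box padded by the 3 Å chelation cap. The
   per-voxel *density* is defined here as the number of coordinator atoms
   at a distance within `[d_min, d_max]` of the voxel center, kept only
   where it reaches the clique size threshold. This is the simplest
   operational reading of "every placement supported by enough chelators";
   no angular term enters the default score, because the underlying
   coordination-angle statistics are not part of this package's inputs —
   `geometry_params()` reserves an `angle_window` hook instead of inventing
   a distribution.
4. **Van der Waals exclusion** — voxels inside any heavy atom's VdW sphere
   are removed (Bondi radii by default, overridable per element).
5. **Ranking** — surviving voxels are clustered by 26-neighbourhood
   connected components; each component is one predicted site, ranked by
   peak density, ties by voxel count, then by lexicographic peak
   coordinates.

### Parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `d_max` | 3.0 | Å | upper bound of observed Zn–chelator contacts |
| `d_min` | 1.7 | Å | clash floor: just below the shortest Zn–O/Zn–S bonds |
| `clique_pair_max` | 6.0 | Å | mutual-proximity cut for coordinator cliques |
| `clique_min_size` | 3 | atoms | fewest chelators that can plausibly hold Zn²⁺ |
| `grid_step` | 0.1 | Å | placement resolution |
| `vdw_radii` | Bondi | Å | standard compilation; no table is canonical here |

`d_min` is not a measured quantity but a guard: without it the mass of a
chelating oxygen itself would count as a feasible cation position before
exclusion is applied.

### Peak position of a site

Inside an ideal chelation shell the integer density is *constant* over a
sizeable region (every point of the sphere-intersection lens sees all the
chelators), so "the highest-count voxel" is a plateau, not a point, and any
single-voxel tie-break rule would report an arbitrary plateau corner up to
~1 Å from the geometric center. `rank_sites()` therefore reports the
**centroid of the maximal-count voxels** of a component. For symmetric
shells this estimates the true cation position to well under one grid step
(empirically ~1e-4 Å for a tetrahedral shell at step 0.1 Å), and it keeps
predictions equivariant under rigid motions to within a step. Site-to-site
*ranking* still uses the peak count itself.

A site's `extent` is the maximal pairwise distance between its voxel
centers (exact for components of up to 2000 voxels; beyond that, taken over
directional extreme points, which coincides with the exact diameter for the
convex blobs this pipeline produces). On a toy tetrahedral shell the extent
of the feasible region comes out near 5 Å — large enough, as in real
EF-hand loops, to accommodate a second cation.

### Degenerate inputs

No coordinators, no cliques, or an all-zero grid each yield an empty site
list rather than an error; an element missing from the radii table raises a
configuration error naming the element; a grid that would exceed the voxel
budget (default 4×10⁷) raises a resource error suggesting a coarser step.
Structures are analysed in the file's native frame with no symmetry
expansion — crystallographic neighbours are deliberately out of scope.

## 2. ITC simulation and fitting

### Binding models

All three models are defined by a bound-per-protein function $B(x)$ of the
free ligand concentration $x$:

* one set of $n$ identical sites: $B(x) = nKx/(1+Kx)$;
* two sets: the sum of two such terms;
* sequential $k$-site binding polynomial with stepwise macroscopic
  constants $K_1 \dots K_k$:
  $B(x) = \sum_i i\,\beta_i x^i \big/ (1+\sum_i \beta_i x^i)$,
  $\beta_i = \prod_{j\le i} K_j$. Trailing zero constants disable steps,
  which reduces the model exactly to a single site — a reduction the test
  suite checks pointwise.

Free ligand comes from the scalar mass balance
$L_\mathrm{tot} = x + P_\mathrm{tot} B(x)$, solved by a safeguarded Newton
iteration (bisection fallback, relative tolerance 10⁻¹³); the left side is
strictly increasing, so the root is unique. The solver is cross-checked
against plain bisection in the tests.

### Cell bookkeeping and heats

The overflow cell uses the discrete dilution form: each injection of $dV$
scales the protein total by $(1-dV/V_0)$ and updates the ligand total as
$X_i = X_{i-1}(1-dV/V_0) + X_\mathrm{syr}\,dV/V_0$. The discrete form (not
the exponential) matches per-injection peak integration; at 2 µL into
200 µL the difference is below 0.1%. Cumulative heat is
$Q_i = V_0 M_t(i) H(x_i)$ with $H$ the enthalpy-weighted occupancy, and the
reported per-injection heat applies the displaced-volume correction
$\Delta Q_i = Q_i - Q_{i-1} + \frac{dV_i}{V_0}\frac{Q_i + Q_{i-1}}{2}$,
normalised per mole of injectant. For a single site class this reproduces
the classic closed-form cumulative-heat expression to 10⁻⁸ relative — an
oracle kept independent in the test suite. Syringe refills are represented
by simply continuing the injection schedule; the first injection is kept by
default (no discard heuristic). Competition titrations are fitted as
apparent constants under the same models, with the competitor recorded as
protocol metadata — the package deliberately does not implement a ternary
competitive model, because the quantities it reproduces are apparent
constants.

### Fitting

`fit_isotherm()` minimises unweighted squared residuals with
Levenberg–Marquardt (`minpack.lm::nls.lm`). Site numbers and association
constants are optimised on the log scale; the optimiser is multi-started
(default 8 starts) with association constants spread over 10³–10⁹ M⁻¹,
because the sequential-model surface is multi-modal. Standard errors come
from the local quadratic approximation, delta-method mapped back to the
natural scale. Two-sets fits are reported with site classes in ascending
affinity so the "high-affinity constant" is always `k_a2`. A flat isotherm
is flagged `converged = FALSE` rather than raising. `derive_thermo()`
applies $K_d = 1/K_a$, $\Delta G = -RT\ln K_a$
($R = 1.98720\times10^{-3}$ kcal K⁻¹ mol⁻¹) and
$\Delta S = 1000(\Delta H-\Delta G)/T$.

## 3. Equilibrium dialysis and the Hill fit

At equilibrium the free metal concentration is equal on both sides of the
membrane, so bound-per-protein is
$(\mathrm{total}_\mathrm{protein\ side} - \mathrm{total}_\mathrm{buffer\ side})/P$.
Negative computed values — noise near zero binding — are clipped to zero
and flagged rather than propagated. The Hill fit
$B(f) = B_\mathrm{max} f^h/(K^h + f^h)$ treats the Hill coefficient as a
free parameter (multi-started over $h \in \{0.5, 1, 2, 4\}$), since the
coefficient used in the original curve is not recoverable from a printed
figure; `fix_h = 1` is available when a hyperbolic fit is wanted.

## 4. Thermal unfolding

Emission spectra are fitted with the Siano–Metzler log-normal band (peak
position, height, FWHM, asymmetry > 1; Gaussian in the symmetric limit),
applied on the wavelength axis, which is the axis the data arrive on.
Melt curves are analysed two ways:

* **Boltzmann fit** of
  $y(T) = N(T) + \frac{D(T)-N(T)}{1+e^{(T_m-T)/s}}$ with linear native and
  denatured baselines; by construction the fitted value at $T_m$ is the
  baseline midpoint.
* **Derivative reading**: 5-point moving average (matching ~0.1–0.5 K
  sampling at 1 K/min scan rates), central differences, the same moving
  average applied to the derivative trace (an unsmoothed argmax is
  dominated by point noise), and $T_m$ at the extremum of $|dy/dT|$ —
  sign-agnostic, so either orientation of a two-wavelength intensity ratio
  works; ties resolve to the lowest temperature. Aggregation onset from
  light scattering uses the *signed* maximal derivative, so only a rising
  signal counts. On clean two-state curves the derivative reading agrees
  with the Boltzmann $T_m$ to within the sampling step; on noisy single
  scans it is intrinsically a grid-resolution, higher-variance estimate,
  so cross-method agreement is asserted on medians over replicates.

Flat traces yield explicit no-transition / no-aggregation flags.
Temperatures are degrees Celsius externally and kelvin only inside the
thermodynamic relations.

## 5. The synthetic-data generator

Every consumer of measured data has a generator with recorded ground
truth, and the generators' defaults *are* the study conditions:

* **ITC**: 200 µL cell at 25 µM protein, forty 2 µL injections, syringe
  375–750 µM depending on the ion; Gaussian noise with sd equal to 1% of
  the isotherm's peak molar heat (integration noise model).
* **Dialysis**: 8 log-spaced free-metal points over 2–150 µM around a 5 µM
  protein; the protein-side total carries Gaussian noise with sd equal to
  5% of that well's bound concentration — a fractional error on the
  binding signal, which is the quantity a bound-vs-free curve reports.
  (Noise proportional to the *total* metal concentration would be a
  different instrument model under which the high-free-metal difference
  measurement carries almost no information; with it no estimator recovers
  the half-saturation point reliably at these levels.) With only 6 wells
  the Hill exponent and the half-saturation point trade off, so the
  free-$h$ fit is noticeably more variable than the hyperbolic
  (`fix_h = 1`) fit on sparse designs — one reason `fit_hill()` exposes
  `fix_h`.
* **Melts**: 15–95 °C at 0.5 °C sampling, transition width 3 °C, λmax
  baselines 338 → 352 nm for the apo-like curve; noise sd 1% of the
  baseline separation.
* **Toy structures**: chelating carboxylate oxygens (named `OD1` on `ASP`
  residues, one per residue, so coordinator selection is exercised rather
  than bypassed) at ideal tetrahedral or octahedral geometry 1.8–3.0 Å
  around a recorded center, plus decoy carbons at 5–12 Å.

Noise is additive Gaussian everywhere: the simplest model consistent with
integrated-peak and photon-count observables at these signal levels. What
the generators do *not* emulate: baseline drift and heats of dilution in
thermograms, Donnan effects in dialysis, aggregation tails and instrument
response in melts, and conformational heterogeneity in structures. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated noise model, not robustness to every artefact of real data.

## 6. Problem sizes and reproducibility

Recovery checks run 20 replicate datasets per experiment (100 structures
for site localisation), sizes chosen to give stable medians while keeping
the whole suite comfortably fast on a laptop. All stochastic paths take
explicit integer seeds; a generator called twice with the same seed is
bit-identical. `scripts/acceptance.R` re-derives the headline quantities
end to end from a single seed.

## 7. Known limitations

* The site score is distance-only; angular preferences and element-specific
  chelation strengths are not modelled.
* Sequential-model parameters are weakly identified when a step's c-value
  is very large or very small; the multi-start reduces but cannot remove
  this, which is why recovery is asserted on medians.
* The two-sets fit can swap site classes on pathological data even after
  canonicalisation (identical fitted affinities).
* The Hill analysis assumes the protein-side free concentration equals the
  buffer-side total; charged-membrane corrections are out of scope.
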