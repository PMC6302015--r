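# ionbind

Tools for characterising divalent-cation (Zn²⁺/Ca²⁺/Mg²⁺) binding to
EF-hand calcium sensor proteins. Neuronal calcium sensors carry three
functional EF-hand loops whose occupancy by Ca²⁺, Mg²⁺ and — transiently —
Zn²⁺ switches the protein between conformers with different stability and
target affinity. Characterising that interplay takes four kinds of
computation, all of which this package implements with a ground-truthed
synthetic-data generator so every stage is testable without measurements:

* **Geometric zinc-site prediction** in a protein structure. Candidate
  chelator atoms (side-chain S/N/O — `SG ND1 NE2 OD1 OD2 OE1 OE2 OG OG1
  OH` — and backbone carbonyl O) are grouped into cliques of ≥ 3 atoms
  mutually within 6 Å; a 0.1 Å grid counts, at every voxel, the chelators
  within the 3 Å coordination cap; sterically excluded voxels are removed
  (Bondi van der Waals radii) and the surviving density is clustered into
  ranked sites. `predict_metal_sites()`.
* **ITC simulation and fitting** under the three standard binding models —
  one set of sites (B(x) = nKx/(1+Kx)), two independent sets, and the
  sequential binding polynomial (B(x) = Σᵢ i βᵢxⁱ / (1+Σᵢ βᵢxⁱ), βᵢ =
  ∏ⱼ≤ᵢ Kⱼ) — with exact overflow-cell dilution bookkeeping, mass-balance
  free-ligand solving, multi-start Levenberg–Marquardt fitting and
  thermodynamic post-processing (K_d = 1/K_a, ΔG = −RT ln K_a,
  ΔS = 1000(ΔH−ΔG)/T). `simulate_isotherm()`, `fit_isotherm()`,
  `derive_thermo()`.
* **Equilibrium-dialysis analysis**: paired-chamber totals to
  bound-per-protein stoichiometry and a Hill fit
  B(f) = B_max·fʰ/(Kʰ+fʰ). `bound_from_well()`, `fit_hill()`.
* **Thermal-stability analysis**: log-normal emission-spectrum fitting,
  Boltzmann sigmoid melts with sloping baselines, derivative-based T_m
  from intensity-ratio scans, and aggregation onset (T_agg) from light
  scattering. `fit_boltzmann()`, `tm_from_ratio_derivative()`,
  `tagg_from_scattering()`, `fit_lognormal_spectrum()`.

See `vignettes/ionbind-methods.Rmd` for the models, defaults and design
decisions.

## Worked example

Simulate a zinc titration of a 25 µM protein cell (forty 2 µL injections
of 500 µM ZnCl₂) under a two-sets-of-sites model, refit it, and derive the
thermodynamics of the high-affinity class:

```r
library(ionbind)

prot  <- titration_protocol(cell_protein_conc = 25e-6,
                            syringe_ligand_conc = 500e-6)
truth <- two_sets_params(0.7, 2.3e5, -11.8,   # n1, Ka1 (1/M), dH1 (kcal/mol)
                         2.0, 9.2e6, -7.3)    # n2, Ka2, dH2
data  <- gen_itc_dataset(prot, truth, noise_frac = 0.01, seed = 42)
fit   <- fit_isotherm(data$isotherm, prot, "two_sets", seed = 42)
fit
#> ITC fit (two_sets): rss 0.2903 over 40 points, converged
#> List of 6
#>  $ n1  : num 0.766
#>  $ k_a1: num 218965
#>  $ dh1 : num -11.1
#>  $ n2  : num 1.96
#>  $ k_a2: num 16484219
#>  $ dh2 : num -7.3
derive_thermo(fit$params$k_a2, fit$params$dh2)
#> Ka 1.648e+07 /M  Kd 6.066e-08 M  dG -9.85 kcal/mol  dH -7.30 kcal/mol  dS 8.55 cal/K/mol (T 298.15 K)
```

One noisy titration recovers the site counts to a few percent and the
association constants to well within their identifiability at this
c-value (the high-affinity constant is steep-limited, hence its larger
spread; medians over replicates centre on the generating values — see the
test suite).

Site prediction on a generated toy structure — a tetrahedral shell of four
carboxylate oxygens 2 Å around a recorded centre amid 30 decoy carbons:

```r
toy   <- gen_toy_structure("tetrahedral", shell_radius = 2.0, decoys = 30,
                           seed = 42, path = "toy.pdb")
sites <- predict_metal_sites(load_structure("toy.pdb"))
sites
#>   rank        peak_x        peak_y        peak_z peak_density   extent voxel_count
#> 1    1 -5.363528e-05 -5.363528e-05 -5.363528e-05            4 4.961854       12149
```

One site is found; its peak sits 9×10⁻⁵ Å from the true centre, all four
chelators are in range at the peak (`peak_density 4`), and the feasible
region spans ~5 Å — roomy enough, as in real EF-hand loops, to host a
second cation.

A command-line wrapper over the same functions is installed at
`inst/cli/ionbind` (`predict-sites`, `simulate-itc`, `fit-itc`, `thermo`,
`fit-dialysis`, `fit-melt`, `fit-spectrum`, `generate`).

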