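# bindkit

Quantitative analysis of direct protein–protein binding, built around the
three experiment types used to characterise the interaction between the
membrane palmitoylated protein MPP1 and the raft-marker proteins
flotillin 1 and flotillin 2:

1. **SPR kinetics.** Surface plasmon resonance sensorgrams from an analyte
   concentration series are double-referenced (buffer blank, then
   empty-surface trace) and fit *globally* — all curves share one set of
   kinetic parameters — to a 1:1 Langmuir binding model, optionally with a
   mass-transport step. The model during association at analyte
   concentration *C* is

   ```
   dR/dt = k_on · Cs · (Rmax − R) − k_off · R
   Cs    = (k_t · C + k_off · R) / (k_t + k_on · (Rmax − R))
   ```

   where `R` is the response (RU), `Rmax` the binding capacity, and `k_t`
   the mass-transport coefficient (`k_t → ∞` recovers plain Langmuir
   kinetics, for which the closed form is used). The equilibrium
   dissociation constant is `K_D = k_off / k_on`. Residuals are screened
   for systematic divergence from the model with a Wald–Wolfowitz runs
   test and lag-1 autocorrelation, and replicate series aggregate into
   mean ± SD tables.

2. **MD contact mapping.** Two-chain coordinate frames (PDB, single or
   multi-MODEL) are post-processed into residue-level cross-molecule
   contact sites: a residue pair is flagged in a frame when ≥ 3 atoms of
   one residue lie within 3 Å of the partner residue. Flags aggregate
   across frames into sites with occupancy, a Coulomb electrostatic score
   (`332.0636 · q_i q_j / (ε · r_ij)` kcal/mol summed over cross-molecule
   atom pairs within 12 Å), and a relative stability screen: sites whose
   score magnitude falls below 10 % of the largest are classed unstable.

3. **CD spectra.** Raw circular dichroism signal (mdeg) is converted to
   molar ellipticity per residue, `θ = CD / (10 · n · p · c)`, with `n`
   residues, path length `p` (cm) and molar concentration `c` (mol/L).

A synthetic-data module generates every input with a machine-readable
ground-truth record — sensorgram series with noise/drift/bulk-jump
structure, toy two-chain complexes with planted interfaces — so the whole
pipeline is testable without instrument data.

## Worked example

Simulate the strongest published interaction (full-length MPP1 binding
flotillin 1: k_on = 4.5e4 1/(M·s), k_off = 1.03e-3 1/s, K_D ≈ 22.9 nM) at
six concentrations, double-reference, and fit globally:

```r
library(bindkit)

truth    <- rate_constants(k_on = 4.5e4, k_off = 1.03e-3,
                           Rmax = 100, k_t = 1e8)
scenario <- sensorgram_scenario(truth, seed = 42)   # 50-2000 nM, 0.5 RU noise
series   <- reference_series(generate_sensorgram_series(scenario))
fit      <- fit_global(series, model = "two_compartment")
fit
#> Global two_compartment fit: 6 curves, chi2 = 4377 RU^2
#>   k_on  = 4.494e+04 (SE 1.7e+02)
#>   k_off = 0.001028 (SE 2.7e-06)
#>   Rmax  = 99.99 (SE 0.1)
#>   k_t   = 1.1e+08 (SE 1.6e+07)
#>   K_D   = 2.287e-08 M (22.87 nM, SE 0.064 nM)
#>   residual diagnostics: 0/6 curves flagged systematic
```

The fitted K_D (22.87 nM) recovers the generating 22.9 nM to 0.1 %; the SEs
come from the Jacobian at the least-squares solution; no curve shows
systematic residual structure. `kinetics_catalog()` returns all eight
published parameter sets (K_D 22.8–982 nM) for the same exercise.

Contact mapping on a synthetic 20-frame trajectory with two planted
interface sites, one strong (unit charges) and one weak:

```r
toy   <- generate_toy_complex(planted_interface(data.frame(
  res_A = c(2, 6), res_B = c(2, 6), n_within = c(3, 4),
  distance = c(2.5, 2.8), occupancy = c(0.9, 0.2),
  q_A = c(1, 0.05), q_B = c(-1, -0.05))), n_frames = 20, seed = 7)
sites <- classify_stability(
  score_sites(aggregate_sites(toy$trajectory), toy$trajectory))
#>   residue_A_number residue_B_number occupancy electrostatic_score stable
#> 1                2                2       0.9          -133.88      TRUE
#> 2                6                6       0.2            -0.30     FALSE
```

Both planted sites are recovered at their scheduled occupancies; the weak
site scores below 10 % of the strongest magnitude and is classed unstable.

CD conversion: `molar_ellipticity(10, n = 100, p = 0.1, c = 1e-5)` returns
`1e4` deg·cm²·dmol⁻¹.

A command-line front end covers the same pipeline
(`Rscript -e 'bindkit::bindkit_cli()' fit --config cfg.json --out report.json`;
subcommands `simulate`, `reference`, `fit`, `summarize`, `contacts`,
`cd-convert`, `make-fixtures`).

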