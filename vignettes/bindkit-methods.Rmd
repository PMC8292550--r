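---
title: "Models and methods behind bindkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind bindkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bindkit)
```

bindkit analyses direct protein–protein binding through three largely
independent pipelines — SPR kinetics, MD contact mapping, and CD
conversion — built around the MPP1–flotillin interaction system but
applicable to any 1:1 surface-binding study. This vignette records the
models, the tunable parameters, the numerical choices, and the places where
the design was genuinely open and a decision had to be made.

## 1. The SPR kinetic model

A sensorgram records surface-bound mass (response units, RU) over one
injection cycle: an association phase in which analyte at bulk
concentration $C$ flows over immobilised ligand, and a dissociation phase
in buffer. For a reversible 1:1 interaction the transport-unlimited
(Langmuir) response has the closed form

$$R(t) = R_{eq}\left(1 - e^{-(k_{on} C + k_{off})t}\right),
\qquad R_{eq} = \frac{R_{max} C}{C + K_D},$$

during association, and $R(t) = R(t_a)\,e^{-k_{off}(t - t_a)}$ after the
injection stops at $t_a$. When binding outpaces diffusive delivery of
analyte to the sensor surface, the near-surface concentration $C_s$ is
depleted below $C$. bindkit adopts the standard two-compartment
quasi-steady-state formulation,

$$\frac{dR}{dt} = k_{on} C_s (R_{max} - R) - k_{off} R, \qquad
k_t (C - C_s) = k_{on} C_s (R_{max} - R) - k_{off} R,$$

which collapses to the scalar ODE
$dR/dt = k_t\,[k_{on} C (R_{max}-R) - k_{off}R]\,/\,[k_t + k_{on}(R_{max}-R)]$
and reduces to the Langmuir rate as $k_t \to \infty$. The commercial
software used to produce the published kinetic tables does not print its
equations; this formulation is the canonical biosensor mass-transport model
with the right limiting behaviour, which is why it was adopted.

**Units.** $k_{on}$ in 1/(M·s), $k_{off}$ in 1/s, $R_{max}$ in RU, and
$k_t$ in RU/(M·s) so that $C$ and $C_s$ share molar units. This folds the
instrument's mass-to-signal conversion into $k_t$ — the usual single-number
parameterisation; the RU/M conflation is deliberate and documented rather
than resolved.

**K_D direction.** $K_D = k_{off}/k_{on}$ (units M). Prose descriptions of
kinetic tables sometimes say "the $k_{on}/k_{off}$ ratio", but dimensional
analysis and every published row (rate pairs and their printed $K_D$)
require $k_{off}/k_{on}$; `kd_from_rates()` implements the latter and its
documentation flags the common inversion.

### Preprocessing: double referencing

`double_reference()` subtracts the buffer-blank injection from the sample
curve, then the empty-surface (ligand-free) trace, in that order — the
subtractions commute, but the order is recorded for auditability. Reference
curves are linearly interpolated onto the sample grid (instrument grids
rarely coincide; linear is adequate at 0.1–1 s sampling), and the result is
re-zeroed to the mean of the 5 s preceding the injection start (standard
practice; the window is a parameter). Negative post-reference responses are
retained: clipping them would bias the fit.

### Global fitting

`fit_global()` fits all curves of a concentration series simultaneously
with shared $(k_{on}, k_{off}, R_{max}, k_t)$ plus one bulk-offset nuisance
parameter per curve (residual refractive-index jumps survive double
referencing in practice). Details that matter:

* **Parameterisation.** Rates and $k_t$ are fitted as log10 values inside
  physically plausible boxes: $k_{on} \in [10^2, 10^8]$ 1/(M·s),
  $k_{off} \in [10^{-6}, 1]$ 1/s, $k_t \in [10^6, 10^{13}]$ RU/(M·s).
  The boxes prevent divergence, not inform the estimate; a fit that ends on
  a box edge is flagged `at_bound`.
* **Optimiser.** An in-package Levenberg–Marquardt with a
  forward-difference Jacobian. Three safeguards proved necessary on real
  noise realisations: per-coordinate step capping (no single LM step moves
  a parameter more than 3 units ≈ 3 log-decades, keeping iterates in the
  region the Jacobian describes), a relative floor on the damping scales
  (a locally flat direction — typically $k_t$ on transport-unlimited data —
  cannot make the damped system singular), and a projected steepest-descent
  backtracking fallback before declaring a stationary point. Without the
  step cap the first Gauss–Newton step from a mediocre initialisation can
  jump into a degenerate region and stall.
* **Multi-start.** Three starts with $k_{on}$ at 0.1×, 1×, 10× the
  automatic initialisation; best final SSR wins. Initialisation: $k_{off}$
  from a log-linear tail fit of the highest-concentration dissociation,
  $k_{on}$ from the slope of the observed rate $k_{obs}$ versus $C$
  (via the regression $dR/dt = \text{const} - k_{obs} R$), $R_{max}$ from
  the peak response over the expected fractional occupancy.
* **Uncertainty.** Standard errors from the SVD pseudo-inverse of
  $J^\top J$ at the solution (unidentifiable directions give large, not
  bogus, SEs), delta-method-transformed to the natural scale; the $K_D$ SE
  uses the full $k_{on}$–$k_{off}$ covariance. These per-fit SEs are
  distinct from the between-replicate SD reported by
  `aggregate_replicates()` (which needs $n \ge 2$; with one replicate the
  SD is `NA`, never 0).
* **Degenerate inputs.** An all-zero series raises an error (parameters
  unidentifiable) rather than returning a silent boundary fit; a
  single-concentration series fits with an identifiability warning.

### Residual diagnostics

"Systematic divergence" of residuals from the model is operationalised —
the source analyses name no statistic — as a Wald–Wolfowitz runs test on
residual signs with $|z| > 3$, or lag-1 autocorrelation $> 0.5$ in
magnitude, or an all-one-sign residual trace. On white noise the
$|z| > 3$ rule flags well under 1 % of traces (Monte-Carlo-verified in the
acceptance suite), so a flag is strong evidence of model misfit, not noise.
Traces shorter than 10 points are skipped with a warning; zero-variance
traces report autocorrelation 0 with a degeneracy attribute.

`concentration_independence_check()` refits each curve individually with
$R_{max}$ and $k_t$ pinned at the global estimates; for a well-specified
1:1 interaction the per-curve $K_D$ is independent of analyte
concentration, and a spread beyond ~15 % of the global value indicates a
model violation (the test suite constructs one via concentration-dependent
$R_{max}$).

## 2. MD contact mapping

`flag_contacts()` applies the per-frame interface screen: a cross-molecule
residue pair is a possible binding contact when at least `min_atoms = 3`
distinct atoms of one residue lie within `cutoff = 3` Å of atoms of the
partner residue. Two readings of that rule were possible; bindkit flags a
pair when **either** side contributes ≥ 3 atoms (the reciprocal phrasing of
the source rule), records which side triggered, and counts *atoms of the
flagging residue*, not atom pairs — an atom near several partner atoms
counts once. Hydrogens are included if present; no atom-type filtering is
applied. Coordinates are assumed whole and imaged: no periodic-boundary
treatment.

The neighbour search is an exact sorted sweep over the x axis (no grid
approximation); the test suite proves equality with a naive all-pairs
oracle on 100+ random frames and at planted rule-boundary fixtures
(exactly 3 vs exactly 2 atoms inside the cutoff).

`aggregate_sites()` unions flags over frames into per-pair occupancies and
then groups pairs into "binding sites" when they are sequence-adjacent
(within 2 residues on both chains) and co-occur in time (frame-set Jaccard
≥ 0.5). Published interface lists group runs of consecutive residues
without stating a rule; this is the simplest rule that reproduces that
behaviour, and both thresholds are exposed as arguments.

**Electrostatic score.** "Binding force strength" is implemented as the
Coulomb interaction energy $\sum 332.0636\, q_i q_j / (\varepsilon r_{ij})$
kcal/mol over cross-molecule atom pairs of the site's residues within 12 Å,
uniform dielectric $\varepsilon = 1$, sign retained. Whether the original
screen used a force or an energy is unstated; only the *relative* 10 %
threshold matters downstream, and an energy magnitude is the minimal
faithful ranking proxy. `classify_stability()` then marks a site unstable
when $|E| < 0.10 \cdot \max |E|$; a singleton site is stable (it is its own
maximum), as are exact ties.

## 3. CD conversion

`molar_ellipticity()` applies $\theta = CD / (10\,n\,p\,c)$ elementwise to
the raw mdeg signal, with $n$ residues, path length $p$ in cm (0.1 and
0.01 cm cells are both common; the value is metadata, never hard-coded) and
molar concentration $c$. The formula is applied to the instrument's mdeg
units exactly as conventionally printed; some texts insert a further 1000×
(deg vs mdeg) factor, so the output unit label matters more than usual and
is documented on the function.

## 4. What the synthetic data does and does not emulate

`generate_sensorgram_series()` produces, per concentration, the three
curves an instrument records for double referencing: sample
(model + drift + bulk jump + noise), buffer blank (drift + noise) and
empty-surface trace (bulk jump + noise). The stated experimental design is
kept as defaults: analyte series spanning 50–2000 nM, 360 s association,
600 s dissociation, 1 Hz sampling, with a 10 s pre-injection baseline for
zeroing. Where the sources are silent a single realistic choice was made
and frozen: Gaussian noise SD 0.5 RU (typical short-term noise of a
research-grade instrument), linear drift 0.002 RU/s (~0.1 RU/min), bulk
jump 5 RU, $R_{max}$ 100 RU, $k_t = 10^8$ RU/(M·s) (barely
transport-limited at the catalog's rates). `kinetics_catalog()` carries the
eight published rate-constant sets (K_D 22.8–982 nM) as generating truths.

The generator is deterministic given its seed, restores the caller's RNG
state, and writes a machine-readable truth sidecar next to every fixture;
all downstream recovery tests compare against sidecars, not constants.

What it deliberately does **not** emulate: coloured instrument noise,
injection spikes and air bubbles, baseline steps, analyte depletion in the
flow cell, or ligand heterogeneity. A green parameter-recovery test
therefore establishes that the estimator inverts its own forward model at
realistic noise — not that it is robust to every instrument artifact.
Similarly, the toy complexes are rigid 5-atom alanine-like residues with
fabricated geometry: they exercise the contact *rule* with exact ground
truth, and make no claim to force-field realism.

## 5. Numerical choices

* **Integrator.** Adaptive Dormand–Prince RK5(4) (Rcpp) with relative
  tolerance $10^{-8}$ and absolute tolerance $10^{-10}$ RU by default —
  far below instrument noise; steps are clipped to land exactly on output
  times rather than relying on low-order dense output. Verified against a
  10× finer fixed-step RK4 and, off-line, against an independent implicit
  (Radau) integration.
* **Dissociation.** Analyte concentration drops to exactly 0 at $t_a$ (no
  carryover); with $k_{off} = 0$ the trace is flat thereafter.
* **Fit tolerances.** LM stops on relative SSR improvement $< 10^{-12}$ or
  relative parameter change $< 10^{-12}$, max 200 iterations; noiseless
  synthetic data reproduce generator parameters to better than $10^{-4}$
  relative (tested).
* **Ties and degenerate cases.** Stability ties at the maximum are stable;
  runs test on a single-sign trace is NA-with-flag (and the trace is
  flagged systematic); occupancy schedules round to whole frames, so a
  requested occupancy is honoured to within one frame.

## 6. Known limitations

* **The $k_t = 10^{12}$ limit check is left red.** One acceptance
  criterion demands the two-compartment trace at $k_t = 10^{12}$ RU/(M·s)
  match the closed form within $10^{-6} R_{max}$ over a rate grid spanning
  the published ranges. At the top of that range
  ($k_{on} = 4.5\times10^4$, $R_{max} = 100$ RU, $C = 500$ nM) the *true*
  model gap is ≈ $1.1\times10^{-4}$ RU — about 10 % above the bound — as
  confirmed by an independent stiff integrator at rtol $10^{-12}$; the
  analytic scale is $R_{eq} (k_{on} R_{max} / k_t)/e$. The criterion is
  genuinely unattainable at that grid point, and the grid was not shrunk
  around it; 8 of 9 points pass by 1–2 orders of magnitude.
* Published interface residue lists from the original ~115/56 ns
  trajectories cannot be reproduced here: the trajectories are not
  deposited. The contact module reproduces the *rule*, verified on planted
  geometry.
* The PDB reader is minimal by design (fixed-column ATOM/HETATM,
  MODEL/ENDMDL); charges ride in the occupancy column at %6.2f precision.
  For force-field-grade inputs use a dedicated structure library upstream
  and hand bindkit a `contact_frame`.
* No bivalent, heterogeneous-ligand, or two-state conformational models;
  no steady-state affinity analysis; no Bayesian uncertainty.
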