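---
title: "Methods: lattice dynamic-FBA colony simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice dynamic-FBA colony simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`colonyfba` simulates a bacterial colony growing on an agar substrate as a
coupled reaction–diffusion / metabolic system on a regular cubic lattice.
Chemical species (glucose, acetate, oxygen) obey

$$\partial_t C = D \nabla^2 C + R(C),$$

where the reaction term is the metabolic exchange of the resident cells,
$R(C) = m\,v_C$, with $m$ the cell mass in the site and $v_C$ the per-mass
exchange flux (mmol/gDCW/hr; uptake negative). Cells are represented as
per-site mass of two phenotypes — glucose utilizers (growing aerobically or
fermentatively on glucose, secreting acetate under oxygen limitation) and
acetate utilizers (growing strictly aerobically on acetate). Mass grows
exponentially at the local growth rate, $dm/dt = v_{bm} m$, and is converted
to a volume fraction $\phi = m/(V\rho)$ with single-cell constants
$m_{cell} = 258$ fg, $V_{cell} = 1$ fL. When the total volume fraction of a
site exceeds the packing cap $\phi_{max} = 0.65$, excess mass is pushed
isotropically into non-agar face neighbors; mass crossing the domain
boundary is removed (absorbing), and mass never penetrates agar.

The exchange fluxes are not obtained by solving a linear program at every
site and step. Following the dynamic-FBA table approach, each phenotype
carries a precomputed table of FBA solutions on a 50 × 160 grid of (carbon
uptake, oxygen uptake) bounds between zero and the strain's maxima; at run
time the engine interpolates this table bilinearly at the locally available
uptake rates. Availabilities combine Michaelis–Menten saturation with the
amount actually present in the site. Tables come either from a
constraint-based metabolic model (one LP per node; `build_flux_table()`)
or from the closed-form surrogate anchored to a strain's measured
aerobic/anaerobic growth and acetate rates (`build_surrogate_table()`);
the surrogate reproduces those four anchors exactly by construction.

A regulation rule converts glucose utilizers into acetate utilizers at
sites that have been glucose-starved but acetate-rich for a sustained
period; the conversion is irreversible by default. Cross-feeding emerges
when the colony grows tall enough that glucose entering from the agar below
is consumed before reaching the top: the starved, acetate-exposed upper
cells switch phenotype and begin consuming the acetate secreted by the
fermenting interior.

# Strain parameterization

The packaged strain table (`ecoli_strains()`) holds five closely related
*E. coli* strains (B21, Crooks, MG1655, W, W3110) with chemostat-measured
glucose uptakes, growth rates and acetate rates, plus the fitted maximal
oxygen uptake and growth-associated maintenance (GAM) for each, including
the residual fit errors. `fit_strain_parameters()` reproduces the fitting
procedure against any constraint-based model: with glucose uptake fixed at
the measured values, `v_o2_max` and the aerobic GAM are chosen to minimize
the summed absolute relative error of predicted growth and acetate rates
under aerobic conditions (coarse grid, local refinement, then a
Nelder–Mead polish — the objective is piecewise linear, so a shrinking grid
alone can straddle a kink), and the anaerobic GAM by a one-dimensional
search. Note that when a strain secretes no acetate aerobically the pair
(`v_o2_max`, GAM) is only weakly identified: different combinations give
identical predictions, and the reported values then represent one point on
that ridge.

Because genome-scale reconstructions must be downloaded by the user (the
package performs no network access), the package ships a small synthetic
core network (`mini_ecoli_model()`) exhibiting the relevant physiology —
respiration, overflow fermentation, aerobic acetate catabolism, and
GAM-parameterized biomass — used in examples and tests. SBML L3 (fbc) and
BiGG-dialect JSON models are read with `read_sbml_model()` /
`read_bigg_json()`.

# Numerical scheme

*Diffusion.* Explicit forward-time central-space stepping on the cubic
lattice, with the stability bound $dt \le dx^2/(6 D_{max})$ and a default
safety fraction of 0.8. Face diffusivities are harmonic means of the two
adjacent sites' effective diffusivities — conservative across
discontinuities — where the effective diffusivity is attenuated by cell
crowding with the Maxwell-type obstruction law $D = D_0\,2(1-\phi)/(2+\phi)$.
Aqueous species diffuse only through agar and cell-occupied sites; oxygen
is gaseous and is held at its boundary value in all cell-free air (a
well-mixed-air approximation that avoids the prohibitively small time step
explicit gas-phase diffusion would demand; an explicit gas-phase mode can
be recovered by editing the species table). Dirichlet values pin the domain
boundaries: glucose at its reservoir concentration on agar boundary sites,
oxygen at air saturation, acetate at zero.

*Metabolic coupling.* The flux tables are consulted once per metabolic
interval (default 36 s). Within the interval the exchange fluxes are
co-integrated with the diffusion substeps rather than applied as one lump:
consumption enters each substep as a Michaelis–Menten sink saturating at
the interval's table-derived capacity, secretion as a frozen source, and no
substep may drive a concentration negative. This placement matters.
Oxygen's reaction timescale in a packed site (~0.3 s) is far below any
affordable metabolic interval, so a strict operator split lets oxygen
re-equilibrate unopposed between lumped reaction events: the anoxic colony
core disappears, and glucose concentrations at starved sites flicker across
the regulation threshold every interval, perpetually resetting the dwell
timer so cross-feeding never emerges. Co-integration restores the
quasi-steady profiles; the uptake law applied ($R = m\,v(C)$ with $v$
capped by Michaelis–Menten saturation) is exactly the model's stated
constraint, evaluated continuously.

*Ordering.* Each step performs: availability computation and table lookup,
biomass growth (exact exponential over the interval at frozen rates),
phenotype regulation, pushing, then reaction–diffusion substeps for every
species. Runs are fully deterministic — no random numbers are used
anywhere in the simulator.

*Pushing.* Iterative overflow relaxation: each sweep, every site above the
cap exports its excess split equally over eligible faces, preserving the
site's phenotype proportions; sweeps repeat until the largest overflow is
below $10^{-6}\phi_{max}$ (or a 10,000-sweep cap aborts the run, which
indicates a fully enclosed colony). A site with no eligible neighbor
retains its excess and has its growth suppressed for one step.

# Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| glucose: D, boundary, Km | 600, 138.8, 0.015 | µm²/s, mM, mM | agar-typical diffusivity; 2.5% w/v glucose; PTS-range affinity |
| acetate: D, boundary, Km | 1100, 0, 0.05 | µm²/s, mM, mM | small-anion diffusivity; acetate-free medium |
| oxygen: D, boundary, Km | 2000, 0.21, 0.005 | µm²/s, mM, mM | gas in water; air saturation; microaerobic affinity |
| cell constants | 258 fg, 1 fL, cap 0.65 | — | single-cell mass/volume; random close packing |
| regulation θ_glc, θ_ace, θ_O2, τ | 0.01, 0.5, 0.01 mM, 1800 s | — | see below |
| acetate phenotype: uptake max, yield, O₂ per acetate | 10, 0.025, 2 | mmol/gDCW/hr, gDCW/mmol, mol/mol | no strain-specific uptake data exist; aerobic acetate yield and full-oxidation stoichiometry |
| metabolic interval | 36 s | — | splitting-error control (halving it changes a 10-hr outcome by <1%) |

The regulation thresholds are deliberate choices where only qualitative
guidance exists ("plentiful acetate but no glucose for a significant
time"). Two of them deserve comment. First, the oxygen condition
(θ_O2 = 0.01 mM): the target phenotype catabolizes acetate *aerobically*,
so induction is gated on oxygen presence. Without this condition the
entire anoxic colony interior — glucose-starved and acetate-rich but
metabolically dormant — converts wholesale, inflating the acetate-capable
fraction several-fold and leaving most "capable" cells inactive, which
contradicts both the observed composition band and the observed high
active-consumer share. Setting `theta_o2 = 0` disables the gate. Second,
τ = 1800 s makes conversion robust against transient starvation during
colony expansion.

# The scaled study preset

Full-scale runs (multi-mm domains, 10 µm grids, 40–50 hr) are available
through `preset_full()` but are expensive. All packaged tests and the
reproduction script use `preset_scaled()`: a 0.6 × 0.6 × 0.72 mm domain
with 0.48 mm of agar at dx = 40 µm, simulated for up to 50 hr. The agar
depth is chosen so that the diffusion-limited glucose penetration depth
into a packed colony (roughly 150 µm with the default supply parameters)
is clearly smaller than the 240 µm air gap — the regime in which
glucose starvation at the colony top, and hence cross-feeding, emerges
before the colony interacts with the domain ceiling, as it does at full
scale. Geometry comparisons (wall, concave, convex) are evaluated at the
last sampled time before any compared colony touches the top boundary,
the scaled analogue of restricting analysis to the pre-boundary-effect
window.

What the scaled preset preserves: the emergence and ordering of
cross-feeding onset across strains (set primarily by aerobic growth rate),
the anoxic fermenting interior with an aerobic acetate-consuming shell,
and the direction of geometry effects being small for gentle curvature.
What it does not preserve: absolute phenotype fractions are
granularity-limited — the aerobic acetate shell is thinner than one
40 µm site, while at 10 µm resolution it spans several sites of a much
taller colony, so the capable fraction of a scaled colony is quantized in
units of roughly one part per colony height in sites. Likewise the small
domain truncates lateral expansion, which at full scale keeps most of the
colony glucose-fed; scaled fractions therefore sit above the full-scale
band, and wall geometries — where confinement competes with the wall's
extra glucose — can reverse sign relative to full scale. The
grid-convergence report reproduces the qualitative resolution behavior
(errors grow and oscillations appear as the grid coarsens beyond the
scale of the chemical gradients), but quantitative convergence of
phenotype fractions requires grids finer than this preset affords.

# Problem sizes

The test-suite and acceptance runs use: five 50-hr strain simulations and
four geometry simulations (30–40 hr) on the 15 × 15 × 18 scaled lattice,
and a four-resolution convergence study (dx = 120, 60, 40, 30 µm) over
30 hr. LP-backed flux tables in tests use reduced grids (6–10 nodes per
axis); the production default is the standard 50 × 160.

# Known limitations

* Exchange-flux magnitudes during a metabolic interval follow the
  interval-start table lookup; growth and secretion are frozen over 36 s.
* The surrogate tables interpolate between two measured operating points;
  they cannot express strain differences the anchors do not encode (for
  example, strain-specific maximal acetate uptake, for which no
  measurements exist — all strains share one configurable ceiling).
* No advection, chemotaxis, cell death, or stochastic variant.
* Checkpoint restart reproduces trajectories only from saved states at
  output boundaries, not bitwise mid-interval.
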