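---
title: "Methods: slab-model reflectivity analysis of adsorbed antibody layers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slab-model reflectivity analysis of adsorbed antibody layers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nrslab)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the design choices made where the
methodology left them open. All distances are in Ångström, SLDs in Å⁻²,
and surface densities in mg/m².

## The structural model

An adsorbed protein layer on a silicon substrate is represented as a
stack: semi-infinite Si fronting, a thin native SiO₂ oxide, N protein
slabs, and semi-infinite solvent backing (`layer_stack()`). Each slab is
homogeneous with thickness τ, protein volume fraction φ and Gaussian
interfacial width σ on its substrate side. Protein and water fill each
slab completely, so the slab SLD at a contrast with solvent SLD ρ_w is

ρ_slab = φ ρ_p + (1 − φ) ρ_w        (`mix_sld()` / `invert_sld()`)

The protein SLD ρ_p itself depends on the solvent because labile
hydrogens on amide linkages and polar side chains exchange with solvent
deuterium. We model this as linear in ρ_w between the measured pure-H₂O
and pure-D₂O values (`protein_sld_for_solvent()`); the shipped
contrast-matched (CM4) entries for COE-3, Fab and Fc reproduce the linear
interpolation to two decimals, which is why no third anchor is used.
Solvent SLDs are restricted to the physically mixable range
−0.56×10⁻⁶ (H₂O) to 6.35×10⁻⁶ (D₂O).

Derived quantities follow the standard conversions. The adsorbed amount
per slab is Γᵢ = τᵢ φᵢ MW / (V N_A) with MW the molecular weight (g/mol),
V the molecular volume (Å³) and N_A Avogadro's number; this is the only
dimensionally consistent product of the slab filling τφ (protein volume
per unit area) and the protein's mass density MW/(V N_A), and it
reproduces all six published per-slab adsorbed-amount values for this
system within their printed uncertainties (checked in the test suite).
The "average" volume fraction of a multi-slab layer is the
thickness-weighted mean. The mass-center distance is the first moment of
the volume-fraction profile with z = 0 at the oxide/solvent boundary and
z increasing into the solvent — the same axis convention used for every
profile in the package.

Degenerate inputs are made loud: φ outside [0, 1] and a slab SLD outside
the protein/water interval are errors (the latter clampable with a
warning for noisy fits via `out_of_range = "clamp"`); a zero-contrast
inversion (ρ_p = ρ_w) is an error because the data carry no
compositional information there; an all-zero profile has no mass center.

## The forward model

`abeles_reflectivity()` computes unpolarized specular reflectivity by the
optical transfer-matrix (Abeles) method. Per layer the perpendicular
wavevector is k_i = sqrt((Q/2)² − 4π(ρ_i − ρ_fronting)); complex square
roots take the branch with non-negative imaginary part so evanescent
waves decay. Interfacial roughness enters as Névot–Croce damping of each
Fresnel coefficient, r → r·exp(−2 k_i k_{i+1} σ²). The kernel is a small
C++ routine (the shape of every reflectivity package's inner loop) because
the bootstrap machinery evaluates it millions of times.

Correctness rests on closed-form oracles rather than reference data: a
single interface must match the Fresnel formula to 10⁻¹⁰ relative
(including the rough-interface variant), the total-reflection plateau
must sit at R = 1 below Q_c = 4√(πΔρ), a slab with the backing SLD must
be invisible, splitting a slab into identical halves must change nothing,
and single-slab fringes must have period 2π/τ. These hold for arbitrary
stacks, which is stronger evidence than agreement on one example curve.

A zero-thickness oxide is removed from the layer vector entirely (its
roughness moves to the first real interface) so that "no oxide" means no
extra interface rather than a phantom zero-width layer.

Resolution smearing uses a fixed 13-point Gauss–Legendre rule on ±3.5
standard deviations of a Gaussian in Q with σ_Q = (dQ/Q) Q / 2.355,
renormalized; 13 points keep the smeared curve within ~2% of a 201-point
rule even across the critical edge, at a cost proportional to the node
count. `smear()` applies the same rule to tabulated curves
(log-linear interpolation where R > 0); `abeles_smeared()` evaluates the
kernel exactly at the nodes, which is what the fitter uses. Instrument
terms are a multiplicative scale and an additive background.

Defaults a user may need to change: Si SLD 2.07×10⁻⁶, SiO₂ SLD
3.41×10⁻⁶, oxide thickness 15 Å and roughness 3 Å (literature-standard
values for polished silicon with a native oxide — the substrates behind
the published curves were characterized but their constants not printed);
dQ/Q = 0.04 (typical of the time-of-flight reflectometers this emulates);
oxide hydration 0 (solvent penetration into the oxide is exposed as an
option but off by default, since nothing in the published analysis
requires it).

## Simultaneous refinement

`fit_simultaneous()` minimizes the global normalized χ² =
Σ[(R_model − R_data)/δR]² / N over all contrasts at once. Structural
parameters (τᵢ, φᵢ; roughnesses fixed at 3 Å against the oxide and 0
between protein slabs) are shared across contrasts; only instrument terms
(background per contrast by default; scale optionally) are per-contrast.
Slab SLDs are recomputed at every evaluation from the mixing rule with
the H/D-adjusted protein SLD, which is what makes contrast co-refinement
meaningful.

The search is a seeded Latin-hypercube multistart over the parameter
bounds (defaults τ ∈ [5, 120] Å, φ ∈ [0, 0.7], background ∈ [0, 10⁻⁵],
scale ∈ [0.9, 1.1]), each start polished by bounded Levenberg–Marquardt;
the midpoint of the bounds is always included as a deterministic anchor,
and the best χ² wins. This plays the role of a stochastic global stage
followed by a local least-squares polish behind a single interface, and
is bit-reproducible given the seed. Non-convergence of the best start is
reported through the fit object and a warning, never silently.

`select_slab_count()` implements the elbow rule: fit n = 1…max slabs and
take the smallest n whose relative χ² improvement to n+1 falls below 10%.
The 10% default reproduces the two-slab choice on synthetic data shaped
like the measured layers, where one slab misfits grossly
(χ² ≈ 8–65) and a third slab buys < 1%.

`bootstrap_fit()` resamples data points with replacement within each
contrast (the unit the established reflectivity fitting packages
resample), refits from the best-fit state, and reports 68%/95% percentile
intervals for all parameters and derived quantities. Residual resampling
is available by flag. Refits are capped at 25 Levenberg–Marquardt
iterations (8 in the large calibration experiment below): starting at the
full-data optimum, refits converge well inside the cap — intervals are
identical at caps 8 and 25 on test problems — so the cap only bounds the
worst case. Failed refits are skipped and counted, and the failure count
is reported.

A calibration experiment in the test suite checks that the machinery is
honest end to end: across 50 independent synthetic experiments at the 2%
noise floor, the bootstrap 68% interval for the total adsorbed amount
(200 resamples each) covers the generating truth at a near-nominal rate.

## Ellipsometry

`defeijter_gamma()` converts an ellipsometric layer (thickness τ in Å,
film index n_f) to surface density Γ = τ(n_f − n₀)/(dn/dc) in mg/m², with
dn/dc = 0.18 mL/g for proteins at 630 nm. The Cauchy film model
n(λ) = A + B/λ² takes B in µm² (the standard ellipsometry convention —
the coefficient values A = 1.45, B = 0.003 are quoted unitless in this
field); the ambient index defaults to 1.335, aqueous buffer at 630 nm,
and is configurable because instrument software versions differ in the
value they assume. `saturation_stats()` summarizes a kinetic series by
the mean over the final 20% of the time span (configurable window) and
reports the first time from which Γ stays within 5% of that plateau.

## Conformation metrics

`density_profile()` histograms atomic mass along the surface normal;
mass is conserved under any binning, and atoms below the surface plane
are flagged but kept. The surface plane is the topmost z among
surface-tagged atoms, since distances are measured from the SiO₂
surface; an explicit `surface_z` overrides it. `contact_count()` counts
distinct protein atoms with at least one surface atom within the cutoff
(default 5 Å = 0.5 nm), with a closed boundary — an atom exactly at the
cutoff counts — via a cell list validated against an exhaustive O(N²)
loop on random configurations. No periodic wrapping is applied: the
inputs are single extracted conformations, not trajectory frames.
`rmsd()` reports raw and optimally superposed values (Kabsch rotation via
SVD, optionally mass-weighted); superposition is implemented in the
package so arbitrary weighted point sets work, and is cross-checked
against an independent structural-bioinformatics implementation in the
tests.

`compare_profiles()` puts a simulation density profile and a
reflectivity volume-fraction profile on a common grid, scales each to
unit area, and reports mass-center difference, 95%-mass extents and the
overlap integral ∫min(p₁, p₂) dz ∈ [0, 1]. Shape normalization is
deliberate: whether published simulation profiles are number or mass
densities, and their normalization, is not stated, so only shapes are
compared.

## The synthetic generator

`simulate_contrast_set()` forward-models each contrast from a known
stack, applies resolution smearing and instrument terms, and adds
Gaussian noise with σ = max(f·R, b) — a relative floor f emulating
counting statistics plus an absolute floor b where the signal approaches
background. Defaults are the study conditions this package emulates:
80 log-spaced Q points in 0.008–0.25 Å⁻¹, f = 2%, b = 5×10⁻⁷, dQ/Q = 4%,
three contrasts (D₂O, CM4, H₂O). Every dataset carries its generating
parameters as ground truth, and the recovery tests close the loop:
thicknesses are recovered within 5% and volume fractions within 0.03 at
these settings.

`make_pseudo_protein()` builds an antibody-shaped point cloud: two
Fab-like ellipsoids (47.3 kDa each) and one Fc-like ellipsoid (50.2 kDa,
total 144.8 kDa), with semi-axes following the printed fragment
dimensions (Fab minor axis ≈ 45 Å, Fc major axis ≈ 70 Å). The flat-on
layout rests all fragments on the surface with the Fab short axes along
the normal; the tilted layout anchors the Fabs and lifts the Fc along
the normal, giving a 95%-mass extent more than 10 Å larger — mirroring
the compact-versus-extended change between the two measured pH states.
The mass center is placed exactly at the requested height.

What passing these tests does and does not show: the generator shares
its forward model with the fitter, so recovery tests validate the
inference machinery (identifiability, optimizer, bootstrap calibration)
under exactly the stated noise model — they cannot detect forward-model
misspecification against real instruments (Q-dependent resolution
tables, non-Gaussian backgrounds, imperfect scale factors), nor do
uniform-density ellipsoids capture real atomic density fluctuations.
The published real-data fits are not reproducible here because the raw
reflectivity curves are not deposited; synthetic twins of the printed
layer structures are therefore the acceptance surface.

## Problem sizes and costs

Chosen so the whole suite runs comfortably on one CPU: fits use 80-point
curves × 3 contrasts (240 observations, 7 free parameters), multistart
with 16 Latin-hypercube starts (a handful of seconds); the elbow scan
fits n = 1…3; the bootstrap calibration uses 50 experiments × 200
resamples (a few minutes — the published uncertainty analysis used 1000
resamples, and the resample count is a config knob, not a method
change). The analysis drivers under `analysis/` run the same settings.

## Known limitations

* Lossless materials only: imaginary SLD (absorption) is fixed at zero,
  appropriate for Si/SiO₂/water but not for strongly absorbing isotopes.
* No polarization, magnetism or off-specular scattering.
* The H/D-exchange model is linear and instantaneous; kinetically slow
  exchange would bias per-contrast protein SLDs.
* The elbow rule is a heuristic; for marginal cases inspect the full χ²
  table it returns rather than the single chosen n.
* Bootstrap intervals are percentile intervals; no bias correction or
  acceleration is applied.
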