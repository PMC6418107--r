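---
title: "Methods: voxel FE hip load capacity, cut-points and overload risk"
author: "hipFE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel FE hip load capacity, cut-points and overload risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Overview

`hipFE` implements the computational chain behind finite-element (FE)
based skeletal health standards for the hip: quantitative computed
tomography (QCT) of the proximal femur is calibrated to equivalent
mineral density, a nonlinear voxel FE model estimates the load capacity
of the hip in single-limb stance (NLS) and posterolateral fall (NLF)
loading, a percentile of a fractured reference cohort's capacity
distribution defines a permissible outcome limit (POL), subjects are
classified against combined DXA T-score / FE operating bands, and a
Monte-Carlo probabilistic risk assessment (PRA) estimates the
probability that activity-specific applied hip loads exceed an
individual's fall load capacity.

The reference imaging cohorts behind such standards are restricted human
data. The package is therefore built around a synthetic-data module that
generates QCT-like volumes, cohorts and DXA measurements with the
statistical structure the downstream stages assume, so that every stage
is testable end to end without restricted data.

## Synthetic volumes and cohorts

The parametric femur is the union of a spherical head, a cylindrical
neck inclined at the neck-shaft angle, and a vertical cylindrical shaft,
wrapped in a uniform cortical shell (default 5 mm) with a trabecular
interior; background soft tissue is fixed at 0 mg/cc equivalent density
so the phantom intercept stays identifiable. This is deliberately not a
statistical shape model: it is the simplest geometry that exercises both
loading configurations (neck compression in stance, neck bending in a
fall). Compartment assignment uses each primitive's penetration depth,
which is exact for a single primitive and approximate near primitive
unions — adequate at the 3–5 mm voxels used throughout.

An in-field calibration phantom of three rods (0, 75, 150 mg/cc calcium
hydroxyapatite) is placed below the femur. The scanner forward model
maps density to Hounsfield units affinely with additive Gaussian noise;
rod ROIs are eroded to 45% of the rod radius to avoid partial-volume
edges. Every generator is a pure function of its inputs and a seed.

Cohort demographics (age, height, weight) are sampled from truncated
normal distributions whose means, SDs and truncation ranges follow the
published cohort summaries ("mean ± SD (range)"). Note that a normal
distribution truncated to an asymmetric published range has a mean
slightly offset from the nominal mean (about +0.4 years for the
fractured cohort); tests check moments against the analytic
truncated-normal values. Equivalent-density distributions are modelling
choices (cortical ≈ 0.90 g/cm³, trabecular ≈ 0.26 g/cm³ for the elderly
cohorts, higher for the younger astronaut cohort); the fractured-cohort
specification shifts density means down by a configurable effect
(defaults 0.05/0.06 g/cm³), encoding the lower bone quality of fracture
cases.

The record-level generator (`generateRecordCohort`) draws T-scores and
NLS/NLF capacities directly, without imaging. Its anchors are the
published summaries: the fractured reference cohort's capacity
distributions are set so that their 75th percentiles sit at the
published POL cut-points (NLS ~ N(8500, 1540), NLF ~ N(3300, 540) N);
the population cohort uses the published mean ± SD (11416 ± 2816 N NLS);
astronaut pre/post marginals follow the published astronaut table. The
latent correlation between T-score and capacity is the square root of
the published R² (0.77/0.63 population, 0.13/0.43 astronauts), so the
moderate population-level and weak astronaut-level DXA–FE agreement is
reproduced by construction. Marginals are clamped to the published
ranges; since the ranges sit well outside the 75th percentile, this
leaves the derived cut-points unaffected.

The spaceflight effect multiplies compartment densities by
`(1 - rate/100)^(days/30.44)` with small lognormal subject-level noise
(SD 0.005). Default rates are 1.5 %/month trabecular and 1.0 %/month
cortical — the published direction (trabecular loss faster than
cortical) with magnitudes as configuration, since rates are not printed
in the source material.

What the generator does *not* emulate: real anatomical shape variation,
beam hardening/scatter/kernel artifacts, DICOM protocol detail, and any
relationship between the voxel geometry and the record-level capacity
distributions. Passing tests therefore demonstrate correctness of the
computational chain under known statistical structure, not clinical
validity on real scans.

## Density calibration and cross-calibration

Phantom calibration regresses nominal rod density on observed rod-ROI
mean HU (ordinary least squares). The regression direction is
deliberate: nominal densities are exact, observed HU carries the noise.
With a noiseless scanner the fit inverts the forward model exactly and
R² = 1. The fitted affine map is applied voxelwise; re-calibrating an
already calibrated volume is an error.

Scanner cross-calibration regresses region-mean calibrated densities on
the reference scanner against the same regions on the source scanner,
using region means (phantom rods, optionally femur compartments of a
designated subject) rather than raw voxels to suppress noise. The
resulting affine map is applied at the voxel level and rewrites the
scanner ID. DXA manufacturer conversion is a configured affine map
(published conversion equations are configuration, not re-derived).

## Voxel finite-element model

`buildMesh` converts every voxel above the bone threshold (default
200 mg/cc) into an 8-node hexahedral element sharing nodes with
face-adjacent voxels, keeps the largest 6-connected component, and
assigns node sets: the distal cut plane (fully constrained) and the
femoral-head loading cap — nodes of the head sphere within a 55° angular
window about the incoming load direction (the window includes interior
head nodes, which makes the loaded cap effectively rigid; a contact
model with a deformable pad is out of scope). Load directions are
configuration, recorded per run: stance tilts the downward load 20° in
the coronal plane; the fall direction is 60° from vertical in the
posterolateral quadrant (azimuth 135°). The published analyses do not
print their directions or element sizes; these defaults are the
package's own documented choices.

Each element follows a density-dependent uniaxial four-region curve:
linear elastic with E(ρ) = 14900·ρ^1.86 MPa to the yield stress
σy(ρ) = 102·ρ^1.72 MPa, a perfectly plastic plateau, linear softening
with slope E/3, and a residual plateau at 0.3·σy (Poisson 0.3). The
constants are configuration with defaults in the range used for QCT
voxel models of the femur (~15 GPa modulus and ~100 MPa yield at
1 g/cm³); all quantitative guarantees are stated relative to the
configured curve, never to particular constants. The plateau is
parameterised by its *length* beyond the yield strain (default 0.004)
rather than an absolute end strain, so the four regions stay ordered at
every density — an absolute end strain could fall below the yield strain
of dense elements.

Nonlinearity is handled by deformation-theory secant iteration on the
von Mises (distortion-energy) effective strain: at each displacement
increment the element effective strain is mapped through the uniaxial
curve and the element modulus replaced by σ(ε)/ε, floored at 1e-4 of the
initial modulus to avoid singularity after full softening, until the
head reaction force changes by less than 0.1% between iterations.
Iterations beyond the sixth are under-relaxed (0.7 new + 0.3 old) to
damp the two-state oscillation softening elements can otherwise enter;
the fixed point is unchanged. This matches the monotone
displacement-controlled loading of the modelled protocols; no unloading
path exists, so incremental flow plasticity is unnecessary.

Displacement control prescribes all three components of the head-cap
nodes (rigid cap translation along the load direction) with the distal
face fixed; the reaction force is the sum of constraint forces on the
cap resolved along the load direction. "Force began to decrease" is
operationalised as force < (1 − δ)·running maximum with δ = 0.02 (0.05
in the coarse demo configuration), robust to float noise; the load
capacity is the running maximum. Stiffness uses full 2×2×2 Gauss
integration of trilinear hexahedra; strains for the material update are
evaluated at element centroids. The sparse symmetric systems are solved
by CHOLMOD Cholesky factorisation with the symbolic pattern reused
across iterations.

Verified analytic behaviour (all in the test suite): a single element
follows E·A·ε then plateaus at σy·A to 1e-6 relative; a two-element
series bar matches the one-element capacity; a homogeneous elastic patch
test reproduces a prescribed uniform strain field to 1e-10 and balances
external work against strain energy; capacities are invariant to rigid
translation and bitwise deterministic; scaling densities by 1.1 strictly
raises both configurations' capacities; and the oblique fall
configuration is strictly weaker than stance on the synthetic femur.

## Cut-points, operating bands and change metrics

`derivePOL` computes the q-th percentile (default 75) with linear
interpolation between closest ranks — the estimator is not specified in
the source material, so the choice is recorded in output metadata.
Applied to the synthetic fractured cohort it recovers the anchored
cut-points near 9537 N (NLS) and 3664 N (NLF).

Classification uses the boundary convention that values *at* a cut-point
pass it (matching "T-score ≥ −1.0" phrasing), while least-significant-
change (LSC) exceedance is strict. Pre-flight: T ≥ −1.0 certifies;
−1.5 < T < −1.0 enters the FE screen and certifies iff F_NLS ≥ POL;
T ≤ −1.5 is never certified. Post-flight flags: T below the −2.0 DXA
POL, capacities below the NLS/NLF POLs, and losses exceeding the LSC
(3.6% NLS, 11.3% NLF — published precision constants, used as given,
not re-derived). One POL serves both sexes. Decisions are monotone in
T-score and capacity, verified exhaustively over a grid spanning all
bands and boundary values.

`regressR2` reports the coefficient of determination of a simple linear
regression and the two-sided p-value of the zero-correlation t-test
(n − 2 df, α = 0.05), holding its nominal type-I error in simulation.
Astronaut-vs-population comparisons use Welch's t-test — the source
material does not name its test; this is an assumption and is labelled
as such.

## Probabilistic risk assessment

Applied hip loads per (mission scenario, event class) follow
configurable lognormal distributions scaled by the scenario's
gravitational loading (ISS 0, Moon 0.165, Mars 0.38, Earth 1). The
published load model is not public; the defaults are placeholders
calibrated to the published chart's qualitative anchors — low-energy
mass concentrated in 1–4 kN with an Earth-return overload probability
near 0.13 at the fall POL, and high-energy shifted upward giving near
0.67. These two probabilities are treated as qualitative anchors, not
validation values. Tail probabilities are computed in closed form, with
Monte Carlo retained as a cross-check converging at the binomial rate
sqrt(p(1−p)/n); overload probability is monotone non-increasing in
capacity, non-decreasing in the location parameter, and ordered by
gravity scaling. Only load-exceedance given an event is computed: fall
frequency and flight-induced muscular deconditioning are out of scope.

## Pipeline, reproducibility and problem sizes

`runPipeline` executes simulate → calibrate → fe → cutpoints → classify
→ pra → report from a single YAML configuration with one master seed;
per-stage seeds are derived by a documented counter scheme
((master mod 1e6)·1000 + stage index). Volumes travel as NIfTI with a
JSON sidecar for phantom ROIs and landmarks; tables are CSV; the
manifest records the configuration snapshot, seeds, package version and
MD5 digests of every output, so every number in every report is
regenerable. Rerunning a configuration reproduces identical tables.
Stage dependencies are validated up front (e.g. classification without
the FE stage is a configuration error).

The shipped demo configuration uses 5 mm voxels (≈1000 elements per
femur, chosen as the coarsest resolution that resolves the neck with
three voxels across its radius), a 0.3 mm displacement increment, a
2000-subject synthetic reference cohort for cut-point derivation and
1e5 Monte-Carlo samples for PRA. These sizes run the full chain in
about half a minute per femur on one core; they are the package's
desk-scale defaults, and all statistical checks are formulated at these
sizes.

## Known limitations

Single-material-per-voxel assignment and the rigid loaded cap make
absolute capacities resolution- and geometry-dependent; the synthetic
femur's capacities are internally consistent but not comparable to
patient-specific models. No cortical shell meshing, anisotropy,
fracture-location prediction or contact mechanics. The DXA T-score
reference population is configuration (manufacturer references are not
public); the synthetic projection yields higher areal BMD than clinical
total-hip values because the parametric femur carries a thick uniform
shell, so the demo configuration sets its reference on the synthetic
scale (mean 2.0, SD 0.25 g/cm²).
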