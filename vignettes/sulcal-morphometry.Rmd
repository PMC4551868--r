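---
title: "Surface-based sulcal morphometry with sulcushape"
author: "sulcushape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based sulcal morphometry with sulcushape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sulcushape)
```

## The problem

A cortical sulcus extracted from a T1 image (for example with BrainVISA) is a
ribbon-shaped triangle mesh: the medial surface between two opposing gyral
banks, bounded above by the brain envelope (the *top ridge*), below by the
fundus (the *bottom ridge*), and terminated by two endpoints. Sulcus-based
morphometry asks whether the shape of such a ribbon — here modelled on the
central sulcus (CS), the fold between primary motor and somatosensory cortex —
differs between clinical groups, and whether local shape covaries with
behavioural scores. sulcushape implements the full analysis chain on labeled
sulcal meshes and, because clinical MRI cohorts of this kind are not freely
redistributable, ships a synthetic sulcus generator whose every output has
analytic ground truth, so that each stage of the chain is testable end to end.

## Surface parameterization

Comparing shape *locally* across subjects requires a common coordinate system
on each ribbon. We compute two scalar fields per mesh as steady states of
surface heat diffusion — equivalently, solutions of the Laplace equation with
Dirichlet boundary data, discretized with the cotangent-weight Laplacian:

* `x`: top ridge (brain envelope) = 0, bottom ridge (fundus) = 100;
* `y`: superior end = 0, inferior end = 100, both ridges free.

The `y` boundary data are placed on the *end walls*: the boundary arcs that
join the two ridges at each extremity. When a sulcus tapers to a point the
walls degenerate to the endpoint vertices, which recovers the
point-source picture; on a ribbon with open ends, wall-based data are also
what makes the field exactly linear on a flat rectangular sheet. Two point
sources alone concentrate the gradient logarithmically around the endpoints
and cannot reproduce a near-arclength coordinate.

Both constructions are intrinsic (they depend only on the mesh metric), so
the fields are invariant under rigid motion and uniform scaling — a property
the test suite checks to 1e-6. Interior field values obey the discrete
maximum principle whenever all cotangent weights are non-negative, which
holds for the generator's right-triangle grids; meshes with degenerate
triangles fall back to uniform weights with a warning.

One property of harmonic coordinates worth keeping in mind: `y` is not an
arclength coordinate. Where the ribbon is deep (wide), the field changes
slowly, so deep regions occupy less of the [0, 100] range than their
arclength share. The depth-position profile below therefore reports depth
against the *parameterization's* y, exactly as the analysis chain uses it;
its mean over positions is closer to a harmonic mean of the depth function
than to its arithmetic mean. This is a property of heat-equation sulcal
parameterization in general, not of this implementation.

## The sulcal profile and its landmarks

The *inertial plane* of a mesh with vertices n_i is given by the barycenter
n̄ and the eigenvectors u1, u2, u3 (decreasing eigenvalues) of the covariance
A = S_c S_c' of the centered vertex matrix. u1 and u2 span the plane; the
signed distance of node i is d_i = (n_i − n̄)·u3. The *sulcal profile* is the
mean of d_i over the nodes in each of P equal y bins (position p covers
y ∈ ((p−1)·100/P, p·100/P]); empty bins are filled by linear interpolation
and flagged, and more than 20 % empty bins is an error rather than a guess.

Eigenvectors have no intrinsic sign. For signed group comparisons the sign
must be *consistent across subjects*, so when gyral-bank companions are
attached we orient u3 from the posterior toward the anterior bank; without
banks we fall back to requiring Σ d_i³ ≥ 0 (skewness rule, ties broken by
the first non-zero component). The fallback is genuinely unstable when the
profile is nearly antisymmetric along the sulcus — the skewness is then a
near-tie — which is exactly why the anatomical rule is the default whenever
the data support it.

A subtlety the synthetic generator exposes: if the planted lateral
undulation correlates with the longitudinal axis (a full-period sine does),
the inertial plane tilts and the measured profile legitimately carries the
induced linear trend. The generator's ground-truth profile is therefore
defined as the signed distance of the *ideal smooth surface to its own
continuous inertial plane* (computed by quadrature), and recovery is judged
against that — not against the raw planted function.

Landmarks L1/L2 anchor the hand-knob region across subjects: L1 is the
global maximum of the profile restricted to the central half (y ∈ [25, 75]),
L2 the first local minimum after L1 (global minimum beyond L1 if none), ties
broken toward smaller y. The upstream literature this rule stands in for
does not publish an algorithm, so this operationalization is our own and is
flagged as such; monotone or constant profiles, and landmarks falling on the
domain boundary, are marked undefined and the subject skips
reparameterization. Reparameterization maps y through the monotone
piecewise-linear map with knots (0, L1, L2, 100) → (0, L1*, L2*, 100), with
targets averaged per group (the pooled-target option exists because
per-group targets make the template correspondence group-dependent).
Template correspondence then interpolates each subject field at the template
nodes' (x, y) by barycentric interpolation in the subject's parameter-space
triangulation; out-of-domain template nodes take the nearest-parameter value
and are counted.

## The seven measures

* **average/max depth** — from the depth-position profile (DPP): at each of
  P = 100 positions, the depth is, in geodesic mode (default), the arclength
  of the y-isoparameter polyline traced across the ribbon (the level set of
  y), or in euclidean mode the straight distance between that polyline's two
  boundary endpoints (fundus and envelope). Geodesic ≥ euclidean by
  construction.
* **length** — mean of the two ridge polyline arclengths.
* **span** — bank-to-bank distance along each medial vertex normal
  (ray-cast against both bank companions), averaged over nodes with both
  intersections; the valid fraction is reported, under 50 % is an error.
* **cortical thickness** — normal-line distance between the CSF/GM and GM/WM
  interface companions, or the mean of a supplied per-vertex thickness field.
* **surface area** — sum of triangle areas.
* **sulcal profile** — as above, the local measure carried into the
  position-wise and node-wise statistics.

## Statistics

Every comparison is the same adjusted linear model: response on
[intercept, predictor, age, gender] by least squares, with the predictor
either the binary group indicator or a clinical score (the "correlation"
analyses are the score coefficient's t, i.e. a partial correlation). Two-sided
p values use Student t with n − 4 df. Multiplicity is controlled by
Benjamini–Hochberg step-up, applied across the P positions of one curve
analysis or across the template nodes of one node-wise analysis (per
hemisphere, since results are reported per hemisphere). Node-wise tests use
|d_i| by default — distance from the plane regardless of side — with a signed
option. Score correlations are evaluated inside the mask of nodes with a
significant group difference, mirroring the two-stage design such studies
use. Degenerate units (zero residual variance) are excluded from the FDR
family with a warning, and an empty mask is an explicit error, not an empty
result.

## The synthetic generator

`generateSulcus()` builds the ribbon as a tensor-product grid over
(along-sulcus, depth), displaced laterally by `profileFn` and reaching
`depthFn(y)` at the fundus, then triangulated — so length, area, depth and
profile ground truth follow by quadrature of the defining functions.
Companions are normal offsets: banks at ±span/2, interfaces at ±thickness/2
around the medial sheet. Defaults are one fixed choice modelled on
control-group central sulci in late childhood: length 98 mm; depth
7.75 + 10.5 sin²(πy/100) mm (mean 13.0, maximum 18.25); profile
3 sin(2πy/100) mm standing in for the hand-knob undulation; span 2.35 mm;
thickness 3.23 mm.

`generateCohort()` perturbs that base per subject: smooth Fourier
perturbations of depth and profile (low-order modes keep meshes smooth),
per-group depth offsets with SDs 1.28 (case) and 1.08 (control) mm, group
effects (default: case +1.33 mm depth, +0.60 mm thickness, and a
+1.2 mm mid-section profile effect on y ∈ [45, 60] with smoothstep edges),
ages near 11 years (case 130.1 ± 23.8 months, control 139.2 ± 22.7, a mild
0.01 mm/month depth slope), mostly boys (18/21 vs 15/21), and clinical
scores with case/control means 64.52/46.95 (inattention, SDs 9.27/5.63),
71.67/50.00 (hyperactivity-impulsivity), 69.19/48.40 (DSM total), the
hyperactivity score coupled to the realized mid-section profile. All
randomness flows from the spec seed; identical specs reproduce cohorts
bitwise.

`simulateProfileCurves()` is the curve-level companion used for statistical
calibration: subject curves are smooth Fourier fields (pointwise SD 1.05 mm,
8 modes, correlation length ≈ 12 positions — the anatomical scale of sulcal
undulations) plus independent per-position noise (SD 0.55 mm, representing
binning/measurement error), total ≈ 1.19 mm. Calibration at the curve level
is what makes 200-replicate type-I studies affordable; the mesh pipeline is
exercised separately.

What the generator does *not* emulate: real extraction artifacts
(topological defects, mislabeled ridges beyond the planted accessory fins),
interruptions of the sulcus, bilateral asymmetries, and any volumetric
context. Passing tests therefore demonstrate correctness of the measurement
and inference chain under known geometry and noise — not robustness to every
failure mode of upstream segmentation.

## Numerical and design choices

* Bin partition: position p covers ((p−1)·100/P, p·100/P], so halving P
  merges bin pairs exactly (count-weighted), and for P = 100 position
  indices coincide with y values.
* Level sets exactly through a vertex are nudged by 1e-9 to keep crossings
  well defined; positions with no level-set support (the y = 100 bin) take
  the nearest supported value and are flagged.
* Accessory-branch removal prunes (a) all connected components other than
  the largest-area sheet and (b) fins attached through non-manifold junction
  edges whose maximal extent from the junction is below 5 mm — the
  conventional size of random accessory folds. Fins joined manifold-fashion
  along the open boundary are not detected; the visual "right angle"
  criterion used by human raters has no algorithmic counterpart here.
* Units are millimetres throughout; meshes are assumed already spatially
  normalized upstream.
* Degenerate designs (collinear covariates, < 2 subjects per group,
  < 5 subjects total) are errors, not silent results.

## Problem sizes used by the shipped simulations

The validation suite runs the type-I study on 200 curve-level null cohorts
(n = 21 per group, P = 100) and the power study on 100 mesh-level cohorts at
a 2 × 3 mm generator grid — at that resolution a full per-subject pipeline
(generation, two harmonic solves, DPP) takes ~30 ms, which keeps 4 200
subject meshes affordable while leaving depth measurement bias identical
across groups. The demo pipeline in `scripts/acceptance.R` uses a
1.5 × 2 mm grid for the 42-subject emulated study.

## Known limitations

* The harmonic y coordinate compresses deep regions (see above); depth
  averages are therefore parameterization-weighted, as in the method itself.
* The L1/L2 rule is a stated stand-in for an unpublished operational
  definition; subjects with degenerate profiles skip reparameterization
  rather than receive guessed landmarks.
* Node-wise inference treats nodes independently under BH; no spatial
  cluster inference or permutation scheme is provided, and no diffeomorphic
  surface registration is attempted.
* With an 11-position effect window among 100 positions, amplitude 1.3 mm
  and per-position SD 1.2 mm at n = 21 per group, the BH step-up threshold
  caps per-window detection near 0.72 even under perfect within-window
  correlation — full-window recovery in the large majority of replicates is
  not achievable at these moments, and the simulations report exactly what
  is.
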