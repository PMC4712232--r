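---
title: "Model-free inverse potential mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-free inverse potential mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ipmap)
```

## Scope

ipmap is an in-silico laboratory for inverse potential mapping (IPM /
ECGI): estimating epicardial surface potentials from body-surface potentials
(BSP) through a patient-specific volume-conductor model, deliberately
*without* a-priori activation models (pre-programmed conduction pathways,
fiber orientation, or activation priors). Its two packaged experiments ask
(i) how reconstruction quality depends on electrode configuration —
surrounding arrays versus anterior patches concentrated over the heart — and
(ii) how accurately a single pacing site can be localized from an anterior
62-electrode patch.

This vignette is the package's methods account: the models, the tunable
parameters and their defaults, the numerical conventions, the genuinely open
design choices and how they were resolved, and what the synthetic testbed
can and cannot say about real recordings.

## Synthetic anatomy

`make_synthetic_anatomy()` builds six closed triangulated surfaces — torso,
two lungs, liver, spleen, heart — as superellipsoids meshed by k-fold
icosahedral subdivision, with seeded vertex jitter along normals (default
0.3 mm) standing in for segmentation irregularity. Units are mm everywhere;
conductivities S/m; times ms; potentials mV. The body frame is +x left,
+y anterior, +z cranial.

Key geometric defaults, chosen once for adult-scale realism:

* torso semi-axes (170, 110, 280) mm, superellipsoid exponent 2.5 (a
  flattened, vaguely barrel-shaped trunk);
* heart semi-axes (40, 34, 52) mm, long axis pointing left-anterior-inferior,
  centred at (25, 50, 30) so that the anterior epicardium lies roughly 20 mm
  beneath the chest wall — the normal precordial standoff. This matters: at
  an unrealistic 40+ mm standoff no anterior patch can resolve epicardial
  detail and the electrode-placement question loses its premise;
* lungs lateral-posterior, liver right-inferior, spleen left-posterior,
  with conductivities torso 0.2, lungs 0.04, liver 0.03, spleen 0.04 S/m.

Compartment invariants (closedness, outward orientation, non-degeneracy,
strict nesting, pairwise disjointness) are enforced at generation;
`validate_surface()` reports violations. If jitter breaks nesting the
anatomy is regenerated at halved jitter with a warning.

Two *independently generated grids* are used throughout the studies: sources
are simulated on grid A and the inverse is computed on grid B with different
target edge lengths, mesh seeds and jitter, so that agreement between source
and reconstruction cannot be a same-grid artefact. Reconstruction-side
comparisons map grid-A movies onto grid-B vertices by closest-point
barycentric interpolation.

## Activation model

Conduction is geometric: vertices closer than a neighbourhood radius
(default twice the mean edge length) are connected iff the connecting
segment does not cross the heart surface itself — a visibility rule
implemented with the Möller–Trumbore ray/triangle kernel, which prevents
conduction "short-circuits" across concavities. Segment endpoints are
canonically ordered so verdicts are independent of vertex numbering. Edge
delay is Euclidean distance over conduction velocity; with mm and m/s the
delay is numerically in ms. The default velocity is 0.8 m/s, a standard
working-myocardium value, overridable per vertex for region-specific
conduction.

Activation times are all-pairs shortest paths (dense Floyd–Warshall in C++;
verified in the test suite to agree exactly with Dijkstra), minimized over
stimuli. The resulting isochrones satisfy the edge inequality
t(j) ≤ t(i) + delay(i, j) exactly.

Local potentials follow a piecewise-smoothstep activation curve: resting
value before local activation, a monotone deflection of `upstroke` (2 ms) to
the plateau, plateau until the action-potential duration `apd` has elapsed,
and a monotone return over `repol` (80 ms). "Location-specific" means per
labelled region: the default study uses an atrial cap (base-side 25 % of the
long axis, APD 180 ms) and a ventricular remainder (APD 250 ms).

The default polarity is extracellular (unipolar-electrogram convention):
baseline 0 mV, plateau −25 mV, so that activated tissue is *negative* and a
pacing stimulus induces a potential minimum. This is the convention under
which minimum-based localization and the threshold test are meaningful;
transmembrane-style parameterizations (−90 → +10 mV) are affine re-mappings
of the same waveform and remain available. Correlation-based metrics are
essentially indifferent to the choice; the minima-based metrics are not.

## Forward model

The transfer matrix is computed by a surface-only boundary-element method
rather than a volumetric field solver: for piecewise-homogeneous
compartments the quasi-static problem is fully determined by its interface
potentials, which keeps the model desk-scale with a few thousand degrees of
freedom. Formulation: Laplace's equation in the torso region (organs
embedded, air outside, zero normal current through the skin) with Dirichlet
data on the epicardial surface; Green-identity collocation at mesh vertices;
flux and potential continuity across organ interfaces.

Numerical choices:

* double layers use the analytic van Oosterom–Strackee solid angle per
  triangle, lumped equally onto the three vertices; the local solid-angle
  coefficient is set from the double-layer row sums ("auto solid angle"), so
  constants are exactly in the null space and transfer-matrix rows sum to 1
  to machine precision;
* single layers integrate the linear (hat) density semi-analytically: each
  triangle is midpoint-subdivided into four, each sub-triangle contributes
  the analytic uniform 1/r integral weighted by the density at its centroid.
  A naive per-triangle lumping admits a discrete checkerboard null space
  (alternating vertex densities average to zero on every triangle) that
  makes the collocation system singular; the subdivision removes it while
  keeping constants exact;
* the assembled system is dense and solved by LU; electrode rows are
  obtained by barycentric interpolation within the containing torso
  triangle (`registration` errors beyond 0.5 mm).

The test suite validates the solver against the closed-form Legendre series
for a radial dipole in an insulated homogeneous conducting sphere (relative
L2 error below 5 % at default resolution, decreasing under refinement,
measured ~0.6 % / ~0.3 %), and checks rigid-rotation invariance and the
constant-source property.

Measurement noise is zero-mean white Gaussian at a configurable SNR
(default 21 dB), scaled per channel to the channel's variance about its
temporal mean. The variance convention (rather than the raw mean square) is
deliberate: under the Dirichlet potential convention every channel carries a
large static offset that says nothing about the ECG waveform, and an SNR
defined against it would be almost noise-free in practice.

## Inverse model

Zero-order Tikhonov only — exactly `(TᵀT + λ²I)⁻¹Tᵀ`, no gradient or
Laplacian penalties — computed via the SVD filter-factor form (the test
suite verifies equality with the normal-equations factorization to 1e-10).

One λ per recording, never per frame (temporal flicker is worse than slight
mis-regularization). λ is chosen at the corner — the point of maximal
unsigned discrete curvature — of the *recording-level* L-curve: residual and
solution Frobenius norms over up to 128 frames subsampled from the movie, on
a 60-point log grid spanning 1e-6…10 times the largest singular value. Two
refinements matter in practice:

* the calibration stack is average-referenced per frame (configurable,
  `lambda_reference`). The arbitrary-reference common-mode component is both
  huge and trivially reconstructable; left in, it dominates both L-curve
  axes and hides the corner of the spatial-pattern components that
  regularization actually needs to balance. Single-frame L-curves proved
  unstable across noise realizations and systematically under-regularized;
  the referenced recording-level corner is deterministic and lands close to
  the error-optimal λ in oracle comparisons. The reconstruction itself is
  always computed from the raw, unreferenced potentials, whose common mode
  is well observable (row sums of T are 1);
* numerically consistent data with a unique least-squares solution (residual
  at the bottom of the grid below 1e-7 of the data norm, full column rank)
  return the smallest grid value: such a curve is one smooth bend with no
  noise corner, and no regularization is needed.

A flat L-curve raises an `uninformative` error advising a fixed λ.

## Evaluation metrics

*Correlations.* `overall_correlation()` is the Pearson correlation of the
flattened node-by-frame matrices (joint space-time convention);
`correlation_map()` gives per-node temporal correlations with `NA` for
constant traces; `anterior_sample_points()` picks 16 farthest-point-sampled
anterior-facing nodes for profile plots; `ecg_consistency()`
forward-transforms the reconstruction and correlates per lead with the
recording — the only quality check available when no source truth exists.

The configuration study's headline statistic is the joint correlation over
the *anterior-facing epicardium* (outward normal with positive +y
component). An anterior electrode patch cannot observe the posterior wall;
its reconstruction there is regularization-shrunk by construction, and an
all-node statistic mostly measures that shrinkage rather than map quality.
The anterior region is fixed across layouts, and the all-node value is
reported alongside in the per-run table.

*Localization.* Each node's depolarization time is the first frame its
trace drops below its own half-depth level (resting minus half its total
deflection, resting taken as the median over the first 2 ms); nodes
reaching at least half the deepest deflection are candidates. The estimated
site is the node nearest the depth-weighted centroid of the emerging
negative region at the earliest crossing frame — the in-silico analogue of
marking the centre of the first negative spot on a colour-coded map. The
per-node criterion (rather than one tied to the global movie minimum) is
deliberately robust to the localized Gibbs-type overshoot of regularized
reconstructions, which otherwise locks detection onto wavefront-rim
ringing. Any monotone criterion aligned with activation order would do;
this one is parameter-light.

*Point spread (threshold test).* On the analysis frame, a display threshold
is tightened from the baseline (frame median) towards the pacing peak while
tracking the connected suprathreshold blob containing the peak on the mesh
adjacency. When the threshold becomes too strict the blob fragments into
two or more candidate sub-peaks (pieces deeper than half depth) — the
false-detail signature. Reported are the last single-blob threshold and the
blob's maximal pairwise extent there: the size of the smallest trustworthy
detail. Sweeping in the opposite direction (from the peak outwards) returns
degenerate single-node components on fragmented reconstructions and was
rejected.

## The packaged experiments

`run_configuration_study()` compares four layouts — 252 and 62 electrodes
surrounding the trunk, and 62-electrode anterior patches at 30 mm and 20 mm
pitch — under a fixed protocol: one paced beat on grid A, BSP through the
grid-A operator, per-layout electrode sampling, 21 dB noise (10 seeds),
L-curve Tikhonov reconstruction on grid B, evaluation against the projected
source. Grid A uses ~1000 torso and ~640 heart nodes at 2048 Hz; grid B
~640 torso and ~490 heart nodes. The surrounding layouts span a 260 mm
vest-like trunk section rather than hugging the heart's axial extent:
heart-hugging bands would make a 252-electrode "surrounding" array as dense
anteriorly as the 20 mm patch, erasing the design question the study exists
to probe. (The bare `layout_surrounding()` default remains heart-spanning.)

`run_pacing_study()` paces at four sites (two apex-region, two
outflow-region) × five seeds with the 20 mm patch, on finer heart grids
(mean edge ≤ 4 mm on both sides, so localization is not mesh-quantized) and
reports localization errors and point spreads per run.

Both studies are pure functions of their `study_config()` (seeds included),
record per-cell errors without aborting, and return tibbles via
`tidy()`/`glance()`.

### What the testbed shows — and what it does not

At these conditions the four layouts converge to anterior correlations near
0.9 with the 20 mm patch the best of the four, the 62-electrode surrounding
array clearly worst, and the 252-electrode array within a hair of the
anterior patches; mean localization error is ~6 mm. Clinical-grade IPM
systems report a wider quality spread between configurations and smaller
point spreads (~7 mm); three differences are worth naming. First, real
studies average many beats from 60-second recordings, giving an effective
SNR far above a single simulated beat at 21 dB — the point-spread statistic
is particularly sensitive to this, since single-beat Tikhonov
reconstructions carry ring artifacts deeper than half the peak, which the
threshold test rightly flags as false detail (measured spreads here are
tens of mm). Second, patient-specific MRI geometry, the real torso's
inhomogeneity, and the clinical λ protocol are not recoverable from
published summaries; the synthetic anatomy is one plausible subject, not a
population. Third, the smoothstep activation curve is a caricature of real
electrograms (no fractionation, no far-field QRS structure), which flattens
differences between layouts. Passing tests here therefore demonstrate the
internal consistency and numerical correctness of the pipeline, and
directionally reproduce the layout ranking — they do not certify clinical
accuracy on real recordings.

## Degenerate inputs and tie-breaks

* Ray tests use a determinant threshold of 1e-12–1e-14 relative scale;
  `ray_triangle_intersect()` refuses triangles below 1e-12 area.
* `point_in_surface()` refuses points within 1e-6 mm of the surface and
  retries a fixed direction list when a crossing grazes a triangle edge.
* Equal shortest-path lengths need no tie-break: distances, not paths, are
  consumed.
* Earliest-site ties break to the deepest trace, then the lowest index.
* Electrode sets enforce >5 mm pairwise spacing and ≤0.5 mm surface
  distance; layouts raise `density` / `coverage` errors when a request
  cannot be met.

## Reproducibility

Every stochastic step (anatomy jitter, noise) derives from explicit integer
seeds; RNG state is isolated and restored, so library calls never perturb a
session's generator. `scripts/acceptance.R --seed N` re-runs both studies
from scratch and writes the headline numbers as JSON; `fixture_generator()`
regenerates the small test fixtures bit-identically.
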