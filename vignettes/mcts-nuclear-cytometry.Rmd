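---
title: "DNA-content cytometry and nuclear organization in tumor spheroids: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{DNA-content cytometry and nuclear organization in tumor spheroids: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mctsnuclei)
```

`mctsnuclei` analyses confocal z-stacks of DNA-counterstained (e.g. DAPI)
multicellular tumor spheroids (MCTS) at single-cell resolution. From a
single stoichiometric DNA stain it extracts, per nucleus, volumetric shape
descriptors and integrated stain intensity, classifies cell-cycle state
from DNA content (2N cells in G1 carry one genome copy; 4N cells in G2/M
carry two and bind twice the stain; S cells fall in between), and maps
proliferation and nuclear organization as a function of distance from the
spheroid surface. This vignette explains the models and algorithms, the
parameters that matter, the synthetic phantom used for validation, and the
numerical and design decisions behind the implementation.

## 1. Nuclear segmentation

Segmentation runs in three stages on the 3D stack (never slice by slice).

**Preprocessing.** The stack is linearly interpolated along z to isotropic
voxels (confocal voxels are anisotropic; the default geometry is
0.4393 µm lateral, 0.9 µm axial), then smoothed with a separable Gaussian.
Foreground is separated from background by a *local-mean* threshold: a
voxel is foreground iff its intensity strictly exceeds the mean over a box
window spanning half the stack extent per axis — so the window volume is
one eighth of the stack volume — plus a configurable offset (default 0).
The strict inequality makes the degenerate constant image yield an empty
foreground deterministically. Interior holes are filled in 3D and
components below `min_object_volume` (default 50 µm³, far below a 2N
nucleus) are removed.

**Seeded watershed.** The Euclidean distance transform (EDT) of the
foreground is negated into a topographic surface; its regional minima,
after H-minima suppression of depth `hmin_depth`, become seeds; a
marker-controlled watershed floods the surface from the seeds and
partitions the foreground, one label per seed. Seeds whose object came
out smaller than 70 % of the median object volume are pruned and the
watershed is re-run, limiting oversegmentation. Objects more than 40 %
larger than the median are flagged as unresolved clusters; replacement
seeds for them can be injected programmatically (a headless, reproducible
substitute for interactively clicked seeds) before the final watershed.

**Parameters.**

| parameter | default | units | role |
|---|---|---|---|
| `gaussian_sigma` | 0.15 | µm | sensor-noise suppression before thresholding |
| `window_fraction` | 0.5 | – | local-mean window, ½ extent per axis |
| `threshold_offset` | 0 | intensity | additive offset on the local mean |
| `hmin_depth` | 0.75 | µm | minimum EDT depth for a separate seed |
| `min_object_volume` | 50 | µm³ | debris cut during mask cleanup |
| `small_seed_fraction` | 0.7 | – | seed pruning cut (fraction of median volume) |
| `oversize_fraction` | 1.4 | – | unresolved-cluster flag (multiple of median) |
| `connectivity` | 26 | – | components, minima and flooding |

`hmin_depth` and `gaussian_sigma` are calibration choices (no published
value exists): the suppression depth must sit above the voxelization
roughness of the EDT (about one lateral voxel, 0.44 µm) and far below the
neck contrast between touching nuclei (about the minor semi-axis, 4 µm);
0.75 µm satisfies both on phantoms across packing densities. For the
smoothing bandwidth we found that the natural-looking choice of one voxel
measurably *dilates* objects — the local-mean threshold sits low on the
edge profile, so every broadening of the edge inflates the mask, costs
boundary accuracy, and merges near-touching nuclei. A bandwidth of about
a third of a voxel suppresses noise without moving boundaries.

**Numerical conventions.** The EDT is exact (Felzenszwalb–Huttenlocher,
generalized to anisotropic spacing, though it runs on isotropic grids
after interpolation). Watershed ties on plateaus are broken by insertion
age (first front to arrive wins), which is deterministic and lets
opposing fronts meet midway across flat regions; breaking ties by raster
order instead lets one front race along the flat one-voxel surface shell
of the distance transform and produce jagged dividing surfaces. The
H-minima transform is morphological reconstruction by erosion of
(surface + h) over the surface, computed with the hybrid raster/queue
algorithm. Seeds are component centroids of the suppressed minima,
snapped to the nearest in-component voxel. A second watershed re-runs on
the full volume after pruning (whether the original procedure re-ran
globally or per cluster is not documented; the global re-run is the
simpler deterministic choice).

## 2. Per-nucleus measurement

For every label the package reports: voxel-count volume (µm³); surface
area; extent (volume over axis-aligned bounding-box volume); centroid and
imaging depth (µm); principal axis lengths and orientations; sphericity
`π^(1/3)·(6V)^(2/3)/A`; and per-channel integrated intensity — the sum of
raw voxel values under the label, measured on the *unsmoothed*
interpolated stack, because smoothing redistributes intensity across
nucleus boundaries (whether the original analysis summed smoothed or raw
voxels is not documented; raw is the stoichiometrically meaningful
choice).

**Axis convention.** Principal axes come from the eigen-decomposition of
the voxel-coordinate covariance (second central moments, µm²), plus a
`spacing²/12` smearing term that accounts for the voxel's own extent. A
solid ellipsoid of semi-axis `a` has second moment `λ = a²/5`, so the
full axis length along eigenvalue `λ` is `2√(5λ)` — the ellipsoid with
the same normalized second central moments as the region, matching
`regionprops3`-style semantics (an ellipsoid with semi-axes 8/6/4 µm
measures 16/12/8 µm). Eigenvectors are sign-fixed (first nonzero
component positive) and sorted by decreasing eigenvalue.

**Surface area.** A raw binary iso-surface overestimates the area of a
sphere by tens of percent (voxel staircase), which would push sphericity
above 1. The mask is therefore smoothed with a one-voxel Gaussian and the
0.5 iso-surface is integrated by marching tetrahedra; a radius-20-voxel
digital sphere then measures within about 1 % of its analytic area. The
smoothing biases areas of very small or very sharp objects (a cube's
corners are rounded), so sphericity is accurate for nucleus-like smooth
bodies, not for polyhedra.

**Volume gate.** Only nuclei between 60 % and 180 % of the median volume
(inclusive bounds, for determinism at the boundaries) enter downstream
analysis, discarding unsplit clusters, polyploid giants (> 4N) and
debris; the discarded partition is returned too, since the polyploid
fraction is itself of biological interest.

## 3. DNA-content cell-cycle analysis

**Reference labels from FUCCI.** In FUCCI-transfected cells, RFP-tagged
cdt1 marks G1 and GFP-tagged geminin marks S/G2, with both expressed in
the G1→S transition. A channel is called positive when its integrated
intensity exceeds the median plus `k` scaled-MADs of the whole channel
(default `k = 3`); the median/MAD pair is a robust background estimate
because fewer than half the nuclei are positive in any single reporter
channel. Nuclei positive in neither channel are non-transfected. Both
definitions of transfection efficacy are available — positives over
negatives, and positives over all nuclei — because the reference count
table (1291 G1 + 111 G1/S + 185 S/G2 against 4698 non-transfected) yields
the published 33.8 % only under the positive/negative ratio
(positive/total gives 25.2 %); the package defaults to the ratio that
reproduces the published number and documents the ambiguity rather than
guessing intent.

**Depth correction.** Even in cleared spheroids, integrated intensity
decays with imaging depth. Per spheroid, median intensity in 5 µm depth
bins is fit linearly against depth (binning resists ploidy-driven
outliers: a 4N nucleus is not an attenuation signal), and intensities are
rescaled by `fit(reference)/fit(depth)` with the shallowest nucleus as
reference. Spheroids with fewer than 10 nuclei or under 20 µm of depth
span are left uncorrected with a warning.

**Normalization and pooling.** Corrected intensities are divided by the
per-spheroid median — placing the 2N mode at 1 and the 4N mode at 2
regardless of staining gain — and only then pooled across spheroids.

**Threshold classifier.** Candidate thresholds (default grid 0.01 over
[0.5, 3.0]) are scanned; content strictly above the threshold is called
S/G2. TPR is computed over FUCCI-S/G2 nuclei and FPR over FUCCI-G1∪G1/S;
the optimum maximizes TPR − FPR, with ties resolved toward the larger
threshold. Values exactly at the threshold are G1 (documented tie rule).

**SVM classifier.** A soft-margin RBF-kernel SVM is trained on the
neighbor-normalized volumetrics plus the normalized DNA content. Each
volumetric feature is divided by its mean over the 5 nearest nuclei of
the same spheroid (self excluded), removing radial size/shape gradients
so the classifier cannot learn position. Features are standardized;
class weights are balanced (G1 far outnumbers S/G2, which is also why
balanced accuracy, (TPR + TNR)/2, is the model-selection metric).
Hyperparameters (cost, kernel width) are selected by stratified 5-fold
cross-validated grid search over log-spaced ranges — a deterministic,
seeded stand-in for Bayesian optimization, which is an implementation
vehicle rather than a modeled quantity — the final model is refit on the
full 80 % training split and evaluated once on the untouched 20 %. All
stochastic steps (split, folds) derive from one explicit seed; identical
seeds give identical models.

## 4. Spatial organization

The spheroid body is approximated by morphologically closing the union of
all nucleus voxels with a 10 µm ball (about the inter-nuclear gap scale;
no published value exists for the structuring element), filling holes and
keeping the largest component. Dilation and erosion are computed from
exact EDTs, so the closing is accurate to about one voxel. The spheroid
center is the centroid of the closed mask — robust to uneven nuclear
density — and nuclei whose centroid falls outside the mask are flagged
detached and excluded. Each retained nucleus gets its Euclidean distance
to the perimeter (interior EDT sampled at the centroid), a concentric
10 µm layer index (half-open intervals, distances beyond 60 µm pooled
into the innermost layer), per-layer S/G2 counts and fractions
(spheroids aggregated as mean ± SD; empty layers flagged NaN — deep
layers contain few cells and their fractions are volatile), and radial
trends of any quantity in 5 µm bins (mean ± SD or median ± MAD, bins
with under 3 nuclei flagged).

**Alignment angle.** For each nucleus, α is the angle between the
center-to-nucleus vector r and the plane spanned by the major (e1) and
intermediate (e2) principal axes: α = arcsin(|r̂·ê3|), using the minor
axis ê3 — equivalent to the vector-plane construction and numerically
stable near 0° and 90°. α = 0° means the nucleus is aligned with the
radius; α = 90° means its long axis lies perpendicular to the radius
(minor axis pointing outward, the tangential arrangement of compressed
nuclei). The z alignment angle replaces r with the microscope z-axis and
quantifies axial elongation artefacts: regressing each axis length on
the z alignment angle (`fit_z_artifact`) expresses the artefact as the
length difference between a 0° and a 90° nucleus.

One geometric caveat documented rather than hidden: for *uniformly
random* nuclear orientations the minor axis is uniform on the sphere, so
|r̂·ê3| is uniform on [0, 1] and the median alignment angle is
arcsin(0.5) = 30°, not 45°. Descriptions of mid-range alignment angles
as "≈ 45° therefore isotropic" are therefore only qualitative; the
package's isotropy tests state the exact law (the z-angle CDF for
isotropic orientations is sin α) and the 45° reading should not be used
as a quantitative isotropy calibration.

## 5. The synthetic phantom

`generate_phantom()` builds ground-truthed stacks with the statistical
structure the analysis assumes; `simulate_records()` is its statistical
twin at the record level (same populations, no rasterization) for
cohort-scale classifier experiments.

What the phantom emulates: a spherical aggregate (default radius 70 µm,
300 nuclei — a 140 µm spheroid of about 300 cells) of ellipsoidal nuclei
with mean axes 16.3/11.8/8.2 µm; non-overlapping dart-throwing placement;
isotropic or tangentially aligned orientations; stoichiometric DNA
intensity (integrated intensity proportional to true content: G1 at one
unit, G2 at two, S uniform in between, G1/S just above one) with nuclear
volume coupled to content (volume ≈ content¹); linear depth attenuation
(default 0.4 % per µm); FUCCI reporter channels consistent with class and
a 25 % transfection rate; diffraction-scale anisotropic Gaussian blur
(0.4 µm axial, 0.15 µm lateral — the point-spread scale of a 63×/1.40 oil
objective with 0.9 µm optical sections); Poisson shot noise on the
rendered photon counts, with optional additive read noise defaulting to
zero — the photon-counting confocal model, under which empty background
stays exactly dark. (This default matters: with any appreciable
additive noise on an empty background, about half of the pure-noise
voxels exceed their own local mean, and at 26-connectivity that fraction
percolates into large connected foam; handling such detectors is what
the threshold offset exists for.) Finally an optional axial stretch
factor
(`z_stretch`) imposing the apparent z-elongation artefact. All randomness
derives from one seed; identical specs regenerate bit-identical output.

Two generator choices deserve emphasis. *Packing:* rejecting overlaps
between bounding spheres cannot reach the paper-scale density (300
nuclei of 8.15 µm semi-major axis need ~49 % of the admissible ball,
above the ~38 % jamming limit of random sequential sphere packing), so
overlap is rejected on the directional support radius of each ellipsoid
along the center–center line, shrunk by 10 % — ellipsoids may nearly
touch, which is exactly what stresses the watershed. *Dispersion:* the
published axis spreads (±2.3/1.4/1.2 µm) are measured over segmented
nuclei and already contain the cell-cycle size coupling and measurement
error; the generator's intrinsic spreads (2.0/1.1/1.0 µm) are the
variance-decomposed values that reproduce the measured spreads after
coupling and noise are added. Using the printed spreads as intrinsic ones
would double-count variance and overpopulate the small-volume tail that
the 70 % seed-pruning rule removes.

What the phantom does *not* emulate: chromatin texture (uniform nuclear
interiors), a full physical point-spread function and spectral
bleed-through, aneuploid DNA-content broadening, polyploid giants,
necrotic cores (those require ~500 µm spheroids), and non-spherical
spheroid shapes. Passing phantom tests therefore validates the geometry,
intensity accounting and statistical machinery of the pipeline — not its
robustness to texture-driven intensity heterogeneity in real stacks.

Validation scales: the end-to-end segmentation check runs on the full
default phantom (300 nuclei, ~42 million interpolated voxels); the
DNA-content cohort check uses ten 48-nucleus phantoms so ten full
segmentations stay comfortable on a laptop; classifier comparisons use
record-level cohorts at the reference-study scale (6285 nuclei), where
rasterizing images would add nothing to what is being tested. The
z-artefact recovery check measures the stretched phantom's rendered
labels directly, because the optical chain (blur, z interpolation,
partial-volume thresholding) has an axial elongation of its own that
even scales with the imposed stretch; the axis-length regression on
fully segmented stacks therefore reports the chain's total artefact,
while the generator parameter is recoverable only downstream of
rasterization.

## 6. Known limitations

* The seed-pruning rule removes the seeds of genuinely small nuclei
  (smallest ~3–4 % of a realistic population), which are then absorbed by
  neighbors; this is inherent to the published 70 %-of-median rule, not
  an implementation artefact. The oversized-cluster flag marks the
  absorbing labels for seed injection.
* The local-mean threshold places boundaries low on the edge profile, so
  measured volumes run 10–20 % above geometric truth; volume *ratios*
  (the gate, pruning, DNA-content normalization) are unaffected.
* Closing-based surface approximation is accurate to about one voxel;
  perimeter distances inherit that uncertainty (~0.5 µm).
* Integrated reporter intensities are blur-redistributed near label
  boundaries; with near-touching nuclei a few percent of a bright
  nucleus's signal can bleed into a dim neighbor.
* The SVM inherits the usual caveat that volumetric morphology is
  cell-line dependent; neighbor normalization reduces but does not
  remove this.
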