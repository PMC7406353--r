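---
title: "Aligning temporal cortices and building probabilistic atlases with cortexalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning temporal cortices and building probabilistic atlases with cortexalign}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

The superior temporal plane — the home of the auditory cortex — shows large
macro-anatomical variation across individuals: the number and shape of
Heschl's gyri differ from brain to brain, and the positions of
cytoarchitectonically defined areas (Te1.0–Te3, STS1/2) move with the
macro-anatomy. `cortexalign` implements the processing stack needed to study
this problem end to end: preparing anatomical volumes for segmentation,
reconstructing and inflating cortical surface meshes, aligning them across
individuals on the sphere — rigidly, by curvature (CBA), or by curvature plus
explicit anatomical landmarks (CBA+) — and quantifying how well
cytoarchitectonic areas overlap after each alignment through probabilistic
maps, overlap histograms, and leave-one-subject-out DICE tables. A
surface-encoding module builds the matching in-vivo maps: a T1w/T2\*w myelin
index and a ridge-regression tonotopy estimate.

Because the postmortem data this kind of study uses are large and partly
interactive to process, every stage here is exercised end to end on seeded
synthetic data with stored ground truth (`make_volume_phantom()`,
`make_cohort()`, `make_sound_experiment()`). This vignette documents the
models, the parameters that matter, and the design decisions taken where the
method family leaves choices open.

# Edge-enhancing structure-tensor diffusion

`enhance()` iterates ten steps: Gaussian pre-smoothing of the image
(`sigma`, default 1 voxel), central-difference gradients, the structure
tensor $S = \nabla\hat v\,\nabla\hat v^{\mathsf T}$, its eigendecomposition
$(\lambda_1 \ge \lambda_2 \ge \lambda_3)$, the surfel features

$$\mathrm{intensity} = \lambda_1+\lambda_2+\lambda_3,\qquad
\mathrm{range} = (\lambda_1-\lambda_3)/\mathrm{intensity},\qquad
W = \bigl|(|\mathrm{range}-0.5|+0.5) - \mathrm{intensity}\bigr|,$$

the diffusion tensor $D = \alpha\,e_1e_1^{\mathsf T} +
W\,(e_2e_2^{\mathsf T}+e_3e_3^{\mathsf T})$ with a small cross-boundary
diffusivity $\alpha = 0.001\max W$, component-wise Gaussian smoothing of $D$
(`rho`, default 1 voxel), the flux $f = \hat D\,\nabla\hat v$, and the
explicit update $v \leftarrow v + \operatorname{div} f$ with a unit time
step. Forty iterations are the default, matching the regime in which the
white–gray boundary of postmortem tissue becomes visibly sharper.

Numerical choices that required decisions:

* **Intensity normalization.** The weight formula mixes a bounded term with
  the unnormalized intensity. We normalize the intensity by its volume-wide
  90th percentile and clip at 1, which saturates the entire edge ridge (so
  $W \approx 0$ across boundaries — no cross-boundary diffusion) while
  structureless voxels keep $W \approx 1$. Normalizing by the single maximum
  instead leaves typical edge voxels far below saturation and lets edges
  erode; percentile normalization is also invariant to acquisition gain.
* **Stability.** With unit time step the explicit central-difference scheme
  is stable only for diffusivities below about $2/3$; all diffusivities are
  rescaled so their maximum is `diffusivity_cap = 0.45` before the update.
  The update itself aborts with the iteration index if any intensity exceeds
  $10^{12}$.
* **Flux gradient.** The flux re-uses the gradient of the *smoothed* image
  — the same vector field that defines the structure tensor. This is what
  makes the filter sharpening rather than merely edge-preserving: flanking
  regions transport intensity toward the frozen edge core, steepening the
  ramp. (With the raw-image gradient the interface gradient of the
  two-tissue phantom decays instead of growing.)
* **Boundaries.** Reflective (zero-flux) boundaries throughout: the gradient
  uses replicated ghost values, the divergence anti-reflected ghost fluxes,
  which makes the grid-total intensity conserved *exactly* — a property the
  tests check at $10^{-6}$ relative per iteration.
* **Degenerate voxels.** Where the intensity is below $10^{-12}$ of its
  maximum, `range` and `W` are defined as 0, so structureless voxels can
  never produce NaN.
* **Anisotropic voxels.** Gradients are computed in physical units through
  the voxel spacing; `sigma` and `rho` are specified in voxels. A trilinear
  upsampling pre-step (`upsample = 0.5`) reproduces the common practice of
  filtering at 0.5 mm isotropic; it is off by default.

The volume phantom used to validate the filter (`make_volume_phantom()`) is
a two-tissue grid (white matter 100, gray matter 60) split by the folded
surface $z_0 + A\sin(2\pi x/L)\sin(2\pi y/L)$ with $A = 5$, $L = 24$ voxels
— a curvature radius of a few voxels, comparable to postmortem sulci at
0.5 mm — blurred by a 0.7-voxel acquisition point-spread function and
corrupted by Gaussian noise of standard deviation 10. The PSF matters: a
perfectly crisp binary step is already as sharp as central differences can
measure, so the filter's sharpening is only observable on a finite-width
ramp, which is also what a scanner produces. The filter's acceptance
property is that the mean absolute boundary-normal gradient across the true
interface increases monotonically at iterations 10/20/30/40.

# Segmentation by joint histograms

`joint_histogram()` bins voxels by intensity and gradient magnitude (robust
0.5–99.5 percentile ranges, values outside clamped into the edge bins so
counts conserve the voxel total), and `mask_from_region()` turns an explicit
box or polygon in that 2-D space into a binary mask. The region objects are
serializable JSON rather than interactive selections, so segmentations are
reproducible. On the filtered phantom, the high-intensity/low-gradient box
recovers ≥95% of true white-matter voxels. Manual correction of
segmentations — hours of interactive work per brain in practice — is out of
scope.

# Surfaces: extraction, topology, inflation, resampling

`extract_mesh()` runs marching tetrahedra on the 0.5 iso-level of the mask
with one voxel of zero padding (closed surfaces at the volume border) and a
6-tet cube decomposition, orienting every triangle outward. By default the
binary field is first band-limited by a 1-voxel Gaussian and iso-vertices
are placed by linear interpolation, which removes the half-voxel staircase
(raw binary extraction is available with `presmooth = 0`). A ball of radius
30 voxels reconstructs with a maximal radial error under 1%.

`euler_characteristic()` ($V - E + F$) is the topology gate: every surface
must reach 2 (genus 0) before inflation, exactly as one checks reconstructed
hemispheres for bridges and holes. `decimate()` collapses shortest edges
first (which equalizes edge lengths), placing merged vertices at the
minimizer of the accumulated quadric (plane-distance) error with a midpoint
fallback and enforcing the link condition, so topology is preserved;
accumulating the quadrics through collapse generations is what lets the
decimated surface average out residual voxelization rather than inherit it.
`inflate_to_sphere()` uses iterative Laplacian smoothing with per-step
re-centering and projection to the unit sphere (default 500 steps),
preserving vertex order so per-vertex maps carry over, and reports flipped
faces (none are tolerated downstream).

Curvature (`vertex_curvature()`) is the umbrella estimate — the displacement
of a vertex from its neighbor average projected on the outward normal —
optionally smoothed by neighbor averaging; the sign convention is sulci
positive / gyri negative and the binarized map thresholds at 0. This is
deliberately the cheapest stable estimator: alignment needs the sulcal/gyral
pattern, not precise principal curvatures.

`resample_to_standard()` transports per-vertex maps from any spherical mesh
onto the standard icosphere (level $L$ has $10\cdot4^L+2$ vertices; level 7
gives the 163842-vertex high-density sphere used throughout). Point location
walks the triangulation from a spatial-grid seed with a brute-force fallback
(counted and reported); scalar maps move by barycentric interpolation
(exact for constants, range-stable), categorical maps by nearest corner. A
useful property of the subdivision scheme: vertices of lower levels keep
their indices at higher levels, so a map's prefix is itself a valid map on
the nested sub-sphere — the rigid aligner exploits this.

# Spherical alignment: rigid, CBA, CBA+

All alignment happens on the standard icosphere, one hemisphere at a time.

**Rigid.** `rigid_spherical_align()` minimizes the mean squared difference
between the rotated-resampled source curvature and the target over SO(3):
a coarse grid (icosphere-level-1 axes × 15° angle steps) followed by
Nelder-Mead refinement of the axis-angle vector, evaluated on icosphere
vertex directions. The residual never exceeds the residual at identity, and
constant (no-signal) maps return identity with a warning. A planted 20°
rotation is recovered to well under 2°.

**CBA.** `cba()` optimizes, per subject, per-vertex warp positions on the
sphere by projected gradient descent on

$$\sum_i \bigl(c_s(w_i) - t(i)\bigr)^2 \;+\;
\lambda \sum_{(a,b)\in E} \bigl(\lVert w_a - w_b\rVert - r_{ab}\bigr)^2,$$

where $c_s$ is the subject's curvature sampled by barycentric interpolation
at the warped position, $t$ the group template, and the second term the
metric-distortion penalty (deviation of warped edge lengths from the
icosphere rest lengths). Steps are accepted only if the cost does not
increase *and* no spherical triangle flips; otherwise the step halves (so
recorded cost traces are non-increasing and warps are always valid). Four
coarse-to-fine scales smooth the curvature maps by 120/60/20/5 rounds of
neighbor averaging, with 100/100/80/60 iterations and initial step sizes
0.3/0.15/0.075/0.0375 mean-edge-lengths; maps are variance-normalized per
scale. The template is refreshed from the currently warped subjects at every
scale boundary (dynamic group averaging), starting from the mean of the
rigidly aligned maps. The defaults $\lambda = 30$ and the schedule above
were fixed on synthetic development cohorts as the point where the planted
deformation is recovered without metric collapse; they are all arguments of
`alignment_schedule()`.

**CBA+.** `cba_plus()` adds, per landmark $m$ (anterior Heschl's gyrus,
superior temporal gyrus, superior temporal sulcus, middle temporal gyrus),
the term $w_{lm}\sum_i (\ell_{m,s}(w_i) - \ell_m^{\mathrm{templ}}(i))^2$
with the landmark indicator maps smoothed alongside the curvature
(60/30/10/3 rounds) and variance-normalized per scale. The default
per-landmark weight is 0.25, i.e. the four landmarks together carry the
same weight as the global curvature term: landmarks should pull the
temporal plane into register, not overrule the curvature everywhere.
`lm_weight = 0` short-circuits to exactly the CBA code path, which the
tests check bitwise. Landmarks enter as polylines drawn through anchor
vertices (`landmark_to_map()` connects anchors by shortest edge-paths with
arc-length weights, the discrete analogue of drawing a geodesic line on the
inflated surface); a split superior temporal gyrus is handled by placing
anchors that bridge the intermediate sulcus — the tool imposes no automatic
detection.

`apply_warp()` transports any per-vertex map through a warp (barycentric
for scalars, nearest corner for labels); `group_average()` produces the
template curvature or the average folded mesh (per-vertex mean of original
3-D coordinates through the warps).

# Atlas construction and evaluation

`probabilistic_map()` tallies, per vertex and area, how many subjects label
that vertex with the area. `overlap_histogram()` normalizes the level-$k$
counts by the number of vertices with count ≥ 1 for the area — the only
normalization under which each area's bars sum to 1 — and reports the
left-skew (mass at level 1 minus mass at level $N$); better alignment means
less left skew. `loo_dice()` evaluates generalization: for each left-out
subject the remaining $N-1$ build an atlas region (count ≥ `min_overlap`,
default 4 of 9 training subjects), compared with the held-out subject's
area by DICE $2|A\cap B|/(|A|+|B|)$. A cell where the area is missing from
the training atlas is defined as 0 with a warning (matching the zero cells
such tables show in practice); two empty sets give 0 with a warning. The
table carries per-area means and standard deviations, recomputable from the
cells.

# The synthetic cohort

`make_cohort()` builds the ground-truth world in which the alignment claims
are testable. The template curvature is a band-limited random field (unit
variance; smoothing rounds scale with $4^{\mathrm{level}}$ so the angular
correlation length is level-independent) plus four ridge/valley strips of
amplitude 2 and width 6° for aHG/STG/STS/MTG (gyri negative, the sulcus
positive); the random field carries the secondary-folding texture that real
curvature has between the named landmarks, and without which tangential
position along a gyrus would be unconstrained. Eight areas tile
latitude/longitude boxes tied to the strips: Te1.0/Te1.1/Te1.2 segment the
aHG strip along its length, Te2.1/Te2.2 the STG strip, Te3 the band between
STG and STS, STS1/STS2 the STS band — so area overlap is sensitive exactly
to how well the landmarks align. Each subject is the template composed with
a smooth tangential deformation (sum of 8 smoothed random tangent fields,
maximum displacement 0.18 rad ≈ 10°, the scale of Heschl's-gyrus positional
variability) and a planted 8° rotation; deformations that would flip any
spherical triangle are regenerated at reduced amplitude (logged). In
addition, with probability 0.4 — the prevalence of duplicated transverse
temporal gyri across hemispheres — a subject carries a posterior duplicate
of the Heschl ridge at half the main ridge's amplitude. The duplicate is a
curvature feature only: it carries no labels and no landmark, so it
reproduces the known failure mode of purely curvature-driven alignment
(the posterior duplicate of one subject matched to the single gyrus of
another) that an explicitly drawn aHG landmark resolves. This is a binary
confuser, not a morphotype model: incomplete versus complete duplication
geometry, split superior temporal gyri and hemispheric asymmetries remain
unmodeled. The true
correspondence is stored with each subject, so that perfect alignment
implies DICE 1 by construction, and amplitude 0 with no rotation makes all
subjects identical. Everything is seeded: the same spec yields bitwise
identical cohorts.

What the cohort does *not* emulate: realistic duplication morphotype
geometry (beyond the binary confuser above), split superior temporal gyri,
hemispheric asymmetries, and area boundaries that disrespect the landmark
geometry.
Passing the ordering tests on this cohort therefore shows that the
machinery behaves as the method family claims *when anatomy varies smoothly
at the stated scale* — it cannot show robustness to the discrete
morphotype variation that real brains add on top.

The headline comparison (run at icosphere level 4 in the test suite, level
6 — 40962 vertices — in `scripts/acceptance.R`; level 4 keeps the default
test run fast while level 6 approaches the density at which such analyses
are published) checks the ordering that motivates landmark-augmented
alignment: mean pairwise curvature correlation CBA > rigid; mean pairwise
DICE of the warped landmark supports CBA+ > CBA; mean leave-one-out DICE
CBA+ ≥ CBA ≥ rigid, strictly for the Te1.x areas adjacent to the aHG
landmark.

# In-vivo maps

**Myelin.** `myelin_index()` divides T1w by T2\*w inside the gray-matter
mask, excludes zero-valued T2\*w voxels (counted), removes the outlier tail
above an adaptive percentile threshold, and min-max rescales survivors to
[0, 100] (monotone, so rank order is preserved; a constant ratio maps to 0
with a warning). The adaptive threshold operationalizes "iterative
deceleration of percentile differences": scan p = 90…99.9 in steps of 0.1,
form the forward differences Δ(p), and cut at the first p where Δ(p) falls
below twice the median Δ after Δ has decreased for three consecutive steps
— the point where the distribution stops decelerating marks the transition
from tissue bulk to vessel tail. All constants are arguments.
`sample_volume_at_vertices()` samples the result at mid-gray vertex
positions (nearest-voxel by default, trilinear optionally).

**Tonotopy.** `cochlear_features()` stands in for a full cochlear model
with a 128-band log-spaced filterbank (180 Hz–8 kHz) evaluated in the
Fourier domain (rectangular bands between geometric edges); band energies
are mean squares, optionally per-Hz. The time-domain equivalent at this
band density would need numerically fragile very-narrow IIR filters, and
the encoding stage only consumes band energies. `estimate_hrf()` recovers
each vertex's hemodynamic response by a 9-stick deconvolution GLM (exact on
noiseless data), `sound_responses()` estimates per-sound betas with the
vertex's own HRF (train and test runs separately per fold), `noise_pcs()`
supplies residual-PC noise regressors estimated on training data only, and
`ridge_encoding()` fits the band-energy-to-response map with an L2 penalty
chosen per vertex by test-fold prediction accuracy across the four
126-train/42-test splits, averaging fold weights at the selected penalty.
The best frequency is the center frequency of the largest weight, ties to
the lowest band. The simulated experiment (`make_sound_experiment()`)
mirrors the design: 168 sounds, four cross-validation splits, volume time
2.6 s, canonical double-gamma HRF, one-hot tuning, noise at SNR 2; the
acceptance check asks for ≥90% of vertices recovered within ±1 of 128 bands
(100% noiseless).

Waveforms enter as numeric vectors with a sampling rate; the package reads
and writes NIfTI volumes, OBJ meshes, and CSV/JSON sidecars — all
plain-text or standard formats.

# Known limitations

* The alignment cost, regularizer, and scale schedule of the proprietary
  software this method family grew up in are unpublished; the
  implementation here claims ordering and sharpness properties on synthetic
  cohorts, not numeric equality with any published figure.
* Curvature estimation and inflation are deliberately simple (umbrella
  estimator, Laplacian inflation); they are adequate for binarized
  sulcal/gyral patterns but not for quantitative curvature analysis.
* The explicit diffusion scheme trades speed for the stability cap; an
  implicit scheme would allow larger effective time steps.
* `decimate()` targets approximately uniform edge lengths, not curvature-
  adaptive density.
* The encoding stage assumes a linear band-energy code and one dominant
  frequency per vertex; spectro-temporal modulation features are out of
  scope.
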