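# cortexalign

Cortical surface alignment and probabilistic cytoarchitectonic atlasing for
the superior temporal cortex — with every stage runnable on seeded synthetic
data.

## The problem

The superior temporal plane, which hosts the human auditory cortex, is one
of the most anatomically variable regions of the brain: the number and shape
of Heschl's gyri differ across individuals and hemispheres, and
microanatomically defined areas (Te1.0, Te1.1, Te1.2, Te2.1, Te2.2, Te3,
STS1, STS2) move with the macro-anatomy. Any group study that averages over
subjects therefore depends on how well individual cortices are brought into
register. This package implements and evaluates three surface registration
strategies on the unit sphere:

* **rigid** — spherical rigid-body alignment minimizing curvature
  differences;
* **CBA** — curvature-based alignment: coarse-to-fine nonlinear warping
  that minimizes per-vertex curvature mismatch against a dynamically
  re-averaged group template, with a metric-distortion penalty;
* **CBA+** — CBA with anatomical priors: smoothed indicator maps of four
  explicit landmarks (anterior Heschl's gyrus, superior temporal gyrus,
  superior temporal sulcus, middle temporal gyrus) added to the cost.

Around the aligners sits the full method stack: a structure-tensor
edge-enhancing diffusion filter that prepares anatomical volumes for
segmentation (iterating `v <- v + div(D * grad(v))` with an anisotropic
tensor built from the structure-tensor eigensystem), joint
intensity/gradient-magnitude histogram segmentation, marching-tetrahedra
mesh extraction with an Euler-characteristic topology gate (`V - E + F = 2`
required of every surface), inflation to the unit sphere, resampling to the
standard 163842-vertex icosphere, probabilistic atlas construction with
normalized overlap histograms and leave-one-subject-out DICE
(`2|A∩B| / (|A|+|B|)`), and in-vivo surface maps: a T1w/T2\*w myelin index
rescaled to [0, 100] and a tonotopy estimate from ridge-regression encoding
of 128-band cochleagram features (best frequency = argmax weight).

Who this is for: anyone building or evaluating surface-based atlases of
highly variable cortex, and anyone who needs a self-contained, seeded test
bed in which alignment claims ("landmark priors improve microanatomical
overlap") can be checked against planted ground truth.

## Worked example

Generate a ten-subject synthetic cohort (a shared template curvature
pattern with landmark ridges, deformed per subject by a smooth spherical
warp plus a small rotation, with area labels tied to the landmarks), align
it with all three methods, and evaluate the overlap of the areas:

```r
library(cortexalign)

cohort <- make_cohort(cohort_spec(seed = 1))     # n = 10, icosphere level 4
aligned <- align_cohort(cohort)                  # rigid, CBA, CBA+

curvs <- lapply(cohort$subjects, `[[`, "curvature")
for (m in c("rigid", "cba", "cba_plus")) {
  tab <- cohort_loo_dice(cohort, aligned[[m]], min_overlap = 4)
  cat(sprintf("%-8s curvature corr %.3f  landmark DICE %.3f  LOO DICE %.3f\n",
      m,
      pairwise_curvature_correlation(curvs, aligned[[m]], cohort$mesh),
      landmark_overlap_dice(cohort, aligned[[m]]),
      mean(tab$Mean)))
}
```

```
rigid    curvature corr 0.943  landmark DICE 0.580  LOO DICE 0.675
cba      curvature corr 0.985  landmark DICE 0.651  LOO DICE 0.713
cba_plus curvature corr 0.985  landmark DICE 0.738  LOO DICE 0.781
```

Reading the numbers: curvature correlation is the mean pairwise Pearson
correlation of the warped curvature maps (macro-anatomical correspondence);
landmark DICE the mean pairwise overlap of the warped landmark supports;
LOO DICE the mean leave-one-subject-out DICE of the eight area labels
against an atlas thresholded at 4 of 9 training subjects
(micro-anatomical correspondence). Nonlinear curvature matching beats rigid
on all three, and adding the landmark priors beats plain CBA — most of the
gain concentrating in the Te1.x areas on the aHG landmark — which is the
ordering that justifies landmark-augmented alignment for temporal cortex.

The filter stage has the same flavor of checkable claim: on a two-tissue
phantom with a folded boundary, PSF blur and noise,

```r
ph <- make_volume_phantom(phantom_spec(seed = 2))
v <- enhance(ph$volume, filter_params())         # sigma 1, rho 1, 40 iters
c(before = interface_gradient(ph$volume, ph), after = interface_gradient(v, ph))
```

```
  before    after
16.25183 18.25309
```

the mean boundary-normal gradient across the true interface *increases*:
the filter sharpens tissue boundaries while smoothing within tissue.

A thin command-line wrapper over the same functions is installed at
`inst/cli/cortexalign.R` (`enhance`, `segment-*`, `surf-*`, `synth-*`).

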