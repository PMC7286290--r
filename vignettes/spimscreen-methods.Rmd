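---
title: "Methods: dual-view light-sheet spheroid screening with spimscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-view light-sheet spheroid screening with spimscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`spimscreen` implements the analysis chain of a dual-view light-sheet
(diSPIM) high-content screen of 3D spheroids: two orthogonal camera views of
every position are registered through fluorescent fiducial beads, fused and
deconvolved into one near-isotropic volume, nuclei are segmented and
described by geometric and Haralick texture features, each nucleus is
assigned a cell-cycle phase by a slice-voting convolutional network (or a
random forest on texture features), the per-nucleus calls are assembled into
spheroid-level time series, and per-sample feature profiles are clustered
into phenotype groups by rank-based hierarchical clustering.

Because real screens of this kind produce terabytes of microscope data that
cannot ship with a package, every stage is validated against a synthetic
scene generator that produces dual-view stacks with exhaustive ground truth.
This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

# The synthetic scene generator

`simulateTimelapse()` evolves a clonal spheroid of H2B-labelled nuclei:

* **Cell-cycle clock.** Every cell owns an age within a cycle of
  `cycleLength` minutes (default 1260, a ~21 h epithelial cycle). The
  mitotic phases occupy fixed windows at the end of the cycle -- prophase
  11.3 min, metaphase 15.1 min, anaphase 40.3 min by default; interphase is
  the remainder. Initial ages are uniform, so the population is
  asynchronous and the expected occupancy of each phase is its duration
  divided by the cycle length (`expectedPhaseOccupancy()`); with the
  defaults, interphase occupies (1260 - 66.7)/1260 = 94.7% of
  nucleus-frames. At the end of anaphase the cell is replaced by exactly
  two children displaced along the division axis, so lineages never skip a
  phase and every division has exactly two children.
* **Geometry.** Nucleus radii are drawn once per cell
  (3.8 +/- 0.35 um); nuclei diffuse slightly (0.12 um per 5-min frame)
  and soft-sphere relaxation keeps neighbours near the packing distance
  (8.5 um, about one nucleus diameter plus chromatin-free margin) while
  pulling outliers back toward the centroid, so the spheroid stays roughly
  ball shaped as it grows.
* **Phase morphologies.** The renderer encodes what a trained eye (or
  classifier) uses on H2B signal: interphase is a smooth sphere of diffuse
  chromatin (density 1.0, faint 2.2 um texture); prophase swells slightly
  (1.05 r) and condenses into high-contrast speckles whose 1.4 um grain
  matches the physical width of condensing chromosomes; metaphase is a
  bright oblate plate (half-thickness 0.32 r) perpendicular to the division
  axis; anaphase is two condensed lobes (0.7 r) separating along the axis
  with a fainter chromatin bridge between them, so the object stays one
  connected structure for segmentation. The bridge and the lobe sizes are
  deliberate: they keep a late-anaphase nucleus one segment rather than
  two. These encodings are minimal geometric abstractions chosen so that
  texture and shape classifiers *can* separate the classes; their absolute
  values are not fitted to any measured chromatin data.
* **Beads and drift.** Fiducial beads are stationary in the sample and move
  only with the stage drift (`driftPerFrame`); bead positions at frame t
  are frame-1 positions plus (t-1) x drift.

`renderDualView()` images a frame through two virtual cameras. View A sits
on the reference grid; view B's grid is the view-A field of view rotated 90
degrees about Y plus a small translation (the true registration transform,
available per optics via `trueViewTransform()`). Each view is blurred with
its own anisotropic Gaussian PSF along its detection axis, scaled to
photons (`photonScale`, default 300 expected counts at unit chromatin
density), degraded with Poisson shot noise and Gaussian read noise (sd 2),
and quantized to 16 bits. Both views sample the *same* world-anchored
chromatin texture, so they are genuinely two projections of one object.
Beads are drawn analytically as post-PSF Gaussians at their exact
continuous positions; rasterising a sub-voxel point source and then
blurring it aliases the bead position to the grid, which is visible as a
~0.2-voxel localisation bias, so the analytic form is used instead.

**What the generator does not emulate:** light-sheet stripe and shadow
artifacts, depth-dependent scattering, optical aberrations away from the
nominal Gaussian PSF, chromatin ultrastructure, apoptosis, and segmentation
ambiguity from overlapping fluorophores other than plain proximity. Tests
passing on this generator therefore demonstrate the correctness and
self-consistency of the algorithms under a controlled forward model -- not
classifier accuracy on real microscope data.

# Problem sizes

All defaults are desk scale so the whole validation suite runs on one CPU:
rendering uses a 112 x 112 x 64 grid at 0.7 um isotropic voxels (a 78 x 78
x 45 um field holding a mid-size spheroid; `deskOptics()`), the control
pipeline processes 40 starting nuclei over 100 frames, and the classifier
benchmark images 800 nuclei per class in packed batches of 160 on a
140 x 140 x 96 grid. The
hardware-scale geometry (0.1625 um laterally, 0.5 um slices,
1024 x 1024 x 260 stacks; `OpticsParams()` defaults) is supported by the
same code paths.

# Calibration: beads, registration, PSF, drift

* **Detection** (`detectBeads()`): strict 26-neighbourhood maxima above
  `background + snrThreshold x noise` (median/MAD). Subvoxel refinement
  uses an intensity-weighted centroid in a local window that is
  *recentred* on the running estimate through trilinear interpolation
  (three iterations); a fixed window truncates the anisotropic spot
  asymmetrically and biases the centroid, while the recentred window's
  fixed point is unbiased for a symmetric spot. On noiseless data the MAD
  is zero and the threshold falls back to 5% of the dynamic range.
* **Registration** (`estimateRegistration()`): iterated closest points
  between the detected bead sets, initialised with the nominal 90-degree
  view rotation, with a 5 um match gate, one-to-one assignment (closest
  claimant wins), and a full 12-parameter affine least-squares fit per
  iteration until the assignment is stable. Affine subsumes the rigid
  truth and absorbs small calibration scale errors. Fewer than four usable
  or coplanar correspondences raise a "degenerate calibration" error. On
  rendered beads the truth transform is recovered to well under 0.05 um.
* **PSF extraction** (`extractPSF()`): isolated beads only (no neighbour
  within twice the kernel radius), background = median of the window
  border, recentred on the subvoxel position, averaged, clipped at zero,
  normalised to unit sum. The view-B PSF is extracted from the *resampled*
  bead stack so its anisotropy axis is expressed in the fused frame.
* **Drift tracking** (`trackDrift()`): nearest-neighbour bead matching
  between consecutive frames within a gate, per-axis median displacement
  (robust to a runaway bead), accumulated relative to frame 1; frames
  without matches inherit the previous offset.

# Fusion and deconvolution

View B is pulled onto the reference grid by trilinear interpolation with a
validity mask. `jointDeconvolve()` then runs alternating multiplicative
Richardson-Lucy with both PSFs, initialised with the mean of the two views;
outside a view's valid footprint its ratio is fixed at 1 so the update
cannot hallucinate. The per-view Poisson objective is logged each
iteration (evaluated on the incoming estimate of that view's update, so the
log entries of one view are comparable across iterations). The default is
10 iterations with epsilon = 1e-6; the control pipeline and the classifier
benchmark use 3, past which the isotropy gain is marginal at desk-scale
PSFs. Kernel taps below 1e-3 of the kernel maximum are pruned for speed;
they carry about 1% of the kernel mass. The claimed outcome -- axial/lateral FWHM anisotropy of
a fused point closer to 1 than either single view -- is asserted by test.

# Segmentation and features

`segmentNuclei()` follows a Gaussian-smooth / global-Otsu / connected
components recipe in 3D, with erosion-based splitting of merged nuclei:
the binary component's iterative 6-erosion depth map is scanned from the
deepest level down, every depth plateau that does not already contain a
marker opens a new core (ultimate erosion, capped at `maxErosions` = 5),
and cores grow back through the component by breadth-first region growing.
Thin condensed objects defeat pure depth markers: a metaphase plate
touching a diffuse nucleus erodes away before it separates, so it never
receives its own core and is absorbed. A second Otsu split *within* the
foreground therefore marks condensed chromatin -- accepted only when the
bright class is at least 1.35 times the diffuse class, so volumes without
mitotic figures do not produce spurious markers -- and condensed regions
still lacking a marker seed additional cores. Undersized pieces surrender
their marker smallest-first and the growth repeats: this keeps genuinely
touching interphase nuclei apart (each piece is a full-size nucleus,
`splitMinSize` = 120 um^3) while the two ~80 um^3 chromatin lobes of one
late-anaphase nucleus collapse back into a single segment. Components below `minSize` (30 um^3) are dropped and labels are
re-numbered contiguously. Otsu is computed globally per volume through the
standard EBImage implementation; a per-spheroid local threshold was
considered and rejected as the default because the synthetic and real
use-cases have a single illumination regime per position.

`computeHaralick()` quantises each segment's intensities to 32 grey levels
*within the segment* (making features invariant to affine intensity
rescaling, i.e. illumination-robust), accumulates symmetric co-occurrence
matrices for the 13 unique unit directions of the 26-neighbourhood
(counting only pairs entirely inside the segment), computes the 13
classical Haralick statistics per direction with natural logarithms, and
averages over directions. Degenerate cases are pinned: a constant segment
has correlation 0 by convention; segments under 8 voxels yield missing
features with a log message.

# Phase classification

`extractSlices()` cuts each nucleus' bounding box into XY, XZ and YZ
planes, masks them to the segment, zero-pads square, resizes to 64 x 64
(bilinear, via EBImage) and normalises each patch to [0, 1]. The default
normalisation divides by a volume-wide reference (2.5 times the
lower-quartile foreground intensity -- a robust proxy for diffuse
interphase chromatin that does not move with the mitotic fraction of the
volume -- clipped at 1) rather than per-patch min-max: the
~1.8-fold brightness of condensed mitotic chromatin over diffuse
interphase chromatin is one of the strongest class cues, and per-patch
min-max deletes it while stretching the faint heterogeneity of dim
interphase patches (neighbour bleed-through, deconvolution noise) into
full-contrast speckle that reads as prophase. Per-patch min-max remains
available (`normalize = "patch"`). Masking is the default because
neighbouring nuclei otherwise leak into the patch; the unmasked variant is
available (`mask = FALSE`). The pipeline classifies
from the three centroid planes (`planes = "central"`), which carries
nearly all of the phase signal at a third of the cost of full per-plane
voting; `planes = "all"` implements the full vote.

Two classifiers share the annotation interface:

* `trainRF()`: a 200-tree random forest on the 13 Haralick features,
  sqrt(p) candidate features per split, inverse-frequency class weights.
* `trainCNN()`: the compact VGG-style network -- three 3 x 3 convolution
  blocks (16, 32, 64 channels) each followed by 2 x 2 max pooling, a
  128-unit fully connected layer and a softmax head. It is implemented in
  the package (RcppArmadillo, im2col + single-precision GEMM) and trained
  with Adam (lr 1e-3, beta 0.9/0.999), inputs centred to [-0.5, 0.5],
  batch 128, 16 epochs under a step learning-rate schedule (full rate for
  half the epochs, then a third, then a tenth), with the eight axis
  rotations/flips as augmentation. Plain SGD was tried first and either
  diverged or underfit within a CPU-scale epoch budget; Adam converges
  reliably here. Training is deterministic for a fixed seed and thread
  count; all randomness comes from the R RNG.

Both record a stratified 10% holdout accuracy in their bundle; the CNN
holds out *nuclei*, not slices, so no nucleus contributes to both sides.
`classifySegment()` selects the class with the highest summed per-slice
likelihood; sums are normalised into aggregated probabilities and exact
ties resolve to the earliest class in the declared order (interphase first
in the canonical order).

The default benchmark (`makePhaseBenchmark()`) renders 800 nuclei per
class in batches of 160 packed at spheroid density and pushes them
through the *full* pipeline -- dual-view rendering, bead calibration,
resampling, joint Richardson-Lucy fusion, segmentation -- before features
and slices are extracted. Both choices matter and were forced by failed
alternatives: Richardson-Lucy amplifies shot noise into speckle-like
texture, so a classifier trained on raw (non-deconvolved) renders
mistakes deconvolved interphase chromatin for prophase wholesale; and a
classifier trained on *isolated* nuclei misreads packing artefacts
(neighbour point-spread bleed, segment masks truncated by adjacent
nuclei) the same way. Training data must carry the same processing and
context artefacts as the data being classified. An isolated-grid layout
remains available (`layout = "grid"`). On this benchmark the CNN's per-slice
holdout accuracy exceeds the random forest's per-nucleus accuracy, which
motivates using the CNN in the pipeline; the 6-class variant (adding
macronuclei and apoptotic condensed DNA) is the same architecture with six
outputs.
Two holdout accuracies are recorded per trained CNN: the per-slice
accuracy (the quantity the 96% floor refers to) and the per-nucleus
summed-likelihood voted accuracy, which is the accuracy of the unit the
pipeline actually deploys and the right quantity to compare against the
random forest's per-nucleus accuracy.

# Spheroid time series

Nuclei are grouped into spheroids by single-linkage clustering of their
centroids cut at 25 um (about two nucleus diameters), with identities kept
stable by matching cluster centres frame to frame. Tracking is greedy
mutual-nearest-neighbour within a 10 um per-frame gate; children appearing
within the gate of a vanished nucleus record its track as their parent.
Migration speed is the per-spheroid median of per-step speeds. Transition
events are emitted wherever consecutive phase calls along a track differ;
the valid set is interphase->prophase, prophase->metaphase,
metaphase->anaphase, anaphase->interphase, plus a division exiting from
anaphase -- everything else (e.g. prophase->interphase, the apoptosis
signature) is flagged improper. Both event counts and the number of
transitioning nuclei are reported, since either convention may be wanted.

Growth rates smooth the count series with `stats::lowess` (span f = 1/3,
3 robustifying iterations, delta = 0.01 x the series range) and take first
differences -- lowess reproduces straight lines exactly, so a linear count
series yields its slope. Spheroid volume is the convex hull of the union
of member segments (own quickhull implementation; no hull package is
available in the target environment); sphericity uses the hull surface
area, convexity the hull volume, compactness the minimal bounding sphere
of the hull vertices, and all three are clipped at 1 because voxelisation
can push a digital ball marginally above the analytic bound.

# Phenotype profiles

`assembleAndScale()` centres and scales feature columns (dropping constant
or all-missing ones with a warning, recording per-plate exclusions), and
`rankCluster()` replaces each column by its ranks across samples (average
ranks on ties), computes Euclidean distances and cuts a complete-linkage
hierarchy at the requested number of clusters. Ranking makes the result
invariant to any strictly monotone per-feature distortion, which is the
point of rank-based clustering; a matrix-global rank mode is available
behind `rankMode = "global"` since either reading of "rank the matrix" is
defensible, with per-column the default as the standard interpretation.
Enrichment against controls flags class fractions exceeding 1.5-fold the
control fraction; classes absent from controls are flagged "control-zero"
rather than dividing by zero.

# Screen layout and pre-screen

`generateSpotGrid()` reproduces the 40 x 8 = 320-spot plate at 2.25 mm
(1536-well) pitch with eight replicate spots per sample in 2 x 4
subarrays. `planAcquisition()` is exact integer bookkeeping (40 positions
x 1200 slices x 2 views = 96,000 pre-screen images; 2 x 1024^2 x 260 x 2
bytes ~ 1.1 GB per dual-view position stack). `selectSpheroids()` applies
the pre-screen exclusions -- minimum volume 2 x 10^4 um^3, aspect ratio at
most 2.5, flatness at most 3 (thresholds chosen by us; the rules
themselves are fixed, their numeric cutoffs were never published) -- and
selects the deepest surviving candidate per spot, minimising light-path
obstruction.

# Numerical conventions

Coordinates are micrometres in right-handed X, Y, Z order; voxel (i, j, k)
(0-based) is centred at (i vx, j vy, k vz). Transforms map view-B
coordinates into the view-A frame. Every stochastic operation takes an
explicit seed and uses `withr::with_seed`; nothing depends on the global
RNG state. Ties are broken deterministically throughout: first class in
declared order for voting, brighter candidate for bead suppression,
queue order for region growing, fixed sample order for clustering.

# Known limitations

* The generator's phase morphologies are stylised; accuracy numbers on the
  synthetic benchmark are upper bounds of self-consistency, not estimates
  of performance on real chromatin images.
* Registration assumes a bead field visible in both views; intensity-based
  (bead-free) registration is out of scope.
* Lineage reconstruction stops at one generation of parent links.
* The alternating Richardson-Lucy update is the standard dual-view
  choice, but its per-view objective is only empirically monotone; no
  convergence proof is claimed for the joint scheme.
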