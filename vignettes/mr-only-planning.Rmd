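---
title: "MR-only treatment planning for the rat brain: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MR-only treatment planning for the rat brain: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Kilovoltage small-animal irradiators plan dose on CT because CT supplies
electron-density information, but CT has poor soft-tissue contrast in the
rodent brain, which makes target selection difficult. MR imaging has
excellent soft-tissue contrast and no ionizing dose, but its voxel values
carry no density information, and conventional spin-echo/gradient-echo
sequences return essentially no signal from bone or air (low proton
density, sub-millisecond T2*), so air and bone cannot be told apart.
Short-echo sequences (UTE, with echo times of tens of microseconds, and
ZTE, with a nominally zero echo time) capture the fast-decaying bone
signal and restore that contrast.

`mr2plan` implements an MR-only planning workflow built on that idea:

1. correct each MR volume for the smooth multiplicative **bias field**;
2. segment any subset of the co-registered sequences into **air / soft
   tissue / bone** by multi-channel fuzzy c-means (FCM), with a T1-derived
   head mask forcing everything outside the head to air;
3. score segmentations against a CT-derived reference with per-class
   **Dice coefficients** (bone and soft tissue averaged);
4. convert a segmentation to a **pseudo-CT** by bulk assignment of tissue
   properties;
5. compute **kV dose** for static beams and arcs with a primary-photon
   ray-trace engine, normalized to a 15 Gy prescription in a 2.5 mm
   spherical target;
6. compare MR-planned to CT-planned dose through cumulative **DVH**
   metrics (D5/D50/D90) and Mann-Whitney U tests.

All volumes are `image_volume` objects (3D array + spacing + origin, mm)
read and written as NIfTI. Inputs are assumed rigidly co-registered;
registration itself is out of scope.

## The synthetic phantom

No animal imaging ships with the package; every stage is exercised on a
digital rat-head phantom (`phantom_spec()`, `simulate_phantom()`):

* an ellipsoidal soft-tissue head (default semi-axes 11 x 20 x 11 mm)
  wrapped in a bone shell (default 0.7 mm), in air, on a 128^3 grid with
  0.275 x 0.5 x 0.275 mm voxels — the acquisition geometry of a typical
  7 T rodent protocol;
* internal air cavities (default 3, radius 1.0–1.8 mm) in the posterior
  head;
* thin coronal bone septa in the anterior head (default 3), emulating the
  complex rostrum that is the known failure region of MR bone
  segmentation. Each septum carries a random 1.2–1.8 mm airway aperture:
  real nasal septa are perforated, and the aperture also keeps the soft
  tissue 6-connected, which the largest-component step of head masking
  relies on;
* per-sequence intensities from editable `sequence_model()` tables
  (arbitrary units, synthetic): soft tissue ~100 on every sequence; bone
  8 / 6 / 140 / 20 / 160 on T1 / T2 / UTE1 / UTE2 / ZTE; air 0 everywhere.
  These encode the qualitative contrast the method needs — bone invisible
  on conventional sequences, weak at a 2 ms echo (UTE2), bright at
  short echo — without claiming any quantitative calibration;
* a smooth multiplicative bias field: white noise smoothed to a 12 mm
  correlation length, centred and scaled so the field has mean exactly 1
  and lies within 1 ± amplitude (default amplitude 0.3). The generator's
  field is deliberately *not* drawn from the estimator's own model class;
* **Rician** noise (default sigma 5, i.e. 5 % of the soft-tissue mean),
  the correct magnitude-image statistics: signal-free air acquires the
  Rayleigh floor sigma * sqrt(pi/2);
* a reference CT with Gaussian noise (air −1000, soft 40, bone 700 HU)
  whose threshold segmentation (`segment_ct()`, cuts −480 / 370 HU)
  stands in for the manual CT segmentation used as planning reference.

What the phantom does **not** model: partial-volume mixing at tissue
boundaries (voxels are pure-class), k-space/pulse-sequence physics,
registration error, and anatomical detail beyond the shell/cavity/septum
geometry. Segmentation on this phantom is therefore nearly perfect for
well-contrasted channel combinations; passing tests demonstrate the
machinery's correctness and the *relative* ordering of sequence
combinations, not the absolute Dice level attainable on real animals,
which is far lower.

## Bias-field correction (CLIC)

`estimate_bias()` minimizes the coherent-local-intensity-clustering
energy: for image $I$, bias $b$, class centroids $c_i$ and fuzzy
memberships $u_i$,

$$E = \sum_x \sum_{i=1}^{3} u_i(x)^q \int K(y-x)\,\bigl(I(x) - b(y)\,c_i\bigr)^2\,dy,$$

with a truncated Gaussian window $K$ and $q = 2$. Each block update is
the analytic minimizer with the other two fixed, and the window sums are
evaluated by separable Gaussian convolution, so one iteration costs a few
convolutions. The energy therefore decreases monotonically
(`energy_trace`), and the iteration stops at a relative change below
`tol` (1e-4) or `max_iters` (50), in which case the state is returned
flagged unconverged rather than raising.

Design choices:

* **Window scale** `kernel_sigma = 2` mm. CLIC's derivation treats the
  bias as constant within a window, so the window must be small against
  the field's correlation length (12 mm here, and coil inhomogeneity in a
  40 mm rodent coil varies on centimetre scales) while still averaging
  enough voxels to be stable; 2 mm is 4–7 voxels at the default spacing.
  With markedly wider windows the estimate over-smooths and recovery
  degrades.
* **Masked processing**: the fit runs inside a head mask only. Outside
  the head the image is a pure Rician floor, which the multiplicative
  model cannot describe.
* **Initialization** is deterministic (10th/50th/90th intensity
  percentiles), removing seed sensitivity from a stage whose
  classification is discarded: only the bias field is used, divided out
  by `apply_correction()`. The returned field is rescaled to mean 1 over
  the mask (centroids absorb the scale), so correction preserves the mean
  masked intensity to within ~1 %.

On phantoms with amplitude-0.3 fields and 5 % noise the estimated field
correlates with the truth at r = 0.96–0.99 across seeds.

## Segmentation

**Head mask** (`make_air_mask()`): Otsu threshold on the (corrected) T1
volume, largest 6-connected component, morphological closing (ball,
2 voxels), then a *physical* dilation of 1.2 mm (anisotropic,
spacing-aware). The dilation is deliberate: on T1 the skull is as dark as
air — that is the whole problem — so the Otsu foreground is the
soft-tissue core only, and without dilation the shell would be clipped
out of the mask and forced to air. The extra ~1 mm air rind inside the
mask is harmless because the clusterer labels it air anyway.

**Features** (`build_features()`): the requested sequences in canonical
order (T1, T2, UTE1, UTE2, ZTE — so permuted subsets are bit-identical),
each channel z-scored over the mask. Standardization is what makes the
Euclidean norm of the objective meaningful across sequences with
different intensity scales.

**FCM** (`fcm_cluster()`): minimizes
$Q = \sum_i \sum_j u_{ij}^m \lVert x_i - c_j \rVert^2$ subject to
$\sum_j u_{ij} = 1$, with the standard alternating closed forms, $m = 2$,
relative tolerance 1e-5, at most 200 iterations; points that coincide
with a centroid get membership 1. Initialization is k-means++ on a
deterministic subsample with a recorded seed: FCM is sensitive to
initialization and reproducibility is required. The recorded
`objective_trace` is non-increasing; on small instances the final Q
matches a 50-restart brute-force optimizer to 1e-6.

**Cluster naming** (`identify_clusters()`): air is the cluster darkest on
average across *all* channels (air gives no signal on any sequence; using
conventional channels only is ambiguous because bone is equally dark
there). Of the remaining two, when a short-echo channel is present, bone
is the cluster with the larger short-echo-to-conventional intensity
ratio; without one, bone is the darker remaining cluster. Ties at
relative 1e-6 are broken by centroid norm with a warning.

**Hard classification** (`classify()`): per-voxel argmax of membership,
ties resolved toward air before soft before bone; voxels outside the head
mask are air. `sweep_combinations()` runs every non-empty subset of the
available sequences — 31 for the full set of five — in deterministic
order (size, then lexicographic).

## Similarity

`dice_class()` is the plain 3D Dice coefficient
$D = 2\lvert A_t \cap B_t\rvert / (\lvert A_t\rvert + \lvert B_t\rvert)$.
Bone and soft tissue are the planning-relevant classes and their average
is the ranking score; air Dice is reported as a diagnostic column only. A
class absent from both volumes scores a vacuous 1 with a warning (keeping
rankings total while remaining auditable). Multi-animal aggregation is
the arithmetic mean ± SD of per-animal scores.

On phantoms, every multi-channel combination that includes a short-echo
sequence outperforms every single conventional sequence — the phantom
reproduces the direction of the real finding (combinations with UTE/ZTE
segment bone well; single conventional images cannot separate air from
bone).

## Pseudo-CT and the dose engine

`assign_properties()` performs bulk assignment: air 0.0012, soft 1.0,
bone 1.6 g/cm^3, with mass attenuation and energy-absorption coefficients
at a single effective energy of ~40 keV (a 70 kVp beam), stored as linear
attenuation per mm. The values are standard tabulated constants but
function here as configuration: CT- and MR-based plans share the table,
so the CT-vs-MR comparison is insensitive to its absolute calibration.
There is deliberately no continuous HU-to-density curve — the workflow is
three-class by construction.

`beam_dose()` is a documented primary-photon engine: inside the diverging
square field (3 x 3 mm at isocenter), dose is proportional to
$(\mathrm{SAD}/r)^2 \, e^{-\int \mu\,dl} \cdot (\mu_{en}/\rho)$, with the
radiological path computed by an exact Siddon voxel walk (compiled code).
No scatter, no spectrum, no penumbra: the package's claims concern
*relative* CT-vs-MR dosimetry, which a transparent engine exercises
fairly, rather than absolute dose, which a commercial treatment-planning
system computes with proprietary algorithms. On a homogeneous block the
central-axis depth dose matches the closed form to well under 1 %.

Geometry: the source lies at SAD (default 350 mm, a typical small-animal
platform scale) along the +z axis rotated by the gantry angle
(right-handed about +y) then the couch angle (right-handed about +z).
Arcs (default 120°) are discretized at `angular_step` (5°) into
equal-weight beams at interval midpoints, making the summed dose
covariant under rotation of the start angle. The default plans mirror the
three study arrangements: one static anterior beam (gantry 90°, couch
90°, entering through the rostrum), one coplanar arc (couch 0°), and
three non-coplanar arcs (couch 0°/45°/90°).

`plan_dose()` sums the segment doses and scales so that the *mean* dose
in the spherical target equals the prescription (15 Gy); a D50-based
normalization is available via `normalization = "d50"` since the
prescription convention of commercial systems varies.

## DVH analysis and the CT comparison

`cumulative_dvh()` uses the standard "receives at least" convention on a
bin grid no coarser than 0.05 Gy; `d_metric()` returns the largest bin
dose still covering x % of the volume (the right-continuous inverse), so
step-function cases are exact — for a two-voxel volume at 10 and 20 Gy,
D50 = 20 Gy — and any dose field satisfies D5 ≥ D50 ≥ D90.

The CT comparison follows the clinical logic of an MR-only workflow: the
plan's machine output is fixed by normalizing on the MR-based pseudo-CT,
and the dose actually delivered is what that output produces on the CT
(truth) anatomy. `compare_to_ct()` reports delivered-to-reference ratios
per metric, aggregated mean ± SD over animals. Under this semantics,
missing bone in the MR segmentation makes the MR calculation optimistic,
the output is scaled down, and the target is under-dosed (ratio < 1);
air misread as bone produces the opposite error. Because the engine
applies a single scale factor to an otherwise identical beam set, the
D5/D50/D90 ratios coincide per plan; the small metric-to-metric spread a
commercial system shows comes from recalculation effects outside this
engine's scope.

With the anterior bone deliberately removed from the "MR" segmentation
(`missegment_rostrum()`), the single anterior beam under-doses the target
by ~15 % while the three-arc plan is ~2 % off — multiple beam directions
dilute a localized segmentation error, which is the qualitative clinical
claim the phantom reproduces across seeds.

`mann_whitney()` wraps the two-sided rank-sum test: exact null
distribution for combined n ≤ 20 without ties, tie-corrected normal
approximation otherwise; when every observation is tied the statistic's
variance is zero and the comparison degenerates to p = 1.

## Numerical choices and edge cases

* Gaussian smoothing is separable banded-matrix multiplication, truncated
  at 3 sigma; unnormalized (fixed-kernel) for the CLIC window, boundary
  renormalized when synthesizing bias fields.
* CLIC distances are floored at machine epsilon; a zero window
  denominator far outside the mask resets the bias to 1 there; an
  identically zero masked image is a degenerate-input error.
* FCM: exact centroid hits get crisp memberships; fewer than c distinct
  feature vectors is an error; ties in cluster naming are broken by
  centroid norm, with a warning.
* DVH bins start at 0 (the curve is exactly 1 there) and extend one bin
  beyond the maximum dose (exactly 0).
* Rays parallel to grid planes, rays missing the grid, and targets
  receiving no dose are all handled explicitly (zero contribution, zero
  path, and a prescription error respectively).
* All randomness flows through explicit seeds; per-animal and
  per-sequence seeds are derived from one master seed, and `provenance`
  output captures every parameter needed to reproduce a run.

## Problem sizes used by the test suite and acceptance script

The package defaults describe the full acquisition geometry (128^3).
The test-suite and `scripts/acceptance.R` choose sizes per stage: the
combination sweep and ranking checks run on the default 128^3 phantom;
bias-field recovery on 64^3 phantoms with proportionally scaled heads
(seeds 1–5); the mis-segmentation dosimetry on 96^3 phantoms over 5
seeds; unit tests on 24^3–48^3 phantoms. These are the package's own
verification scales; the statistical structure (noise fraction, bias
amplitude, class geometry) is identical at every scale.

## Known limitations

* Pure-class voxels: no partial-volume effect, which inflates absolute
  Dice relative to real data.
* The dose engine is primary-photon only at one effective energy; output
  is meaningful only for CT-vs-MR *ratios* on shared geometry.
* Three tissue classes suit the head; thoracic or abdominal sites would
  need more classes (lung, fat) and are out of scope.
* The "modified" FCM variants in the literature differ in unpublished
  details; this implementation is the standard multi-channel FCM, and the
  clustering stage is deliberately pluggable.
* Head masking assumes a single connected head with a perforated internal
  bone structure; a fully sealed internal compartment would be masked
  out.
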