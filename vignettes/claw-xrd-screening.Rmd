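---
title: "Screening for cancer from claw-keratin X-ray diffraction patterns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for cancer from claw-keratin X-ray diffraction patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the measurement

Keratin in claws, nails and hair is a fiber-forming protein whose packing
produces a characteristic wide-angle X-ray diffraction signature: on a 2D
photon-counting detector, a thin claw shaving yields two pairs of antipodal
arcs, at real-space periods of about 0.51 nm (the molecular packing along
the coiled-coil) and 0.98 nm (the intermolecular distance between keratin
molecules), on top of an amorphous background and an intense primary-beam
spot. The working hypothesis behind this package is that systemic disease —
cancer in particular — subtly alters keratin packing, and that those
alterations are readable in the diffraction pattern of a claw shaving: a
non-invasive, cheap screening signal.

`clawxrd` implements the complete analysis as a tested pipeline:

1. **simulate** a cohort of detector frames with realistic structure
   (patients, multiple shavings per patient, a binary cancer label),
2. **preprocess** each frame into a standardized, comparable image,
3. **extract** Fourier-series features from radial and circular intensity
   profiles,
4. **classify** samples with a cross-validated random forest under a
   patient-level blind split, and
5. **aggregate** per-sample cancer probabilities into per-patient
   diagnoses with ROC/sensitivity/specificity/balanced-accuracy reporting.

Because the measured canine cohort this design mirrors is private, the
synthetic generator is a first-class module: it defines the study
conditions under which every claim in the test suite is checked.

## Detector geometry

A frame is a 256 x 256 grid of photon counts, 55 um pixels, Cu-anode
wavelength $\lambda$ = 0.1540562 nm. A period $d$ diffracts at the Bragg
angle $\sin\theta = \lambda/2d$ and lands at detector radius
$r = (D/p)\tan 2\theta$ ($D$ the sample-to-detector distance, $p$ the pixel
pitch); the transfer momentum is $q = 4\pi\sin\theta/\lambda = 2\pi/d$. The
default $D$ = 21 mm is chosen so that the recorded window spans roughly
2-13 nm$^{-1}$: the 0.98 nm arc sits at $q \approx 6.4$ nm$^{-1}$
(r $\approx$ 61 px) and the 0.51 nm arc at $q \approx 12.3$ nm$^{-1}$
(r $\approx$ 119 px), both strictly on-detector. The geometry object
validates this at construction.

## What the simulator emulates — and what it does not

`render_pattern()` draws Poisson counts around a closed-form expected
surface: exponential amorphous background, Gaussian beam spot, and per arc
a radial Gaussian multiplied by a two-lobed von-Mises-like angular profile
(period 180 degrees, fiber symmetry) mixed with an isotropic ring;
`ring_fraction` is the isotropic share of the arc's intensity. Hot pixels
(saturating constants at 65535) and dead pixels (zeros) are injected after
the counting noise, as on a real readout. Raw integrals are drawn uniformly
in the instrument's 2-10 mln count range. The Monte-Carlo mean of rendered
frames is tested against the analytic surface annulus by annulus.

The cancer effect follows the direction seen in group-averaged difference
images of measured claw patterns: oriented 0.98 nm peaks are suppressed,
the isotropic 0.98 nm ring is enhanced, with a weaker same-direction change
at 0.51 nm and a mild loss of orientation order. The magnitude of the
effect is **not** quantified by real measurements; the defaults here were
chosen once so that the full pipeline operates in a realistic screening
regime — discriminative but overlapping classes, with patient aggregation
visibly improving on per-sample classification — and the `effect`
multiplier exposes the whole family from a null cohort (`effect = 0`)
upward.

Biological variability acts at two levels, deliberately on the same
parameters that separate the classes (otherwise intensity standardization
absorbs it and patients separate unrealistically well): per patient,
independent lognormal amplitude multipliers per arc (sd 0.20), ring-fraction
perturbations (sd 0.14) and a concentration multiplier (sd 0.15); per
sample, a shared amplitude multiplier (sd 0.15), smaller ring-fraction
jitter (sd 0.05) and a concentration multiplier (sd 0.10). A cancer
patient's shaving is drawn from the *non-cancer* structural distribution
with probability 0.15 (`unaffected_sample_rate`): not all claw keratin is
altered by disease, which is what makes some cancer patients
all-samples-misclassified, as observed in practice.

What the simulator does **not** model: atomic form factors, polarization,
absorption and solid-angle corrections, instrumental smearing beyond the
Gaussian arc widths, parasitic scattering streaks, or any cancer-type
structure. Passing tests therefore demonstrate that the *pipeline*
recovers what it is designed to recover under controlled conditions — they
are not evidence about measured claws.

## Preprocessing choices

The standardization chain runs in a fixed order: AgBH q-scale calibration
(optional) - centering - hot/dead-pixel repair - central-spot and circular
crop - rotation alignment - intensity standardization. Several steps are
underdetermined by common practice, so the package fixes them explicitly:

* **Calibration** measures the azimuthal-profile peak near one harmonic of
  the silver behenate lamellar period $d_{001}$ = 5.838 nm (harmonic 3 by
  default, parabolic sub-pixel refinement) and rescales only when the
  measured/expected discrepancy exceeds 3% — data with spread inside the
  tolerance are left untouched, matching the source study's handling.
* **Centering** seeds an outlier-clipped centroid of the central region and
  refines each coordinate against the mirror symmetry of the marginal sums
  (a fiber pattern is inversion-symmetric through the beam center);
  tolerance 0.5 px, verified against simulator ground truth and by
  translation equivariance.
* **Hot-pixel repair** screens within unit-width annuli (median + 6 MAD)
  — annulus statistics respect the radial structure the substitution rule
  assumes — but adds a spatial isolation veto: a hot candidate must also
  tower over its immediate neighbors (count > 4x the trimmed neighbor mean
  + 10), because diffraction arcs make annuli legitimately anisotropic and
  a pure annulus screen flags the lobes themselves. Dead pixels are
  isolated zeros whose neighbors clearly count photons. Flagged pixels are
  replaced by the unflagged annulus mean and *masked* — they never reach a
  profile.
* **Cropping** masks $q <$ 2 nm$^{-1}$ (the window floor; this removes the
  primary-beam spot) and everything outside the inscribed disk.
* **Rotation** estimates the fiber orientation as the circular mean
  (period 180 degrees) of the intensity on the 0.98 nm annulus — the
  stronger-anisotropy arc — after subtracting the annulus median, and
  rotates it onto the vertical axis. A flat angular distribution (resultant
  length < 0.1) yields rotation 0 and an isotropy flag. Recentering,
  rotation and any calibration rescale are fused into a single bilinear
  resampling so each pixel is interpolated once; an output pixel whose
  interpolation neighborhood touches a masked source pixel is itself
  masked.
* **Standardization** multiplies the unmasked intensities by one scalar so
  they sum to exactly 5 mln counts; ratios between pixels are preserved
  exactly.

Conventions: 0-based pixel indices, centers as fractional (row, col),
angles in degrees counter-clockwise from the +x (column) axis, annuli
half-open $[r, r+1)$.

## Features

Four profiles per frame: radial profiles along the horizontal and vertical
axes (5 px band, antipodal rays averaged, one point per unit radius from
the crop floor to the disk edge) and circular profiles on the 0.98 and
0.51 nm annuli (5 px annulus, 1-degree bins folded onto the semicircle
$[0^\circ, 180^\circ)$ by fiber symmetry). Each curve is expanded in an
order-$N$ Fourier series over its range $L$,

$$S_N(x) = \frac{a_0}{2} + \sum_{n=1}^{N} a_n \cos\frac{2\pi n x}{L}
  + b_n \sin\frac{2\pi n x}{L},$$

with coefficients evaluated by trapezoidal quadrature on the native
sampling grid (tested against a 100x-resolution oracle; an aliasing guard
rejects $N \ge (\text{points}-1)/2$). At the default $N = 10$ this gives
40 radial and 40 circular features; $a_0$ is excluded because the total
intensity is standardized to a constant (a switch restores it). The
feature-group selector (radial / circular / both) reproduces the study's
three experiments. The pipeline's central comparability claim — that
features do not depend on the stored orientation or beam position of the
raw frame — is tested directly: feature vectors of one structure rendered
at different orientations and centers differ by a small fraction of the
between-class distance.

## Classification and patient aggregation

Patients, never samples, are split into training and blind sets
(stratified, default test fraction 68/265). The random forest is tuned by
grid search — trees in {100, 300, 500}, depth in {unlimited, 5, 10},
features-per-split in {sqrt, log2}, balanced class weights — scored by
mean ROC-AUC over 10-fold cross-validation whose folds are *grouped by
patient*. Grouping is a deliberate strengthening over optimizing on raw
samples: it closes the leakage channel between shavings of one dog, and the
leakage audit (no patient in both halves of any fold pair or of the blind
split) is part of the test suite.

Three sample-to-patient transfer rules are provided: mean predicted
probability per patient (the default and the most reliable; indifferent to
unequal sample counts), N-of-4 voting (warns and falls back to a
proportional rule when sample counts differ), and per-patient feature
averaging before training (supported but known to be unstable — it
discards within-patient information). Averaging independent per-sample
noise shrinks it, so the patient-level ROC-AUC should exceed the
sample-level one; the suite asserts this on the default cohort.

Metrics follow the screening objective: over a threshold grid (0 to 1,
step 0.01) the report tabulates sensitivity, specificity and balanced
accuracy = (sensitivity + specificity)/2, and singles out the operating
point with maximal balanced accuracy subject to specificity > 90%. ROC
curves use the midrank tie convention; the trapezoid AUC is tested to
$10^{-10}$ against an independent Mann-Whitney implementation.

## Numerical and degenerate-input choices

* Bilinear interpolation everywhere a frame is resampled; masked pixels
  never enter an interpolation neighborhood.
* Annuli with fewer than 8 pixels skip hot-pixel repair (warning).
* A frame whose angular distribution is flat is processed with rotation 0
  and flagged; the workbench's quality control can reject such frames,
  along with frames whose repaired-pixel fraction exceeds 1% or whose
  centering fails — counts are logged, mirroring real acquisition QC.
* Zero unmasked intensity at standardization, single-class metric inputs,
  off-detector geometries and aliasing-order Fourier requests raise errors
  that name the offending stage.
* Ties in the CV grid resolve to the earliest grid row; every stochastic
  step (cohort, split, folds, forest) takes an explicit seed.

## Problem sizes used by the checks

The test suite exercises the full default cohort — 265 patients at
prevalence 104/265, modal 4 shavings per patient with 15% dropout,
`unaffected_sample_rate` 0.15, fixed seeds — for the headline
patient-versus-sample comparison (radial features, the study's best
group), and smaller cohorts (80-120 patients) for the effect-size
monotonicity ladder and the null cohort, whose AUC is asserted to sit
within binomial noise of 1/2. The Monte-Carlo render oracle uses 200
replicate frames. These sizes are the package's own choice of
desk-scale reproduction; `run_config()` scales all of them.

## Known limitations

* The synthetic effect size is a design choice, not a measured quantity;
  absolute blind-set metrics on synthetic cohorts are therefore
  plausibility anchors, not reproductions of measured performance.
* The relative ranking of the three feature groups is **not** a reliable
  property of the simulator: measured claw data are reported to favor
  radial features because real circular profiles are noisy, but the
  simulated arcs are smooth two-lobed profiles whose circular features
  carry the class signal (ring fraction, orientation order) quite
  directly, and on the default cohort the circular group performs
  on par with or slightly above the radial one. Only the
  patient-beats-sample and effect-monotonicity properties are asserted.
* The rotation-alignment criterion (circular mean on the 0.98 nm annulus)
  is one reasonable choice among several; it is validated against
  simulator ground truth, not against the original instrument software.
* Real-data mode (`process_manifest()`) reads TIFF or text matrices with a
  manifest CSV but has, by construction, never seen measured claw data.
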