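---
title: "Quantifying PLA signals in 3D confocal stacks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying PLA signals in 3D confocal stacks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plaq)
```

## The measurement problem

A proximity ligation assay (PLA) renders each close apposition (under ~40
nm) of two antibody-bound proteins as one bright fluorescent dot. In a
two-channel confocal z-stack the total dot area is therefore a readout of
how much two proteins — here an amyloid-precursor-protein species and one
of its secretases — colocalize in a field of cells. Raw dot area is not
comparable across images with different cell numbers, so the score of
interest is the **ratio of PLA dot area to DAPI nucleus area**, a per-cell
colocalization index. A second readout asks *where* the colocalization
happens: with a GFP-tagged organelle marker (Rab5a early endosomes, Rab7a
late endosomes, Lamp1 lysosomes) in the primary channel, the score is the
**percentage of organelle volume occupied by PLA signal**.

`plaq` implements both measurements, the statistics applied to them (ROUT
outlier removal, Student's two-tailed t test, calibrator-normalized fold
changes), the qPCR and immunoassay bookkeeping rules that accompany such
experiments (delta-delta-CT, half-LOD censoring), and an algebraic
decomposition that turns two measured fold changes into inequality bounds
on the unobserved C-terminal-fragment (CTF) contribution to a composite
PLA signal.

## The nucleus-normalized pipeline

For a `{nucleus, PLA}` stack pair, each channel is processed independently:

1. **3D Gaussian blur**, sigma 3 voxels for the nucleus channel and 1 for
   the PLA channel. The blur is separable, isotropic in voxel units, uses
   reflective boundaries (total intensity is conserved), and its output is
   kept in real arithmetic — nothing is re-quantized before thresholding.
2. **Best-focus plane**: the z index with the highest mean intensity, ties
   to the smallest z.
3. **Auto-threshold on that single plane**: Li's minimum cross-entropy
   method for the nucleus, the Triangle method for the PLA channel. Each
   yields a lower cut; the upper bound of the band is the top of the
   representable range, which is non-binding for bright-on-dark signal.
4. **3D application**: the one band is applied to every plane of the stack
   (foreground is `lower <= v <= upper`, inclusive). The band is frozen per
   channel per image; there is no per-plane re-thresholding.
5. **Size filter**: connected components (26-connectivity) smaller than a
   minimum voxel count are removed — defaults 4 voxels for PLA dots and
   500 for nuclei. The source procedure states that dots and nuclei are
   detected "based on fluorescence intensity and size" without printing
   the size cut-offs, so both minimums are exposed as parameters and
   recorded in every result.

The score is `pla_area / nucleus_area` in voxels. "Area" of a 3D-thresholded
stack is read as the **total foreground voxel count summed over z** — the
only unit-consistent reading of an area ratio taken after 3D thresholding;
whatever the unit, it cancels in the ratio. Whether the nucleus denominator
should instead be the best-focus-plane area alone is not decidable from the
source description; the 3D sum is the default and
`nucleus_area_mode = "plane"` provides the plane-only variant.

Li's threshold is computed by an exhaustive scan: over every candidate cut
the image is split into the below/above classes and the cross-entropy
`-(M1 log mu1 + M2 log mu2)` (class intensity masses `M`, class means `mu`)
is minimized; ties go to the smallest cut. For continuous (blurred) data
the candidates are 256 bin centers over the observed range; for discrete
data, the exact intensity levels. The Triangle threshold builds a 256-bin
histogram over the observed range, draws the line from the histogram peak
to the farthest non-empty tail bin (mirroring the histogram first if the
long tail is on the left, so the rule is symmetric under intensity flips),
and takes the bin with maximal perpendicular distance from that line, ties
to the bin nearest the peak. Both implementations are checked exactly
against independent brute-force oracles in the test suite.

## The organelle-occupancy pipeline

For an `{organelle, PLA}` pair both channels get the same treatment — blur
(sigma 1 by default for both; `sigma = 0` reproduces the literal
description of the original second macro, which mentions no blur), best
focus per channel, Triangle threshold on the best-focus plane, 3D band
application — then the binary colocalization (voxelwise AND) of the two
masks is formed and

`percent_occupied = 100 * |PLA AND organelle| / |organelle|`.

No size filter is applied by default (the size criterion belongs to the
nucleus-normalized procedure); a `min_size` parameter enables one. The
reverse fraction `100 * |AND| / |PLA|` is carried as a diagnostic: it only
coincides with the primary metric when both masks have equal area. The
sigma-1 default is the more robust choice on noisy data and is what every
built-in check runs.

## Statistics layer

**ROUT outlier removal.** The robust-regression-and-outlier-removal
procedure is published for curve fitting; applied to univariate samples it
specializes to a location-only model, and that specialization is what
`rout_outliers()` implements: a robust center fitted by iteratively
reweighted averaging with Lorentzian weights `1/(1 + (r/RSDR)^2)`; the
robust SD of residuals (RSDR) as the 68.27th percentile of absolute
residuals scaled by `n/(n - K)`, `K = 1`; candidate outliers tested largest
residual first with two-tailed t-tail p-values (`df = n - K`) through a
Benjamini–Hochberg-style gate at FDR level `Q`. `Q = 0.001` (0.1%) removes
only definite outliers: on clean normal samples of n = 50 fewer than 1% of
datasets lose any point, while a 10-sigma contaminant is essentially always
removed (both rates are recomputed by the test suite and the acceptance
script). At most `floor(n/2)` points can ever be removed, and constant
samples are returned untouched. Whether the original analysis ran ROUT per
group or on pooled values is not stated; `compare_groups()` applies it per
group, and `rout_outliers()` can be called on any pooling the user
prefers. Groups smaller than 3 skip ROUT (its own precondition).

**Group comparison.** Pooled-variance Student's t with
`df = n_a + n_b - 2`, two-tailed, significance at p < 0.05; Welch's form
is behind a flag but is not the default because the source analysis used
Student's form. Zero-variance degeneracies are resolved by convention
(equal means: t = 0, p = 1; unequal: p = 0 with a flag). Fold changes are
calibrator-normalized so the calibrator group maps to exactly 1. No
multiple-testing correction is applied across panels, matching the source
analysis; this is a faithful reproduction, not an endorsement.

**qPCR and censoring rules.** `delta_delta_ct()` averages technical
duplicates, subtracts the mean CT of the reference genes (RPL27 and HPRT1
by default) per sample, references the calibrator group's mean dCT and
reports `RQ = 2^(-ddCT)`; a global CT shift leaves every RQ unchanged.
`censor_below_lod()` assigns half the detection limit to every measurement
strictly below it.

## The CTF decomposition

The C-terminal APP antibody sees both full-length APP (flAPP) and its
C-terminal fragment, so the C-terminal PLA total splits as `T = F + C`
with per-event detection efficiency assumed equal for the two species —
the model's central, and only, structural assumption. Two fold changes are
measured between the cell states: `r_flapp` for the flAPP-specific signal
(default 1.63, a 63% increase in neurons) and `r_cterm` for the composite
signal (default 0.21; the published account rounds this to "almost 80%
lower", and 0.21 is the value that reproduces both printed bounds
simultaneously, so it is the default and a parameter). Over all feasible
non-negative splits:

* `C_npc / C_neu >= 1 / r_cterm` (≈ 4.76): the CTF contribution falls at
  least ~4.8-fold, minimized as the flAPP share of the NPC signal goes to
  zero;
* `C_npc / F_npc >= (r_flapp - r_cterm) / r_cterm` (≈ 6.76): non-negativity
  of the neuronal CTF contribution forces the NPC CTF contribution to be
  at least ~6.8 times its flAPP contribution.

Both bounds involve only fold changes, so any rescaling of absolute
signals cancels. When `r_flapp < r_cterm` the second bound is vacuous and
is clamped to zero with `feasible = FALSE`. `sensitivity_table()` scans
`r_cterm` over a plausible interval (0.18–0.25 by default) since the input
is a rounded published figure; both bounds fall monotonically in
`r_cterm`. The closed forms are verified against brute-force grid
minimization over the feasible region in the tests.

## The synthetic-scene generator

No imaging data accompany the source work, so `generate_scene()` builds
two-channel stacks with exact voxel ground truth. The default spec mimics
the acquisition regime the pipelines target: 21 planes at 0.5 µm z
spacing; ~0.2 µm lateral sampling on a 256×256 field; three mutually
non-overlapping DAPI-like nuclei as filled ellipsoids with semi-axes
(12, 30, 30) voxels — a ~12 µm nucleus is cropped by a 10.5 µm stack, as
adherent-culture nuclei are in practice; 150 diffraction-limited PLA dots
as 3D Gaussian spots (sigma 1.5 voxels, truncated at 3 sigma, additive);
sixty 0.8-µm organelle spheres free to overlap; 8-bit intensities
(background 20, amplitudes 170/200/160 for nucleus/dot/organelle); Poisson
shot noise at unit gain plus additive Gaussian read noise (SD 8), giving a
raw dot SNR of ~12 (`scene_snr()`); and 30% of dot centers placed
uniformly on organelle voxels. One generator is seeded per scene and draws
are consumed in a fixed documented order, so scenes are bit-reproducible
and determinism survives refactoring.

**Ground-truth labels** are exact voxel sets: nuclei and organelles are
the painted ellipsoids/spheres; a dot's label is its *rendered support* —
the voxels inside the truncation ball where the noise-free contribution is
at least 0.5 intensity units, i.e. exactly the voxels the generator
painted above background. An alternative convention, labeling only the
FWHM core of each spot, was considered and rejected: the Triangle cut on
sparse-dot histograms sits near the background mode, so the pipeline
recovers the full rendered support, ~20× the FWHM core for these spot
sizes, and the FWHM convention would make every recovery comparison
meaningless.

**What the generator does not emulate:** optical PSF physics (no
Gibson–Lanni model), spectral bleed-through, photobleaching, camera gain
calibration, cell-shaped signal backgrounds, or clustered (non-uniform)
dot placement. Passing recovery tests on these scenes therefore shows the
pipeline is implemented correctly and behaves sanely in the intended
regime — it does not certify accuracy on real microscopy data.

**Known recovery biases**, visible in the numbers the acceptance script
reports: thresholds computed from histogram geometry do not sit at the
half-height of object edges. Li's cut on the sigma-3-blurred nucleus lands
near 30% of the nucleus amplitude and includes a ~1.6-pixel halo shell
(nucleus area biased high by roughly a sixth); on noise-free scenes the
Triangle cut sits 1–3 histogram bins above the background spike and the
recovered Gaussian-spot support is very sensitive to which bin wins. The
per-cell ratio consequently runs ~15–20% below truth at default noise —
stable across seeds, and irrelevant to *comparative* conclusions, which
is what the score is used for: a 4× dot-density contrast at 15
images/group is detected (p < 0.05) in essentially every repetition.

## Numerical choices and conventions

* Axis order is (z, y, x); indices user-facing are 1-based (R convention);
  TIFF page order equals ascending z; coordinates in results refer to the
  stored orientation.
* Only unsigned 8/16-bit grayscale TIFFs are accepted; float or RGB pages
  raise format errors rather than being converted silently, keeping
  threshold semantics well defined.
* The manifest CSV, not filename parsing, carries all channel/group
  metadata; paths are resolved relative to the manifest.
* Foreground predicates are inclusive on both ends; best-focus ties break
  to the smallest z; threshold-objective ties break to the smallest cut
  (Triangle: nearest the peak).
* Blur kernels are sampled Gaussians truncated at `ceiling(3 sigma)` and
  renormalized; a plane whose intensity spread is at floating-point noise
  level is treated as constant and rejected by the thresholders.
* Per-image seeds in multi-image experiments derive linearly from one base
  seed and stay within 32-bit integer range.
* xy pixel size is metadata only; no result depends on it.

## Problem sizes used by the built-in checks

The test suite and acceptance script run: full-size default scenes
(21×256×256) for recovery checks — 6 noise-free and 20 noisy seeds in the
tests, 8 noisy seeds in the script; compact scenes (11×64×64, one nucleus,
no organelles) for the 50-repetition power study at 15 images per group;
10,000 datasets of n = 50 for the ROUT null calibration in the tests
(2,000 in the script); and 20+ fixed 8-bit planes for exact threshold
oracle equivalence. These sizes are the package's choices for its own
checks; all of them are parameters the user can scale up.

## Limitations

The pipelines reproduce a specific published macro pair, including its
quirks: one threshold per channel per image computed on a single plane,
intensity-based segmentation without instance separation, and no
correction for the halo biases described above. They quantify total areas,
not per-dot counts or per-vesicle statistics. The statistics layer
implements the published analysis choices (equal-variance t, no
multiple-testing correction) rather than the most defensible modern ones.
The CTF decomposition yields bounds, not estimates, and stands or falls
with the equal-detection-efficiency assumption.
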