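---
title: "Erosion-shell analysis of radial nuclear position: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Erosion-shell analysis of radial nuclear position}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nucshell)
```

## The measurement problem

Radial position — how close a locus or a chromosome territory sits to
the nuclear envelope — is the quantity of interest in screens for
proteins that tether chromatin to the nuclear periphery. Absolute
distances are a poor readout: nuclei vary in size and shape, and in
adherent cells they are strongly flattened, so "distance to the
boundary" conflates lateral position with depth in z. The erosion-shell
construction normalizes both problems away: the nucleus is divided into
K concentric bands of *equal area* (2D) or *equal volume* (3D), so that
a uniformly positioned marker has probability exactly 1/K of landing in
each band regardless of nuclear geometry. Enrichment in shell 1 (the
outermost band) is then directly interpretable as peripheral
recruitment, and the uniform baseline (~20% per shell at K = 5) is a
built-in negative control.

## The partition

`erode_shells_2d()` / `erode_shells_3d()` compute the interior Euclidean
distance transform of the segmented nucleus — the distance of each
pixel/voxel to the nearest point outside the mask, in physical units so
that a 0.2 µm z-step against 0.1 µm pixels is weighted correctly — and
split the pixels into K equal-count quantile bands of the distance,
periphery first. Two properties follow by construction and are asserted
as invariants in the test suite:

* **Equal areas.** Shell sizes differ by fewer than K pixels (the
  discretization remainder of ⌈A/K⌉-sized blocks).
* **Nesting.** Shells are distance-ordered bands: the shell index never
  decreases along any inward path of increasing boundary distance.

The classical implementation of this analysis iterated a morphological
erosion until ~1/K of the area was removed, K times. Iterated erosion
cannot hit exact area targets on irregular shapes (each erosion step
removes a boundary-dependent number of pixels), so this package
implements the stated contract — shells of equal area — directly via
distance quantiles. On analytic shapes the two constructions coincide:
for a disc of radius R the first quantile boundary sits at R·√0.8, for a
ball at R·(5/6)^(1/3), and the tests require agreement within one
pixel/voxel.

Numerical choices worth knowing:

* The distance transform is an exact separable lower-envelope transform
  (implemented in C++); the array border counts as background.
* Ties in distance (common on symmetric shapes) are broken by raster
  order, deterministically; partitions are reproducible bit-for-bit and
  equal, label for label, to a brute-force "sort all distances and cut
  into quantiles" oracle.
* Inside the partition the spacing vector is normalized by its minimum,
  so the common 2:1 z-anisotropy yields integer squared distances and
  tie-breaking is immune to floating-point noise.
* Masks smaller than 25·K pixels (125·K voxels) are rejected rather than
  partitioned into degenerate shells.

## Segmentation and spot scoring

`segment_nucleus()` thresholds each z-slice of the counterstain channel
automatically (Otsu on the slice rescaled to its own range, making the
mask invariant to global intensity scaling; a manual threshold can be
supplied), keeps the largest connected component of the volume, and
fills holes slice-wise so that weakly stained nucleoli are not carved
out of the nuclear area. Contrast-free slices (no nucleus) are skipped.
The midplane is the widest slice, ties resolved toward the lower index.

`detect_spot()` applies an automatic threshold to the spot channel
inside the mask and returns the intensity-weighted centroid of the
brightest connected component — one locus per cell, matching the
single-integration-site design of lacO screens. Cells whose spot sits
more than `tol_slices` (default 1) from the midplane are excluded from
2D scoring by `midplane_gate()`; the default of ±1 slice reflects that
with 0.2 µm steps, demanding the exact slice would discard most
legitimate midplane spots. `assign_spot_shell()` scores the shell at the
rounded (half-up per axis) centroid pixel.

The original analyses did not state their thresholding algorithm nor
whether spot picking was manual; Otsu and brightest-component are this
package's choices, recorded per cell in the pipeline outputs so a run
can be audited.

## Territory profiling

Extended chromosome paints span several shells, so they are scored as
intensity fractions. In 2D, `shell_intensity_profile_2d()` subtracts a
constant background (default: the mode of the outside-mask intensities,
emulating manual background boxes; a manual value can be given), zeroes
sub-threshold pixels, and normalizes per-shell sums to the total. In 3D,
`binarize_territory()` thresholds the paint (territory thresholds are
manual in this literature — the pipeline records the value used),
intersects it with the nucleus and removes connected components below
`min_component_size` voxels (default 27, a 3×3×3 block). "Minimum
density" filters of this kind are known to trim very diffuse internal
signal; the default is deliberately conservative.
`unique_shell_fractions_3d()` then measures colocalization with each
successive erosion and differences consecutive cumulative fractions —
the sequential-subtraction procedure — which is algebraically identical
to direct per-shell summation and asserted equal to 1e-9 on every
fixture.

The per-cell summary statistics are the peripheral sum (shells 1+2) and
internal sum (the two innermost shells).

## Cohort statistics

* **Loci:** `chi2_shell_test()` builds the 2×2 table of shell-1 vs
  internal (3+4+5) counts for test vs control — shell 2 is *excluded*,
  which is easy to get wrong when reimplementing — and computes the 1-df
  chi-squared without continuity correction (a Yates flag exists). "One
  tailed" is formalized as halving the upper tail when the test cohort
  is the more peripheral, and taking the complement otherwise; an
  exactly null table reports p = 0.5. This directional halving is this
  package's construction (the source analyses name the test but not the
  construction); a two-sided mode is available.
* **Territories:** `ks_peripheral_test()` compares the distributions of
  per-cell peripheral sums. A 1-D KS statistic needs a scalar per cell;
  the peripheral sum is that scalar (the alternative reading — KS on
  shellwise vectors — is incompatible with the test). For tie-free
  cohorts with min(n₁, n₂) ≤ 10 the p-value is exact (lattice-path
  counting over all orderings, cross-checked against exhaustive
  permutation enumeration in the tests); otherwise the asymptotic
  Kolmogorov distribution with effective size n₁n₂/(n₁+n₂) is used.
* No multiple-testing correction is applied; results are classified
  against the two customary stringency thresholds (p < 0.01 high,
  p < 0.05 low) by `classify_stringency()`.
* `replicate_summary()` reports mean ± sample (n−1) SD across the means
  of replicate experiments, the error bars used for cohort plots.
* The pipeline tests pooled cohorts by default; per-experiment testing
  is available by running cohorts separately and summarizing with
  `replicate_summary()` — which mode was used is visible in the run log.

Calibration of both tests is part of the acceptance suite: under the
null (two uniform cohorts) the rejection rate at α = 0.05 stays within
3σ of nominal over 1,000 replicates for both tests.

### A note on resolvable effect sizes

With n = 50 cells per arm, the one-tailed chi-squared comfortably
resolves a strong recruitment (shell-1 occupancy 68% vs 20%: >98% power
at p < 0.01) but *not* a 50% → 60% shift (~26% power at p < 0.05,
measured over 500 simulated replicate pairs). Screens that report such
shifts as significant pooled several replicate experiments before
testing; single 50-cell arms should not be expected to resolve them.
The suite computes and reports this power honestly rather than
overstating what the design can detect.

## The synthetic-data generator

`sim_config()` + `simulate_nucleus_2d()` / `simulate_territory_3d()`
emulate the study conditions so the pipeline can be validated without
real images:

* **Nuclei** are ellipses/ellipsoids (default midplane semi-axes 45×35
  px at 0.1 µm/px; 3D semi-axes 3.0 × 2.4 × 1.6 µm over a 20-slice,
  0.2 µm-step stack — a flattened adherent-cell geometry) with a
  low-frequency radial perturbation (`roughness`, default 0.05) so that
  equal-area partitioning is exercised on non-circular shapes while the
  unperturbed case stays analytic, and 2 nucleolar discs (radius 6 px)
  at a 50% intensity dip — the segmentation must fill them.
* **Spots** are Gaussian peaks (σ = 1.5 px). Ground truth is the
  area-rank u ∈ [0,1]: the fraction of nuclear area outside the spot's
  distance contour. This is *exactly* the quantity the shell partition
  discretizes, so uniform u ⇒ uniform shells by construction and
  recovery tests are exact. `"uniform_area"` draws u ~ U(0,1);
  `"shell_mixture"` places the spot in the outermost 1/K band with
  probability p, else uniformly, giving the documented marginal
  P(shell 1) = p + (1−p)/K. p = 0.375 and p = 0.5 reproduce the ~50%
  and ~60% shell-1 regimes of peripherally biased loci.
* **Territories** occupy a set fraction (default 0.1) of the nuclear
  volume. The centre is placed at a Beta(e^{−b}, e^{b})-distributed
  midplane area-rank (b = `radial_bias`; 0 = uniform, positive =
  peripheral) and the region grows as the nearest nuclear voxels in a
  z-compressed metric (`z_compression` = 0.35), making territories
  columnar. This design is deliberate: in flattened nuclei a centre
  drawn by 3D distance rank lands mostly on the top/bottom surfaces,
  which is not what "peripheral chromosome position" means — radial
  position is lateral, and real territories span much of the nuclear
  height. No quantitative model of territory morphology exists in this
  literature; the columnar model is a stand-in and is not claimed to
  match real chromosome paints.
* **Noise** is Poisson shot noise (full-scale photon count 200) plus
  Gaussian read noise (SD 0.01), both mild and optional. Intensities
  are quantized to the 16-bit grid so TIFF fixtures round-trip
  losslessly.
* **Determinism:** every cell derives its RNG substream from
  (config seed, cell id); identical config + seed reproduces
  byte-identical images, and generators restore the caller's RNG state.

What the generator does *not* emulate: optical PSF blur and
deconvolution artifacts, multi-nucleus fields, mitotic cells,
chromatin texture in the counterstain, and territory shape complexity.
Passing tests therefore demonstrate that the *measurement pipeline* is
correct and calibrated on known ground truth — not that segmentation or
thresholding choices are optimal for any particular microscope or
staining protocol.

## 2D vs 3D consistency

The 3D analysis recapitulates the 2D ordering of conditions (both views
rank a peripherally biased cohort above an unbiased one, and the
per-cell peripheral sums correlate), and the suite asserts exactly that.
The two peripheral sums are *not* numerically interchangeable: 3D shells
1+2 (outermost 1/3 of the volume) include the top and bottom surface
caps of the nucleus, which a midplane section cannot see, and the 2D
baseline (shells 1+2 of 5 = 40% of the area) differs from the 3D one
(1/3 of the volume). A central full-height territory can score 15% 3D
peripheral and 0% 2D peripheral. Comparisons should therefore always be
within one analysis dimension, never across.

## Problem sizes used in validation

The shipped validation uses cohorts of 5,000 simulated spot placements
for shell-occupancy calibration (3σ binomial tolerance ±1.7 percentage
points around 20%), 100 random 2D masks (≥10⁴ px) and 50 random 3D
volumes for equal-area/equal-volume and oracle-identity checks, 1,000
replicates for type-I calibration, 500 for power, and 8–50 cell image
cohorts for the end-to-end runs — sizes chosen to make binomial error
bands a few times tighter than the effects being asserted.

## Known limitations

* One nucleus per image; no declumping of touching nuclei.
* The midplane rule assumes roughly convex-in-z nuclei; strongly lobed
  nuclei would need a different gating rule.
* Otsu segmentation assumes a bimodal intensity histogram; dim or very
  noisy counterstains may need the manual threshold override.
* The chi-squared comparison discards shell-2 cells by definition; at
  small n this costs power (see the effect-size note above).
* Territory thresholds are manual by design, as in the source
  literature; the pipeline records but cannot choose them for you.
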