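# nucshell

Radial nuclear position analysis by equal-area erosion shells.

Interphase chromosomes and individual loci occupy preferred radial
positions in the nucleus — gene-poor chromosomes sit near the nuclear
envelope, gene-rich ones toward the centre — and these patterns can be
tissue-specific and actively remodelled by nuclear envelope proteins.
`nucshell` is an R package for quantifying such positioning from
multi-channel fluorescence microscopy: a DNA counterstain (DAPI) channel
defines the nucleus, and either a point-like tagged locus (a lacO/lacI-GFP
array) or an extended whole-chromosome FISH paint is scored against
concentric *erosion shells* of the nuclear interior. It is aimed at cell
biologists running repositioning screens (over-expression or knockdown
cohorts vs controls) and at anyone who needs a tested, scriptable
replacement for the classical image-analysis macros used in that
literature.

Because screens of this kind rarely deposit raw images, the package also
ships a ground-truthed synthetic-image generator so that every stage —
segmentation, shell partitioning, spot detection, profiling, statistics —
is testable end to end without microscopy data.

## The method

**Shells.** The segmented nucleus is divided into K nested shells of
equal area (2D midplane, K = 5) or equal volume (z-stacks, K = 6),
numbered 1 at the periphery to K at the centre. Writing d(x) for the
interior Euclidean distance of pixel x to the nuclear boundary (computed
exactly, with anisotropic voxels handled in physical units), the pixels
are ranked by d and split into K equal-count quantile bands:

    shell(x) = k  such that  rank(d(x)) ∈ ((k−1)·A/K, k·A/K],  A = |nucleus|

This realizes the "erode 20% of the area at a time" construction exactly,
even on irregular shapes where iterated morphological erosion cannot hit
the area targets. For a disc of radius R the shell-1/shell-2 boundary
falls at R·√0.8 ≈ 0.894 R; for a ball with K = 6 at R·(5/6)^(1/3) ≈
0.941 R.

**Scoring.** A detected locus is scored by the shell containing its
centroid, restricted to cells where the spot lies at the nuclear midplane
(the widest z-slice, ± a slice tolerance). A chromosome territory is
scored as the fraction of its thresholded, background-subtracted signal
in each shell; the per-cell headline statistics are the *peripheral sum*
(shells 1+2) and *internal sum* (two innermost shells). In 3D the
fractions are obtained by cumulative colocalization with successive
erosions followed by sequential subtraction, which is algebraically
identical to direct per-shell summation (and asserted to be, at 1e-9).

**Statistics.** Locus cohorts are compared by a one-tailed chi-squared
test on the 2×2 table of shell-1 vs internal (shells 3+4+5) counts,
test vs control — note shell 2 is excluded by definition. Territory
cohorts are compared by a two-sample Kolmogorov–Smirnov test on the
per-cell peripheral sums, with exact small-sample p-values. P-values are
reported raw against two stringency thresholds: p < 0.01 ("high", `**`)
and p < 0.05 ("low", `*`).

Nuclear morphometrics (midplane area, longest/shortest Feret diameter)
and tissue western-blot quantification (per-tissue percentage of summed
band signal, fold ratios) round out the cohort controls.

## Worked example

```r
library(nucshell)

## one cell: simulate, segment, partition, score the locus
cfg  <- sim_config(seed = 42)
sim  <- simulate_nucleus_2d(cfg, cell_id = 1)
nm   <- segment_nucleus(sim$stack)
part <- erode_shells_2d(nm, K = 5)
assign_spot_shell(part, detect_spot(sim$stack, nm))
#> spot_record: centre (72.99, 97.91, 0.00), peak 0.707, shell 1
part
#> shell_partition: K = 5, sizes [993, 993, 993, 993, 990]
str(nucleus_morphometrics(nm))
#> List of 3
#>  $ area    : num 49.6
#>  $ longest : num 9.06
#>  $ shortest: num 6.82

## two 50-cell cohorts: peripherally enriched vs uniform baseline
enr <- simulate_spot_cohort(sim_config(seed = 1,
         spot = list(placement = "shell_mixture", shell1_prob = 0.6)), 50)
ctl <- simulate_spot_cohort(sim_config(seed = 2), 50)
shell_spot_histogram(enr$true_shell, 5)$percent
#> [1] 78  4  6  8  4
chi2_shell_test(tabulate(enr$true_shell, 5), tabulate(ctl$true_shell, 5))
#> chi2_shell: statistic = 24.2, p = 4.342e-07** (high, peripheral_gain)
```

The spot lands in shell 1 (the periphery); the five shells cover the
4,962-pixel nucleus to within three pixels of exact equality; and the
enriched cohort (78% of loci in shell 1, versus ~20% expected under
uniform placement) is separated from the uniform control at high
stringency.

## Analysis workflow

The `analysis/` directory holds numbered drivers that reproduce the
package's cohort analyses from scratch (synthetic fixtures under
`scratch/`, tables under `results/`):

1. `01_simulate_cohorts.R` — builds the spot and territory cohorts.
2. `02_spot_screen.R` — 2D locus screen: shell occupancy per condition,
   one-tailed chi-squared, nuclear morphometrics.
3. `03_territory_3d.R` — 2D and 3D chromosome-paint profiling with KS
   tests; checks that 3D recapitulates the 2D ordering.
4. `04_blot_tissue_restriction.R` — tissue percentages and liver/kidney
   fold ratios from the bundled synthetic band table.

Run them in order with `Rscript analysis/01_simulate_cohorts.R`, etc.

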