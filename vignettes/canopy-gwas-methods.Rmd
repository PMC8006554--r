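---
title: "Methods: canopy segmentation, architecture scoring and haplotype-based GWAS on synthetic MAGIC rice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: canopy segmentation, architecture scoring and haplotype-based GWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(canopygwas)
```

`canopygwas` re-creates, at desk scale, a field-phenotyping analysis for an
8-founder MAGIC rice population: vegetation fraction (VF) from top-down RGB
imagery, an "archery-target" (AT) score of plant architecture, and a
haplotype-based genome-wide association scan linking both to shoot biomass.
Because the original field images, genotyping-by-sequencing haplotypes and
phenotype tables are not publicly deposited, every input is produced by a
first-class synthetic-data module with known ground truth. This vignette
explains the models, the defaults and why they were chosen, the numerical
conventions, and what the passing checks do and do not demonstrate about
real data.

## Imaging geometry

A plot region is a `plot_layout()`: a 450 x 270 px rectangle at 2 mm/px
covering a 3 x 3 grid of plants transplanted 18 cm apart within rows
(90 px) in rows 30 cm apart (150 px). Only one orientation embeds that
grid in the rectangle: the across-row axis must run along the 450 px
dimension (row centres span 300 px) and the within-row axis along the
270 px dimension (plant centres span 180 px); `plot_layout()` enforces
centres strictly inside the region. Rectangles use 0-based half-open
indexing internally so crops compose without off-by-one ambiguity, and
`extract_plot_region()` never resamples. Upstream photogrammetry
(orthomosaic stitching, rotation, UTM projection) is out of scope and is
represented only through the layout.

Per-plant tiles are squares of odd side centred on each plant. The default
side is the largest odd integer below the tighter spacing
(`min(90, 150) - 1 = 89`), the maximal per-plant field of view that cannot
overlap a neighbouring plant in the tight direction.

## Vegetation fraction

RGB is converted to CIELAB and only the a* (green-red opponent) channel is
kept: green vegetation sits well below a* = 0 while soil and water sit
near or above it. The conversion uses the standard piecewise sRGB
companding curve (linear below 0.04045, exponent 2.4 above) and an
RGB-to-XYZ matrix carried at full precision as derived from the sRGB
primary chromaticities and the D65 white point (x, y) = (0.3127, 0.3290);
the Lab white point is taken as the row sums of that matrix so achromatic
pixels map to a* = 0 exactly rather than to within rounding of a
separately-quoted white.

Segmentation (`segment_plants()`) rescales a* per image to 0..255
(min to 0, max to 255), rounds to integer bins, and applies Otsu's
threshold to the 256-bin histogram. Conventions that needed fixing:

* **Search and ties.** All 255 splits are scored by between-class variance
  computed in an exact-integer form, so the maximizer is reproducible to
  the last bit. Among equally optimal thresholds the midpoint of the
  optimal run is returned (rounded down) - deterministic and symmetric for
  symmetric histograms. Maximizing between-class variance and minimizing
  within-class variance are equivalent; the tests check both give the same
  optimum set.
* **Polarity.** The plant class is always the low-a* side, and the
  threshold bin itself belongs to the plant class. A `polarity = "high"`
  flag exists for sanity checks only.
* **Rescaling.** Whether the original workflow rescaled a* per image
  before 8-bit thresholding is not documented; per-image min-max rescale is
  the default because it reproduces common 8-bit auto-threshold tools, and
  `rescale = FALSE` (fixed [-128, 128) quantization) is exposed as config.
* **Degenerate images** (constant a*, single occupied bin) are errors, not
  0% or 100% - VF is undefined by this method there.

VF is then `100 * n_plant / n_total` over the full plot rectangle.

## Archery-target (AT) architecture score

The nine per-plant tiles of the binary VF mask are averaged pixel-wise
into a mean mask, which is partitioned into five concentric regions
labelled `a` (outermost) to `e` (innermost) with weights 1..5. The score is

AT = sum_i w_i * P_i / P_all,

with P_i the mean mask value over region i and P_all the mean over all
partition pixels. A uniform mask scores exactly 15 (the weight sum); mass
concentrated centrally pushes the score toward 25 and mass pushed outward
toward 5 (exact bounds on equal-area geometry). The score is invariant to
scaling the mask, so it measures *where* canopy is, not how much.

The source method fixes neither ring widths nor ring shape, so both are
explicit config. The default is square annuli with boundaries at fractions
{0.2, 0.4, 0.6, 0.8, 1.0} of the half-side (max-norm distance from the
centre pixel; boundary pixels belong to the inner region; the centre pixel
is region `e`): square frames partition the raster exactly, with no
excluded corners. Circular annuli at the same fractions are the
alternative; corner pixels beyond the outer circle then belong to no
region and are excluded from every mean. With five width-one rings a
square-annuli map needs side >= 9 for all regions to be non-empty; smaller
sides are an explicit error. `region_map()` accepts an arbitrary label
matrix for non-default geometries (the equal-area analytic checks use it).

## The synthetic canopy generator

`gen_canopy_scene()` is the ground-truth source for the imaging stages.
Each of the nine plants is a rosette of 8-15 elliptical leaves at
uniformly random angles. The `spread` parameter in [0, 1] encodes growth
habit twice over: leaf length scales with (0.5 + spread), and each leaf's
inner end is offset from the plant centre by 0.3 x spread x length - so
spread -> 0 gives a compact, centrally dense rosette (upright habit) and
spread -> 1 a sparse, outward-reaching one. Leaf dimensions scale with
`plant_spacing_px`, making scenes resolution-independent.

Ground cover is controlled by bisection: all leaf geometry is drawn once
from the seed, then an isotropic size multiplier is bisected until the
rendered plant fraction hits `coverage_target`. Calibration area estimates
use a 2x-decimated lattice for speed with a full-resolution polish pass if
the decimation error exceeds 1 pp; the realized `truth_vf` (always
reported) is typically within 0.3 pp of target and guaranteed within 3 pp.
Unreachable targets (and targets above 0.8) are errors. Because
calibration is deterministic given the drawn geometry, identical arguments
and seed give bit-identical scenes.

Colours place the classes on opposite sides of a* = 0 without making
segmentation trivial: plant pixels around RGB (40, 120, 35), soil around
(110, 95, 80), each pixel jittered by a shared-luminance offset of +/-15
plus +/-4 per channel. Keeping most of the jitter achromatic bounds soil
at a* > -5; fully independent per-channel jitter of +/-15 would push some
soil pixels to a* ~ -12 and violate the intended class separation.
A per-plant size jitter (default +/-10%) stands in for within-line
variability among the nine plants, for which no field calibration exists;
it is exposed as a parameter rather than tuned.

What the generator does **not** emulate: shadows, specular water
reflections, leaf overlap across neighbouring plots' plants, panicles, or
photorealistic texture. Segmentation recovering truth essentially exactly
on these scenes therefore validates the *implementation* of the a*/Otsu
chain, not its field accuracy; on real imagery the method inherits all the
usual failure modes of colour thresholding.

## Synthetic genotypes and phenotypes

`gen_founder_mosaic()` builds each line x chromosome as a contiguous
founder mosaic: start founder uniform on the 8, crossover count Poisson
with mean `breakpoint_rate`, positions uniform along the chromosome (in bp
space, not SNP-index space), and the founder after each breakpoint drawn
uniformly from the 7 *others*. Drawing from all 8 would leave one in eight
crossovers invisible in the label matrix; restricting to the other 7 makes
the realized label-change count match the configured rate, which is what
the structural checks verify. The default rate of 4 per chromosome per
line reflects an advanced-generation inter-cross, which accumulates
several meioses of recombination beyond a biparental RIL. SNP positions
are equally spaced per chromosome by default (the map is config).

`gen_phenotypes()` is purely additive: phenotype = baseline + sum of
planted per-founder QTL effects + independent Gaussian noise per
environment. The genetic part is identical across environments - the
two-year design with year-stable haplotype effects. For a target
heritability, `calibrate_noise_sd()` sets the noise SD so the planted
genetic values explain a chosen fraction of variance in that realized
population (the realized R-squared of fitted 8-group means slightly
exceeds the target because 7 group contrasts absorb noise; at n = 165 the
inflation is ~3 points).

## Haplotype-based GWAS

At every SNP, lines are grouped by founder label and tested with the
Kruskal-Wallis rank sum test: joint mid-ranks,
H = [12 / N(N+1)] * sum n_i (rbar_i - (N+1)/2)^2, divided by the tie
correction 1 - sum(t^3 - t)/(N^3 - N), with the p-value from the
chi-squared upper tail on k - 1 degrees of freedom. All-identical values
make the tie correction zero; such tests are flagged degenerate rather
than given a p-value. Scans reuse the phenotype's ranks and tie term
whenever no line is dropped at a SNP, so a 1000-SNP scan is subsecond.

Filtering follows the discard rule for under-segregating loci: a SNP is
tested only if at least `min_groups = 3` founder groups remain (1 or 2
haplotypes are discarded), after dropping groups smaller than
`min_group_size = 2` - a singleton group contributes a degenerate rank
mean; whether the original analysis kept singletons is unstated, so the
threshold is config. No genome-wide significance threshold is applied:
peaks are ranked, and a Bonferroni-adjusted column is emitted for
information only.

Peak calling works on the -log10 p track in map order: candidates are
strict interior local maxima, a flat plateau higher than both flanks
contributes its leftmost index (the reference routine's plateau behaviour
is unspecified, so determinism wins), and candidates are selected greedily
by decreasing height subject to a minimum separation of 100 SNP *indices*
(not bp), up to 8 peaks. `NA` entries (discarded SNPs) can never be peaks
and break plateaus. At the pipeline's sparser default map (480 SNPs vs the
~13.6k of a real genotyping-by-sequencing map) the separation default
scales down to 20 indices.

Founder effect vectors are per-founder phenotype means at a SNP, discarded
wholesale when fewer than 3 founders are represented. Effect vectors are
compared by Pearson correlation over pairwise-complete founders with a
two-sided t-transform p-value and significance tiers (** p<0.01, * p<0.05,
+ p<0.1); allele-class contrasts (e.g. a three-founder allele group versus
the rest at a candidate gene) use the pooled-variance Student's t-test,
matching the named test rather than Welch's variant.

## Design of the statistical checks

Three choices deserve explanation because they determine what a pass
means.

**Type-I calibration** is measured on 1000 *independent* loci (one SNP per
simulated chromosome) at n = 165. The binomial band [0.036, 0.064] around
0.05 is only a valid reference for independent tests; SNPs within a
mosaic chromosome are in strong linkage disequilibrium, which leaves the
expected rejection rate at 0.05 but inflates its variance far beyond the
binomial band. The stage-3 analysis script shows the within-chromosome
version for comparison.

**Power** uses the prescribed conditions - one QTL explaining ~20% of
variance, 165 lines, 1008 SNPs, 50 replicates - and asks the rank-1 peak
to fall within 10 indices of the causal SNP. With the default
recombination rate, linkage decays over a few SNPs at this map density, so
the apex can sit a step or two off the causal index; 10 indices is the
natural resolution of the design, not slack.

**Effect stability across years** has a structural subtlety: with shared
genetic effects and independent noise, the founder-group means at *every*
SNP - linked to the QTL or not - share the line-level genetic values
between years, so the expected between-year correlation at a null SNP is
the heritability itself, not zero (E[r] = h2, ~0.2 here; confirmed
empirically). Requiring near-zero null correlation in the same simulation
that must show causal r >= 0.8 is therefore impossible at these group
sizes. The implemented check measures causal-SNP stability in the
single-QTL simulation and takes the no-signal reference from the matched
no-QTL simulation, where E[r] = 0 exactly - the meaningful sense of "no
stable signal without a QTL".

## The end-to-end pipeline

`run_pipeline()` chains everything: genotypes, one cover QTL and one
architecture QTL (unless `null_run = TRUE`), true cover/spread/shoot-dry-
weight per line and year, scene rendering, composition into field strips
and re-extraction of plot regions, segmentation (measured VF), AT scoring,
GWAS per trait and year, peak calling, effect vectors at the top peaks,
between-year effect correlations, and VF-SDW trait correlations. Shoot
dry weight is a linear function of true cover plus noise, with the slope
and noise chosen so measured VF and SDW correlate around 0.5-0.65 -
the moderate, biologically plausible regime rather than a tautological 1.

Defaults are desk-scale by design: 60 lines, 480 SNPs, the half-scale
layout (225 x 135 px at 4 mm/px - the same field geometry imaged
coarser), two years; a run takes ~10 s and the wider checks use the full
450 x 270 px layout and the 165 x 1008 study scale where the property
under test demands it. Every source of randomness descends from the
single config seed through per-stage offsets, so a repeated run is
byte-identical including the summary JSON; wall-times go to a separate
log so they cannot break determinism. Each output directory carries the
config copy, the log, per-stage tables and optional figures.

## Known limitations

* The canopy model is geometric, not photorealistic; segmentation
  performance on these scenes is an upper bound.
* The GWAS is a plain per-SNP rank test: no kinship or population-structure
  correction, no multiple-testing control, by design - peaks are ranked,
  not declared significant.
* Founder-haplotype reconstruction from raw SNP calls is out of scope;
  haplotype matrices are inputs (or simulated).
* The AT region geometry brackets, but cannot reproduce exactly, the
  original figure's undocumented ring layout; both modes are config.
* `breakpoint_rate`, leaf-shape constants and the colour palette are
  field-plausible choices, not fitted to data.
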