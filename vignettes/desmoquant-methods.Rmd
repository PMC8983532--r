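---
title: "Methods: quantifying desmosomal adhesion readouts"
author: "desmoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying desmosomal adhesion readouts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desmoquant)
```

## Background

Desmosomes are intercellular junctions that anchor keratin intermediate
filaments at the plasma membrane through desmosomal cadherins
(desmogleins, desmocollins) and plaque proteins (desmoplakin,
plakophilins). Mature desmosomes can enter a calcium-independent,
*hyperadhesive* state. Work on keratinocytes expressing different keratin
isotypes links this state to several quantitative readouts: enrichment of
plaque proteins at cell-cell borders, the evenness of desmoplakin
staining along the membrane, the density of the keratin network next to
the junction, the single-molecule binding behaviour of desmogleins
measured by AFM, and the mechanical integrity of the monolayer in dispase
dissociation assays. `desmoquant` implements each of these readouts as a
tested, reusable estimator, and pairs every estimator with a synthetic
generator that produces inputs with known ground truth so the whole
pipeline can be validated end to end.

## Line-scan enrichment ratios

A *line scan* is a short intensity profile sampled perpendicular to a
bicellular border. For each scan the mean intensity of a junctional band
centred on the border is divided by the mean of cytoplasmic bands at the
profile ends; the per-scan ratios are summarised per condition as
boxplots (median, first/third quartile, full range) and compared with the
rank-sum test.

The implementation:

* `trace_borders()` extracts one ordered pixel path per pair of touching
  cells from a label mask. Pixels whose 8-neighbourhood touches three or
  more cells are treated as tricellular corners and excluded, so scans
  stay strictly bicellular.
* `place_line_scans()` distributes segments of equal length and width
  along the trace (defaults: length 31 px, or about 5 µm at the default
  0.161 µm/pixel; width 3 px; one segment every 10 px). The scan
  direction is the local border normal, estimated by the principal axis
  of an 11-pixel window of the trace; for closed (loop) borders the
  window wraps around the seam. Segments leaving the image or crossing a
  third cell are dropped.
* `measure_line_scan()` samples the profile by bilinear interpolation,
  averaging across the segment width.

Band definitions are not fixed by convention anywhere, so they are
explicit parameters: the junctional band spans the central
`3 * border_width_px` samples and the cytoplasmic band the outer 25% of
samples at each end. The ratio is invariant under global multiplicative
rescaling of the image; no background subtraction is performed (users
with a camera offset should subtract it first). Quartiles use linear
interpolation (R's default type 7).

One practical consequence of the band definition matters for validation:
the junctional *mean* equals the true enrichment only when the band lies
inside the enriched stripe. Recovery tests therefore set
`border_width_px` from the generator's recorded stripe width; with that
choice the pipeline recovers a generated enrichment ratio of 3 to within
5% both noiselessly and at a signal-to-noise ratio of 10 (256×256
images, 6 cells).

## Irregularity score

The irregularity score summarises how dominant supra-average intensities
are along a membrane trace. For border intensities \(I_1, \dots, I_N\)
with mean \(\bar x\):

\[
\mathrm{score} \;=\; \frac{1}{N\,\bar x}\sum_{i=1}^{N} \max(I_i - \bar x,\, 0)
\]

Pixels brighter than the mean contribute their excess; sub-average pixels
contribute zero; the average contribution is normalized by \(\bar x\) so
differently strong stainings are comparable. A perfectly uniform border
scores exactly 0, and the score never exceeds
\((\max_i I_i - \bar x)/\bar x\).

Two readings of the verbal definition differ in the averaging
denominator: all \(N\) membrane pixels, or only the supra-average ones.
Both are implemented (`denominator = "all_pixels"` is the default,
`"bright_pixels"` the alternative); for a profile with a fraction \(p\)
of bright pixels the two differ exactly by the factor \(1/p\). The
default follows the reading that the deviation is averaged over all
pixels along the membrane.

Note that the score depends only on the multiset of intensities — it
measures amplitude dispersion, not spatial frequency. Two borders with
the same histogram but different patch layouts score identically; users
wanting spatial structure should look at autocorrelation-type measures,
which are out of scope here.

`border_irregularity()` builds the profile from an image by averaging a
configurable width (default 3 px) across the local border normal at each
trace pixel.

## Keratin network density

Keratin organisation at the border is quantified by thresholding the
image, thinning the foreground to unit-width centrelines, and counting
filament *bundles* (skeleton branches) and *bundle junctions* (skeleton
nodes with at least three neighbours) per region-of-interest area:

* `binarize()` — Otsu by default, fixed threshold as override; the value
  used is recorded on the mask so a run can document that the same
  parameters were applied to every image in a comparison (the pipeline
  runner writes it into its metrics table).
* `skeletonize()` — two-subiteration (Zhang–Suen-style) thinning with a
  connectivity-preserving cleanup of residual 2×2 blocks, then graph
  extraction with 8-connectivity. Redundant diagonal links (a diagonal
  pair that already shares an orthogonal skeleton neighbour) are
  suppressed, the standard reduction that keeps branch counting well
  defined at crossings. Adjacent junction pixels are merged into one
  node, and junction nodes connected by a branch of at most
  `merge_junction_px` pixels (default 3) are merged into a single
  junction cluster: crossings closer than the rendering point-spread
  width are not separable in any image, and without the merge a
  rasterized shallow-angle crossing counts as two junctions plus a
  2-pixel branch.
* `prune_spurs()` — iterative removal of terminal branches shorter than
  `min_branch_px` (default 3 px) to suppress noise-induced stubs;
  pruning runs to a fixed point and is therefore idempotent.
* `skeleton_metrics()` — counts restricted to an ROI, a branch (or
  junction cluster) counting when at least half of its pixels fall
  inside; area is the ROI pixel count times the squared pixel size.
  Whether "number of bundles" should mean branches or connected
  components is genuinely ambiguous; branches are used (matching the
  branch table of the common skeleton-analysis plug-in) and the
  connected-component count is reported alongside for transparency.

**Validation and its limits.** The synthetic generator grows filaments
as random walks with branching from seeded anchor points, rasterizes the
centrelines, and renders them as Gaussian ridges. The ground-truth graph
is extracted from the exact centreline raster, so crossings created
during growth count as junctions exactly as an image-based analysis will
see them. Because a per-step branching probability over many steps is a
supercritical branching process, the generator caps the total filament
count (`max_filaments`, default 64). Recovery is tested at densities
below the resolution limit of the rendering (ridge sigma 1.2 px): pooled
over 8 networks (256×256, 6 seeds, branching 0.05, at most 16
filaments), branch and junction counts from the image pipeline agree
with ground truth to within 10%. At higher densities nearby ridges merge
under the point-spread function and branches are systematically
under-counted — a real property of the skeletonization readout on dense
networks, not an artifact of the tests.

## AFM force-distance curves and adhesion maps

Adhesion is probed with cadherin-functionalized tips in force-mapping
mode: small regions (6 × 2 µm by default) along a border are scanned on
a 0.1 µm grid, one force-distance curve per pixel (1200 per map), with
setpoint 0.5 nN, ramp length 1.5 µm, pulling speed 10 µm/s, 0.1 s
contact time, 0.03 N/m nominal spring constant and 20 nm tip radius as
the acquisition defaults carried in the metadata.

The curve model used by the simulator is piecewise linear: a contact
ramp of slope `contact_stiffness_pN_per_nm` (default 5 pN/nm, a soft
cellular contact) that reaches the setpoint at zero tip-sample distance,
and on retraction either a linear ramp to rupture or a constant-force
membrane tether, ending in a single instantaneous force step back to
baseline. The rupture is snapped to the nearest z sample and the
*realized* force and step position are recorded in the ground truth.
Noise is additive i.i.d. Gaussian on force. Multi-rupture curves,
worm-like-chain elasticity, drift and hysteresis are deliberately not
modelled.

Analysis operates on the retract sweep:

* `find_contact_point()` fits a baseline to the outer 30% of the
  extension, estimates its noise by median absolute deviation, fits a
  second line to the samples exceeding baseline + 5σ (the repulsive
  contact regime), and intersects the two lines. On noiseless curves
  this recovers the simulated contact point to machine precision;
  shifting the z axis shifts the estimate exactly.
* `detect_unbinding_events()` estimates the baseline level and σ from
  the final 20% of the extension, then computes a step statistic — the
  running median (window 9 samples) just after minus just before each
  sample. Samples where the statistic exceeds `threshold_sigma`·σ
  (default 6) while the pre-step median sits below an adhesive gate
  (baseline − 2σ) are candidates; each contiguous candidate run yields
  one event at its largest single-sample jump. The event force is the
  post-step median minus a linear fit to the 15 pre-step samples
  evaluated at the rupture sample — so ramp-to-rupture curves are
  measured without the slope bias a plain pre-median would add — and the
  step position is the rupture z minus the contact point. The detector
  assumes the rupture ramp spans clearly more samples than the median
  window; at the default geometry this means at least ~500 samples per
  sweep, and the simulator default is 1024.
* `map_statistics()` reports the binding frequency (fraction of pixels
  with at least one event) overall, on the junctional stripe and on the
  surrounding surface, and the *distribution coefficient* — the ratio of
  on-border to off-border binding frequency, values above 1 indicating
  binding concentrated along the junction. When the surface frequency is
  zero the coefficient is reported as `NA` together with the raw counts,
  never as infinity. A delta-method standard error of the log
  coefficient at the realized counts accompanies the estimate.
* `pool_events()` collects per-event force and step position across maps
  into a long table for group comparisons (one-way ANOVA with Bonferroni
  correction for three or more groups).

Operating characteristics, measured by the test suite at the default
threshold of 6σ: false positives on 500 non-binding curves below 1%;
detection power above 95% for ruptures of 10·σ; over 200 curves at
signal-to-noise 10, the median recovered force is within 5% of truth and
the median step position within 5 nm; per-pixel binding on a simulated
map is recovered almost everywhere, and the estimated distribution
coefficient of a 0.6/0.3 border/surface simulation falls within the 95%
binomial interval of 2.

## Dispase fragment counting

The dispase assay lifts the monolayer enzymatically and applies
mechanical stress; the number of fragments is an inverse readout of
intercellular adhesion (a hyperadhesion variant adds an EGTA incubation
before the stress, changing only the condition label). `count_fragments()`
counts 8-connected foreground components, discarding components smaller
than `min_size_px` (default 50) as debris — the automated stand-in for
manual counting, with the filter disclosed in every output. Counts are
invariant to image rotation and to intensity rescaling above the
threshold. `compare_conditions()` reports per-group mean ± SEM and
pairwise two-tailed Student's t tests. The synthetic well generator
packs non-touching elliptical fragments (separated by at least 2 px so
8-connectivity keeps them distinct) plus sub-threshold debris, and
errors out rather than silently under-filling when the requested packing
does not fit.

## Statistics

`compare_groups()` implements the decision rule used for two-condition
comparisons: two-tailed Student's t test (equal variances) by default,
and in `"auto"` mode an F test for equal variances at α = 0.05 decides
between the t test and the Wilcoxon–Mann–Whitney rank-sum test. The
rank-sum p-value is computed by full enumeration of all
\(\binom{n_1+n_2}{n_1}\) group assignments (midranks make this tie-safe)
when both groups have at most 8 observations, and by the tie- and
continuity-corrected normal approximation otherwise; the enumeration
agrees with `wilcox.test(exact = TRUE)` wherever the latter is exact.
`anova_bonferroni()` computes the omnibus one-way F (degenerate
all-constant input reports F = 0, p = 1 rather than 0/0) and all
pairwise pooled-variance t tests with each raw p multiplied by the
number of pairs, capped at 1.

Significance stars follow the figure-legend convention by default
(\* p < 0.05, \*\* p < 0.01, \*\*\* p < 0.001, strict inequalities);
the methods-text variant with \*\*\* at p < 0.005 is available via
`convention = "methods"`, since the two conventions genuinely disagree
and outputs should say which one they used. Boxplot summaries report the
full range rather than 1.5·IQR whiskers.

## Synthetic data: what it does and does not emulate

The generators reproduce the *statistical structure* the estimators
rely on: border-enriched fluorescence with controllable enrichment,
patchiness and noise on a seeded nearest-seed tessellation; filament
networks with known branch/junction topology; force curves with known
contact point, rupture force and step position; Bernoulli binding fields
with different probabilities on and off a border stripe; wells with a
known fragment count. All randomness flows through one seed per
generator call, generators restore the caller's RNG state, and identical
parameters give bit-identical output.

They deliberately do not emulate: optics (no PSF beyond the Gaussian
ridge profile, no photon noise, no cross-talk), cell-shape irregularity
beyond convex-ish tessellation cells, multi-rupture or nonlinear AFM
force curves, thermal drift, or fragment shapes beyond ellipses. Passing
the parameter-recovery tests therefore demonstrates correctness of the
estimators under the stated models, not robustness to every property of
real micrographs. Image noise levels and dynamic range are not reported
for the original acquisitions; generator defaults (cytoplasm 100,
noise SD 5 for monolayers; ridge amplitude 100, noise SD 2 for
networks; 5 pN force noise) were chosen once for estimator testability.

## Numerical choices and degenerate inputs

* Sub-pixel sampling is bilinear everywhere; profile averaging uses
  symmetric offsets around the centre.
* Otsu thresholding refuses constant images with an error directing the
  user to a fixed threshold; a threshold above the maximum produces an
  empty mask and zero metrics downstream, not an error.
* Coincident monolayer seed points (< 1 px apart) are a degenerate
  geometry error; collinear seeds are fine (any two seeds are
  collinear).
* A zero cytoplasmic mean makes the line-scan ratio undefined and is an
  error, as is a zero-mean profile for the irregularity score.
* The rank-sum enumeration threshold (8 per group) keeps the largest
  enumeration at \(\binom{16}{8} = 12870\) assignments.
* Tests and examples run at reduced problem sizes (256×256 images, 512
  samples per curve, 8–20 replicate networks) chosen so the full suite
  completes in about a minute while every tolerance is still binding.

## Known limitations

* Branch counts on dense filament networks are biased low by PSF
  merging (see above); densities remain usable for *comparisons* across
  conditions imaged identically, which is how the readout is used.
* The irregularity score ignores spatial arrangement by construction.
* Step positions inherit any contact-point error; on very soft contacts
  (stiffness approaching the baseline noise over a few samples) the
  contact fit degrades before event detection does.
* The distribution coefficient is a ratio of frequencies; with few
  bound surface pixels its variance is large, and the reported
  log-scale standard error should always be read alongside it.
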