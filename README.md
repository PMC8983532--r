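# desmoquant

Quantification of desmosome hyperadhesion readouts from microscopy and
atomic force spectroscopy, for cell biologists studying keratin–desmosome
cross-talk in epithelial monolayers (and for anyone who needs these
estimators with a validated synthetic benchmark).

Desmosomes anchor keratin filaments at cell–cell contacts and can mature
into a calcium-independent, hyperadhesive state. Establishing whether a
condition (for example, the keratin isotype expressed) supports that
state rests on a handful of bespoke quantifications, all implemented
here:

* **Line-scan enrichment ratios** — for a scan crossing a bicellular
  border with junctional band J and cytoplasmic band C,
  `ratio = mean(I[J]) / mean(I[C])`; profiles are also normalized to the
  cytoplasmic mean. Functions: `trace_borders()`, `place_line_scans()`,
  `measure_line_scan()`, `aggregate_ratios()`.
* **Irregularity score** of membrane staining — with border intensities
  I₁..I_N and mean x̄, `score = (1/(N·x̄)) · Σ max(Iᵢ − x̄, 0)`; 0 means
  perfectly uniform staining. Functions: `irregularity_score()`,
  `border_irregularity()`.
* **Keratin network density** — threshold, thin to a unit-width
  skeleton, and count filament bundles (branches) and bundle junctions
  per ROI area. Functions: `binarize()`, `skeletonize()`,
  `prune_spurs()`, `skeleton_metrics()`.
* **AFM force-distance analysis** — contact point, unbinding events
  (force steps after an adhesive excursion), unbinding force, step
  position, per-map binding frequency, and the junctional distribution
  coefficient `BF_border / BF_surface`. Functions:
  `find_contact_point()`, `detect_unbinding_events()`,
  `map_statistics()`, `pool_events()`.
* **Dispase fragment counting** — 8-connected components above a
  disclosed debris size filter. Functions: `count_fragments()`,
  `compare_conditions()`.
* **Statistics** — two-tailed Student's t, exact (enumerated)
  Wilcoxon–Mann–Whitney, one-way ANOVA with Bonferroni correction, and
  the star conventions used in figure legends. Functions:
  `compare_groups()`, `anova_bonferroni()`, `significance_stars()`.

Every estimator has a matching synthetic generator with machine-readable
ground truth (`generate_monolayer()`, `generate_filament_network()`,
`generate_force_curve()`, `generate_force_map()`,
`generate_fragment_image()`), and `run_pipeline()` drives complete runs
from a YAML/JSON configuration (`inst/scripts/desmoquant.R` is a thin
command-line front end). See `vignettes/desmoquant-methods.Rmd` for the
models, parameter choices and limitations.

## Worked example

```r
library(desmoquant)

## 1. junctional enrichment on a synthetic monolayer (true ratio 3)
p  <- monolayer_params(enrichment_ratio = 3, noise_sd = 5, rng_seed = 7)
ml <- generate_monolayer(p)
ratios <- unlist(lapply(trace_borders(ml$mask), function(tr) {
  segs <- place_line_scans(tr, ml$mask, spacing_px = 8, border_width_px = 1)
  vapply(segs, function(s) measure_line_scan(ml$image, s)$ratio, 0)
}))
aggregate_ratios(ratios, rep("K14", length(ratios)))$summary
#>   group  n   median       q1       q3      min      max
#> 1   K14 17 2.999866 2.961748 3.015274 1.496724 3.060075

## 2. irregularity of a patchy border
pp  <- monolayer_params(patchiness = 0.4, patch_amplitude = 1.5,
                        noise_sd = 0, rng_seed = 8)
mlp <- generate_monolayer(pp)
border_irregularity(mlp$image, trace_borders(mlp$mask)[[1]])
#> irregularity_score: 0.2228 (N = 120, mean intensity = 486.955, denominator = all_pixels)

## 3. AFM adhesion map: 6 x 2 um, 0.1 um grid -> 1200 curves
tmpl <- curve_params(binding = TRUE, unbinding_force_pN = 50,
                     step_position_nm = 80, baseline_noise_sd_pN = 5,
                     n_points = 512, rng_seed = 0)
fm <- generate_force_map(map_params(p_bind_border = 0.6, p_bind_surface = 0.3,
                                    curve_params = tmpl, rng_seed = 42))
ev <- detect_map_events(fm)
map_statistics(fm, events = ev)
#> map_statistics: binding frequency 0.407 (border 0.631 over 360 px,
#>   surface 0.311 over 840 px), distribution coefficient 2.029
tab <- pool_events(fm, "K14", events = ev)
sprintf("%d events; median force %.1f pN, median step position %.1f nm",
        nrow(tab), median(tab$force_pN), median(tab$step_position_nm))
#> "488 events; median force 50.0 pN, median step position 79.1 nm"

## 4. dispase well with 37 fragments and 10 debris specks
well <- generate_fragment_image(fragment_params(n_fragments = 37,
                                                debris_count = 10,
                                                rng_seed = 3))
count_fragments(well$image, min_size_px = 50)
#> fragment_count 'well': 37 fragments (of 47 components, min size 50 px)
```

The recovered median ratio (3.00 against a true enrichment of 3), the
distribution coefficient (2.03 against a true probability ratio of
0.6/0.3 = 2), the median unbinding force (50.0 pN against a simulated
50 pN) and the exact fragment count illustrate the parameter-recovery
guarantees the test suite enforces.

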