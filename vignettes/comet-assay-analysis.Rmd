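---
title: "Comet assay segmentation and DNA-damage statistics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comet assay segmentation and DNA-damage statistics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cometseg)
```

## The measurement problem

In a comet assay, electrophoresis pulls fragmented DNA out of a lysed
cell's nucleoid. Under fluorescent staining an undamaged cell images as a
bright, near-circular blob (the *head*); a damaged cell trails a smear of
migrated DNA (the *tail*) in the electrophoresis direction. The standard
per-cell damage statistic is the **tail moment**,

$$\mathrm{TM} = L_\mathrm{tail} \times
  \frac{\mathrm{DNA}_\mathrm{tail}}{\mathrm{DNA}_\mathrm{head} + \mathrm{DNA}_\mathrm{tail}},$$

with the tail length in pixels and the DNA amounts as
background-subtracted integrated intensities. `cometseg` computes it from
raw micrographs, and models how its per-female mean (and the paired
sperm-viability percentage) evolves with sperm storage time.

Note the units: the DNA fraction is kept in $[0,1]$, not percent, so a
~100 px tail holding ~70 % of the DNA scores a tail moment near 70
px·fraction. Comet-assay literature is inconsistent here; the scale is
stated explicitly in `measure_comet()`'s documentation.

## The segmentation pipeline

`segment_image()` composes four deterministic stages plus classification
and discard rules. There is no randomness anywhere in segmentation.

1. **Preprocessing** (`preprocess`): grayscale morphological opening then
   closing with a square element (default 3 px). Opening removes
   single-pixel noise spikes without raising any intensity; closing fills
   matching dark pinholes.
2. **Candidate location** (`locate_candidates`): one global automatic
   threshold, binarization, 8-connected component labelling, and an area
   filter (defaults 30–20 000 px). Connectivity is 8-way because diagonal
   runs of dim tail pixels must not sever a comet.
3. **Head segmentation** (`segment_head`): within each candidate region
   the head is the brightest spot. The within-region histogram is
   thresholded automatically and the connected blob with the highest mean
   intensity is kept, subject to shape constraints — area within
   [30, 5000] px, circularity $4\pi A / P^2 \ge 0.7$ (perimeter from the
   boundary pixel chain), convexity $A / A_\mathrm{hull} \ge 0.9$. A
   region whose blob fails every constraint is discarded as `no_head`.
4. **Tail delimitation** (`segment_tail`): the region is smoothed by a
   binary closing (disc, default diameter 5 px) and the tail is the
   filled convex hull of the smoothed region minus the head. For an
   undamaged cell this leaves at most a thin hull-slack ring, which the
   classifier then removes.

**Classification.** Some candidate regions are undamaged cells with no
tail. A CART decision tree (Gini impurity, exhaustive midpoint threshold
search, depth ≤ 3) decides `tailed_comet` vs `head_only` from four
features: head/tail area ratio (capped at 100 when the tail candidate is
empty), the head centroid's normalized x-position within the candidate
bounding box (−1 = leftmost; heads sit at the anode-side end of their
tail), and the mean head and tail intensities. A predicted head-only cell
has its tail mask emptied. Split ties resolve to the lowest feature
index, then the lowest threshold, so training is bit-reproducible.

**Geometric discard rules** (`apply_geometric_filters`): tailed comets
are dropped when the head/tail area ratio leaves [0.05, 20]
(`ratio`), or when the vector from the head centroid to the farthest
tail pixel deviates more than 15° from the +x electrophoresis axis
(`orientation`). "Parallel to the x axis" has no canonical pixel-level
definition; the farthest-tail-pixel operationalization is this package's
choice, as is the ratio interval. Head-only cells skip both tests.

## Numerical choices that matter

* **Threshold criterion.** Both the global and the within-region
  thresholds maximize Otsu's between-class variance, but on the
  *log1p-intensity* histogram (513 bins) rather than the raw one.
  Comet scenes are extremely background-dominated; on the linear
  histogram the criterion parks the threshold far above the faint tails
  (measured: threshold 81 on a background-20 default scene, i.e. zero
  tail capture), while the log-domain criterion lands just above the
  background mode. `otsu_threshold(..., scale = "linear")` retains the
  classical variant, and `seg_config(threshold_offset=)` adds a constant
  rescue offset for unusually dim images.
* **No-signal guard.** On a background-only image the automatic split
  falls inside the noise, at or below the global median intensity;
  `locate_candidates` returns no candidates in that case instead of
  labelling noise speckle.
* **Unimodality guard.** Otsu always returns *some* split. For an
  undamaged cell the within-region histogram is unimodal and the split
  would shave the head down to its brighter core. When the separability
  statistic $\eta$ (between-class over total variance) falls below
  `head_separability_min = 0.85`, the whole region is taken as the head.
  On the default synthetic fixtures the two cases are well separated
  ($\eta \le 0.77$ for unimodal head-only regions vs $\ge 0.93$ for
  tailed ones).
* **Breakpoint fitting.** `fit_segmented()` fits
  $y = \beta_0 + \beta_1 x + \beta_2 (x-\psi)_+$ by iterative
  linearization: the working model adds the breakpoint-derivative
  covariate $V = -\mathbf{1}(x > \psi)$ and the update
  $\psi \leftarrow \psi + \hat\gamma/\hat\beta_2$ is step-halved so the
  SSE profile never increases. Because gapped x designs can produce
  near-tied SSE basins, the iteration is started from every local
  minimum of a 50-point coarse grid (interior 10–90 % quantiles) and the
  lowest-SSE solution wins; `profile_breakpoint()` provides the
  independent dense-grid oracle the tests compare against. Wald slope
  intervals come from the converged working model
  ($\mathrm{var}(\hat\beta_1+\hat\beta_2)$ via the full covariance);
  no bootstrap.
* **Degrees of freedom.** The adjusted $R^2$ counts four estimated
  parameters ($\beta_0, \beta_1, \beta_2, \psi$), i.e. $n-4$ residual
  df — the convention of the broken-line literature. With the packaged
  viability table this choice matters in the third decimal.
* **Background subtraction** is clamped ($\max(p - b, 0)$): DNA mass
  cannot be negative. The background is the median intensity outside all
  comet masks.
* **Tail length anchor.** Lengths are measured along x from the head
  mask's rightmost column to the tail mask's rightmost column — sensible
  because the discard rules enforce near-parallelism to x.
* **Tie-corrected Spearman** is computed as the Pearson correlation of
  average ranks; the two-sided p-value uses the $t$ approximation with
  $n-2$ df and is reported as descriptive, not as a calibrated test.
* **Densities.** `ridgeline_summary()` uses Gaussian kernels with
  Silverman's rule per group on one shared grid; modes are local maxima
  above 10 % of the tallest group density, so baseline wiggles are not
  reported as modes.

## The synthetic scene generator

Real annotated micrographs for this assay are not redistributable, so
correctness is demonstrated on synthetic scenes with exact ground truth
(`generate_assay_image()`). A comet is a flat-topped Gaussian head disc
(intensity σ = 2r truncated at radius r, so the rim keeps ≈ 88 % of the
peak) plus, for damaged cells, a horizontal band of width 2r and length
L whose intensity decays exponentially with length constant 4L. The band
amplitude is solved analytically so the integrated tail intensity equals
the drawn DNA fraction exactly; integer quantization keeps the rendered
fraction within 2 %. Scenes add Gaussian read noise and are placed under
a minimum-spacing constraint (overlapping comets are out of scope by
design). All randomness flows through an explicitly selected
Mersenne-Twister seed, with a documented draw order, so fixtures are
identical across platforms.

Defaults (640×480 8-bit, background 20, noise σ 3, heads r ∈ [8, 11] px
at peaks 160–230, tails L ∈ [55, 85] px holding 40–60 % of the DNA,
orientation jitter ±6°, damage probability 0.5) were chosen once, as the
package's study conditions, from a physical consistency argument: the
tail surface brightness is ≈ 1.4·(r/L)·f/(1−f) of the head peak, and it
must clear the detection floor (a few noise σ over background) while
staying below the head rim so head and tail remain separable. Those
constraints bound the realistic (r, L, f) window; the defaults sit inside
it.

What the generator does **not** emulate: optical point-spread blur,
uneven illumination and gel-edge halos, overlapping or touching comets,
staining heterogeneity within a nucleoid, and tails brighter than their
head (heavily fragmented cells). Passing the packaged bars (detection
≥ 90 %, mean head IoU ≥ 0.8, mean tail IoU ≥ 0.7 on ten 10-comet scenes)
therefore shows the algorithm chain is implemented correctly, not that it
meets any particular accuracy on real micrographs — the published
evaluation data for this method are not available, and the packaged
default classifier is likewise trained on 400 synthetic patches (seed
1003). On real data, annotate a few dozen cells, retrain with
`train_tree()`, and validate with `match_and_evaluate()`.

## Problem sizes used by the test-suite

The shipped checks run at desk scale: ten 640×480 scenes of 10 comets
each for detection/IoU, 50 matched comets for tail-moment parameter
recovery (regression slope of measured on true moment within [0.9, 1.1]),
and 200 simulated n = 30 datasets (σ = 5, breakpoint at 3 months on the
packaged storage-time design) for breakpoint recovery, confidence
coverage, and iterative-vs-grid oracle agreement. The full suite runs in
about two minutes on one CPU.

## Known limitations

* Touching or overlapping comets are not separated (no watershed); the
  generator's spacing constraint mirrors that scope.
* The head/tail boundary is a hard set partition; partial-volume pixels
  at the head rim are assigned to the head.
* One breakpoint only; the storage-time analyses this package targets fit
  a single changepoint, and nested multi-breakpoint models are out of
  scope.
* Tail moments of head-only cells are exactly 0, so per-female means mix
  a point mass at zero with the damaged-cell distribution; the ridgeline
  summaries make that visible rather than hiding it.
* The Spearman p-value's t approximation is inaccurate below n ≈ 10; r
  itself is always exact.

## Session info

```{r}
sessionInfo()
```
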