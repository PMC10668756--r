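# cometseg

Quantifying DNA damage from comet-assay micrographs, and modelling how
sperm quality decays with storage time.

The comet assay (single-cell gel electrophoresis) embeds cells in agarose,
lyses them, and electrophoreses the DNA: fragmented DNA migrates toward
the anode and smears into a "tail" behind the bright nucleoid "head",
while intact DNA stays put. Scoring hundreds of cells per slide by hand is
slow and subjective, so this package automates it:

* a deterministic **four-stage segmenter** — grayscale morphological
  noise filtering, global-threshold candidate location (between-class
  variance criterion on the log-intensity histogram), per-region head
  segmentation under shape constraints (area, circularity 4πA/P²,
  convexity A/A_hull), and convex-hull tail delimitation;
* a **four-feature CART decision tree** (head/tail area ratio, head
  position along the electrophoresis axis, mean head and tail
  intensities) that separates damaged, tailed comets from undamaged
  head-only cells, plus geometric discard rules (head/tail area ratio
  bounds, parallelism to the x axis);
* **tail-moment quantification**. For each accepted comet,

  `tail moment = tail length (px) × tail DNA fraction`,

  where the DNA fraction is the background-subtracted integrated tail
  intensity over the comet total. Larger values mean more degradation;
* an **evaluation harness** (one-to-one greedy matching, detection rate,
  head/tail intersection-over-union) and a **synthetic scene generator**
  with exact ground truth, so the whole pipeline is testable without the
  original micrographs;
* the **downstream statistics**: tie-corrected Spearman rank correlation,
  one-breakpoint segmented (broken-line) regression
  `y = β₀ + β₁x + β₂(x − ψ)₊` fitted by Muggeo-style iterative
  linearization with Wald slope intervals, per-female aggregation, and
  ridgeline-style kernel-density summaries per storage time.

The package ships the published viability table of 30 female spider crabs
(*Maja brachydactyla*) whose seminal receptacles stored sperm for 0–14
months; the statistical examples and the acceptance script reproduce that
analysis end to end.

## Worked example

```r
library(cometseg)

## sperm viability vs storage time (packaged 30-female table)
fem <- load_female_table()
spearman_cor(fem$storage_time, fem$viability)
#> Spearman rank correlation: r = -0.9109 (n = 30, two-sided p = 2.81e-12)

fit <- fit_segmented(fem$storage_time, fem$viability)
summary(fit)
#> One-breakpoint segmented linear regression
#>   breakpoint psi = 4.221
#>   slope left  = -13.3, slope right = -4.603
#>   R2 = 0.7898 (adjusted 0.7655), n = 30
#>   intercept = 98.43
#>   95% CI slope left : [-22.4295, -4.1784]
#>   95% CI slope right: [-7.8294, -1.3769]
#>   residual sigma = 20.05 on 26 df; converged in 2 iteration(s)
```

Viability collapses at 13.3 % per month until the breakpoint near 4.2
months, then declines at 4.6 % per month toward zero — storage itself
degrades the stored sperm, fastest in the first few months.

```r
## segment a synthetic scene against its own ground truth
scene <- generate_assay_image(synth_config(seed = 42))
segs  <- segment_image(scene$image, seg_config(), default_tree_model())
match_and_evaluate(segs, scene$truth)
#> <match_result> detection 90.0% (9/10 truth, 10 predicted)
#>   mean IoU head 0.999 | tail 1.000

bg  <- estimate_background(scene$image, lapply(segs, function(s) s$head | s$tail))
acc <- Filter(function(s) s$accepted && s$has_tail, segs)
measure_comet(scene$image, acc[[1]], bg)
#> first damaged comet: tail length 84 px, tail DNA fraction 0.578, tail moment 48.54
```

The same pipeline is scriptable from a shell via the bundled CLI
(`inst/exec/cometseg`): `synth`, `segment`, `train`, `evaluate` and
`stats` subcommands; see `run_cli("--help")`.

## Caveats

The default decision-tree model and the detection/IoU figures above are
obtained on the synthetic generator, not on real micrographs; real data
need retraining (`train_tree()` on your own annotated examples) and their
own validation. See the methods vignette
(`vignettes/comet-assay-analysis.Rmd`) for the model, parameter
rationale, and known limitations.
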