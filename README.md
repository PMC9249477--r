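# markercut

Binary segmentation of grayscale bone CT slices by a **seeded graph cut with
automatically generated threshold markers**, together with the evaluation
metrics and the tibial-plateau imaging score used to grade fracture
reduction on the segmented images.

Interactive graph-cut segmentation needs a user to paint foreground and
background markers before the min-cut can be solved; for routine clinical
CT reading that manual step is the bottleneck. This package replaces it
with markers derived from an automatically selected histogram threshold, so
bone tissue in a CT slice is segmented with no interaction at all. It is
aimed at researchers in medical image analysis who need a compact,
fully reproducible reference implementation — every input it requires can be
generated by its own phantom module with exact ground truth.

## Method

For a grayscale image with levels `0..L-1`, histogram probabilities
`p_i = n_i / n`, and a candidate threshold `t` splitting the levels into
`C0 = {0..t}` and `C1 = {t+1..L-1}` with class probabilities
`w0 = Σ_{i≤t} p_i`, `w1 = 1 − w0`, means `m0, m1`, variances `s0², s1²` and
entropies `H0, H1`, two selectors are provided:

* **maximum entropy** (Kapur): `t* = argmax f(t)`, `f(t) = H0 + H1`;
* **minimum error** (Kittler–Illingworth, two-Gaussian model):
  `t* = argmin J(t)`, `J(t) = 1 + w0·log(s0²/w0²) + w1·log(s1²/w1²)`.

Pixels brighter than `t* + b` become foreground seeds, pixels at or below
`t* − b` background seeds (`b` = seed band, default 10 gray levels); the
band in between stays unlabeled. The segmentation is the global minimum of
the standard two-terminal energy

```
E(A) = λ Σ_p R_p(A_p) + Σ_{(p,q)} B_pq [A_p ≠ A_q]
```

with region costs `R_p(l) = −log P_l(I_p)` from smoothed seed-intensity
histograms and contrast costs `B_pq = exp(−(I_p−I_q)²/2σ²)/dist(p,q)`,
solved exactly by a bundled augmenting-path max-flow (an `igraph` backend
is available as a cross-check). Seeds are hard constraints.

Quality is measured by the Dice similarity coefficient
`Dice(M, N) = 2|M∩N| / (|M|+|N|)` plus counts of holes (enclosed
background components) and isolated points — the artifacts plain
thresholding produces. The scoring module implements the Rasmussen-style
tibial-plateau imaging score: collapse / broadening / angular deformity
(0–18 points), damage area over the five-region articular surface division
and comminution (0–6 points each), total 0–30 with
excellent / good / common / bad grades.

## Worked example

```r
library(markercut)

ph  <- generate_slice(phantom_spec(rng_seed = 42))   # 64x64 disk phantom
res <- segment_auto(ph$image, method = "max_entropy")
res
#> <segmentation_result> method = max_entropy, t* = 68, energy = 1.829e+04
#>   seeds: 1568 fg / 1003 bg / 1525 unlabeled; foreground pixels: 1568
#>   elapsed: 0.015 s

evaluate_segmentation(ph$truth_mask, res$mask)
#> <evaluation_report> Dice = 1.0000 (|M| = 1568, |N| = 1568, overlap = 1568)
#>   holes: 0, isolated points: 0, elapsed: 0.003 s
```

The phantom is bright bone (mean 200, SD 5) on dark soft tissue (mean 60,
SD 5); the entropy selector puts `t*` at 68, the ±10 seed band leaves 1525
uncertain pixels to the cut, and the recovered mask matches the ground
truth exactly (Dice 1). Scoring a measurement record:

```r
imaging_score(collapse_mm = 3, broadening_mm = 0, angulation_deg = 12,
              damaged_regions = c("anterolateral", "anteromedial"),
              fragment_count = 2)
#> <imaging_score>
#>   displacement: collapse 4 + broadening 6 + angulation 2 = 12/18 (good)
#>   damage area: 4/6, comminution: 2/6
#>   total: 18/30 (common)
```

A command-line front end wrapping the same functions lives at
`inst/cli/markercut.R` (`segment`, `evaluate`, `score`, `phantom`
subcommands).

## Vignette

`vignettes/markercut-methods.Rmd` documents the model, the parameter
defaults, the numerical conventions and the limitations in detail.
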