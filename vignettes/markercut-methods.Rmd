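---
title: "markercut: methods, parameters and numerical conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{markercut: methods, parameters and numerical conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markercut)
```

# The problem

Segmenting bone from a grayscale CT slice with an interactive graph cut
requires a human to mark foreground (bone) and background pixels first.
`markercut` automates that step: an intensity threshold is selected from
the histogram, pixels confidently above or below it become the markers, and
the usual two-terminal min-cut then labels the uncertain remainder. The
package also carries the downstream clinical piece — a Rasmussen-style
imaging score for tibial-plateau fractures — and a phantom generator so the
whole pipeline is testable with exact ground truth and no external data.

Bone is the bright phase in CT, so foreground means the above-threshold
class throughout; `invert = TRUE` in `graphcut_params()` flips this for
dark-phase targets.

# Histograms and class statistics

An image has integer intensities in `0..L-1` (`L = 256` for 8-bit input;
other depths are configurable, and out-of-range intensities are rejected
rather than clipped so probabilities stay exact). With `p_i = n_i / n`, a
threshold `t` induces classes `C0 = {0..t}` and `C1 = {t+1..L-1}` with

* probabilities `w0 = Σ_{i≤t} p_i`, `w1 = Σ_{i>t} p_i` (always `w0 + w1 = 1`),
* means `m0, m1` and variances `s0², s1²` (probability-weighted, per class),
* Shannon entropies `H0, H1` of the renormalized class distributions.

Conventions, fixed once and unit-tested:

* **Natural logarithms** everywhere. The base rescales objectives but can
  never change an argmax/argmin, so this is purely a reporting convention.
* **`0·log 0 = 0`**: zero-probability levels contribute nothing to
  entropies.
* **Empty classes are undefined, not zero.** `class_stats()` returns `NA`
  for the mean/variance/entropy of an empty class; selectors never visit
  such candidates because the candidate range is
  `{min populated level, ..., max populated level − 1}`, which keeps both
  classes non-empty by construction.

# Threshold selection

**Maximum entropy** maximizes `f(t) = H0 + H1`. **Minimum error** fits the
histogram with a two-component Gaussian mixture and minimizes the
classification-error criterion

`J(t) = 1 + w0·log(s0²/w0²) + w1·log(s1²/w1²)`,

the standard minimum-classification-error form (equivalently
`1 + 2[w0·log s0 + w1·log s1] − 2[w0·log w0 + w1·log w1]`); the additive
constant does not affect the argmin. Candidates with a zero class variance
are excluded rather than floored: the log diverges there and any floor
would plant a spurious minimum at the histogram edges. A two-point
histogram therefore has *no* valid minimum-error candidate and raises an
error, while maximum entropy still returns a separating threshold.

Ties break to the smallest `t`, making every selection deterministic. Both
selectors depend on `p_i` only, so scaling all counts leaves `t*`
unchanged, and the full objective trace is kept on the returned scan object
(exportable as CSV) for inspection.

On a discretized equal-weight, equal-variance two-Gaussian mixture the
minimum-error threshold lands within two levels of the analytic
equal-likelihood boundary (the midpoint of the means); with unequal priors
it shifts toward the minority mode, as the Bayes boundary does. Both
behaviors are asserted in the test suite against exhaustive independent
scans of the objectives.

A caveat worth knowing: on *sampled* histograms the inter-mode gap contains
empty bins, across which both objectives are flat. With the smallest-`t`
tie rule, and because Kapur's objective often genuinely peaks just above
the dominant mode, `t*` tends to hug the background mode rather than sit
mid-gap. For segmentation this is harmless — any threshold in or near the
gap separates the phases — but `t*` should not be read as an estimate of
the mixture boundary.

# Automatic markers

With a selected `t*` and band half-width `b` (`seed_band`, default 10 gray
levels):

* intensity `> t* + b` → foreground seed,
* intensity `≤ t* − b` → background seed,
* otherwise unlabeled.

If either class comes out empty the band is halved until both are
populated; once it falls below half a gray level (sub-quantization, hence
meaningless for integer intensities) it snaps to 0, where the split
`I > t*` vs `I ≤ t*` is non-degenerate for every valid threshold, so the
procedure terminates and only a constant image can fail (with an explicit
ill-posed-input error).

`seed_filter = "median"` places the markers from a 3×3 median-filtered copy
of the image, while the segmentation energy keeps the raw intensities. The
motivation: markers are *hard constraints*, and a single impulse-corrupted
pixel (salt-and-pepper noise) otherwise becomes an irrevocable seed of the
wrong class — a hole the cut can never close. With despeckled markers the
automatic pipeline removes the holes and isolated points that plain
thresholding produces on impulse-noisy images, which is precisely the
failure mode it is meant to fix; the test suite demonstrates this over 20
noisy phantoms with a paired sign test. The default stays `"none"` so that
marker placement follows the band rule verbatim; the filtered mode also
sacrifices structures thinner than 2 px, so it should be switched on only
when impulse noise is a real concern.

# The graph cut

The labeling minimizes

`E(A) = λ Σ_p R_p(A_p) + Σ_{(p,q)} B_pq [A_p ≠ A_q]`

* `R_p(l) = −log P_l(I_p)`, with `P_fg`, `P_bg` the intensity histograms of
  the respective seed pixels, Laplace-smoothed with pseudocount
  `hist_smoothing` (default 1) over all `L` levels so every term is finite.
* `B_pq = exp(−(I_p − I_q)² / 2σ²) / dist(p,q)`, `dist = 1` for 4-neighbors
  and `√2` for diagonals; connectivity defaults to 8.
* `σ` defaults to the median absolute 4-neighbor intensity difference — a
  robust, data-driven contrast scale — floored at 1 gray level so constant
  regions remain well-defined.
* `λ` (region weight) defaults to 1.

Seeds are enforced by terminal links of effectively infinite capacity (a
finite value strictly larger than the total of all other capacities, so it
can never sit in a minimal cut). The min cut is computed by a bundled
Dinic augmenting-path max-flow written for this package; residual
reachability from the source yields the labeling, and the flow value equals
the energy of the returned labeling exactly. `backend = "igraph"` runs
`igraph::max_flow()` on the identical graph and is used in the tests as an
independent solver: both backends must agree on the cut value and, for the
instances tested, the mask. On small images the returned energy is also
checked against exhaustive enumeration of all labelings.

Two consequences of the construction worth stating:

* With `λ = 0` and `seed_band = 0` every pixel is a seed and the output *is*
  plain thresholding at `t*` — the cut only ever changes the uncertain band.
* The mask depends on `t*` only through the seeds: two thresholds whose
  bands lie in the same empty intensity gap give identical seeds and hence
  identical segmentations.

# Evaluation

`dice()` implements `2|M∩N| / (|M| + |N|)` on foreground pixel sets: 1 iff
identical, 0 iff disjoint. Two empty masks raise an error — the 0/0 case
is undefined and silently returning 0 or 1 would bias aggregate statistics.
`artifact_counts()` reports holes (background 4-connected components not
touching the border; background is 4-connected where foreground is
8-connected, the standard dual pairing) and isolated points (foreground
8-connected components below `min_size`, default 5 px). Wall-clock timing
is recorded wherever a pipeline runs, as the efficiency measure, but no
correctness criterion ever depends on it.

# Imaging score

The displacement score follows the Rasmussen anatomical bands: each of
collapse, broadening and angular deformity is worth 6/4/2/0 points, total
0–18, graded excellent (18) / good (12–17) / common (6–11) / bad (0–5).
Damage area scores 6/4/2/0 for 0 / 1–2 / 3 / 4 damaged articular quadrants;
comminution 6/4/2/0 for 0/1/2/≥3 fragments; total 0–30 graded
excellent (28–30) / good (20–27) / common (10–19) / bad (0–9).

The printed bands leave edge cases open, resolved here once and tested
exhaustively:

* Collapse: the good band is printed as a bare "5 mm", leaving 5–6 mm
  unassigned; bands are closed as `(0,5] / (5,10] / (10,∞)`.
* Broadening and angulation: printed as `<5 / 6–10 / >10` and
  `<10 / 10–20 / >20`; boundary values join the lower-scoring band
  (conservative), i.e. `(0,5) / [5,10] / (10,∞)` and `(0,10) / [10,20] /
  (20,∞)`.
* "None" always means exactly zero.
* A record with no damage at all takes the best damage band (6 points);
  the table has no explicit no-damage row.
* Intercondylar involvement never changes the damage-area count, which is
  defined over the four articular quadrants only; whether combined
  intercondylar + two-quadrant damage should count as three areas is
  unspecified in the source grading scheme, and this package counts two.
* A fragment count of 0 is by definition a fracture line confined to the
  intercondylar eminence, so it is inconsistent with articular-quadrant
  damage and rejected.

Because every category awards an even number of points, odd totals are
unattainable; grade boundaries at odd values (19/20) are still honored by
the mapping.

`divide_plateau()` reproduces the top-view drawing construction
algorithmically: the longitudinal line and the horizontal line are anchored
at the foreground centroid, and the intercondylar band half-width is a
fraction (`eminence_halfwidth_frac`, default 0.15) of the foreground
bounding-box width. Manual line placement on anatomy cannot be reproduced
exactly, so the geometry is parameterized instead. Smaller column indices
are labeled lateral and smaller row indices anterior — a pure labeling
convention, since true laterality depends on which knee is imaged. A
region counts as damaged when at least `min_overlap_px` (default 1) damage
pixels fall in it.

# Phantoms

`generate_slice()` realizes exactly the intensity model the minimum-error
selector assumes: foreground and background intensities are independent
Gaussians, clipped to `[0,255]` and rounded (R's round-half-to-even, so
fixtures are platform-stable). Defaults — bright bone mean 200 on soft
tissue mean 60, both SD 5, on a 64×64 canvas — emulate a high-contrast
trabecular bone slice; fracture lines are thick line segments whose pixels
take the background distribution and leave the truth mask. Noise options
are additive Gaussian and fixed-value (0/255) salt-and-pepper. Each
phantom draws from a private RNG stream seeded by `rng_seed`; the caller's
`.Random.seed` is untouched and equal specs are bit-reproducible.

`generate_plateau()` routes fracture segments analytically (center column
for the intercondylar band, quadrant anchor points at ±0.6·a, ±0.5·b for
the articular regions) so the damaged-region ground truth equals the
requested target set under the default division — a closed loop with the
scoring module that the tests exercise for every single- and two-region
target.

What the phantoms deliberately do *not* model: trabecular texture, partial
volume effects at bone boundaries, beam hardening and scanner artifacts,
and 3-D structure. Passing the phantom suite therefore shows the pipeline
is correct under its own intensity model, not that it meets any particular
accuracy on clinical scans.

# Problem sizes and test design

The test suite runs entirely on generated data: 64×64 phantoms (128×128
where a sampling check needs ≥10⁴ pixels), 20 seeds for the end-to-end
Dice ≥ 0.95 recovery and the hole-suppression comparison, and exhaustive
enumeration of labelings on random images up to 3×4 pixels with 2–3 gray
levels for the min-cut oracle — sizes chosen so each property has enough
replication to be meaningful while the whole suite stays interactive
(well under a minute). Brute-force oracles (histogram tallies, class
statistics, objective scans, flood fills, labeling enumeration, the scoring
tables) are reimplemented independently in the test helpers and never share
code with the package.

# Known limitations

* **Small foreground fractions.** The seed-histogram likelihoods are built
  from band-truncated samples; when the unlabeled band covers a large part
  of one class and the two seed sets are very unbalanced, Laplace smoothing
  makes the *smaller* seed class more likely at unseen intensities, and the
  unlabeled sea can tip to the wrong label. With the default phantom
  geometry this never occurs, but for small, off-center targets a narrower
  `seed_band` (or `min_error` thresholds with better-separated bands) is
  advisable.
* `t*` on sampled bimodal histograms sits near the dominant mode, not
  mid-gap (see above).
* The minimum-error selector is undefined on histograms where every split
  leaves a zero-variance class (e.g. exactly two populated levels).
* Strictly 2-D, strictly binary; no multi-label cuts, no iterative region
  re-estimation, no 3-D voxel graphs, no DICOM/NIfTI I/O.
* Fragment counting is an input to the score, not measured from images.
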