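---
title: "Seed outline morphometrics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed outline morphometrics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seedmorph implements an outline-based morphometric workflow for
discriminating seed taxa — built around the *Papaver* (poppy) problem of
telling wild-type from domesticated seeds — and for assigning seeds of
unknown origin to taxa. This vignette explains the underlying models,
the parameters that matter, the design decisions taken where the design
was genuinely open, and what the synthetic data generator does and does
not emulate.

## The analysis chain

A specimen enters as a binary mask (one seed photographed laterally,
hilum to the right, broader end down) plus five landmarks: three on the
hilum arch (1–3) and the two length extremes (4 top, 5 bottom). The
chain is:

1. **Outline extraction** — `extract_outline()` traces the largest
   foreground component at the 0.5 iso-level with marching squares
   (`grDevices::contourLines`), giving a sub-pixel, counterclockwise
   closed polygon in y-up pixel-center coordinates. Border-touching
   components are kept but flagged.
2. **Size** — `bounding_box_size()` records length (the vertical, i.e.
   landmark 4–5 axis) and width as axis-aligned extents, exactly as a
   rectangular measuring tool would on the oriented photograph. Sizes
   enter all statistics as natural logs.
3. **Normalization** — `resample_outline()` places 360 points at equal
   arc spacing starting at landmark 2; `gpa_align()` estimates
   translation, scale and rotation by iterative generalized Procrustes
   alignment *of the five-landmark configurations* and applies those
   similarity transforms to the full outlines. After convergence the
   whole set is rotated so the consensus landmark 5→4 axis points up,
   which makes the result invariant to acquisition pose (verified to
   below 1e-6 in the tests).
4. **Elliptic Fourier transform** — `efourier()` decomposes x(t), y(t)
   into H harmonics with four coefficients each, (a_n, b_n, c_n, d_n),
   plus center terms. `choose_harmonics()` retains the smallest H whose
   mean cumulative harmonic power reaches 95%.
5. **Statistics and classification** — Kruskal–Wallis and pairwise
   Wilcoxon tests on the univariate descriptors; PCA of the coefficient
   matrix with unknowns reprojected as supplementary individuals;
   permutational MANOVA on Euclidean distances between coefficient
   rows; per-taxon mean shapes and a UPGMA tree on their distances;
   class-balanced repeated LDA with leave-one-out accuracies and a
   shuffled-label chance ceiling; majority-vote assignment of unknowns
   over the same balanced ensemble.

## The Fourier parameterization, carefully

The elliptic Fourier integrals are computed with the piecewise-linear
chain-sum formulas, with the curve parameter taken as vertex index
scaled to the measured perimeter. When the input points are equally
spaced along the curve — which `resample_outline()` guarantees and the
protocol always applies first — this *is* the classical
curvilinear-abscissa formulation. The distinction matters for one
subtle reason: a truncated Fourier series evaluated at uniform
parameter values does not have constant speed, so re-parameterizing a
reconstruction by its own arc length shifts power between harmonics.
Two practical consequences:

- `inverse_efourier()` followed by `efourier()` (no resampling in
  between) round-trips coefficients to about 6e-4 relative at the
  protocol's 360 points — this is what makes the generator's ground
  truth recoverable and is asserted in the tests.
- a shape *resampled by arc length* carries the arc-length
  parameterization's coefficients, which differ from the generating
  ones. The classic example is the 2:1 ellipse x = 2cos t, y = sin t:
  its arc-length EFT has a1 ≈ 1.83 (not 2) and a small odd-harmonic
  remainder. The tests pin these values against a dense numeric
  integration oracle rather than against the naive (2, 0, 0, 1).

Orientation is forced counterclockwise before the transform; ties when
snapping landmark 2 to the outline are broken toward the lower
arc-length position.

## Harmonic retention

Harmonic power is (a² + b² + c² + d²)/2; cumulative fractions include
*every* computed harmonic, harmonic 1 included, and H\* is chosen on the
population mean. Because seed outlines are mostly convex, harmonic 1
typically carries well over 90% of total power under this convention,
and the default 95% threshold retains H\* = 2 on the synthetic design. A
convention that excludes harmonic 1 from the denominator (common in
outline-morphometrics software) would retain around 5 harmonics on the
same material; both are defensible, the inclusive rule is implemented
because it makes "fraction of total shape variance" mean what it says.
`run_config(max_harmonics = …)` bounds the search; coefficients are
always computed at that bound before truncation to H\*.

## Measurement error

`measurement_error()` implements the variance-component definition of
reproducibility error: a one-way ANOVA with individuals as groups gives
MS_within and MS_among; the among-individual component is
(MS_among − MS_within)/m clamped at zero, and
%ME = 100·s²_within/(s²_within + s²_among). The ANOVA needs a scalar,
and shape is multivariate; `measurement_error_shape()` therefore
reports %ME per retained principal component of the repeated-measures
coefficient matrix *and* pooled across PCs from summed variance
components. The pooled figure is what the pipeline tables report.

## The synthetic seed generator

No real images ship with the package; every downstream stage is
exercised on populations from `default_taxon_models()` +
`simulate_population()`. Shape families are parameterized directly in
coefficient space so ground truth is known: two elongated taxa
(argemone, hybridum analogues), two reniform taxa (rhoeas, dubium), and
three rounded, strongly overlapping taxa (setigerum, somniferum,
nigrum — the somniferum-group analogue) built as a shared base template
plus taxon offsets scaled by `separation`. Distances between the
triple's mean coefficient vectors are exactly linear in `separation`
(zero makes them identical), which is what makes the
accuracy-vs-separation monotonicity testable. Sizes are log-normal per
taxon (setigerum ~0.95 mm long, somniferum ~1.25 mm, the wild small
taxa 0.6–0.8 mm), cell counts negative-binomial with setigerum lowest
and argemone highest, matching the qualitative ordering of the real
material. Template amplitudes were calibrated once so that (i) all
shapes stay simple closed curves across `separation` 0–3 under
acquisition noise, (ii) the 95% rule retains the harmonics that carry
the triple's discriminating signal, and (iii) single-descriptor LDA
accuracies land mid-range at `separation = 1` rather than saturating;
these are testability calibrations, fixed before the acceptance runs
and not revisited.

Acquisition noise has three dials mirroring the reproducibility tests:
`rotation_sd` (radians of re-positioning — the dominant error for round
seeds, exercised with 5 repeats), `outline_jitter_sd` (digitising /
cleaning noise: spatially correlated radial jitter, as a fraction of
the RMS centroid radius; iid per-vertex noise would self-intersect at
the 720-vertex generation density) and `landmark_jitter_sd` (placement
noise, 3 repeats each). Defaults (0.08, 0.004, 0.008 for the main
acquisition) were chosen so the position test dominates the error
budget, as it does on real round seeds. Seeds are rendered by even-odd
scanline fill at 100 px/mm (a 1 mm seed spans ~100 px) and re-traced,
so rasterization error (~half a pixel) is part of every measured
quantity.

What the generator does **not** emulate: seed surface texture and the
cell pattern (cell counts are drawn, not measured from the image),
focus-stacking artifacts, lighting, and taphonomic deformation
(waterlogging, charring). Passing tests therefore validate the
*computational* chain under controlled noise, not the biological
fidelity of any particular taxon's shape distribution — the paper-style
conclusions one can draw from the synthetic runs are about the method,
not about *Papaver*.

Two further honesty notes. The measured coefficients are the
arc-length push-forward of the generating ones (see above), so
"recovering the taxon mean" is asserted as agreement between
independent replicates and exact recovery in the noise-free case,
rather than naive equality with the generator vector. And the GPA
consensus of noisy copies sits at the noise level (not noise/√n) from
the template, because landmark-placement noise induces per-specimen
rotations that do not average out; the tests bound it at twice the
per-point noise sd.

## Classification choices

LDA uses the shared-covariance Gaussian model with equal priors — the
benchmark design is balanced to 30 per class by construction
(`priors = "proportional"` is available). Features are never
standardized (LDA is affine-equivariant); sizes enter as natural logs.
A near-singular pooled covariance is ridge-regularized with
epsilon = 1e-8·trace/p and a warning. Leave-one-out accuracies default
to a rank-one downdate path (Sherman–Morrison on the pooled scatter
inverse), with the literal refit-n-times loop kept as `method =
"refit"` and asserted equal in the tests. The benchmark repeats the
balance–LOOCV cycle (defaults: 1000 permutations for the modern
benchmark, 100 for the assignment ensemble, both configurable); the
chance ceiling shuffles labels within each permutation and reports the
maximum per-class accuracy observed. Unknowns are assigned by majority
vote over the ensemble; ties are flagged ambiguous and resolved to the
lexicographically first class rather than silently broken.

## Permutation tests and seeds

The permutational MANOVA partitions the Euclidean distance matrix
(computed directly from the coefficient matrix, which is equivalent to
the Gower-centered form), with p = (1 + b)/(n_perm + 1) and the
adjusted R² using the degrees-of-freedom penalty
1 − (1 − R²)(N − 1)/(N − g). Every stochastic function in the package
— permutation tests, the benchmark, the generator — requires an
explicit seed; `run_pipeline()` forks named sub-seeds per stage from
one master seed, so a configuration is a pure function from seed to
outputs (asserted by hashing the summary of two identical runs).

## Problem sizes

The study-shaped runs used throughout the tests and the acceptance
script follow the reference design: 270 modern seeds (7 taxa × 30 plus
two extra 30-seed accessions of setigerum and somniferum), 33 unknowns
drawn half and half from the setigerum and somniferum models, 360-point
outlines, balancing to 30 per class, and 100 balanced permutations for
both the benchmark and the assignment ensemble; null-calibration checks
use 2000 permutation-test datasets and 5000 rank-test datasets. These
sizes keep a complete run in the tens of seconds on one core while
leaving the Monte Carlo error well below the effects being asserted.

## Known limitations

- Whether the original protocol ran GPA on landmarks only or on full
  outlines is not documented; the landmark-driven variant is
  implemented (it is the one the five recorded landmarks support), and
  outline-point GPA would be a straightforward extension.
- Pairwise Wilcoxon P-values are emitted raw by default (`p_adjust`
  switches on correction); multiple-testing policy is left to the
  analyst.
- The harmonic-retention convention (harmonic 1 in the denominator)
  retains fewer harmonics than the drop-first convention; on real,
  less convex material the two can disagree substantially.
- The assignment ensemble reuses the benchmark's balanced-resampling
  mechanism for every descriptor set; per-descriptor runs are
  consistent with each other by construction.
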