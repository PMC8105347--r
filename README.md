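# seedmorph

Outline-based geometric morphometrics for seed identification, built
around a concrete archaeobotanical problem: opium poppy (*Papaver
somniferum*) seeds are abundant in Neolithic sites, but wild-type and
domesticated forms cannot be told apart by size alone, so assemblages
cannot be read as evidence of domestication. The workflow implemented
here combines three descriptor families — surface cell counts, bounding
box length/width (log-transformed), and outline shape — to discriminate
modern seed taxa and then assign seeds of unknown origin by a
classifier ensemble.

The core of the package:

- **Elliptic Fourier transforms (EFT).** A closed outline's
  coordinates x(t), y(t), parameterized by the curvilinear abscissa
  over 360 equally spaced points, are decomposed into H harmonics with
  coefficient quadruples (a_n, b_n, c_n, d_n); the harmonic power
  (a_n² + b_n² + c_n² + d_n²)/2 drives the retention rule (smallest H
  reaching 95% of mean cumulative power). `efourier()`,
  `inverse_efourier()`, `harmonic_power()`, `choose_harmonics()`.
- **Landmark-anchored normalization.** Five landmarks per seed (hilum
  arch 1–3, length extremes 4–5); generalized Procrustes alignment of
  the landmark configurations supplies the similarity transforms
  applied to the full outlines, and landmark 2 anchors the outline
  start point. `gpa_align()`, `resample_outline()`.
- **The statistical suite.** Measurement-error variance components
  (%ME = 100·s²_within/(s²_within+s²_among) from a one-way ANOVA with
  individuals as groups), Kruskal–Wallis and pairwise Wilcoxon tests,
  PCA with supplementary projection of unknowns, permutational MANOVA
  on the coefficient matrix (pseudo-F, adjusted R², permutation P),
  per-taxon mean shapes and a UPGMA tree. `measurement_error()`,
  `permutational_manova()`, `mean_shapes()`, `upgma_tree()`, …
- **Balanced LDA benchmarking and assignment.** Classes are randomly
  balanced to 30 per permutation; leave-one-out accuracies per class
  and descriptor set are compared against a shuffled-label chance
  ceiling, and unknown seeds are assigned by majority vote over the
  ensemble. `balanced_benchmark()`, `shuffled_label_baseline()`,
  `assign_unknowns()`.
- **A synthetic seed generator** with known ground truth (shape
  templates written directly in coefficient space; log-normal sizes;
  negative-binomial cell counts; positioning / cleaning / landmarking
  noise; rendering to binary masks at 100 px/mm), so the whole chain
  is testable end to end without any deposited images.
  `default_taxon_models()`, `simulate_population()`,
  `simulate_repeats()`.

## Worked example

Three closely related rounded taxa (the *somniferum*-group analogue),
30 seeds each, acquired with realistic positioning and digitising
noise, then normalized, transformed and classified by shape alone:

```r
library(seedmorph)

models <- default_taxon_models(separation = 1)
pop <- simulate_population(models[c("setigerum", "somniferum", "nigrum")],
                           noise_spec(rotation_sd = 0.08,
                                      outline_jitter_sd = 0.004,
                                      landmark_jitter_sd = 0.008, seed = 1),
                           render = FALSE)

res <- mapply(function(o, l) resample_outline(o, 360, start = unclass(l)[2, ],
                                              check = FALSE),
              pop$outlines, pop$landmarks, SIMPLIFY = FALSE)
ali <- gpa_align(res, pop$landmarks)

cfs <- lapply(ali$outlines, efourier, H = 8)
sel <- choose_harmonics(cfs, threshold = 0.95)
sel$H_star
#> [1] 2
coeffs <- coeff_matrix(cfs, H = sel$H_star)

permutational_manova(coeffs, pop$records$taxon, n_perm = 999, seed = 2)
#> <permanova> df = 2, F = 13.31, r2 = 0.234, adj r2 = 0.217, p = 0.001 (999 perms)
round(loocv_accuracy(coeffs, pop$records$taxon)$per_class, 3)
#>     nigrum  setigerum somniferum
#>        0.9        0.9        0.9
```

Two harmonics carry 95% of the mean harmonic power on these mostly
convex outlines; the permutational MANOVA rejects shape equality of the
three taxa at the permutation floor (p = 0.001 with 999 permutations),
and shape alone already classifies 90% of seeds correctly per taxon —
adding cell counts and log sizes raises this further (see
`analysis/04_classify.R`).

## The analysis workflow

`analysis/` contains the numbered study scripts, each a thin driver
over the package that prints what it finds and writes its tables under
`results/`:

| script | what it does |
|---|---|
| `01_simulate.R` | generates the modern reference collection (7 taxa × 30 seeds + two extra accessions) and 33 archaeological-style unknowns as masks + landmarks + records |
| `02_measurement_error.R` | %ME of the shape coefficients under the position / cleaning / landmark perturbations |
| `03_morphospace.R` | size and cell-count tests, PCA with supplementary unknowns, permutational MANOVA, mean shapes, UPGMA tree |
| `04_classify.R` | class-balanced repeated LDA benchmark per descriptor set, with the shuffled-label ceiling |
| `05_assign.R` | majority-vote assignment of the unknowns per descriptor set |

`run_pipeline(run_config(...))` executes the same chain in one call
with per-stage seeding and a machine-readable `summary.json`.

## Vignette

`vignettes/seed-outline-morphometrics.Rmd` documents the models and
their assumptions, the Fourier parameterization subtleties, the
harmonic-retention convention, what the generator emulates (and what it
deliberately does not), and the package's known limitations.
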