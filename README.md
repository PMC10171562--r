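# comptraj

Riemannian functional principal component analysis for sparse longitudinal
compositional data.

## What it does

`comptraj` models how a three-part composition — for example the relative
volumes of cerebrospinal fluid (pCSF), grey matter (pGM) and white matter
(pWM) in the developing brain — changes over time when each subject is
observed at only a handful of irregular ages. The design it targets is
extremely sparse: most subjects contribute one or two scans, and no subject
is observed on a common grid.

The pipeline:

1. **Geometry.** Each composition `(c1, c2, c3)` (nonnegative, summing to 1)
   is mapped to the unit sphere by the square-root transform
   `(sqrt(c1), sqrt(c2), sqrt(c3))`. The geodesic distance between
   transformed compositions is the Fisher–Rao distance
   `acos(sum(sqrt(c * c')))`, which respects the simplex constraint instead
   of treating proportions as unconstrained reals.
2. **Sparse Riemannian FPCA (RPACE).** The mean trajectory is a
   kernel-localized Fréchet mean on the sphere; observations are lifted to
   tangent vectors by the log map; the tangent covariance surface is
   estimated from between-visit products (same-visit products are excluded
   because they carry the noise term) with local-linear smoothing; its
   quadrature eigendecomposition yields eigenvalues, tangent eigenfunctions
   and a measurement-noise variance; per-subject scores are best linear
   unbiased predictions (the PACE conditional-expectation formula), which
   work with a single observation per subject.
3. **Inference.** Two groups of subjects are compared by an energy-distance
   permutation test on their top-2 score vectors from a single pooled fit.
   Uncertainty in the mean composition at fixed ages is summarized by
   bootstrap confidence regions drawn on the ternary diagram.
4. **Baseline.** A per-tissue random-intercept linear mixed model, with a
   drop-latest-scan holdout benchmark comparing both methods by scaled
   Fisher–Rao prediction error.
5. **Simulation.** A seeded cohort generator with known Karhunen–Loève
   ground truth, emulating a real pediatric study design (343 children,
   1–6 visits each, ages 1.5–8 years).

See the vignette in `vignettes/compositional-trajectories.Rmd` for the
model, estimation details, defaults, and design decisions.

## Worked example

```r
library(comptraj)

gen <- generate_sample(default_scenario())   # two-group synthetic cohort
gen$sample
#> Longitudinal sphere-valued sample: 343 subjects, 541 observations
#>   visits per subject: 1-5 (median 1)
#>   time range: [1.52, 7.99]
#>   groups: group1=227, group2=116

fit <- fit_rfpca(gen$sample)
fit
#> Sparse Riemannian FPCA fit on S^2
#>   grid: 51 points on [1.52, 7.99]
#>   K = 2 components (FVE 99.5%), sigma2 = 0
#>   leading eigenvalues: 0.0159, 0.00582, 0.00237, 0.000699

test_group_difference(gen$sample, n_perm = 9999, seed = 2, fit = fit)
#> Energy-distance two-sample permutation test
#>   statistic = 0.0114784, p-value = 0.0038 (9999 permutations)
#>   group sizes: 227 vs 116

# predict subject 1's composition at age 6 from their observed scans
predict_at_age(fit, gen$sample$times[[1]], gen$sample$obs[[1]], 6)
#> [1] 0.0839 0.6228 0.2932
```

(The pooled fit warns that the noise-variance estimate clipped at zero —
pooling two groups with different means inflates the covariance diagonal —
and falls back to a tiny ridge in the score systems.)

Other entry points:

```r
bm <- holdout_benchmark(gen$sample)          # RPACE vs LMM holdout errors
reg <- bootstrap_mean_regions(gen$sample)    # 95% regions at ages 2.8..6.7
rfpca_save(fit, "model.json")                # bit-exact archive
fit2 <- rfpca_load("model.json")
```

A command-line interface wrapping simulate / fit / test-groups / benchmark /
regions / predict lives at `inst/cli/comptraj-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "comptraj-cli.R", package = "comptraj"))')" \
  simulate --out cohort.csv --seed 1
```

## Data format

Long-format delimited text (comma or tab), one row per scan:

```
subject_id,age,csf,gm,wm,group
s001,2.31,0.102,0.591,0.307,group1
```

`read_longitudinal_table()` accepts proportions (rows must sum to 1) or raw
volumes (`mode = "volumes"`, rows normalized by their total), and ages in
years or months (`unit` flag — never guessed).

## Reproducing results

Everything is deterministic given seeds. The test suite
(`testthat::test_dir("tests/testthat")`) includes an acceptance file
mirroring the package's acceptance criteria: parameter recovery on the
default scenario at n = 300, a dense-subject score oracle, energy-test
type-I error and power simulations, the benchmark ordering (RPACE beats the
LMM baseline), bootstrap-region coverage, and bit-exact serialization
round trips. A standalone run:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

fits the central scenario and writes the headline quantities (eigenvalue
errors, eigenfunction alignments, FVE, group-test and null p-values,
benchmark scaled errors) as JSON.
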