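# trajqtl

Functional mapping of longitudinal growth traits in clonal tree trials.

Breeders and tree geneticists measure the same clones year after year —
height in metres, diameter at breast height (DBH, cm at 1.3 m) — and want to
know (i) which sigmoidal growth law best describes the trajectories, (ii)
whether candidate SNPs change the *whole trajectory* rather than the trait
at a single age, and (iii) when trees pass from rapid into reduced growth,
which bears directly on rotation age. `trajqtl` implements that workflow
end to end for small candidate-SNP panels, plus a seeded synthetic-trial
generator for validation, since raw multi-year phenotypes of such trials
are rarely published.

## What it computes

**Growth laws.** Four three-parameter models with analytic derivatives,
inflection times and asymptotes:
Gompertz `y = a·exp(−b·cᵗ)`, Chapman–Richards `y = a·(1−e^(−bt))ᶜ`,
logistic `y = Asym/(1+exp((xmid−t)/scal))`, asymptotic regression
`y = a+(b−a)·exp(−eᶜ·t)`.

**Fitting and selection.** Levenberg–Marquardt least squares with
self-start heuristics and seeded restarts (`fit_growth()`,
`fit_growth_curves()`); five metrics (AIC, BIC, R², RMSE, MAE) with paired
t-tests across clones, Holm-adjusted, and a non-domination winner rule
(`compare_growth_models()`).

**Trajectory QTL test.** The likelihood ratio

```
LR = −2·(log L0 − log L1)  ~  χ² with 3·(G−1) df
```

compares one pooled curve (`L0`) against genotype-class-wise curves (`L1`)
for the `G` classes of a SNP (`lr_trajectory_test()`), with
Hardy–Weinberg-aware class construction, minimum class sizes, optional
merging of classes with indistinguishable curves, per-year one-way GLM
association, a MANOVA on fitted parameter vectors, and Mendelian
segregation chi-square tests.

**Ontogenetic staging.** Phase boundaries at the point of maximum curvature
`κ(t) = |y''|/(1+y'²)^{3/2}` on the decelerating limb
(`max_curvature_point()`, `phase_report()`), separating rapid from reduced
growth.

## Worked example

Simulate a 24-clone trial with one additive SNP shifting the height
asymptote by 10% per alt allele, then run the analysis:

```r
library(trajqtl)
library(dplyr)

cfg <- sim_config(
  snp_specs = tibble::tibble(snp = "SNP12", maf = 0.4, effect_target = "a",
                             effect_size = 0.1, dominance = "additive"),
  seed = 42)
geno  <- simulate_genotypes(cfg)
pheno <- simulate_trajectories(geno, cfg)

fits <- fit_growth_curves(filter(pheno, trait == "height_m"), seed = 42)
glance(compare_growth_models(fits))
#>   trait    winner  n_clones n_significant_pairs
#> 1 height_m richard       24                  28

cl <- genotype_classes(geno, "SNP12")
lr_trajectory_test(pheno, cl, "height_m", seed = 42)
#> <lr_test> SNP SNP12, height_m, richard law:
#>   LR = 590.769, df = 6, p = 2.28e-124 (3 classes)
```

The generating law (Chapman–Richards, "richard") wins the metric
comparison, and the trajectory test detects the simulated SNP decisively:
the pooled single-curve model loses 591 log-likelihood ratio units against
class-wise curves on 6 degrees of freedom (three curve parameters × two
extra classes).

Staging the three genotype classes:

```r
phase_report(lr_trajectory_test(pheno, cl, "height_m", seed = 42)$class_fits)
#>   class     t_mc t_max_growth asymptote extrapolated
#> 1   A/A 13.52157     2.672719  28.03070         TRUE
#> 2   A/G 13.74474     2.631820  30.25314         TRUE
#> 3   G/G 14.53154     2.597079  33.85730         TRUE
```

Each class grows fastest around age 2.6 y (`t_max_growth`, the inflection)
and enters reduced growth at `t_mc` ≈ 13.5–14.5 y — the better-performing
alt-homozygote (asymptote 33.9 m) latest. Boundaries past the 11-year
record are flagged `extrapolated`. Per-year association confirms the
divergence grows with age:

```r
per_year_glm(pheno, cl, "height_m", ages = c(3, 7, 11))
#>     age statistic   df1   df2        p     n
#>       3      38.0     2    21 1.05e- 7    24
#>       7     194.      2    21 2.88e-14    24
#>      11     423.      2    21 1.08e-17    24
```

`run_pipeline(run_config(pheno, geno, seed = 42, out_dir = "reports"))`
chains all stages and writes CSV reports plus a JSON manifest.

## License

MIT.
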