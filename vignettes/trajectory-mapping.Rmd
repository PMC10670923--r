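---
title: "Functional mapping of longitudinal growth traits with trajqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional mapping of longitudinal growth traits with trajqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajqtl)
library(dplyr)
```

## The problem

Perennial trees in a clonal field trial are measured repeatedly — here
height (m) and diameter at breast height (DBH, cm, taken at 1.3 m) at ages
1, 2, 3, 5, 6, 7, 9, 10 and 11 years from planting, with years 4 and 8
unmeasured. Two questions drive the analysis:

1. **Does a SNP affect the whole growth trajectory**, not just the trait at
   one age? Single-time association throws away the longitudinal structure;
   functional mapping instead fits a parametric growth law per genotype
   class and tests whether the classes need different curves.
2. **When does a tree switch from rapid to reduced growth?** The answer
   informs rotation age. We locate the switch at the point of maximum
   curvature of the fitted trajectory.

## Growth laws

Four three-parameter sigmoidal laws are supported (`growth_models()`):

| law | form | plateau |
|---|---|---|
| Gompertz | $y = a\,e^{-b c^t}$, $0<c<1$ | $a$ |
| Chapman–Richards | $y = a (1-e^{-bt})^c$ | $a$ |
| logistic | $y = \mathrm{Asym} / (1 + e^{(x_{mid}-t)/scal})$ | Asym |
| asymptotic regression | $y = a + (b-a)e^{-e^{c} t}$ | $a$ |

All four are nondecreasing on $t \ge 0$ for admissible parameters;
`validate_growth_params()` enforces admissibility and names the violated
constraint. Analytic first and second time-derivatives
(`growth_deriv()`) back the inflection solver and the curvature module;
they are closed-form, so staging is deterministic.

The Chapman–Richards law is the printed three-parameter form
$a(1-e^{-bt})^c$, not the four-parameter generalized logistic that also
travels under the name "Richards". Both the sigmoid ($c>1$) and the
concave ($c\le 1$) sub-cases are supported; the latter has no interior
inflection and `time_of_max_growth()` returns a typed `NA` sentinel
rather than an error. Its growth rate is singular at exactly $t=0$ when
$c<1$; derivative code returns the one-sided `Inf` limit and the
curvature module refuses that point by name.

## Fitting

`fit_growth()` minimizes the residual sum of squares with
Levenberg–Marquardt least squares. Parameter bounds are enforced by
transformation — log for positive parameters, logit for the Gompertz
$c\in(0,1)$ and for the asymptotic-regression ratio $b/a\in[0,1)$ —
rather than by a constrained solver, so any unconstrained least-squares
backend could be substituted. Starting values come from closed-form
heuristics (`initial_growth_params()`): amplitude $1.05\max y$, logistic
midpoint from the half-maximum age, rates from log-linearizations. A
non-converged or non-improving start is retried with up to 10 seeded
multiplicative lognormal jitters (sd 0.3); the returned SSE never
exceeds the SSE at the initial guess. Convergence uses a relative SSE
tolerance of `1e-10` with at most 500 iterations; all of these sit in
`growth_control()`.

The log-likelihood is the concentrated Gaussian form
$\ell = -\tfrac n2(\log 2\pi\hat\sigma^2 + 1)$ with
$\hat\sigma^2 = \mathrm{SSE}/n$, floored at $10^{-12}$ so that perfect
fits stay finite. The five comparison metrics use the full-Gaussian
convention with $k = 4$ counted parameters ($\sigma$ included), matching
`stats::AIC()` on `nls` objects:
$\mathrm{AIC} = n\log(2\pi\hat\sigma^2) + n + 2k$. AIC conventions
differ by additive constants between implementations — harmless for
ranking, fatal for cross-implementation comparison, hence documented
here. $\hat\sigma^2$ is per-series (standard for independent `nls`
fits); no sharing across clones. Missing ages are simply absent rows —
no imputation, ever.

Measurement-error assumptions are deliberately simple: independent
Gaussian noise. Autocorrelated residual structures (SAD/AR) used by full
functional-mapping machinery are out of scope.

## Model selection

`compare_growth_models()` reproduces metric-wise significance
comparison across clones: for each metric, all six law pairs are
compared with a paired two-sided t-test (the clone is the pairing unit)
and Holm-adjusted within metric. The winner is the law with the best
mean AIC among laws never significantly worse than another on AIC, with
ties broken by mean BIC, then mean RMSE, then catalogue order; the full
rationale is recorded in `decision_trace`. A degenerate paired t
(zero-variance, nonzero-mean differences) is reported as $p = 0$ with a
flag — in the paired-t framework a constant nonzero difference is
infinitely strong evidence, and it must not crash.

## The trajectory LR test

For one SNP, clones partition into genotype classes
(`genotype_classes()`; heterozygote order is normalized; classes under
`min_class_size = 3` are dropped; fewer than two usable classes makes
the SNP untestable, as with a monomorphic locus). The test statistic is

$$\mathrm{LR} = -2(\log L_0 - \log L_1)$$

where $L_0$ is the likelihood of one curve fitted to all usable clones'
observations pooled and $L_1$ that of class-wise curves. Class fits are
initialized from the pooled fit, which guarantees nesting
($\mathrm{LR} \ge 0$ up to solver slack) by construction.

**Residual-variance convention.** By default $L_1$ uses a single
residual variance pooled across classes, so
$\mathrm{LR} = n\log(\mathrm{SSE}_0/\sum_g \mathrm{SSE}_g)$ and the
class split frees exactly the $3(G-1)$ curve parameters that the
$\chi^2_{3(G-1)}$ reference counts. The alternative — each class its own
concentrated $\hat\sigma^2$, as fully independent per-class `nls` fits
would give — additionally frees $G-1$ variances; pairing it with the
curve-parameters-only df is therefore anticonservative, while counting
the variances (`count_sigma_df = TRUE`, df $= 4(G-1)$) restores
calibration. All three
pairings are available; the calibrated shared-variance convention is the
default, and the suite verifies its null rejection rate at the trial's
own scale (24 clones, 500 replicates) against the binomial confidence
band.

`merge_similar_classes()` collapses classes whose fitted curves are
nearly identical (normalized $L^2$ distance of predictions over the
observation window, divided by the squared pooled asymptote, below a
threshold; greedy, refitting after each merge) — the situation where a
heterozygote tracks one homozygote so closely that the two act as one
genotype. The merge history is retained. `threshold = 0` disables
merging.

Companion tests: `per_year_glm()` (one-way fixed-effects GLM per age —
exactly one-way ANOVA, no kinship or structure covariates, defensible
for a small panel of unrelated clones), `param_association()` (one-way
MANOVA on the per-clone fitted parameter vectors; Wilks' $\Lambda$ with
Rao's F transform as the primary p-value — exact at one response
dimension, where it collapses to the per-year ANOVA — and Bartlett's
chi-square as a secondary), and `genotype_count_test()` (Pearson
chi-square of class counts against 1:2:1 or 1:1 Mendelian ratios). No
multiple-testing correction across SNPs by default (raw $p < 0.05$
reporting); Benjamini–Hochberg by flag in the pipeline.

## Ontogenetic staging

Curvature $\kappa(t) = |y''| / (1+y'^2)^{3/2}$ is evaluated from the
analytic derivatives. `max_curvature_point()` finds
$t_{mc} = \arg\max \kappa$ by dense grid ($\Delta t = 0.01$ y) plus
golden-section refinement to $10^{-4}$ y — fully deterministic. The
search is restricted to the decelerating limb ($t$ past the inflection)
by a default guard, since the phase boundary of interest is the onset of
*reduced* growth; a window confined to the accelerating limb is flagged,
as is an argmax on the window boundary.

Two numerical facts shape the design:

* **Curvature is not unit-invariant.** Rescaling either axis moves
  $\kappa$'s argmax; height-in-metres and DBH-in-centimetres therefore
  live on different curvature scales. The default computes on raw units
  (reproducing staging done with curvature tools on raw data); a
  `normalize = "minmax"` mode rescales both axes to $[0,1]$ over the
  window, which makes staging unit-free and makes exact
  reparameterization identities hold (stretching time twofold exactly
  doubles $t_{mc}$ — a property the suite checks).
* **On raw units, a larger asymptote with identical shape parameters
  gives a later $t_{mc}$** (e.g. Chapman–Richards $a=30$ vs $a=36$ at
  $b=0.2$, $c=2$: 14.14 vs 15.05 y). Better-performing genotypes thus
  enter reduced growth later even without shape differences; the phase
  report evaluates and reports this concordance rather than asserting
  it.

`phase_report()` emits the two phases (rapid $[0, t_{mc}]$, reduced
beyond), the inflection age, and the asymptote per genotype class, and
stamps rows whose boundary lies past the last observation with an
extrapolation flag — fitted curves are routinely read beyond an 11-year
record (the boundary itself often falls at 10–15 years), and the flag
keeps that honest.

## The synthetic trial generator

Raw phenotypes of this kind of trial are rarely published, so the
package carries a seeded generator (`sim_config()`,
`simulate_genotypes()`, `simulate_trajectories()`) producing data with
the statistical structure the analysis assumes:

* 24 clones; diploid SNP genotypes iid under Hardy–Weinberg equilibrium
  at a chosen MAF (the trial's observed MAF range was roughly
  0.08–0.44);
* Chapman–Richards trajectories with base parameters
  height $(a, b, c) = (28, 0.18, 1.6)$ and DBH $(33, 0.26, 1.35)$.
  These are realism placeholders, not estimates from any real trial:
  they put 11-year height near 22 m and DBH near 30 cm (inside typical
  field ranges of 12–28 m and 19.8–36.3 cm) and the maximum-curvature
  onsets at 13.5 y (height) and 10.7 y (DBH), in the bands field studies
  report;
* genotype effects act **multiplicatively on curve parameters**
  ($(1+\text{effect})^{\text{dose}}$ with additive, dominant or
  recessive dose coding), so class trajectories are similar early and
  diverge with age — the signature the trajectory test is built to
  detect, as opposed to a constant additive offset;
* three ramets per clone, each observing curve value plus iid Gaussian
  noise (default sd 2% of the clone's asymptote), averaged to clone
  means for analysis (ramet-level rows by flag).

What the generator does **not** emulate: linkage disequilibrium between
SNPs, pedigree/kinship structure, spatial block effects, autocorrelated
within-tree measurement error, and genotype-by-environment interaction.
Passing tests on this generator therefore show the machinery is correct
and calibrated under the stated assumptions; they do not show those
assumptions hold in any particular field trial.

## Numerical choices and degenerate inputs

* Solver tolerances: SSE relative `1e-10`, max 500 iterations, 10
  restarts, jitter sd 0.3 (`growth_control()`).
* $\hat\sigma^2$ floored at `1e-12`; zero-variance series are refused at
  initialization; $R^2$ on a zero-SST series errors.
* Degenerate paired t in model selection: $p = 0$ with a `degenerate`
  flag.
* Monomorphic or under-sized SNP classes: typed untestable sentinel, not
  an exception; untestable SNPs flow through the pipeline as flagged
  rows.
* Wilks' $\Lambda$ refuses a near-singular within-class covariance
  (reciprocal condition below `1e-12`) with advice to standardize.
* Grid/golden-section staging is bit-deterministic; ties on a flat
  curvature plateau resolve to the grid argmax, which is flagged as a
  boundary case when it touches the window edge.

## Problem sizes used in the checks

The shipped verification uses the trial's own scale: 24 clones, nine
ages, 500-replicate null calibration of the LR test, 20-replicate model
recovery and 25-replicate power runs, and randomized-oracle sweeps of
1,000 parameter draws for derivatives and 50 for staging. These sizes
make the whole suite run in minutes while leaving the binomial
confidence bands tight enough to detect the miscalibrations the design
guards against.

## A worked run

```{r, eval = FALSE}
cfg <- sim_config(
  snp_specs = tibble::tibble(
    snp = "SNP12", maf = 0.4, effect_target = "a",
    effect_size = 0.1, dominance = "additive"
  ),
  seed = 42
)
geno <- simulate_genotypes(cfg)
pheno <- simulate_trajectories(geno, cfg)

res <- run_pipeline(run_config(pheno, geno, seed = 42, out_dir = "reports"))
res$winner          # selected growth law
res$qtl             # LR test per SNP x trait
res$staging         # phase boundaries per genotype class
```

## Known limitations

Independent-Gaussian likelihood (no serial correlation within a clone's
series); no mixed-effects or hierarchical curve fitting; no
population-structure or kinship correction in any association test; no
genome-wide scan tooling (the design targets a small candidate-SNP
panel); two growth phases only — segmented regression with more
breakpoints is a different tool; curvature staging inherits the
unit-dependence discussed above unless the normalized mode is used.
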