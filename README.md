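# survcompare

Benchmarking machinery for right-censored survival prognosis on cohorts
that combine categorical clinical covariates with high-dimensional gene
expression. The package asks — and lets you re-ask on data with known
ground truth — two questions that matter for prognostic-model design:

1. does gene expression add predictive value over a complete set of
   clinical covariates, and
2. does a random survival forest (RSF) outperform an unpenalized Cox
   proportional-hazards model as the number of features grows?

## What is inside

* **Synthetic cohort generator** — seeded cohorts with planted prognostic
  structure: categorical clinical covariates, an `n x p` expression matrix
  with a small informative subset, proportional-hazards Weibull event
  times with optional gene-gene interactions, dropout plus administrative
  censoring, and a molecular-subtype stand-in label derived from the
  informative genes.
* **Preprocessing** — equal-width discretization (`low`/`medium`/`high`),
  deterministic mode/median imputation, and the per-year `alive`/`dead`/`NA`
  follow-up grid from which binary landmark survival targets (year 5/10/15)
  are read.
* **Relief feature weighting** — the single-nearest-neighbour, binary-target
  Relief algorithm with the `W[F] - Diff(F,D,H)/m + Diff(F,D,M)/m` update,
  a deterministic exhaustive variant, and the two clinical/gene integration
  strategies (Method 1: Relief on the pooled table; Method 2: Relief on
  genes only, all clinical features added).
* **Cox model** — Breslow-tie partial likelihood maximized by
  Newton-Raphson, Breslow baseline hazard, per-patient survival step
  curves. Deliberately unpenalized.
* **Random survival forest** — bootstrap survival trees with standardized
  log-rank splitting, unique-death stopping, Nelson-Aalen leaf cumulative
  hazards, ensemble curves and out-of-bag error; compiled core.
* **Evaluation** — exact areas under survival step curves, the area-based
  concordance index (patient `j` dead before patient `k` observed later is
  concordant iff `area_j < area_k`, strictly), chi-square comparison of two
  concordance results, a leakage-free 5-fold cross-validation harness, and
  a full experiment grid over dataset variants
  (`Clinical_Only` / `Clinical_PAM` / `Clinical_Gene`), models, landmark
  years, and feature counts `k` in {30, 50, 100, 150}.

## Worked example

```r
library(survcompare)

# an n = 500 cohort, 200 genes (10 informative, with interactions)
coh <- generate_cohort(cohort_spec(seed = 1))
coh
#> Synthetic survival cohort: 500 patients, 200 genes ( 10 informative ), 371 deaths

# 5-year survival, clinical + Relief-selected genes (Method 2, 50 features),
# random survival forest, 5-fold cross-validation
cv <- cross_validate(coh, "Clinical_Gene", model = "rsf", year = 5,
                     k = 50, method = 2, seed = 1,
                     rsf_config = rsf_config(n_trees = 100))
cv
#> Concordance index 0.5730 (58529 concordant of 102140 evaluable pairs)

# clinical covariates alone, same folds
cross_validate(coh, "Clinical_Only", model = "rsf", year = 5, seed = 1,
               rsf_config = rsf_config(n_trees = 100))
#> Concordance index 0.5468 (55847 concordant of 102140 evaluable pairs)
```

The concordance index is the fraction of evaluable patient pairs — a death
paired with any strictly later observation — in which the earlier death had
the smaller area under its predicted survival curve. Here the planted gene
signal lifts 5-year concordance by about three points over the clinical
covariates alone; with no signal the index sits at chance (0.5). Absolute
values are deliberately modest: the cohort carries realistic effect sizes,
and the strict-tie area rule reads lower than Harrell-style estimators.

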