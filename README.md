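# optivalid

Optimism-corrected internal validation of logistic prediction models — and
a framework for studying how well the corrections themselves work.

## The problem

A prediction model for a binary outcome, fitted on a small development
sample, looks better on its own training data than it will in new
patients: apparent performance is optimistic.  Internal validation
corrects this with resampling — cross-validation or the bootstrap — but
the corrections interact with the *estimator* used to fit the model.
Pooled leave-one-out (LOO) cross-validation biases the c-statistic
downwards, and the bias is far more severe for estimators that shrink
predicted probabilities towards the observed event fraction (ridge
regression tuned on small null data shrinks almost completely): leaving
out an event lowers the training event fraction, so the left-out event's
prediction is systematically too low, and a non-event's too high.  A
shrunken model turns this small systematic gap into a near-deterministic
ordering, and the pooled c-statistic collapses below 0.5.

`optivalid` is for biostatisticians who build or evaluate prediction
models in small samples and want to know which correction to trust.  It
implements:

* **Estimators** — maximum likelihood (`fit_ml`), Firth's penalized
  likelihood (`fit_firth`; finite coefficients under separation), and
  ridge logistic regression (`fit_ridge`, `tune_ridge`) tuned by the
  penalized AIC `-2 l(b) + 2 df_e`, with `df_e` the effective degrees of
  freedom `trace(I (I + penalty)^-1)`.
* **Measures** — c-statistic (AUC), discrimination slope (Tjur's R²),
  Brier score; `winsorize_c` for floor-at-0.5 sensitivity analyses.
* **Corrections** — apparent, pooled LOO CV, leave-pair-out CV, repeated
  5-fold CV, enhanced bootstrap, and the .632+ bootstrap with
  relative-overfitting-rate weighting.
* **Study machinery** — a synthetic data-generating mechanism with mixed
  covariate types, an exact linear-programming separation diagnostic
  (`detect_separation`), and a simulation driver (`run_study`) that
  scores every technique against a 100,000-observation independent
  validation set by mean difference, RMSD, and Monte-Carlo standard
  errors.

## Worked example

Draw one adverse-case development sample (n = 50, event fraction 0.25, no
true effects) and validate a tuned ridge model internally:

```r
library(optivalid)
scenario <- make_scenario(50, 0.25, "null")
dev <- gen_dataset(scenario, seed = 42)
dev
#> <ov_dataset> n = 50, 5 covariates, 12 events (24.0%)

internal_validation(dev, "rr",
                    techniques = c("apparent", "loo", "kfold", "boot632plus"),
                    seed = 1)
#>      technique measure estimate n_fits n_failed
#> 1     apparent   cstat  0.76316      1        0
#> 2     apparent  dslope  0.08551      1        0
#> 3     apparent   brier  0.15831      1        0
#> 4          loo   cstat  0.43640     50        0
#> 5          loo  dslope -0.03352     50        0
#> 6          loo   brier  0.20122     50        0
#> 7        kfold   cstat  0.63430    200        0
#> 8        kfold  dslope  0.00175    200        0
#> 9        kfold   brier  0.19747    200        0
#> 10 boot632plus   cstat  0.62756    200        0
#> 11 boot632plus  dslope  0.05220    200        0
#> 12 boot632plus  brier   0.18951    200        0
```

The gold standard — the same model scored on a fresh 100,000-observation
draw from the same population — shows what each correction was trying to
estimate:

```r
valset <- gen_validation_set(scenario, 1e5, seed = 99)
unlist(independent_validation(tune_ridge(dev), valset))
#>        cstat       dslope        brier
#> 0.5031200329 0.0008222553 0.1950302178
```

The data carry no signal, so the true c-statistic is 0.50.  The apparent
value (0.76) is wildly optimistic; repeated 5-fold CV and the .632+
bootstrap land near 0.63 on this single draw; pooled LOO (0.44) has
overshot *below* chance — and averaged over replicates it is the only
technique biased this way, most severely for ridge.  The Brier score, by
contrast, is estimated nearly without bias by LOO (0.201 vs. 0.195).

Your own data go through the same pipeline via
`validate_data("mydata.csv", outcome = "y")`, and `loo_trace(seed)`
reproduces the per-iteration mechanism of the LOO bias on a 20-observation
toy example.

## Package layout

| file | contents |
|---|---|
| `R/dgm.R` | scenarios, covariate/outcome generators, validation sets |
| `R/separation.R` | LP-based complete/quasi-separation diagnostic |
| `R/estimators.R` | ML, Firth, ridge + penalized-AIC tuning |
| `R/measures.R` | c-statistic, discrimination slope, Brier score |
| `R/resampling.R` | the five optimism-correction techniques |
| `R/evaluation.R` | replicates, summaries (bias, RMSD, MCSE), study driver |
| `R/interface.R` | external-data pathway, LOO toy trace |
| `src/fitters.cpp` | compiled IRLS / Firth / ridge-path cores |
| `vignettes/internal-validation.Rmd` | methods, design decisions, limitations |
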