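# scmsim

Bed-day simulation and severe-adverse-event prediction for
chemotherapy-based stem-cell mobilization in multiple myeloma.

Autologous stem-cell transplantation requires a mobilization course —
chemotherapy (cyclophosphamide and/or etoposide regimens plus G-CSF),
a leukopenic phase, apheresis stem-cell collection around day 13, and a
short recovery tail — that many centers run fully inpatient over roughly
two weeks. Most severe adverse events (SAEs: CTCAE grade ≥ 3 or requiring
in-hospital management, chiefly neutropenic fever) cluster either within
72 h of therapy start or from day 5 onward, which opens a window for
risk-stratified outpatient management. `scmsim` is for biostatisticians and
clinical modellers who want to quantify that opportunity:

* a **cohort model** — per-patient timelines on an integer day axis
  (day 0 = therapy start) plus a long adverse-event table, with validation
  and lossless CSV/JSON interchange;
* a **fixture cohort** of 109 patients deterministically reconstructed so
  that every published summary marginal (event counts, onset
  medians/ranges, leukopenia and collection timing, SAE tallies) is
  reproduced exactly;
* a **synthetic cohort generator** with calibrated event co-occurrence
  (one-factor Gaussian copula), enforced bimodal SAE onsets, and plantable
  covariate–outcome effects for statistical testing;
* a **bed-day simulator**: admission policies (`current`, `day5`, `worst`,
  `empirical`, `best` × sub-models X1/X2/X3) map each timeline to
  hospitalization intervals; totals are normalized against the observed
  course with patient-level percentile-bootstrap 95% CIs
  (`total_bd(scenario) / total_bd(current)` on each resample);
* a **two-step prediction framework**: stage 1 classifies SAE occurrence
  after the 72 h window (stratified nested 5-fold CV, class weights,
  accuracy / ROC-AUC / MCC); stage 2 regresses the first-SAE day from
  admission-day features for predicted-positive patients (3-fold CV, MAD
  and RMSD in days).

## Worked example

```r
library(scmsim)
library(dplyr)

fx <- build_fixture_cohort(seed = 0)
all(verify_marginals(fx)$pass)
#> [1] TRUE

suite <- scenario_suite(fx, n_boot = 2000, seed = 1)
suite |> select(label, total_bd, fraction, ci_low, ci_high)
#>      label total_bd fraction ci_low ci_high
#> 1  Current     1779    1.000  1.000   1.000
#> 2      S51     1466    0.824  0.815   0.835
#> 3      S52     1206    0.678  0.667   0.690
#> 4      SW1      868    0.488  0.444   0.532
#> 5      SW2      608    0.342  0.308   0.379
#> 6      SE1      825    0.464  0.427   0.503
#> 7      SE2      565    0.318  0.287   0.351
#> 8      SE3      456    0.256  0.214   0.301
#> 9      SB1      782    0.440  0.409   0.475
#> 10     SB2      522    0.293  0.267   0.325
#> 11     SB3      413    0.232  0.194   0.274
```

The observed inpatient course occupies 1779 bed-days on the fixture
cohort. Admitting everyone without an early SAE on day 5 (`S51`/`S52`)
needs 82%/68% of that; admitting at the observed first SAE with
outpatient therapy and collection (`SE3`) needs 26% — a 74% reduction —
with best/worst-case fever-shift scenarios bracketing it. `autoplot(suite)`
draws the fraction bar chart with CI error bars;
`plot_sae_onset_distribution(fx)` shows the bimodal onset split (days 0–2
vs ≥ 5).

```r
ds <- make_ml_dataset(fx, endpoint = "fever", feature_set = "clinical")
glance(run_classification(ds, models = c("logistic", "random_forest"),
                          seed = 1))
#>           model accuracy roc_auc     mcc endpoint n_folds seed
#> 1      logistic    0.476   0.498 -0.0505    fever       5    1
#> 2 random_forest    0.457   0.478 -0.0878    fever       5    1
```

Chance-level scores are expected here and are themselves informative: the
fixture reproduces published *marginals* while its covariates are drawn
independently of outcomes, so a leak-free pipeline must score near AUC 0.5.
The framework's power is demonstrated on generated cohorts with planted
effects (see the test suite and the vignette), e.g. a 1.5 log-odds
hemoglobin effect on fever is recovered at AUC > 0.7 with n = 500.

## Documentation

The methods vignette (`vignettes/outpatient-mobilization.Rmd`) describes
the models, their assumptions, the tunable parameters with defaults and
units, and the package's design decisions and limitations.
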