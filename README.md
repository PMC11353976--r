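# tempheno

Temporal computational phenotyping of longitudinal outpatient EHR data, and
interpretable prediction of a first acute myocardial infarction (AMI) within
six months.

Most first heart attacks happen outside the hospital, in patients without any
recorded cardiac diagnosis. The question this package addresses is whether
the *temporal* structure of ordinary outpatient records — labs, vitals,
diagnoses, prescriptions accumulating over five years — carries predictive
signal that snapshot features miss, and whether that signal can be expressed
in a form a clinician can read. It is written for biostatisticians and
clinical-informatics researchers who want to run, test, or extend this kind
of analysis without access to a protected hospital extract: a synthetic
cohort generator with a planted, known ground truth stands in for the real
data, so every stage of the pipeline is verifiable.

## What it does

* **Synthetic matched cohorts** (`cohort_spec()`, `generate_cohort()`):
  five years of irregular outpatient encounters per patient; continuous labs
  with missingness; binary diagnosis/medication events with ICD-10-like
  hierarchical codes; outcomes driven by planted low-rank temporal
  phenotypes; 2:1 control matching exact on sex and within ±2 years of age
  and ±2 frailty points; a 70/30 train/test split by matched set.
* **Preprocessing** (`preprocess_events()` and its parts): value cleaning
  and temperature unit conversion, ICD-9→10 mapping, chapter-Z removal,
  3-character hierarchy roll-up, and train-frozen missingness (>60%) and
  prevalence (<1% in both classes) filters.
* **Feature representations**: latest values + demographics, five-year
  summary statistics, and two patient × time × feature tensors (10 six-month
  bins; labs discretized into training-set quintiles; diagnoses
  carried forward across encounter-free intervals then zero-filled).
* **Tensor phenotyping** (`nncp_hals()`): non-negative CP/PARAFAC
  decomposition by hierarchical alternating least squares, written in-repo.
  Each rank-one component

  `X ≈ Σ_r λ_r · a_r ∘ b_r ∘ c_r,  a_r, b_r, c_r ≥ 0`

  is a *phenotype*: patient memberships `a_r`, a temporal signature `b_r`,
  and feature weights `c_r`. Held-out patients are projected onto fixed
  phenotypes by non-negative least squares (`project_patients()`); ranks are
  scanned by downstream discriminability (`select_rank()`).
* **mRMR feature selection and kNN imputation** (`mrmr_select()`,
  `knn_impute()`): greedy relevance/redundancy selection with random-forest
  relevance and Pearson redundancy, then train-fitted nearest-neighbour
  imputation.
* **TGFNN** (`fit_tgfnn()`, `extract_rules()`): a tropical-geometry
  fuzzy-rule neural network — Gaussian concept encodings (low/medium/high),
  learned conjunction rules through a product↔minimum T-norm, sum↔maximum
  T-conorm inference — trained by backpropagation, with human-readable rule
  extraction.
* **Evaluation** (`kfold_evaluate()`, `binary_metrics()`,
  `platt_calibrate()`, `friedman_nemenyi()`, `kendall_concordance()`):
  stratified cross-validation against a fixed test set, class weighting or
  majority downsampling, random hyperparameter search, Platt calibration
  with reliability curves, and rank-based model comparisons.

## A worked example

```r
library(tempheno)

spec <- cohort_spec(n_cases = 50, control_ratio = 2, n_lab_features = 6,
                    n_dx_features = 8, n_rx_features = 4, planted_rank = 2,
                    outcome_coefs = c(1.5, 0), seed = 1)
dat  <- generate_cohort(spec)
prep <- preprocess_events(dat$events, dat$cohort)

train <- dplyr::filter(dat$cohort, split == "train")
q     <- fit_quintiles(prep$events, train$patient_id,
                       variables = prep$kept_continuous)
lv    <- build_labvital_tensor(prep$events, train, q)
fit   <- nncp_hals(lv, rank = 2, seed = 1)
glance(fit)
#> # A tibble: 1 × 5
#>    rank rel_error iterations reseeds  seed
#>   <int>     <dbl>      <int>   <int> <dbl>
#> 1     2     0.428        181       0     1
phenotype_report(fit, k = 3)$features
#> # A tibble: 6 × 4
#>   component position feature weight
#>       <int>    <int> <chr>    <dbl>
#> 1         1        1 lab_04   0.564
#> 2         1        2 lab_06   0.533
#> 3         1        3 lab_02   0.518
#> 4         2        1 lab_03   0.567
#> 5         2        2 lab_05   0.545
#> 6         2        3 lab_01   0.502
```

The relative error is substantial because the quintile-discretized tensor is
far from exactly low-rank — what matters is that the component structure
separates the planted phenotypes: the generator loads even-numbered labs on
one planted factor and odd-numbered labs on the other, and each fitted
component's top features are exactly one of those groups. `autoplot(fit)` draws the two temporal
signatures; `project_patients(fit, test_tensor)` scores held-out patients on
the same phenotypes.

The full synthetic study — six feature sets, classifiers behind a common
contract, calibration and rank-based comparisons — is one call:

```r
run_phenotyping_pipeline(cohort_spec(), seed = 1)
```

which returns test-set AUROC/AUPRC/F1 per feature set. On the default
conditions the phenotype-containing sets clearly beat latest-value features
(AUROC ≈ 0.70 vs ≈ 0.52 at seed 101 in our runs).

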