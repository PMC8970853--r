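# icuprior

Prior distributions of ICU-monitored vital signs from hidden Markov
models and conditional inference trees.

## The problem

When a patient is admitted to an intensive care unit, their basic
clinical data (sex, age, weight, height, BMI) are available immediately,
while the monitored variables (heart rate, mean arterial pressure, ...)
only accumulate during the stay. If the *distribution* of a monitored
variable under each latent patient state can be predicted from the basic
data alone, clinicians get a patient-specific prior — a heart rate that
is normal for one patient may be alarming for another — and downstream
state-prediction models get informative initial distributions.

`icuprior` implements that estimation pipeline for researchers working
with ICU cohort data (or, out of the box, with a synthetic cohort that
emulates its structure):

1. **Per-patient Gaussian HMM.** For patient *n* with monitored series
   `A[n, k, t]` (variable *k*, time *t*), a hidden first-order Markov
   chain `y[n, t] ∈ {1, …, S}` (default S = 2) emits
   `A[n, k, t] | y[n, t] = s ~ N(μ[n, k, s], σ[n, k, s]²)`,
   independently across variables given the state (a full-covariance
   variant is available). Parameters are estimated per patient by
   Baum–Welch EM with a uniform initial distribution; smoothed
   posteriors `p(y[n, t] = s | A[n, ·, ·])` come from the scaled
   forward–backward recursions, and states are decoded by posterior
   argmax.
2. **Rule-based validation.** Each time point is independently labelled
   *circulatory failure* iff MAP ≤ 65 mmHg, or vasoactive/inotropic
   drugs are present and lactate > 2 mmol/l. After aligning the fitted
   states (the state with lower mean MAP is failure), the posterior
   failure probability is scored against these labels with a
   Mann–Whitney AUC, per patient, restricted to patients whose labels
   contain both classes.
3. **Association testing.** Each fitted parameter `μ̂[n, k, s]`,
   `σ̂[n, k, s]` is tested across patients against each basic covariate:
   Welch's t-test for sex, Pearson correlation for age / weight /
   height / BMI, giving a significance table over
   covariate × variable × parameter × state.
4. **Interval forecasting.** A conditional inference tree (p-value-based
   split selection with Bonferroni adjustment; defaults alpha = 0.1,
   max depth 5, min leaf 20) partitions patients by their basic
   covariates. Each terminal node forecasts a parameter as a symmetric
   quantile interval — the nominal-80% interval spans the leaf's 0.1 to
   0.9 quantiles — scored on held-out patients by

   - coverage rate = (observations inside the interval) / (total), and
   - relative interval width = interval width / (0.95 − 0.05 quantile
     span of the training responses), a unit-free width.

## Worked example

```r
library(icuprior)

cfg <- cohort_config(n_patients = 60, t_range = c(40L, 80L), seed = 2024)
g <- generate_cohort(cfg)
g$cohort
#> <icu_cohort> 60 patients, 3441 series rows, 2 variables

labels <- label_states(g$cohort$series)
fits <- fit_cohort(g$cohort, seed = 1)    # fit + align + extract
head(fits$records[, 1:5], 4)
#>   patient_id   variable state   mu_hat sigma_hat
#> 1     P00001 heart_rate     1 95.66233  9.714229
#> 2     P00001        map     1 54.67285  3.199328
#> 3     P00001 heart_rate     2 92.33220  8.585632
#> 4     P00001        map     2 85.87462  4.773615

res <- evaluate_cohort_auc(fits$fits, labels)
attr(res, "summary")[c("n", "mean", "median")]
#> multi-state patients: 56   mean AUC: 0.999   median AUC: 1.000

tab <- build_association_table(fits$records, g$cohort$profiles)
tab
#> <association_table> 40 cells, alpha = 0.01: 0 significant, 0 untestable

curve <- coverage_width_curve(fits$records, g$cohort$profiles,
                              levels = c(0.5, 0.8, 0.95), min_leaf = 10,
                              split_seed = 1)
attr(curve, "averages")
#>   level  coverage relative_width n_eval
#> 1  0.50 0.5208333      0.3782255    144
#> 2  0.80 0.6805556      0.6815861    144
#> 3  0.95 0.8611111      1.7569753    144
```

Reading the output: state 1 is the failure-aligned state — for patient
P00001 it has a low MAP mean (54.7 mmHg vs 85.9 mmHg in the safe
state), so the decoded states track the labelling rule and the
per-patient AUC is near 1 in this well-separated synthetic world. The
default generator has *no* covariate effects, so the association table
is correctly null (0 of 40 cells significant at 0.01) and each forecast
tree is a single leaf. Held-out coverage rises with the nominal level
while the relative width rises faster — the coverage/width tradeoff.
With only ~40 training patients per leaf the empirical quantile
intervals visibly undercover (0.68 at nominal 0.80 here); at the cohort
sizes the method targets, coverage concentrates at the nominal level
(see the acceptance report below).

An end-to-end run writing all artifacts (labels, params, posteriors,
AUC table + histogram, association table, one tree JSON per response,
coverage/width curve, manifest with hashes):

```r
run_pipeline(pipeline_config(simulate = cfg, out_dir = "run1"))
```

or from the shell, mirroring each stage:

```sh
Rscript inst/cli/icuprior.R pipeline --n-patients 60 --seed 2024 --out run1
Rscript inst/cli/icuprior.R tree --params run1/params.csv \
    --profiles run1/profiles.csv --response map:mu:1 --out tree.json
```

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the model and
its assumptions, every tunable parameter with its default and
rationale, what the synthetic generator does and does not emulate, and
the numerical conventions (variance floor, quantile definition,
tie-breaks).
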