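---
title: "Methods: hidden-state priors for ICU-monitored variables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hidden-state priors for ICU-monitored variables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icuprior)
```

## Overview

`icuprior` estimates, for each ICU patient, the per-state distribution
parameters of monitored vital signs, and then models those parameters as
a function of the patient's basic clinical data. The chain of models is:

1. a per-patient Gaussian hidden Markov model (HMM) giving
   $\hat\mu_{n,k,s}, \hat\sigma_{n,k,s}$ per patient $n$, monitored
   variable $k$ and latent state $s$;
2. a rule-based circulatory-failure label used to check that the decoded
   latent states mean what we think they mean (per-patient AUC);
3. association tests between the fitted parameters and the basic
   covariates;
4. a conditional inference tree that forecasts each parameter from the
   covariates as a quantile interval, scored by held-out coverage and a
   unit-free relative width.

This vignette records the modelling assumptions, every tunable that
matters, the numerical conventions, and what the synthetic generator
does and does not establish.

## The data model

Patient $n$ carries a covariate vector $B_{n,\cdot}$ = (sex, age,
weight, height, BMI) and a monitored matrix $A_{n,k,t}$,
$t = 1,\dots,T_n$, with patient-specific length $T_n$. Time is an
abstract integer index: no sampling period is assumed, and no alignment
across patients is needed because every model is fit per patient.
Missing values are handled by dropping the whole patient at ingest (a
deliberate, simple policy — no imputation), with the dropped count
reported.

## The per-patient HMM

Conditional on a hidden first-order Markov chain
$y_{n,t} \in \{1,\dots,S\}$ with initial distribution $\pi$ and
row-stochastic transition matrix $P$, emissions are Gaussian. The
default emission model treats variables as conditionally independent
given the state,
$$A_{n,k,t} \mid y_{n,t}=s \;\sim\; N(\mu_{n,k,s}, \sigma_{n,k,s}^2)
\quad \text{independently over } k,$$
with a full-covariance per-state Gaussian available via
`emission = "full"`. The independence default keeps the parameter count
at $2KS$ per patient, which matters because series are often short; the
full model is for sensitivity checks.

**Estimation.** Baum–Welch EM: the E-step computes smoothed
responsibilities with the scaled forward–backward recursions (per-step
normalisation plus a per-step log-density shift, so series of length
$10^5$ and beyond cannot underflow); the M-step uses
responsibility-weighted means and (MLE, divide-by-weight) variances and
expected transition counts. $\pi$ is initialised uniform. Emission
means are initialised from a per-variable quantile split — state $s$
starts at the mean of the $s$-th quantile band — which is deterministic;
restarts 2..R add seeded Gaussian jitter of 0.1 sd per variable, and the
restart with the highest log-likelihood wins. Decoding is by per-time
posterior argmax (ties broken toward the lower state index), not
Viterbi: the quantity of scientific interest is the per-time posterior
probability itself, which also serves as the AUC score.

Tunables and defaults: `n_states = 2` (safe vs failure-like),
`tol = 1e-6` (relative log-likelihood change), `max_iter = 200`,
`n_restarts = 3`, variance floor `1e-6 * (sample variance + 1e-12)` per
variable. The floor prevents the well-known Gaussian-EM likelihood
blow-up when a state collapses onto a near-constant segment; an
all-constant series yields a fit flagged `degenerate`. Note the printed
per-state likelihood alone would describe an independent mixture; the
package deliberately fits the full HMM — estimated transition matrix and
all — because Baum–Welch and forward–backward are only meaningful with
Markov dynamics, and state persistence is exactly what distinguishes an
episode of circulatory failure from independent noisy draws.

**State identity.** The HMM likelihood is invariant to relabelling
states, so fitted states are aligned by convention before any
cross-patient use: the state with the lower fitted mean on a reference
variable (MAP when present, else the first variable) becomes state 1,
the failure-aligned state — circulatory failure presents with low mean
arterial pressure. Exact ties keep the original order and are reported.

## The labelling rule and AUC validation

A time point is labelled `failure` iff MAP $\le 65$ mmHg (inclusive) or,
non-exclusively, vasoactive/inotropic drugs are present *and* lactate
$> 2$ mmol/l (strict). Thresholds are configurable; the boundary
conventions are pinned by tests. The label is pointwise, so labelling
commutes with row permutations.

Per patient, the posterior probability of the failure-aligned state is
scored against these labels with the Mann–Whitney AUC (ties credited
0.5). Patients whose label sequence contains a single class carry no
ranking information and are excluded — the package reports how many.
Using posteriors rather than hard decoded states preserves
threshold-free ROC semantics; this is a documented choice, not an
inference about how any particular historical analysis computed it.

## Association testing

Each fitted parameter column (variable × parameter × state) is tested
across patients against each basic covariate: Welch's unequal-variance
t-test for the binary covariate, Pearson correlation (Spearman behind a
flag) for continuous ones. Welch is used rather than the pooled-variance
t-test as the robust modern default. Raw two-sided p-values are
reported with a significance flag at `alpha = 0.01`; no multiplicity
correction is applied inside the table because the threshold is a
reporting convention, not a decision procedure. Cells with a constant
response or a degenerate group are marked `untestable` rather than
dropped, so the table shape is always the full cross-product. By
default all fitted patients contribute; `records` can be pre-filtered
to multi-state patients if desired.

## The conditional inference tree

`grow_tree()` performs binary recursive partitioning in the conditional
inference style: at each node, each predictor is tested against the
response (Welch for binary, correlation for continuous — the same
machinery as the association table), the minimum p-value is Bonferroni
multiplied by the number of testable predictors (capped at 1), and the
node stops splitting when the adjusted p exceeds `alpha`. The split
threshold maximises the absolute Welch statistic between the `≤` and
`>` children over candidate cutpoints at midpoints of adjacent distinct
values, subject to `min_leaf` on both sides; binary predictors split at
the category midpoint so routing is uniformly "≤ goes left", with
boundary values going left.

Defaults: `alpha = 0.1` and `max_depth = 5` (balancing fit against
complexity), `min_leaf = 20` — chosen so leaf quantiles at the
0.05/0.95 level rest on at least one observation per tail. Asymptotic
p-values are used rather than the exact permutation distribution of the
full conditional-inference framework; this keeps the tree dependency
free and fast, and on null data the root-split rate is still ≈ alpha
(property-tested). Ties in selection go to the first predictor in
declaration order; all choices are deterministic given the data.

Two useful consequences, both property-tested: leaves partition the
training set exactly at every depth, and lowering `alpha` can only
prune, never deepen, the tree.

## Interval forecasts and their metrics

A terminal node forecasts the response as a symmetric empirical
quantile interval: nominal level $c$ maps to quantile levels
$((1-c)/2,\; 1-(1-c)/2)$ — 80% is (0.1, 0.9), 84% is (0.08, 0.92).
Quantiles use linear interpolation between order statistics (R type 7),
stated so results are bit-reproducible.

Metrics, computed on held-out patients routed through the tree:

- **coverage rate** = (count inside the interval) / (count evaluated),
  exact rational arithmetic;
- **relative interval width** = (upper − lower) divided by the 0.95 −
  0.05 quantile span of the *training-set* response column. The
  denominator is the full training column, not the leaf: the point of
  the normalisation is comparability across variables with different
  units, which leaf-local scaling would destroy. A zero reference
  span makes the width undefined; such leaves are flagged and excluded
  from averages with a warning.

The out-of-sample protocol is a single seeded 70/30 patient-level
split (configurable). Whether historical analyses of this design
evaluated in-sample or held-out is not stated anywhere we rely on;
held-out is the defensible choice and is what all reported numbers
mean here. For the tradeoff curve, each response column gets its own
tree and the per-level metrics are averaged across responses.

With unit-variance Gaussian responses inside leaves, the expected
relative width of the nominal-80% interval is the normal-theory ratio
$(z_{0.9}-z_{0.1})/(z_{0.95}-z_{0.05}) = 2.5631/3.2897 \approx 0.779$
— the anchor used by the acceptance suite. Empirical quantile
intervals undercover slightly at small leaf sizes (order $1/n$), which
is why `min_leaf` matters and why the calibration tests use large
leaves.

## The synthetic cohort: a stated world

The generator replaces request-only real ICU data in all tests and
demos. What it emulates:

- covariates: sex ~ Bernoulli(0.5); age, weight, height ~ truncated
  normal (inverse-CDF sampling) with plausible adult ICU ranges
  (age 62 ± 15 on [18, 95]; weight 78 ± 15 kg on [40, 160]; height
  1.70 ± 0.10 m on [1.40, 2.10]); BMI is always derived as
  weight/height², never sampled, so covariates stay internally
  consistent;
- per-patient true parameters linear in covariates:
  $\mu_{n,k,s} = \beta_{0,k,s} + \sum_c \beta_{c}\,B_{n,c} +
  \varepsilon$, with $\varepsilon \sim N(0, \texttt{mu\_noise\_sd}^2)$;
  $\sigma$ effects act additively on $\log\sigma$ (multiplicatively on
  $\sigma$) so any effect size keeps SDs positive;
- a persistent two-state chain (self-transition 0.95 per state,
  uniform initial distribution) with state-dependent Gaussian
  emissions: by default state 1 has MAP 55 ± 5 vs 85 ± 5 and heart
  rate 96 ± 10 vs 87 ± 9 — well separated on MAP so the labelling
  rule tracks the hidden state (calibrated by
  `rule_state_agreement()`, ≈ 0.99 under the defaults);
- labelling channels tied to the state: lactate lognormal with median
  3 mmol/l (failure) vs 1.2 (safe), drug indicator Bernoulli 0.6 vs
  0.05 per time point — so both branches of the rule are exercised;
- series lengths uniform on `t_range` (default 50–200); patient $i$
  draws from a substream derived from the seed and $i$, so a patient's
  data is invariant to the cohort size and runs are byte-reproducible.

What it does **not** emulate: real waveform morphology, missingness
mechanisms, drug pharmacokinetics, higher-order or non-stationary
dynamics, heavy-tailed emissions. A green test on this world therefore
establishes that the estimators and metrics behave as specified under
their own assumptions — not that the assumptions hold in any real ICU.
Where no external value existed for a default (noise SDs, lactate and
drug parameters, series-length range), it was chosen once for
testability and plausibility and is not tuned against test outcomes.

## Numerical conventions and degenerate inputs

- Nominal-level → quantile-level arithmetic is rounded at 12 decimal
  digits so that, e.g., $(1-0.8)/2$ is exactly 0.1.
- Posterior rows are renormalised after the forward–backward product;
  row sums are unit to 1e-8 by construction and asserted in tests.
- EM convergence is relative: $|\ell_{i}-\ell_{i-1}| <
  \text{tol}\,(|\ell_{i-1}| + 10^{-12})$; the trace is monotone to
  1e-6 absolute (EM guarantee, asserted on every fit in the suite).
- Constant series → degenerate flagged fit; constant association cells
  → `untestable`; constant reference span → undefined relative width;
  empty leaves cannot arise (min_leaf), empty cohorts round-trip with
  valid schemas.
- All tie-breaks (posterior argmax, selection order, boundary routing,
  alignment ties) are deterministic and documented above.

## Known limitations

- Per-patient HMMs need enough time points per state; with very short
  series the fitted $\sigma$ rests on few effective observations and
  the association table inherits that noise.
- Asymptotic p-values in the tree are approximate at small node sizes;
  the seeded Monte-Carlo permutation route
  (`p_method = "permutation"`) exists as a fidelity check but is not
  the default because it is orders of magnitude slower.
- The tree forecasts one response column at a time; joint modelling of
  $(\mu, \sigma)$ or across variables is out of scope.
- Model selection over the number of states is not provided; $S$ is a
  design choice (default 2).
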