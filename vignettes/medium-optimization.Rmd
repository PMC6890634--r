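---
title: "Modeling and optimizing tissue-culture media with RBF surrogates and NSGA-II"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and optimizing tissue-culture media with RBF surrogates and NSGA-II}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediumopt)
```

`mediumopt` implements a complete surrogate-assisted optimization workflow
for plant tissue-culture media: replicate-level simulation of a factorial
experiment, Gaussian radial-basis-function (RBF) regression surrogates, a
real-coded NSGA-II, ideal-point compromise selection, and VSE/VSR
sensitivity ranking. This vignette explains the models, the tunable
parameters, the numerical choices, and what the package's tests do and do
not establish about real cultures.

## The data and what the simulator emulates

The built-in dataset (`chrysanthemum_treatments()`) is a 3⁴ full factorial
on chrysanthemum single-node explants: BAP (0, 2.22, 4.44 µM), IBA
(0, 0.25, 0.49 µM), phloroglucinol (0, 0.2, 0.4 mM) and sucrose (43.82,
87.64, 131.46 mM), with mean ± SE of proliferation rate (PR, %), shoot
number (SN), shoot length (SL, cm) and basal callus weight (BCW, g) per
treatment. Each printed mean summarizes nine repetitions. Media without
cytokinin (BAP = 0, a third of the design) produced no regeneration at
all; those 27 cells are exact zeros with zero SE.

Model fitting needs data-line-level records, so `simulate_replicates()`
re-expands each treatment into `n_rep` lines (default 9, giving the
canonical 81 × 9 = 729). Each response is drawn from a normal law centred
on the treatment mean with standard deviation 3 × SE — the printed SE of a
nine-repetition mean, multiplied by √9 to recover the per-line spread —
and truncated to its physical range (PR to [0, 100], the rest to
non-negative values). The √9 factor is tied to the experiment's repetition
count, not to the number of lines requested, so the simulated dispersion
is the same whether you draw 9 or 10 000 lines per treatment.

What the simulator does *not* emulate: the nesting of repetitions within
the experiment's five replicate vessels (a hierarchical variance
component), any correlation between the four responses within an explant,
and any non-Gaussian features (overdispersion, zero-inflation at partially
responsive media). Passing tests therefore demonstrate that the pipeline
recovers structure from data with the *printed* first and second moments,
not that it would behave identically on raw laboratory records.

A direct consequence worth knowing: the noise calibration caps the
achievable held-out R² per response at the ratio of between-treatment
variance to total variance. For SL that ceiling is ≈ 0.97 and the fitted
surrogates reach ≈ 0.965; for BCW — a small, noisy quantity with many
exact zeros — the ceiling is ≈ 0.71, so BCW surrogates plateau around
0.65–0.73 no matter how well they fit. SN is the least noisy response
relative to its spread (ceiling ≈ 0.98), so its test R² typically edges
out SL's under this noise model.

## The RBF surrogate

Each response gets its own single-output network (`rbf_fit()`). On
min–max-scaled inputs, hidden unit $b$ responds to Euclidean distance:

$$f(x, c_b) = \exp\!\left[-\left(\frac{0.8326\,\lVert x - c_b\rVert}{h}\right)^2\right],
\qquad \hat y(x) = \sum_{b=1}^{m} w_b f(x, c_b) + w_0 .$$

The constant 0.8326 ≈ √ln 2 places activation ½ exactly at distance $h$
(the *spread*), so $h$ is read directly as a kernel half-width in
scaled-input units.

**Scaling.** The four factors differ by two orders of magnitude in raw
units (0.49 µM IBA vs 131 mM sucrose), so distances are taken on the
min–max-scaled unit cube (`fit_scaler()`; exact inverse available). On
this cube the three factorial levels per factor sit at 0, ½ and 1.

**Centre selection.** Greedy forward selection: start from a bias-only
model, repeatedly promote the training input with the largest absolute
residual to a centre (skipping locations already used), and re-solve all
weights plus bias by least squares. Growth stops at `max_centers`
(default 80, just under the 81 distinct design locations), at a training
MSE of `goal_mse` (default 0, i.e. run to the centre budget) or when the
distinct candidate locations are exhausted. The re-solve uses the normal
equations with a ridge term (default 1e-8, never applied to the bias) so
near-duplicate columns can never make the fit fatal.

**Spread selection.** Candidate spreads (default grid 0.05–1.6 on the
scaled cube) are scored by K-fold cross-validation (K = 5, seeded folds
differing in size by at most one). A replicated factorial has a structural
quirk here: every held-out record shares its input location with training
records, so CV error is almost completely flat in $h$ — measured profiles
are identical to three or four significant digits for all $h \le 0.4$.
The bare argmin then lands essentially at random, and can land on wide
spreads whose activation columns are so collinear that the solved weights
reach ±10⁴ on a response bounded by 100; such networks interpolate the
design cells perfectly yet oscillate wildly *between* them (raw PR
predictions above 120 %, negative callus weights), which poisons the
optimization stage that queries exactly those intermediate points. The
default selection rule (`cv_rule = "stable_1se"`) therefore treats
numerical stability as a hard constraint and smoothness as the
tie-breaker, the classic accuracy–stability trade-off of RBF
interpolation: discard spreads whose normal-equations condition number
exceeds `1/sqrt(.Machine$double.eps)`, then, among stable spreads within
one fold-standard-error of the CV minimum, pick the widest. On the
built-in data this deterministically selects $h = 0.4$ (0.8 × the level
spacing) for all four responses. The bare minimum remains available as
`cv_rule = "min"`.

**Metrics.** `regression_metrics()` reports R², RMSE, the mean *absolute*
error (printed as `mbe`, following the absolute-difference form of the
mean-bias-error formula) and the signed mean error `signed_bias`. Both
bias readings are reported because both conventions circulate; the signed
one is what can go negative. When the observed vector is constant, R² is
undefined and reported as `NA` with a warning while the error metrics are
still returned.

## The optimizer

`nsga2()` is a from-scratch, real-coded, elitist NSGA-II. Per generation:
crowded binary tournament selection (rank, then crowding distance, then a
fair coin), two-point crossover (probability 0.7) that exchanges the
middle segment of the 4-gene vectors — values are swapped, never blended,
so box bounds are preserved by construction — and uniform mutation
(probability 0.05 per gene; a per-individual reading is available via
`mutation_scope`) that redraws a gene uniformly within its bounds.
Parents and offspring are pooled (µ + λ), the pool is refilled front by
front, and the last partial front is truncated by descending crowding
distance. The run length is a fixed generation budget (default 1000) with
no convergence-based early stop; duplicate decision vectors are collapsed
(tolerance 1e-9) in the returned front. The dominance work is vectorized
(pairwise comparison matrices plus dominator-count peeling), which keeps a
200-individual, 1000-generation, 4-objective run around half a minute.

The medium problem itself (`optimize_medium()`) minimizes
$(-\widehat{PR}, -\widehat{SN}, -\widehat{SL}, +\widehat{BCW})$ over the
box spanned by the observed factor ranges — RBF surrogates interpolate
well but extrapolate poorly, so leaving the experimental region is never
allowed. Objectives are evaluated on *raw* surrogate outputs to keep the
landscape smooth; only reported predictions are clipped to physical
ranges.

## Compromise selection and its scaling

The recommended recipe is the front member minimizing

$$d = \sqrt{(PR-m)^2 + (SN-n)^2 + (SL-o)^2 + (BCW-p)^2}$$

after each objective is min–max scaled, where $(m, n, o, p)$ is the ideal
point: the maxima of PR, SN, SL and the minimum of BCW in the observed
data (for the built-in experiment: 100 %, 12.76 shoots, 5.89 cm, 0 g —
taken from the treatment-level table, not from simulated replicates whose
noisy maxima would inflate the target). Two design choices deserve
explanation:

* **Scaling set.** By default each axis is scaled by the observed data
  range of its response, which puts the ideal at the corner (1, 1, 1, 0)
  and makes distances comparable across runs. Scaling by the front's own
  extremes (available as `scale_from = "front"`) seems natural but
  distorts precisely the axes that matter: the non-dominated set
  concentrates at low BCW, so its BCW span collapses and a biologically
  negligible 0.05 g difference can dominate the distance. Surrogate
  predictions that overshoot an observed extreme scale slightly outside
  [0, 1]; the distance stays well-defined and the overshoot is penalized
  symmetrically, as the squared-difference form dictates.
* **Ties.** Exact ties (possible when two members coincide on the scaled
  axes) break toward smaller predicted BCW, then lexicographically by the
  decision vector, so selection is deterministic.

`run_pipeline()` derives all stage seeds from one master seed
(replicates: seed, split: +1, CV folds: +2, optimizer: +3), writes an
artifact bundle (CSV front and metrics, JSON recipe and provenance) when
asked, and is the single entry point the command-line wrapper and the
reproduction script both call.

## Sensitivity analysis

`vse()` implements "what if this input were not available" as
hold-at-mean substitution: the factor column is replaced by its dataset
mean everywhere and the *same fitted model* is re-scored against the
observed responses (RMSE by default, MSE by option). The ratio
VSR = VSE / full-model error is 1 for a factor the model ignores and
grows with the factor's influence; factors are ranked per response by
descending VSR with ties broken in factor order. Substitution rather than
retraining keeps the comparison within one model class — a retrained
three-input network is a different model and its error is not comparable
to "the error of the model with all variables available"; a refit hook is
nevertheless exposed via the `refit` argument for users who want the
other convention. On the built-in experiment BAP ranks first for PR, SN
and SL in every tested seed, matching the biological reading that
cytokinin supply is the binding constraint on shoot regeneration.

## Problem sizes used by the test suite

The suite replicates the study at its stated sizes — 9 lines per
treatment, 547/182 split, K = 5, NSGA-II at 200 × 1000 — across ten seeds
for the end-to-end checks, sharing each seed's fitted models and optimizer
run between check families; one full replication takes roughly a minute on
a single core. Unit and property tests run on deliberately small synthetic
instances (populations ≤ 100, a few hundred records) chosen so each
property is sharp: exhaustive-oracle equivalence for the sorting, analytic
fronts for the optimizer, hand arithmetic for kernels, metrics and the
selection rule.

## Known limitations

* The replicate simulator reproduces printed moments only (see above);
  hierarchical replicate structure and response correlations are out of
  scope, as is any ANOVA-style treatment comparison.
* With a centre available at essentially every design cell, held-out
  accuracy cannot identify the spread; the stability-based tie-break is a
  principled default, but the surrogate's behaviour *between* cells —
  exactly what the optimizer exploits — remains under-determined by this
  kind of replicated factorial data. Recommendations at intermediate
  compositions inherit that uncertainty, and the package deliberately
  reports the whole Pareto front, not just the single compromise recipe.
* BCW is modeled on the edge of its noise floor; its surrogate is the
  weakest of the four and its predicted values near zero should be read
  as "little callus expected", not as gram-level estimates.
* The optimizer handles box constraints only; no constraint functions,
  preference weights or uncertainty propagation from surrogate error to
  the recommended recipe.
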