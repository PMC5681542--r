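---
title: "Modelling craniofacial change with linear-Gaussian Bayesian networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling craniofacial change with linear-Gaussian Bayesian networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephnet)
```

## The model

`cephnet` models the growth of Class III malocclusion patients through the
*differences* of six cephalometric features between two visits, rather
than their raw values. With `dT = age_t2 - age_t1` and
`dY = Y(T2) - Y(T1)`, each difference is assumed to follow a linear
regression on a subset of the other differences plus the elapsed time and
the binary treatment and prognosis flags:

$$\Delta Y = \mu + \beta_1 \Delta T + \beta_2 \Delta X_1 + \dots +
  \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2).$$

Dividing through by $\Delta T$ shows this is a discrete rate-of-change
model: each feature's rate depends on other rates but not on time itself,
so raw trajectories are implicitly linear in time. With only two visits
per patient nothing richer than a linear trend is identifiable, which is
why the difference parameterisation is used directly, with `dT` as an
ordinary node (an equivalent rate form is obtained by dividing through;
it is not implemented separately).

Which regressors enter which equation is exactly a directed acyclic graph:
the joint density factorises as
$p(X) = \prod_i p(X_i \mid \mathrm{Pa}(X_i))$, a linear-Gaussian Bayesian
network over the nine variables
`dT, Treatment, Growth, dANB, dIMPA, dPPPM, dCoA, dGoPg, dCoGo`.
Assumptions: independent, homoscedastic, mean-zero Gaussian errors per
equation; linearity of every local relationship; acyclicity.

### Binary nodes are Gaussian on 0/1 codes

`Treatment` (1 = treated) and `Growth` (1 = good grower) are modelled as
Gaussian variables on their 0/1 coding. A conditional-Gaussian scheme that
forbids continuous parents of discrete nodes could not express the forced
`dT -> Growth` dependence, and the unified likelihood keeps scoring,
sampling and exact conditioning simple. Query semantics recover the binary
meaning: forward samples of binary nodes are thresholded at 0.5 before
predicates are evaluated, and prognosis classification thresholds the
predicted conditional mean at 0.5. This is a deliberate mismatch with the
truly binary data-generating process and is stress-tested by the synthetic
studies.

## Structure learning

Structures are scored by the Bayesian Information Criterion on the
log-likelihood scale, decomposed per node:
$\hat\ell - \tfrac{k}{2}\log n$ with $k = |\mathrm{Pa}| + 2$ (intercept,
slopes, variance) and the residual variance estimated with the
maximum-likelihood $n$ denominator. `hill_climb()` starts from the
whitelist-only graph and greedily applies the best single arc addition,
deletion or reversal until no move improves the score by more than 1e-10.
Moves are evaluated in lexicographic (parent, child, move-type) order, so
results are deterministic given the data and column order; score ties are
broken by that order. Restarts and tabu lists are out of scope by design.

Clinical prior knowledge enters as constraints
(`malocclusion_constraints()`): nothing may point into `dT` or
`Treatment` (patients are treated or not for the whole observation
window; elapsed time depends on nothing measured); craniofacial features
may not point into `Growth` (the prognosis summarises the overall
evolution, giving per-prognosis regimes for the features); and
`dANB -> dIMPA <- dPPPM` (incisor compensation) plus `dT -> Growth` (the
prognosis may change with the window length) are forced.

Parameters are then estimated by ordinary least squares per local model
(`fit_ols()`), with residual standard deviations floored at
`sd_floor = 1e-6` so degenerate (interpolating) fits cannot produce
zero-variance nodes in sampling or log-likelihoods.

### Missing prognosis values

A cohort may record the prognosis for untreated patients only. Parameter
estimation drops incomplete rows *per local model*, so only models whose
scope includes `Growth` lose rows. Structure search, however, scores on
complete cases only: BIC move deltas compare log-likelihoods, which scale
as $O(n)$, so letting different parent sets of the same node use different
row counts makes "drop some rows" look like a score improvement regardless
of fit — in early experiments this systematically attracted arcs to
`Growth` and masked genuine `Treatment` effects. Note that with the
prognosis blanked for all treated patients, complete cases are all
untreated and treatment effects are inherently unidentifiable from the
search's viewpoint; this is a property of that missingness design, not of
the implementation.

## Model averaging

To quantify structure uncertainty, `bootstrap_strengths()` redraws the
rows with replacement `R = 200` times (resample size = original n), learns
a structure from each resample, and tabulates per undirected pair the
*arc strength* (fraction of replicates containing the pair) and the
*direction strength* (fraction of those orienting it the majority way;
exact ties are oriented from the lower-ordered node).

`estimate_threshold()` picks the inclusion threshold from the data: the
noiseless strength distribution is a step function (a fraction of pairs at
0, the rest at 1), so the estimator chooses the step fraction minimising
the L1 distance to the empirical CDF of the observed strengths (ties
toward the smaller fraction) and places the cut at the midpoint between
the two sides. Perfectly separated strengths {0,...,1,...} therefore give
0.5; an uninformative all-equal table returns 0.5 with a warning.

`consensus_network()` keeps pairs with strength `>=` the threshold
(inclusive, so a reported cut of 0.85 retains arcs of exactly 0.85),
oriented by majority. Majority directions from different replicates can
conflict and close a directed cycle; arcs on a cycle are then dropped
weakest-first (strength, then direction, then lexicographic), each drop
reported loudly via `message()`. Fixed 0.5 and 0.85 views are conventional
sparser summaries alongside the estimated threshold.

## Inference

`logic_sample()` forward-samples the network in topological order.
`conditional_query()` estimates $P(\text{event} \mid \text{evidence})$ by
rejection: among `n` draws (default $10^4$; $10^4$–$10^6$ is the customary
range), those matching the evidence are kept and the event fraction is
returned with the binomial standard error $\sqrt{\hat p(1-\hat p)/n_E}$.
Evidence on continuous nodes must be interval-valued — a point has
probability zero under forward sampling — and "approximately x" defaults
to the interval `near(x, halfwidth = 0.1)` in the variable's units. A
query for a node name instead of a predicate returns the posterior mean
over evidence-matching draws. Queries that match no draw return an
explicit no-match result rather than a number.

`exact_conditional()` resolves the recursive system into its implied joint
normal, $X = (I - B')^{-1}(a + \varepsilon)$, and conditions exactly on
point evidence; it is the closed-form oracle the sampler is tested
against and the deterministic predictor used in cross-validation.
`exact_query()` extends it to one-node interval evidence by Gaussian
quadrature. Near-singular implied covariances (floored residual sds) are
handled by an eigenvalue pseudo-inverse, which gives the correct
conditional-mean limit for deterministic relationships.

Interventions follow the do-operator: `intervene_fix(fit, node, value)`
removes all arcs into the node and replaces its local model by the fixed
value (sd at the floor), leaving every other local model untouched. This
implements "fix $\Delta ANB \approx 0$" readings of treatment hypotheses
as hard graph surgery; interval conditioning on the same value is also
available for the soft reading, since which of the two a published
phrasing means can be ambiguous.

## Cross-validation

`cross_validate()` splits patients into `k = 10` folds by a seeded uniform
shuffle (sizes differ by at most one; stratification by `Treatment` is
available but off by default), learns structure and parameters on each
training set, and predicts every variable of every test row from all its
other variables via the exact conditional mean. Pooled
(observed, predicted) pairs give the *predictive correlation* per
continuous variable — computed by the same `pearson_r()` used everywhere —
and the prognosis *classification error* after thresholding at 0.5
(identically `1 - accuracy`). Rows with a missing prognosis are predicted
without conditioning on `Growth` and excluded from the `Growth` metric
only. Using the exact conditional mean instead of sampling-based
prediction is a deliberate substitution: it is deterministic, faster, and
equal in expectation.

Two properties of this metric are worth knowing. First, for a variable
with no predictive relationships, the pooled leave-fold-out prediction is
anti-correlated with the held-out fold by construction (the prediction is
minus the fold's own contribution to the training mean), giving an
expected predictive correlation of $-1/\sqrt{n_f}$ — about $-0.18$ for
fold size 30 — rather than 0. Second, near-deterministic generating
relations push predictive correlations to 1, so values from low-noise
synthetic cohorts say nothing about clinical performance.

## The synthetic-data generator

The study's clinical data are not redistributable, so the generator
emulates the design: 143 patients, 66/143 expected treated; first-visit
age normal with mean 8, sd 1 year, truncated to 6–19; between-visit gap
uniform on 4–9 years (`T2 > T1` is enforced; published age summaries are
treated as descriptive). First-visit baselines are order-of-magnitude
plausible cephalometric values (`ANB` near $-1^\circ$ for a Class III
cohort, `IMPA` $87^\circ$, `PPPM` $28^\circ$, `CoA` 85 mm, `GoPg` 72 mm,
`CoGo` 55 mm) and are explicitly arbitrary — only the differences carry
signal.

`make_truth()` draws a tier-respecting random DAG over the nine variables
(whitelist arcs always present), with arc coefficients of magnitude 1–5,
random signs, and feature residual sds proportional to `noise_scale`.
Treatment affects features only through `regime_effects` (default: +2 on
`dCoA` and `dANB`, the maxillary length targeted by expansion and the
imbalance the facemask aims to stabilise); the prognosis follows a
logistic rule in `dT` and `Treatment` with a modest treatment effect
(0.6 on the log-odds scale), chosen so that prognosis differences are
realistic rather than trivially learnable at n = 143. A linear-threshold
`Growth` link is available for clean recovery studies in which the
generative law is exactly linear-Gaussian given the realised binary
parents. The expected consensus density under these defaults (~17 arcs
over 9 nodes) matches the density of published craniofacial consensus
networks.

What passing the synthetic studies does *not* show: robustness to
measurement error in landmarking, non-Gaussian heavy-tailed variation,
informative missingness, more-than-two-visit dynamics, or nonlinear
feature coupling. The generator is linear-Gaussian by construction, the
same family the learner assumes (apart from the binary links), so these
studies validate the machinery, not the clinical model class.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` run, at sizes chosen to give
stable statistics in minutes on one core: exhaustive-search comparisons on
20 four-node datasets of n = 500 (543 candidate DAGs each); OLS recovery
on 10 truths at n = 10^4 judged against theoretical standard errors;
20 rejection-sampling queries at n = 10^5 against the exact oracle;
mediator-intervention contrasts at n = 2×10^4 draws; bootstrap consensus
recovery on 20 cohorts of n = 1000 at R = 200; cross-validation checks at
n = 300; and exact round-trip identities on the 143-patient design.

## Known limitations

* **Greedy search finds local optima.** On dense, strong-signal (near
  deterministic) 9-node systems, single-move hill-climbing can terminate
  at genuine local optima scoring far below the generating structure, and
  bootstrap averaging then reproduces the same trap arcs with high
  strength. Measured on random 4-node instances, the search attains the
  exhaustive-enumeration optimum in roughly 60–85% of runs depending on
  density and effect size; skeleton recovery of dense 17-arc truths
  within SHD ≤ 1 is likewise unreliable, while ~11-arc truths recover
  well. Conclusions about individual weak arcs should lean on the
  strength table, not the point-estimate consensus.
* **Collinear parents inflate coefficient uncertainty.** With chained
  effects of magnitude up to 5, a parent's partial sd given a co-parent
  can shrink to $\sigma/|\beta|$, so coefficient standard errors reach
  $|\beta|/\sqrt{n}$ regardless of the noise scale; recovery should be
  judged against theoretical standard errors, not a flat tolerance.
* **Two visits only.** The linear difference model is forced by the
  design; with more visits the linearity assumption becomes testable and
  would likely need relaxing.
* **All-Gaussian binary handling** biases prognosis probabilities toward
  the linear-probability approximation when logistic effects are strong.
* The atlas-adjustment path interpolates linearly between tabulated ages
  and refuses to extrapolate; users must supply reference tables covering
  their cohort's age range.
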