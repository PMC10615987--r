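---
title: "Classification accuracy in cognitive diagnosis models and the multiple-imputation correction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification accuracy in cognitive diagnosis models and the multiple-imputation correction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The models

A cognitive diagnosis model (CDM) is a constrained latent class model. Each
respondent occupies one of the $L = 2^K$ binary attribute profiles
$\boldsymbol\alpha_l$; an item $j$ interacts with a profile only through the
attributes its Q-matrix row declares ($K^*_j$ of them), i.e. through the
*reduced* profile $\boldsymbol\alpha^*_{lj}$. `cdmi` implements two response
processes for dichotomous items:

* **DINA** (conjunctive): success probability $1 - s_j$ when all required
  attributes are mastered, $g_j$ otherwise — two parameters per item
  regardless of $K^*_j$.
* **G-DINA** (saturated, identity link): a free success probability for each
  of the $2^{K^*_j}$ reduced profiles. We store those class probabilities
  directly rather than the equivalent intercept/main-effect/interaction
  coefficients; the two parameterizations are a linear bijection, and the
  M-step is closed-form in the class probabilities. DINA is exactly nested in
  this representation (`dinaToGdina()`), which the tests exploit.

Throughout the package the profile space is ordered by binary counting with
attribute 1 as the most significant bit (`attributePatterns()`); the order is
arbitrary but must be fixed, because posteriors, latent distributions and
item probability tables index it silently.

Assumptions: binary attributes, dichotomous responses, local independence of
items given the profile, a correctly specified Q-matrix, and one population
(no covariates). MAP/MLE classifiers, polytomous data, other link functions,
and Q-matrix validation are out of scope.

## Estimation

Parameters $(\boldsymbol\delta, \boldsymbol\pi)$ — item success probabilities
and the latent profile distribution — are estimated by marginal maximum
likelihood with EM (`fitCDM()`, inner loop in C++):

* **E-step**: posteriors $P(\boldsymbol\alpha_l \mid \mathbf{x}_i) \propto
  lik(\mathbf{x}_i \mid \boldsymbol\alpha_l, \boldsymbol\delta)\,\pi_l$,
  computed in the log domain with a per-person log-sum-exp shift.
* **M-step**: each latent response group's probability is the expected
  proportion correct among persons expected in that group; $\boldsymbol\pi$
  is updated to the mean posterior (empirical Bayes).

Numerical choices, all deliberate and all exercised by tests:

* **Starting values** are deterministic: DINA $g_j = s_j = 0.2$; G-DINA class
  probabilities linearly spaced $0.2 \to 0.8$ over the reduced classes in
  canonical order; $\boldsymbol\pi$ uniform. Reproducibility matters more
  here than clever initialization, and the likelihood surface in these small
  latent spaces rarely rewards restarts.
* **Stopping rule**: largest absolute change in any item probability or
  $\pi_l$ below $10^{-4}$, or log-likelihood change below $10^{-7}$; at most
  1000 iterations (all exposed as arguments).
* **Bounds**: estimated success probabilities are clamped to
  $[10^{-4}, 1 - 10^{-4}]$. Because the constrained M-step is still the
  constrained maximizer, the log-likelihood trajectory remains monotone
  (asserted to $10^{-8}$ on every fitted dataset). Likelihood evaluation
  additionally clamps probabilities to $[10^{-10}, 1-10^{-10}]$ so boundary
  estimates cannot produce NaNs; within the EM the estimation bounds make
  this second clamp inert.
* **Degenerate inputs**: latent groups with (numerically) zero expected mass
  keep the previous iterate's value; constant response columns drive that
  item's parameters to the bounds and the fit completes. A posterior row
  whose likelihood-prior products all underflow falls back to the prior with
  a warning — reachable only with degenerate priors, since the clamps keep
  likelihoods positive.
* **No monotonicity constraint during estimation.** The generator enforces
  monotone item parameters, but the estimator does not: imposing it would
  change the estimator whose behaviour under sparse data (boundary estimates
  and all) is exactly what the reliability indices react to.

EAP classification thresholds each attribute's marginal posterior mastery
probability at 0.5; a value exactly at the threshold classifies as mastery.
The tie rule is arbitrary but must be fixed; with continuous posteriors it
has probability zero of mattering.

## The accuracy indices and their correction

`reliabilityEM()` computes
$\tau = \frac 1N \sum_i P(\hat{\boldsymbol\alpha}_i \mid \mathbf{x}_i,
\boldsymbol\delta, \boldsymbol\pi)$ and
$\tau_k = \frac 1N \sum_i [\hat\alpha_{ik} P_{ik} +
(1-\hat\alpha_{ik})(1-P_{ik})]$, where $P_{ik}$ is the marginal posterior
mastery probability. Two interface decisions:

* $\tau$ evaluates the posterior at the profile *assembled from the
  attribute-wise EAP decisions*, which can differ from the modal profile.
* $\tau_k$ is written with $P_{ik}$ = probability of *mastery*; the
  "probability of the estimated category" phrasing found in the literature
  is notationally ambiguous for $\hat\alpha_{ik}=0$, and under the formula
  above both readings coincide. Each summand is $\max(P_{ik}, 1-P_{ik})
  \ge 0.5$, so $\tau_k \ge 0.5$ under EAP at 0.5 — a property test.

Both indices inherit the sin of their posteriors: $\hat{\boldsymbol\delta}$
and $\hat{\boldsymbol\pi}$ are treated as known, the posteriors are too
peaked in finite samples, and the indices overestimate the true accuracy.
`reliabilityMI()` corrects this by integrating the parameters out:

1. resample persons with replacement and refit (`buildEnsemble()`), keeping
   $(\hat{\boldsymbol\delta}_r, \hat{\boldsymbol\pi}_r)$ **jointly** from
   each converged refit — independent recombination would destroy their
   sampling correlation;
2. average the per-draw posteriors (`miPosterior()`), which stays row
   normalized;
3. recompute $\tau$, $\tau_k$ with the averaged posteriors while **holding
   the classifications fixed** at the original EAP estimates — the
   correction re-evaluates the certainty of the original classifications,
   not a new classifier.

The bootstrap is nonparametric because small-sample fits produce boundary
estimates that make information-matrix covariance estimates unreliable.
Refits use the same deterministic starting values as the original fit; warm
starting would shrink the sampling distribution the ensemble is supposed to
capture. Nonconverged refits are discarded and redrawn, capped at $5R$
attempts, after which estimation aborts with a diagnostic. The default is
$R = 500$ (conservative); $R = 100$ is a documented fast mode, and the
stability study below is how we quantify what that costs. When every draw
equals the original estimates the MI indices collapse to the EM indices to
machine precision — an exact identity asserted in the tests.

## What the generators emulate

The simulation harness reproduces a standard Monte Carlo design for
reliability studies with $K = 5$ attributes:

* **Attribute structures.** `simAttributesUniform()` draws attributes as
  independent Bernoulli(0.5) — equivalently uniform over the 32 profiles
  (these coincide only at prevalence 0.5, which is why "uniform" is
  unambiguous here). `simAttributesHigherOrder()` drives all attributes from
  one standard normal trait through a 2PL link with $a_k = 1.5$, $b_k = 0$:
  prevalence 0.5 per attribute and pairwise attribute correlations near 0.3.
* **Item quality.** $IQ = 1 - P(\mathbf{0}) - P(\mathbf{1})$ with
  $P(\mathbf{0}) = P(\mathbf{1}) = (1-IQ)/2$, i.e. endpoint probabilities
  (0.3, 0.7), (0.2, 0.8), (0.1, 0.9) for $IQ$ = 0.4, 0.6, 0.8. DINA items
  are fully determined by the endpoints. G-DINA interior class probabilities
  are drawn uniformly on $(P(\mathbf{0}), 1-P(\mathbf{1}))$ and accepted
  only if strictly increasing along the componentwise dominance order of the
  reduced profiles (e.g. $P(1,1) > P(1,0) > P(0,0)$); for three-attribute
  items the constraint is applied over the full dominance partial order, the
  natural generalization of the two-attribute chain. Rejection sampling
  keeps the accepted draws exactly uniform on the monotone region. With
  ties having measure zero, strict versus weak monotonicity is immaterial.
* **Q-matrices.** `simQmatrix(30)` is a balanced 30-item design (ten items
  each of one, two and three attributes); `simQmatrix(15)` is its balanced
  half (five of each, every attribute required six times). `ecpeQmatrix()`
  ships the 28-item, 3-attribute expert Q-matrix of the ECPE grammar test
  for use with that public dataset (the responses themselves are not
  bundled).

`runCondition()` chains generation, fitting, classification, the EM and MI
indices, and the true-accuracy benchmarks PCV/PCA computed against the known
generating profiles, with per-replication child seeds spawned from one
master seed. RMSE and mean absolute error are computed against the
*per-condition mean* PCV/PCA — the benchmark is the expected true accuracy
of the condition, not each replication's realization. `stabilityStudy()`
repeats the MI estimate on one fixed dataset with fresh bootstrap seeds to
report its Monte Carlo SD per candidate $R$; `subsampleStudy()` transplants
the design onto a real dataset by subsampling without replacement and using
full-sample-parameter posteriors as the benchmark.

What the generators do **not** emulate — and what passing tests therefore do
not establish about real data: misspecified Q-matrices or response models,
attribute structures other than the two above, unbalanced attribute
prevalences, polytomous data, and respondent-level dependence (clustering).
The conclusions the test suite supports are about estimator behaviour under
a correctly specified model.

## Problem sizes and tolerances in the test suite

The replicated-design checks run at 20–30 replications with $R = 100$
bootstrap draws and a ±0.05 tolerance on condition means — the Monte Carlo
error of a 25-replication mean in these cells. Oracle agreement
(enumeration Bayes rule, brute-force likelihood products) is asserted at
$10^{-12}$ on $K \le 4$ instances; EM fixed-point and recovery checks use
single large samples ($N$ = 5000–20000) where binomial noise is ~0.01 per
group. The stability and shrink properties use the worst-case cell
(G-DINA, $N = 100$, $IQ = 0.4$) and the best-case one (DINA, $IQ = 0.8$)
respectively. `scripts/acceptance.R` re-derives the two headline quantities
(the G-DINA $J=30$ low-quality $\tau^{EM}$ mean and the MI stability SD)
from a single command-line seed.

## Known limitations

* $2^K$ scaling: everything enumerates the full profile space; fine for
  $K \lesssim 12$, not for large-K screening batteries.
* The MI correction inherits bootstrap bias: with very small N, boundary
  estimates inside the refits can leave the corrected index slightly
  optimistic when the true accuracy is very low.
* EAP only; no standard errors for item parameters (by design — the
  bootstrap ensemble is the uncertainty representation).
* The ECPE illustration requires obtaining the response data separately;
  only the Q-matrix ships with the package.
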