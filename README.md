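# cdmi — cognitive diagnosis models with multiple-imputation reliability

Cognitive diagnosis models (CDMs) classify respondents on K binary latent
attributes (mastery / non-mastery) from structured test data, using a
Q-matrix that declares which attributes each item requires. `cdmi` is for
psychometricians and applied researchers who fit these models in small
educational or clinical samples and need an honest answer to the question
*"how accurate are these classifications?"*

The package provides:

* **Model fitting** — marginal maximum likelihood (EM over the 2^K latent
  profiles) for the conjunctive **DINA** model
  (P(X<sub>j</sub>=1|α) = 1−s<sub>j</sub> if α masters all required
  attributes, g<sub>j</sub> otherwise) and the saturated **G-DINA** model
  (one success probability per reduced attribute profile of each item),
  with the EM inner loop in C++.
* **Classification** — posterior distributions over all 2^K profiles,
  marginal mastery probabilities, and EAP classification at threshold 0.5.
* **Reliability** — the classification-accuracy indices
  τ = (1/N) Σ<sub>i</sub> P(α̂<sub>i</sub> | x<sub>i</sub>, δ, π) (profile
  level) and τ<sub>k</sub> = (1/N) Σ<sub>i</sub> [α̂<sub>ik</sub>P<sub>ik</sub> +
  (1−α̂<sub>ik</sub>)(1−P<sub>ik</sub>)] (attribute level), estimators of the
  true proportions of correct profile (PCV) and attribute (PCA)
  classification.
* **The MI correction** — the point-estimate ("EM") versions of τ and
  τ<sub>k</sub> treat the estimated item parameters δ̂ and latent
  distribution π̂ as known, so their posteriors are too peaked and the
  indices are inflated — badly so in small samples. The multiple-imputation
  estimator integrates the parameters out,
  P(α<sub>l</sub>|x<sub>i</sub>) ≈ (1/R) Σ<sub>r</sub>
  P(α<sub>l</sub>|x<sub>i</sub>, δ̂<sub>r</sub>, π̂<sub>r</sub>),
  with the R draws (δ̂<sub>r</sub>, π̂<sub>r</sub>) taken jointly from
  nonparametric-bootstrap refits; classifications stay fixed at the
  original estimates.
* **A simulation harness** — uniform and higher-order (2PL) attribute
  generators, monotone item-parameter generators indexed by item quality
  IQ = 1 − P(**0**) − P(**1**), built-in K=5 Q-matrices (J = 15, 30) and the
  ECPE grammar Q-matrix, a condition runner, a bootstrap-count stability
  study and a subsampling study for real datasets.

## Worked example

Small sample (N = 100), low item quality (IQ = 0.4), saturated model — the
conditions where naive reliability estimation is most misleading:

```r
library(cdmi)
set.seed(2024)
Q     <- simQmatrix(15)                       # 15 items, 5 attributes
alpha <- simAttributesUniform(100, 5)         # true profiles
pars  <- simItemParams("GDINA", Q, IQ = 0.4)  # monotone saturated items
X     <- simResponses(alpha, pars, Q)

fit <- fitCDM(X, Q, model = "GDINA")
reliabilityEM(fit)
reliabilityMI(fit, X, R = 100, seed = 1)
trueAccuracy(alpha, fit$alpha)$pcv
```

Output:

```
Classification accuracy (EM posteriors)
  tau   = 0.8344
  tau_k = 0.9375 0.9498 0.9703 0.9485 0.9359
Classification accuracy (MI posteriors)
  tau   = 0.2432
  tau_k = 0.7001 0.8016 0.7087 0.6851 0.7050
[1] 0.12
```

The point-estimate index claims 83% of profiles are correctly classified;
the true proportion (known here because the data are simulated) is 12%.
The MI-corrected index, computed from the same fit plus 100 bootstrap
refits, reports 24% — imperfect, but honest enough to stop a practitioner
from trusting these classifications. With large samples and good items the
two indices agree (see the vignette).

A thin command-line interface over the same functions is installed at
`inst/cli/cdmi.R` (subcommands `fit`, `reliability`, `mi`, `simulate`,
`subsample`, `fixtures`; CSV in, JSON/CSV out).

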