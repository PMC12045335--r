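---
title: "Measuring symptom-perception accuracy with actual category probabilities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring symptom-perception accuracy with actual category probabilities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acpscore)
```

## The problem

People differ widely in how accurately their self-reported symptoms track
objective physiology: spirometric lung function correlates only weakly with
reported breathlessness, and psychosocial characteristics — negative
affect, health anxiety, worry about disease — systematically shift symptom
reports away from what physiology alone would predict. `acpscore`
implements a per-person *symptom-perception accuracy* score that can be
computed from variables routinely collected in large population cohorts:
an ordinal dyspnea item (1 "not at all" to 5 "extremely"), FEV~1~%pred
from spirometry, and body weight.

The score is the **actual category probability (ACP)**: fit a multinomial
logistic model

$$\log \frac{P(Y_i = k)}{P(Y_i = r)} = \mathbf{x}_i^\top \beta_k,
\qquad k \ne r,$$

with $Y$ the 5-level dyspnea item and $\mathbf{x}$ = (intercept,
FEV~1~%pred, weight), and define
$\mathrm{ACP}_i = \widehat P(Y_i = y_i \mid \mathbf{x}_i)$ — the fitted
probability of the participant's *observed* report. A high ACP means
physiology classifies the person's report accurately; a low ACP flags a
report that diverges from its physiological prediction. The ACP is
dichotomized at its stratum-specific median, and the high/low flag is then
related to psychosocial compound scores by logistic regression.

Because the cohort data the measure was designed for are access-restricted,
the package ships a calibrated synthetic-cohort generator; every stage of
the pipeline is exercised and tested against it.

## Model engines and numerical choices

All four model families are fitted by full Newton–Raphson on the exact
log-likelihood, with step-halving, convergence declared when the
log-likelihood changes by less than $10^{-8}$, a cap of 100 iterations, and
a $10^{-8}$ ridge on the information matrix. Covariances are inverses of
the observed information. The test suite verifies each fitter against a
generic quasi-Newton optimizer run on an independently written
log-likelihood (to $10^{-6}$ relative) and against `nnet::multinom`,
`MASS::polr` and `glm` where applicable.

* **Multinomial**: baseline-category logit. The reference category is the
  lowest symptom level ("not at all"), the natural baseline that matches
  the absent/present dichotomization of the item ($\ge 2$ = present). The
  ACP itself is invariant to this choice (tested).
* **Ordinal**: cumulative-logit proportional odds with the convention
  $\operatorname{logit} P(Y \le k) = \theta_k - \mathbf{x}^\top\beta$, so a
  positive slope shifts mass toward higher categories. Thresholds are kept
  strictly increasing by halving any Newton step that would violate
  monotonicity. Starting values are the logits of the empirical cumulative
  proportions.
* **Binary logistic**: Wald standard errors, odds ratios and 95% CIs.
  Separation is flagged when any coefficient exceeds 15 in absolute value
  at convergence, and the error names the offending predictor.
* **Linear**: QR least squares, with the Gaussian ML log-likelihood
  attached so linear models join the same nested-model bookkeeping.

**Missing data** are removed listwise per model, with the dropped count
recorded on the fit.

### The parallel-lines check

The proportional-odds model is attractive but restrictive: it forces one
shared slope across all cumulative splits of the ordinal outcome. The
package reports the conventional likelihood-ratio comparison

$$X^2 = 2(\ell_{\text{multinomial}} - \ell_{\text{ordinal}}),
\qquad df = p_{\text{slope}} \times (K - 2),$$

and a failed check is the recorded justification for reporting ACPs from
the multinomial model. Two caveats are documented deliberately:

1. The multinomial relaxation is *not strictly nested* above the
   cumulative-logit model — the proportional-odds probability surface is
   not linear on the baseline-logit scale — so the statistic can come out
   slightly negative when the proportional-odds model fits well. This is
   not evidence against parallel lines; the statistic is clamped to zero
   (p = 1) with a warning. Under data generated from a proportional-odds
   model the test stays conservative (verified by simulation), and under a
   built-in threshold-varying effect it rejects reliably.
2. With 2 predictors and a 5-level outcome the conventional degrees of
   freedom are $2 \times 3 = 6$. Published applications sometimes print
   other df for this check depending on the software's general model; the
   package always uses the formula above.

### Pseudo-R²

Cox & Snell, Nagelkerke and McFadden are all computed;
**Nagelkerke** is the headline value wherever a single "pseudo R²" is
reported, being the conventional normalized choice. All three are emitted
so either reading of a published table can be reproduced.

## The ACP measure

* **Stratification**: the multinomial ACP model is fitted separately for
  the control and asthma/COPD populations by default; a
  `stratify = "group-sex"` switch fits each group × sex cell separately.
  Both schemes are exposed because either may be wanted for comparison
  with published work; sex always enters the association models as a
  covariate in the pooled scheme.
* **Median split**: within each stratum against that stratum's own median.
  Ties go to the *low* class (`high_flag = acp > median`), keeping the
  "accurately classified" class conservative; the rule is recorded in the
  output.
* **Quantiles** use linear interpolation between order statistics
  (`quantile(type = 7)`), stated because IQR bounds are reported to two
  decimals.
* The summary fraction counts ACP values **at or below 0.5** — the share
  of participants the physiological model would misclassify more often
  than not.
* **Spearman correlation** is computed as the Pearson correlation of
  mid-ranks with the two-sided t approximation on $n-2$ df.

## Psychometrics

The psychosocial battery (neuroticism facet sums, negative-affect items,
binary health-anxiety items, two stressor sums) is reduced by PCA on the
item correlation matrix with **direct-oblimin rotation** ($\gamma = 0$,
i.e. direct quartimin — the common default, exposed in the API), because
psychosocial constructs are expected to correlate. The rotation is an
oblique gradient-projection minimizer of the oblimin criterion; the tests
assert that rotation never worsens the criterion and that
$\text{structure} = \text{pattern} \times \Phi$.

* **Retention**: Kaiser criterion (eigenvalue > 1) by default with a
  `fixed_k` override; on the bundled battery both give 3 components.
* **Item rule**: an item is kept iff exactly one component carries an
  absolute *pattern* loading $\ge 0.4$; cross-loaders and non-loaders are
  removed before scoring. The pattern matrix is used because the rule
  concerns an item's unique contribution.
* **Compound scores** are unit-weighted means of z-scored, sign-aligned
  retained items, re-standardized to mean 0 / SD 1. Unit weighting (rather
  than regression scores) is what a per-component Cronbach's α
  presupposes, and α is reported for every component.
* **Variance explained** per component is the unrotated eigenvalue share
  of total item variance, the convention of standard statistical software
  output.
* Sampling adequacy: overall KMO (anti-image partial correlations) with
  the usual 0.7 threshold, and the Bartlett sphericity statistic
  $-(n-1-(2p+5)/6)\log|R|$ on $p(p-1)/2$ df; inadequate values warn but do
  not stop the analysis.

## The synthetic cohort generator

`generate_cohort()` draws from an explicit generative model whose defaults
encode the population the measure targets: 59% female, 12.1% asthma/COPD;
FEV~1~%pred normal per group (96.7 ± 12.2 control, 85.3 ± 14.3 asthma/COPD,
truncated to the plausible 16–225 window); weight derived from BMI
(25.8 ± 4.24 / 26.7 ± 4.93) times height² so that BMI calibration holds
while weight remains the model predictor; and exclusion-flag prevalences
matching the target cohort (8.8% CVD, 4.2% GAD, 0.2% PD, 29.6% invalid
spirometry, 0.4% unconfirmed asthma self-report).

The 5-level dyspnea report follows a cumulative-logit latent-propensity
model

$$\eta_i = \beta_F(-z^{FEV1}_i) + \beta_W z^{W}_i
  + \mathbf{w}^\top \mathbf{F}_i + \delta\,[\text{asthma/COPD}]_i,
  \qquad Y_i = 1 + \sum_k \mathbf 1\{\eta_i + \varepsilon_i > t_k\},$$

with standard-logistic noise $\varepsilon$, three correlated latent
psychosocial factors $\mathbf{F}$ (negative affect, fear of illness,
worry; correlations 0.3/0.2/0.25), and **distortion weights** $\mathbf{w}$
that inject psychosocial influence into the report. Because the model is
cumulative-logit by construction, the proportional-odds assumption holds
exactly at the defaults; a `nonparallel_fev1` switch adds a
threshold-varying FEV~1~ effect so the parallel-lines test has something
real to detect.

Default choices, made once and frozen:

* **Physiology coefficients are weak** (0.25 on −z-FEV~1~, 0.10 on
  z-weight): in general-population data physiology explains only a few
  percent of report variance, and that is the regime the measure is meant
  for. The asthma/COPD offset $\delta = 1.58$ carries the diagnosed
  group's excess reporting.
* **Distortion weights are positive** (0.5/0.5/0.4): the target population
  shows clear psychosocial influence on reporting; zero-distortion
  configurations are used in the null-calibration tests.
* **Thresholds** (3.00/4.15/5.22/6.32) were calibrated by simulating the
  latent model at large n so that dyspnea (item ≥ 2) is reported by ~7.1%
  of controls and ~27.8% of the asthma/COPD group (~9.6% overall), and the
  item marginal is strongly right-skewed.
* **Battery**: 16 continuous items on the negative-affect factor, 10
  binary items on fear of illness, 4 binary + 2 continuous on worry;
  loadings evenly spaced over 0.6–0.8 within block; binary items
  thresholded at 30% endorsement. The sumscore couplings were calibrated
  so the explained-variance decomposition lands in the single-digit to
  low-tens percent range typical of published cohort analyses.

What the generator does **not** emulate: family structure, longitudinal
waves, item-level missingness patterns, reference-equation internals
behind FEV~1~%pred, and measurement artifacts of real questionnaires.
Passing tests on synthetic data therefore demonstrate the *statistical
machinery* — not that any particular real cohort will show the same
effect sizes.

## Test design and problem sizes

The suite favors property-based checks at sizes that keep a full run
under a minute of fitting per block: oracle equivalence at n ≤ 500,
structure recovery at n = 5,000 over 20 seeds, null calibration with 200
replicates of n = 2,000 zero-distortion cohorts, directional reproduction
at n = 20,000, and Wald-coverage simulation with 1,000 replicates at
n = 500. In the null-calibration check the rejection rate is pooled over
the replicate × compound-score Wald tests (600 tests): at 200 replicates a
per-score ±2-point band around 5% would be narrower than its own Monte
Carlo noise, while the pooled rate is a stable calibration diagnostic.

## Known limitations

* The ACP inherits the outcome imbalance of rare symptom reports: with
  ~90% of participants in category 1, the intercept-only ACP is already
  ~0.9 for non-reporters, so the informative variation is concentrated in
  the low-ACP tail. This mirrors the behavior of the measure on real
  cohort data and is visible in the bimodal histograms.
* The parallel-lines comparison is conservative (see above); a dedicated
  non-parallel cumulative model would give an exactly nested test but is
  outside the measure's published definition.
* Compound scores are unit-weighted; regression or Bartlett factor scores
  would correlate slightly more with the latent factors but break the
  α-based reliability reporting.
* No survey weights, robust covariances, penalized or Bayesian fits.
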