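---
title: "Measuring cognitive-ability signal in questionnaire response errors"
author: "resperr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cognitive-ability signal in questionnaire response errors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resperr)
```

## The problem

Completing a standardized self-report questionnaire is itself a cognitively
demanding task: every item requires reading, retrieval, judgment, and
response mapping. If some responses deviate strongly from what a person's
own trait standing predicts, those deviations ("response errors") may carry
information about the respondent's general cognitive ability — without any
cognitive test being administered. Two robust regularities from intelligence
research guide where that signal should sit:

* **Worst performance rule (WPR).** A person's *worst* performances across
  repeated trials correlate more strongly with general ability than their
  average or best performances, usually explained by attentional lapses
  that people with higher ability suppress better.
* **Task complexity hypothesis (TCH).** Performance on *more complex*
  (higher information-load) tasks is more strongly ability-related than
  performance on simpler versions of the same task.

`resperr` implements an item-response-theory pipeline that quantifies
item-level response errors, and the two corresponding analyses: a decile
analysis of each person's error distribution, and moderated multilevel
models of the error-by-complexity interaction, up to a joint latent-variable
model of latent response errors and a latent ability factor.

## Response-error scores

Each multi-item rating scale is fitted with a unidimensional logistic graded
response model (GRM). For item $j$ with $m_j$ ordered categories,
discrimination $a_j$ and strictly increasing thresholds $b_{j1} < \dots <
b_{j,m_j-1}$, the cumulative category probabilities are

$$P^*_{jk}(\theta) = \mathrm{logit}^{-1}\{a_j(\theta - b_{j,k-1})\},\qquad
P_{jk} = P^*_{jk} - P^*_{j,k+1},$$

with $P^*_{j1} \equiv 1$ and $P^*_{j,m_j+1} \equiv 0$. We use the pure
logistic metric (no 1.7 scaling constant) and identify the model by fixing
the latent trait to $N(0,1)$.

Each person's trait is estimated by the expected a posteriori (EAP) mean
under the standard-normal prior, and the model-expected response is the
probability-weighted category value
$E(Y\mid\hat\theta) = \sum_k k\,P_k(\hat\theta)$. The response-error score

$$e = \frac{\lvert y - E(Y\mid\hat\theta)\rvert}{m_j - 1} \in [0, 1]$$

is 0 when the observed response equals the expectation and 1 when it is
maximally different. Error scores are computed only for person-scale blocks
with *no* missing responses (the complete-scale rule), while all available
responses still inform the GRM fit and the EAP estimate.

### Estimation choices

* **Quadrature.** 61 equally spaced nodes on $[-6, 6]$ with normal-density
  weights, for both the EM algorithm and EAP scoring; tests validate EAP
  against a 2001-node grid.
* **Convergence.** EM stops when the largest absolute parameter change
  falls below $10^{-4}$, capped at 500 iterations; hitting the cap is
  reported, never silently accepted.
* **Keying.** The GRM likelihood is invariant to reflecting the latent
  axis, so estimation fixes the orientation by requiring the majority of
  items to key positively. Items whose item-rest correlation is negative
  are reverse-coded before estimation (mixed keying directions put the EM
  in a poor basin); any item the unconstrained EM still estimates with
  negative discrimination is flagged, reverse-coded, and the scale
  refitted. All reversals are recorded in the fit object.
* **Unused categories** are collapsed onto adjacent observed categories
  with a recorded mapping; the post-collapse $m_j$ is used everywhere,
  including the error-score denominator.
* **Fit summary.** An SRMR-style quantity: the root mean square difference
  between observed polychoric correlations and polychorics of the
  GRM-implied joint category tables, over all item pairs of a scale.
  Polychorics are computed by maximum likelihood with bivariate-normal
  rectangle probabilities evaluated by Gauss–Legendre quadrature of the
  conditional normal. Limited-information indices (CFI/TLI/RMSEA) are out
  of scope.

## Worst-performance analysis

Error scores are strongly right-skewed (most responses sit near their
expectation), so they are cube-root transformed before the decile analysis;
the transform maps $[0,1]$ onto itself and is strictly monotone, so decile
*membership* is identical on the raw and transformed scales — only the bin
means differ.

Each person's transformed scores are sorted ascending and averaged within
ten bins. When the item count is not a multiple of ten, remainder items go
to the *lowest* bins, so bin sizes differ by at most one (102 items gives
sizes 11, 11, 10, ..., 10). Persons with fewer than 10 scored items cannot
fill ten bins and are excluded (threshold configurable). The ten decile
means are correlated with the ability score, giving dependent correlations
$r_1, \dots, r_{10}$.

**Testing equality of the ten dependent correlations.** The correlations
are Fisher $z$-transformed, and their joint covariance is estimated by the
delta method over the empirical joint moments of the eleven variables: each
correlation's influence function is
$\psi_i = z_{x,i}z_{y,i} - \tfrac{r}{2}(z_{x,i}^2 + z_{y,i}^2)$ (standardized
scores), and the covariance of the $\hat r$ vector is the sample covariance
of the stacked influence scores divided by $n$. We chose the joint-moment
estimator over the normal-theory (Pearson–Filon) formula because decile
means of sorted, bounded scores are not bivariate normal with ability; the
normal-theory covariance remains available (`cov_method = "normal"`), and a
person-level bootstrap serves as fallback and as the test oracle.

The omnibus statistic uses a successive-difference contrast $C$ (the
statistic is invariant to the choice of full-rank contrast basis):
$W = (Cz)^\top (C\hat\Sigma_z C^\top)^{-1} (Cz)$ with 9 degrees of freedom.
Because $\hat\Sigma_z$ is estimated from the same $n$ persons, $W$ is
referred to Hotelling's $T^2$ distribution — an $F(9,\,n-9)$ reference —
rather than the asymptotic $\chi^2_9$. In a 2000-replicate null calibration
at $n = 500$ the $\chi^2$ reference rejected at rate 0.072 and the $T^2$
reference at 0.060 at nominal 0.05; the $T^2$ reference is therefore the
default whenever $n$ is known. Post hoc pairwise comparisons use the
delta-method standard error of $z_k - z_l$.

## Task-complexity analysis

### Item complexity coding

Ten binary indicators per item, summed into a 0–10 composite:

1. **WC** — 10 or more words (tokens are maximal runs of letters, digits
   and intra-word apostrophes/hyphens after punctuation stripping,
   lowercased; hyphenated forms count once).
2. **DC** — two or more words absent from an easy-word familiarity list.
   The shipped list is an open ~800-word approximation of the classic
   fourth-grade list; numeric tokens count as familiar. Users can supply a
   replacement list.
3.–5. **UTT, VRT, VNP** — unfamiliar technical terms, vague relative
   terms, vague noun phrases: precomputed flags from an external
   question-understanding tool, ingested and validated as data (the tool is
   not reimplemented). With `strict = FALSE`, absent flags default to 0
   with a logged warning.
6.–10. **CON, NEG, DIS, TEN, EXC** — conjunctions, negations,
   discrepancies, tentative words, differentiation/exclusion words:
   contained-any matching against shipped open category lists (stems marked
   `*`). Exact reproduction of proprietary dictionaries is not promised.

The word-count and off-list cutoffs (10 and 2) are the printed
median-split values for the motivating item bank and are exposed as
parameters; `recompute_medians = TRUE` re-derives them from the item set at
hand. The composite's five-bin partition is 0–1, 2–3, 4–5, 6–7, 8–9; a
composite of 10 (never observed in realistic banks) goes to the top bin.

### Moderated multilevel model

With transformed error $e_{ij}$ for person $i$ and item $j$:

$$e_{ij} = \gamma_{00} + \gamma_{01}\,\mathrm{ability}_i +
\gamma_{10}\,c_{ij} + \gamma_{11}\,\mathrm{ability}_i \times c_{ij} +
u_{0i} + u_{1i} c_{ij} + r_{ij},$$

with $(u_{0i}, u_{1i}) \sim N(0, T)$ and $r_{ij} \sim N(0, \sigma^2)$. The
cross-level interaction $\gamma_{11}$ carries the TCH prediction: a
negative $\gamma_{11}$ (with ability beneficial) means the ability–error
slope steepens with complexity. Ability and complexity enter uncentered, so
$\gamma_{01}$ is the ability simple slope at complexity 0 and $\gamma_{10}$
the complexity simple slope at ability 0.

Estimation is direct maximization of the per-person marginal Gaussian
likelihood: the fixed effects are profiled out by GLS at every evaluation
and the optimizer works on the log-Cholesky factor of $T$ and
$\log\sigma$, which enforces positive semidefiniteness. ML (not REML) is
used throughout so that reparameterized fits are likelihood-comparable.
Per-person cross-products are precomputed and persons sharing an item
pattern are grouped, so balanced designs reduce each likelihood evaluation
to a handful of small matrix contractions via the Woodbury identity; a fit
with 2000 persons and 100 items takes well under a second. Fixed-effect
standard errors are person-clustered sandwich estimates. If the random
slope variance collapses to the boundary the model is refitted without the
random slope, with a warning. Non-convergence triggers up to three
perturbed restarts and is flagged in the result.

A sensitivity variant replaces linear complexity by the five bins
interacted with ability (random structure unchanged) and reports the
percent change of the per-bin ability slope relative to the lowest bin.
Empty bins are dropped with a warning; a single-bin design degenerates to
an intercept–ability model with contrasts reported as undefined.

### Low/high-complexity basis parameterization

The same model can be written with neither intercept nor slope, using the
basis weights $(9-c)/9$ and $c/9$: the two person effects are then latent
individual differences in response errors at complexity 0 and complexity 9
(the top of the observed range), and ability joins as a third person-level
variable with free mean and variance, all with a free $3\times3$
covariance. The package fits this by its exact factorization: the
conditional-on-ability model is a bijective reparameterization of the
moderated model (same mean span, same random-effect span), and the ability
margin is a saturated Gaussian; the joint ML solution is assembled from the
two pieces. Consequently the conditional component's maximized likelihood
equals the moderated model's likelihood exactly — a property the tests
assert to $10^{-4}$ — and the reported joint likelihood adds the ability
margin. The quantities of interest are
$\mathrm{corr}(u_{\mathrm{low}}, \mathrm{ability})$ and
$\mathrm{corr}(u_{\mathrm{high}}, \mathrm{ability})$.

### Latent ability

Ability composites are measured with error, which attenuates the
correlations above. Two latent-variable extensions address this:

* `fit_ability_factor()`: a one-factor model of the four cognitive
  subtests with a free residual covariance between the two recall subtests
  (their shared memory-specific variance), factor variance fixed at 1,
  fitted by ML on the covariance structure; 1 df against the saturated
  model. Heywood cases are reported. Regression factor scores with their
  (constant) SE are returned.
* `fit_latent_mlm()`: the joint model — item errors through the
  low/high-complexity basis, subtests through the factor model, and a free
  covariance among $(u_{\mathrm{low}}, u_{\mathrm{high}}, g)$ with
  $\mathrm{var}(g) = 1$. Estimation is ML on the stacked per-person vector
  of items and subtests; persons are grouped by missingness pattern, and
  with complete data the profile reduces to a single covariance-structure
  fit, which keeps the joint model fast. The unit-variance constraint is
  built into the parameterization (the factor row of the Cholesky factor
  is a unit vector in two unconstrained coordinates), so no constrained
  optimizer is needed. A two-step fallback (factor scores, then the basis
  model) is available and always labeled an approximation — factor-score
  correlations are attenuated relative to joint estimates — and the
  pipeline only substitutes it, visibly, when too few persons have
  complete data for the joint fit.

The disattenuation property — the latent-factor correlation with
high-complexity errors exceeds the manifest-composite correlation in
magnitude — is asserted on simulated data in the test suite.

### Scale-level analysis

For each scale, the mean item complexity and the correlation of
person-level mean error with ability; across scales, the correlation of
those two quantities with a Fisher-z 95% CI. Scales with zero error
variance are excluded with a warning; identical complexity across scales
makes the meta-correlation undefined, reported as such.

## The synthetic-data generator

No restricted survey data ship with the package; everything is exercised on
synthetic data whose default configuration mirrors the motivating study's
design:

* 21 scales with sizes 5, 5, 6, 4, 3, 4, 4, 5, 5, 4, 5, 3, 4, 5, 5, 5, 7,
  7, 5, 4, 7 — 102 items — with 3–7 response categories per scale
  (5 most likely).
* A standard-normal general ability $g$; per-scale latent traits
  correlated with $g$ at 0.2 by default (psychosocial constructs are only
  modestly ability-related; the value barely matters downstream because
  the ability–error link is carried by the lapse mechanism, not by trait
  levels).
* **Lapse contamination.** On each person-item encounter, with probability
  $\mathrm{logit}^{-1}(\lambda_0 + \lambda_1 g + \lambda_2 c + \lambda_3
  g c + \omega_i)$ the response is drawn off-model (uniform over
  categories by default; an extreme-response mode is available), otherwise
  from the GRM at the person's trait. Defaults $\lambda_0 = -2.8$,
  $\lambda_1 = -0.5$, $\lambda_2 = 0.15$, $\lambda_3 = -0.08$,
  $\mathrm{SD}(\omega) = 0.7$ give a baseline lapse rate near 5% (about 9%
  averaged over persons and items) — "occasional" lapses — chosen once as
  a qualitatively realistic operating point; no empirical lapse rates
  exist to calibrate against. The resulting error distribution is strongly
  right-skewed, as in real questionnaire data. Its *median* (~0.17 under
  the defaults) sits above the ~.08 typical of well-fitting real scales:
  the median is governed by the ordinary GRM residual dispersion at
  discriminations around 1.5, not by the lapse tail, and pushing it down
  would require unrealistically deterministic items rather than a
  different contamination model.
* Four cognitive subtests (0–10, 0–10, 0–5, 0–2) as truncated-and-rounded
  linear transforms of $g$, with a shared residual between the two recall
  subtests; the composite is their sum, bounded 0–27, with mean near 15.
  Exact composite moments are not targets.
* Item complexity 0–9 drawn from a beta-binomial (9, 1.05, 1.85), giving
  mean ≈ 3.3 and SD ≈ 2.5; each item gets a random indicator vector
  summing to its complexity, and item text is constructed so the
  text-based indicators recode *exactly* to the generating values with the
  shipped lexicons — an end-to-end identity the tests assert.
* Multi-wave panels share person latents with compound-symmetric
  across-wave correlation; item draws are independent within wave.
* Response-level missingness (3% by default, matching the motivating
  study's order of magnitude) exercises the complete-scale rule.
* One seeded RNG stream drives all stages; identical config and seed give
  byte-identical output files. Reproducibility is guaranteed within this
  implementation, not across implementations.

What the generator does *not* emulate: panel sampling designs, attrition,
proxy respondents, demographic covariates, acquiescence or other
style-driven response patterns, and item-level random effects. Passing
tests therefore show that the machinery recovers the structure it assumes;
they cannot show that real questionnaire data satisfy those assumptions.

## Problem sizes and numerical tolerances

The test suite runs the analytic oracle checks at full precision
($10^{-10}$ for the scoring formulas, $10^{-6}$ for likelihood oracles,
$10^{-4}$ for the reparameterization identity) and the Monte Carlo checks
at sizes chosen to keep the whole suite in the tens of minutes: GRM
recovery at $n = 2000$ (5 items, 5 categories, MAE tolerance 0.15), null
calibration of the omnibus test with 1000 replicates at $n = 500$, the WPR
power pattern at $n = 5000$ with a 30-item bank, interaction-coverage at
200 replicates of 2000 persons × 100 items, and latent-model recovery at
$n = 2000$–3000. The default pipeline run in the package's documentation
uses 2000 persons — large enough for stable GRM estimation in every scale,
small enough to run in minutes.

## Known limitations

* The GRM is fitted per scale assuming unidimensionality and a common
  measurement model across persons; multidimensional models, scale
  purification, and differential item functioning are out of scope.
* The complexity lexicons are open approximations; indicator values for
  individual items can differ from proprietary-dictionary codings.
* The two-step latent fallback understates latent correlations; it is
  labeled whenever used.
* The generator's lapse model is one simple mechanism producing
  heavy-tailed errors; real careless or low-quality responding is more
  heterogeneous.
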