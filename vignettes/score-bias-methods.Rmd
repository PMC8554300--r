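---
title: "Latent skills as regression predictors: scores, plausible values, and SEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent skills as regression predictors: scores, plausible values, and SEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multi-item rating scales — socio-emotional skills, personality traits,
attitudes — measure a unidimensional latent construct $\theta$ with a
handful of 5-point items. Applied research then enters some *score* for
$\theta$ into a multiple regression next to an error-free covariate $C$:

$$Y = \beta\,\theta + \gamma\,C + e.$$

Because every score is a fallible proxy, the estimated $\hat\beta$ is
attenuated and — less widely appreciated — $\hat\gamma$ is *inflated*,
since the part of $\theta$ the score misses leaks into the correlated
covariate. `scorebias` provides a tested simulation pipeline that
quantifies these distortions, as mean percent bias
$100(\hat\beta-\beta)/\beta$, for seven ways of handling the skill:

* **SMS** — standardized mean score (per-person item mean, z-standardized);
* **RFS** — regression factor score $\Phi\Lambda'\Sigma^{-1}x$ from a
  one-factor ML CFA;
* **WLE** — Warm's weighted likelihood estimate under a generalized
  partial credit model (GPCM);
* **EAP** — posterior mean under the GPCM with a standard-normal prior;
* **EBM** — posterior mode (MAP) under the same model;
* **PV** — ten plausible values drawn from the posterior of a
  latent-regression GPCM conditioned on $(C, Y_1, Y_2)$, analyzed per
  draw and pooled by Rubin's rules;
* **SEM** — the full structural equation model fitted by normal-theory ML.

## The generating model

One replication draws $(\theta, C)$ bivariate standard normal with
$\phi = \mathrm{corr}(\theta, C) = 0.30$, continuous congeneric items
$X^*_j = \lambda_j\theta + \varepsilon_j$ with
$\varepsilon_j \sim N(0, 1-\lambda_j^2)$, and two outcomes

$$Y_1 = 0.35\,\theta + 0.30\,C + e_1, \qquad
  Y_2 = 0.20\,\theta + 0.30\,C + e_2,$$

with residual variances chosen so $\mathrm{Var}(Y) = 1$ exactly; the
"stronger" conditions analyze $Y_1$ (skill dominates), the "weaker" ones
$Y_2$. Items are then cut at $(-1.5, -0.5, 0.5, 1.5)$ into five ordered
categories, giving the familiar symmetric bell-shaped category histogram
(proportions about 7/24/38/24/7%).

Design factors (fully crossed, 36 cells): number of items
$k \in \{4, 8, 12\}$; loading profile *high* (alternating 0.8/0.7),
*mixed* (tiling 0.9/0.7/0.6/0.4), *low* (alternating 0.5/0.4); sample
size $n \in \{300, 1000\}$; and relative outcome strength. The loading
vectors are calibrated so McDonald's omega
$\omega = (\sum\lambda)^2 / [(\sum\lambda)^2 + \sum(1-\lambda^2)]$
reproduces the nine reference scale reliabilities (0.50–0.94) to two
decimals; `build_design()` carries the implied omega per condition.

Three generating quantities are not pinned down by the reference design and are
fixed here as package choices: the thresholds above (the simplest
symmetric cut set with a bell-shaped histogram), the structural
coefficients $(\beta, \gamma) = (0.35, 0.30)$ and $(0.20, 0.30)$ (skill
bias is insensitive to them; covariate-bias levels are conditional on
them), and the unit-variance normalization of the outcomes (so
unstandardized and population-standardized coefficients coincide).

## Estimation machinery and numerical choices

**CFA / SEM.** One-factor ML with the factor variance fixed at 1,
minimizing $F_{ML} = \log|\Sigma| + \mathrm{tr}(S\Sigma^{-1}) -
\log|S| - p$ by quasi-Newton with analytic gradients; 5-category items
are treated as continuous, as applied practice overwhelmingly does with
5-point scales. Start values come from the CFA and an OLS of $Y$ on (SMS, $C$);
residual variances are floored at $10^{-4}$ and flagged when hit
(Heywood); a fit whose gradient sup-norm exceeds $10^{-5}$ restarts once
from perturbed starts and is flagged non-converged above $10^{-3}$. Point
estimates are identical to robust-ML variants, which differ only in
standard errors that play no role for bias.

**GPCM.** Marginal ML by EM on 41 equally spaced quadrature nodes on
$[-6, 6]$ with $N(0,1)$ weights renormalized to sum 1. The E-step
accumulates expected node-by-category tables; the M-step runs a damped
Fisher-scoring Newton per item. Convergence: maximum absolute parameter
change $< 10^{-4}$, cap 500 iterations. A category unobserved in a
replication (possible at $n = 300$ with low loadings) is collapsed into
its lower neighbour and the fit flagged, so sparse replications are
scored rather than dropped. WLE and EBM maximize their criteria
continuously on $[-6, 6]$ (grid scan to bracket, then golden-section);
both are verified against a $10^{-4}$-resolution brute-force grid oracle.

**Plausible values.** The conditioning model
$g(\theta \mid c) = N(\mu + \beta_c'c, \sigma^2)$ with background
variables $(C, Y_1, Y_2)$ is estimated *jointly* with the item
parameters by EM, each person's prior centred at their conditioning
mean. The joint model is identified only up to a shift/rescaling of the
latent scale, which we resolve by standardizing the latent marginal to
mean 0 and variance 1 at each M-step — the metric of the generating
model. PV are drawn from the discrete node posterior with a uniform
jitter inside the node spacing (jitter variance $0.3^2/12$ is negligible
against the posterior spread); item and conditioning parameters are held
fixed at their estimates, the standard operational shortcut, which
slightly understates imputation-model uncertainty but leaves point
estimates unaffected. Each of the 10 PV enters its own OLS and the
estimates are pooled as $\bar Q$, $W$, $B$, $T = W + (1 + 1/m)B$.

**EBM.** An alternative formulation computes posterior modes under a
limited-information (WLSMV) categorical model; here EBM is the posterior
mode under the same fitted GPCM as WLE/EAP. This preserves the operative
property — EBM, EAP and RFS behave near-identically in bias — without a
second estimation stack.

**Seeds.** Replication $r$ of condition $c$ uses seed
$(\text{base} \cdot 10^6 + c \cdot 10^4 + r) \bmod (2^{31}-1)$:
conditions are independent deterministic streams, and every result in
the package is bit-reproducible from the base seed.

## What the runner reports

`run_condition()` executes the replications of one cell: simulate,
score, regress the analyzed outcome on (score, $C$) per method, pool the
PV fits, fit the SEM, and convert both coefficients to percent bias
against the generating $(\beta, \gamma)$. Replications where an
estimator fails to converge are excluded from that method's average and
counted (`n_flagged`), never silently dropped; a condition aborts only
if more than 10% of replications fail outright. The runner also
accumulates the mean correlation matrix of the five scores and both
outcomes — those correlations approach unity, which is exactly why
correlation-level agreement says nothing about coefficient-level bias:
the slope also depends on each score's variance, and WLE (anti-shrunk,
variance above 1) and EAP (shrunk, variance below 1) sit on opposite
sides of it. For the four model-based scores the runner additionally
records standardized-coefficient bias (`standardized = TRUE` rows),
which repairs most of WLE's attenuation and worsens EBM/RFS/EAP, while
leaving covariate bias essentially unchanged.

## Problem sizes, Monte-Carlo error, and what tests can show

The full study design is 36 conditions × 500 replications. The
package's analysis scripts and acceptance checks run 100 replications
per condition — a full sweep takes a few minutes on one CPU — and the
oracle-style checks use single large samples ($n = 10^4$–$10^5$). At 100
replications the Monte-Carlo standard error of a cell mean reaches
2–3 bias points in the $n = 300$, low-loading cells (per-replication SD
of SEM percent bias is ~23 points there), with two consequences worth
stating plainly:

* cell-level comparisons are meaningful only within ±2.5 points, and a
  *maximum* over 36 cell means of a nearly unbiased method (SEM, PV)
  reflects the noise floor (~4–6 points) rather than systematic bias —
  at 500 replications the same maximum would still sit near 2–3;
* design *trends* (bias falls with more items and stronger loadings; the
  skill's bias ignores the outcome-strength factor) are therefore
  checked on cell means averaged over the factors the full-scale results
  show they do not interact with.

The generator emulates exactly the stated population: normal latent
skill, linear structural model, congeneric items, complete data. Passing
tests demonstrate correct machinery under that model; they do not speak
to non-normal skills, non-classical measurement error, multidimensional
scales, or missing data, all of which are out of scope here.

## Known limitations

* EBM is a GPCM posterior mode, not a WLSMV-based one (see above).
* PV conditioning uses the untransformed background design
  $(1, C, Y_1, Y_2)$; no parameter redraws between PV sets.
* The CFA/SEM treat 5-category items as continuous by design; no
  polychoric/WLSMV variants are provided.
* No fit indices are computed — parameter recovery is the only outcome.
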