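---
title: "Adaptive testing for sleep quality and quality of life: models and methods"
author: "paincat developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive testing for sleep quality and quality of life: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paincat)
```

## The measurement model

`paincat` treats each questionnaire item as a graded response model (GRM)
item: for an item with $K$ ordered categories, discrimination $a > 0$ and
thresholds $b_1 < \dots < b_{K-1}$, the probability of answering in
category $k$ or above at trait level $\theta$ is the two-parameter
logistic

$$P^*_k(\theta) = \frac{1}{1 + e^{-a(\theta - b_k)}},$$

and the category probabilities are the adjacent differences
$P_k = P^*_k - P^*_{k+1}$ (with $P^*_0 = 1$, $P^*_K = 0$). We use the pure
logistic metric — no 1.7 scaling constant — which is what mainstream GRM
software estimates, so slopes are directly comparable with the
conventional discrimination bands (very low $<0.35$, low $<0.65$, moderate
$<1.35$, high $<1.70$, very high $\ge 1.70$). The latent trait is oriented
so that higher $\theta$ means *better* sleep quality or quality of life;
items keyed the other way are inverted before calibration
(`invert_categories()`), which maps code $c$ to $K-1-c$ and records the
flip.

Fisher information of an item is
$I_i(\theta) = \sum_k (P^{*\prime}_k - P^{*\prime}_{k+1})^2 / P_k$ with
$P^{*\prime}_k = a P^*_k (1-P^*_k)$; test information adds over items
under local independence and the measurement SE is
$1/\sqrt{I(\theta)}$.

### Assumptions

* **Unidimensionality** — one latent factor per construct. Screened with
  maximum-likelihood exploratory factor analysis: an item survives only if
  exactly one absolute loading reaches 0.30 (`loading_filter()`).
* **Local independence** — responses independent given $\theta$. The
  original analysis names the principle without its diagnostic; we use
  Yen's Q3 (correlation of residuals at the EAP trait estimate), flagging
  pairs whose Q3 deviates more than 0.2 from the $-1/(J-1)$ baseline that
  Q3 exhibits under independence.
* **No differential item functioning (DIF)** — item parameters equal
  across gender strata, tested with Wald statistics (below).

## Calibration

`fit_grm()` maximizes the marginal likelihood under a standard-normal
latent trait via EM:

* Quadrature: 61 equally spaced nodes on $[-6, 6]$ with normalized
  N(0,1) weights. Deterministic and exchangeable with Gauss–Hermite at
  this density; the node count matters only below ~21 nodes.
* M-step: per-item BFGS on $(\log a,\, b_1,\, \log(\Delta b_m - 10^{-3}))$,
  which enforces $a > 0$ and strictly increasing thresholds with a minimum
  gap of $10^{-3}$. The M-step is capped at 30 BFGS iterations — a
  generalized EM step — so the marginal likelihood still increases every
  cycle (asserted in the tests).
* Convergence: maximum absolute parameter change below $10^{-4}$, cap 500
  cycles. Starting values are $a = 1$ and thresholds at normal quantiles
  of the observed cumulative category frequencies, so fits are
  deterministic given data and settings.
* Missing responses are skipped in the likelihood (missing at random).
  Categories observed zero times are collapsed into their lower neighbour
  with a warning; calibration refuses items left with fewer than two
  categories, and refuses samples below $N = 150$ (warning below 200,
  reflecting the usual 200–300 subject guidance for item calibration).
* Probabilities are floored at $10^{-10}$ inside logarithms. This is a
  numerical guard against $-\infty$ at extreme $\theta$, not a model
  change.

Standard errors come from the observed information matrix by default: the
marginal score vector is computed analytically through Fisher's identity
(posterior-expected complete-data score) and differentiated numerically.
The cheaper outer-product-of-gradients (OPG) estimator is also available;
we measured it to overstate the joint covariance by roughly 25% at
$N = 500$, which makes Wald tests built on it noticeably conservative —
that is why DIF testing defaults to the observed-information estimator.

## Differential item functioning

`dif_wald()` calibrates each gender group separately, links the focal
group to the reference scale by mean/sigma linking on the thresholds of
*all other* items (anchor-all-other-items), and tests the joint difference
of the studied item's parameters with
$W = \delta^\top V^{-1} \delta \sim \chi^2_K$. Two details matter:

* The sampling error of the linking constants is propagated by a full
  delta method through both groups' complete covariance matrices. The
  scale error shared by the studied item and its anchors partially
  cancels in the linked difference; ignoring that correlation deflates
  the type-I error severalfold.
* P-values are Benjamini–Hochberg adjusted across items (the original
  report names no multiplicity procedure; raw p-values are also
  returned).

In null simulations (12 items, $N = 500$ per group) the raw-p rejection
rate at $\alpha = 0.05$ is 0.046 with mean $W/\mathrm{df} = 0.96$, and a
0.75 threshold shift is detected in essentially every replicate.

## The adaptive testing engine

A session starts with a uniformly random first item (seeded), matching
practice where the opening item should not always be the same; a
maximum-information start is available. After each response the trait is
re-estimated — EAP by default, with ML, MAP and WLE (Warm's
bias-corrected likelihood) available; SEs are estimator-consistent
(posterior SD for EAP/MAP, $1/\sqrt{I}$ for ML/WLE). ML estimates are
clamped to $[-4, 4]$ and flagged for all-extreme patterns; WLE stays
finite there.

Item selection is maximum Fisher information at the current estimate. The
determinant-, trace-, asymptotic-covariance-, weighted-composite- and
eigenvalue-rules familiar from multidimensional CAT software all reduce
to exactly this criterion in a unidimensional model, so the engine
deliberately exposes MFI plus a posterior-weighted Kullback–Leibler index
rather than pretending five distinct rules exist. Ties break to the
lowest item index; an item is never administered twice.

The session stops when the SE reaches 0.3 (about reliability 0.91) or the
bank is exhausted — no time limit, no item cap by default. The final
score is reported as $T = 10\hat\theta + 50$.

For clinical interpretation, `endorsement_table()` dichotomizes every
polytomous category $k \ge 1$ into the event "responds in category $k$ or
above", whose endorsement probability at a trait level is $P^*_k(\theta)$,
drops items with $a < 0.65$ (below "moderate"), and ranks the ten most
endorsed categories per trait level.

## Equating

`equipercentile_equate()` maps a source score to the target score with
the same percentile rank, using the plus-half convention
$PR(x) = 100(F(x-1) + f(x)/2)/N$ and linear interpolation inside the
target score interval holding that rank. The concordance is reduced to a
linear crosswalk by frequency-weighted least squares — the original
report prints linear conversion functions without stating how they were
linearized, and weighted LS on the equipercentile pairs is the
reduction that reproduces a truly linear concordance exactly.
`apply_crosswalk()` rounds half away from zero (spreadsheet `ROUND`
semantics — banker's rounding would change converted scores) and clamps
into the target range, since a printed conversion of this form can
produce $-1$ at the bottom of the scale. Equating is intended for groups
(20+); `equate_instruments()` warns below that.

## Synthetic data: what it emulates, and what a green test establishes

No patient-level data are distributable, so the package carries a
generator whose defaults mirror the published setting:

* `sleep_bank_template()`: 23 items — 16 PSQI-like (one dichotomous, two
  3-category, ten 4-category, three 5-category quantile-split-style) and
  seven 5-category ISI-like items, with the published discrimination
  banding (10 very high, 2 high, 10 moderate, 1 low).
* `qol_bank_template()`: 41 items (11 SF-12-like, 25 WHOQOL-BREF-like,
  5 EQ-5D-3L-like) with banding 15/9/14/3.
* Discriminations are drawn uniformly inside each band
  (very high capped at 2.8); thresholds are sorted uniform draws on
  $[-2.5, 2.5]$ with a minimum gap of 0.25 so that categories remain
  identifiable at cohort sizes near 300. These spreads were fixed once as
  typical of patient-reported-outcome banks.
* Cohorts draw $\theta \sim N(0,1)$ (the burden simulation uses 5000
  simulees, matching the published simulation size), responses from the
  model, and MCAR missingness at a configurable rate.

The synthetic world is homogeneous by construction: it has no real
violations of unidimensionality, no response styles, no informative
missingness, and its instrument structure (not wording) merely resembles
the real questionnaires. Green tests therefore establish that the
*machinery* is correct — calibration recovers known parameters, the CAT
stops where it claims, arithmetic matches the published formulas — not
that any particular clinical bank will reproduce the published item
counts (mean 6.58 sleep items per session, for instance, depends on the
unavailable calibrated parameters of the real cohort; our synthetic banks
land near 10 of 23). The per-instrument burden breakdown is reported but
never asserted against, because the published per-instrument accounting
is internally inconsistent (a sleep mean of 6.58 items cannot coexist
with "no decrease" for the 7-item ISI).

## Numerical and design choices

* Probability floor $10^{-10}$ in logs; information terms treat $0/0$ as 0
  in padded categories.
* EAP/MAP/KL share the 61-node quadrature; curve exports default to a
  0.01 grid on $[-6, 6]$.
* `quantile_split()` uses left-closed bins at empirical quantiles with
  ties to the lower bin — deterministic and order-preserving.
* Hot-deck imputation (the deliberately simple surrogate for chained
  equations: complete synthetic data never exercises more) draws donors
  from the same total-score decile under a seed; empty donor pools fall
  back to the item mode.
* Oblimin rotation is gradient-projection on the quartimin criterion,
  started from the varimax solution — the ML solution itself is a
  symmetric saddle point of quartimin where the gradient projection
  stalls.
* Response codes are 0-based internally; file readers accept a declared
  0- or 1-based origin. Missing cells are empty/`NA` in files, never a
  sentinel inside the code range.
* All randomness flows through `with_seed()`, which restores the caller's
  RNG state; every simulation artifact embeds its seed.

## Known limitations

* Unidimensional GRM only; no multidimensional or non-parametric models.
* Limited-information fit statistics (M2, RMSEA, SRMSR, TLI, CFI) are not
  implemented; calibration quality is established by parameter recovery
  instead.
* Full multiple imputation by chained equations is out of scope (the
  hot-deck surrogate above).
* The Wald DIF covariance ignores uncertainty in the quadrature
  discretization; its calibration was verified by simulation at
  $N = 500$ per group, not asymptotically.
* Equating supports two instruments per call, without presmoothing;
  chained equating across more instruments is out of scope.
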