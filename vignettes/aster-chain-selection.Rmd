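---
title: "Aster chain models for phenotypic selection in common-garden experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aster chain models for phenotypic selection in common-garden experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asterchain)
```

## The problem

Selection on seeds and seedlings is expressed through a *sequence* of
fitness components: a seedling must survive its first season before it
can survive the second, and it must be alive at the final census before
its height can be measured.  Analyzing each component separately wastes
the joint structure; analyzing height among survivors alone ignores the
mortality that did most of the selecting.  Aster models solve this by
writing one likelihood for the whole life history, with each component
conditioned on its predecessor.

`asterchain` implements the chain special case that covers early
life-history data from common-garden experiments: a linear chain of
Bernoulli survival indicators (one per year) optionally terminated by a
normally distributed size measure.  On top of the model it implements
the full selection-analysis pipeline used with such data: Spearman
screening of trait multicollinearity, forward-stepwise retention of
linear ($\beta_i$), quadratic ($\gamma_{ii}$) and cross-product
($\gamma_{ij}$) selection-gradient terms by likelihood-ratio test,
fitness surfaces, and classification of the selection regime — plus a
calibrated simulator of the underlying field design so that the whole
pipeline runs, and is tested, without any external data.

## The model

Let the graph nodes be $y_1 \to y_2 \to \dots \to y_K (\to h)$, where
$y_k \in \{0,1\}$ is survival through year $k$ and $h \ge 0$ is final
height (mm).  The joint density factorizes along the arrows:

$$
f(y, h \mid x) \;=\; \prod_{k} f(y_k \mid y_{k-1}, x) \; \cdot \;
f(h \mid y_K, x),
$$

with $y_k \mid y_{k-1}{=}1 \sim \mathrm{Bernoulli}(p_k(x))$,
$h \mid y_K{=}1 \sim N(\mu(x), \sigma^2)$, and both conditional
distributions *degenerate at zero* when the predecessor is 0 (the
structural zeros; `validate_records()` enforces them and fits refuse
violating data).  A node whose predecessor is dead contributes exactly
zero to the log-likelihood.

Two fitness measures follow:

* **cumulative survival** $\;S(x) = \prod_k p_k(x)$, and
* **unconditional expected height**
  $\;W(x) = S(x)\,\mu(x)$,

the latter accounting for mortality: with no mortality it reduces to
the ordinary mean height, and it decreases as mortality increases.
Both are computed by `predict()` (`type = "survival"` and
`type = "uncond_height"`), and the factorization
$W = S \times \mu$ holds *exactly* for every fit — it is the
definition, not an approximation — which the test suite asserts.

### Parameterization

Linear predictors act on the **conditional canonical scale**: the logit
of each $p_k$ and the identity for $\mu$.  (The alternative,
unconditional canonical parameterization, couples all nodes through the
cumulant transform; the conditional scale was chosen for transparency —
closed-form node MLEs, interpretable coefficients — and the fitness
measures above are defined by the product formula, independent of link
choice.)  Every node has its own intercept.  Covariate terms receive

* one **shared coefficient across all Bernoulli nodes** (a treatment
  contrast shifts each year's conditional survival logit equally), and
* a **separate coefficient block for the height node**, in mm.

This makes the model degrees of freedom for a survival analysis equal
to (number of nodes) + (number of covariate columns), e.g. 3 + 2 + 1 +
1 = 7 for treatment plus two traits on a three-year chain.  On
height-fitness graphs a trait term contributes one column per block,
hence 2 test df.  Setting `by_node = TRUE` instead gives every
Bernoulli node its own coefficients; with a saturated group factor this
reproduces the empirical per-group, per-node survival fractions exactly
(another tested invariant).  `forward_stepwise(blocks=)` can confine
candidate terms to one block — `blocks = "height"` with no mortality
reduces the analysis, ledger line for ledger line, to ordinary normal
model selection.

Under the conditional parameterization the fixed-effects MLE separates:
the survival part is a single stacked Bernoulli regression over
(node, at-risk individual) pairs, solved exactly by iteratively
reweighted least squares, and the height part is a least-squares fit
with $\sigma^2$ profiled by maximum likelihood.  No general-purpose
optimizer is involved in fixed fits, so they are deterministic and
fast; standard errors come from the observed information.

### Random effects

Field designs group individuals into blocks, maternal families and
row-plots.  `asterchain(random = c("block", "family"))` adds
independent normal random intercepts per grouping, *shared across all
nodes of an individual* with loading 1 on each node's conditional
canonical parameter (so a family effect moves every year's survival
logit and the height mean coherently; because height is on the mm
scale, its share of a logit-scale component is numerically negligible —
which is also why height-model variance components in such analyses
are typically reported as vanishingly small).  The marginal likelihood
is approximated by the **Laplace method**: an inner Newton iteration
finds the random-effect mode (the penalized joint log-likelihood is
concave, so this is safe), and an outer L-BFGS-B maximizes the Laplace
objective over fixed effects and log standard deviations, bounded
below so variance components stay non-negative.  Components estimated
below $10^{-3}$ on the SD scale are flagged `boundary` and reported as
negligible.  Reported quantities follow the conventions of the model
class: the square root of each variance component with a delta-method
SE, and a one-tailed p-value from the 50:50 mixture of $\chi^2_0$ and
$\chi^2_1$ appropriate for a boundary test, computed by a drop-one
refit.  The implementation agrees with `lme4::glmer` to three decimals
on single-node data (tested), but `glmer` is used only as a
cross-check, never as the engine.  Like every Laplace-based binary
GLMM fit, variance components carry a small finite-cluster bias; at 50
clusters of 40 it is well inside Monte-Carlo error (tested).

## The selection pipeline

1. **Window.** `subset_cohort()` selects the analysis cohort:
   `from_2009` (all emergents; graphs "a"/"c") or `from_2010`
   (survivors of the emergence year; graphs "b"/"d").  Second-year
   traits such as shoot-elongation rates exist only for the
   `from_2010` cohort — the classic *invisible fraction*: selection on
   those traits through first-year mortality is unobservable, and the
   package does not pretend otherwise (the generator masks the rates
   of first-year deaths as missing).
2. **Screen.** `screen_traits()` computes Spearman rank correlations
   (midranks for ties) among traits of terminal survivors per stratum
   and flags pairs with $r_s^2 \ge 0.70$; flagged pairs never co-occur
   downstream (neither their linears nor their cross-product), and a
   trait constant in a stratum is unusable there.
3. **Standardize.** `standardize_traits()` centers and scales traits
   to unit variance *within the analysis stratum* before gradient
   terms are formed.  Stratum-wise scaling matches stratum-wise
   analyses; the scaling is stored so raw-scale coefficients can be
   reported.  The quadratic model term is $z^2$ with fitted
   coefficient $c$; `selection_gradients()` reports both $c$ and the
   Lande–Arnold $\gamma = 2c$ to avoid the classic factor-of-two
   ambiguity.
4. **Stepwise.** `candidate_terms()` enumerates candidates in forward
   order — factors, trait linears, trait quadratics, factor-by-trait
   interactions, cross-products — with marginality prerequisites
   ($\beta_i$ before $\gamma_{ii}$; both $\gamma_{ii}, \gamma_{jj}$
   before $\gamma_{ij}$).  `forward_stepwise()` adds, at each step,
   the admissible candidate with the smallest LRT p-value below
   $\alpha = 0.05$ (exact ties broken by candidate order), skipping
   non-convergent candidates with a warning, and emits a
   model-comparison ledger (model df, model deviance, test df, test
   p).  Deviance is defined as $-2\times$ log-likelihood; only
   differences are ever interpreted.  No multiplicity correction is
   applied beyond the per-term $\alpha$ — a deliberate mirror of
   standard practice in this literature, stated rather than "fixed".
5. **Surfaces and classification.** `fitness_surface()` evaluates the
   fitted fitness measure on a grid (default $50\times50$, inclusive
   endpoints) spanning the observed trait ranges, with non-plotted
   numeric covariates at their stratum means (standardized traits at
   0), factors at a reference level, and random effects at their mode
   of zero; observed trait pairs are overlaid with multiplicity
   counts.  `classify_selection()` profiles fitness along one trait
   and classifies: *stabilizing* (retained quadratic, interior
   maximum; for survival fitness the optimum has the closed form
   $-\beta/2c$ on the standardized scale, since the logit link is
   monotone), *disruptive* (interior minimum), *directional* (monotone
   profile, sign from its direction), or *none* (no term retained).
   For unconditional height the survival and height blocks jointly
   shape the profile, so the optimum is located numerically on the
   profile rather than by a closed form.

## The synthetic common garden

`simulate_experiment()` reproduces the two-experiment field design:
five blocks, three drought treatments (mid/late-summer drought,
late-summer drought, none) randomized within block; every maternal
family in every block-by-treatment cell in two row-plots of eight
positions (experiment 1: 36 families of one provenance; experiment 2:
eight families from each of three provenances, four positions), two
seeds per position — 17,280 seeds sown in experiment 1 by the closed
form the design implies.  For experiment 2 the same closed form gives
5,760; the generator always reports its own design arithmetic rather
than pinning a printed total.  Where two seedlings emerge at a
position, the second-sown seed is removed ("easternmost" culling,
implemented as a deterministic index rule; spatial coordinates are not
modelled).

Calibrated defaults (each chosen once, to emulate the study
conditions, and then left alone):

* per-seed emergence probability 0.588 (experiment 1) / 0.634
  (experiment 2); emergence days from a discretized normal truncated
  to Julian days [100, 140), family means around JD 114–116 (between-
  family SD 3 d, within-family SD 5.5 d — total ≈ 6.3 d, and earlier
  mean emergence for drier-origin provenances);
* family mean seed density uniform on 5.6–12.4 mg/ml (experiment 1;
  narrower per-provenance ranges in experiment 2), constant within
  family; elongation rates (mm/day) drawn from a conditional normal
  with a configurable 4×4 trait correlation (validated positive
  semi-definite), by default weakly positive with density, weakly
  negative with emergence day and with each other;
* year-1 survival on the logit scale:
  intercept 0.91 (exp. 1) / 0.57 (exp. 2), treatment offsets
  (−0.25 mid/late drought, +0.15 late drought), and the headline
  selection regime $\beta_{ED} = -0.30$, $z^2$ coefficient
  $-0.15$ (a stabilizing optimum at $z = -1$, i.e. about one SD
  *earlier* than the mean emergence date) and
  $\beta_{SD} = +0.25$ — effect sizes of the order routinely reported
  for juvenile viability selection, large enough to be real and small
  enough to be hard;
* later-year conditional survival high and trait-independent
  (logit 4.09 / 3.68), so that roughly 94% of all deaths fall in the
  emergence year while overall mortality centers on ≈36% /
  ≈46%;
* survivor height normal around 260 mm / 270 mm (SD 70 mm) with
  treatment offsets and elongation-rate effects (+25 mm per SD of
  early rate, −8 mm per SD of late rate, −6 mm per SD of emergence
  day);
* random intercept SDs: block 0.28, family 0.20, row-plot 0 (the
  row-plot component is deliberately negligible).

Every dataset can be exported with its `truth_record`, and the
recovery tests close the loop: fixed-effect gradients and the family
variance component are re-estimated within Monte-Carlo error, and the
stepwise pipeline re-identifies the stabilizing regime on emergence
date in ≥90% of replicates at the design's scale.

**What the generator does not emulate** — and hence what passing tests
do not demonstrate about real field data: spatial autocorrelation
within beds, seed predation, weather-driven hazard variation within
seasons, non-normal height distributions, correlated random effects
across groupings, and selection acting through the invisible fraction.

## Numerical choices

* Fixed fits: exact IRLS (`glm.fit`, tolerance $10^{-10}$, up to 200
  iterations) on the stacked design plus closed-form least squares;
  rank-deficient model matrices drop aliased trailing columns with a
  warning, and df counts retained columns only.  Fitted probabilities
  within $10^{-7}$ of 0/1 raise a separation warning and flag the fit.
* Mixed fits: inner Newton with step-halving (ascent guaranteed) to
  gradient tolerance $10^{-9}$; outer L-BFGS-B with log-SD bounds
  $[\log 10^{-6}, \infty)$; deterministic starts (fixed-fit
  coefficients, residual-moment $\sigma$, group SD 0.25).
* LRTs: statistic clipped to 0 within tolerance; a negative statistic
  beyond tolerance is an error instructing a tighter refit, never
  silently truncated.  Identical models give statistic 0, p = 1.
* Tie-breaks in stepwise: smallest p wins; exact ties resolve by
  candidate order.
* Test problem sizes (the package's own choices): oracle checks on
  20–25-record toys; calibration at 1,000 null simulations of n = 300;
  recovery at ≈2,000 individuals × 100 replicates; stepwise recovery
  at ≈2,000 × 200 replicates.

## Known limitations

* Only linear chains with one terminal normal node — no branching
  graphs (e.g. reproduction counts), matching the scope of early
  life-history data.
* The shared-coefficient layout across Bernoulli nodes is an analysis
  choice; when selection acts only in one year, the shared coefficient
  is an information-weighted compromise (use `by_node = TRUE` to see
  per-year gradients).
* Laplace, not adaptive quadrature, for the integrated likelihood;
  fine at the design's cluster sizes, biased for very small clusters.
* Predictions condition on random effects at zero (their mode); no
  population-averaged (marginalized) predictions.
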