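---
title: "Joint Bayesian spatial modelling of cardiometabolic survey outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint Bayesian spatial modelling of cardiometabolic survey outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomap)
```

## The problem

National health surveys are designed for national inference, yet health
planning needs prevalence estimates for much smaller administrative
units, many of which contribute a handful of interviews or none at all.
`cardiomap` implements a Bayesian small-area estimation pipeline for
four correlated binary cardiometabolic outcomes — diabetes (`dm`),
obesity (`ob`), hypertension (`ht`) and high LDL cholesterol (`ldl`) —
observed in survey microdata over an adjacency graph of provinces.  The
pipeline produces smoothed posterior prevalence estimates for every
province (sampled or not), national summaries, and *hotspot* flags
based on posterior exceedance probabilities.

## The model

Two submodels are run in the same MCMC chain.  They share no
parameters; the individual-level model supplies covariate effects and
the joint-outcome correlation, while the aggregated model drives the
prevalence maps.

**Individual level.**  For person $i$ in province $j(i)$ and outcome
$k = 1, \dots, K$:

$$y_{ik} \sim \mathrm{Bernoulli}(p_{ik}), \qquad
\mathrm{logit}(p_{ik}) = \beta_{0k} + \beta_{a,k}(a_i - \bar a)
 + \beta_{m,k} m_i + \beta_{am,k}(a_i - \bar a) m_i
 + \beta_{w,k} w_i + u_{j(i)k} + v_{j(i)k} + b_{ik},$$

with age $a_i$ centred at the sample mean, sex $m_i$ (1 = male), and
the survey weight $w_i$ normalised to mean 1 and entered as a covariate
(not as a design-based weight).  The area effects follow the BYM
convolution: $u_{\cdot k}$ is intrinsic CAR (ICAR) with precision
$\tau_{u,k}$ and $v_{jk} \sim N(0, 1/\tau_{v,k})$ is unstructured.  The
joint-outcome association is carried by an individual random vector
$b_i \sim N_K(0, \Sigma)$ — the standard BUGS-style realisation of
"correlated outcomes within the same individual".

**Aggregated (province) level.**  With $r_{jk}$ observed cases among
$n_j - m_{jk}$ non-missing outcome measurements:

$$r_{jk} \sim \mathrm{Binomial}(n_j - m_{jk}, \pi_{jk}), \qquad
\mathrm{logit}(\pi_{jk}) = \alpha_{0k}
 + \alpha_{a,k}(\bar a_j - \bar a) + \alpha_{m,k} \bar m_j
 + \alpha_{am,k} (\bar a_j - \bar a) \bar m_j
 + \alpha_{w,k} \bar w_j + U_{jk} + V_{jk},$$

again with BYM effects $U, V$.  Posterior prevalence maps, national
summaries and exceedance probabilities are all functionals of
$\pi_{jk}$.  Provinces with no sample contribute no likelihood; their
$\pi_{jk}$ is predicted through the spatial prior, and their unknown
mean survey weight receives a restricted prior — normal around the
global mean weight with a 10% coefficient of variation, truncated at
zero.

**The ICAR prior** is improper; up to a constant its log-density is
$\frac{J - C}{2}\log\tau - \frac{\tau}{2}\sum_{j \sim l}(u_j - u_l)^2$,
where $C$ is the number of connected components.  Propriety is enforced
by re-centring to a zero sum within each component at every sweep, with
singleton components pinned at zero and excluded from the rank term.
When the field is re-centred, the removed component mean is transferred
into the corresponding intercept; on a connected graph this is an exact
reparameterisation of the linear predictor (the vague intercept prior
makes the residual distortion negligible), and on disconnected graphs
the residual per-component adjustment follows the long-standing
`car.normal` convention.

**Priors.**  Fixed effects $N(0, 10^2)$; all precisions
$\mathrm{Gamma}(0.5, 0.0005)$; $\Sigma \sim
\mathrm{InvWishart}(I_K, K + 2)$.  All are configurable through
`prior_spec()`.

## Missing data

Missingness is assumed missing-at-random and handled inside the chain:
missing outcomes are parameters drawn each sweep from their exact
Bernoulli full conditionals; missing ages are updated by random-walk
Metropolis under a truncated-normal prior with empirical centre and
spread; missing sex indicators are drawn from their exact two-point
conditionals.  With zero missingness the imputation machinery consumes
no random numbers, so enabling it cannot change a draw — this is
asserted bitwise in the test suite.  The aggregated likelihood uses
only observed counts ($n_j - m_{jk}$ trials), so imputation widens
credible intervals where data are missing rather than inventing
precision; the LDL outcome, with 44% missingness, is the prominent
case.

## Posterior computation

The sampler is a hand-written Metropolis-within-Gibbs, because the
bespoke mechanics — ICAR constraint handling, imputation inside the
chain, and two submodels co-running — are the point of the exercise and
need to be explicit and testable.  Per sweep:

1. fixed effects: adaptive scalar random-walk Metropolis
   (Robbins–Monro scaling of the log step towards 0.44 acceptance,
   frozen at the end of burn-in);
2. eta-invariant *shift* moves exchanging mass between each intercept
   and the mean of its unstructured (and joint) random effects — the
   classic intercept/effect-mean confounding otherwise mixes very
   slowly;
3. ICAR fields: single-site Metropolis vectorised over graph-colour
   classes (sites within a colour class are conditionally independent),
   followed by per-component re-centring, plus blocked proposals along
   the three lowest-frequency Laplacian eigenvectors.  Smooth field
   components are the slowest directions of an ICAR posterior under
   single-site updating; the spectral moves restore mixing for
   long-range trends;
4. unstructured effects: vectorised single-site Metropolis;
5. precisions: conjugate gamma Gibbs; $\Sigma$: conjugate
   inverse-Wishart Gibbs given $b$; $b_i$: per-individual blocked
   random-walk Metropolis, vectorised over individuals;
6. imputation steps as above.

Random effects are initialised at damped empirical-logit residuals
rather than zero: an all-zero start makes the first conjugate gamma
draw see a zero sum of squares and collapse the field precisions to
enormous values from which single-site updates cannot escape.

Default run length is 3 chains of 20,000 iterations with 10,000
burn-in and thinning 5; reduced presets are used throughout the tests
(typically 2–3 chains of 2,000–4,000 iterations on surveys of
600–2,400 individuals over the 52-province geography), which the
convergence diagnostics (split-chain R-hat on national prevalences,
intercepts and precisions; effective sample sizes by Geyer's initial
positive sequence) show to be adequate for the reported functionals.
The R-hat pass threshold is 1.1.

## The synthetic survey generator

No microdata ship with the package; the generator is the test bed.  It
emulates the structure of a national cardiometabolic survey on an
elongated geography:

* 52 provinces on a latitude chain with a few chord edges; a single
  connected component;
* 4,800 individuals by default; 60% women; age truncated-normal
  46 (18.5) on 15–95 years;
* centre-heavy, non-proportional sampling: allocation follows a
  population curve with a capital-like peak, small sampled strata are
  oversampled to a floor of 1.2% of the sample, and six provinces are
  unsampled; survey weights are inverse sampling fractions with
  log-normal individual jitter, normalised to mean 1;
* a north–south linear gradient on the logit scale (−0.008, +0.012,
  +0.012, +0.010 per latitude rank for `dm`, `ob`, `ht`, `ldl`),
  scaled ICAR fields with precision 40 (typical marginal SD ≈ 0.16)
  and unstructured province effects with precision 12 (SD ≈ 0.29),
  and a joint individual effect with variance 0.25 and correlation
  0.3.  Together these reproduce province prevalence spreads of the
  size seen in real national surveys (e.g. obesity ranging roughly
  19–41% across provinces);
* missingness 44% on `ldl` and 2% elsewhere, MCAR by default with a
  missing-by-age MAR option;
* age effects 0.06, 0.02, 0.12, 0.04 logit/year and sex effects 0,
  −0.54, +0.40, 0 — values of the size reported for this class of
  outcomes.

Intercepts are *calibrated*: a fixed quadrature sample of 120,000
covariate/latent draws is used to solve, per outcome, for the intercept
making the expected unweighted mean over all provinces of the province
prevalence equal the targets 10.9, 30.0, 36.4 and 13.7%.  The unweighted
province mean is the national estimand used throughout (the mean of the
"global simulated parameters of all provinces"), and its ICAR component
is exactly zero under the sum-to-zero constraint, which makes the
calibration stable across realisations.  The ICAR field is scaled so
that the geometric-mean marginal variance equals $1/\tau$, keeping the
precision parameter interpretable on a chain-like graph whose raw
marginal variances grow towards the ends.

What the generator does **not** emulate: the multistage stratified
design (strata, PSUs, non-response adjustment), informative
missingness beyond the age-dependent option, measurement error in the
outcome definitions, and real covariate geography (education, income
enter only optionally).  Passing recovery tests on this generator
therefore demonstrates the estimation machinery, not robustness to
design features it does not contain.

## Hotspot detection

For each outcome a threshold $c_k$ is chosen — by default the median
over provinces of the posterior mean prevalence, with the national
mean and fixed user values as alternatives (the two defaults coincide
to rounding when the prevalence distribution is symmetric).  The
exceedance probability $q_{jk} = \Pr(\pi_{jk} > c_k \mid \text{data})$
is the fraction of posterior draws strictly above $c_k$, and a province
is flagged when $q_{jk} > 0.95$ (configurable; ties are not flagged).

Two properties are worth spelling out, because they shape what the
tests can assert.  First, detectability of a localised elevation
depends on the residual heterogeneity of the field: with a single
shared precision across provinces, a lone +1-logit outlier in an
otherwise tight field is *correctly* shrunk away by the posterior —
detection is only possible when the generator's heterogeneity matches
the realistic spread above.  Second, with a median threshold roughly
half the provinces lie near $c_k$, so the count of "false" flags under
a heterogeneous truth is dominated by threshold-estimation error
rather than by the exceedance machinery.  The specificity of the
machinery itself is therefore tested on a fully flat truth — no
gradient, no random effects and no covariate effects, so that even
compositional differences between provinces vanish — where any flag is
unambiguously false.

## Frequentist baseline

`pql_fit()` fits, per outcome, a logistic GLMM with a province random
intercept by penalised quasi-likelihood (Breslow–Clayton working
response with an REML variance solve), using listwise deletion, Wald
intervals, and no prediction for unsampled provinces.  At zero
between-province variance it collapses to ordinary logistic
regression, which the tests verify against a direct GLM fit; under
weak spatial structure its fixed effects agree with the Bayesian
posterior means within two posterior SDs.

## Numerical conventions and edge cases

* Bernoulli likelihoods are computed on the log scale
  (`y * eta - log(1 + exp(eta))` with a stable `log1pexp`), so linear
  predictors of magnitude 800 remain finite.
* `icar_logdensity()` uses the fixed constant convention shown above
  (no $2\pi$ terms) and requires per-component zero sums to `1e-8`.
* Exceedance uses a strict inequality; `c = 0` gives probability 1.
* Degenerate inputs: provinces with `n = 0` contribute zero aggregated
  likelihood; an all-zero outcome column keeps the chain finite (the
  stable link prevents overflow); a single sampled area pins the PQL
  variance component at its boundary with a warning; constant chains
  yield `ESS = 0` and `R-hat = Inf`, both with warnings.
* All random number use is seeded: one seed per chain derived from a
  base seed, and generator functions take explicit seeds.  Identical
  configuration and seed give byte-identical outputs end to end.

## Design choices that were genuinely open

* **Scaled ICAR in the generator** (geometric-mean marginal variance
  $1/\tau$): keeps variance targets geography-independent.
* **MCAR as the default missingness** with a MAR-by-age option: the
  realized mechanism in surveys of this kind is unknown; MCAR is the
  cleaner default for calibration studies.
* **Parameter-separate submodels co-run in one chain**: the individual
  and aggregated models are distinct models of the same survey; running
  them in one chain reproduces the analysis design without asserting a
  sharing of parameters that was never claimed.
* **Pin-at-zero for singleton components** of the adjacency graph, and
  their exclusion from the ICAR rank term.
* **Hotspot cutoff 0.95**: the field convention for exceedance-based
  flagging.

## Known limitations

Random-walk Metropolis on strongly coupled hierarchical posteriors
mixes slowly for the precision parameters (R-hats above 1.1 on
$\tau$'s in short runs are common even when prevalence functionals are
stable); the diagnostics report makes this visible rather than hiding
it.  The aggregated model's ecological covariates (province mean age,
percent male) can absorb genuine spatial signal in small samples.  The
PQL baseline inherits the known downward bias of penalised
quasi-likelihood for binary data with small cluster sizes.
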