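---
title: "Bayesian linear and threshold animal models with animalgibbs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian linear and threshold animal models with animalgibbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(animalgibbs)
```

## The models

`animalgibbs` estimates variance components and genetic parameters for
continuous and ordinal traits recorded on pedigreed animals, the setting of
carcass evaluation in small-ruminant breeding: a few hundred recorded
goats, a relationship matrix covering several hundred ancestors, body
condition and marbling scored on 5- or 6-point scales, and continuous
anchor traits (ultrasound ribeye area, sternal fat thickness, hip height,
leg perimeter, body weight).

The linear animal model is

$$y = X\beta + Z\alpha + e, \qquad
  \alpha \mid A, \sigma_a^2 \sim N(0, A\sigma_a^2), \qquad
  e \sim N(0, I\sigma_e^2),$$

where $A$ is Wright's numerator relationship matrix and $\alpha$ holds one
additive genetic value per pedigree animal, observed or not. Fixed effects
are the contemporary group (farm x birth year x sex), collection year, age
class and doe category. Heritability is
$h^2 = \sigma_a^2 / (\sigma_a^2 + \sigma_e^2)$.

For an ordinal trait with $K$ categories the same linear model is placed on
an unobserved liability $U$; the observed score is $j$ when
$t_{j-1} < U \le t_j$ for thresholds
$-\infty = t_0 < t_1 < \dots < t_K = \infty$, so

$$\Pr(y_i = j) = \Phi\!\left(\frac{t_j - \eta_i}{\sigma_e}\right) -
                 \Phi\!\left(\frac{t_{j-1} - \eta_i}{\sigma_e}\right).$$

The two-trait model pairs one ordinal and one continuous trait with
residual covariance $R_0$ and additive covariance $G_0$
($y \sim N(X\beta + Za,\, R_0 \otimes I)$,
$a \sim N(0,\, G_0 \otimes A)$); the genetic correlation is
$r_g = G_{0,12} / \sqrt{G_{0,11} G_{0,22}}$.

## Sampling scheme

All three samplers are single-site Gibbs with residual updating, the
memory-light scheme of the classical Gibbs-sampling programs for animal
models: each location effect is redrawn from its scalar normal full
conditional and the residual vector is updated in place; variances come
from scaled inverse chi-square full conditionals whose scales are the
quadratic forms $\alpha' A^{-1} \alpha$ and $e'e$; in the two-trait model
$G_0$ and $R_0$ come from inverse-Wishart conditionals. Two deliberate
deviations from the plainest scheme:

* **Breeding values of the two traits are drawn jointly per animal** in
  the bivariate sampler (a 2x2 solve per animal). Trait-at-a-time updates
  freeze when $|r_g|$ is large — the conditional of one trait's value given
  the other approaches a point mass — and we observed chains ratcheting
  onto the $|r_g| = 1$ boundary and staying there. The joint draw keeps the
  pair mobile at any correlation.
* **Liabilities are drawn by inverse-CDF truncated-normal sampling with
  complementary-tail evaluation** (the upper-tail CDF is used when the
  interval lies right of the mean), because cycles routinely visit
  intervals several standard deviations from the current linear predictor
  and the naive formula collapses to the bound there.

The A-inverse never forms dense $A$: inbreeding coefficients come from the
Meuwissen-Luo ancestor-tracing algorithm and the Henderson/Quaas rules add
$1/d_i$ contributions with Mendelian-sampling variance
$d_i = 0.5 - 0.25(F_s + F_d)$. The dense tabular $A$ exists as
`makeA()` for validation and small pedigrees.

## Identification of the liability scale — why two thresholds are fixed

A probit liability with estimated thresholds has one location and one scale
non-identifiability. The location is absorbed by fixing $t_1 = 0$ (the
intercept is free). For the scale, the textbook choice of fixing
$\sigma_e^2 = 1$ turned out to be insufficient *when all remaining
thresholds are sampled*: the configuration (liabilities, effects,
thresholds, $\sigma_a^2$) can then inflate jointly while the categorical
fit only sharpens, and with flat variance priors nothing penalises the
inflation — the posterior is improper and chains drift without bound (we
observed $\sigma_a^2$ passing 500 with thresholds at 35 within 60,000
cycles on 500 records). `animalgibbs` therefore pins the scale with **two**
fixed thresholds, $t_1 = 0$ and $t_2 = 1$, and estimates $\sigma_e^2$
(for $K \ge 3$). Records in the first two categories then anchor the unit
of the liability axis. Reported heritabilities are
$\sigma_a^2/(\sigma_a^2 + \sigma_e^2)$ and are invariant to the scale
convention, so they are directly comparable with analyses that fix
$\sigma_e^2 = 1$ instead.

Binary traits have no second interior threshold, so $\sigma_e^2$ stays
fixed at 1 and nothing in the likelihood caps the separation direction:
with an additive value per recorded animal, pushing all effects and
$\sigma_a^2$ upward fits any binary pattern arbitrarily well. A proper
prior on $\sigma_a^2$ is therefore *required* for $K = 2$ (the sampler
refuses flat priors); the default is weakly informative
(scaled inverse chi-square, 4 df, scale 0.25, prior mean 0.5, i.e. a
liability heritability around 1/3). Even so, variance components of binary
traits mix poorly across scales with single-site updates and should be
interpreted cautiously; the package's validated recovery cases are
$K \ge 3$. A marginal Metropolis update of $\sigma_a^2$ with the breeding
values integrated out would remove the limitation but is outside the
present sampling scheme.

## Priors

* Location effects: flat. This requires a full-column-rank $X$, so the
  design builder uses a global intercept with drop-first (treatment)
  coding for every factor and removes aliased columns with a warning.
* Linear-model variances: improper flat on $(\sigma_a^2, \sigma_e^2)$
  (scaled inverse chi-square with $\nu = -2$, scale 0), matching the
  uninformative-prior convention of the Gibbs-sampling programs this
  package mirrors.
* Threshold-model residual variance ($K \ge 3$): weakly proper scaled
  inverse chi-square, 3 df, scale one third of the phenotypic-scale
  estimate implied by the initial threshold spacing (so the prior mean is
  that phenotypic estimate). With latent responses a flat prior has a
  second defect besides the inflation direction: all augmented residuals
  can deflate jointly, giving a density spike at $\sigma_e^2 = 0$; three
  pseudo-records remove it while leaving a few hundred real records in
  charge.
* Bivariate $G_0$ and $R_0$: inverse-Wishart with df $p + 3 = 5$ and
  diagonal scale centred at the starting values (half the phenotypic
  variance per trait; 1 for the liability residual), about two effective
  records per matrix. The minimal-proper choice (df $p+1$, scale
  $10^{-6} I$) implies a uniform prior on the correlation, and with it the
  $|r_g| = 1$ boundary is numerically absorbing: a near-singular $G_0$
  makes its inverse dominate the breeding-value conditionals, the data
  lose their grip, and the next scale matrix is again near-singular. The
  df $p+3$ prior's correlation density vanishes at $\pm 1$, which repels
  the boundary at the cost of mild shrinkage.

## Chain design and diagnostics

The production configuration mirrors the long chains used in this
literature: 2,000,000 cycles, 1,000,000 burn-in, retaining every 250th
draw — 4,000 retained samples; `gibbs_config()` enforces the arithmetic.
Validation and the package's own tests use scaled-down chains (8,000 to
20,000 cycles on 150-1,000 records), sizes at which the recovery
experiments below stabilise.

`posterior_report()` gives, per monitored parameter, the posterior mean,
median, equal-tail 95% credible interval (equal-tail rather than HPD, for
reproducibility; the level is configurable), the Monte Carlo error
$\sqrt{\widehat{\mathrm{var}}(\text{chain})/n}$, and the Geweke Z
comparing the first 10% to the last 50% of the chain with window variances
from 20 non-overlapping batch means. The report also flags whether adding
the Monte Carlo error to a posterior mean leaves it unchanged at the
second decimal place — the informal convergence confirmation used
alongside the Geweke test in this literature.

Model comparison uses DIC ($\bar D + p_D$, observable-scale deviance, with
$p_D$ the mean deviance minus the deviance at the posterior means) as the
primary criterion, and a harmonic-mean Bayes factor (log-sum-exp
stabilised) as the secondary one — the harmonic-mean estimator is the
simplest defensible choice from Gibbs output but is high-variance, which
is why DIC leads. For the linear-vs-threshold contrast on ordinal codes
the linear model's deviance uses the Gaussian likelihood of the codes, the
threshold model's the probit category probabilities, both on the
observable scale so the two are comparable.

## The synthetic-data generator

`sim_config()` defaults emulate the structure the analysis is meant for: a
793-animal random-mating pedigree (145 founders, four generations), 385
recorded animals, a 5-category body-condition score (liability $h^2$
0.11) and a 6-category marbling score ($h^2$ 0.03), five continuous
anchors with the study-scale variance components (e.g. ribeye area
0.79/2.03, body weight 62.23/52.78), contemporary groups from 4 farms x 3
birth years x 2 sexes, and three-level collection-year, age-class and
category effects whose level contrasts sum to at most +/-0.5 residual SD —
estimable but not dominant. Breeding values come from gene dropping
(founders $N(0, G_0)$, descendants parent-average plus a Mendelian deviate
with variance $(0.5 - 0.25(F_s + F_d))\,G_0$), so inbreeding accumulates
exactly as $A$ says it should; ordinal traits are thresholded liabilities
whose category frequencies follow the configured target probabilities.

What the generator does *not* emulate: selection (matings are random),
maternal and permanent-environment effects, heterogeneous variances
across farms, missing-at-random patterns, or the real study's trait means.
Passing recovery tests therefore demonstrate correctness of the machinery
under the stated model, not robustness to the ways field data violate it.

## Numerical choices and degenerate inputs

* Ordinal fits require every category observed at least once (merge
  sparse categories first) and at least two distinct categories.
* One record per animal per trait is enforced; there is no
  permanent-environment effect.
* Thresholds are initialised from normal quantiles of the observed
  cumulative frequencies mapped to the $t_1 = 0, t_2 = 1$ scale;
  variances start at half the phenotypic variance unless overridden.
* Non-positive-definite inverse-Wishart draws are retried with a jittered
  scale (up to 10 times, counted and reported); non-finite variance draws
  abort with the cycle index.
* Category probabilities are floored at $10^{-300}$ inside deviance
  computations to keep logs finite.
* `geweke()` refuses windows under 20 draws and zero-variance windows;
  `summarize_chain()` reports `NA` for the Geweke columns in those cases.

## Known limitations

* Binary-trait variance components: see above; supported but fragile by
  construction of the sampling scheme.
* Very small data sets (records fewer than location effects, e.g. 150
  records against ~260 effects) leave the threshold model's variance split
  weakly identified; chains then wander widely and DIC comparisons are not
  meaningful at that size.
* In simulation at the study's own scale, the single-trait threshold
  posterior mean of a weak-signal liability heritability is inflated by
  the boundary pile-up of $\sigma_a^2$ under its flat prior, and the
  two-trait estimate (which carries a weakly informative prior) typically
  sits *below* the single-trait one. The field observation that two-trait
  analyses raise heritability estimates is a property of particular data
  sets, not a general property of these estimators, and the package's
  acceptance suite records it as such.
* The harmonic-mean marginal likelihood is known to be unstable; treat
  Bayes factors as directional evidence only.

## A worked example

```{r example, eval = FALSE}
st <- simulate_study(sim_config(), seed = 42)
Ainv <- makeAinv(st$pedigree)
mm <- build_design(st$records, st$pedigree, trait = "bcs")
cfg <- gibbs_config(n_cycles = 20000, burn_in = 10000, thin = 10, seed = 1)
thr <- gibbs_threshold(mm, Ainv, K = 5, cfg)
lin <- gibbs_linear(mm, Ainv, cfg)
posterior_report(thr, c("sigma_a2", "sigma_e2", "h2"))
compare_models(lin, thr)
```

The README shows the numbers this prints and how to reproduce the
package-level acceptance quantities with `scripts/acceptance.R`.
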