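---
title: "Modeling distorted sex ratios at birth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling distorted sex ratios at birth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In several Asian and Caucasus populations, the sex ratio at birth (SRB) rose
far above its natural level of about 105 male births per 100 female births
during the 1980s and 1990s, even while stated son preference was declining.
The reconciliation of these seemingly contradictory trends runs through
three micro-level preconditions for prenatal sex selection, often summarized
as *ready, willing, and able*: a woman resorts to sex-selective abortion only
if she wants a son (willing), has access to prenatal sex-determination
technology (able), and faces a *fertility squeeze* — the pressure to
reconcile son preference with a small family — that makes abortion
preferable to a further birth (ready).

`srbsim` implements an individual-based yearly microsimulation of this
mechanism, together with the machinery needed to use it seriously:
synthetic rate-schedule generation, RMSE calibration on a Latin hypercube
design, regression-metamodel interpolation of the fit surface, and ANOVA
variance decomposition for sensitivity analysis.

# The model

## Agents and demographic regime

Each agent carries an id, sex, birth year, and age (0–50 completed years);
female agents additionally carry son preference $sp \in \{0, 1\}$, parity
$p$, living sons $so$, technology access $tech$, and an abortion count
$ab$. Children record their mother's id, so a son's death can feed back on
her reproductive behavior. Agents die by sex- and age-specific yearly death
probabilities $q(x, s, t)$ up to age 50 and leave the simulation at 50; the
model's focus is reproduction and the child/young-adult mortality that
shapes it, not old-age dynamics.

One tick is one calendar year. Within a tick the order of events is:

1. **technology update** — each woman 15–49 draws a uniform against the
   prevailing ability level;
2. **son-preference assignment** (see below);
3. **mortality** — resolved before conception, so a woman whose son dies in
   year $t$ can respond the same year;
4. **conception, abortion decision, birth**;
5. **aging** and retirement at 50; newborns enter at age 0.

## Willingness: son preference and stopping behavior

The population probability of wanting (exactly one) son is logistic in
calendar time,
$$sp(t) = \operatorname{logit}^{-1}\!\big(\delta_0 + \delta_1 (t - t_0)\big),$$
fitted through survey proportions of women stating they must have a son.
The packaged default solves the curve exactly through anchors of 48% in
1985 and 26% in 1994 (reference year 1980).

Women with unmet son preference practice differential stopping behavior
(DSB): their period age-specific birth hazard $h^*(x, t)$ is expanded
proportionally,
$$h(x,t) = \begin{cases} h^*(x,t) & sp = 0,\\
h^*(x,t)\,(1+\gamma) & so < sp,\\
h^*(x,t)\,(1-\alpha) & so \ge sp,\ sp \neq 0,\end{cases}$$
with $\gamma$ the son-preference intensity and $\alpha$ the birth-risk
reduction once the preference is met. Hazards are used as per-year
conception probabilities (discrete-time Bernoulli per tick); the expanded
hazard is capped at 1, a choice the source formulation leaves open.

## Ability: logistic technology diffusion

Access to prenatal sex determination follows the classic logistic
diffusion-of-innovations curve
$$\mathrm{Ability}(t) = \frac{e^{\rho (t - \phi)}}{1 + e^{\rho (t-\phi)}},$$
with model time $t = 0$ at the simulation start, diffusion rate $\rho$, and
inflection step $\phi$ (where adoption passes 50%).

## Readiness: the fertility squeeze

Conditional on willingness ($sp > so$) and ability ($tech$), the
probability of aborting a female conception is the ratio of the woman's
parity to prevailing fertility levels, scaled and capped:
$$\mathrm{Readiness}(t) = \begin{cases}
\min\{1, \beta / \mathrm{TFR}(t-1)\} & p = 0,\\
\min\{1, p\,\sigma / \mathrm{TFR}(t-1)\} & p \ge 1.\end{cases}$$
$\mathrm{TFR}(t-1)$ is the *model-generated* total fertility rate of the
previous tick, so fertility decline endogenously strengthens the squeeze;
the first tick uses the schedule TFR, and a degenerate year with no
measurable fertility (possible only in very small populations) falls back
to the schedule value. Sex is determined at conception (male with
probability 0.5122, a natural SRB of 105) before the abortion decision;
male fetuses are never aborted, and at most one conception event occurs per
woman per year.

## Parameters

| parameter | meaning | units / scale | range | default |
|---|---|---|---|---|
| $\gamma$ | son-preference intensity (DSB expansion) | proportional | [0, 1] | 0.20 |
| $\alpha$ | birth-risk reduction when preference met | proportional | [0, 1] | 0.075 |
| $\sigma$ | squeeze scale, parity $\ge 1$ | — | [0, 2.5] | 1.7 |
| $\beta$ | squeeze scale, parity 0 | — | [0, 0.5] | 0.2 |
| $\rho$ | technology diffusion rate | per year | [0, 2] | 0.5 |
| $\phi$ | diffusion inflection | model years | [0, 20] | 7 |

The defaults are the parameter combination that calibration studies of the
South Korean transition identify as best-fitting; the ranges are the
theoretically plausible box over which designs are drawn.

# Design choices on genuinely open points

**Son-preference assignment.** Whether an agent's $sp$ persists across
years or tracks the period curve is the single most consequential
under-specification in this model family. By default `srbsim` re-draws
$sp$ annually for every woman 15–49 with probability $sp(t)$, so the
population proportion willing tracks the fitted period curve — observed
period proportions fall faster (about 45% to 25% within a decade) than
cohort replacement alone could deliver. A cohort mode (assignment once at
age 15, `sp_mode = "cohort_fixed"`) is available for comparison.

**Technology as an absorbing state.** The textual formulation re-draws a
uniform each tick, which under a rising ability curve is statistically
close to absorbing acquisition. The default here is absorbing (once able,
always able), matching the saturation notion of diffusion;
`tech_mode = "redraw"` gives the literal per-tick re-draw. Constant-ability
counterfactuals (`ability_override`) force the re-draw mode, since holding
the *population share* at, say, 50% is their point.

**Burn-in.** Simulations start 35 years before the period of interest
(default) from a stable-population pyramid implied by the first year's
rates, and run plain mortality and fertility — no stopping behavior, no
abortion — so women entering the period carry realistic parity histories.
A `dsb_in_burnin` flag exists for sensitivity checks.

**RMSE denominator.** The model-fit measure divides the summed squared
yearly SRB errors by the *year span* (`end - start`, 30 for a 1980–2010
window) although 31 yearly terms enter the sum. This follows the printed
convention of the fit measure literally; the off-by-one is deliberate and
documented rather than silently corrected.

**Sequential ANOVA.** Metamodel variance shares use type-I (sequential)
sums of squares with a fixed, documented term order — main effects
$\gamma, \alpha, \sigma, \beta, \rho, \phi$, then quadratics, then pairwise
interactions — with parameters centered on their design means before
squaring. Shares are non-negative and sum with the residual share to 100%.

**Design scoring and common random numbers.** Design evaluation shares the
run-index seed (and the parameter-free burn-in population) across design
points, so point comparisons are paired and identical parameter rows score
bit-identically. Two scores are available: the mean of per-run RMSEs
(default), and `score = "rmse_of_mean"`, which scores the point's
ensemble-mean SRB trajectory. At desk-scale populations the per-run score
carries a Monte Carlo noise floor that *differs across design points*
(points generating more births have less yearly SRB noise), which can
out-rank genuinely better-fitting regions; ensemble-mean scoring shrinks
this floor by the run count and discriminates parameter regions much more
sharply. Design points whose trajectories leave the SRB undefined in a
window year (no female births, possible under extreme abortion regimes in
small populations) score infinite and rank last.

# The synthetic-data generator

`synthesize_schedule()` emulates the input regime the simulation assumes —
a population moving through the fertility transition:

* a fixed unimodal fertility age shape (beta-density over ages 15–49,
  peaking near age 25), scaled so the schedule TFR interpolates
  log-linearly between its endpoint values (default 2.8 falling to 1.2);
* yearly death probabilities with an infant/child component, a floor, and a
  Gompertz adult component, the male profile 15% higher, the overall level
  declining monotonically (the `e0_proxy` knob is the final/initial level
  ratio, default 0.35);
* deterministic output given arguments, so fixtures never need to be
  shipped.

`synthesize_initial_population()` draws the starting pyramid from the
stable age/sex structure implied by the first-year rates (female dominant
Leslie eigenvector, with the fertility row discounted by maternal survival
to match the within-tick order of mortality before conception; males scaled
by the sex ratio at birth and relative survivorship).

What the generator does **not** emulate: migration (also absent from the
model), mortality above age 50, age-pattern shifts of fertility over time
(the age shape is fixed; real transitions also postpone or advance
childbearing), marriage and birth-interval structure, regional
heterogeneity, and period shocks. Tests passing on synthetic schedules
therefore validate the mechanics and internal consistency of the model,
not its fit to any particular country; reproducing published
country-specific trajectories (e.g. the South Korean SRB peak near 114 and
its counterfactual TFR gap of about 0.05 around 1990–1995) requires
user-supplied schedules derived from UN World Population Prospects data.

# Numerical and reproducibility notes

* All randomness flows from a single base seed; replicate $r$ runs on
  `seed + r`, and design evaluation offsets the period stream from the
  burn-in stream. Identical configuration and seed give bit-identical
  ensembles.
* SRB is reported missing for a year with zero female births; moving
  averages skip missing values; ensembles summarize with empirical
  2.5/5/95/97.5 percentiles.
* 5-year age-group input rates are expanded constant-within-group by
  default (exactly preserving group means); a mean-preserving linear
  graduation is available. Period rates are treated as constant within any
  grouping the user supplies.
* The full-grid metamodel interpolation defaults to 7 levels per parameter;
  the grid resolution is a user choice, not a model constant.

# Problem sizes

The package's own test suite exercises the model at desk scale, chosen so
the full suite runs in minutes on one CPU: ensembles of 20,000 agents with
20 replicates for distributional checks (the natural-SRB property uses a
10-year window and a 3-binomial-SD criterion), and self-calibration on a
224-point Latin hypercube with 10 runs per point at 20,000 agents, scored
against a 20-replicate simulator-generated reference with known parameters
(the true parameter set, evaluated as a candidate, must rank in the top
decile). Production-scale runs of the kind used for published calibrations
(populations of 10^6, hundreds of runs) are a configuration choice, not a
different code path.

# Known limitations

* The abortion decision admits no retry within a year and no male-fetus
  abortion; sex-selection technologies other than abortion are out of
  scope.
* Twins and birth intervals below one year are not modeled.
* Son preference is dichotomous (desire for exactly one son); desire for
  several sons is represented only indirectly through the son-mortality
  feedback.
* No social-network or regional feedback: the model family is known to
  under-predict the sharpness of the South Korean turnaround of the
  mid-2000s, plausibly for exactly this reason.
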