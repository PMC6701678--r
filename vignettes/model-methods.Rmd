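---
title: "Modelling the lifetime cost-effectiveness of adolescent physical-activity interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the lifetime cost-effectiveness of adolescent physical-activity interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpasim)
```

## The decision problem

School-based programmes can raise adolescents' moderate-to-vigorous physical
activity (MVPA), but their health and cost consequences accrue over decades:
more active adults face lower risks of coronary heart disease (CHD), stroke,
heart failure, type 2 diabetes, and breast and colorectal cancer. `mvpasim`
implements an age- and sex-stratified Markov cohort model that converts a
change in adolescent MVPA into lifetime disease risk, mortality, discounted
costs (NHS/PSS perspective, 2013-14 GBP) and quality-adjusted life-years
(QALYs), and summarises value for money as incremental cost-effectiveness
ratios (ICERs), net monetary benefit (NMB) and cost-effectiveness
acceptability curves (CEACs).

A closed cohort (default 10,000; half male) enters healthy at age 16 and is
followed for 65 annual cycles to age 81. The state space has 11 mutually
exclusive states: four healthy activity levels — inactive, low, moderate,
high, defined on weekly MVPA minutes as the contiguous half-open intervals
$[0,30)$, $[30,150)$, $[150,421)$, $[421,\infty)$ — six chronic disease
states, and dead. Disease states are absorbing until death: there are no
between-disease transitions and no comorbidity, a deliberate simplification
that likely understates the benefit of activity (e.g. diabetes raising
cardiovascular risk is not captured).

## Transition probabilities

Population incidence rates $r(d, a, s)$ (disease $d$, age $a$, sex $s$) are
converted to annual probabilities $p = 1 - e^{-r}$ and deflated to the
inactive reference group using the population activity mix $w_L$ and the
relative risks $RR_L$ of each level:

$$p_I = \frac{p_{\text{all}}}{\sum_L w_L \, RR_L}, \qquad p_L = p_I \, RR_L .$$

Re-aggregation $\sum_L w_L p_L = p_{\text{all}}$ recovers the population
probability exactly, which the test suite asserts to $10^{-12}$. The weights
$w_L$ are the bundle's activity prevalence for the age band containing $a$.

Competing transitions out of a healthy state (six diseases plus other-cause
death) are composed on the hazard scale: each cause-specific probability
becomes a hazard $h_c = -\log(1 - p_c)$, hazards add, the total leaving
probability is $1 - e^{-\sum h_c}$, and it is apportioned across causes by
hazard share. This keeps every row of the transition matrix stochastic
without ad-hoc truncation, at the cost of assuming conditionally independent
causes within a cycle. Other-cause mortality is the all-cause life-table rate
minus the rate attributable to the six modelled diseases, floored at zero
(with a data-quality warning when the floor binds).

A fixed fraction of CHD, stroke and heart-failure events is immediately
fatal; those transitions route directly to dead in the event cycle and are
charged the fatal-event cost once. Survivors face disease-specific mortality
by years since the event ("tenure"), tracked explicitly by the engine:

* **CHD and stroke** — a first-year case-fatality probability, then the
  background (all-cause life-table) probability scaled by a post-event
  multiplier (2.0 for stroke). The multiplier acts on the hazard scale,
  $1 - (1 - p)^m$, so probabilities can never exceed 1 at high ages; a
  `multiplier_scale = "naive"` setting switches to $p \times m$ (capped) for
  sensitivity analysis.
* **Type 2 diabetes** — background mortality scaled by a hazard ratio.
* **Heart failure** — an annual case-fatality schedule (years 1-10, last
  value carried forward), combined with background mortality on the
  complement scale.
* **Cancers** — 5-year net survival $S_5$ annualised to a constant excess
  risk $1 - S_5^{1/5}$ in years 1-5 after diagnosis and zero thereafter,
  added to background mortality.

## Activity dynamics

All movement between activity levels comes from additive shifts in weekly
MVPA minutes. Because only the category shares are observed, MVPA is assumed
uniform within each level's interval, so a shift of $\Delta$ weekly minutes
moves the fraction $\min(1, \Delta / W)$ of a level of width $W$ to the
adjacent level. The unbounded high level absorbs promotions; for demotions it
is assigned a bounded proxy width (default 419 minutes, mirroring the
moderate width; configurable via `settings$high_level_width`).

The control arm starts from the adolescent (16-23) activity prevalence and
declines by 6.5 (male) or 5.5 (female) weekly minutes per year through age
23 — seven annual steps whose total, 45.5/38.5 weekly minutes, equals the
reported 6.5/5.5 min/day fall from adolescence to adulthood. At ages 24, 45
and 65 the distribution is re-targeted to the adult, middle-age and
retirement band prevalence; between boundaries it is held constant, since
the prevalence data carry no finer age signal. The overlap between the
adolescent decline and the first band boundary is resolved by applying the
per-year decline through age 23 and the re-targeting at 24.

The intervention adds $7 \times \delta \times m_k$ weekly minutes on top of
the control distribution in cycle $k$, where $\delta$ is the effect in
min/day (4.84 after-school; 7.0 multicomponent) and
$m_k = (1-d)^{k - k_0}$ is the residual effect after $k_0$ sustained years
(default 1) at decay rate $d$ (base case 50%/year). Implementing decay on
the uplift minutes — rather than on promoted shares — matches the additive
semantics of the effect estimates and makes the arms converge as $m_k \to 0$:
under the base case the maximum share difference between arms falls below
$10^{-3}$ by year 8, and with $d = 1$ the arms are identical from year 2.
With $d = 0$ the uplift persists for life.

Members who enter a disease state retain no activity bookkeeping; the
disease utility and cost dominate, and activity is modelled for the healthy
only.

## Rewards, half-cycle correction and discounting

Healthy members accrue the baseline utility of their age group and activity
level (a 6x4 grid, non-decreasing from inactive to high within each age
group); disease members accrue the disease utility and the first-year or
subsequent-year cost according to tenure; dead accrues nothing. Cancer costs
are weighted per-case treatment costs and are charged as first-year costs in
the year of diagnosis (subsequent-year cancer cost zero); type 2 diabetes
carries the same annual cost in every year. No fatal-event cost is published
for heart failure, so it defaults to zero (the field exists and can be set).

State rewards use a half-cycle correction: each cycle credits
$\tfrac{1}{2}(\text{start} + \text{end})$ occupancy at the annual reward
rate, the trapezoid approximation under mid-cycle transitions. Point
expenditures are not half-cycle corrected: fatal-event costs are charged per
fatal transition in the event cycle, and the intervention cost (£51
after-school, £190 multicomponent per participant) is charged to the whole
cohort at delivery (cycle 0), undiscounted. Cycle $k \ge 1$ rewards are
discounted by $(1.035)^{-k}$; whether the first cycle is discounted is a
settings switch (`discount_first_cycle`, default on), since either
convention is found in practice.

The engine is a deterministic cohort expectation (fractional persons), not a
microsimulation; parameter uncertainty is handled by the probabilistic
layer. Its correctness anchors are (i) exact population conservation at
every cycle — the model's internal-validity check, asserted to $10^{-6}$
persons in every tested scenario — and (ii) agreement to $10^{-10}$ with an
exhaustive path-enumeration oracle on a three-state, five-cycle reduction
(single disease, single activity level), which exercises tenure tracking,
the fatal split, half-cycle rewards and discounting end to end.

## Economics and probabilistic sensitivity analysis

Strategies are compared pairwise against no intervention on unrounded
per-person discounted totals: $\text{ICER} = \Delta C / \Delta Q$, with
dominance flagged when the signs disagree and "undefined" when
$|\Delta Q| \le 10^{-9}$ (a pure floating-point guard; increments are never
rounded). NMB is $\lambda Q - C$.

PSA follows the conventional distribution assignment: probabilities and
utilities are beta (method of moments,
$\alpha + \beta = m(1-m)/SE^2 - 1$), costs are gamma (shape $(m/SE)^2$,
scale $m/\text{shape}$ — with SE at 10% of the mean, shape is 100), and
relative risks, post-event multipliers and hazard ratios are lognormal with
log-SD $(\log hi - \log lo)/(2 \times 1.96)$ from their 95% CI. Intervention
effect sizes are mean differences that can legitimately be negative, so they
are sampled normally from their 95% CI (truncated at zero uplift) rather
than lognormally. Incidence curves are scaled by a beta draw of their
reference (age-40) rate; life-table rates and intervention unit costs are
held fixed, having no published uncertainty. Sampled baseline-utility grids
are re-sorted within each age group to preserve the monotone
inactive-to-high gradient. Zero-SE parameters collapse to their means, so a
bundle with no uncertainty reproduces the deterministic run exactly.

Each PSA iteration applies one joint parameter draw to **all** arms (common
random numbers), which removes sampling noise from the increments. The CEAC
reports, per threshold on a £0-50,000 grid, the fraction of iterations in
which a strategy's NMB strictly exceeds the comparator's (ties count as not
cost-effective); a `method = "best"` option gives the multi-way
"probability best" variant instead of the pairwise default.

## The synthetic parameter generator

The model's full epidemiological inputs (age-incidence curves, relative
risks, life tables, case fatality, activity prevalence) come from sources
that are not available as machine-readable tables, so `fixture_recipe()` /
`make_bundle()` generate seeded synthetic bundles with the same schema and
statistical shape, and every such bundle is flagged
`epidemiology_source: "synthetic"`. The defaults were chosen once for
UK-plausible magnitudes and are not tuned to reproduce any published result:

* **Mortality** — Gompertz-like all-cause rates $a e^{b \cdot \text{age}}$
  per sex (about 1.5 per 1,000 at 40 and 6% per year at 80), with 25%
  attributed to the six modelled diseases.
* **Incidence** — exponential age curves anchored at age 40 (e.g. CHD 2 per
  1,000 male person-years at 40, doubling roughly every 9 years; breast
  cancer essentially female-only), capped at 0.5, with a small seeded
  log-normal scale jitter per disease and sex so different seeds give
  different but equally plausible bundles.
* **Relative risks** — monotone non-increasing from inactive (reference, 1)
  to high (0.55-0.85 depending on disease), strongest for type 2 diabetes.
* **Activity prevalence** — inactivity rising from about 4% at 16-23 (self-
  reported inactivity below 30 MVPA min/week is rare in adolescence) to
  40-44% at 65+, with the high level shrinking correspondingly.
* **Post-event parameters** — case-fatality fractions 15-25%, stroke/CHD
  post-event multiplier 2, diabetes mortality hazard ratio 1.8 (1.5-2.2),
  5-year net survival 85% (breast) and 59% (colorectal), a declining 10-year
  heart-failure case-fatality schedule.

The generator emulates the *structure* of real inputs — age gradients, sex
differences, risk gradients, schema and units — but not secular trends,
cohort effects, regional variation, or correlated uncertainty between
parameters. Passing tests therefore demonstrate the correctness and
qualitative behaviour of the machinery (conservation, monotonicity, decay
ordering, convergence), not the numerical accuracy of any published ICER;
headline results computed on synthetic bundles are labelled as such. On the
default bundle the base case lands in an interpretable range (per-person
lifetime discounted QALYs about 21.1, after-school ICER about £10,000 per
QALY), and the qualitative orderings across decay rates and horizons match
what the deterministic structure implies: the cheaper intervention dominates
on value when effects persist, and ICERs deteriorate monotonically as decay
accelerates. Under zero decay the after-school programme becomes cost-saving
on the synthetic bundle (its lifetime disease-cost offsets exceed £51),
which ranks below any positive ICER in the decay ordering.

## Numerical and design choices

* The published activity categories leave integer gaps (149 to 150, 420 to
  421); they are implemented as contiguous half-open intervals so every
  non-negative MVPA value maps to exactly one level.
* The published baseline-utility grid lists "65-74" twice; the second row is
  treated as 75+, since monotone age coverage to 81 requires it.
* The baseline-utility grid has no published SEs; a nominal SE of 0.02 is
  used for sampling and can be overridden in the table.
* CHD post-event survival has no published structure in the text; it is
  given the same first-year-fatality-plus-multiplier form as stroke, with a
  synthetic default multiplier of 2.
* Probabilities are clamped below 1 by $10^{-15}$ before hazard conversion;
  disease-row death probabilities are capped at 1.
* The run settings (`default_settings()`) carry every tunable: cohort size
  10,000, ages 16-81, 3.5% discount, £20,000/QALY threshold, 2,000 PSA
  iterations, seed, high-level proxy width, convergence tolerance
  ($10^{-3}$ share difference), multiplier scale and discount convention.
* Test problem sizes: the full 65-cycle engine is exercised throughout; the
  PSA determinism and zero-SE checks use small iteration counts and 10-20
  year horizons, while parameter-moment recovery uses the full 2,000 draws;
  these sizes were chosen as the smallest that pin down each property.

## Worked example

```{r example, eval = FALSE}
bundle <- default_bundle()           # printed tables + synthetic epidemiology
base <- run_cohort(bundle)           # no intervention, lifetime
after <- run_cohort(bundle, "after_school")
icer(strategy_result(base), strategy_result(after))

psa <- run_psa(bundle, iterations = 500, seed = 1)
head(ceac(psa))
```

## Limitations

Beyond the synthetic epidemiology, the model inherits the structural limits
of its design: no between-disease transitions, no mental-health or
musculoskeletal outcomes, no sedentary-behaviour pathway, activity modelled
only for the healthy, cohort-level (not individual) MVPA trajectories, and
a single closed cohort entering at 16. Costs are 2013-14 GBP with no
inflation machinery, and the NHS/PSS perspective excludes productivity and
social-care spillovers.
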