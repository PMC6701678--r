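# mvpasim

An age- and sex-stratified Markov cohort model for the lifetime
cost-effectiveness of physical-activity interventions delivered to
adolescents. A closed cohort of 10,000 healthy 16-year-olds is followed for
65 annual cycles to age 81 through 11 mutually exclusive health states —
four physical-activity levels defined on weekly moderate-to-vigorous
physical activity (MVPA: `[0,30)`, `[30,150)`, `[150,421)`, `[421,∞)`
min/week), six chronic diseases (coronary heart disease, stroke, heart
failure, type 2 diabetes, breast and colorectal cancer) and dead. The model
converts an intervention's MVPA uplift (min/day, decaying over time) into
disease and mortality risk via activity-specific relative risks, and
accumulates half-cycle-corrected costs (2013–14 GBP, NHS/PSS perspective)
and QALYs, both discounted at 3.5%/year.

It is written for health-economic modellers and public-health analysts who
want a scriptable, testable alternative to spreadsheet cohort models:
deterministic scenario analysis (decay rates, time horizons), probabilistic
sensitivity analysis (2,000-iteration Monte Carlo with beta/gamma/lognormal
parameter distributions), ICERs, net monetary benefit and
cost-effectiveness acceptability curves.

## The model in brief

* **Risk adjustment.** Population incidence `p_all` is deflated to the
  inactive group, `p_I = p_all / Σ_L w_L·RR_L`, and re-inflated per level as
  `p_L = p_I·RR_L`, so re-aggregation recovers the population probability
  exactly. Competing transitions (six diseases + other-cause death) are
  composed on the hazard scale, keeping transition rows stochastic.
* **Mortality.** A fraction of CHD/stroke/HF events is immediately fatal;
  survivors face first-year case fatality then a ×2 multiplier on background
  mortality (hazard scale); diabetes carries a mortality hazard ratio; HF an
  annual case-fatality schedule; cancers an excess risk `1 − S5^(1/5)` in
  the five years after diagnosis.
* **Activity dynamics.** An uplift of Δ weekly minutes promotes the
  fraction `min(1, Δ/width)` of each level (MVPA uniform within a level).
  Effects are sustained one year, then decay at 50%/year (base case).
  The control arm declines by 6.5 (boys) / 5.5 (girls) weekly minutes per
  year through age 23 and is re-targeted to adult prevalence at 24, 45, 65.
* **Economics.** `ICER = ΔC/ΔQ` from unrounded per-person totals vs no
  intervention; NMB `λQ − C`; CEAC as the fraction of PSA iterations with
  strictly higher NMB than the comparator (common random numbers across
  arms).

The epidemiological inputs (incidence curves, life tables, relative risks,
case fatality, prevalence) are **synthetic**: generated by a seeded fixtures
module with realistic UK-scale shapes and flagged
`epidemiology_source: "synthetic"` — the published point values (utility and
cost tables, intervention effects £51/4.84 min/day and £190/7.0 min/day) are
shipped as printed. See `vignettes/model-methods.Rmd` for the full account.

## Worked example

```r
library(mvpasim)
bundle <- default_bundle()    # printed tables + synthetic epidemiology
base  <- run_cohort(bundle)                  # no intervention, lifetime
after <- run_cohort(bundle, "after_school")  # +4.84 min/day, £51/participant
base
#> <pa_trace> strategy=no_intervention, 65 cycles
#>   discounted totals: cost GBP 29021435.04, QALYs 210901.662 (per person: 2902.14 / 21.0902)
icer(strategy_result(base), strategy_result(after))
#> <pa_econ> after_school vs no_intervention: dC = 48.61, dQ = 0.00469, ICER = 10374
```

A 16-year-old gains, on average, 21.09 discounted QALYs over the 65-year
horizon with no intervention; the after-school programme costs £48.61 more
per person net of disease-cost offsets and yields 0.0047 extra QALYs, an
ICER of about £10,400/QALY — cost-effective at the £20,000/QALY threshold.
Scenario analysis shows the decisive role of effect sustainability:

```r
scenario_table(bundle, strategies = "after_school")
#>      scenario        strategy   cost   qaly delta_cost delta_qaly  icer
#>     base_case    after_school 2950.8 21.095      48.61   0.004686 10374
#>       decay_0    after_school 2824.9 21.528     -77.25   0.437403    NA  (dominant)
#>      decay_33    after_school 2949.1 21.098      46.99   0.007630  6158
#>     decay_100    after_school 2952.1 21.092      49.93   0.002161 23108
#>    horizon_10    after_school  207.6  7.725      50.07   0.004255 11768
#>    horizon_20    after_school  521.7 13.056      49.44   0.004455 11097
```

With no decay the programme is cost-saving (dominant); at 100% decay after
the first year the ICER exceeds the threshold. Probabilistic analysis:

```r
psa <- run_psa(bundle, iterations = 2000, seed = 1)
ceac(psa, lambda_grid = 20000)   # P(cost-effective at £20k/QALY)
```

## Parameter bundles

Model inputs live in a directory of plain CSV tables plus a `settings.yml`
key-value config; `load_bundle()` validates every invariant (age coverage,
shares summing to 1, monotone utility grid, RR(inactive)=1, ...) and errors
name the offending table and rows. A complete example ships in
`inst/extdata/synthetic_bundle/` — one file per table: `incidence.csv`
(disease, sex, age, rate), `relative_risks.csv`, `lifetable.csv`,
`activity_prevalence.csv`, `disease_utilities.csv`, `baseline_utilities.csv`,
`disease_costs.csv` (first-year / subsequent / fatal-event phases),
`mortality.csv` (case fatality, multipliers, HR, net survival),
`hf_case_fatality.csv`, `interventions.csv`, `incidence_uncertainty.csv`.
`write_bundle()` round-trips losslessly. Seeded synthetic bundles with the
same schema come from `make_bundle(fixture_recipe(...))`.

## Command line

```sh
mvpasim validate --bundle inst/extdata/synthetic_bundle
mvpasim run --bundle inst/extdata/synthetic_bundle --out results \
        --strategy all --decay 0.5 --horizon lifetime --psa 2000 --seed 42
```

(The script installs to `system.file("cli", "mvpasim", package = "mvpasim")`.)
`run` writes per-cycle traces, a results table with increments and ICERs,
the PSA cloud and CEAC, and a JSON manifest (bundle checksum, seed, version)
so identical flags and seed reproduce identical outputs. Exit codes for
`validate`: 0 valid, 1 invalid content, 2 unreadable.

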