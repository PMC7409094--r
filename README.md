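# brcacea

Cost-effectiveness modelling of population-based BRCA1/BRCA2 testing.

Most BRCA1/BRCA2 carriers are missed by the current practice of offering
genetic testing only to women whose family history meets clinical criteria.
`brcacea` is an R implementation of a lifetime Markov cohort model that asks
whether testing *all* women aged 30 and over is worth it: it compares
population-based testing against clinical-criteria/family-history-based
testing for six country profiles (UK, USA, Netherlands, China, Brazil,
India), from both payer and societal perspectives. It is aimed at health
economists and epidemiologists who want a tested, scriptable version of
this class of cancer-prevention decision model.

## The model in brief

An annual-cycle cohort model over 37 states propagates a cohort of
30-year-old women through `T` country-specific cycles (UK 53 … India 38):

```
trace[t+1] = trace[t] %*% M(age_t)
```

Detected carriers may take risk-reducing mastectomy (RRM, age 37),
salpingo-oophorectomy (RRSO, age 40, ± hormone replacement to 51) or
chemoprevention, which multiply their breast/ovarian cancer incidence by the
published risk reductions (RRSO→OC ×0.04, RRM→BC ×0.09, RRM+RRSO→BC ×0.05,
RRSO→BC hazard ratio 0.49, chemoprevention hazard ratio 0.71). Undetected
carriers progress at baseline carrier risk. Outcomes are discounted
life-years and QALYs (`QALY = life-years × utility`), payer costs, societal
costs (payer + human-capital productivity losses), and the incremental
cost-effectiveness ratio

```
ICER = (Cost_pop − Cost_FH) / (Effect_pop − Effect_FH)
```

classified against WHO (1×/3× GDP per capita) and country-guideline
willingness-to-pay thresholds. Scenario analyses, one-way sensitivity
analysis with tornado ordering, probabilistic sensitivity analysis with
cost-effectiveness acceptability curves, population-impact scaling and a
test-cost threshold search are included. Because the underlying registry
data (life tables, incidence, survival, wages, country cost appendices) are
not redistributable, a synthetic-data module generates calibrated stand-ins
(e.g. carrier breast-cancer risk to 80 calibrated to 70%), so the whole
pipeline runs out of the box; see the vignette
(`vignettes/model-methods.Rmd`) for what the emulation does and does not
preserve.

## Worked example

```r
library(brcacea)

uk <- make_country_fixture("UK")          # synthetic UK input bundle
ev <- evaluate_strategies(uk, discount_mode = "who")
ev
#> <brca_evaluation> UK (discounting: who )
#>   payer ICER:    $   34214/QALY (highly-cost-effective)
#>   societal ICER: $    8675/QALY (highly-cost-effective)
#>   life expectancy gained: 0.9 days
```

Population testing costs $34,214 per QALY gained from the payer
perspective — under the UK 1× GDP-per-capita threshold ($42,656/QALY), so
"highly cost-effective" by the WHO convention. Adding averted productivity
losses (societal perspective) cuts the ICER to $8,675/QALY. Per arm:

```r
ev$pop
#> <brca_strategy_result> population
#>   LY 25.3870 | QALY 25.2905 | payer $6603 | societal $10749
#>   per million: bc_cases 107553, oc_cases 14720, bc_deaths 14154, oc_deaths 8912, chd_deaths 3
```

i.e. a 30-year-old woman accrues 25.39 discounted life-years; per million
women, the population-testing arm sees 107,553 breast cancers over their
lifetimes versus 108,720 under family-history testing — 1,167 cancers
prevented per million, at the price of 3 excess fatal heart-disease events
(RRSO without HRT). Scaling to the UK female population over 30 and
searching for the highest test price that stays under the threshold:

```r
report_impact(uk)$impact[1, ]
#>       event per_million_population_testing per_million_fh_testing difference_per_million actual
#>    BC cases                         107553                 108720                  -1167 -25403

threshold_test_cost(uk$profile$wtp_1gdp, uk, "payer")$test_cost
#> [1] 243
```

`run_psa()`, `ceac()`, `tornado()`, `report_scenarios()` and `plot_ceac()`
cover the uncertainty analyses; every analysis is deterministic given a
seed.

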