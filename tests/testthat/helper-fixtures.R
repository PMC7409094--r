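# Shared fixtures, built once per test process.

.fixture_cache <- new.env(parent = emptyenv())

country_fixture <- function(name) {
  if (is.null(.fixture_cache[[name]])) {
    .fixture_cache[[name]] <- make_country_fixture(name)
  }
  .fixture_cache[[name]]
}

all_countries <- function() {
  c("UK", "USA", "Netherlands", "China", "Brazil", "India")
}

# A degenerate bundle with no mortality, no cancer incidence and no
# intervention uptake: the cohort stays healthy forever, so accruals have
# closed forms.
null_hazard_params <- function(cycles = 30L) {
  p <- country_fixture("UK")
  p$profile$cycles <- as.integer(cycles)
  p$life_table$qx[] <- 0
  p$incidence$incidence[] <- 0
  for (nm in c("p2", "p8", "p15")) p <- set_model_param(p, nm, 0)
  p
}

# Published lifetime-impact rows: per-million counts per arm and the printed
# national "Actual" difference, with the national female populations over 30.
table2_rows <- function() {
  read.csv(text = "country,population,event,pm_pop,pm_fh,actual
UK,21760299,bc_cases,112014,114666,-57708
UK,21760299,oc_cases,15822,16269,-9727
UK,21760299,bc_deaths,12985,13258,-5941
UK,21760299,oc_deaths,278,550,-5919
UK,21760299,chd_deaths,17,0,370
USA,101428241,bc_cases,106431,109084,-269089
USA,101428241,oc_cases,9985,10417,-43817
USA,101428241,bc_deaths,8113,8285,-17446
USA,101428241,oc_deaths,235,475,-24343
USA,101428241,chd_deaths,17,0,1724
Netherlands,5694479,bc_cases,111732,114398,-15181
Netherlands,5694479,oc_cases,10964,11413,-2557
Netherlands,5694479,bc_deaths,11822,12072,-1424
Netherlands,5694479,oc_deaths,277,542,-1509
Netherlands,5694479,chd_deaths,17,0,97
China,422831894,bc_cases,27062,29546,-1050314
China,422831894,oc_cases,3862,4228,-154756
China,422831894,bc_deaths,3728,4015,-121353
China,422831894,oc_deaths,163,369,-87103
China,422831894,chd_deaths,12,0,5074
Brazil,58670634,bc_cases,66227,68891,-156299
Brazil,58670634,oc_cases,5358,5787,-25170
Brazil,58670634,bc_deaths,12901,13421,-30509
Brazil,58670634,oc_deaths,271,539,-15724
Brazil,58670634,chd_deaths,17,0,997
India,298650697,bc_cases,13713,16032,-692571
India,298650697,oc_cases,2826,3153,-97659
India,298650697,bc_deaths,3796,4391,-177697
India,298650697,oc_deaths,168,429,-77948
India,298650697,chd_deaths,8,0,2389",
           stringsAsFactors = FALSE,
           colClasses = c("character", "numeric", "character",
                          "numeric", "numeric", "numeric"))
}

# Minimal strategy-result stub for ICER algebra tests.
fake_result <- function(qaly, ly, payer, societal,
                        rates = list(cost = 0.03, effect = 0.03)) {
  structure(list(qaly = qaly, ly = ly, cost_payer = payer,
                 cost_societal = societal, rates = rates),
            class = "brca_strategy_result")
}
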