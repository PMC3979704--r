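# niptscreen

Decision-analytic evaluation of non-invasive prenatal testing (NIPT) for
Down's syndrome (DS), for health economists and screening-programme
analysts. The package models a cohort of 10,000 pregnant women moving
through three testing strategies —

- **current screening**: combined test (first trimester) or quadruple test
  (late bookers), with invasive diagnosis (CVS or amniocentesis) offered to
  screen-positive women;
- **contingent NIPT**: identical screening, but screen-positives are offered
  NIPT first and only NIPT-positives proceed to an invasive test;
- **first-line NIPT**: NIPT offered to the whole cohort in place of
  screening —

and reports the expected numbers screened, tested, diagnosed and miscarried,
plus a cost decomposition in 2011/12 GBP.

## The model in brief

The engine is an expected-value decision tree interleaved with gestational
survival. A cohort enters at week 10 split into DS-affected and unaffected
pregnancies; each week carries a piecewise-constant spontaneous-loss hazard
(unaffected: 0.0012 for weeks 10–25, 0.00034 afterwards; affected: 0.07067
for weeks 10–15, 0.0051 afterwards), so the probability of surviving from
week *a* to *b* is

    S(a, b) = prod over w in [a, b) of (1 - h(status, w)).

At each testing stage, a test with detection rate DR and false-positive rate
FPR splits takers as `positives_affected = takers_affected x DR` and
`positives_unaffected = takers_unaffected x FPR`. Every invasive procedure
carries a 0.5% procedure-related miscarriage risk; a DS case is "detected"
only on invasive confirmation. Confirmed diagnoses accept termination with
probability 0.921; survivors deliver at week 40 (75.2% vaginal / 24.8%
caesarean). Every pregnancy ends in exactly one terminal state, and the
engine conserves the cohort to machine precision.

Around the deterministic engine the package provides: a validated YAML/JSON
parameter bundle with uptake-scenario presets; pooling of eight published
NIPT validity studies (2x2 counts, Wilson score intervals); a scenario grid
runner over strategy x cut-off x NIPT price; ggplot2 `autoplot()` methods;
and a seedable individual-level microsimulator used as a stochastic oracle
for the expectation engine.

## Worked example

```r
library(niptscreen)

params <- default_parameters()
current    <- run_current_screening(params)   # cut-off 1 in 150
contingent <- run_contingent_nipt(params)

dplyr::bind_rows(glance(current), glance(contingent))
#> # A tibble: 2 × 8
#>   strategy        cutoff n_screened n_nipt n_nipt_positive n_invasive
#>   <chr>            <dbl>      <dbl>  <dbl>           <dbl>      <dbl>
#> 1 current            150      6875.     0              0        161.
#> 2 contingent_nipt    150      6875.   161.            13.4       11.2
#>   n_procedure_miscarriages n_ds_detected
#>                      <dbl>         <dbl>
#> 1                   0.807           12.0
#> 2                   0.0562          10.0

cost_events(contingent)        # NIPT priced at GBP 500 by default
#> <nipt_costs> (2011/12 GBP)
#>   screening:  199,796
#>   NIPT:       84,693
#>   invasive:   5,482
#>   total:      289,971
```

Reading: out of 10,000 pregnancies, about 6,875 are actually screened (69%
uptake minus early fetal losses). Under current screening ~161 women have an
invasive test, causing ~0.8 procedure-related miscarriages for ~12 DS cases
detected, at ~£278k total. Offering NIPT contingently cuts invasive tests to
~11 and miscarriages to ~0.06, detects slightly fewer cases (women who are
NIPT-positive may still decline invasive confirmation), and costs about the
same as current screening when NIPT is priced at £500.

Pooling the published validity studies:

```r
merge_studies(nipt_validity_studies())$estimate
#>   study          tp    fn    tn    fp sensitivity specificity
#> 1 Merged data   701     5 11480     6        99.3        99.9
```

Other entry points: `run_grid()` sweeps strategies, cut-offs and NIPT prices
into one tidy tibble (`autoplot()` plots cost against price);
`write_reports()` emits the outcome/cost CSVs plus an exact JSON sidecar;
`simulate_women()` / `tabulate_events()` / `compare_to_expectation()` run
the microsimulation oracle; `inst/cli/niptscreen.R` is a thin command-line
front end (`run`, `grid`, `accuracy`, `simulate` subcommands).

See the vignette (`vignettes/model-methods.Rmd`) for the model assumptions,
the synthetic England-like cohort, calibrated defaults, and known
limitations.

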