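---
title: "An expected-value cohort model of Down's syndrome screening with NIPT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An expected-value cohort model of Down's syndrome screening with NIPT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(niptscreen)
```

## The model

`niptscreen` evaluates three ways of organising antenatal Down's syndrome
(DS) testing in a cohort of 10,000 pregnant women representative of the
England screening population:

1. **Current screening.** Women are offered the combined test in the first
   trimester (85% of the cohort) or, if they book after 14 weeks, the
   quadruple test (15%); uptake is 69% for both. Women whose screening risk
   exceeds the cut-off (1 in 150 by default) are offered an invasive
   diagnostic test — CVS with QF-PCR in the first trimester, amniocentesis
   with full karyotyping in the second — taken up by 80% of unaffected and
   90% of DS-affected pregnancies. Each procedure carries a 0.5% risk of
   procedure-related miscarriage.
2. **NIPT as contingent testing.** The screening stage is identical, but
   screen-positive women are offered non-invasive prenatal testing (NIPT)
   from cell-free fetal DNA first; only NIPT-positive women proceed to an
   invasive test. NIPT has a 99% detection rate, a 1% false-positive rate, a
   5% sample-failure rate (the failed sample is redrawn exactly once, at
   full test cost) and no procedural loss.
3. **NIPT as first-line testing.** Conventional screening is replaced by
   NIPT offered to the whole cohort at 69% uptake, with invasive
   confirmation of positives.

Detection always requires invasive confirmation: a woman who is
NIPT-positive but declines the invasive test is not counted as a detected
case, and a DS pregnancy lost to the procedure itself is not counted either.
Confirmed diagnoses accept termination of pregnancy with probability 0.921;
everyone else is propagated to week 40 and delivers vaginally (75.2%) or by
caesarean section (24.8%).

The engine is an *expected-value* (cohort) model: it pushes expected counts,
not individuals, through the decision tree, interleaving each testing stage
with gestational survival.

## Fetal-loss dynamics

Spontaneous fetal loss is modelled as a piecewise-constant weekly hazard
applied per completed gestational week (no within-week proration):
unaffected pregnancies 0.0012 in weeks 10–25 and 0.00034 in weeks 26–40;
DS-affected pregnancies 0.07067 in weeks 10–15 and 0.0051 in weeks 16–40.
Survival between weeks is the product of the weekly complements, so
advancing 10→12→15 equals advancing 10→15 and every advance conserves
counts exactly (`in = out + losses`). The much higher loss hazard of
affected pregnancies is what makes DS prevalence fall with gestational age.

Events are booked at configurable weeks (`timing` in the parameter bundle):
combined screen at week 12 with CVS at 13, quadruple screen at 16 with
amniocentesis at 17, contingent NIPT one week after the screen with invasive
follow-up one week later, first-line NIPT at week 11 with invasive follow-up
at week 12. All are inside the clinically recommended windows (combined test
11–14 weeks; quadruple after 14 weeks). The first-trimester boundary for
TOP costing is week 14, so a CVS-confirmed diagnosis — including the
contingent follow-up at week 14 — is costed as a first-trimester
termination. Between-stage survival attrition is why, for example, 6,900
offered-and-accepting screeners become ≈6,875 women actually screened.

## The synthetic cohort

No individual-level population data are distributed with the source model,
so the package ships a synthetic England-like cohort with two replaceable
ingredients (both accept a two-column `age,value` CSV):

* **Maternal age.** A unimodal Gaussian-shaped weight curve centred at 29.7
  years (SD 5.9) over single years 13–50, affinely mapped into the band
  [0.0024, 0.0165] and normalised to proportions at use. The band
  constraint fattens the tails relative to true national statistics — one
  reason the packaged cohort is an approximation, not a reconstruction.
* **DS prevalence.** The standard logistic maternal-age risk curve at term
  is converted to week-10 risks by inverse survival under the loss hazards,
  clamped into [0.001, 0.026] (at young ages and late weeks the floor
  binds), and scaled by a single factor so the 10,000-pregnancy cohort
  holds 29.5 affected pregnancies at week 10 (2.95 per 1,000). That
  calibration target reflects national register estimates of combined
  antenatal and postnatal DS diagnoses in England and Wales around 2011
  (roughly 2.7–3.0 per 1,000 births) and is fixed once; it is deliberately
  not tuned per table cell.

Because the cited national age and prevalence tables are approximated
rather than reprinted, the package reproduces published screening volumes
and costs to within a few per cent rather than exactly; the per-cell
residuals are tolerance-checked in the test suite rather than forced.

## Costing

Costs are 2011/12 GBP with no inflation hook, over the duration of
pregnancy (no discounting needed). Three programme components: screening
(combined £27, quadruple £35, repeat nuchal-translucency measurements),
NIPT (every test, including the repeat after a sample failure, at the unit
price — £50/£250/£500/£750 are the canonical sweep), and invasive diagnosis
(procedures and repeat procedures at £479, procedure-related miscarriages
at £511, booked under this component). An optional pregnancy-outcome mode
adds spontaneous losses (£511), terminations (£697 first trimester, £882
second) and births (£1,341 vaginal, £2,436 caesarean); these are large and
similar across strategies, so they mask the programme-cost differences.

Two packaged values are this package's own calibration, not published unit
costs: the repeat-NT unit cost (£6.50; the source programme includes repeat
NT in screening costs but prints no unit value — £6.50 makes the default
pack's screening component ≈£200k, the published level) and the
NT-failure-by-week curve (linear 14% at week 11 to 19% at week 14; only the
14–19% range is published). Reported tables round counts to 2 decimal
places and costs half-up to the nearest £1,000; exact values are always
preserved in the JSON sidecar.

## Diagnostic-accuracy pooling

Eight published NIPT validity studies are shipped as 2×2 counts.
Sensitivity and specificity are pooled by summing counts; intervals are
95% Wilson score intervals (the source table does not state its CI method,
and several printed intervals are not reproducible by any common method, so
intervals are reported but not treated as reproduction targets). Two
residuals are inherited from the source: the printed pooled counts
(736/5/11601/6) are not the column sums of the printed study rows
(701/5/11480/6), so the pooled row is shipped separately as printed; and
the printed pooled specificity (99.94) is 99.95 when computed from its own
counts at 2 dp.

## The microsimulation oracle

`simulate_women()` replays the same pathway rules woman by woman with
independent Bernoulli draws at the exact parameter-bundle rates, using one
fixed row of uniform variates per woman (so trajectories are reproducible
and enlarging the cohort never reshuffles earlier women). Spontaneous loss
is drawn by inverting a single uniform through the cumulative weekly
survival curve, which reproduces the weekly-hazard chain exactly.
`tabulate_events()` yields realised counts in the same ledger shape as the
deterministic engine and `compare_to_expectation()` forms per-field
z-scores with binomial-style standard errors. At 200,000 women every field
sits well inside |z| ≤ 3, and an injected two-fold corruption of the NIPT
false-positive rate is flagged — the strong-law check that the expectation
engine and the individual-level rules agree.

What passing these checks does *not* show: the synthetic cohort matches a
real maternity population (its age tails are band-constrained, prevalence
is curve-based), NIPT uptake behaves as assumed under real-world
conditions, or that trisomies 13/18 and other chromosomal anomalies (out of
scope here) would behave similarly.

## Numerical choices and degenerate inputs

* All percentages are stored as proportions once, at load; validation
  rejects any probability outside [0, 1], any negative cost, and any
  unknown configuration key (strict schema), naming the offending key path.
* Conservation is exact by construction: every pregnancy ends in exactly
  one of never-tested/declined delivery, spontaneous loss, procedural
  miscarriage, termination, or live birth; the suite asserts this to 1e-6
  across random parameter bundles and to 1e-9 under the defaults.
* Zero uptake at any stage degrades gracefully to an all-zero testing
  ledger with an intact delivery flow; a zero-size cohort yields an empty
  slice; empty 2×2 denominators raise explicit undefined-estimate errors.
* Wilson bounds at boundary counts (0 or n successes) are set to their
  algebraic limits exactly, avoiding floating-point excursions past the
  point estimate.
* Problem sizes used by the packaged checks: 10,000-woman deterministic
  cohorts, 100 random parameter bundles for the conservation sweep, and
  200,000 simulated women for the stochastic oracle — large enough that
  every ledger field's relative Monte-Carlo error is below ~1%.

## Known limitations

* The packaged age/prevalence tables are approximations; published outcome
  volumes are matched to within a few per cent, not digit-for-digit.
* Several cells of the source tables are mutually inconsistent under any
  single set of rates (contingent NIPT volume versus invasive volume under
  identical uptakes; first-line NIPT positives versus the stated 1%
  false-positive rate; the first-line cost rows). The engine reports its
  own internally consistent ledger and does not reverse-engineer those
  cells.
* Only DS is modelled: no trisomy 13/18 or sex-chromosome aneuploidy
  testing, no invasive follow-up of structural anomalies after a normal
  NIPT, no twin pregnancies, no maternal-age-dependent unaffected loss
  (exposed as a hook, without default data), and no QALY or lifetime-cost
  modelling.

## A worked run

```{r}
params <- default_parameters()
current <- run_current_screening(params)
contingent <- run_contingent_nipt(params)
dplyr::bind_rows(glance(current), glance(contingent))
glance(cost_events(contingent))
```

```{r, fig.width = 6, fig.height = 4}
grid <- run_grid(params, strategies = c("current", "contingent_nipt"),
                 cutoffs = 150, prices = c(50, 250, 500, 750))
autoplot(grid)
```
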