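# pvsignal

Disproportionality-based signal detection for spontaneous adverse-event
report databases in the style of the FDA Adverse Event Reporting System
(FAERS).

Spontaneous reporting systems have no denominator of exposed patients,
so drug safety questions are asked as *disproportionality*: is a
drug–event pair reported more often than the rest of the database would
predict? pvsignal implements that screen for a single target event —
the motivating application is carpal tunnel syndrome (CTS) — for
pharmacoepidemiologists and drug-safety analysts who want the full
pipeline (report storage, 2×2 contingency counting restricted to
primary-suspect drugs, the standard statistics, layered decision rules,
demographic summaries) as tested, scriptable R functions rather than a
point-and-click query tool.

## The statistics

For drug *D* and event *E*, reports collapse to the 2×2 table
(*a*, *b*, *c*, *d*) = (drug∧event, drug∧other, other∧event, neither),
with N = a+b+c+d. The package computes, per pair:

- **ROR** = (a/c)/(b/d), with the Woolf 95% CI
  exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d));
- **PRR** = (a/(a+b))/(c/(c+d));
- **χ²**: Pearson, 1 df, Yates correction by default;
- **BCPNN information component**: IC = log₂ P(D,E)/(P(D)P(E)) under
  the closed-form Bayesian posterior-moment approximation (Bate et al.
  1998), with IC025 = E(IC) − 1.96·√V(IC).

A pair is flagged as a signal when it passes all three layers: the
Evans criteria (a ≥ 3, PRR ≥ 2, χ² ≥ 4), BCPNN validation (IC025 > 0),
and conservative custom floors (a ≥ 10 and ROR ≥ 10). All thresholds
are parameters of `signal_criteria()`.

## Worked example

The package bundles the margin specification of a FAERS-scale CTS
screen (12,929,504 reports, 6,837 naming CTS, ten drugs with their
primary-suspect counts). Screening those margins:

```r
library(pvsignal)
spec <- cts_margin_spec()
st <- detect_signals_from_margins(spec$drugs, spec$n_event, spec$n_total,
                                  event_pt = spec$event_pt)
st[, c("drug", "a", "n_drug", "ror", "ci_low", "ci_high", "prr",
       "ic025", "is_signal")]
#>                         drug   a n_drug  ror ci_low ci_high  prr ic025 is_signal
#> 1                idursulfase  54   2064 51.2  39.01    67.1 49.9  4.33      TRUE
#> 2                 galsulfase  20   1435 26.8  17.22    41.7 26.4  2.95      TRUE
#> 3                 laronidase  28   2577 20.8  14.35    30.3 20.6  3.09      TRUE
#> 4                tesamorelin  23   2130 20.7  13.71    31.2 20.5  2.91      TRUE
#> 5                anastrozole 109  10273 20.6  17.02    24.9 20.4  3.82      TRUE
#> 6            alendronic acid 151  17251 17.0  14.50    20.0 16.9  3.68      TRUE
#> 7  gamma-hydroxybutyric acid  14   1640 16.3   9.63    27.6 16.2  2.27      TRUE
#> 8                  rofecoxib 268  32890 16.1  14.26    18.2 16.0  3.69      TRUE
#> 9                alendronate 157  23592 12.9  11.04    15.2 12.9  3.32      TRUE
#> 10                 tafamidis  55   8770 12.0   9.21    15.7 11.9  2.93      TRUE
```

Each row is one drug's 2×2 table against all other drugs: idursulfase
is primary suspect in 2,064 reports, 54 of which name CTS — 51.2 times
the CTS reporting odds of the rest of the database, with the interval
(39.0, 67.1) well clear of 1 and IC025 > 0, so it passes every layer.

Synthetic databases with known structure support end-to-end checks.
An injected association is recovered where planted:

```r
sim <- simulation_spec(n_reports = 200000,
                       injected = data.frame(drug = "drug a", target_ror = 20),
                       seed = 42)
st2 <- detect_signals(simulate_reports(sim), "carpal tunnel syndrome")
head(st2[, c("drug", "a", "n_drug", "ror", "ci_low", "ci_high", "is_signal")], 3)
#>     drug    a n_drug     ror  ci_low ci_high is_signal
#> 1 drug a 3353  20101 20.9983 19.7660 22.3075      TRUE
#> 2 drug d  212  19849  0.3910  0.3405  0.4491     FALSE
#> 3 drug c  209  20084  0.3801  0.3307  0.4369     FALSE
```

and an exact-margin reconstruction (here down-scaled ×100) reproduces
the event demographics it was asked for:

```r
small <- reconstruct_from_margins(spec, seed = 11, scale = 100)
summarize_reports(small, spec$event_pt)
#> <demographic_summary> event: 'carpal tunnel syndrome'
#>   68 of 129,295 reports (0.05%) name the event
#>   sex: 47 female (69.1%), 17 male (25.0%), 4 unknown (5.9%)
#>   age: 57.4 +/- 14.4 years (n=68 with stated age)
#>   top countries: united states (47, 69.1%)
#>   years: 2005-2024 (68 dated reports)
```

File-based workflows (FAERS-style DEMO/DRUG/REAC tables, TSV or
`$`-delimited) go through `read_reports()` / `run_analyze()`, or the
shell wrapper:

```sh
Rscript inst/scripts/pvsignal analyze --demo demo.tsv --drug drug.tsv \
    --reac reac.tsv --event "carpal tunnel syndrome" --out results/
```

See `vignette("signal-detection-methods")` for the model, the counting
rules, the BCPNN priors, and the synthetic-data design.

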