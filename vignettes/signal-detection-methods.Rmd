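---
title: "Disproportionality methods for spontaneous-report signal detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality methods for spontaneous-report signal detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting
System (FAERS) collect voluntary reports of suspected adverse drug
events. They have no denominator of exposed patients, so absolute risks
cannot be estimated; what can be asked is whether a drug-event pair is
reported *disproportionately often* relative to the rest of the
database. pvsignal implements that question for a single target event —
the motivating application is carpal tunnel syndrome (CTS), a median
nerve compression neuropathy with suspected pharmacological
contributors — as a reusable pipeline: report storage, contingency
counting, disproportionality statistics, layered signal criteria, and
descriptive summaries, together with a synthetic-data module that makes
every step testable against known ground truth.

## The 2x2 table and its counting rules

For a drug $D$ and event $E$ the database is collapsed to

|                | event $E$ | other events |
|----------------|-----------|--------------|
| drug $D$ (PS)  | $a$       | $b$          |
| other drugs    | $c$       | $d$          |

with $n_\mathrm{drug} = a+b$, $n_\mathrm{event} = a+c$ and
$N = a+b+c+d$ the database size. Three counting rules pin the table
down, and all are report-level:

* **Exposure is the primary-suspect (PS) role.** A drug listed as
  secondary suspect or concomitant does not contribute to $a$ or $b$.
  The event margin $n_\mathrm{event}$, by contrast, counts every report
  naming the event regardless of drug roles.
* **One report, one count.** A pair is counted at most once per report
  even if the report repeats the drug or the term; a report with
  several distinct PS drugs contributes to each of their tables. This
  keeps the four cells of every table summing to $N$.
* **Events match as exact normalized preferred-term strings** (trimmed,
  case-folded, internal whitespace collapsed). No MedDRA hierarchy
  expansion and no synonym mapping: `alendronate` and
  `alendronic acid` are distinct drugs, as they are in FAERS itself.

On report sets of up to a few hundred reports the data.table-based
counting is verified in the test suite against an independent
per-report double loop.

A note on an observable consequence of report-level counting: when the
bundled CTS margin table is recomputed from its printed margins, eight
of the ten reporting odds ratios reproduce the published value at one
decimal, while two (laronidase, alendronic acid) land one last-decimal
step lower (20.8 vs 20.9, 17.0 vs 17.1). Systems that count drug-event
*mentions* rather than reports in some cells would shift the last
decimal in exactly this way; the report-level contract is retained
because it is the one under which cells sum to the database total.

## Statistics

**Reporting odds ratio.** $\mathrm{ROR} = (a/c)/(b/d)$, with the Woolf
(log-normal) interval
$\exp\!\left(\ln \mathrm{ROR} \pm z\sqrt{1/a+1/b+1/c+1/d}\right)$ and
$z = 1.96$ for 95% coverage. A zero cell leaves the estimate undefined;
`ror()` then errors unless the Haldane–Anscombe correction (+0.5 to
every cell) is explicitly enabled. The correction is **off by
default** because the case-count floors below make zero-cell pairs
irrelevant to any signal decision, and silently shifted estimates are
worse than a clear error. Under a seeded null simulation (2,000 tables
with a true odds ratio of 1 at margins of 1,000 vs 20,000 reports and
a 5% event rate) the interval covers 1 in 93–97% of tables, as the
test suite asserts.

**Proportional reporting ratio.**
$\mathrm{PRR} = \frac{a/(a+b)}{c/(c+d)}$. For tables with
$\mathrm{ROR} \ge 1$, $\mathrm{PRR} \le \mathrm{ROR}$ algebraically;
this invariant is asserted over randomized tables. A zero $a$ or $c$ is
treated as undefined on the ratio scale, matching the ROR behaviour.

**Pearson chi-squared.** One degree of freedom, Yates continuity
correction on by default (the form the Evans criteria were defined
with), delegated to `stats::chisq.test()`. Degenerate tables (a zero
margin) return 0 with a warning so database-wide screens keep running.

**BCPNN information component.** The IC is
$\log_2 \frac{P(D,E)}{P(D)P(E)}$ under a Bayesian model of the cell
probabilities; pvsignal implements the closed-form posterior-moment
approximation of Bate et al. (1998). With margin pseudo-counts
$\alpha_1 = \beta_1 = 1$, total pseudo-counts $\alpha = \beta = 2$,
joint pseudo-count $\gamma_{11} = 1$ and

$$\gamma = \gamma_{11}\frac{(N+\alpha)(N+\beta)}
  {(n_1+\alpha_1)(n_2+\beta_1)},$$

the posterior expectation and variance are

$$E(\mathrm{IC}) = \log_2 \frac{(a+\gamma_{11})(N+\alpha)(N+\beta)}
  {(N+\gamma)(n_1+\alpha_1)(n_2+\beta_1)},$$

$$V(\mathrm{IC}) = \frac{1}{\ln^2 2}\left[
  \frac{N-a+\gamma-\gamma_{11}}{(a+\gamma_{11})(1+N+\gamma)} +
  \frac{N-n_1+\alpha-\alpha_1}{(n_1+\alpha_1)(1+N+\alpha)} +
  \frac{N-n_2+\beta-\beta_1}{(n_2+\beta_1)(1+N+\beta)}\right],$$

and $\mathrm{IC025} = E(\mathrm{IC}) - z\sqrt{V(\mathrm{IC})}$. These
priors are the standard uninformative choice: with no data the IC
shrinks to 0, and at scale $E(\mathrm{IC})$ approaches the
maximum-likelihood $\log_2(aN/n_1 n_2)$ (asserted within 0.01 bits at
$N = 10^7$). Published screens of this kind typically cite the BCPNN
methodology without printing the formulation; the priors and the
$z = 1.96$ multiplier are therefore exposed in `bcpnn_priors()` so
sensitivity to these assumptions can be checked directly.

## Layered signal criteria

`signal_criteria()` combines three layers by conjunction, evaluated per
drug-event pair:

1. **Evans criteria**: $a \ge 3$, $\mathrm{PRR} \ge 2$,
   $\chi^2 \ge 4$;
2. **BCPNN validation**: $\mathrm{IC025} > 0$ (strict);
3. **Custom floors** against low-count false positives: the drug is
   primary suspect in $a \ge 10$ event reports and
   $\mathrm{ROR} \ge 10$.

All thresholds are parameters with the above defaults. The conjunction
is order-independent, and raising any threshold can only remove
signals (asserted as a monotonicity property). The output table is
sorted signals-first by ROR descending, then non-signals by ROR
descending, with `NA` estimates last and lexicographic tie-breaks, so
repeated runs are byte-identical. Pairs with $a = 0$ are retained in
the output for audit but can never be signals. No multiple-testing
adjustment is applied — the decision rules are fixed thresholds, not
p-value cutoffs — and the run manifest records the number of pairs
tested so a reader can judge the implied multiplicity.

## Synthetic data: the study conditions

The package carries one bundled margin specification
(`cts_margin_spec()`): a FAERS-scale database of 12,929,504 reports of
which 6,837 (0.05%) name CTS, ten listed drugs with their
$(a, n_\mathrm{drug})$ margins (idursulfase 54 of 2,064 through
tafamidis 55 of 8,770), and the CTS reports' demographics — 4,753
female (69.5%), 1,717 male (25.1%), 367 unknown (5.4%), age
57.0 ± 14.9 years, 4,699 from the United States, years 2004–2024.

`reconstruct_from_margins()` materializes a report set satisfying any
such specification *exactly*: each synthetic report carries one PS drug
and one reaction (the event or a filler term), listed drugs receive
exactly $a$ event and $n_\mathrm{drug} - a$ non-event reports, and a
filler drug absorbs the remainder. Sex, country and year requirements
are met exactly on the event reports (assignment shuffled under the
seed); ages are drawn from the requested normal distribution truncated
to [0, 130] and rounded to 0.1 years, so realized age moments match
approximately rather than exactly. Demographics of non-event reports
are unconstrained by any published summary, so they are left as
unknown sex with no stated age, country or year. Reconstruction at
full FAERS scale takes under a minute and roughly 2 GB, so the
generators build the three tables in memory directly (sharing the
report-id vector across tables and skipping the public constructor's
validation scans, which the construction guarantees); the optional
`scale` argument apportions every count by largest remainders for
fast small-set work, keeping cells summing to margins after rounding.

`simulate_reports()` is the stochastic counterpart for
parameter-recovery work: each report draws a PS drug from a catalogue,
then the event with background probability $p_0$, raised for injected
drugs to $q = r\,o_0/(1+r\,o_0)$ with $o_0 = p_0/(1-p_0)$, so the
expected odds ratio of the injected drug's table equals the target
$r$. The test suite verifies at $r = 20$, 500,000 reports and 50
seeded replicates that the mean $\ln\mathrm{ROR}$ lands within 5% of
$\ln 20$ and the Woolf interval covers the target in at least 90% of
replicates.

What the generators deliberately do **not** emulate: polypharmacy and
correlated drug co-mentions, multi-reaction reports (supported by the
data model but not generated), FAERS case versioning and deduplication
(input is assumed pre-deduplicated), reporting lags, and realistic
drug vocabularies. Passing tests therefore demonstrate the statistical
machinery on structurally clean databases, not robustness to FAERS
parsing quirks.

## Numerical and interface choices

* Statistics are computed in full double precision; rounding (1 d.p.
  for ROR/CI and event percentages, 2 d.p. for the rest) happens only
  in written TSV output and print methods.
* Ages arriving in months or days are converted to years at parse
  time; unparseable units become missing.
* Missing demographics are retained (`sex = unknown`, age `NA`), never
  imputed; age summaries use stated ages only, with the sample
  ($n-1$) standard deviation.
* `detect_signals_from_margins()` exposes the screen directly on
  $(a, n_\mathrm{drug})$ margins plus totals. Every statistic above
  depends on the 2x2 table alone, so margin-level screening at full
  database scale is exact, not an approximation; materialization is
  only needed when the reports themselves are the input.
* The shell entry point (`inst/scripts/pvsignal`) is a thin optparse
  wrapper over `run_analyze()` / `run_simulate()` /
  `run_summarize()`; those functions are the tested surface.
* Test problem sizes: property suites run on report sets of ≤ 200
  reports (against brute-force oracles), 2,000-table null coverage
  simulations, and 50 × 500,000-report recovery replicates; the
  demographic reproduction runs once at the full 12.9M-report scale.

## Worked screen

```{r}
spec <- cts_margin_spec()
st <- detect_signals_from_margins(spec$drugs, spec$n_event, spec$n_total,
                                  event_pt = spec$event_pt)
st[, c("drug", "a", "n_drug", "ror", "ci_low", "ci_high", "ic025",
       "is_signal")]
```

## Limitations

Disproportionality is a hypothesis-generating screen, not a causal
estimate: no exposure denominator exists, reporting is voluntary and
selective, and confounding by indication is untestable from the
database alone — enzyme replacement therapies for mucopolysaccharidoses
flag strongly for CTS at least partly because the treated diseases
themselves cause CTS. The package accordingly reports association
statistics and decision flags, never risk language.
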