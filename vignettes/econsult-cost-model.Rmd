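---
title: "The eConsult cost model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The eConsult cost model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(econsultcost)
```

## The problem

Web-based triage and consultation ("eConsult") services let patients
submit a structured request to their GP practice online — an
administrative query, a condition questionnaire, or a request for advice
— answered by the practice within one working day. For a practice the
question is economic: an eConsult consumes more administrative time than
a booking call, but less GP time than a face-to-face appointment, and the
service carries an annual per-patient licence charge. `econsultcost`
implements an activity-based cost model of this trade-off, calibrated to
a Scottish 11-practice pilot, together with usage analytics for the
service's web logs and a synthetic log generator for testing them.

## The timing model

Every submission falls into one of seven outcome categories
(`econsult_categories()`): two administrative outcomes (change of
details/other, fit note), two GP outcomes without patient recall (no
further action, prescription) and three recall outcomes (other
appointment such as bloods, GP phone back, GP face-to-face appointment).
Per category, staff time is composed from task-level timings
(`activity_timings()`, all in minutes):

* **Admin minutes** = receive (3) + close-off. Closing off requires
  contacting the patient for five categories (fit note, prescription,
  other appointment, phone back, GP appointment; 3 min) and not for the
  other two (1.5 min), giving 6.0 vs 4.5 admin minutes.
* **GP minutes** start from the *note check*, a mixture of minimal
  (2.5 min) and detailed (5 min) use of the patient's notes with mixing
  fraction `detailed_fraction` (default 0.5, hence 3.75 min). A
  prescription adds 1 min, other follow-up 0.5 min; a fit note is a
  fixed 4 min; a change of details 0.5 min. The recall categories add
  the follow-up consultation itself: 5 min of telephone time for phone
  back (3.75 + 5) and a 10-min face-to-face appointment (3.75 + 10).

The source tables state the per-category totals but not which categories
use the with-contact close-off; the assignment above is inferred — it is
the only one whose components reproduce the published admin column — and
is flagged as an inference here.

The expected time per eConsult is the category-mix-weighted sum. Under
the pilot mix (12/15/10/20/13/15/15%):

```{r expected}
expected_resource()
```

Full precision (5.67 and 5.9125 min) is propagated downstream; the money
table below is only reproducible from the unrounded values. All
presentation rounding uses `round_half_away()` (round half away from
zero), the convention the published tables follow in every checked cell;
base R's round-half-even would disagree (e.g. 73.6 must round to 74).

## The economic model

A saved conventional contact is costed as one booking call (3 admin min)
plus one 10-min face-to-face GP appointment; telephone consultations are
not part of the comparator (this is the only composition that reproduces
the published savings). With hourly rates $r_a$ (admin, GBP 17.82) and
$r_g$ (GP, GBP 95.08) and replacement fraction $s$ (the fraction of
eConsults replacing a conventional appointment), the saving per eConsult
is

$$\Delta_a = (3s - E[\text{admin}])\,\frac{r_a}{60}, \qquad
  \Delta_g = (10s - E[\text{gp}])\,\frac{r_g}{60}, \qquad
  \Delta = \Delta_a + \Delta_g.$$

Rates are supplied per hour and divided by 60 at full precision;
pre-rounded per-minute rates do not reproduce the published table.
$\Delta$ is affine in $s$ with slope $(3 r_a + 10 r_g)/60$ and crosses
zero once, between $s = 0.66$ and $0.68$ under the defaults:

```{r table4}
format_savings_table(savings_table())
```

The break-even submission rate is the annual number of eConsults per
registered patient whose savings cover the annual charge $c$ (default
GBP 0.63): $c / \Delta$ when $\Delta > 0$. At non-positive saving no
volume breaks even; `breakeven_rate()` returns an explicit undefined
flag rather than an infinity, so reports never propagate non-finite
numbers.

```{r breakeven}
breakeven_rate(savings_per_econsult(s = 0.73))
```

Sensitivity: administrative timings were interview estimates, so
`sensitivity_sweep()` rescales them by a chosen fraction and recomputes
the chain. Because the avoided booking call is itself an admin task, the
sweep reports two variants — scaling the eConsult-side admin tasks only,
and scaling all admin tasks including the booking call. In either
variant the effect is small relative to the GP component, since admin
time costs about a fifth of GP time per minute.

## Scenarios and induced demand

`appointments_saved()` sums the mix over the saved-category set: by
default every category except change-of-details (never an appointment)
and the GP-appointment outcome (the appointment still happens). Phone
back is counted as saved — the *face-to-face* appointment is avoided,
and the GP's phone time is already charged on the cost side as follow-up
time; dropping it cannot reproduce the published 73% base figure.

Some submissions come from patients who would not otherwise have
contacted the practice (8% in the English pilot); they save nothing, so
the minimum estimate is $s \cdot 0.92$. The base mix gives 73% raw and
67% adjusted.

Scenario mixes are data, not code: `inst/extdata/scenarios.csv` packages
the base mix and four directed-marketing scenarios, each with its
declared admin and patient-recall shares, which the tests recompute from
the mixes as a consistency check. Because the published analysis quotes
the annual charge both as GBP 0.63 (body) and GBP 1 (figure caption),
`evaluate_scenarios()` reports break-even rates at any set of charges
and asserts neither as canonical.

## Usage analytics

The analytics are pure functions of an event-log CSV (one row per
website event: practice, ISO date, kind, category, sex, age band) and a
practice-roster CSV:

* `conversion_rate()`: submissions / site visits (undefined, reported as
  missing, with no visits in scope).
* `annualised_rate()`: submissions × (12 / window months) × 1000 / adult
  list size. The pilot's 17 April–17 August window is treated as 5
  months, matching how the pilot itself annualised; the day count (123)
  is deliberately not used.
* `demographic_shares()`: shares over submissions with *known*
  demographics; unknowns are counted and reported separately, never
  silently folded into denominators (the pilot's trial-period logs had
  no demographics at all).
* `deprivation_association()`: Spearman rank correlation of per-practice
  rates against the most- and least-deprived SIMD quintile shares, with
  a seeded permutation p-value (999 permutations). The pilot made this
  claim visually; the package reports a statistic instead, and flags the
  degenerate zero-variance case (correlation 0 by convention).
* `survey_summary()`: survey proportions with Wilson 95% score intervals
  — preferred over Wald at the pilot's small response counts
  (n = 291, a 6.5% response rate).

## The synthetic generator

The pilot's raw logs were never released, so the generator emulates
their statistical structure for testing: per practice and day, site
visits are Poisson with mean `daily_visit_rate_per_1000 × adults/1000`,
scaled by a log-normal practice multiplier (usage varied ten-fold across
pilot practices), a linear within-window growth ramp normalised to mean
1 (interest grew over the window), and optionally a deprivation slope
(default 0: rates independent of deprivation). Each visit independently
becomes a submission with `conversion_probability` (0.30), carries a
24-hour-unique flag (probability 0.8 — the pilot did not state this
share; the analytics treat the flag as given) and an urgent-divert flag
(0.05, likewise an assumption). Submissions draw a broad class
(32/27/24/17% across specific condition, administrative help, new and
existing general advice), a sex, and an age band.

Demographic skew is implemented as odds multipliers against the roster
composition. Female usage odds of 2.0 against ~50.4% female rosters give
$P(\text{female}) = 2 \cdot 0.504/0.496\,/\,(1 + 2 \cdot 0.504/0.496)
\approx 0.67$; an 18–44 multiplier of 1.708 against rosters whose adults
are ~51% 18–44 gives $0.51 \cdot 1.708/(0.51 \cdot 1.708 + 0.49) = 0.64$.
Both were calibrated once, in closed form, to the pilot's reported
shares. Rosters mirror the pilot's spread: averages of 64% aged 18–64
and 20% aged 65+, one young-skewed outlier (student practice, 2.3% aged
65+) and one old-skewed rural outlier (28.1% aged 65+), two
high-deprivation practices. The default daily visit rate of 0.67 per
1000 adults makes the month-annualised pooled submission rate ≈ 0.05 per
registered patient per year, the pilot's average, at conversion 0.30.

Identical (seed, config) pairs give identical output; rosters, log and
survey use distinct streams derived from the one seed, so each can be
regenerated independently.

**What passing tests do and do not show.** The round-trip tests
demonstrate that the analytics recover the generator's parameters
(conversion, class mix, demographic shares, a null deprivation slope)
at realistic sample sizes — they validate the *analytics code*, not the
pilot's findings, whose raw logs remain unavailable. The generator omits
features of real logs: within-week and diurnal patterns (timestamps are
dates), repeat users, practice-level conversion differences, and any
behavioural response to marketing.

## Problem sizes and numerical choices

The test suite and the analysis scripts run the generator at between 2
and 11 practices with list sizes from 2,000 to 32,000, chosen so that
parameter-recovery checks see roughly 5,000 submissions (the scale of
the pilot's pooled log) while repeated-seed checks (20 recovery
replicates, 50 null-association runs) stay small. Mix validation
tolerates 1e-9 on the simplex; linearity and break-even consistency are
asserted to 1e-9; equality with published cells is asserted at the
printed precision (2 dp for times, 1 dp for money, whole percent for
saved fractions).

## Known limitations

Single-period staff-time costing only: no discounting, no multi-year
horizon, no QALYs or ICERs, no triage by non-GP staff, and no modelling
of practice-to-practice timing variation beyond the sensitivity sweep.
The unit costs (GBP 95.08 and 17.82 per hour) are configuration inputs,
not derived. The 0.74 upper bound of the published replacement-fraction
range and the 0.73 category-based estimate are both exposed as plain
inputs; neither is hard-coded anywhere in the model.
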