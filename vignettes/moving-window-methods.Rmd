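---
title: "Detecting extra-home range movements with a moving window"
author: "ehrmdetect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting extra-home range movements with a moving window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrmdetect)
```

## The detection problem

An extra-home range movement (EHRM) — a sally, foray, or excursion — is a
temporary, long-distance movement outside an animal's usual area of use.
Detecting one requires answering two questions: *what is the animal's home
range?* and *did the animal leave it?*  The conventional answer builds a
seasonal or annual home range from **all** fixes in the period and screens
the same fixes against it (the Fixed-Period method).  That definition is
retrospective in a way the animal's behavior is not: at the moment of
departure the animal has not yet experienced anything that happens
afterwards, yet the contour it is tested against includes data collected
afterwards.  The practical consequence is masking — an excursion followed
by a shift of space use into the visited area is absorbed into the seasonal
contour and disappears from the record, and even excursions that are still
detected are measured against a contour inflated by their own fixes, so
their distances are biased low.

The Moving-Window method tests each day's fixes only against the home
range used over a fixed period immediately *preceding* that day.  Both
detectors, the criteria engine that interrogates the resulting EHRM sets,
and a simulator that provides ground truth, make up this package.

## Home-range model

Home ranges are Brownian bridge movement model (BBMM) utilization
distributions.  Between consecutive fixes $z_0, z_1$ separated by elapsed
time $T$, the animal's position at interior fraction $\alpha$ is modelled
as an isotropic Gaussian with mean $(1-\alpha) z_0 + \alpha z_1$ and
variance

$$\sigma^2_m\, T\, \alpha(1-\alpha) \;+\; \delta^2 (1-\alpha)^2 \;+\;
  \delta^2 \alpha^2,$$

which collapses to the squared telemetry error $\delta^2$ at the endpoints.
The utilization distribution (UD) is the time-weighted integral of these
bridge densities over all consecutive-fix pairs, evaluated at the centers
of a square grid and normalized to total mass one.  The home-range contour
at level $p$ (default 0.95) is the smallest set of grid cells, taken in
descending mass order, whose cumulative mass reaches $p$; ties are broken
by ascending (row, column) index so results are bit-reproducible.  The
contour geometry is the union of those cells — with a 100-m grid the cell
resolution *is* the native precision, and we do not smooth the isopleth.
Distances from a point to the contour are Euclidean distances to the
nearest exterior cell edge; membership uses half-open cells, so a fix
exactly on a boundary edge belongs deterministically to the cell on its
upper-right side and a fix exactly on the contour's edge counts as inside.

### Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `cell_size` | 100 | m | UD grid resolution |
| `delta` | 15 | m | telemetry error SD |
| `sigma2_m` | estimated | m²/s | Brownian motion variance |
| `contour_level` | 0.95 | — | isopleth level |
| `max_gap` | 8 × median interval | s | longest bridge integrated |
| `min_points` | 3 | fixes | minimum EHRM membership, brackets included |
| `min_distance` | 500 | m | minimum extent beyond the contour edge |
| `prehr_days` | 60 | days | PreHR length *t* |
| `window_days` | 2 | days | detection window |

$\sigma^2_m$ is estimated by leave-one-out maximum likelihood: every
second fix is predicted from its temporal neighbours under the bridge
variance above, and the likelihood of the observed middle positions is
maximized over a bounded positive interval with `stats::optimize`.  By
default it is re-estimated for every home-range segment (each season, each
PreHR); a fixed value can be supplied instead.  The 95% level and the
0.5-km distance threshold are the field's conventional choices: 95% is the
standard level at which occasional sallies fall outside the contour, and
0.5 km is conservative enough to capture purposeful excursions while
excluding ordinary peripheral variation.

### Numerical choices

The bridge time integral uses the midpoint rule.  The node count per bridge
is at least $\max(10, \lceil T/5\,\mathrm{min}\rceil)$ and additionally at
least $3 L/\max(\delta, \sqrt{\sigma^2_m T}/4)$, where $L$ is the bridge
displacement: the integrand seen by a cell near the path is a Gaussian bump
of width about $\delta/L$ in bridge time, and midpoint spacing below a
third of that width makes the rule effectively exact (the package's tests
hold it to $10^{-4}$ per cell against dense quadrature).  A fixed-order
rule, including Gauss–Legendre, fails here precisely because the bump can
fall between nodes.  The grid extent is the fix bounding box buffered by
$\max(3\sqrt{\sigma^2_m T_{\max}/4 + \delta^2},\; 5\,\mathrm{cells})$,
snapped to cell multiples, so effectively all bridge mass lies on the grid.
Bridges across gaps longer than `max_gap` (collar outages) are skipped;
iterations whose PreHR retains fewer than three usable fixes are skipped
with a logged reason.

## The two detectors

**Fixed-Period.**  Fixes are partitioned into seasons — spring (1 Mar–30
Jun), summer (1 Jul–31 Oct), fall/winter (1 Nov–28/29 Feb, absorbing leap
days), configurable, including a single annual period.  A segment is
analyzed when at least 60 days of relocation data are available, measured
as the elapsed span between its first and last fix (the span, not the count
of days with fixes, is what governs how representative the home range is).
Partial segments at the record edges qualify on the same rule; when fewer
than 60 days remain in the capture season, analysis effectively begins at
the next season.  Per eligible segment, the contour is built from the
segment's fixes and the same fixes are scanned — the method's defining
property and the source of its masking problem.

**Moving-Window.**  Iteration $i$ builds the PreHR from days
$[i, i+t-1]$ and screens the window days $[i+t, i+t+1]$; day 1 of the
record is the calendar day (UTC by default, configurable) of the first fix,
and a window day is the half-open interval [00:00, 24:00).  An EHRM is
accepted only if *initiated* on window day 1 — we read "initiated" as the
first fix outside the contour, the reading that makes the day-2 deferral
rule coherent (the departure, not the last inside fix, is what must fall on
day 1; users should be aware this is an interpretation).  The 2-day window
exists to capture movements that run past midnight; a movement still in
progress at window end freezes the PreHR and extends the window day by day.
Extension ends at the animal's first fix back inside the frozen contour,
or at the first indication of fidelity to a new area, whichever comes
first.

Fidelity is operationalized as the earliest time from which all fixes over
`fidelity_days` (default 7) consecutive days stay within `fidelity_radius`
(default 1000 m) of their own centroid — invented, prominently
configurable defaults standing in for the visual review used in field
practice.  Two guards proved necessary in implementation.  First, a 95%
contour leaves roughly 5% of ordinary fixes just outside it, so brief
sub-threshold border flickers are common; a flicker must not consume an
iteration's day-1 slot, so the departure scan continues past any run that
fails the thresholds.  Second, fidelity must be to a genuinely *new* area:
the settlement window's centroid must lie outside the PreHR contour,
otherwise the slow final fixes of a return transit can anchor a spurious
"settlement" just before the actual return fix and misclassify an ordinary
excursion as a dispersal.  After a confirmed dispersal, iteration restarts
once a full fresh PreHR of post-dispersal data exists (first new window day
= dispersal end day + $t$ + 1); after an ordinary extended EHRM closes,
iteration resumes at the next calendar day with the PreHR again the $t$
days immediately preceding it.  EHRM member fixes are *not* excluded from
later PreHRs — the cost is that an immediately repeated excursion to the
same locale can be partially absorbed; we note the alternative (exclusion)
would instead distort the PreHR sample size, and leave the choice visible
rather than resolved.

Causality is the method's contract, and the per-iteration audit log
(attached to every `run_moving_window()` result) records each PreHR span
and outcome so the tests can assert that no contour ever uses a fix at or
after its window start.

## Criteria engine and method comparison

The criteria engine applies fixed distance and/or duration definitions
with AND/OR conjunctions and strict or non-strict comparisons taken
literally from the source studies' printed symbols; the built-in registry
covers the seven published white-tailed-deer definitions of this form.
Sector classification at a distance/duration threshold pair partitions any
EHRM set into II (both), I (distance only), III (duration only) and IV
(neither), and the engine enforces the inclusion–exclusion identity
$n(\mathrm{OR}) = n(\mathrm{dist}) + n(\mathrm{dur}) - n(\mathrm{AND})$
exactly — summary percentages that violate it cannot arise here.
Open-ended EHRMs have no defined duration and never satisfy a duration
clause.

For contrasting the two detectors, availability is filtered first: EHRMs
initiated during the establishment of the first PreHR are unavailable to
the Moving-Window method, and EHRMs in seasonal segments with under 60 days
of data are unavailable to the Fixed-Period method.  Remaining EHRMs are
paired when their bracketed time intervals overlap — both methods bracket
the same outside run when they both see it — using earliest-end greedy
matching, which attains the maximum pair count for interval overlap (the
tests verify this against exhaustive matching).  The paired contrast is the
standard paired-sample *t* on moving-minus-fixed maximum distances.

## What the simulator emulates — and what it does not

The home-ranging null is a discretized Ornstein–Uhlenbeck process using the
exact transition (mean-reversion factor $e^{-\beta \Delta t}$), with
stationary SD 400 m per axis and reversion rate 0.1 h⁻¹: a stable home
range roughly 2 km across at the 95% level, so the 0.5-km threshold is
meaningful at deer scale.  Fix schedules of 1 h and 3.5 h emulate the two
field regimes; independent Gaussian error of SD 15 m is added per fix.
Events are spliced onto the baseline: a *sally* travels to a target offset
at 1000 m/h, dwells with 100-m positional SD, and returns (the simplest
shape exercising bracketing, extension and the distance metric); *shifts*
and *dispersals* move the home center permanently.  Everything is
reproducible from one seed, and ground truth records each event's realized
fix range.

The named scenarios freeze the validation conditions: `stationary`,
`single_sally`, `sally_then_shift` (three 2.5-km sallies, the third into
the area of a subsequent permanent shift — the masking configuration),
`mid_season_shift` (a 4-km shift followed by sallies from the new range
back into the old one, invisible to a seasonal contour), `dispersal`, and
`year_of_sallies` (365 days, twelve sallies of 1.5–4 km).  Problem sizes
were chosen so the full validation runs comfortably on a laptop: scenario
records are 110–150 days (a year for `year_of_sallies`), and the
behavioral suite uses 50 seeds of `sally_then_shift`.

What the simulator does *not* emulate bounds what passing tests show:
there is no habitat structure or covariate-driven movement, no
autocorrelated error, no behavioral states or migration, no fix-failure
bias, and transit paths are straight lines.  Passing tests demonstrate
that the algorithms do what they claim under a clean home-ranging null
with known perturbations — not that any particular field dataset will
yield particular detection rates.

On these conditions the package's acceptance tests reproduce the central
methodological claim in scaled form: across 50 seeds of
`sally_then_shift`, the Moving-Window detector recovers the planted
post-PreHR sallies, the Fixed-Period detector misses the shift-masked
sally, and paired maximum distances are larger under the Moving-Window
method (its contours never contain the movement's own aftermath).  The
tests compute these rates at run time; no empirical number is asserted
that the suite does not itself produce.

## Degenerate inputs and edge rules

Coincident fixes give $\sigma^2_m = 0$ with a warning; fewer than three
fixes, an empty contour, or a record shorter than the PreHR are errors or
warnings with empty results, as appropriate.  Duplicate timestamps keep
the first occurrence.  Fixes with missing DOP values are retained by the
quality filter (absence of the metric is not evidence of a bad fix) and
counted; the 7-day post-capture censor is half-open (a fix exactly at
capture + 7 days survives).  A sequence that begins outside the contour
yields a leading run with no start bracket, flagged and excluded from
closed-EHRM statistics; a run still outside at the record end is returned
open-ended.  Geographic coordinates are projected to the UTM zone of the
trajectory centroid (override available) by a built-in WGS84
transverse-Mercator implementation accurate to well under a centimeter,
verified in the tests against independently computed reference points.

## Known limitations

The fidelity defaults are operational stand-ins and should be set per
species.  The pairing rule formalizes what field studies do by manual
inspection; genuinely ambiguous overlaps (two movements by one method
spanning one movement by the other) are resolved by the greedy order, not
by movement characteristics.  Sub-threshold excursions that drift past the
distance threshold only days after departure are not revisited once their
day-1 evaluation closes.  And the Fixed-Period eligibility rule measures
elapsed span, so a segment with sparse but widely spaced fixes can qualify
with little data — matching conventional practice, not improving on it.
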