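---
title: "Scoring and modeling a digital attention battery for depression screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and modeling a digital attention battery for depression screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmarker)
```

## The measurement problem

People living with depressive symptoms show reliable performance differences
on tasks of sustained attention, visual working memory and spatial working
memory. A battery of three such tasks, delivered in the browser and played
on participants' own machines, yields error-based behavioral measures that
correlate with self-reported depression severity (the PHQ-9 total score)
strongly enough to be useful as sub-clinical screening signals. Error
measures are preferred over latency measures because they are robust to the
uncontrolled hardware and software of home computing environments.

`cogmarker` is a headless re-implementation of that pipeline: it generates
the stimulus batteries, scores raw interaction logs into the fourteen
behavioral measures, applies careless-responding filters, and fits the
hierarchical regressions that relate the measures to PHQ-9 totals. A
generative participant simulator closes the loop so that every stage can be
validated without human data.

## The three tasks and their scoring rules

**d2 test of attention.** Twenty pages, each a 7x6 grid of 42 abstract
items carrying 1-4 dots and a left or right notch; the target is *2 dots
with a left notch*. Pages default to 45% targets (the density of the
classic pen-and-paper instrument; the published digital design does not
state its proportions, so this is configurable), with the remainder split
evenly over the three admissible distractor classes. Participants sweep a
cursor with arrow keys and mark items; a page lasts 15 s. Scoring counts,
per page, the *processed range* -- one plus the maximum item index the
cursor reached; backtracking never shrinks it -- and, within it: correctly
marked targets, omissions (unmarked targets), commissions (marked
non-targets), their sum, and the error rate defined as errors per 100
processed items. The error rate could also be read as errors per unit time;
we adopt the per-items reading because it is the only one that reproduces
the magnitude (~10) of the published cohort means. Omissions are counted
only among processed items: an unreached target says nothing about
attention.

**Delayed matching to sample (DMTS).** Forty trials, ten at each retention
delay of 0, 1, 4 and 12 s, interleaved in seeded random order (the original
ordering is unstated; a blocked mode is available by configuration). A
4-quadrant color-form pattern is shown for 4,500 ms; after the delay, four
choices appear: the match, a novel distractor (new colors and forms), a
color distractor (the prompt's forms with the novel colors), and a shape
distractor (the prompt's colors with the novel forms). All four agree with
the prompt in one randomly chosen shared quadrant, which blocks
single-quadrant memorization strategies. Selection is forced to continue
until the match is found, but only the *first* selection is scored: the
four first-selection outcome counts then partition the 40 trials exactly,
which is the behavior the published descriptive statistics display (their
means sum to 40.0). Latency is averaged over all trials, correct and error
alike, since the source does not restrict it; this too is configurable.

**Spatial working memory (SWM).** Six trials at 4, 6, 8, 10, 12 and 14
boxes. Each trial runs one search sequence per box; the token is placed
uniformly among the not-yet-emptied boxes at each sequence start, so each
box yields a token exactly once and a token never returns to an emptied
box. (The adversarial token placement of the commercial instrument is
deliberately not emulated; the published design does not claim it.)
Re-opening a box within a sequence is a *within* error; opening an emptied
box is a *between* error; an open can be both, and by default increments
both counters, because the two definitions are logically independent. The
*strategy score* is the number of distinct boxes used to start sequences,
summed over all six trials (6 = perfectly systematic, 54 = maximally
scattered). The phrase "sum of the different starting boxes" could in
principle mean a sum of box indices, but indices are meaningless under the
per-trial position re-randomization, so the count-of-distinct reading is
used.

## Questionnaire scoring and data quality

PHQ-9 items (nine, 0-3) are summed to a 0-27 total and banded with the
standard cut points (0-4 minimal, 5-9 mild, 10-14 moderate, 15-19
moderately severe, 20-27 severe). The tenth "difficulty" item is stored
but never scored.

Because online cohorts contain careless responders and bots, three
per-scale filters act on every questionnaire scale a cohort carries:

* **speed** -- a scale completed in strictly less than 1 s per item;
* **zero variance** -- every item of a scale answered identically
  (a one-item scale is degenerate and counts as flagged; configurations
  should exclude singleton scales);
* **outlier variance** -- a response variance strictly greater than the
  cohort mean plus three standard deviations of variances on that scale
  (sample, n-1, statistics throughout).

A participant is removed when any single filter flags *more than two* of
their scales (read strictly: three or more). Thresholds are computed once
on the original cohort and not re-estimated after removals, which makes
filtering deterministic and idempotent on the kept cohort.

## The statistical models

The prediction model is a hierarchical ordinary least-squares regression:
demographic controls (age; gender coded male = 1, female = 0 -- the coding
is unstated in the source, so the simulator and fitter share this
convention to keep recovery well-defined) enter in the first block, and
behavioral measures in the second. Each block reports unstandardized
coefficients `B` with standard errors, standardized `beta = B sd(x)/sd(y)`,
two-tailed `t`/`p`, and block-level `R^2`, model `F`, `dR^2` and the
F-change statistic

```
dF = (dR^2 / m) / ((1 - R^2_full) / (n - k_full - 1)),
```

with `m` added predictors and `k_full` total predictors. `fchange_from_r2()`
and `model_f_from_r2()` expose the algebra directly so published statistics
can be recomputed from printed `R^2` values. Multicollinearity is
diagnosed with variance inflation factors, `1/(1 - R^2_j)`. Missing data
are handled by listwise deletion; the significance threshold is a plain
two-tailed 0.05 with no multiplicity correction, matching the original
analysis plan.

For the combined model, one measure per task is chosen by a principal
component analysis of the candidate measures with three retained components
and a direct oblimin (gamma = 0) rotation, Kaiser-normalized, implemented
via the standard gradient-projection algorithm; no installed package
provides oblique rotation, so the rotation is implemented in this package
and verified by its invariants (communalities preserved, unit-diagonal
factor correlation, criterion decrease). Each component is attributed to
the task holding the majority of its absolute pattern-loading mass, and the
highest-|loading| measure per component is selected. Component signs and
order are indeterminate; the implementation fixes signs by the dominant
loading direction and tests assert invariance under measure permutation.
One caveat inherent to *principal components* (as opposed to common-factor
analysis): with only 3-4 measures per component, loadings absorb unique
variance and within-block loading differences compress, so nearby
population loadings can swap ranks in small samples. The selection
machinery is therefore validated on planted structures with a clearly
separated strongest marker per block (0.92 versus at most 0.6, n = 400,
inter-factor correlation 0.2), where recovery is essentially certain; with
closely spaced loadings the selected measure is a toss-up among the top
candidates, which is a property of the method, not of the implementation.

Effect sizes for the added block are exposed in both conventions,
`dR^2/(1 - R^2_full)` (Cohen) and `dR^2/(1 - dR^2)`; applied to the
published combined model they give 0.398 and 0.353. The source text quotes
a much larger value for this quantity that neither convention reproduces,
so the package asserts neither as "the" published effect size. Similarly,
the chi-squared statistic the source attaches to its component analysis is
reported without a named test and with degrees of freedom inconsistent
with a Bartlett sphericity test on eleven variables; it is documented here
and not implemented.

## The participant simulator

The simulator is a test harness, not a cognitive theory. A latent severity
(standard normal) drives:

* **PHQ-9 responses** through a graded ordinal model: item `i` endorses at
  least category `k` with probability
  `plogis(a (severity - t_k - d_i))`, discrimination `a = 2.0`, thresholds
  `t = (0.28, 1.00, 1.72)`, item shifts `d_i` spread over ±0.35. One
  uniform draw per item against the decreasing exceedance probabilities
  yields a draw with exactly those margins.
* **d2 lapses** through logit-linear omission/commission propensities with
  slope 0.75 per severity SD and a shared person-level heterogeneity
  (SD 1.1) that produces the heavy right skew of real error counts.
* **DMTS memory fidelity** through
  `plogis(base - 0.28 sqrt(delay_s) - 0.55 severity + noise)`; first
  selections are correct with this probability, and errors split over the
  distractor types with weights 0.23/0.58/0.19 (color/shape/novel),
  matching the observed error composition. Latencies are lognormal.
* **SWM lapses** through a per-open probability of revisiting an emptied
  box (or, with probability 0.16, a box already opened this sequence), and
  sequence starts that explore not-yet-started boxes with probability
  0.75 -- real participants scatter their starting boxes far more than
  uniform sampling from the remaining boxes would.

All constants live in `default_config()$simulate`, not in code. They are
calibrated once so that a simulated cohort's metric means and spreads land
near the published descriptive statistics of the within-subjects validation
study (n = 90): about 419 d2 items with 43 errors (SD ~53), 31.7 correct
DMTS choices, 90 between and 20 within SWM errors, strategy ~40, PHQ-9
7 ± 6.9, age normal(37.944, 11.155) truncated to 18-72, male proportion
57/90. Demographics are generated independent of severity: the simulator
does not attempt to reproduce the (small) published age effect, so
age/gender act as null controls in recovered fits. What passing tests on
simulated cohorts demonstrate is that the *pipeline* -- generation,
logging, scoring, filtering, fitting -- is correct and recoverable; they
cannot demonstrate that real human behavior follows the behavioral model,
and no such claim is made.

Careless responders are planted by type -- speeders (0.3 s per item),
straight-liners (one repeated response everywhere), and random clickers
(alternating scale extremes, which drives response variance far above any
honest respondent's) -- each violating at least three scales so the
matching filter must catch them exactly.

A second, purely tabular simulator (`simulate_from_fitted_model()`) draws
independent predictors from published moments and an outcome from published
regression coefficients plus Gaussian noise. The residual standard
deviations 5.6 (combined model) and 6.6 (demographics-only model) follow
from the published outcome SD 6.892 and the models' `R^2` via
`sd_y sqrt(1 - R^2)`. This generative twin underlies the
coefficient-recovery checks in `scripts/acceptance.R`: at n = 20,000 the
refitted unstandardized coefficients must land within three Monte-Carlo
standard errors of the published values.

## Numerical choices and problem sizes

Seeded generation uses an isolated RNG stream (the caller's `.Random.seed`
is saved and restored), and every sub-stream (per-participant batteries,
cohort draws) derives deterministically from the master seed, so cohorts
are byte-identical across replays. The oblimin rotation iterates gradient
projection to a gradient norm of 1e-6 (capped at 1,000 iterations) with
step halving; correlation matrices must be positive semi-definite to
within 1e-8. Ties in d2 event ordering are resolved by event kind
(page_start, navigation, mark, page_end). The test suite exercises
structural invariants over 1,000 generation seeds, scores a
1,000-participant simulated cohort for the conservation checks, and runs
100 PCA-selection replicates; these sizes keep the default suite around
two minutes while leaving Monte-Carlo margins wide.

## Known limitations

* The behavioral agent is phenomenological; it reproduces first and second
  moments of the published metrics, not reaction-time dynamics or learning
  effects within a session.
* PCA-based selection inherits the loading-compression property discussed
  above; with real, closely correlated measures the chosen metric can vary
  between samples even when the component structure is stable.
* The published human-data results (e.g. the combined model's R^2 = 0.344
  on n = 90) cannot be reproduced without the raw data, which is not
  deposited; the package recomputes the printed test statistics from
  printed inputs and validates parameter recovery on simulated twins
  instead.
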