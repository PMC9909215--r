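---
title: "Methods: co-occurrence analysis of toddler pointing and caregiver behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence analysis of toddler pointing and caregiver behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pointseq)
```

## The scientific question and the data model

In naturalistic caregiver–toddler interaction, a toddler's point is a bid
for the caregiver's attention, and when the toddler chooses to point may
depend on what the caregiver is doing at that moment — feeding, handling
objects, or simply watching the child. `pointseq` analyzes this dependence
from interval codings: every coded behavior is an `(actor, category, onset,
offset)` interval, a session is one continuous observation of a fixed dyad
(a mealtime), and each toddler is observed at two developmental periods
(13 and 17 months), several meals per period.

Caregiver activity is coded into ten mutually exclusive categories
(`feeding`, `scooping`, `objects`, `touching`, `looking`, `pointing_cg`,
`other_person`, `gestures`, `self`, `no_data`). The last three are too rare
for stable per-meal statistics and are excluded from analysis while
remaining legal input; toddler behavior is coded as `pointing` and
`face_look` (gaze at the caregiver's face). Times are stored as integer
milliseconds; the 30 fps frame grid the codings were made on enters only at
discretization, so storage is exact whatever the source frame rate.

Caregiver coding is intended to be exclusive and exhaustive. Real manual
codings violate this in small ways, so overlapping caregiver intervals and
coverage below 95% of the session are *warnings* from `validate_session()`,
not errors; overlaps are resolved deterministically at discretization
(below). Out-of-bounds events and unknown labels are errors.

## The co-occurrence statistic

Each session is discretized into bins of `bin_width_ms` (default 33 ms,
approximating one 30 fps frame). A fixed bin width avoids the cumulative
drift that alternating 33/34 ms frames would introduce over a 20-minute
session; the ≤0.1% length error is immaterial to counts of tens of
thousands of bins. An interval is active in a bin iff it covers the bin
midpoint — a rule that gives every bin exactly one owner per stream and
makes activity independent of how an interval's endpoints align with bin
edges. Where caregiver intervals overlap, the latest-onset interval wins:
in practice a late-starting code is the coder correcting or refining the
running one, and the rule is order-independent and deterministic.

For a category *r*, the session's 2×2 table counts bins by category
presence × pointing presence: `N` bins total, `f_r` with the category,
`f_c` with pointing, `o_rc` with both. The expected joint frequency under
independence is the overall pointing rate times the row frequency,
`e_rc = (f_c/N) · f_r`, and the adjusted residual

`z = (o_rc − e_rc) / sqrt(e_rc (1 − p_r)(1 − p_c))`

is approximately standard normal when the streams are unassociated. Two
counting choices deserve comment:

- **Frame vs onset units.** By default the column event is "pointing is
  active in this frame" (`pointing_mode = "frame"`), consistent with
  frame-by-frame coding; `"onset"` mode instead marks bins containing a
  pointing onset and is provided for sensitivity analysis. Reports record
  the mode used.
- **Degenerate margins.** If a category never occurs in a meal (or covers
  it entirely), or the toddler never points, z is undefined. It is reported
  as missing with a reason, never as 0 — so a rare category like caregiver
  pointing contributes fewer meals downstream and its t-test runs on fewer
  degrees of freedom, which is the honest accounting.

A caveat documented rather than "fixed": consecutive frames are serially
dependent, so within a single meal z is not exactly N(0,1) when behavior
comes in intervals. The pipeline therefore never tests single meals; the
per-meal z is the unit of analysis and inference runs across meals. The
exact N(0,1) calibration is asserted (tests and `scripts/acceptance.R`)
under i.i.d. units, where it is the correct null.

## Coupling and frequencies

A pointing event with onset *t* is *coupled* iff some face-look interval
overlaps `[t − 2 s, t + 2 s]` (window configurable). The window is anchored
at the pointing onset, making the proportion invariant to pointing
duration; overlap is closed at the endpoints, and the tie (a look ending
exactly at the window edge counts) is fixed and tested. Meals without
pointing have an undefined proportion and are excluded from period
comparisons of coupling — visible downstream as a smaller denominator df.
Event frequencies are onset counts; abutting intervals are never merged.

## Inference

Per category, the per-meal z-scores (both periods pooled) are tested
against zero with a two-sided one-sample t-test; missing z's are dropped
listwise. No multiple-testing correction is applied across the seven
categories by default — each category is a separate substantive question at
α = 0.05 — but `adjust = "holm"` is available.

The period effect (13 vs 17 months) on any per-meal response (z per
category, pointing or look frequency, coupling proportion) is modeled as

`value ~ period, random = ~ 1 + period | toddler`

via `nlme::lme`: a fixed period effect plus a random intercept and period
slope per toddler. The period test is the conditional F with nlme's
containment denominator df (`N − n_toddlers − 1` on the complete design,
e.g. F(1, 29) for 36 meals of 6 toddlers; fewer when meals are missing for
a category). Satterthwaite approximations would be an alternative;
containment is used because it is what `lme` reports and it behaves
sensibly at these sizes.

Children also differ in how *variable* their behavior is meal to meal, and
`variance_strata = TRUE` adds a separate residual variance per toddler
(`varIdent`), a structure sometimes used for such designs. It is **off by
default** as the result of a calibration study run while building the
package: with only six meals per toddler each stratum variance is estimated
from six residuals, and the resulting REML F-test is anti-conservative —
empirical size ≈ 0.10 at nominal α = 0.05 over 400 null-simulated studies
at the reference design — whereas the homoscedastic random-slope model
holds its size (≈ 0.04, within Monte-Carlo error of nominal). A test that
doubles its false-positive rate is a worse default than a slightly coarser
variance model, so the strata are opt-in, intended for designs with enough
meals per child to support them.

Random slopes are themselves demanding for 36 observations. When a fit
fails to converge the model is simplified stepwise — drop the variance
strata (if requested), then the random slope, then ordinary least
squares — and the step taken is recorded in the fit object and the output
tables (`model` column) rather than raised as an error, so a batch
analysis never dies on one ill-conditioned category. Degenerate inputs
(constant response, a period with fewer than two estimable meals) return a
flagged `degenerate` result.

## The synthetic-data generator

Real codings of this kind are typically privacy-restricted, so the package
ships a generator that reproduces the statistical structure the analysis
assumes, calibrated to reference per-meal summary statistics for a
two-period mealtime design (six dyads, three meals per period):

- **Caregiver stream**: a semi-Markov chain over the ten categories — next
  category drawn from transition weights with no immediate self-transition,
  exponential dwell with a per-category mean, final dwell truncated at the
  session end. Intervals exactly tile the session. The stationary visit
  distribution of such a chain is proportional to `w(1 − w)`; the weights
  are solved (fixed point) so visit frequencies match the calibration
  per-meal category counts, and relative dwell lengths (watching-over long,
  scoops and single points short) are scaled so the expected number of
  intervals per session is right. Exponential dwell is a tractability
  choice; the calibration table constrains counts, not dwell shapes.
- **Toddler pointing**: an inhomogeneous Poisson process with rate
  `base_rate × multiplier(active caregiver category)`. All default
  multipliers are 1 (no association), and the base rate matches the
  calibration pointing counts (13.28 per meal at 13 months, 18.89 at 17).
  Pointing duration is a nominal 1 s — onset-based counting makes the
  downstream statistics insensitive to it, which is tested.
- **Face-looks**: a baseline Poisson stream plus, with probability
  `look_point_coupling_prob` per point, one look placed uniformly inside
  the ±2 s window (clamped into the session, which keeps it in-window).
  Defaults 0.3 at 13 months and 0.5 at 17 months encode the observed
  strengthening of look–point coupling while keeping total look counts at
  their calibration values (15.33 / 23.94); the published sources report
  the increase but not the proportion itself, so these are the generator's
  own choices.
- **Sessions**: durations from a truncated normal (mean 19 m 6 s / SD
  3 m 51 s at 13 months, 17 m 2 s / 3 m 53 s at 17; floor 5 min), ages from
  the period's mean/SD. Period effects are expressed by giving each period
  its own parameter block — injecting an effect means editing one field of
  the 17-month block, which is more direct than a separate shift vector.
- **Reproducibility**: each session's RNG seed derives from the master seed
  and the (toddler, period, meal) counter, so a study is bit-reproducible
  and individual sessions do not change when `n_toddlers` grows.

What the generator does *not* emulate: within-category dwell-time
distributions (unknown from per-meal counts), coder noise and drift,
behavioral autocorrelation beyond the semi-Markov structure, and any
dependence of caregiver behavior on the toddler's actions (the real
interaction is bidirectional). Passing recovery tests on simulated data
therefore shows the *estimators* work under the assumed generative
structure, not that the assumptions hold in real mealtimes.

## Numerical and design choices

- Bin membership by midpoint; default bin 33 ms; both are configurable.
- `e_rc`, `p_r`, `p_c` are kept as exact ratios of integer counts; the
  four table cells always reconstruct `N` exactly (asserted).
- Missingness (degenerate margins, zero-pointing meals) propagates as `NA`
  with a machine-readable reason, never as an imputed 0.
- The coupling window is closed at both endpoints; coupled looks count by
  interval overlap, not onset inclusion (both are common in the
  literature; overlap is the more inclusive and the default, onset-in-bin
  pointing is available via `pointing_mode = "onset"`).
- Fixed-point weight solving and all calibration arithmetic are
  deterministic; nothing is fitted at package load.

## Problem sizes used in the test suite

Module tests use studies of 2–6 toddlers and replicate batches of 40–400
sessions; the statistical acceptance checks use 5,000 null tables (N =
2,000 units), 1,000 random tables against the chi-square oracle, 100
replicate 36-meal studies for sign-pattern recovery, 100 for power and 400
for the null size of the period contrast, and 500 replicate sessions per
coupling-strength level. These sizes give Monte-Carlo standard errors
comfortably inside the asserted bounds while keeping the default suite
quick to run.

## Known limitations

- The frame-level z treats bins as exchangeable units; its single-meal
  null distribution is over-dispersed under interval-structured behavior
  (documented above; inference is across meals).
- The mixed model treats frequencies and proportions as Gaussian
  responses, as is conventional for this design; count GLMMs are out of
  scope.
- The containment df convention will not reproduce every published df
  exactly when missingness patterns differ; output tables print df
  explicitly so discrepancies are visible.
- The simulator's caregiver stream is independent of the toddler's
  behavior; coupling runs one way (points trigger looks).
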