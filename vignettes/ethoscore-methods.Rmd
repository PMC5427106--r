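---
title: "ethoscore: scoring model, indices, and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ethoscore: scoring model, indices, and simulation methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethoscore)
```

## The scoring model

Manual scoring of rodent tests records two kinds of behavior. *State*
behaviors (immobility, swimming, open-arm occupancy, object exploration)
are mutually exclusive and have duration: at any instant the animal is in
at most one state, so the scored states partition time. *Point* behaviors
(a head shake) are instantaneous counted events that do not interrupt the
ongoing state.

A session is scored as a stream of timestamped keystrokes with **toggle
semantics**: a state key pressed at time $t$ closes whatever state bout is
open and opens a bout of the pressed behavior; the last open bout closes
at the trial end. A point key inserts an occurrence without touching the
open bout. Pressing the key of the currently open behavior again is a
no-op, so a bout is one contiguous episode and bout counts measure
behavior *transitions*. Two state keys at the same instant yield a
zero-length bout, which is dropped — the later keystroke wins.

All intervals are **half-open**, $[\mathrm{start}, \mathrm{end})$: a
transition instant belongs to the new behavior. This convention makes
adjacent bouts partition time with no double counting, and it is applied
consistently in slicing, binning, sampling and rendering. Time before the
first state keystroke is an *unscored gap*; gaps are representable (and
surface in `coverage()`), because continuous scoring is the norm but
cannot be assumed. A `strict = TRUE` mode rejects gapped trials. Events
after the trial duration are rejected rather than clamped — silent
clamping would hide timing errors in the acquisition pipeline.

The keystroke log format (one `t<TAB>key` event per line, `#` comments)
and the `.etho` ethogram file format (DCF-style key–value records) are
this package's own: the original scoring system kept both internal to its
GUI and database, and plain text makes templates and logs shareable and
diffable.

## Built-in templates and their defaults

* **FST**: immobility (blue), swimming (red), climbing (black) as states,
  head shake (green) as a point event; 2 sessions × 1 trial × 300 s — the
  classic two-session design in which the 5-minute second session is
  scored. The colors follow the conventional map colors for this test.
* **NOR**: explore_A (red), explore_B (black), general_area (blue);
  1 session × 2 trials × 300 s (habituation/sample trial then the scored
  5-minute recognition trial). Which object is *novel* is a property of
  the trial, not of the test — counterbalanced designs swap it between
  animals — so `novel_designation` lives on the ethogram but can be
  overridden per call to `summarize_trial()`.
* **EPM**: open_arm, closed_arm, center; 1 session × 1 trial × 300 s.

Key bindings (and the EPM palette) are package defaults chosen from a
fixed documented palette; the original default bindings were never
published, and we make no attempt to replicate them. Everything is
remappable with `customize_template()`, which re-validates key/name
uniqueness and referential integrity after every edit set and never
mutates its input.

## Measures and indices

For every behavior, `summarize_trial()` reports total time, bout or
occurrence count, and latency to first onset. **Censored latencies**: a
behavior that never occurs gets latency equal to the trial duration with
`latency_censored = TRUE`. This is the common forced-swim convention, and
it keeps exported tables rectangular; the flag lets downstream survival
analyses treat the value correctly.

**EPM**: `pct_open_time` $= 100\,T_{open}/(T_{open}+T_{closed})$, with
center time excluded from the denominator by default — the published
convention for this test; `epm_include_center = TRUE` switches to the
full-trial denominator, since usage varies between laboratories. An
*entry* is the start of an arm bout with no minimum-duration debounce:
manual scoring already debounces at the scorer's reaction time. With no
arm time (or no arm entry) scored, the percentage is undefined and is
reported as missing, never as 0.

**NOR**: $DI = (T_N - T_F)/(T_N + T_F)$ and $PI = 100\,T_N/(T_N+T_F)$.
The implementation computes $PI$ as $50(DI+1)$ so the algebraic identity
holds bitwise, not merely to rounding. Both are missing when neither
object was explored. The familiar object is resolved from the ethogram's
`object_pair`.

**FST** has no composite index; latencies are exposed for all behaviors
rather than only immobility, which costs nothing and avoids privileging
one endpoint.

`segment_summaries()` bins a trial into $[k w, (k+1)w)$ windows (final
partial window included). Because slicing uses the same half-open
convention, per-behavior totals are exactly additive across bins (tested
to $10^{-9}$ s).

## Visual maps

A trial renders as a horizontal bar of width
$\mathrm{round}(T \cdot \mathrm{px/s})$: each bout is a run of its
behavior's color, gaps are light gray, point events are full-height
ticks. Bout boundaries map to pixels by round-half-up on *cumulative*
positions, so adjacent bouts can never overlap or leave seams, and every
run length is within ±1 px of `duration × px_per_second`. When two ticks
collide in a pixel column, the behavior later in ethogram order wins
(draw order is deterministic).

PNG output is specified byte-exactly: no pre-installed R package writes
PNG in this environment, and graphics devices are not byte-reproducible,
so the package carries a minimal codec (8-bit truecolor, filter 0, one
zlib IDAT via `memCompress`, no ancillary chunks, own CRC-32/Adler-32).
Identical inputs therefore produce byte-identical files — the property
that makes map-based rater audits and regression tests trustworthy.
Row labels in collated maps use a built-in 3×5 bitmap font for the same
reason: no system font can leak into the raster.

## Rater agreement

`measure_agreement()` computes, per measure, the Pearson product-moment
correlation across animals between two raters and a two-tailed p-value
from the $t$ reference with $n-2$ degrees of freedom — the standard
analysis for validating manual scoring between raters. Zero-variance
vectors make $r$ undefined; it is reported missing with a reason rather
than coerced. Fewer than 3 animals is an error. Point behaviors enter as
counts only (durations do not exist); published validations of such
systems report both duration and frequency correlations, so
`trial_measure_pairs()` exposes both for every state behavior, plus the
total event count.

`timeline_concordance()` operationalizes the side-by-side visual
comparison of two raters' maps: both timelines are sampled at midpoints
of consecutive 0.1 s windows (configurable; 0.1 s balances resolution
against cost), each sample is labeled with its state or `"gap"`, and the
output is the percent of matching samples plus Cohen's kappa over the
label confusion matrix. Kappa is undefined (reported `NA`) when a single
label fills both timelines, since chance agreement is then 1. Midpoint
sampling avoids ever sampling exactly on a boundary, where the half-open
convention would otherwise make results sensitive to floating-point ties.

## The simulator: a stated world

`simulate_trial()` draws an alternating-renewal (semi-Markov) process:
initial state from $\pi$, bout lengths from per-state exponential or
gamma distributions, transitions from a zero-diagonal stochastic matrix,
final bout clipped at the trial end; point events are homogeneous
Poisson. Generated trials always have coverage 1.

The default FST model (`fst_model()`) fixes the world the tests run in:
mean bout durations of 15 s (immobility), 10 s (swimming) and 5 s
(climbing), uniform transitions, head shakes at 0.02 s⁻¹ (≈6 per
5-minute trial). These are round values in the range a scorer sees in rat
FST sessions — tens of bouts per 5-minute trial with immobility dominating
late in the session — chosen once and not tuned against any test outcome.

`simulate_second_rater()` models trainee errors seen in practice:
Gaussian jitter of transition *instants* (applied to the shared boundary
between consecutive segments, then re-sorted and clamped — so jitter can
reorder boundaries but can never un-partition the timeline; this is why
noise acts on transitions rather than independently on bout endpoints),
per-bout mislabeling to a uniformly random other state, missed points,
and spurious points. One seed drives one reproducible stream per call;
cohorts derive per-animal seeds by a documented counter offset
(`seed + i − 1`).

What a green test establishes: the pipeline's algebra (conservation,
additivity, index identities), its agreement machinery, and the ordering
property that less rater noise yields higher inter-rater correlations.
What it does not establish: the published correlation magnitudes from
real rat scoring (raw rater data unavailable), or realism of fine
behavioral sequence structure — real FST behavior is non-stationary
within a session (immobility rises), which the homogeneous semi-Markov
model deliberately ignores.

## Numerical choices

* Interval coincidence tolerance $10^{-9}$ s throughout; conservation and
  additivity are asserted at that tolerance.
* The oracle used in tests samples at a 10 ms grid; test keystroke times
  are generated on that grid, where "agreement within one sample width"
  is exact. Off-grid boundaries would each contribute up to one sample of
  irreducible discretization error — a property of the oracle, not of the
  timeline algebra, which is exact.
* CSV seconds use 6 decimal places: sub-millisecond precision exceeds
  human keystroke accuracy, and round-tripping reproduces measure sets to
  $10^{-6}$.
* The project store is a canonical-JSON single file (fixed field order,
  full-precision numbers) so `save → load → save` is byte-identical. A
  relational single-file store (SQLite) was the natural alternative, but
  no SQLite binding is available in the supported dependency set, and the
  JSON file simultaneously serves as the portable text export for
  diffing and sharing; the documented schema keeps migration to a
  relational engine mechanical.
* Unassigned groups export as empty CSV cells, not the text `"NA"`.

## Known limitations

* No video playback, live progress bar, or GUI key capture — this is the
  scriptable analysis layer, not an acquisition front end.
* No bout-length distribution fitting, transition-matrix analysis, ICC
  or Bland–Altman agreement statistics.
* Multi-rater comparisons are pairwise; no multi-user store concurrency.
* The simulator does not model pharmacological effects or within-session
  non-stationarity.
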