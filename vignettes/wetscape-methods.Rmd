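---
title: "Methods: cross-scale wetland phenology from acoustic, hydrologic and satellite sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-scale wetland phenology from acoustic, hydrologic and satellite sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wetscape)
library(dplyr)
```

## The problem

In seasonally snow-covered landscapes of the north-central United States,
the transition from winter to spring cascades through a chain of events:
eight-day mean air temperatures rise past 0 °C, snow leaves the landscape,
early-breeding frogs (spring peepers, chorus frogs, wood frogs) begin
calling at wetlands, weekly temperatures reach the ≈10 °C floor for
photosynthesis, vegetation greens up, and landscape evapotranspiration (ET)
switches on. `wetscape` implements the analysis chain that extracts each of
these events from its sensor stream — hourly acoustic spectral summaries,
hourly water-depth loggers, daily station weather, and 8-day/7-day satellite
composites — and aligns them on a common calendar so that their ordering and
associations can be studied per wetland and per 4-km² landscape block.

Because multi-sensor field campaigns of this kind do not come with
deposited raw data, the package pairs every analysis stage with a seeded
synthetic generator that plants known ground truth (melt date, first/last
call dates, calling peaks, green-up week, depth–precipitation coupling).
Every detector can therefore be tested as a parameter-recovery problem.

## Calendars

All analyses use a 365-day civil year. Eight-day composite intervals and
seven-day weeks both start on January 1: interval *k* covers days
`1 + 8(k−1) … 8k` (46 per year), week *w* covers days `1 + 7(w−1) … 7w`.
Leap days are not modelled; the final periods are truncated at day 365.

Mixed-cadence satellite streams are aligned by a deterministic crosswalk:
each 8-day composite is assigned to the week whose start day is nearest its
own, ties to the later week. The assignment is injective, and the weeks left
without a composite ("orphans") within the January–August analysis span
(weeks 1–34) are exactly weeks 5, 13, 21 and 29 — so a weekly stream
contributes 34 records per site-year and an 8-day stream 30. The
nearest-start/ties-later rule was chosen because it is the unique simple
rule that reproduces this orphan set; it is pinned by a unit test.

## Acoustic analyses

A *spectral-summary grid* holds, for each 5-minute recording (24 per day),
the min/mean/max dB in 110 bins of 100 Hz covering 0–11 000 Hz. Values live
in [−88, 0] dB: −88 dB is the recorder noise floor, 0 dB the clipping
ceiling.

**Template matching.** A species' *call signature* is a short list of
harmonic peaks (centre frequency, offset in dB from the loudest peak). A
recording matches when every peak bin clears `−88 + margin + offset` in
max-dB *and* is a strict local maximum within ±1 bin. The margin defaults
to 10 dB: it must exceed any plausible excursion of the recorder's own
noise floor, because a season of monitoring contains hundreds of thousands
of recording × bin opportunities for a chance exceedance, while genuine
calls sit tens of dB above the floor. (Note that for strongly attenuated
harmonics the level threshold `−88 + margin + offset` can fall below the
floor and become vacuous; the local-maximum condition is then the operative
test for those peaks, and the loudest peak carries the level test.)
The local-maximum condition is what rejects broadband wind/rain noise: a
flat loud spectrum has no local maxima. Dates whose out-of-band median
exceeds −40 dB across the evening hours are additionally flagged *masked*
and excluded from peak ranking; the threshold stands in for the visual
screening a human analyst would do on contour plots.

**First call.** The first call of the season is the earliest matched
recording by *any* species, excluding days on which the station temperature
never exceeded 0 °C (configurable: `tmax` by default; the choice of daily
maximum is deliberately permissive, since one above-zero hour suffices for
activity). The result is reported both as a date and as the 8-day interval
containing it; a detection on the deployment date itself is flagged
"already underway". We scan every recording rather than reproducing the
labour-saving backward search a human analyst would use — the machine cost
is negligible and the interval-level result is identical.

**Calling activity.** Daily spring-peeper activity is the area under the
curve of hourly band medians (2900–3200 Hz, the species' dominant harmonic)
across the evening hours 21–23, by the trapezoidal rule at unit (1-hour)
spacing, integrating `(median + 88)` so that silence maps to exactly zero.
The band median uses bins fully contained in the half-open interval
[2900, 3200), i.e. bins starting at 2900, 3000, 3100. "2100 to 2300 h" is
read as the three recordings at 21, 22 and 23 h (configurable; two hours is
the defensible alternative). Trapezoid-with-unit-spacing is the standard
default for a generic area-under-curve tool; the offset makes the statistic
nonnegative, which matches how such integrands are plotted.

**Phenophase and peaks.** First/last call dates bound the phenophase
(`last − first + 1` days). The seasonal peak is the median of the top three
unmasked dates by integrand, ties broken toward the earlier date.

**Occupancy.** Presence of spring peepers in a site-year is at least one
signature match between deployment and June 7 (when calling is typically
complete), extended through June 30 when candidate detections occur later
in June. Area-level occupancy is summarised as the median across years of
the annual proportion of occupied monitored sites.

## Hydrology

Hourly logger depths reduce to daily medians; a day is valid only with the
full 24 readings. A depth-increase day is a valid day whose median exceeds
the previous valid *consecutive* day's by more than a tolerance (default
0 m — any positive change; a sensor-resolution tolerance is configurable).
Gap handling is not obvious for this kind of record, so both behaviours
exist behind `consecutive_only`; consecutive is the default because an
increase across a multi-day gap cannot be attributed to a day. The season
window defaults to the record span, matching how deployment periods bound
such analyses.

Increase-day counts are tested against precipitation-day counts
(days with > 0 mm at the nearest station) per site-year with Spearman rank
correlation (mid-ranks for ties, p from the t approximation). For n ≤ 8 an
exact permutation p-value over all n! pairings is available as an oracle
mode; the t approximation agrees with it to within 0.05 for n ≥ 6, while at
n ≤ 5 the approximation is structurally too coarse for that band (measured
worst cases ≈ 0.08 at n = 5, 0.15 at n = 4), which is why the agreement
property is asserted for n in 6–8.

## Weather indices

- **Eight-day temperature integrand**: trapezoid of the eight daily mean
  temperatures (seven unit panels, so a constant *c* integrates to 7*c*).
  Up to two missing days are linearly interpolated; more invalidate the
  interval, mirroring the substitution practice used for patchy station
  records. The first interval with integrand ≥ 0 °C·day marks the
  winter-to-spring transition.
- **Threshold week**: first week whose mean daily temperature is ≥ 10 °C
  (inclusive).
- **Growing degree units**, "Method 2": clamp `tmin` and `tmax` into
  [10, 30] °C *before* averaging, then subtract the 10 °C base, giving
  daily values in [0, 20] °C·day. When a station provides no `tmean`,
  `(tmin + tmax)/2` is used — the standard convention.
- **Climatograph**: a four-week window (incremented weekly) is a water
  *deficit* when total precipitation falls below `2 mm × max(T̄, 0 °C)` —
  the Walter-diagram equivalency that pairs 20 mm with 10 °C. Equality
  counts as surplus and sub-zero means floor the threshold at 0, so a
  frozen window can never be a deficit. The four-week total is compared
  directly against the 2 mm/°C line with no rescaling to a 30-day month;
  with windows this coarse, the ≈7% calendar correction is far below the
  rule's own precision.

## Landscape remote sensing

- **Snow-free onset** (per 500-m cell): start date of the first pair of
  contiguous snow-free 8-day composites whose *first* composite starts on
  or after the late-winter cutoff (day 46 = Feb 15 for field-scale
  analyses, day 59 = end of February for remote analyses). Requiring the
  pair's first composite to start after the cutoff (rather than merely
  occur after it) is the stricter reading and is the default. Block
  snow-off is the mean of cell onset days (half-up rounding), mapped to a
  week.
- **NDVI smoothing**: sliding three-point weighted least-squares with a
  peak-preserving upward bias — windows whose linear prediction is at or
  above the observation get double weight, so transient cloud/snow
  *downward* spikes are lifted while genuine peaks survive. The upweight
  factor (×2) is a documented parameter standing in for the published
  weight tables of operational NDVI smoothers. Linear series pass through
  unchanged.
- **Green-up**: first post-February week (week start day ≥ 60) with
  smoothed NDVI strictly above 0.60. Strict (">") is the default because
  "rose above" is the operative phrasing; an inclusive flag exists. The
  post-February window suppresses false green-up from intermittent snow
  over evergreen canopy.
- **ET onset**: first week of the weekly-aligned ET series strictly above
  1 mm.
- **Accumulations**: weekly, running four-week (from week 4), and to-date
  totals. Missing (orphan) weeks are skipped-and-summed: they contribute
  nothing but do not invalidate a window — the alternative (invalidating)
  would discard a quarter of all four-week ET windows.
- **Correlation battery**: pooled block-week records over weeks 1–34 are
  correlated (Spearman) with station GDU and precipitation at all three
  time scales. A `deltas` mode correlates week-over-week first differences
  instead, which strips the shared seasonal trend; on seasonally trending
  series the levels-mode coefficients are expected to exceed the delta-mode
  ones, and they do — the levels-mode associations are largely temporal
  autocorrelation, which is worth knowing before interpreting them.

## The synthetic generator

The generator emulates the study conditions, not any particular dataset:

- **Weather**: annual mean 6 °C, sinusoid amplitude 18 °C peaking at day
  200, AR(1) noise (marginal sd 3 °C, coefficient 0.6), ±4 °C diurnal
  half-range; wet-day probability 0.3 with gamma amounts (shape 0.7, scale
  10 mm). These reproduce upper-Midwest station climatology to first
  order: January means near −12 °C, July near +24 °C, ≈110 wet days/year.
- **Snow**: each of a block's 16 cells melts permanently once accumulated
  thaw degree-days exceed a cell threshold (mean 30 °C·day, sd 6), so
  block-mean onset is nondegenerate.
- **Depth**: a daily bucket balance (start 0.5 m, recharge 0.002 m/mm of
  rain, drawdown 0.008 m/day, daily process noise sd 0.003 m, clamped at
  0), not a groundwater model — the simplest mechanism with a tunable
  association strength between rain days and rise days. The noise term is
  what keeps the zero-coupling null well-defined (without it the increase
  count is identically zero and rank correlation is undefined). The 24
  hourly readings of a day are identical to the daily balance, so daily
  medians recover it exactly.
- **Acoustics**: half-normal background noise (sd 1 dB) above the −88 dB
  floor; planted calls raise each signature peak bin to `floor + SNR +
  offset` (SNR 30 dB) with a −5 dB rolloff on adjacent bins — the spectral
  width that makes the three-bin band median respond to calling. Calling
  windows open on the first day at or after block melt with `tmean ≥ 0` and
  after the first non-negative eight-day integrand; the integrand condition
  encodes that emergence follows *sustained* warmth, not a single warm day,
  and makes the observed ordering (no calls before the first warm interval)
  a structural property rather than a statistical tendency. Spring-peeper
  intensity follows a triangular seasonal profile with three boosted
  (+8 dB) planted peak days. Each species is absent in a site-year with
  probability 0.1 (occupancy ≈ 0.9, the observed range for such wetlands).
  Broadband masking events exist but default off: resolving a masked first
  call requires the aural review that automated matching deliberately does
  not model.
- **Landscape**: NDVI rises logistically from a 0.45 winter background to
  a 0.85 plateau (rate 0.35/week) with midpoint four weeks after snow-off,
  plus noise sd 0.02; the planted green-up truth is the first
  post-February week the *noise-free* logistic exceeds 0.60. ET is
  `0.2 mm/GDU × moisture`, moisture ramping with 30-day antecedent
  precipitation, summed into 8-day totals — zero all winter by
  construction.

All randomness flows from one master seed through fixed per-stream offsets,
so a configuration is byte-reproducible and streams can be regenerated
independently.

**What the generator does not emulate** — and hence what passing recovery
tests do not show about field data: real call spectra vary in shape and
overlap between species; wind/rain masking is pervasive rather than absent;
loggers fail mid-season; snow products suffer cloud contamination; NDVI
green-up is not logistic; and real depth dynamics include groundwater and
evapotranspiration terms. Recovery at 100%/±1 week on synthetic data
demonstrates the *detectors are faithful to their definitions*, not that
field error rates would be zero.

## Problem sizes and numerical choices

The standard validation study is 200 site-years (40 units × 5 years) for
event recovery; 200 replicate studies of 125 site-years each for the
zero-coupling null (the scale of a pooled multi-area deployment, where the
null sampling sd of ρ is ≈0.09); 1000 random vectors for the rank-formula
oracle; and 200 random years for the integrand/weekly-mean brute-force
scans. Quartiles use linear interpolation between order statistics
(quantile type 7). Ties in peak ranking go to the earlier date; equality at
thresholds is resolved as documented per index (green-up and ET onset
strict, temperature thresholds and climatograph surplus inclusive).

## Limitations

Leap years are not modelled. The NDVI smoother approximates, not
reproduces, any specific operational smoother. The climatograph rule is a
coarse 2 mm/°C screen, not a water-balance model. Occupancy is summarised
as a median proportion — detection probability is not modelled, which is
appropriate only when detection is effectively certain, as it is for
planted synthetic calls and for saturated acoustic sampling of loud,
prolonged callers.
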