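---
title: "Models and methods behind lickometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lickometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lickometry)
```

`lickometry` is an in-silico testbed for wireless multi-cage two-bottle
lickometer systems: devices that timestamp individual tongue contacts of
mice drinking from sippers, eight cages with two bottles each, multiplexed
into a single wireless acquisition channel. The package simulates the
entire measurement chain — licking behavior, capacitive-style sensing,
polled and frame-based detection, lossy UDP-style transmission — and the
analyses a drinking-microstructure study performs downstream. This
vignette explains the models, the parameters that matter, and the design
choices where the design was genuinely open.

## The lick-train model

Mouse drinking is strongly bout-structured: runs of rhythmic licking
separated by pauses. The generator is an alternating-renewal process:

* **Inter-bout gaps** are exponential with mean
  `inter_bout_interval_mean` (default 30 s for motivated test sessions;
  the overnight intake simulator uses 600 s, since drinking spreads over
  16 h there).
* **Bout lengths** (licks per bout) are geometric on 1, 2, ... with mean
  `licks_per_bout_mean` (default 30).
* **Within-bout interlick intervals (ILIs)** follow a gamma distribution
  with shape 10, truncated below at a 60 ms refractory floor. A shape-10
  gamma is unimodal, strictly positive, and has the coefficient of
  variation (~0.32) of the regular rhythm rodents show within bouts. The
  floor keeps the instantaneous rate below ~16.7 licks/s, just above what
  a 50 ms polling detector can in principle resolve.
* **Contact durations** are lognormal with mean 40 ms and SD 10 ms,
  clipped below the following ILI so contacts never overlap. This is a
  free parameter: it was chosen so that a 50 ms polling detector yields
  recall in the ~0.9 range typical of capacitive in vivo validations, and
  it is documented rather than hidden because recall depends on it
  directly.

The nominal within-bout rate defaults to 8.5 licks/s, the average licking
rate of a C57Bl/6 mouse; reported strain means range between 6 and 9
licks/s, which is the default plausibility band. One subtlety: truncating
a gamma at 60 ms raises its mean, so naively parameterizing the
pre-truncation mean at `1000/8.5` ms would deliver a realized rate of
about 8.33 licks/s. `lick_gen_params()` therefore calibrates the
pre-truncation mean numerically (by root finding at construction) so that
the *realized* truncated mean ILI is exactly `1000/rate`. The stated
parameter is the rate you measure back:

```{r rate}
train <- generate_lick_train(lick_gen_params(session_duration = 900, seed = 1))
ili <- diff(train$onset_ms)
1000 / mean(ili[ili <= 1000]) # close to the nominal 8.5 licks/s
```

Recovering the rate from data uses `ILI <= 1000 ms` as the within-bout
criterion; the ~3% of inter-bout gaps shorter than 1 s contaminate the
mean by well under the 0.3 licks/s acceptance band.

## The sensor model

A channel reads a baseline level (default 100 a.u.) with Gaussian noise
(SD 2 a.u.); a tongue contact adds `touch_amplitude` (50 a.u.) for the
contact's duration. Units are abstract because raw capacitance counts are
hardware-specific; what matters is the amplitude-to-noise ratio, 25 at
the defaults, which makes clean detection essentially certain. Samples
are instantaneous point reads — the integration a real capacitive
library performs over its read window is not modeled, which is simpler
and changes nothing about the detection logic being validated. Gaussian
baseline noise is an assumption; the real noise distribution is not
documented for this class of device.

"Confuser" events — elevations not caused by licks, like a snout
blocking a photoelectric beam — arrive as a Poisson process
(`confuser_rate` per minute, default 0). They exist to reproduce the
precision gap between sensor types: a photoelectric-style sensor counts
approaches, a capacitive one counts tongue contacts, so confusers
manufacture false positives without touching recall.

Thresholds come from a one-minute mouse-free baseline capture
(1000 samples at the 60 ms period): `threshold = mean + k * sd` with
`k = 5`. The in vivo procedure only says a threshold "was established"
post hoc; mean + 5 SD separates the default noise from a 50 a.u. touch
with more than 20 SDs of margin, and `k` is exposed for degraded
regimes. The file-based CLI detector uses the median and scaled MAD of
the whole trace instead, since a stored trace contains licks and a
robust location/scale pair is the right baseline estimate there.

## Two detectors

The **prototype** polls one channel every 50 ms and counts rising edges
(a poll above threshold whose predecessor was below), then ignores polls
inside a 5 ms refractory window — debounce semantics that prevent double
counting a single contact. Timestamps are poll instants: the hardware
cannot know the true onset. With contacts at least one poll period long,
ILIs at least two periods, and no noise, every lick is counted exactly
once for every poll-grid phase offset; the tests sweep the offsets
exhaustively.

The **wireless** system scans 16 channels through a multiplexer once per
60 ms frame (16.67 samples/s per channel; sequential scan offsets of
`frame_period/16`, so channel 16 is read 56.25 ms after channel 1 — the
scan schedule is not documented for the real firmware and uniform offsets
are the natural choice). Two firmware models are provided because the
deployed behavior is not fully specified:

* **Edge mode** counts threshold crossings at the instantaneous reads.
  At 5 Hz pulses (100 ms high per 200 ms period) every high phase spans a
  60 ms read grid and edge detection is exact. At 10 Hz with 50% duty the
  high phase (50 ms) is shorter than a frame, and instantaneous reads
  *must* miss pulses — incompatible with the sub-0.1% reading errors the
  hardware achieves at 10 Hz.
* **Latched mode** (the default for protocol emulation) models a front
  end in which each pulse sets a per-channel latch consumed by the next
  frame read. A latch is one bit: event rates above the frame rate
  saturate it, but at 5 and 10 Hz at most one pulse falls between
  consecutive reads. The residual acquisition failure is a per-pulse miss
  probability, default `5e-4`, chosen to sit in the middle of the
  ~0.02–0.07% reading-error band such systems report; it is a calibrated
  artifact default, not a measurement.

## Transmission model

The wireless link is UDP: delivery is not guaranteed. The unit of loss is
one frame-packet carrying all 16 channel values (packet granularity is
not documented for the real system; frame-packets are the natural unit
and make transmission error depend on how many active channels had events
in a dropped frame, reproducing the observed variation across phases and
cage counts). Bernoulli loss with `loss_prob = 0.008` gives a mean
transmission error of about −0.8%, the order of magnitude wireless
validations of this design report (−0.4% to −1.2%); this too is an
explicit tuning. A two-state Gilbert–Elliott burst model is available for
busy-bandwidth conditions, and packet duplication (default off) covers
the possibility of positive transmission errors. Signed transmission
error is `(received − sent)/sent × 100`, negative meaning net loss;
reading error is `(emitted − detected)/emitted × 100`.

## The three-phase validation grid

`run_insilico_protocol()` reproduces the emulated-signal validation:
Phase 1 pulses bottle A only, Phase 2 bottle B only, Phase 3 both
alternately, at 5 and 10 Hz, with 12,000 pulses per pulsed output, for
1–8 simultaneously active cages. "Alternately" is interpreted as A/B
interleaving at a half-period offset within each cage (the offset is not
otherwise defined, and half-period interleaving is what an alternating
driver produces). Replicates default to 10 per cell — the replicate count
behind the published error boxes is not stated, so it is configurable and
documented rather than inferred — and per-cell seeds are
`base_seed + cell index`, so any cell is reproducible in isolation.

```{r grid}
grid <- run_insilico_protocol(cages = c(1, 8), replicates = 3,
                              n_pulses = 2000, seed = 1)
glance(grid)
```

For speed the grid runner computes the latched acquisition at the event
level (per-pulse frame-read assignment) rather than materializing dense
40,000-frame × 16-channel matrices per cell; the package tests assert
this path produces identical counts and timestamps to the dense
`multiplex()` + `detect_wireless()` chain. Statistical comparisons across
phases (Kruskal–Wallis and post hoc corrections) are deliberately not
built in: the report exposes every per-cell value so any test can be
applied externally.

## Scoring detections

`match_events()` matches detections to truth greedily in time order: each
detection takes the nearest unmatched truth onset whose window contains
it, ties toward the earlier onset. The window is asymmetric —
`[onset, onset + contact + tolerance]` with tolerance defaulting to one
60 ms frame — because detections are stamped at read instants, which
always trail onsets: a detection within the same contact or the
immediately following frame is the same lick. Greedy nearest matching is
the production algorithm; on instances in the physiological regime
(truth onsets separated by at least the refractory floor, detection
latency below the window) it coincides with exhaustive optimal
assignment, which the tests verify on hundreds of small random
instances. Pathologically overlapping windows can separate greedy from
optimal, which is why the equivalence is asserted in that regime rather
than universally.

## Microstructure and intake

Bout segmentation cuts wherever an ILI exceeds `bout_break_ms`. The
source studies name bouts without defining them; 1000 ms is the common
rodent-lickometry convention and the parameter is deliberately prominent.
Light/dark tagging of time bins uses the standard housing schedule
(lights on 07:00, 12/12 h) with sessions starting 2 h before lights-off
for 16 h by default; a bin takes the tag of its start instant.

The intake correlation is Spearman's rank correlation between consumed
grams (bottle weight before minus after) and total licks, with a
least-squares R² reported descriptively; p-values are exact permutation
for n ≤ 20 and large-sample otherwise (both via `stats::cor.test`).
Rank correlation is the right choice because per-lick volume varies
across animals, making the relationship monotone but not linear.

Because real overnight drinking data cannot ship with a simulator,
`simulate_intake_sessions()` provides a synthetic analogue: per
animal × session × bottle lick trains, grams = licks × 1.5 µL × density
(1.0 water, 0.984 g/mL for 10% v/v ethanol) plus 0.05 g weighing noise.
Animals receive lognormal multipliers on drinking propensity (SD(log)
0.4) and per-lick volume (SD(log) 0.2): without between-animal variance
every session would have the same expected intake and a correlation
would be meaningless. The 1.5 µL per lick and the heterogeneity SDs are
stated assumptions — the device class explicitly does not measure
volume. With these defaults a 96-session data set yields Spearman rho
above 0.8, qualitatively matching in vivo validations of such devices;
the package makes no claim to reproduce any particular animal data set's
coefficient, and the pooling (each point is one animal × session ×
bottle) is its own documented convention.

```{r intake}
sessions <- simulate_intake_sessions(
  n_animals = 12, n_sessions = 1,
  lick_params = lick_gen_params(session_duration = 3600,
                                inter_bout_interval_mean = 120),
  seed = 2
)
tidy(intake_correlation(sessions, by_liquid = TRUE))
```

## Numerical conventions and degenerate inputs

Time is milliseconds from session start, real-valued and 0-based;
wall-clock conversion uses a configured session-start timestamp
(ISO-8601 with milliseconds in files — a 1 s hardware RTC resolution
would be too coarse for detection math). Pulse-train periods are exact
(`1000/f` ms arithmetic, no accumulation). A sample belongs to a contact
interval under the half-open convention `[onset, onset + contact)`; a
latch consumes onsets at the first read at-or-after the onset.
Zero-duration sessions give empty trains; empty event sets give empty
ILI lists, empty bout tables and zero-rate windows; precision, recall,
transmission error, reading error and correlations *error* rather than
return a value when their denominators are empty, because "undefined" and
"zero" mean different things in every one of those metrics. Truncated
gamma sampling uses the inverse-CDF transform (no rejection loops), so
generated streams are reproducible sample-for-sample under a seed.

## Problem sizes used by the checks

The packaged checks run the full default grid — 3 phases × 2 frequencies
× 8 cage counts × 10 replicates at 12,000 pulses per output (640 report
rows) — plus a 3600 s rate-recovery session; together they complete in
well under a minute. Oracle-equivalence properties use exhaustive
matching on instances of up to ~7 events and dense-grid detector
reimplementations on signals up to 5 s, sizes at which brute force is
exact and fast.

## Known limitations

* The sensor model is a level-plus-noise abstraction: no drift, no
  electrode polarization, no integration window, no animal-specific
  capacitance variation. Passing tests validate the detection and
  transmission logic, not any claim about a particular hardware build.
* The latch model conserves at most one event per channel per frame;
  event rates above the frame rate alias, as they would in the hardware.
* Loss and miss probabilities are calibrated defaults, so grid error
  magnitudes are model-consistency checks, not measurements of a
  physical link.
* The synthetic intake data set encodes its own heterogeneity
  assumptions; real two-bottle data have structure (circadian preference
  drift, side biases, evaporation) the simulator does not attempt.
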