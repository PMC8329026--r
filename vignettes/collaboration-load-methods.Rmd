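---
title: "Measuring collaboration load from pupillary and gaze responses: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring collaboration load: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dyadload)
```

## The measurement problem

In task-oriented dialogue, speakers often deliver an instruction not as one
utterance but as a sequence of intonationally complete fragments, each an
installment toward common ground, while monitoring the listener for evidence
of understanding. `dyadload` operationalises the cost of that strategy for
both partners: task-evoked pupillary responses as a cognitive-load index,
and 3D gaze-target measures as an index of visual grounding. The unit of
analysis is the (utterance segment × participant role) pair; segments arrive
as hand-made annotations (an ELAN tier or a flat tab-separated export) —
detecting fragment boundaries from audio or prosody is explicitly out of
scope.

## Pupil pipeline

The chain is merge → interpolate → filter → exclude → baseline → metrics.

**Binocular merge.** Left and right pupil diameters are highly correlated;
frames with both eyes take their mean, one-eyed frames take the available
eye, frames with neither are invalid placeholders. Missingness is data, not
an error, and every frame carries a provenance flag
(`merged-both`/`merged-left-only`/`merged-right-only`/`none`/`interpolated`/
`excluded`) exportable for audit.

**Gap interpolation.** Runs of unusable frames up to `max_gap_frames`
(default 25 frames = 0.5 s at 50 Hz, a typical blink) are bridged linearly
between their flanking valid frames. Edge gaps are never extrapolated;
longer gaps stay invalid.

**Low-pass filtering.** A 5th-order Butterworth low-pass with a 4 Hz
cut-off at the 50 Hz sampling rate, the standard smoothing choice for
video-based pupillometry. Two numerical choices matter:

* *Zero phase.* The default applies the filter forward and backward so the
  smoothed trace has no group delay — metric windows would otherwise be
  shifted by several frames. A causal single-pass mode
  (`filter_spec(zero_phase = FALSE)`) is retained for sensitivity checks.
* *Edge handling.* The forward–backward pass is run on an odd-reflection
  padded copy of the signal (pad length 250 frames or the series length,
  whichever is smaller) so start-up transients decay inside the pads; a
  constant series is reproduced to better than 1e-9. Frames that were
  invalid are bridged only so the filter sees a finite signal — the
  validity mask is untouched and those frames never enter a metric.

**Outlier exclusion.** Two rules: the physiologically feasible diameter
range 1.5–9 mm, and a z-score rule excluding samples more than 2 SD from
the mean. The range rule is applied first and the z statistics are computed
on range-surviving frames — the stricter reading of a rule that is usually
stated in one breath. Statistics default to per-participant-per-recording
scope (participant variability is otherwise absorbed downstream by the
participant random intercept); a pooled global scope is available by
passing explicit `center`/`scale`. With the default
`recompute_stats = FALSE`, re-applying the rule is idempotent. Whether
exclusion should run before or after filtering is not settled practice;
the pipeline default filters first, and the operations are exposed
separately so the other order is one line of code.

**Baseline and metrics.** The baseline is the mean diameter over a
pre-stimulus window (default 5 s, ending at the first instruction onset;
at least 50% of window frames must be usable). "A few seconds" is the
conventional prescription; 5 s is this package's fixed choice. Per segment
with at least 2 usable frames: signed mean dilation, peak dilation, and the
least-squares slope of diameter on frame index. **Slope is in mm per frame
at 50 Hz** — multiply by 50 for mm/s. This matches the magnitudes
(~1e-3–1e-4) conventionally reported for per-frame regressions; using
per-second units would scale every slope by 50.

## Gaze pipeline

Each valid gaze sample is a ray; the angular distance to a candidate is the
visual angle between the ray and the vector from eye origin to candidate
centre. Candidates are all scene objects plus the partner's head region (a
sphere, default radius 0.15 m). The frame target is the candidate with the
smallest angle within `threshold_deg`; ties break by 3D distance, then
lexicographic id (deterministic and order-free). The capture cone default
of 10° is a config choice, not an empirical constant — no published value
exists for this apparatus — and all structural properties hold for any
positive threshold.

Two conventions needed a decision:

* *Denominator.* Proportions are of **segment time**: invalid frames and
  frames on no candidate stay in the denominator, so gaze-to-target +
  gaze-to-other + gaze-to-person + remainder = 1. A valid-time mode exists
  (`denominator = "valid-time"`). Invalid samples and "gazing elsewhere"
  are kept as distinct flags throughout.
* *First-gaze horizon.* The latency of the first fixation on the referent
  is counted from utterance onset, within the segment **extended to the
  next segment's onset**, so an identification that lands just after the
  fragment is still captured. If the referent is never fixated the value
  is *undefined* (an empty CSV cell, `NA` in memory) and such rows are
  dropped listwise from that metric's statistics — never imputed.

Joint attention counts frames where both roles' target is the uttered
referent simultaneously; mutual gaze counts frames where both targets are
the partner. Both are symmetric in the roles by construction.

## Instruction coding

Segments sharing an instruction id form one unit directed at one referent;
ordinals Utt-1..Utt-n are (re)assigned in temporal order and a unit is
fragmented iff n > 1. The sequence analysis slices fragmented units by
ordinal; slice sizes are non-increasing by construction. Ordinals above 4
are coded but flagged, and the analysis caps at Utt-4 by default (a config
override exists): fifth and later fragments are too rare to support
per-ordinal cells. Listener back-channels are not segments of the unit;
annotated segment extents are authoritative.

## Statistical design

All models are linear mixed models fitted by **maximum likelihood** (not
REML), because log-likelihoods are compared across fixed-effects
structures. Each term's chi-square is twice the log-likelihood difference
of a nested pair, with df = parameters added; df is always reported
explicitly. The nesting is *drop-one*: main effects are tested within the
additive model, the interaction against the additive model — a scheme that
keeps each test a clean one-term comparison. Random intercepts default to
interaction and instructed object, adding participant for the pupil
responses. A singular random-effects fit falls back to a reduced structure
(smallest variance component dropped, logged as a warning), and the reduced
structure is reused for every model in the comparison so the tests stay
nested. A constant response short-circuits to χ² = 0 for every term: all
nested fits are identical. Dyad-shared measures (duration, joint attention,
mutual gaze) are analysed on one role's rows with the fragment factor only,
to avoid duplicating every observation.

The correlation screen computes Spearman's ρ (midrank-based, asymptotic p)
between each measure and the instruction's fragment count, multiplies p by
the number of correlations screened (Bonferroni, capped at 1, divisor
recorded in the output), and flags as reported only |ρ| > 0.15 with
adjusted p < 0.05. Constant measures have no defined rank correlation and
are excluded with a note.

## The synthetic dyad generator

`generate_dyads()` is first-class, tested code, not a fixture. It emulates:
50 Hz binocular pupil with per-eye missingness and blink artefacts
(dropout plus negative edge spikes, the signature of video-based trackers);
baseline-referenced dilation differences between conditions; gaze rays that
dwell on referent/distractor/partner targets with condition-dependent
first-gaze latencies; and fragment-structured tiers with 1–4 fragments per
instruction. Defaults are the benchmark profile: duration, latency and
dilation cells and the fragment-count distribution are set to a reference
corpus's per-cell values, and validity rates to 77%/78%.

Choices worth recording:

* **Durations are moment-matched lognormal** (right-skewed, positive) so
  the configured cell mean and SD are reproduced without the truncation
  bias a clipped Gaussian would introduce.
* **Pupil noise is AR(1)** (coefficient 0.95 at 50 Hz, marginal SD 0.1 mm)
  rather than white, so the low-pass filter has realistic work to do; slow
  noise also puts honest between-segment variance into the dilation cells.
* **Scripted latencies are frame-quantised** at generation time, so
  pipeline recovery can be checked at exact frame resolution (the suite
  verifies ±1 frame at zero angular jitter and full validity).
* Gaze jitter perturbs ray directions by ~2° RMS by default; scene
  geometry keeps candidate separations an order of magnitude larger than
  the jitter, so assignment is unambiguous at the default cone.

What it does **not** emulate: scan-path realism (saccade kinematics,
microsaccades), the pupil light reflex or luminance coupling, listener
speech, head motion, or annotation noise in segment boundaries. Passing
tests therefore demonstrate that the measurement chain is correct and
well-calibrated on signals with known structure — not that any scientific
conclusion transfers to a particular human corpus.

## Calibration and problem sizes

The suite checks, among others: the filter's impulse response against a
naive direct-form recursion (1e-9) and its pass/stop-band behaviour (1 Hz
> 0.95, 10 Hz < 0.05); every exclusion set, interpolated value, slope,
proportion, vote and overlap against brute-force recomputation on 200
randomized inputs; LRT type-I error within [0.025, 0.085] under a
200-replicate null at n = 400 rows and power ≥ 0.90 (p < 0.01) for a 1 SD
role effect over 100 replicates; recovery of a configured 0.14 mm
instructor dilation delta within 2 Monte-Carlo SEs over 50 replicate
corpora (3 dyads × 6 instructions each); and seed determinism of the whole
simulate → metrics → tables path. These sizes are the package's chosen
trade-off between Monte-Carlo resolution and a test suite that runs in a
couple of minutes; all are plain arguments, so heavier calibration runs are
one call away.

## Known limitations

* The EAF reader supports alignable annotations with
  `instruction:ordinal:referent` values — the dialect the writer emits —
  not arbitrary ELAN tier hierarchies.
* Person regions are static spheres; a moving-head scene would need
  time-varying person positions (the scene schema has a single centre).
* The z-score exclusion operates per recording; drifting recordings could
  mask local outliers (the explicit `center`/`scale` override is the
  escape hatch).
* Chi-square magnitudes from LRTs grow with n; comparing them across
  corpora of different sizes is meaningful only for sign/significance, not
  magnitude.
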