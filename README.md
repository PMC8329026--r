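# dyadload

Measurement and analysis chain for quantifying **collaboration load** in
task-oriented dyadic interaction — for researchers in psycholinguistics,
psychophysiology and human–robot interaction who study how speakers package
instructions into fragments ("installments") and what that costs both
conversational partners.

In a referential assembly task an *instructor* tells a *builder* which
object to pick next. An **instruction unit** (all utterances about one
referent object) is *non-fragmented* when delivered as a single utterance
and *fragmented* when delivered as a sequence of fragments coded
Utt-1..Utt-n. `dyadload` turns synchronized 50 Hz sensor streams plus an
ELAN-style utterance tier into ten behavioural measures per
(utterance segment × participant role), and tests how they differ by
fragmentation, fragment ordinal and role.

## What it computes

**Task-evoked pupillary response** (cognitive-load index). The binocular
pupil stream is merged (mean of both eyes, else the available eye), short
gaps (blinks) are bridged linearly, the trace is smoothed with a zero-phase
5th-order low-pass Butterworth filter (4 Hz cut-off at 50 Hz), and samples
outside the feasible range [1.5–9 mm] or more than 2 SD from the mean are
excluded. Relative to a pre-stimulus baseline b, each utterance segment
yields

- mean dilation `mean(d_t − b)` (positive = dilation, negative = contraction),
- peak dilation `max(d_t − b)`,
- slope: least-squares slope of `d_t` on frame index (mm/frame at 50 Hz).

**3D gaze-target measures.** Each gaze sample is a ray (origin, direction)
in the shared scene frame; the frame's target is the candidate (objects and
the partner's head) with the smallest visual angle within a capture cone
(default 10°). Per segment: first gaze to target referent (latency from
utterance onset, s), proportional gaze to target / other objects / person
(proportions of segment time), joint attention (both partners on the
uttered referent simultaneously) and mutual gaze (both looking at each
other). The segment's most prominent target is resolved by majority voting.

**Statistics.** Linear mixed models fitted by maximum likelihood
(`lme4`), with fragmentation (2-level type, or 4-level ordinal sequence),
role, and their interaction as fixed factors and random intercepts for
interaction and instructed object (plus participant for pupil responses).
Each term is tested by a likelihood-ratio chi-square (χ² = 2Δlogℒ of nested
ML fits), with per-cell mean ± SD tables; a Spearman screen correlates each
measure with the number of fragments per instruction, Bonferroni-corrected,
reporting |ρ| > 0.15.

**Synthetic dyads.** `generate_dyads()` emits full recordings with known
ground truth — scripted per-frame gaze targets and first-gaze latencies,
per-segment dilation effects, AR(1) pupil noise, blink dropouts with edge
spikes, configurable gaze validity — so the whole chain is testable end to
end. `benchmark_profile()` packages generative parameters anchored to a
reference corpus's cell means.

## Worked example

```r
library(dyadload)
gen  <- generate_dyads(sim_config(n_interactions = 6), seed = 42)
print(gen$recordings[[1]])
#> <dyad_recording> sim001: 9 instruction units (16 segments), 0-71.84 s

rows <- compute_metrics_all(gen$recordings)
rows[1:2, c("instruction_id", "fragment_ordinal", "role",
            "first_gaze_to_target", "gaze_to_target", "mean_dilation")]
#>   instruction_id fragment_ordinal       role first_gaze_to_target gaze_to_target mean_dilation
#> 1          ins01                1 instructor                 1.86      0.2575758    -0.1546392
#> 2          ins01                1    builder                 1.44      0.3484848     0.1932573

rows$fragment <- rows$instruction_type
fit_and_test(rows, model_spec("mean_dilation", c("fragment", "role")))
#> <stats_result> mean_dilation ~ fragment * role + (1 | referent_id) (ML) [n = 202]
#>   fragment               chisq(1) =     0.73  p = 0.3915
#>   role                   chisq(1) =     0.09  p = 0.7672
#>   fragment:role          chisq(1) =     0.31  p = 0.5796
```

Row 1 reads: during the first fragment of instruction `ins01` the
instructor first fixated the referent 1.86 s after utterance onset, spent
26% of the segment on it, and their pupil was 0.15 mm *below* baseline. The
model output lists, per fixed term, the likelihood-ratio χ², its degrees of
freedom and p-value (at this small demo scale no term is significant; the
singular interaction intercept was dropped automatically and logged). The
correlation screen on the same corpus reports, e.g., builders' first-gaze
latency falling steeply with fragment count (ρ = −0.84, adjusted
p < 0.001).

The one-command variant writes every table plus a run log:

```r
run_pipeline(list(sim = list(n_interactions = 6)), out_dir = "out", seed = 42)
```

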