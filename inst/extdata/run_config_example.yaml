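# Full run-configuration schema for run_pipeline(). Every field is optional;
# the values below are the defaults.
mode: simulate            # simulate | corpus
# corpus_dirs: [path/one, path/two]   # corpus mode: recording directories
sim:                      # simulate mode: sim_config() overrides
  n_interactions: 28
  instructions_per_interaction: 9
threshold_deg: 10         # gaze capture cone half-angle, degrees
max_gap_frames: 25        # longest pupil gap bridged (frames, 0.5 s at 50 Hz)
denominator: segment-time # gaze proportions: segment-time | valid-time
filter:
  order: 5
  cutoff_hz: 4
  sampling_hz: 50
  zero_phase: true
outlier:
  feasible_min_mm: 1.5
  feasible_max_mm: 9
  z_threshold: 2
  z_scope: per-participant
max_ordinal: 4            # sequence analysis cap (Utt-1..Utt-4)
write_audit: true         # emit per-frame gaze-target audit CSV
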