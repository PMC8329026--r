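# Readers/writers and domain-type validation.

test_that("tsv tier dialect round-trips and single-utterance units are non-fragmented", {
  segs <- rbind(make_segments(c(10, 12, 14), c(11.5, 13, 15.2), "i01",
                              ordinal = 1:3),
                make_segments(20, 24.24, "i02", ordinal = 1, referent = "obj02"))
  tier <- code_instructions(segs)
  expect_equal(tier$units$type, c("fragmented", "non_fragmented"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotation_tier(tier, path)
  back <- read_annotation_tier(path, dialect = "tsv")
  expect_equal(back$segments[names(tier$segments)], tier$segments)
  expect_equal(back$units, tier$units)
})

test_that("EAF dialect parses the packaged fragmented/non-fragmented example", {
  path <- system.file("extdata", "dialogue_example.eaf", package = "dyadload")
  tier <- read_annotation_tier(path)
  u <- tier$units[order(tier$units$instruction_id), ]
  expect_equal(u$instruction_id, c("i01", "i02"))
  expect_equal(u$n_fragments, c(4L, 1L))
  expect_equal(u$type, c("fragmented", "non_fragmented"))
  s1 <- tier$segments[tier$segments$instruction_id == "i01", ]
  expect_equal(s1$fragment_ordinal, 1:4)
  expect_equal(s1$start[1], 6.0)
  expect_equal(s1$end[4], 14.5)
  expect_equal(tier$segments$referent_id[tier$segments$instruction_id == "i02"],
               "obj03")
})

test_that("tier validation rejects bad ordinals, overlaps and unknown referents", {
  expect_error(code_instructions(make_segments(c(1, 3), c(2, 4), "i01",
                                               ordinal = c(1, 3))),
               "non-contiguous")
  expect_error(code_instructions(rbind(
    make_segments(1, 3, "i01", ordinal = 1),
    make_segments(2.5, 4, "i02", ordinal = 1))),
    "overlapping.*i01.*i02")
  expect_error(code_instructions(data.frame(
    interaction_id = "ia1", instruction_id = "i01", fragment_ordinal = 1:2,
    start = c(1, 3), end = c(2, 4), referent_id = c("obj01", "obj02"),
    speaker_role = "instructor")), "mixes referent")

  gen <- generate_dyads(quiet_sim(), seed = 1)
  rec <- gen$recordings[[1]]
  bad_tier <- rec$tier
  bad_tier$units$referent_id[1] <- "ghost"
  expect_error(dyad_recording(rec$interaction_id, rec$gaze, rec$pupil,
                              rec$scene, bad_tier, rec$baseline_window),
               "ghost")
})

test_that("stream readers snap to the 50 Hz grid and insert invalid placeholders", {
  # 11 frames, then a 9-frame gap, then 5 frames: oracle row count is
  # (t_end - t_start) * 50 + 1
  t <- c(seq(0, 0.2, by = 0.02), seq(0.4, 0.48, by = 0.02))
  df <- data.frame(t = t, ox = 0, oy = 0, oz = 0, dx = 0, dy = 1, dz = 0,
                   valid = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  g <- read_gaze_stream(path)
  expect_equal(nrow(g), (0.48 - 0) * 50 + 1)
  expect_equal(sum(!g$valid), nrow(g) - length(t))
  expect_true(all(diff(g$t) > 0))

  # empty file -> empty stream, no error
  write.csv(df[0, ], path, row.names = FALSE)
  expect_equal(nrow(read_gaze_stream(path)), 0)

  # non-monotone timestamps -> error
  df2 <- df[c(2, 1, 3), ]
  write.csv(df2, path, row.names = FALSE)
  expect_error(read_gaze_stream(path), "non-monotone")

  # pupil unit sanity: micrometre-scale values are rejected
  pp <- data.frame(t = seq(0, 1, by = 0.02), left_mm = 4000, right_mm = 4100)
  write.csv(pp, path, row.names = FALSE)
  expect_error(read_pupil_stream(path), "millimetres")
})

test_that("metric tables round-trip losslessly, preserving undefined sentinels", {
  gen <- generate_dyads(quiet_sim(), seed = 2)
  rows <- compute_metrics(gen$recordings[[1]])
  rows$first_gaze_to_target[1] <- NA   # force an undefined cell
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_table(rows, path)
  back <- read_metric_table(path)
  expect_equal(back, rows, tolerance = 1e-12)
  expect_true(is.na(back$first_gaze_to_target[1]))

  # 0 rows -> header-only file that still round-trips
  write_metric_table(rows[0, ], path)
  expect_equal(nrow(read_metric_table(path)), 0)
  expect_equal(names(read_metric_table(path)), names(rows))
})

test_that("metric durations equal their segment extents and scenes round-trip", {
  gen <- generate_dyads(quiet_sim(), seed = 3)
  rec <- gen$recordings[[1]]
  rows <- compute_metrics(rec)
  key <- paste(rows$instruction_id, rows$fragment_ordinal)
  segs <- rec$tier$segments
  skey <- paste(segs$instruction_id, segs$fragment_ordinal)
  expect_equal(rows$duration, (segs$end - segs$start)[match(key, skey)],
               tolerance = 1e-12)

  path <- withr::local_tempfile(fileext = ".json")
  write_scene(rec$scene, path)
  back <- read_scene(path)
  expect_equal(back$objects, rec$scene$objects)
  expect_equal(back$persons, rec$scene$persons)
})
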