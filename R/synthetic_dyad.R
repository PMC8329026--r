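# Synthetic dyad generator: emits DyadRecordings with scripted ground truth
# (gaze-target sequences, first-gaze latencies, dilation effects, fragment
# structure) so every pipeline stage and the statistics are testable without
# any corpus download. Default parameters are anchored to the reference
# study conditions: 50 Hz streams, binocular pupil with blink artefacts,
# baseline-referenced dilation differences between fragmented and
# non-fragmented instructions, condition-dependent first-gaze latencies, and
# 1-4 fragments per instruction.

#' Simulation configuration
#'
#' Defaults encode the benchmark profile: cell means for durations,
#' dilations and latencies follow the reference corpus tables, the fragment
#' count distribution follows its instruction counts, and the noise model
#' (AR(1) pupil noise, blink dropouts with edge spikes, gaze validity around
#' 77-78%) mimics video-based eye-tracker data.
#'
#' @param n_interactions number of dyads.
#' @param instructions_per_interaction instruction units per dyad.
#' @param fragment_dist probability over 1..4 fragments per instruction.
#' @param n_objects scene objects (half referent candidates, half
#'   distractors).
#' @param object_radius,person_radius capture radii, metres.
#' @param baseline_mean_mm,baseline_sd_mm between-participant resting pupil
#'   diameter distribution.
#' @param baseline_s pre-stimulus baseline window length, seconds.
#' @param dilation_mm per-role condition effects (mm above baseline during a
#'   segment): `non_fragmented` scalar and `ordinal` vector (Utt-1..4).
#' @param dilation_sd_mm between-segment SD of the dilation effect.
#' @param latency_mean_s per-role scripted first-gaze latency means:
#'   `non_fragmented` scalar and `ordinal` vector.
#' @param latency_sd_s SD of scripted latencies.
#' @param p_no_gaze probability a role never fixates the referent in a
#'   segment (undefined first-gaze latency).
#' @param duration_mean_s,duration_sd_s utterance duration cells:
#'   `non_fragmented` scalar and `ordinal` vector, seconds.
#' @param ar_coef,pupil_noise_sd_mm AR(1) coefficient at 50 Hz and marginal
#'   noise SD of the pupil trace.
#' @param eye_noise_sd_mm independent per-eye measurement noise SD.
#' @param blink_rate_per_min,blink_duration_frames,blink_spike_mm blink
#'   artefact model: dropout length and the amplitude of the edge spikes
#'   flanking each dropout.
#' @param eye_missing_rate per-eye independent missing-sample rate outside
#'   blinks.
#' @param gaze_validity per-role valid gaze sample rate.
#' @param angular_jitter_deg RMS angular perturbation of emitted gaze rays;
#'   0 gives rays exactly through target centres.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_interactions = 28,
                       instructions_per_interaction = 9,
                       fragment_dist = c(0.45, 0.32, 0.14, 0.09),
                       n_objects = 8,
                       object_radius = 0.10,
                       person_radius = 0.15,
                       baseline_mean_mm = 4.0,
                       baseline_sd_mm = 0.4,
                       baseline_s = 5,
                       dilation_mm = list(
                         instructor = list(non_fragmented = 0.00,
                                           ordinal = c(0.04, 0.16, 0.24, 0.36)),
                         builder = list(non_fragmented = 0.12,
                                        ordinal = c(0.15, 0.07, 0.09, 0.13))),
                       dilation_sd_mm = 0.25,
                       latency_mean_s = list(
                         instructor = list(non_fragmented = 1.22,
                                           ordinal = c(1.40, 0.49, 0.46, 0.37)),
                         builder = list(non_fragmented = 1.79,
                                        ordinal = c(1.79, 0.57, 0.45, 0.44))),
                       latency_sd_s = 0.40,
                       p_no_gaze = 0.03,
                       duration_mean_s = list(non_fragmented = 4.24,
                                              ordinal = c(3.75, 1.79, 1.49, 1.49)),
                       duration_sd_s = list(non_fragmented = 2.49,
                                            ordinal = c(1.80, 0.89, 0.73, 0.78)),
                       ar_coef = 0.95,
                       pupil_noise_sd_mm = 0.10,
                       eye_noise_sd_mm = 0.02,
                       blink_rate_per_min = 15,
                       blink_duration_frames = 10,
                       blink_spike_mm = 0.8,
                       eye_missing_rate = 0.05,
                       gaze_validity = c(instructor = 0.77, builder = 0.78),
                       angular_jitter_deg = 2) {
  stopifnot(abs(sum(fragment_dist) - 1) < 1e-8, all(fragment_dist >= 0),
            length(fragment_dist) == 4,
            dilation_sd_mm >= 0, latency_sd_s >= 0,
            duration_mean_s$non_fragmented > 0,
            all(duration_mean_s$ordinal > 0),
            ar_coef >= 0, ar_coef < 1)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' The benchmark simulation profile
#'
#' A packaged [sim_config()] whose generative parameters are set to the
#' reference study's per-cell means and SDs (durations, dilation cells,
#' first-gaze latency cells), so a simulated corpus resembles that study's
#' metric tables in its cell means. These are also the package defaults.
#'
#' @param ... overrides passed to [sim_config()].
#' @return a `sim_config`.
#' @export
benchmark_profile <- function(...) sim_config(...)

# Scene template: two participants facing each other over a table of
# objects. Object columns alternate referent-candidate / distractor.
build_scene <- function(cfg) {
  n <- cfg$n_objects
  gx <- rep(seq(-0.3, 0.3, length.out = ceiling(n / 2)), each = 2)[1:n]
  gy <- rep(c(-0.2, 0.2), length.out = n)
  objects <- data.frame(
    object_id = sprintf("obj%02d", seq_len(n)),
    kind = rep(c("referent-candidate", "distractor"), length.out = n),
    x = gx, y = gy, z = 0.75,
    radius = cfg$object_radius,
    stringsAsFactors = FALSE)
  persons <- data.frame(
    role = c("instructor", "builder"),
    x = c(0, 0), y = c(-0.9, 0.9), z = 1.2,
    radius = cfg$person_radius,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(persons))) {
    d2 <- sqrt((objects$x - persons$x[i])^2 + (objects$y - persons$y[i])^2 +
                 (objects$z - persons$z[i])^2)
    if (any(d2 < objects$radius + persons$radius)) {
      stop("infeasible geometry: object overlaps a person region")
    }
  }
  dyad_scene(objects, persons)
}

rtrunc_norm <- function(n, mean, sd, lo, hi = Inf) {
  pmin(hi, pmax(lo, stats::rnorm(n, mean, sd)))
}

# Moment-matched lognormal: positive, right-skewed (realistic for durations)
# and with exactly the configured mean and SD -- no truncation bias.
rlnorm_ms <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, log(mean) - s2 / 2, sqrt(s2))
}

cell_value <- function(cells, type, ordinal) {
  if (type == "non_fragmented") cells$non_fragmented
  else cells$ordinal[min(ordinal, length(cells$ordinal))]
}

ar1_noise <- function(n, phi, marginal_sd) {
  if (marginal_sd == 0 || n == 0) return(numeric(n))
  innov_sd <- marginal_sd * sqrt(1 - phi^2)
  x <- numeric(n)
  e <- stats::rnorm(n, 0, innov_sd)
  x[1] <- stats::rnorm(1, 0, marginal_sd)
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + e[i]
  x
}

# Perturb unit rows of `d` by ~jitter_deg RMS and renormalise.
jitter_directions <- function(d, jitter_deg) {
  if (jitter_deg == 0) return(d)
  s <- tan(jitter_deg * pi / 180) / sqrt(2)
  d <- d + matrix(stats::rnorm(length(d), 0, s), ncol = 3)
  d / sqrt(rowSums(d^2))
}

#' Generate a synthetic dyad corpus with ground truth
#'
#' Emits `n_interactions` [dyad_recording()]s at 50 Hz. The pupil trace is
#' baseline + per-segment condition effect + AR(1) noise + blink artefacts
#' (dropouts flanked by negative edge spikes); gaze rays point at scripted
#' per-frame targets, perturbed by angular jitter; the annotation tier is
#' consistent with the scripted fragment structure. Reproducible: the same
#' seed yields bit-identical output.
#'
#' @param cfg a [sim_config()].
#' @param seed integer RNG seed.
#' @return `list(recordings, truth)`; `truth` holds `segments` (scripted
#'   per-segment latencies and dilation effects per role), `validity`
#'   (scripted vs emitted gaze validity rates) and the config.
#' @export
generate_dyads <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  scene <- build_scene(cfg)
  referent_pool <- scene$objects$object_id[
    scene$objects$kind == "referent-candidate"]
  roles <- c("instructor", "builder")
  recordings <- list()
  truth_segments <- list()
  truth_validity <- list()

  for (ia in seq_len(cfg$n_interactions)) {
    interaction_id <- sprintf("sim%03d", ia)
    ## -- annotation timeline ------------------------------------------------
    segs <- list()
    t_cursor <- cfg$baseline_s + 0.5
    for (ins in seq_len(cfg$instructions_per_interaction)) {
      nfrag <- sample.int(4, 1, prob = cfg$fragment_dist)
      type <- if (nfrag > 1) "fragmented" else "non_fragmented"
      referent <- sample(referent_pool, 1)
      for (k in seq_len(nfrag)) {
        dur <- if (type == "non_fragmented") {
          rlnorm_ms(1, cfg$duration_mean_s$non_fragmented,
                    cfg$duration_sd_s$non_fragmented)
        } else {
          rlnorm_ms(1, cfg$duration_mean_s$ordinal[k],
                    cfg$duration_sd_s$ordinal[k])
        }
        dur <- max(dur, 0.4)
        dur <- round(dur * DYADLOAD_RATE_HZ) / DYADLOAD_RATE_HZ
        segs[[length(segs) + 1]] <- data.frame(
          interaction_id = interaction_id,
          instruction_id = sprintf("ins%02d", ins),
          fragment_ordinal = k,
          start = t_cursor, end = t_cursor + dur,
          referent_id = referent,
          speaker_role = "instructor",
          type = type, stringsAsFactors = FALSE)
        gap <- if (k < nfrag) rtrunc_norm(1, 0.7, 0.2, 0.3) else
          rtrunc_norm(1, 1.5, 0.5, 0.6)
        t_cursor <- t_cursor + dur + round(gap * DYADLOAD_RATE_HZ) /
          DYADLOAD_RATE_HZ
      }
    }
    segs <- do.call(rbind, segs)
    t_max <- t_cursor + 1.5
    n_frames <- time_to_frame(t_max) + 1L
    t <- (seq_len(n_frames) - 1) / DYADLOAD_RATE_HZ
    tier <- code_instructions(segs[, setdiff(names(segs), "type")])

    ## -- per-role signals ---------------------------------------------------
    gaze <- list(); pupil <- list()
    for (r in roles) {
      own <- scene$persons[scene$persons$role == r, ]
      partner <- scene$persons[scene$persons$role != r, ]
      origin <- matrix(rep(c(own$x, own$y, own$z), each = n_frames), ncol = 3)

      ## scripted target sequence: idle blocks, overwritten per segment
      target <- character(n_frames)
      block <- 25L
      for (b in seq(1, n_frames, by = block)) {
        idx <- b:min(b + block - 1L, n_frames)
        target[idx] <- if (stats::runif(1) < 0.4) "person" else
          sample(scene$objects$object_id, 1)
      }
      seg_latency <- rep(NA_real_, nrow(segs))
      seg_effect <- rep(NA_real_, nrow(segs))
      level <- numeric(n_frames)
      for (i in seq_len(nrow(segs))) {
        s <- segs[i, ]
        horizon_end <- if (i < nrow(segs)) segs$start[i + 1] else t_max
        hsel <- which(t >= s$start & t < horizon_end)
        ssel <- which(t >= s$start & t < s$end)
        distractors <- setdiff(scene$objects$object_id, s$referent_id)
        away <- sample(distractors, 1)
        if (stats::runif(1) < cfg$p_no_gaze) {
          target[hsel] <- away
        } else {
          lat_mean <- cell_value(cfg$latency_mean_s[[r]], s$type,
                                 s$fragment_ordinal)
          lat <- rtrunc_norm(1, lat_mean, cfg$latency_sd_s, 0,
                             horizon_end - s$start - 0.04)
          onset_frame <- time_to_frame(s$start + lat)
          pre <- hsel[t[hsel] < onset_frame / DYADLOAD_RATE_HZ]
          post <- hsel[t[hsel] >= onset_frame / DYADLOAD_RATE_HZ]
          target[pre] <- away
          if (length(post) > 0) {
            dwell <- post[seq_len(min(length(post), 50L))]
            target[dwell] <- s$referent_id
            rest <- setdiff(post, dwell)
            for (b in if (length(rest) > 0) seq(1, length(rest), by = block) else integer()) {
              idx <- rest[b:min(b + block - 1L, length(rest))]
              u <- stats::runif(1)
              target[idx] <- if (u < 0.5) s$referent_id else
                if (u < 0.8) away else "person"
            }
            seg_latency[i] <- onset_frame / DYADLOAD_RATE_HZ - s$start
          }
        }
        eff <- cell_value(cfg$dilation_mm[[r]], s$type, s$fragment_ordinal) +
          stats::rnorm(1, 0, cfg$dilation_sd_mm)
        seg_effect[i] <- eff
        level[ssel] <- level[ssel] + eff
      }

      ## gaze rays toward scripted targets
      pts <- rbind(scene$objects[, c("x", "y", "z")],
                   person = c(partner$x, partner$y, partner$z))
      rownames(pts) <- c(scene$objects$object_id, "person")
      tp <- as.matrix(pts[target, ])
      dirs <- tp - origin
      dirs <- dirs / sqrt(rowSums(dirs^2))
      dirs <- jitter_directions(dirs, cfg$angular_jitter_deg)
      valid <- stats::runif(n_frames) < cfg$gaze_validity[[r]]
      dirs[!valid, ] <- NA_real_
      gaze[[r]] <- gaze_stream(t, origin, dirs, valid)

      ## pupil trace
      base_mm <- rtrunc_norm(1, cfg$baseline_mean_mm, cfg$baseline_sd_mm,
                             2.5, 6.5)
      trace <- base_mm + level +
        ar1_noise(n_frames, cfg$ar_coef, cfg$pupil_noise_sd_mm)
      left <- trace + stats::rnorm(n_frames, 0, cfg$eye_noise_sd_mm)
      right <- trace + stats::rnorm(n_frames, 0, cfg$eye_noise_sd_mm)
      n_blinks <- stats::rpois(1, cfg$blink_rate_per_min * t_max / 60)
      if (n_blinks > 0) {
        starts <- sort(sample.int(n_frames - cfg$blink_duration_frames - 4,
                                  n_blinks, replace = TRUE)) + 2L
        for (bs in starts) {
          drop_idx <- bs:(bs + cfg$blink_duration_frames - 1L)
          edge_idx <- setdiff(c(bs - (2:1), drop_idx[length(drop_idx)] + 1:2),
                              drop_idx)
          edge_idx <- edge_idx[edge_idx >= 1 & edge_idx <= n_frames]
          left[edge_idx] <- left[edge_idx] - cfg$blink_spike_mm
          right[edge_idx] <- right[edge_idx] - cfg$blink_spike_mm
          left[drop_idx] <- NA_real_
          right[drop_idx] <- NA_real_
        }
      }
      if (cfg$eye_missing_rate > 0) {
        left[stats::runif(n_frames) < cfg$eye_missing_rate] <- NA_real_
        right[stats::runif(n_frames) < cfg$eye_missing_rate] <- NA_real_
      }
      left[!is.na(left)] <- pmax(0.6, left[!is.na(left)])
      right[!is.na(right)] <- pmax(0.6, right[!is.na(right)])
      pupil[[r]] <- pupil_stream(t, left, right)

      truth_segments[[length(truth_segments) + 1]] <- data.frame(
        interaction_id = interaction_id,
        instruction_id = segs$instruction_id,
        fragment_ordinal = segs$fragment_ordinal,
        instruction_type = segs$type,
        referent_id = segs$referent_id,
        role = r,
        scripted_latency = seg_latency,
        scripted_dilation = seg_effect,
        duration = segs$end - segs$start,
        stringsAsFactors = FALSE)
      truth_validity[[length(truth_validity) + 1]] <- data.frame(
        interaction_id = interaction_id, role = r,
        scripted_rate = unname(cfg$gaze_validity[[r]]),
        emitted_rate = mean(valid), stringsAsFactors = FALSE)
    }
    recordings[[interaction_id]] <- dyad_recording(
      interaction_id, gaze, pupil, scene, tier,
      baseline_window = c(0, cfg$baseline_s))
  }
  list(recordings = recordings,
       truth = list(segments = do.call(rbind, truth_segments),
                    validity = do.call(rbind, truth_validity),
                    config = cfg))
}

# ---------------------------------------------------------------------------
# On-disk corpus layout (one directory per interaction): the exact package
# formats, so generated fixtures double as format documentation.

#' Write a dyad recording to a directory
#'
#' Emits `gaze_<role>.csv`, `pupil_<role>.csv`, `tier.tsv`, `scene.json`,
#' `meta.json` (interaction id and baseline window) -- all plain text.
#'
#' @param recording a `dyad_recording`.
#' @param dir output directory (created).
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (r in c("instructor", "builder")) {
    write_stream(recording$gaze[[r]], file.path(dir, paste0("gaze_", r, ".csv")))
    write_stream(recording$pupil[[r]], file.path(dir, paste0("pupil_", r, ".csv")))
  }
  write_annotation_tier(recording$tier, file.path(dir, "tier.tsv"))
  write_scene(recording$scene, file.path(dir, "scene.json"))
  jsonlite::write_json(list(interaction_id = recording$interaction_id,
                            baseline_window = recording$baseline_window),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a dyad recording from a directory written by [write_recording()]
#' @param dir recording directory.
#' @return a `dyad_recording`.
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  gaze <- list(); pupil <- list()
  for (r in c("instructor", "builder")) {
    gaze[[r]] <- read_gaze_stream(file.path(dir, paste0("gaze_", r, ".csv")))
    pupil[[r]] <- read_pupil_stream(file.path(dir, paste0("pupil_", r, ".csv")))
  }
  dyad_recording(meta$interaction_id, gaze, pupil,
                 read_scene(file.path(dir, "scene.json")),
                 read_annotation_tier(file.path(dir, "tier.tsv")),
                 unlist(meta$baseline_window))
}

#' Simulate metric rows for mixed-model calibration studies
#'
#' A lightweight row-level generator (no sensor streams): a balanced
#' two-factor design with random intercepts, used to check likelihood-ratio
#' test calibration and power.
#'
#' @param n number of rows.
#' @param fragment_effect,role_effect,interaction_effect effect sizes in
#'   residual-SD units (applied as level contrasts).
#' @param n_groups,n_objects numbers of interaction and object grouping
#'   levels.
#' @param group_sd,object_sd random-intercept SDs.
#' @return data.frame with `response, fragment, role, interaction_id,
#'   referent_id`.
#' @export
simulate_lmm_rows <- function(n = 400, fragment_effect = 0, role_effect = 0,
                              interaction_effect = 0, n_groups = 20,
                              n_objects = 8, group_sd = 0.5, object_sd = 0.5) {
  fragment <- sample(c("non_fragmented", "fragmented"), n, replace = TRUE)
  role <- sample(c("instructor", "builder"), n, replace = TRUE)
  interaction_id <- sample(sprintf("g%02d", seq_len(n_groups)), n, replace = TRUE)
  referent_id <- sample(sprintf("o%02d", seq_len(n_objects)), n, replace = TRUE)
  g_eff <- stats::setNames(stats::rnorm(n_groups, 0, group_sd),
                           sprintf("g%02d", seq_len(n_groups)))
  o_eff <- stats::setNames(stats::rnorm(n_objects, 0, object_sd),
                           sprintf("o%02d", seq_len(n_objects)))
  response <- stats::rnorm(n) +
    fragment_effect * (fragment == "fragmented") +
    role_effect * (role == "instructor") +
    interaction_effect * (fragment == "fragmented") * (role == "instructor") +
    g_eff[interaction_id] + o_eff[referent_id]
  data.frame(response = as.numeric(response), fragment = fragment, role = role,
             interaction_id = interaction_id, referent_id = referent_id,
             stringsAsFactors = FALSE)
}
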