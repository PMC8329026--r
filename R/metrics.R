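# End-to-end feature extraction: one metric row per (utterance segment x
# participant role), combining the gaze and pupil pipelines with the coded
# annotation tier.

#' Compute all behavioural measures for one dyad recording
#'
#' Runs the pupil chain ([process_pupil()], [extract_baseline()]) and the
#' gaze chain ([assign_targets()]) for both roles, then emits one row per
#' (utterance segment x role) with the ten measures: first gaze to target,
#' the three gaze proportions, joint attention, mutual gaze, mean/peak pupil
#' dilation, slope, and duration. The first-gaze measurement horizon for a
#' segment extends to the next instructor segment's onset.
#'
#' @param recording a `dyad_recording`.
#' @param threshold_deg gaze capture cone, degrees.
#' @param fspec,ospec,max_gap_frames pupil pipeline settings.
#' @param denominator gaze proportion denominator, see [proportional_gaze()].
#' @return data.frame of metric rows (columns as in [write_metric_table()]).
#' @export
compute_metrics <- function(recording, threshold_deg = 10,
                            fspec = filter_spec(), ospec = outlier_spec(),
                            max_gap_frames = 25L,
                            denominator = "segment-time") {
  stopifnot(inherits(recording, "dyad_recording"))
  roles <- c("instructor", "builder")
  series <- lapply(roles, function(r)
    process_pupil(recording$pupil[[r]], fspec, ospec, max_gap_frames))
  names(series) <- roles
  baselines <- lapply(series, extract_baseline,
                      window = recording$baseline_window)
  targets <- lapply(roles, function(r)
    assign_targets(recording$gaze[[r]], recording$scene, r, threshold_deg))
  names(targets) <- roles

  segs <- recording$tier$segments[order(recording$tier$segments$start), ]
  t_max <- max(recording$gaze$instructor$t)
  rows <- vector("list", 2 * nrow(segs))
  k <- 0
  for (i in seq_len(nrow(segs))) {
    seg <- segs[i, ]
    unit <- recording$tier$units[
      recording$tier$units$instruction_id == seg$instruction_id &
        recording$tier$units$interaction_id == seg$interaction_id, ]
    horizon <- if (i < nrow(segs)) segs$start[i + 1] else t_max
    ja <- joint_attention(targets$instructor, targets$builder, seg,
                          seg$referent_id)
    mg <- mutual_gaze(targets$instructor, targets$builder, seg)
    for (r in roles) {
      pg <- proportional_gaze(targets[[r]], seg, seg$referent_id, denominator)
      pm <- segment_pupil_metrics(series[[r]], baselines[[r]], seg)
      k <- k + 1
      rows[[k]] <- data.frame(
        interaction_id = seg$interaction_id,
        instruction_id = seg$instruction_id,
        fragment_ordinal = seg$fragment_ordinal,
        instruction_type = unit$type,
        referent_id = seg$referent_id,
        role = r,
        participant_id = paste(seg$interaction_id, r, sep = "/"),
        first_gaze_to_target = first_gaze_latency(targets[[r]], seg,
                                                  seg$referent_id, horizon),
        gaze_to_target = pg$gaze_to_target,
        gaze_to_other = pg$gaze_to_other,
        gaze_to_person = pg$gaze_to_person,
        joint_attention = ja,
        mutual_gaze = mg,
        mean_dilation = pm$mean_dilation,
        peak_dilation = pm$peak_dilation,
        slope = pm$slope,
        duration = seg$end - seg$start,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compute metric rows for a list of recordings
#'
#' @param recordings list of `dyad_recording`s.
#' @param ... passed to [compute_metrics()].
#' @return combined metric data.frame.
#' @export
compute_metrics_all <- function(recordings, ...) {
  do.call(rbind, lapply(recordings, compute_metrics, ...))
}

#' Per-frame gaze-target audit table for a recording
#'
#' Every number in the metric table is re-derivable from this table plus the
#' pupil audit; exported for spot-checking.
#'
#' @param recording a `dyad_recording`.
#' @param threshold_deg gaze capture cone, degrees.
#' @return data.frame of per-frame targets for both roles.
#' @export
gaze_audit <- function(recording, threshold_deg = 10) {
  do.call(rbind, lapply(c("instructor", "builder"), function(r)
    assign_targets(recording$gaze[[r]], recording$scene, r, threshold_deg)))
}
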