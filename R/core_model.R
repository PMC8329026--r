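#' @keywords internal
"_PACKAGE"

# Nominal sensor rate (frames per second) shared by gaze and pupil streams.
DYADLOAD_RATE_HZ <- 50

#' Convert a time in seconds to a frame index on the shared 50 Hz clock
#'
#' All streams in a recording share one clock; a frame is `round(t * rate)`.
#'
#' @param t numeric vector of times in seconds.
#' @param rate sampling rate in Hz (default 50).
#' @return integer frame indices.
#' @export
time_to_frame <- function(t, rate = DYADLOAD_RATE_HZ) {
  as.integer(round(t * rate))
}

#' Construct a gaze stream
#'
#' A gaze stream is one participant's eye position and gaze direction over
#' time: origin (metres) and a unit direction vector in the shared 3D frame.
#'
#' @param t time in seconds, non-decreasing.
#' @param origin n x 3 matrix of eye positions (metres).
#' @param direction n x 3 matrix of gaze directions; normalised on valid rows.
#' @param valid logical; invalid rows carry no usable direction.
#' @return a data.frame of class `gaze_stream` with columns
#'   `t, ox, oy, oz, dx, dy, dz, valid`.
#' @export
gaze_stream <- function(t, origin, direction, valid = rep(TRUE, length(t))) {
  origin <- as.matrix(origin)
  direction <- as.matrix(direction)
  stopifnot(nrow(origin) == length(t), nrow(direction) == length(t),
            length(valid) == length(t))
  if (length(t) > 1 && any(diff(t) < 0)) {
    stop("gaze stream timestamps must be non-decreasing")
  }
  nrm <- sqrt(rowSums(direction^2))
  ok <- valid & is.finite(nrm) & nrm > 0
  direction[ok, ] <- direction[ok, , drop = FALSE] / nrm[ok]
  valid <- valid & ok
  out <- data.frame(t = t,
                    ox = origin[, 1], oy = origin[, 2], oz = origin[, 3],
                    dx = direction[, 1], dy = direction[, 2], dz = direction[, 3],
                    valid = valid)
  class(out) <- c("gaze_stream", "data.frame")
  out
}

#' Construct a binocular pupil stream
#'
#' @param t time in seconds, aligned to the gaze clock.
#' @param left_mm,right_mm pupil diameters in millimetres; `NA` where the eye
#'   was not measured. Present values must be finite and positive.
#' @return a data.frame of class `pupil_stream`.
#' @export
pupil_stream <- function(t, left_mm, right_mm) {
  stopifnot(length(left_mm) == length(t), length(right_mm) == length(t))
  if (length(t) > 1 && any(diff(t) < 0)) {
    stop("pupil stream timestamps must be non-decreasing")
  }
  bad <- function(x) any(!is.na(x) & (!is.finite(x) | x <= 0))
  if (bad(left_mm) || bad(right_mm)) {
    stop("present pupil diameters must be finite and positive")
  }
  out <- data.frame(t = t, left_mm = left_mm, right_mm = right_mm)
  class(out) <- c("pupil_stream", "data.frame")
  out
}

#' Construct a scene description
#'
#' The scene holds every gaze-capturable region: task objects (referent
#' candidates and distractors) and the two participants' head regions.
#'
#' @param objects data.frame with columns `object_id, kind, x, y, z, radius`;
#'   `kind` is `"referent-candidate"` or `"distractor"`, radii in metres.
#' @param persons data.frame with columns `role, x, y, z, radius`; exactly one
#'   row per role (`"instructor"`, `"builder"`).
#' @return a list of class `dyad_scene`.
#' @export
dyad_scene <- function(objects, persons) {
  objects <- as.data.frame(objects)
  persons <- as.data.frame(persons)
  stopifnot(all(c("object_id", "kind", "x", "y", "z", "radius") %in% names(objects)),
            all(c("role", "x", "y", "z", "radius") %in% names(persons)))
  if (anyDuplicated(objects$object_id)) {
    stop("object_ids must be unique within a scene")
  }
  if (any(objects$radius <= 0) || any(persons$radius <= 0)) {
    stop("capture radii must be positive")
  }
  if (!setequal(persons$role, c("instructor", "builder")) ||
      nrow(persons) != 2) {
    stop("scene needs exactly one person region per role")
  }
  structure(list(objects = objects, persons = persons), class = "dyad_scene")
}

#' @export
print.dyad_scene <- function(x, ...) {
  cat(sprintf("<dyad_scene> %d objects (%d referent candidates), 2 person regions\n",
              nrow(x$objects),
              sum(x$objects$kind == "referent-candidate")))
  invisible(x)
}

#' Assemble a dyad recording
#'
#' One synchronised two-participant interaction: per-role gaze and pupil
#' streams, the scene, the annotation tier and the pupil baseline window.
#'
#' @param interaction_id identifier.
#' @param gaze named list `list(instructor = , builder = )` of gaze streams.
#' @param pupil named list of pupil streams, same roles.
#' @param scene a `dyad_scene`.
#' @param tier an `instruction_tier` (see [code_instructions()]).
#' @param baseline_window numeric length-2 `(start, end)` in seconds,
#'   preceding the first instruction onset.
#' @return a list of class `dyad_recording`.
#' @export
dyad_recording <- function(interaction_id, gaze, pupil, scene, tier,
                           baseline_window) {
  stopifnot(setequal(names(gaze), c("instructor", "builder")),
            setequal(names(pupil), c("instructor", "builder")),
            inherits(scene, "dyad_scene"),
            inherits(tier, "instruction_tier"),
            length(baseline_window) == 2,
            baseline_window[2] > baseline_window[1])
  missing_ref <- setdiff(tier$units$referent_id, scene$objects$object_id)
  if (length(missing_ref) > 0) {
    stop("referent id(s) not present in scene: ",
         paste(missing_ref, collapse = ", "))
  }
  if (nrow(tier$segments) > 0 &&
      baseline_window[2] > min(tier$segments$start)) {
    stop("baseline window must precede the first instruction onset")
  }
  structure(list(interaction_id = interaction_id, gaze = gaze, pupil = pupil,
                 scene = scene, tier = tier,
                 baseline_window = baseline_window),
            class = "dyad_recording")
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("<dyad_recording> %s: %d instruction units (%d segments), %g-%g s\n",
              x$interaction_id, nrow(x$tier$units), nrow(x$tier$segments),
              min(x$gaze$instructor$t), max(x$gaze$instructor$t)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Annotation tiers

tier_tsv_columns <- c("interaction", "instruction", "ordinal",
                      "start", "end", "referent", "role")

#' Read an utterance annotation tier
#'
#' Supports two dialects: the flat 7-column tab-separated export
#' (`interaction, instruction, ordinal, start, end, referent, role`, with a
#' header line) and ELAN's EAF XML. In the EAF dialect each alignable
#' annotation's value encodes `instruction_id:ordinal:referent_id` and the
#' tier's `PARTICIPANT` attribute carries the speaker role.
#'
#' @param path path to the annotation file.
#' @param dialect `"tsv"` or `"eaf"`; guessed from the file extension when
#'   omitted.
#' @param interaction_id identifier used when the file does not carry one
#'   (EAF dialect).
#' @return an `instruction_tier` (see [code_instructions()]).
#' @export
read_annotation_tier <- function(path, dialect = NULL, interaction_id = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.eaf$", path, ignore.case = TRUE)) "eaf" else "tsv"
  }
  dialect <- match.arg(dialect, c("tsv", "eaf"))
  segs <- if (dialect == "tsv") {
    read_tier_tsv(path)
  } else {
    read_tier_eaf(path, interaction_id = interaction_id)
  }
  code_instructions(segs)
}

read_tier_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "integer",
                                         "numeric", "numeric", "character",
                                         "character"))
  if (!identical(names(df), tier_tsv_columns)) {
    stop("tier file ", path, " must have columns: ",
         paste(tier_tsv_columns, collapse = ", "))
  }
  data.frame(interaction_id = df$interaction,
             instruction_id = df$instruction,
             fragment_ordinal = df$ordinal,
             start = df$start, end = df$end,
             referent_id = df$referent,
             speaker_role = df$role,
             stringsAsFactors = FALSE)
}

read_tier_eaf <- function(path, interaction_id = NULL) {
  doc <- xml2::read_xml(path)
  slots <- xml2::xml_find_all(doc, ".//TIME_ORDER/TIME_SLOT")
  slot_ms <- stats::setNames(
    as.numeric(xml2::xml_attr(slots, "TIME_VALUE")),
    xml2::xml_attr(slots, "TIME_SLOT_ID"))
  if (is.null(interaction_id)) {
    interaction_id <- sub("\\.eaf$", "", basename(path), ignore.case = TRUE)
  }
  rows <- list()
  for (tier in xml2::xml_find_all(doc, ".//TIER")) {
    role <- xml2::xml_attr(tier, "PARTICIPANT")
    if (is.na(role)) role <- "instructor"
    anns <- xml2::xml_find_all(tier, ".//ALIGNABLE_ANNOTATION")
    for (a in anns) {
      val <- xml2::xml_text(xml2::xml_find_first(a, ".//ANNOTATION_VALUE"))
      parts <- strsplit(trimws(val), ":", fixed = TRUE)[[1]]
      if (length(parts) != 3) {
        stop("EAF annotation value must be 'instruction:ordinal:referent', got: ",
             val)
      }
      rows[[length(rows) + 1]] <- data.frame(
        interaction_id = interaction_id,
        instruction_id = parts[1],
        fragment_ordinal = as.integer(parts[2]),
        start = slot_ms[[xml2::xml_attr(a, "TIME_SLOT_REF1")]] / 1000,
        end = slot_ms[[xml2::xml_attr(a, "TIME_SLOT_REF2")]] / 1000,
        referent_id = parts[3],
        speaker_role = role,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(interaction_id = character(), instruction_id = character(),
                      fragment_ordinal = integer(), start = numeric(),
                      end = numeric(), referent_id = character(),
                      speaker_role = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Write an annotation tier in the tab-separated dialect
#'
#' Inverse of [read_annotation_tier()] for the `"tsv"` dialect; round-trips
#' losslessly.
#'
#' @param tier an `instruction_tier`.
#' @param path output path.
#' @export
write_annotation_tier <- function(tier, path) {
  stopifnot(inherits(tier, "instruction_tier"))
  s <- tier$segments
  out <- data.frame(interaction = s$interaction_id,
                    instruction = s$instruction_id,
                    ordinal = s$fragment_ordinal,
                    start = s$start, end = s$end,
                    referent = s$referent_id, role = s$speaker_role)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sensor streams

#' Read a gaze stream from CSV
#'
#' Columns: `t, ox, oy, oz, dx, dy, dz, valid`. Rows are snapped onto the
#' nominal 50 Hz frame grid; frames absent from the file become invalid
#' placeholder samples, so the returned stream is gap-free in time.
#'
#' @param path CSV path.
#' @param rate nominal sampling rate, Hz.
#' @return a `gaze_stream`.
#' @export
read_gaze_stream <- function(path, rate = DYADLOAD_RATE_HZ) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "ox", "oy", "oz", "dx", "dy", "dz", "valid")
  if (!all(need %in% names(df))) {
    stop("gaze stream ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(gaze_stream(numeric(), matrix(numeric(), 0, 3),
                       matrix(numeric(), 0, 3), logical()))
  }
  if (any(diff(df$t) <= 0)) stop("non-monotone timestamps in ", path)
  reg <- regularize_frames(df$t, rate)
  full <- data.frame(t = reg$t,
                     ox = NA_real_, oy = NA_real_, oz = NA_real_,
                     dx = NA_real_, dy = NA_real_, dz = NA_real_,
                     valid = FALSE)
  full[reg$idx, c("ox", "oy", "oz", "dx", "dy", "dz")] <-
    df[, c("ox", "oy", "oz", "dx", "dy", "dz")]
  full$valid[reg$idx] <- as.logical(df$valid)
  gaze_stream(full$t, as.matrix(full[, c("ox", "oy", "oz")]),
              as.matrix(full[, c("dx", "dy", "dz")]),
              full$valid & !is.na(full$dx))
}

#' Read a binocular pupil stream from CSV
#'
#' Columns: `t, left_mm, right_mm` (diameters in millimetres, empty cells for
#' missing samples). As for gaze, missing frames are inserted as placeholders
#' on the 50 Hz grid. A crude unit check rejects files whose typical diameter
#' is implausible for millimetres.
#'
#' @inheritParams read_gaze_stream
#' @return a `pupil_stream`.
#' @export
read_pupil_stream <- function(path, rate = DYADLOAD_RATE_HZ) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "left_mm", "right_mm")
  if (!all(need %in% names(df))) {
    stop("pupil stream ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(df) == 0) return(pupil_stream(numeric(), numeric(), numeric()))
  if (any(diff(df$t) <= 0)) stop("non-monotone timestamps in ", path)
  vals <- c(df$left_mm, df$right_mm)
  med <- stats::median(vals, na.rm = TRUE)
  if (is.finite(med) && (med < 0.5 || med > 15)) {
    stop("pupil diameters in ", path, " do not look like millimetres (median ",
         signif(med, 3), ")")
  }
  reg <- regularize_frames(df$t, rate)
  left <- rep(NA_real_, length(reg$t)); right <- left
  left[reg$idx] <- df$left_mm
  right[reg$idx] <- df$right_mm
  pupil_stream(reg$t, left, right)
}

# Map observed timestamps onto the nominal frame grid spanning them.
regularize_frames <- function(t, rate) {
  f <- time_to_frame(t, rate)
  if (anyDuplicated(f)) stop("two samples map to the same nominal frame")
  frames <- seq(f[1], f[length(f)])
  list(t = frames / rate, idx = match(f, frames))
}

#' Write a gaze or pupil stream to CSV
#' @param stream a `gaze_stream` or `pupil_stream`.
#' @param path output path.
#' @export
write_stream <- function(stream, path) {
  utils::write.csv(as.data.frame(stream), path, row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Scene config (JSON or YAML by extension)

#' Read a scene description from JSON or YAML
#'
#' Expects top-level keys `objects` (list of `object_id, kind, x, y, z,
#' radius`) and `persons` (list of `role, x, y, z, radius`).
#'
#' @param path file path; `.json`, `.yaml` or `.yml`.
#' @return a `dyad_scene`.
#' @export
read_scene <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  to_df <- function(x) if (is.data.frame(x)) x else do.call(rbind, lapply(x, as.data.frame))
  dyad_scene(to_df(cfg$objects), to_df(cfg$persons))
}

#' Write a scene description to JSON
#' @param scene a `dyad_scene`.
#' @param path output path (`.json`).
#' @export
write_scene <- function(scene, path) {
  jsonlite::write_json(list(objects = scene$objects, persons = scene$persons),
                       path, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Metric tables

metric_columns <- c("interaction_id", "instruction_id", "fragment_ordinal",
                    "instruction_type", "referent_id", "role",
                    "participant_id", "first_gaze_to_target",
                    "gaze_to_target", "gaze_to_other", "gaze_to_person",
                    "joint_attention", "mutual_gaze", "mean_dilation",
                    "peak_dilation", "slope", "duration")

#' Write the per-segment behavioural metric table
#'
#' One row per (utterance segment x participant role), in a fixed column
#' order. Undefined metrics (e.g. a first-gaze latency where the referent was
#' never fixated) are written as empty cells, never dropped, and survive a
#' round-trip through [read_metric_table()].
#'
#' @param rows metric data.frame (see [compute_metrics()]).
#' @param path output CSV path.
#' @export
write_metric_table <- function(rows, path) {
  miss <- setdiff(metric_columns, names(rows))
  if (length(miss) > 0) stop("metric table missing columns: ",
                             paste(miss, collapse = ", "))
  utils::write.csv(rows[, metric_columns, drop = FALSE], path,
                   row.names = FALSE, na = "")
  invisible(path)
}

#' Read a metric table written by [write_metric_table()]
#' @param path CSV path.
#' @return metric data.frame; empty cells become `NA` ("undefined").
#' @export
read_metric_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                  colClasses = c(interaction_id = "character",
                                 instruction_id = "character",
                                 instruction_type = "character",
                                 referent_id = "character",
                                 role = "character",
                                 participant_id = "character"))
}
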