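# Instruction-unit coding: group annotated utterance segments into
# referent-directed instruction units, classify fragmented vs non-fragmented,
# assign fragment ordinals in temporal order.

#' Code utterance segments into instruction units
#'
#' Segments sharing an `instruction_id` form one instruction unit directed at
#' one referent object. Segments are sorted by start time and the fragment
#' ordinals (Utt-1..Utt-n) reassigned in temporal order; a unit is
#' `"fragmented"` iff it has more than one segment. Only instructor
#' utterances carry ordinals under the annotation scheme; listener
#' back-channels are not segments of the unit.
#'
#' @param segments data.frame with columns `interaction_id, instruction_id,
#'   fragment_ordinal, start, end, referent_id, speaker_role`. Supplied
#'   ordinals, when present, must be contiguous from 1 within each unit; they
#'   are re-derived from time order.
#' @param max_ordinal ordinals above this are kept but flagged
#'   (`above_cap = TRUE`); the downstream sequence analysis defaults to
#'   dropping them.
#' @return an `instruction_tier`: `list(segments, units)` where `units` has
#'   one row per instruction (`instruction_id, interaction_id, referent_id,
#'   n_fragments, type`).
#' @export
code_instructions <- function(segments, max_ordinal = 4L) {
  segments <- as.data.frame(segments)
  need <- c("interaction_id", "instruction_id", "fragment_ordinal",
            "start", "end", "referent_id", "speaker_role")
  miss <- setdiff(need, names(segments))
  if (length(miss) > 0) stop("segments missing columns: ",
                             paste(miss, collapse = ", "))
  if (nrow(segments) > 0) {
    if (any(segments$end <= segments$start)) {
      bad <- which(segments$end <= segments$start)[1]
      stop(sprintf("segment %s of instruction %s has end <= start",
                   segments$fragment_ordinal[bad], segments$instruction_id[bad]))
    }
    check_no_overlap(segments)
  }
  segments <- segments[order(segments$interaction_id, segments$start), ]
  rownames(segments) <- NULL

  units <- list()
  for (key in unique(paste(segments$interaction_id, segments$instruction_id,
                           sep = "\r"))) {
    sel <- paste(segments$interaction_id, segments$instruction_id,
                 sep = "\r") == key
    seg <- segments[sel, ]
    if (length(unique(seg$referent_id)) > 1) {
      stop("instruction ", seg$instruction_id[1],
           " mixes referent ids: ", paste(unique(seg$referent_id), collapse = ", "))
    }
    supplied <- sort(seg$fragment_ordinal)
    if (!all(is.na(supplied)) && !identical(as.integer(supplied),
                                            seq_len(nrow(seg)))) {
      stop("instruction ", seg$instruction_id[1],
           " has non-contiguous fragment ordinals: ",
           paste(supplied, collapse = ","))
    }
    segments$fragment_ordinal[sel] <- seq_len(nrow(seg))
    units[[length(units) + 1]] <- data.frame(
      instruction_id = seg$instruction_id[1],
      interaction_id = seg$interaction_id[1],
      referent_id = seg$referent_id[1],
      n_fragments = nrow(seg),
      type = if (nrow(seg) > 1) "fragmented" else "non_fragmented",
      stringsAsFactors = FALSE)
  }
  units <- if (length(units)) do.call(rbind, units) else
    data.frame(instruction_id = character(), interaction_id = character(),
               referent_id = character(), n_fragments = integer(),
               type = character(), stringsAsFactors = FALSE)
  segments$above_cap <- segments$fragment_ordinal > max_ordinal
  structure(list(segments = segments, units = units),
            class = "instruction_tier")
}

check_no_overlap <- function(segments) {
  for (who in split(segments, paste(segments$interaction_id,
                                    segments$speaker_role))) {
    who <- who[order(who$start), ]
    if (nrow(who) > 1) {
      ov <- which(who$start[-1] < who$end[-nrow(who)] - 1e-9)
      if (length(ov) > 0) {
        stop(sprintf(
          "overlapping segments for one speaker: instruction %s [%g-%g] and %s [%g-%g]",
          who$instruction_id[ov[1]], who$start[ov[1]], who$end[ov[1]],
          who$instruction_id[ov[1] + 1], who$start[ov[1] + 1], who$end[ov[1] + 1]))
      }
    }
  }
  invisible(TRUE)
}

#' @export
print.instruction_tier <- function(x, ...) {
  cat(sprintf("<instruction_tier> %d units (%d fragmented), %d segments\n",
              nrow(x$units), sum(x$units$type == "fragmented"),
              nrow(x$segments)))
  invisible(x)
}

#' Utterance duration in seconds
#'
#' @param segment a one-row segment data.frame (or any list with `start` and
#'   `end` in seconds).
#' @return `end - start`, seconds.
#' @export
segment_duration <- function(segment) {
  d <- segment$end - segment$start
  if (any(d <= 0)) stop("segment duration must be positive")
  d
}

#' Per-ordinal slices of fragmented instructions
#'
#' Slice k collects the k-th fragment of every *fragmented* unit with at
#' least k fragments, so slice sizes are non-increasing in k. Non-fragmented
#' (single-utterance) units are excluded by definition.
#'
#' @param tier an `instruction_tier`.
#' @param max_ordinal largest slice index (default 4, the analysis cap).
#' @return named list `Utt-1..Utt-k` of segment data.frames.
#' @export
sequence_slices <- function(tier, max_ordinal = 4L) {
  stopifnot(inherits(tier, "instruction_tier"))
  key <- paste(tier$segments$interaction_id, tier$segments$instruction_id)
  frag_key <- paste(tier$units$interaction_id, tier$units$instruction_id)[
    tier$units$type == "fragmented"]
  segs <- tier$segments[key %in% frag_key, ]
  out <- lapply(seq_len(max_ordinal), function(k) {
    segs[segs$fragment_ordinal == k, , drop = FALSE]
  })
  names(out) <- paste0("Utt-", seq_len(max_ordinal))
  out
}

#' Slice sizes as a named integer vector
#' @inheritParams sequence_slices
#' @export
slice_counts <- function(tier, max_ordinal = 4L) {
  vapply(sequence_slices(tier, max_ordinal), nrow, integer(1))
}
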