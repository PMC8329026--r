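# 3D gaze-target assignment by visual angle and the six per-segment
# attention measures: first gaze to target referent, proportional gaze to
# target / other objects / person, joint attention and mutual gaze.

#' Angular distance between a gaze ray and a point
#'
#' The visual angle between the gaze direction and the vector from the eye
#' origin to a target point, in degrees, in [0, 180].
#'
#' @param origin n x 3 matrix (or length-3 vector) of eye positions, metres.
#' @param direction n x 3 matrix (or length-3 vector) of unit gaze directions.
#' @param point length-3 target point, metres.
#' @return numeric vector of angles, degrees.
#' @export
angular_distance <- function(origin, direction, point) {
  origin <- matrix(origin, ncol = 3)
  direction <- matrix(direction, ncol = 3)
  v <- cbind(point[1] - origin[, 1], point[2] - origin[, 2],
             point[3] - origin[, 3])
  vn <- sqrt(rowSums(v^2))
  if (any(vn == 0)) stop("target point coincides with gaze origin")
  dn <- sqrt(rowSums(direction^2))
  cosang <- rowSums(direction * v) / (dn * vn)
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Assign a gaze target to every frame of a stream
#'
#' For each valid frame, the candidate (every scene object plus the
#' conversational partner's head region) with the smallest visual angle wins
#' if that angle is within `threshold_deg`; otherwise the frame's target is
#' `none`. Ties are broken by smallest 3D Euclidean distance, then
#' lexicographic id. Invalid frames are `none` with an `NA` angle.
#'
#' @param stream a `gaze_stream`.
#' @param scene a `dyad_scene`.
#' @param role the stream owner's role; the partner region is the other role.
#' @param threshold_deg capture cone half-angle, degrees (default 10).
#' @return data.frame (`gaze_targets`) with `t, role, target,
#'   angular_error_deg`; the partner target is the literal id `"person"`.
#' @export
assign_targets <- function(stream, scene, role, threshold_deg = 10) {
  stopifnot(inherits(stream, "gaze_stream"), inherits(scene, "dyad_scene"))
  role <- match.arg(role, c("instructor", "builder"))
  partner <- scene$persons[scene$persons$role != role, , drop = FALSE]
  cand <- rbind(
    data.frame(id = scene$objects$object_id,
               x = scene$objects$x, y = scene$objects$y, z = scene$objects$z,
               stringsAsFactors = FALSE),
    data.frame(id = "person", x = partner$x, y = partner$y, z = partner$z,
               stringsAsFactors = FALSE))
  n <- nrow(stream)
  target <- rep("none", n)
  best_ang <- rep(NA_real_, n)
  if (n == 0) {
    return(structure(data.frame(t = numeric(), role = character(),
                                target = character(),
                                angular_error_deg = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("gaze_targets", "data.frame")))
  }
  ok <- stream$valid
  if (any(ok)) {
    o <- as.matrix(stream[ok, c("ox", "oy", "oz")])
    d <- as.matrix(stream[ok, c("dx", "dy", "dz")])
    nc <- nrow(cand)
    ang <- matrix(NA_real_, sum(ok), nc)
    dist <- matrix(NA_real_, sum(ok), nc)
    for (j in seq_len(nc)) {
      p <- c(cand$x[j], cand$y[j], cand$z[j])
      ang[, j] <- angular_distance(o, d, p)
      dist[, j] <- sqrt((o[, 1] - p[1])^2 + (o[, 2] - p[2])^2 +
                          (o[, 3] - p[3])^2)
    }
    # lexicographic argmin over (angle, distance, id) per frame; the fast
    # path takes the unique minimum, exact angle ties fall to a per-row sort
    id_rank <- rank(cand$id, ties.method = "first")
    amin <- do.call(pmin, as.data.frame(ang))
    j_star <- max.col(-ang, ties.method = "first")
    tied <- rowSums(ang == amin) > 1
    for (i in which(tied)) {
      j_star[i] <- order(ang[i, ], dist[i, ], id_rank)[1]
    }
    hit <- amin <= threshold_deg
    idx <- which(ok)[hit]
    target[idx] <- cand$id[j_star[hit]]
    best_ang[idx] <- amin[hit]
  }
  structure(data.frame(t = stream$t, role = role, target = target,
                       angular_error_deg = best_ang,
                       stringsAsFactors = FALSE),
            class = c("gaze_targets", "data.frame"))
}

in_segment <- function(t, segment) t >= segment$start & t < segment$end

#' Majority-vote gaze target of a segment
#'
#' The most prominent visual target over the in-segment frames: the target
#' with the maximal proportional gaze. `none` frames do not vote; a segment
#' whose frames are all `none` has target `none`. Count ties are broken
#' lexicographically for determinism.
#'
#' @param targets a `gaze_targets` frame.
#' @param segment list/row with `start`, `end` (seconds).
#' @return the winning target id, or `"none"`.
#' @export
majority_target <- function(targets, segment) {
  lab <- targets$target[in_segment(targets$t, segment)]
  lab <- lab[lab != "none"]
  if (length(lab) == 0) return("none")
  tab <- table(lab)
  names(tab)[which.max(tab)]      # which.max takes the first = lexicographic
}

#' Latency of the first gaze to the target referent
#'
#' Time from the segment (utterance) onset until the first frame whose
#' target is the referent object, in seconds. The measurement horizon is the
#' segment itself extended to `horizon_end` (typically the next segment's
#' onset), so identifications just after the utterance are still captured.
#' `NA` ("undefined") if the referent is never fixated within the horizon.
#'
#' @param targets a `gaze_targets` frame.
#' @param segment list/row with `start`, `end`.
#' @param referent_id the instructed object id.
#' @param horizon_end end of the measurement horizon, seconds; defaults to
#'   the segment end.
#' @return latency in seconds, or `NA`.
#' @export
first_gaze_latency <- function(targets, segment, referent_id,
                               horizon_end = segment$end) {
  sel <- targets$t >= segment$start & targets$t < max(horizon_end, segment$end)
  hit <- sel & targets$target == referent_id
  if (!any(hit)) return(NA_real_)
  targets$t[which(hit)[1]] - segment$start
}

#' Proportional gaze to target, other objects, and person
#'
#' Each proportion is the count of matching in-segment frames over the total
#' in-segment frame count -- proportions of segment time, so invalid and
#' elsewhere-directed frames stay in the denominator and the three
#' proportions plus the remainder sum to 1. Set
#' `denominator = "valid-time"` to divide by targeted frames only.
#'
#' @param targets a `gaze_targets` frame.
#' @param segment list/row with `start`, `end`.
#' @param referent_id the instructed object id.
#' @param denominator `"segment-time"` (default) or `"valid-time"`.
#' @return `list(gaze_to_target, gaze_to_other, gaze_to_person)`.
#' @export
proportional_gaze <- function(targets, segment, referent_id,
                              denominator = "segment-time") {
  denominator <- match.arg(denominator, c("segment-time", "valid-time"))
  sel <- in_segment(targets$t, segment)
  n_total <- sum(sel)
  if (n_total == 0) stop("segment contains no frames")
  lab <- targets$target[sel]
  denom <- if (denominator == "segment-time") n_total else max(1, sum(lab != "none"))
  list(gaze_to_target = sum(lab == referent_id) / denom,
       gaze_to_other = sum(lab != "none" & lab != "person" &
                             lab != referent_id) / denom,
       gaze_to_person = sum(lab == "person") / denom)
}

# Align two target frames on the shared frame grid within a segment,
# returning the pair of label vectors.
aligned_labels <- function(targets_a, targets_b, segment) {
  sa <- in_segment(targets_a$t, segment)
  fa <- time_to_frame(targets_a$t[sa])
  fb <- time_to_frame(targets_b$t[in_segment(targets_b$t, segment)])
  la <- targets_a$target[sa]
  lb <- targets_b$target[in_segment(targets_b$t, segment)]
  m <- match(fa, fb)
  keep <- !is.na(m)
  list(a = la[keep], b = lb[m[keep]], n = sum(sa))
}

#' Joint attention over a segment
#'
#' Fraction of in-segment frames where both participants' gaze target is the
#' uttered referent object at the same time. Symmetric in the two roles.
#'
#' @param targets_a,targets_b `gaze_targets` for the two participants.
#' @param segment list/row with `start`, `end`.
#' @param referent_id the instructed object id.
#' @return proportion in [0, 1].
#' @export
joint_attention <- function(targets_a, targets_b, segment, referent_id) {
  al <- aligned_labels(targets_a, targets_b, segment)
  if (al$n == 0) stop("segment contains no frames")
  sum(al$a == referent_id & al$b == referent_id) / al$n
}

#' Mutual gaze over a segment
#'
#' Fraction of in-segment frames where the partners look at each other
#' simultaneously (both frames' target is `person`). Symmetric in roles.
#'
#' @inheritParams joint_attention
#' @return proportion in [0, 1].
#' @export
mutual_gaze <- function(targets_a, targets_b, segment) {
  al <- aligned_labels(targets_a, targets_b, segment)
  if (al$n == 0) stop("segment contains no frames")
  sum(al$a == "person" & al$b == "person") / al$n
}
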