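# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately naive (per-element loops, direct formulas)
# and share no code with the implementation paths they check.

# Direct-form recursive evaluation of a rational transfer function:
# a[1] y[n] = sum(b[k] x[n-k+1]) - sum(a[k] y[n-k+1]), k >= 2.
oracle_direct_form <- function(b, a, x) {
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_along(b)) {
      if (i - k + 1 >= 1) acc <- acc + b[k] * x[i - k + 1]
    }
    for (k in seq_along(a)[-1]) {
      if (i - k + 1 >= 1) acc <- acc - a[k] * y[i - k + 1]
    }
    y[i] <- acc / a[1]
  }
  y
}

# Least-squares slope by the explicit covariance/variance formula.
oracle_slope <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# Spearman rho via Pearson on midranks.
oracle_midrank_rho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exhaustive per-candidate scan with the (angle, distance, id) tie rules.
oracle_assign <- function(origin, direction, cand, threshold_deg) {
  best <- NULL
  for (j in seq_len(nrow(cand))) {
    v <- c(cand$x[j] - origin[1], cand$y[j] - origin[2], cand$z[j] - origin[3])
    ang <- acos(max(-1, min(1, sum(direction * v) /
                              (sqrt(sum(direction^2)) * sqrt(sum(v^2)))))) * 180 / pi
    d <- sqrt(sum(v^2))
    rec <- list(id = cand$id[j], ang = ang, dist = d)
    if (is.null(best) ||
        ang < best$ang ||
        (ang == best$ang && d < best$dist) ||
        (ang == best$ang && d == best$dist && rec$id < best$id)) {
      best <- rec
    }
  }
  if (best$ang <= threshold_deg) best$id else "none"
}

# Build a pupil_series directly (frames at 50 Hz starting at t0).
make_series <- function(d, valid = !is.na(d), excluded = rep(FALSE, length(d)),
                        t0 = 0) {
  t <- t0 + (seq_along(d) - 1) / 50
  dyadload:::new_pupil_series(t, d, valid, excluded,
                              rep("merged-both", length(d)))
}

# Build a gaze_targets frame from a label vector (frames at 50 Hz from t0).
make_targets <- function(labels, role = "builder", t0 = 0) {
  structure(data.frame(t = t0 + (seq_along(labels) - 1) / 50, role = role,
                       target = labels, angular_error_deg = NA_real_,
                       stringsAsFactors = FALSE),
            class = c("gaze_targets", "data.frame"))
}

# Minimal valid segments table.
make_segments <- function(starts, ends, instruction, ordinal = NULL,
                          referent = "obj01", interaction = "ia1") {
  data.frame(interaction_id = interaction, instruction_id = instruction,
             fragment_ordinal = if (is.null(ordinal)) NA_integer_ else ordinal,
             start = starts, end = ends, referent_id = referent,
             speaker_role = "instructor", stringsAsFactors = FALSE)
}

# A small quiet corpus for end-to-end tests.
quiet_sim <- function(...) {
  args <- utils::modifyList(list(n_interactions = 2,
                                 instructions_per_interaction = 4),
                            list(...))
  do.call(sim_config, args)
}
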