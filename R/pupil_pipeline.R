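# Pupil preprocessing: binocular merge, gap interpolation, zero-phase
# low-pass Butterworth smoothing, range/z-score outlier exclusion, baseline
# referencing, and the three per-segment task-evoked pupillary response
# metrics (mean dilation, peak dilation, slope).

#' Low-pass filter specification
#'
#' Defaults follow standard pupillometric practice for 50 Hz video-based
#' eye-trackers: a 5th-order Butterworth with a 4 Hz cut-off. Zero-phase
#' (forward-backward) application is the default so that metric windows are
#' not shifted by the filter's group delay; set `zero_phase = FALSE` for a
#' causal single pass.
#'
#' @param order filter order (>= 1).
#' @param cutoff_hz cut-off frequency, Hz; must be below Nyquist.
#' @param sampling_hz sampling rate, Hz.
#' @param zero_phase logical; forward-backward filtering when `TRUE`.
#' @export
filter_spec <- function(order = 5L, cutoff_hz = 4, sampling_hz = 50,
                        zero_phase = TRUE) {
  stopifnot(order >= 1, cutoff_hz > 0, cutoff_hz < sampling_hz / 2)
  structure(list(order = as.integer(order), cutoff_hz = cutoff_hz,
                 sampling_hz = sampling_hz, zero_phase = zero_phase),
            class = "filter_spec")
}

#' Outlier exclusion specification
#'
#' Two rules: a physiologically feasible diameter range, and a z-score rule
#' excluding samples more than `z_threshold` standard deviations from the
#' scope mean. The range rule is applied first and the z statistics are
#' computed on range-surviving frames. `z_scope` records whether statistics
#' are per participant per recording (default) or pooled globally; the scope
#' is resolved by the caller via the `center`/`scale` overrides of
#' [remove_outliers()].
#'
#' @param feasible_min_mm,feasible_max_mm feasible diameter range, mm.
#' @param z_threshold exclusion threshold in standard deviations.
#' @param z_scope `"per-participant"` or `"global"`.
#' @export
outlier_spec <- function(feasible_min_mm = 1.5, feasible_max_mm = 9,
                         z_threshold = 2, z_scope = "per-participant") {
  stopifnot(feasible_min_mm < feasible_max_mm, z_threshold > 0)
  structure(list(feasible_min_mm = feasible_min_mm,
                 feasible_max_mm = feasible_max_mm,
                 z_threshold = z_threshold,
                 z_scope = match.arg(z_scope, c("per-participant", "global"))),
            class = "outlier_spec")
}

new_pupil_series <- function(t, diameter_mm, valid, excluded, provenance) {
  out <- data.frame(t = t, diameter_mm = diameter_mm, valid = valid,
                    excluded = excluded, provenance = provenance,
                    stringsAsFactors = FALSE)
  class(out) <- c("pupil_series", "data.frame")
  out
}

# Frames that may enter metric computation.
usable_frames <- function(series) series$valid & !series$excluded

#' Merge a binocular pupil stream into one monocular series
#'
#' Left and right diameters are highly correlated; when both eyes are
#' available their mean is taken, otherwise the available eye is used. Frames
#' with neither eye are invalid placeholders. Missingness is data here, never
#' an error.
#'
#' @param stream a `pupil_stream`.
#' @return a `pupil_series` with per-frame provenance flags
#'   (`merged-both`, `merged-left-only`, `merged-right-only`, `none`).
#' @export
merge_binocular <- function(stream) {
  stopifnot(inherits(stream, "pupil_stream"))
  l <- stream$left_mm; r <- stream$right_mm
  both <- !is.na(l) & !is.na(r)
  lonly <- !is.na(l) & is.na(r)
  ronly <- is.na(l) & !is.na(r)
  d <- rep(NA_real_, length(l))
  d[both] <- (l[both] + r[both]) / 2
  d[lonly] <- l[lonly]
  d[ronly] <- r[ronly]
  prov <- rep("none", length(l))
  prov[both] <- "merged-both"
  prov[lonly] <- "merged-left-only"
  prov[ronly] <- "merged-right-only"
  new_pupil_series(stream$t, d, !is.na(d), FALSE, prov)
}

#' Interpolate short gaps in a pupil series
#'
#' Runs of unusable frames no longer than `max_gap_frames`, flanked on both
#' sides by usable frames, are filled by linear interpolation and flagged
#' `interpolated`. Longer gaps and gaps touching either end of the series
#' (no flank to anchor the line) remain invalid -- extrapolation is refused.
#' The default of 25 frames (0.5 s at 50 Hz) covers a typical blink.
#'
#' @param series a `pupil_series`.
#' @param max_gap_frames longest gap, in frames, that will be bridged.
#' @return the series with short gaps filled.
#' @export
interpolate_gaps <- function(series, max_gap_frames = 25L) {
  ok <- usable_frames(series)
  n <- length(ok)
  if (n == 0 || all(ok)) return(series)
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (i in seq_along(runs$lengths)) {
    if (runs$values[i]) next
    a <- starts[i]; b <- ends[i]
    if (a == 1 || b == n) next                      # edge gap: no flank
    if (runs$lengths[i] > max_gap_frames) next
    left <- a - 1; right <- b + 1
    w <- (seq(a, b) - left) / (right - left)
    series$diameter_mm[a:b] <- (1 - w) * series$diameter_mm[left] +
      w * series$diameter_mm[right]
    series$valid[a:b] <- TRUE
    series$excluded[a:b] <- FALSE
    series$provenance[a:b] <- "interpolated"
  }
  series
}

#' Low-pass filter a pupil series
#'
#' Smooths the diameter trace with a Butterworth low-pass (see
#' [filter_spec()]). Remaining unusable frames are bridged linearly (edges:
#' nearest usable value) purely so the filter sees a finite signal; the
#' validity mask is unchanged, so those frames stay out of all metrics.
#'
#' @param series a `pupil_series`; gaps should have been bridged with
#'   [interpolate_gaps()] first.
#' @param spec a `filter_spec`.
#' @return the filtered series.
#' @export
lowpass_filter <- function(series, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  ok <- usable_frames(series)
  if (sum(ok) < 3 * spec$order) {
    stop("series too short to filter: need at least ", 3 * spec$order,
         " usable frames, have ", sum(ok))
  }
  x <- series$diameter_mm
  if (any(!ok)) x <- bridge_na(ifelse(ok, x, NA_real_))
  bf <- signal::butter(spec$order, spec$cutoff_hz / (spec$sampling_hz / 2),
                       type = "low")
  y <- if (spec$zero_phase) {
    # odd-reflection padding so the forward-backward pass starts from a
    # signal-consistent state and edge transients decay inside the pads
    n <- length(x)
    pad <- min(n - 1, 250L)
    xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
    yp <- signal::filtfilt(bf, xp)
    yp[(pad + 1):(pad + n)]
  } else {
    as.numeric(signal::filter(bf, x))
  }
  series$diameter_mm <- y
  series
}

# Linear interior interpolation + nearest-value edge fill over NAs.
bridge_na <- function(x) {
  n <- length(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0) stop("no finite values to bridge")
  out <- stats::approx(idx, x[idx], xout = seq_len(n), rule = 2)$y
  out
}

#' Exclude outlying pupil samples
#'
#' Applies the feasible-range rule, then flags frames whose diameter lies
#' more than `spec$z_threshold` standard deviations from the mean. The z
#' statistics are computed over valid, range-surviving frames; previously
#' excluded frames are kept in the statistics unless
#' `recompute_stats = TRUE`, which makes a repeated application with the
#' default exclude nothing new (idempotence).
#'
#' @param series a `pupil_series`.
#' @param spec an `outlier_spec`.
#' @param recompute_stats logical; recompute mean/SD on currently surviving
#'   frames instead of all range-surviving frames.
#' @param center,scale optional explicit statistics (e.g. for a global
#'   z-scope pooled across participants); both must be given together.
#' @return the series with `excluded` flags set.
#' @export
remove_outliers <- function(series, spec = outlier_spec(),
                            recompute_stats = FALSE,
                            center = NULL, scale = NULL) {
  stopifnot(inherits(spec, "outlier_spec"))
  d <- series$diameter_mm
  in_range <- series$valid & d >= spec$feasible_min_mm & d <= spec$feasible_max_mm
  out_range <- series$valid & !in_range
  stat_frames <- if (recompute_stats) in_range & !series$excluded else in_range
  if (is.null(center) != is.null(scale)) {
    stop("center and scale must be supplied together")
  }
  if (is.null(center)) {
    center <- mean(d[stat_frames])
    scale <- stats::sd(d[stat_frames])
  }
  z_out <- if (is.finite(scale) && scale > 0) {
    in_range & abs(d - center) / scale > spec$z_threshold
  } else {
    rep(FALSE, length(d))                     # constant signal: nothing to cut
  }
  series$excluded <- series$excluded | out_range | z_out
  series$provenance[out_range | z_out] <- "excluded"
  if (!any(usable_frames(series))) {
    stop("all frames excluded: unusable pupil signal")
  }
  series
}

#' Extract the pre-stimulus pupil baseline
#'
#' Mean diameter over the usable frames of a window preceding the first
#' instruction onset. Dilation metrics are later referenced to this value so
#' they reflect task-evoked change, not resting diameter.
#'
#' @param series a cleaned `pupil_series`.
#' @param window numeric `(start, end)` seconds.
#' @return a `pupil_baseline`: `list(value_mm, window, n_frames)`.
#' @export
extract_baseline <- function(series, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  sel <- series$t >= window[1] & series$t < window[2]
  if (!any(sel)) stop("baseline window outside the series time span")
  ok <- sel & usable_frames(series)
  if (sum(ok) < 0.5 * sum(sel)) {
    stop(sprintf("baseline window has %.0f%% valid coverage; need >= 50%%",
                 100 * sum(ok) / sum(sel)))
  }
  structure(list(value_mm = mean(series$diameter_mm[ok]),
                 window = window, n_frames = sum(ok)),
            class = "pupil_baseline")
}

#' Per-segment pupillary response metrics
#'
#' Over the usable frames of one utterance segment: mean dilation (signed
#' mean of diameter minus baseline; positive = dilation, negative =
#' contraction), peak dilation (maximum of the same difference), and slope
#' (least-squares slope of diameter against frame index, in mm per frame at
#' the 50 Hz rate -- multiply by 50 for mm per second).
#'
#' @param series a cleaned `pupil_series`.
#' @param baseline a `pupil_baseline` (or a plain number, mm).
#' @param segment list/row with `start` and `end` in seconds.
#' @return `list(mean_dilation, peak_dilation, slope, n_frames)`; all three
#'   metrics are `NA` ("undefined") when fewer than 2 usable frames fall in
#'   the segment.
#' @export
segment_pupil_metrics <- function(series, baseline, segment) {
  b <- if (inherits(baseline, "pupil_baseline")) baseline$value_mm else baseline
  sel <- series$t >= segment$start & series$t < segment$end & usable_frames(series)
  n <- sum(sel)
  if (n < 2) {
    return(list(mean_dilation = NA_real_, peak_dilation = NA_real_,
                slope = NA_real_, n_frames = n))
  }
  d <- series$diameter_mm[sel]
  f <- time_to_frame(series$t[sel])
  fit <- stats::lm.fit(cbind(1, f), d)
  list(mean_dilation = mean(d - b),
       peak_dilation = max(d - b),
       slope = unname(fit$coefficients[2]),
       n_frames = n)
}

#' Run the full pupil preprocessing chain
#'
#' merge -> interpolate short gaps -> low-pass filter -> outlier exclusion,
#' in that order, returning the cleaned series ready for
#' [extract_baseline()] and [segment_pupil_metrics()].
#'
#' @param stream a `pupil_stream`.
#' @param fspec a `filter_spec`.
#' @param ospec an `outlier_spec`.
#' @param max_gap_frames see [interpolate_gaps()].
#' @return a cleaned `pupil_series`.
#' @export
process_pupil <- function(stream, fspec = filter_spec(),
                          ospec = outlier_spec(), max_gap_frames = 25L) {
  series <- merge_binocular(stream)
  series <- interpolate_gaps(series, max_gap_frames)
  series <- lowpass_filter(series, fspec)
  remove_outliers(series, ospec)
}
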