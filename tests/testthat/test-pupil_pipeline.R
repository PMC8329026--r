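# Binocular merge, filtering, outlier exclusion, interpolation, baseline,
# per-segment pupillary metrics.

test_that("binocular merge averages, falls back to the available eye, flags provenance", {
  s <- pupil_stream(t = (0:3) / 50,
                    left_mm = c(3.0, NA, NA, 3.4),
                    right_mm = c(3.2, 3.2, NA, NA))
  m <- merge_binocular(s)
  expect_equal(m$diameter_mm, c(3.1, 3.2, NA, 3.4))
  expect_equal(m$provenance,
               c("merged-both", "merged-right-only", "none", "merged-left-only"))
  expect_equal(m$valid, c(TRUE, TRUE, FALSE, TRUE))
})

test_that("low-pass filter has unit DC gain and matches a direct-form oracle on an impulse", {
  const <- make_series(rep(3.7, 400))
  out <- lowpass_filter(const, filter_spec())
  expect_equal(out$diameter_mm, rep(3.7, 400), tolerance = 1e-9)

  # causal single-pass impulse response vs naive difference-equation oracle
  x <- c(1, rep(0, 299))
  sp <- filter_spec(zero_phase = FALSE)
  y <- lowpass_filter(make_series(x), sp)$diameter_mm
  bf <- signal::butter(sp$order, sp$cutoff_hz / (sp$sampling_hz / 2), "low")
  expect_equal(y, oracle_direct_form(bf$b, bf$a, x), tolerance = 1e-9)
})

test_that("filter magnitude response: 10 Hz is stopped, 1 Hz passes", {
  t <- (0:999) / 50
  amp_after <- function(freq) {
    x <- sin(2 * pi * freq * t)
    y <- lowpass_filter(make_series(x), filter_spec())$diameter_mm
    mid <- 200:800
    fit <- lm(y[mid] ~ sin(2 * pi * freq * t[mid]) + cos(2 * pi * freq * t[mid]))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_lt(amp_after(10), 0.05)
  expect_gt(amp_after(1), 0.95)
})

test_that("too-short series refuse to filter with advice", {
  expect_error(lowpass_filter(make_series(rep(3, 10)), filter_spec()),
               "at least 15")
})

test_that("outlier exclusion: range rule, constant series, idempotence, monotonicity", {
  d <- c(rep(3.0, 30), 10.0, rep(3.0, 30))
  out <- remove_outliers(make_series(d), outlier_spec())
  expect_equal(which(out$excluded), 31L)     # infeasible 10 mm frame

  const <- remove_outliers(make_series(rep(3, 50)), outlier_spec())
  expect_equal(sum(const$excluded), 0)       # SD = 0, range satisfied

  # idempotence with fixed scope statistics
  once <- remove_outliers(make_series(rnorm(200, 4, 0.3)), outlier_spec())
  twice <- remove_outliers(once, outlier_spec())
  expect_equal(twice$excluded, once$excluded)

  # lowering the threshold never shrinks the excluded set
  set.seed(21)
  d <- rnorm(300, 4, 0.4)
  hi <- remove_outliers(make_series(d), outlier_spec(z_threshold = 2.5))
  lo <- remove_outliers(make_series(d), outlier_spec(z_threshold = 1.5))
  expect_true(all(lo$excluded[hi$excluded]))

  expect_error(remove_outliers(make_series(rep(12, 20)), outlier_spec()),
               "unusable")
})

test_that("interpolation fills short interior gaps linearly and refuses edges", {
  s <- make_series(c(3.0, NA, 3.2))
  out <- interpolate_gaps(s)
  expect_equal(out$diameter_mm[2], 3.1)
  expect_equal(out$provenance[2], "interpolated")

  lead <- interpolate_gaps(make_series(c(NA, NA, 3.0, 3.1)))
  expect_false(any(lead$valid[1:2]))

  long <- interpolate_gaps(make_series(c(3, rep(NA, 30), 4)), max_gap_frames = 25)
  expect_false(any(long$valid[2:31]))
})

test_that("baseline is the mean of valid window frames with coverage guard", {
  expect_equal(extract_baseline(make_series(rep(3, 100)), c(0, 2))$value_mm, 3)
  s <- make_series(c(3.0, 3.0, 4.0, NA))
  expect_equal(extract_baseline(s, c(0, 0.08))$value_mm, 10 / 3)
  expect_error(extract_baseline(make_series(rep(NA_real_, 50)), c(0, 1)),
               "coverage|valid")
  # 1 valid of 4 frames is under 50%
  expect_error(extract_baseline(make_series(c(3, NA, NA, NA)), c(0, 0.08)),
               "coverage")
})

test_that("segment metrics: null segment, exact linear ramp, undefined under 2 frames", {
  flat <- make_series(rep(3.5, 200))
  m <- segment_pupil_metrics(flat, 3.5, list(start = 1, end = 3))
  expect_equal(unlist(m[1:3]), c(mean_dilation = 0, peak_dilation = 0, slope = 0))

  d <- 3 + 0.002 * (0:199)                  # exactly linear in frame index
  m2 <- segment_pupil_metrics(make_series(d), 3, list(start = 0, end = 4))
  expect_equal(m2$slope, 0.002, tolerance = 1e-12)
  expect_equal(m2$peak_dilation, d[200] - 3, tolerance = 1e-12)

  two <- make_series(c(3, NA, NA, NA))
  m3 <- segment_pupil_metrics(two, 3, list(start = 0, end = 0.08))
  expect_true(all(is.na(unlist(m3[1:3]))))
})

test_that("peak dilation is never below mean dilation when both are defined", {
  set.seed(33)
  for (i in 1:25) {
    d <- 4 + cumsum(rnorm(150, 0, 0.02))
    s <- make_series(d)
    m <- segment_pupil_metrics(s, 4, list(start = runif(1, 0, 1),
                                          end = runif(1, 1.5, 2.9)))
    expect_gte(m$peak_dilation, m$mean_dilation)
  }
})

test_that("the full chain reports near-zero dilation on a null synthetic signal", {
  gen <- generate_dyads(quiet_sim(
    dilation_mm = list(instructor = list(non_fragmented = 0, ordinal = rep(0, 4)),
                       builder = list(non_fragmented = 0, ordinal = rep(0, 4))),
    dilation_sd_mm = 0, pupil_noise_sd_mm = 0, eye_noise_sd_mm = 0,
    blink_rate_per_min = 0, eye_missing_rate = 0), seed = 4)
  rows <- compute_metrics_all(gen$recordings)
  expect_lt(max(abs(rows$mean_dilation)), 1e-6)
})
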