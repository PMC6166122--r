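# dyadic tick grid (exact binary fractions) so closed-form boundary
# assertions are immune to floating-point grid noise
make_rec <- function(t_end = 60, handset = NULL, extra = list(),
                     rate = 64) {
  ts <- (0:(t_end * rate)) / rate
  if (is.null(handset)) handset <- numeric(length(ts))
  chans <- c(list(handset = channel("handset", ts, handset, rate)),
             lapply(stats::setNames(names(extra), names(extra)), function(nm)
               channel(nm, ts, extra[[nm]], rate)))
  resample_to_master(channels = chans)
}

test_that("interval extraction matches the linear-scan oracle", {
  ts <- (0:(60 * 64)) / 64
  expect_equal(nrow(extract_intervals(make_rec(60))), 0L)

  v <- as.numeric(ts >= 5.0 & ts <= 12.5)
  iv <- extract_intervals(make_rec(60, v))
  expect_equal(nrow(iv), 1L)
  expect_identical(iv$onset, 5.0)
  expect_identical(iv$offset, 12.5)
  expect_identical(iv$duration, 7.5)

  # two presses ~0.1 s apart merge under a 0.2 s merge gap
  v2 <- as.numeric((ts >= 5 & ts <= 8) | (ts >= 8.1 & ts <= 11))
  iv2 <- extract_intervals(make_rec(60, v2), merge_gap = 0.2)
  expect_equal(nrow(iv2), 1L)
  expect_identical(iv2$duration, 6)
  iv2b <- extract_intervals(make_rec(60, v2), merge_gap = 0.05)
  expect_equal(nrow(iv2b), 2L)

  # sub-min_duration runs are dropped
  v3 <- as.numeric(ts >= 5 & ts <= 5.2)
  expect_equal(nrow(extract_intervals(make_rec(60, v3),
                                      min_duration = 0.5)), 0L)

  # random bursty trace against the independent scan+merge oracle
  set.seed(21)
  v4 <- numeric(length(ts))
  for (o in runif(6, 1, 55)) v4 <- v4 + runif(1) *
      as.numeric(ts >= o & ts <= o + runif(1, 0.2, 4))
  iv4 <- extract_intervals(make_rec(60, v4), press_threshold = 0.02,
                           merge_gap = 0.3, min_duration = 0.5)
  orc <- oracle_intervals(ts, v4, 0.02, 0.3, 0.5)
  expect_equal(iv4$onset, orc$onset)
  expect_equal(iv4$offset, orc$offset)
  # interval endpoints sit on above-threshold samples
  for (i in seq_len(nrow(iv4))) {
    expect_gt(v4[which(ts == iv4$onset[i])], 0.02)
    expect_gt(v4[which(ts == iv4$offset[i])], 0.02)
  }
  expect_error(extract_intervals(make_rec(60, v4 - 1)), ">= 0")
})

test_that("sequences carry exact 10 s windows with truncation flags", {
  ts <- (0:(60 * 64)) / 64
  v <- as.numeric(ts >= 25 & ts <= 33)
  rec <- make_rec(60, v, extra = list(x = sin(ts)))
  iv <- extract_intervals(rec)
  sq <- build_sequence(rec, iv[1, ])
  expect_equal(sum(sq$pre), 640L)           # 10 s x 64 Hz
  expect_equal(sum(sq$post), 640L)
  expect_false(sq$truncated_pre || sq$truncated_post)
  # slicing identity: sequence values equal recording values at same ticks
  expect_identical(sq$data$x,
                   rec$x[rec$timestamp_s >= 15 & rec$timestamp_s <= 43])

  # onset 4 s after trip start: pre truncated to 4 s and flagged
  v2 <- as.numeric(ts >= 4 & ts <= 9)
  rec2 <- make_rec(60, v2)
  sq2 <- build_sequence(rec2, extract_intervals(rec2)[1, ])
  expect_true(sq2$truncated_pre)
  expect_equal(sum(sq2$pre), 256L)          # 4 s x 64 Hz

  expect_error(build_sequence(rec, list(onset = -5, offset = 2)),
               "outside")
})

test_that("percent resampling matches the per-slice mean oracle", {
  ts <- (0:(60 * 64)) / 64
  v <- as.numeric(ts >= 25 & ts <= 35)
  x <- ifelse(ts < 25, 0, ifelse(ts < 35, (ts - 25) / 10, 1))
  rec <- make_rec(60, v, extra = list(x = x, const = rep(2.5, length(ts))))
  iv <- extract_intervals(rec)
  sq <- build_sequence(rec, iv[1, ])

  pc <- percent_resample(sq, "const")
  expect_equal(pc$values, rep(2.5, 300))
  expect_identical(unname(pc$slice_width["pre"]), 0.1)
  expect_identical(unname(pc$slice_width["post"]), 0.1)
  expect_equal(unname(pc$slice_width["during"]), iv$duration[1] / 100)

  px <- percent_resample(sq, "x")
  orc <- oracle_percent_slices(sq$data$timestamp_s, sq$data$x,
                               iv$onset[1], iv$offset[1])
  filled <- !px$interpolated & !px$missing
  expect_equal(px$values[filled], orc[filled], tolerance = 1e-9)
  mid <- 101:200
  expect_true(all(abs(px$values[mid] - (mid - 100.5) / 100) < 0.002))

  # affine equivariance: resample(a x + b) = a resample(x) + b
  rec2 <- make_rec(60, v, extra = list(x2 = 3 * x - 1))
  sq2 <- build_sequence(rec2, iv[1, ])
  px2 <- percent_resample(sq2, "x2")
  expect_equal(px2$values, 3 * px$values - 1, tolerance = 1e-9)

  expect_error(percent_resample(sq, "nope"), "not present")
})

test_that("short intervals interpolate empty slices and flag them", {
  ts <- (0:(60 * 64)) / 64
  v <- as.numeric(ts >= 30 & ts <= 31)   # 1 s press: 65 samples, 100 slices
  rec <- make_rec(60, v, extra = list(x = sin(ts)))
  sq <- build_sequence(rec, extract_intervals(rec)[1, ])
  px <- percent_resample(sq, "x")
  expect_length(px$values, 300L)
  expect_true(any(px$interpolated[101:200]))
  expect_true(all(!is.na(px$values[101:200])))

  # truncated pre window: out-of-span slices are missing, not interpolated
  v2 <- as.numeric(ts >= 3 & ts <= 8)
  rec2 <- make_rec(60, v2, extra = list(x = cos(ts)))
  sq2 <- build_sequence(rec2, extract_intervals(rec2)[1, ])
  px2 <- percent_resample(sq2, "x")
  expect_true(all(is.na(px2$values[1:69])))
  expect_true(all(!is.na(px2$values[101:300])))
  expect_false(any(px2$interpolated[1:69]))
})

test_that("interval bookkeeping reports count and duration descriptives", {
  ts <- (0:(60 * 64)) / 64
  v <- as.numeric((ts >= 5 & ts <= 9) | (ts >= 30 & ts <= 38))
  iv <- extract_intervals(make_rec(60, v))
  st <- interval_stats(iv)
  expect_equal(st$n, 2L)
  expect_equal(st$mean_duration, 6)
  expect_equal(st$sd_duration, sd(c(4, 8)))
})
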