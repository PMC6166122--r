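test_that("zscore standardizes over its scope with degenerate handling", {
  expect_equal(as.numeric(zscore(c(1, 2, 3))), c(-1, 0, 1))
  z <- zscore(rep(4, 10))
  expect_equal(as.numeric(z), rep(0, 10))
  expect_true(attr(z, "degenerate"))
  set.seed(3)
  x <- rnorm(500, 7, 3)
  x[c(5, 80)] <- NA
  z2 <- zscore(x)
  expect_lt(abs(mean(z2, na.rm = TRUE)), 1e-9)
  expect_lt(abs(sd(z2, na.rm = TRUE) - 1), 1e-9)
  expect_true(all(is.na(z2[c(5, 80)])))
  expect_error(zscore(c(1, NA, NA)), "at least 2")
})

test_that("pupil preprocessing averages eyes then smooths over +/-300 ms", {
  n <- 200
  expect_equal(pupil_preprocess(rep(3.5, n), rep(3.5, n)), rep(3.5, n))
  expect_equal(pupil_preprocess(rep(3, n), rep(4, n)), rep(3.5, n))

  # unit impulse spreads to 37 consecutive outputs of 1/37
  imp <- numeric(n); imp[100] <- 1
  sm <- pupil_preprocess(imp, imp)
  expect_equal(sm[82:118], rep(1 / 37, 37))
  expect_equal(sm[c(81, 119)], c(0, 0))

  # matches the brute-force window-mean oracle, including missing samples
  set.seed(4)
  l <- rnorm(n, 3.5, 0.2); r <- rnorm(n, 3.5, 0.2)
  l[30:40] <- NA; r[35:45] <- NA
  got <- pupil_preprocess(l, r)
  mono <- rowMeans(cbind(l, r), na.rm = TRUE)
  mono[is.nan(mono)] <- NA
  expect_equal(got, oracle_moving_avg(mono, 18), tolerance = 1e-12)
  # both eyes missing and no neighbours -> missing output propagates
  l2 <- rep(NA_real_, n); r2 <- rep(NA_real_, n)
  l2[1] <- r2[1] <- 3
  expect_true(all(is.na(pupil_preprocess(l2, r2)[20:n])))
})

test_that("frame luminance is mean HSL lightness", {
  black <- matrix(0, 10, 3)
  white <- matrix(1, 10, 3)
  expect_equal(frame_luminance(black), 0)
  expect_equal(frame_luminance(white), 1)
  expect_equal(frame_luminance(rbind(black, white)), 0.5)
  # saturated red: L = (1 + 0) / 2
  expect_equal(frame_luminance(matrix(c(1, 0, 0), 1)), 0.5)
  arr <- array(0.25, dim = c(4, 5, 3))
  expect_equal(frame_luminance(arr), 0.25)
  expect_error(frame_luminance(matrix(numeric(0), 0, 3)), "non-empty")
})

test_that("luminance adjustment is exact elementwise subtraction", {
  z <- rnorm(50)
  expect_equal(luminance_adjust(z, numeric(50)), z)
  expect_equal(luminance_adjust(z, z), numeric(50))
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(luminance_adjust(a + b, b), a)     # linear and exact
  expect_error(luminance_adjust(z, numeric(10)), "length")
})

test_that("luminance adjustment improves dilation recovery on synthetic data", {
  # over >=100 sequences, the adjusted pupil profile correlates better
  # with the generator's true inverse-u dilation template than the
  # unadjusted one
  template <- c(rep(0, 100), sin(pi * ((1:100) - 0.5) / 100), rep(0, 100))
  cor_adj <- c(); cor_raw <- c()
  for (s in study_cohort()[1:40]) {
    rec <- augment_recording(resample_to_master(s))
    iv <- extract_intervals(rec)
    for (i in seq_len(nrow(iv))) {
      sq <- build_sequence(rec, iv[i, ], all_intervals = iv)
      pz <- tryCatch(as.numeric(zscore(sq$data$pupil)),
                     error = function(e) NULL)
      if (is.null(pz)) next
      adj <- percent_resample(sq, "adj", luminance_adjust(pz, sq$data$lum_z))
      raw <- percent_resample(sq, "raw", pz)
      ok <- !is.na(adj$values) & !is.na(raw$values)
      cor_adj <- c(cor_adj, cor(adj$values[ok], template[ok]))
      cor_raw <- c(cor_raw, cor(raw$values[ok], template[ok]))
    }
  }
  expect_gt(length(cor_adj), 100)
  expect_gt(mean(cor_adj), mean(cor_raw))
})

test_that("blink rate is onset count over window duration", {
  expect_equal(blink_rate(numeric(0), 0, 10), 0)
  expect_equal(blink_rate(c(1, 2, 3), 0, 7.5), 0.4)
  expect_equal(blink_rate(c(1, 2, 3), 2, 4), 1)     # [start, end) convention
  expect_error(blink_rate(c(1), 5, 5), "positive")
})

test_that("interblink timer resets at blink starts and slopes upward", {
  ts <- (0:640) / 64
  tm <- interblink_timer(c(2, 6), ts)
  expect_equal(tm[ts == 5.90625], 3.90625)
  expect_equal(tm[ts == 6.0], 0)
  # slope contract: never decreases except across a reset to zero
  d <- diff(as.numeric(tm))
  expect_true(all(d >= 0 | abs(as.numeric(tm)[-1]) < 1e-12))
  # no blinks: elapsed time from window start, flagged pre-first
  tm2 <- interblink_timer(numeric(0), ts)
  expect_equal(as.numeric(tm2), ts - ts[1])
  expect_true(all(attr(tm2, "pre_first")))
  expect_false(any(attr(tm, "pre_first")[ts >= 2]))
})

test_that("rmssd matches the direct-formula oracle", {
  expect_equal(as.numeric(rmssd(rep(0.8, 10), collapse = FALSE)), 0)
  expect_equal(as.numeric(rmssd(c(0.80, 0.85, 0.80), collapse = FALSE)),
               0.05)
  set.seed(6)
  ibi <- 0.8 + cumsum(rnorm(50, 0, 0.01))
  expect_equal(as.numeric(rmssd(ibi, collapse = FALSE)),
               oracle_rmssd(ibi), tolerance = 1e-12)
  # 10 Hz device log repeats each beat ~8x; collapsing recovers the beats
  logged <- rep(ibi, times = sample(6:9, 50, replace = TRUE))
  expect_equal(as.numeric(rmssd(logged)), oracle_rmssd(ibi),
               tolerance = 1e-12)
  short <- rmssd(c(0.8, 0.9))
  expect_true(is.na(short))
  expect_true(attr(short, "short_window"))
})

test_that("skin resistance converts to microsiemens reciprocally", {
  expect_equal(scl_convert(1000), 1)
  expect_equal(scl_convert(500), 2)
  x <- runif(20, 100, 2000)
  expect_equal(1000 / scl_convert(x), x)            # round trip
  expect_warning(out <- scl_convert(c(500, -1, 0)), "non-positive")
  expect_equal(out, c(2, NA, NA))
})

test_that("movement mask dilates spikes and only removes values", {
  ts <- (0:600) / 10
  still_a <- rep(1, length(ts)); still_g <- rep(5, length(ts))
  expect_false(any(movement_mask(still_a, still_g, ts)))

  a <- still_a; a[301] <- 1.6                       # spike at t = 30
  m <- movement_mask(a, still_g, ts, dilation = 0.5)
  expect_identical(which(m), which(ts >= 29.5 & ts <= 30.5))

  g <- still_g; g[101] <- 120                       # gyro route, t = 10
  m2 <- movement_mask(still_a, g, ts, dilation = 0.5)
  expect_identical(which(m2), which(ts >= 9.5 & ts <= 10.5))

  # on synthetic sessions the masked fraction tracks the injected
  # artifact time plus the dilation overhead (3-min trip: ~6 artifacts)
  s <- study_cohort()[[1]]
  rec <- resample_to_master(s)
  art <- attr(s$channels$band_scl, "artifacts")
  expect_gt(nrow(art), 0)
  msk <- movement_mask(rec$band_accel, rec$band_gyro, rec$timestamp_s)
  t_end <- max(rec$timestamp_s)
  injected <- sum(pmin(art$offset, t_end) - pmin(art$onset, t_end))
  overhead <- nrow(art) * 2 * 0.5
  expect_gt(mean(msk), injected / t_end * 0.5)
  expect_lt(mean(msk), (injected + overhead) / t_end + 0.02)
})

test_that("linear detrending returns residuals with zero mean and slope", {
  ts <- seq(0, 30, by = 0.1)
  line <- 2 + 0.3 * ts
  expect_equal(detrend_linear(line, ts), rep(0, length(ts)),
               tolerance = 1e-9)
  wave <- sin(2 * pi * ts / 7)
  got <- detrend_linear(line + wave, ts)
  expect_equal(got, oracle_detrend(line + wave, ts), tolerance = 1e-9)
  set.seed(8)
  y <- rnorm(length(ts))
  y[c(3, 33)] <- NA
  res <- detrend_linear(y, ts)
  ok <- !is.na(res)
  expect_lt(abs(mean(res[ok])), 1e-9)
  expect_lt(abs(coef(lm(res[ok] ~ ts[ok]))[2]), 1e-9)
  expect_true(all(is.na(res[c(3, 33)])))
  expect_error(detrend_linear(c(1, 2, 3), rep(1, 3)), "degenerate")
})

test_that("displacement from start begins at exactly zero", {
  expect_equal(as.numeric(displacement_from_start(c(100, 98, 97))),
               c(0, -2, -3))
  expect_equal(as.numeric(displacement_from_start(rep(5, 8))), rep(0, 8))
  d <- displacement_from_start(c(NA, 10, 12))
  expect_equal(as.numeric(d), c(NA, 0, 2))
  expect_true(attr(d, "ref_shifted"))
  expect_error(displacement_from_start(numeric(0)), "empty")
})
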