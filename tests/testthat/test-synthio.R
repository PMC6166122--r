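test_that("braking controller reaches the configured minimum gap", {
  kin <- simulate_scenario()
  cfg <- scenario_config()
  # integration error bound: half * decel * dt^2 with dt = one master tick
  v0 <- (cfg$ego_speed - cfg$lead_speed) / 3.6
  decel <- v0^2 / (2 * (cfg$brake_onset_gap - cfg$min_gap))
  tol <- 0.5 * decel * (1 / cfg$master_rate)^2 + 1e-9
  expect_lt(abs(min(kin$gap) - cfg$min_gap), tol + 1e-3)
  expect_true(all(kin$gap > 0))

  # closed-form closing time from 100 m to 9 m at 20 km/h relative speed
  sched <- attr(kin, "approaches")
  expect_equal(sched$t_brake_onset[1], 91 / (20 / 3.6), tolerance = 1e-9)

  # per-approach gap is unimodal: non-increasing to its minimum, then
  # non-decreasing until the reset
  for (k in seq_len(nrow(sched))) {
    seg <- kin[kin$time >= sched$t_start[k] & kin$time < sched$t_reset[k], ]
    i_min <- which.min(seg$gap)
    expect_true(all(diff(seg$gap[1:i_min]) <= 1e-9))
    expect_true(all(diff(seg$gap[i_min:nrow(seg)]) >= -1e-9))
    expect_lt(abs(min(seg$gap) - cfg$min_gap), tol + 1e-3)
  }

  # TTC defined only while closing, and equals gap / closing speed there
  closing <- kin$ego_speed > kin$lead_speed
  expect_true(all(is.na(kin$ttc[!closing])))
  expect_equal(kin$ttc[closing],
               kin$gap[closing] / (kin$ego_speed - kin$lead_speed)[closing])
})

test_that("degenerate and infeasible scenarios are handled", {
  kin <- simulate_scenario(scenario_config(ego_speed = 80, lead_speed = 80))
  expect_true(all(kin$gap == 100))
  expect_equal(nrow(attr(kin, "approaches")), 0L)
  expect_error(scenario_config(min_gap = 10, brake_onset_gap = 9),
               "infeasible")
  expect_error(scenario_config(ego_speed = 70, lead_speed = 80),
               "infeasible")
})

test_that("handset press episodes follow the configured behaviour", {
  kin <- simulate_scenario()
  set.seed(31)
  none <- simulate_handset(kin, response_config(press_probability = 0))
  expect_true(all(none$data$value == 0))
  expect_equal(nrow(attr(none, "episodes")), 0L)

  all3 <- simulate_handset(kin, response_config(press_probability = 1))
  expect_equal(nrow(attr(all3, "episodes")), 3L)
  expect_true(all(attr(all3, "episodes")$peak > 0 &
                    attr(all3, "episodes")$peak <= 1))
  expect_true(all(all3$data$value >= 0 & all3$data$value <= 1))

  # pressed share over the study cohort (900 approaches) ~ 208/240,
  # within binomial sampling error; durations match the log-normal law
  eps <- lapply(study_cohort(), function(s)
    attr(s$channels$handset, "episodes"))
  n_ap <- 3L * length(study_cohort())
  n_ep <- sum(vapply(eps, nrow, 0L))
  durs <- unlist(lapply(eps, function(e) e$duration))
  p <- 208 / 240
  expect_lt(abs(n_ep / n_ap - p), 3 * sqrt(p * (1 - p) / n_ap))
  expect_lt(abs(mean(durs) - 8.10), 3 * 5.52 / sqrt(length(durs)))
  expect_lt(abs(sd(durs) - 5.52), 3 * 5.52 / sqrt(2 * length(durs)))
  expect_true(all(durs > 0.5))
})

test_that("identical seed and config reproduce a session bit-identically", {
  a <- simulate_session(scenario_config(trip_duration = 40,
                                        approaches_per_trip = 1),
                        response_config(seed = 77))
  b <- simulate_session(scenario_config(trip_duration = 40,
                                        approaches_per_trip = 1),
                        response_config(seed = 77))
  for (nm in names(a$channels))
    expect_identical(a$channels[[nm]]$data, b$channels[[nm]]$data)
  expect_identical(a$events$blinks$data, b$events$blinks$data)
})

test_that("generated blink statistics match the configured phase rates", {
  counts <- c(0, 0, 0); times <- c(0, 0, 0)
  for (s in study_cohort()[1:120]) {
    ep <- attr(s$channels$handset, "episodes")
    on <- s$events$blinks$data$onset_s
    for (i in seq_len(nrow(ep))) {
      counts[1] <- counts[1] + sum(on >= ep$onset[i] - 10 & on < ep$onset[i])
      times[1] <- times[1] + 10
      counts[2] <- counts[2] + sum(on >= ep$onset[i] & on < ep$offset[i])
      times[2] <- times[2] + ep$duration[i]
      counts[3] <- counts[3] + sum(on >= ep$offset[i] & on < ep$offset[i] + 10)
      times[3] <- times[3] + 10
    }
  }
  expect_gt(sum(counts > 0), 2)
  rates <- counts / times
  expected <- c(0.25, 0.17, 0.37)
  se <- sqrt(expected / times)          # Poisson-count standard error
  expect_true(all(abs(rates - expected) < 3 * se))
})

test_that("session serialisation round-trips exactly", {
  s <- small_session(seed = 13L)
  dir <- file.path(tempdir(), "rt_session")
  write_session(dir, s)
  back <- read_session(dir)
  expect_setequal(names(back$channels), names(s$channels))
  for (nm in names(s$channels))
    expect_identical(back$channels[[nm]]$data, s$channels[[nm]]$data)
  expect_identical(back$events$blinks$data, s$events$blinks$data)

  # the manifest records the study's multi-rate sensor inventory
  rates <- vapply(back$manifest$channels, function(e) as.numeric(e$rate), 0)
  names(rates) <- vapply(back$manifest$channels, function(e) e$name, "")
  expect_equal(unname(rates["handset"]), 60)
  expect_equal(unname(rates["band_hr"]), 10)
  expect_equal(unname(rates["eye_pupil_left"]), 60)
  expect_equal(unname(rates["mocap_shoulder_z"]), 120)
  expect_equal(unname(rates["pressure_back"]), 10)
  unlink(dir, recursive = TRUE)
})

test_that("a manifest-only session round-trips to an empty recording", {
  dir <- file.path(tempdir(), "empty_session")
  write_session(dir, channels = list(), events = list(),
                manifest = list(participant = "px", session = "s0",
                                seed = 0L))
  back <- read_session(dir)
  expect_length(back$channels, 0L)
  expect_length(back$events, 0L)
  expect_equal(back$manifest$participant, "px")
  unlink(dir, recursive = TRUE)
})
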