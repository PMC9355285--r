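noise_free <- sensor_params(baseline_noise_sd = 0)

test_that("threshold estimation is mean + k * sd and rejects bad k", {
  expect_equal(estimate_threshold(list(mean = 100, sd = 0), k = 5), 100)
  expect_equal(estimate_threshold(list(mean = 100, sd = 2), k = 5), 110)
  expect_error(estimate_threshold(list(mean = 100, sd = 2), k = 0))
  # default-parameter threshold leaves clean touches far above it
  thr <- estimate_threshold(capture_baseline(sensor_params(seed = 1)))
  expect_lt(thr, 100 + 50)
  expect_gt(thr, 100 + 5)
})

test_that("prototype detector counts each resolvable lick exactly once", {
  # flat baseline: nothing
  quiet <- render_continuous(make_train(numeric(0), numeric(0)), noise_free,
                             duration_ms = 5000)
  expect_identical(nrow(detect_prototype(quiet, threshold = 110)), 0L)

  # one 100 ms contact, every poll-grid phase offset in [0, 50)
  tr <- make_train(500, 100)
  sig <- render_continuous(tr, noise_free, duration_ms = 2000)
  for (off in seq(0, 49.5, by = 0.5)) {
    ev <- detect_prototype(sig, threshold = 110, phase_offset_ms = off)
    expect_identical(nrow(ev), 1L)
  }
})

test_that("prototype detector matches the dense brute-force oracle", {
  cfg <- detector_config("prototype")
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    onsets <- sort(runif(n, 0, 4000))
    onsets <- onsets[c(TRUE, diff(onsets) >= 65)] # honour the refractory floor
    contacts <- runif(length(onsets), 20, 120)
    contacts <- pmin(contacts, c(diff(onsets) * 0.9, Inf))
    tr <- make_train(onsets, contacts)
    sig <- render_continuous(tr, noise_free, duration_ms = 5000)
    got <- detect_prototype(sig, cfg, threshold = 110)
    polls <- seq(0, 5000, by = 50)
    want <- oracle_detect(onsets, onsets + contacts, 50, 100, 110, polls,
                          refractory = 5)
    expect_equal(got$time_ms, want)
  }
})

test_that("two close licks are counted at most twice and match the oracle", {
  tr <- make_train(c(300, 370), c(40, 40))
  sig <- render_continuous(tr, noise_free, duration_ms = 1000)
  got <- detect_prototype(sig, threshold = 110)
  polls <- seq(0, 1000, by = 50)
  want <- oracle_detect(c(300, 370), c(340, 410), 50, 100, 110, polls,
                        refractory = 5)
  expect_lte(nrow(got), 2L)
  expect_equal(got$time_ms, want)
})

test_that("prototype recall is 1 in the guaranteed-resolvable regime", {
  # contacts >= poll period and ILIs >= 2x poll period, zero noise:
  # exhaustive over poll-grid phase offsets
  onsets <- c(0, 150, 400, 900, 1100)
  contacts <- rep(55, 5)
  tr <- make_train(onsets, contacts)
  sig <- render_continuous(tr, noise_free, duration_ms = 1500)
  for (off in seq(0, 49, by = 1)) {
    ev <- detect_prototype(sig, threshold = 110, phase_offset_ms = off)
    cm <- match_events(ev, tr, tolerance_ms = 60)
    expect_equal(recall(cm), 1.0)
  }
})

test_that("multiplexer frames carry 16 channels at the sequential scan offsets", {
  expect_equal(round(per_channel_rate(60), 2), 16.67)

  pt <- generate_pulse_trains(pulse_protocol(1, 5, n_pulses = 10))
  frames <- multiplex(pt, frame_period_ms = 60)
  expect_identical(nrow(frames) %% 16L, 0L)
  first <- frames[frames$frame == 1L, ]
  expect_identical(nrow(first), 16L)
  # channel 16 (cage 8 bottle B) read 56.25 ms after channel 1 (cage 1 A)
  expect_equal(
    first$read_time_ms[first$cage_id == 8 & first$bottle_id == "B"] -
      first$read_time_ms[first$cage_id == 1 & first$bottle_id == "A"],
    15 * 60 / 16
  )
})

test_that("edge-mode wireless detection catches every 5 Hz pulse", {
  # 200 ms period, 100 ms high: every high phase contains a 60 ms read and
  # is separated by a low read, so exactly one count per pulse
  pt <- generate_pulse_trains(pulse_protocol(1, 5, n_pulses = 300))
  frames <- multiplex(pt, frame_period_ms = 60)
  ev <- detect_wireless(frames, threshold = 0.5, mode = "edge")
  expect_identical(nrow(ev), 300L)
  expect_true(all(ev$cage_id == 1L & ev$bottle_id == "A"))

  # all-baseline frames: zero events anywhere
  quiet <- multiplex(make_train(numeric(0), numeric(0)), duration_ms = 3000)
  expect_identical(nrow(detect_wireless(quiet, threshold = 0.5)), 0L)
})

test_that("latched wireless acquisition conserves events when nothing is missed", {
  pt <- generate_pulse_trains(pulse_protocol(3, 10, n_pulses = 400,
                                             active_cages = 2))
  frames <- multiplex(pt, frame_period_ms = 60)
  ev <- detect_wireless(frames, mode = "latched", miss_prob = 0)
  counts <- dplyr::count(ev, cage_id, bottle_id)
  expect_identical(nrow(counts), 4L)
  expect_true(all(counts$n == 400L))
})

test_that("detection never over-counts with zero noise and no confusers", {
  for (s in 1:5) {
    tr <- generate_lick_train(lick_gen_params(session_duration = 60, seed = s))
    sig <- render_continuous(tr, noise_free, duration_ms = 60000)
    ev <- detect_prototype(sig, threshold = 110)
    expect_lte(nrow(ev), nrow(tr))
  }
})
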