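test_that("identity and empty detections produce the obvious confusions", {
  truth <- make_train(c(0, 200, 400, 600), rep(30, 4))
  identical_det <- make_events(truth$onset_ms)
  cm <- match_events(identical_det, truth, tolerance_ms = 10)
  expect_identical(c(cm$tp, cm$fp, cm$fn), c(4L, 0L, 0L))

  cm0 <- match_events(make_events(numeric(0)), truth)
  expect_identical(c(cm0$tp, cm0$fp, cm0$fn), c(0L, 4L - 4L, 4L))
  expect_error(precision(cm0))
  expect_equal(recall(cm0), 0)
})

test_that("greedy matching equals the exhaustive optimal oracle on random instances", {
  for (s in 1:60) {
    inst <- random_match_instance(n_truth = sample(3:6, 1), tolerance = 60,
                                  seed = 1000 + s)
    truth <- make_train(inst$truth_onsets, inst$truth_contacts)
    cm <- match_events(make_events(inst$detected), truth, tolerance_ms = 60)
    want_tp <- oracle_optimal_tp(inst$detected, inst$truth_onsets,
                                 inst$truth_contacts, tol = 60)
    expect_identical(cm$tp, want_tp)
    expect_identical(cm$tp + cm$fn, length(inst$truth_onsets))
    expect_identical(cm$tp + cm$fp, length(inst$detected))
  }
})

test_that("a spurious detection among correct ones is scored 4/1/1", {
  truth <- make_train(c(0, 300, 600, 900, 1200), rep(30, 5))
  det <- make_events(c(5, 310, 2000, 610, 1210)) # one miss, one spurious
  cm <- match_events(det, truth, tolerance_ms = 60)
  expect_identical(c(cm$tp, cm$fp, cm$fn), c(4L, 1L, 1L))
  expect_equal(precision(cm), 0.8)
  expect_equal(recall(cm), 0.8)
})

test_that("precision and recall follow their defining ratios", {
  expect_equal(precision(list(tp = 91, fp = 9, fn = 0)), 0.91)
  expect_equal(recall(list(tp = 90, fp = 0, fn = 9)), 90 / 99)
  expect_equal(precision(list(tp = 10, fp = 0, fn = 0)), 1)
  expect_equal(recall(list(tp = 0, fp = 0, fn = 7)), 0)
  expect_error(precision(list(tp = 0, fp = 0, fn = 3)))
  expect_error(recall(list(tp = 0, fp = 2, fn = 0)))
})

test_that("the protocol's event-level acquisition equals the dense frame chain", {
  # same counts and timestamps from multiplex() + detect_wireless() and
  # from the grid runner's internal path, on a lossless reduced protocol
  for (phase in 1:3) {
    proto <- pulse_protocol(phase, 10, n_pulses = 120, active_cages = 2)
    pt <- generate_pulse_trains(proto)
    frames <- multiplex(pt, frame_period_ms = 60)
    dense <- detect_wireless(frames, mode = "latched", miss_prob = 0)
    grid <- run_insilico_protocol(phases = phase, frequencies_hz = 10,
                                  cages = 2, replicates = 1, n_pulses = 120,
                                  miss_prob = 0,
                                  loss = loss_model(loss_prob = 0), seed = 1)
    for (out_row in seq_len(nrow(grid))) {
      expect_identical(
        grid$central_detected[out_row],
        sum(dense$bottle_id == grid$output[out_row])
      )
    }
  }
})

test_that("a lossless chain yields exactly zero reading and transmission error", {
  rep0 <- run_insilico_protocol(phases = 1:3, frequencies_hz = c(5, 10),
                                cages = c(1, 4), replicates = 1,
                                n_pulses = 300, miss_prob = 0,
                                loss = loss_model(loss_prob = 0), seed = 5)
  expect_true(all(rep0$reading_error_pct == 0))
  expect_true(all(rep0$transmission_error_pct == 0))
  expect_true(all(rep0$emitted == rep0$central_detected))
  expect_true(all(rep0$received == rep0$central_detected))
})

test_that("grid cells satisfy conservation and phase structure", {
  rep1 <- run_insilico_protocol(cages = c(1, 8), replicates = 2,
                                n_pulses = 2000, seed = 17)
  # pulsed outputs per phase: 1 -> A, 2 -> B, 3 -> both
  expect_true(all(rep1$output[rep1$phase == 1] == "A"))
  expect_true(all(rep1$output[rep1$phase == 2] == "B"))
  expect_setequal(unique(rep1$output[rep1$phase == 3]), c("A", "B"))
  # emitted = n_pulses x active cages, always
  expect_true(all(rep1$emitted == 2000 * rep1$active_cages))
  # misses and drops only remove events
  expect_true(all(rep1$central_detected <= rep1$emitted))
  expect_true(all(rep1$received <= rep1$central_detected))
  # single-cell reproducibility from its recorded seed
  cell <- rep1[5, ]
  again <- run_insilico_protocol(
    phases = cell$phase, frequencies_hz = cell$frequency_hz,
    cages = cell$active_cages, replicates = 1, n_pulses = 2000,
    seed = cell$cell_seed - 1
  )
  again <- again[again$output == cell$output, ]
  expect_identical(again$central_detected, cell$central_detected)
  expect_identical(again$received, cell$received)
})

test_that("reading error in a default cell stays within its binomial band", {
  # miss_prob 5e-4 over 12000 pulses: error in [0, 0.2]% across seeds
  cells <- run_insilico_protocol(phases = 1, frequencies_hz = 5, cages = 1,
                                 replicates = 8, n_pulses = 12000, seed = 23)
  expect_true(all(cells$reading_error_pct >= 0))
  expect_true(all(cells$reading_error_pct <= 0.2))
})

test_that("reading error does not trend with the number of active cages", {
  # per-pulse miss model: regressing per-cage-count cell means over 50
  # replicates gives a slope CI containing 0
  rep2 <- run_insilico_protocol(phases = 1, frequencies_hz = 5, cages = 1:8,
                                replicates = 50, n_pulses = 2000, seed = 41)
  means <- dplyr::summarise(dplyr::group_by(rep2, active_cages),
                            m = mean(reading_error_pct))
  fit <- lm(m ~ active_cages, data = means)
  ci <- confint(fit)["active_cages", ]
  expect_lt(ci[1], 0)
  expect_gt(ci[2], 0)
})

test_that("validation report exports the long-form CSV contract", {
  rep3 <- run_insilico_protocol(cages = 1, replicates = 1, n_pulses = 100,
                                seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_validation_report(rep3, path)
  back <- read.csv(path)
  expect_identical(
    names(back),
    c("phase", "frequency_hz", "active_cages", "output", "replicate",
      "emitted", "central_detected", "received", "reading_error_pct",
      "transmission_error_pct")
  )
  # full default grid cardinality: 3 phases x 2 freqs x 1 cage, phase 3 both outputs
  expect_identical(nrow(back), (1L + 1L + 2L) * 2L)
})
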