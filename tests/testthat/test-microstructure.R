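test_that("interlick intervals are successive differences", {
  expect_equal(interlick_intervals(c(0, 200, 400)), c(200, 200))
  expect_equal(interlick_intervals(c(0, 100, 350)), c(100, 250))
  expect_identical(length(interlick_intervals(42)), 0L)
  multi <- dplyr::bind_rows(make_events(c(0, 100), 1L, "A"),
                            make_events(c(0, 300), 2L, "B"))
  tbl <- interlick_intervals(multi)
  expect_equal(tbl$ili_ms, c(100, 300))
})

test_that("bout segmentation cuts at gaps above the break", {
  one <- segment_bouts(seq(0, by = 120, length.out = 50))
  expect_identical(nrow(one), 1L)
  expect_identical(one$n_licks, 50L)

  two <- segment_bouts(c(0, 120, 240, 5000, 5120), bout_break_ms = 1000)
  expect_identical(two$n_licks, c(3L, 2L))
  expect_equal(two$inter_bout_interval_ms, c(NA, 5000 - 240))
})

test_that("bout partition equals the brute-force gap-partition oracle", {
  for (s in 1:100) {
    tr <- generate_lick_train(lick_gen_params(session_duration = 120, seed = s))
    bouts <- segment_bouts(tr, bout_break_ms = 1000)
    want <- oracle_bout_partition(tr$onset_ms, 1000)
    expect_identical(sum(bouts$n_licks), nrow(tr)) # partition covers all licks
    expect_identical(bouts$n_licks,
                     as.integer(tabulate(want, nbins = length(unique(want)))))
    expect_equal(bouts$onset_ms, tr$onset_ms[!duplicated(want)])
  }
})

test_that("lick frequency recovers uniform rates and reciprocal ILIs", {
  ev <- (0:84) * (10000 / 85)
  lf <- lick_frequency(ev, window_ms = 10000, session_ms = 10000)
  expect_equal(lf$rate_hz, 8.5)

  empty <- lick_frequency(numeric(0), window_ms = 1000, session_ms = 5000)
  expect_true(all(empty$rate_hz == 0))

  wb <- within_bout_frequency(seq(0, by = 125, length.out = 20))
  expect_equal(wb$within_bout_rate_hz, 8)
})

test_that("preference index is the A fraction", {
  expect_equal(preference_index(300, 100), 0.75)
  expect_equal(preference_index(0, 10), 0)
  expect_equal(preference_index(make_events(1:50 * 100),
                                make_events(1:50 * 100, bottle = "B")), 0.5)
  expect_error(preference_index(0, 0))
})

test_that("time-binned counts conserve licks and tag the light phase", {
  ev <- c(1000, 2000, 3000, 7.5 * 3600000) # three early licks, one late
  tb <- time_binned_counts(ev, bin_minutes = 60, session_start_clock = "17:00",
                           session_minutes = 960)
  expect_identical(nrow(tb), 16L)
  expect_identical(sum(tb$n_licks), length(ev))
  # session starts 2 h before lights-off: first two bins light, rest dark
  # until lights-on at 07:00 (bin 15)
  expect_identical(tb$phase_of_day[1:2], c("light", "light"))
  expect_identical(tb$phase_of_day[3:14], rep("dark", 12))
  expect_identical(tb$phase_of_day[15:16], c("light", "light"))
  expect_identical(tb$n_licks[1], 3L)
})

test_that("intake correlation is exact for proportional data and rank-invariant", {
  sessions <- tibble::tibble(
    weight_before = 100,
    weight_after = 100 - (1:12) * 0.25,
    total_licks = (1:12) * 200
  )
  # exactly proportional data: lm warns about the perfect fit, rho is 1
  res <- suppressWarnings(intake_correlation(sessions))
  expect_equal(res$spearman_rho, 1.0)
  expect_equal(res$r_squared, 1.0)

  # invariance under strictly monotone transforms of either variable
  set.seed(9)
  for (i in 1:10) {
    x <- runif(15, 1, 5)
    y <- runif(15, 100, 5000)
    base <- intake_correlation(tibble::tibble(
      weight_before = 100, weight_after = 100 - x, total_licks = y))
    warped <- intake_correlation(tibble::tibble(
      weight_before = 100, weight_after = 100 - exp(x), total_licks = y^3))
    expect_equal(base$spearman_rho, warped$spearman_rho)
  }

  expect_error(intake_correlation(tibble::tibble(
    weight_before = 100, weight_after = 99, total_licks = 1:5)))
})

test_that("shuffled intake decorrelates from licks", {
  # licks independent of grams: |rho| < 0.3 in at least 95% of seeds;
  # the observed fraction is allowed its two-SE Monte Carlo error
  n_seeds <- 300
  ok <- vapply(seq_len(n_seeds), function(s) {
    set.seed(s)
    g <- runif(48, 0.5, 6)
    licks <- sample(round(g * 2000)) # shuffled: same marginals, no pairing
    res <- intake_correlation(tibble::tibble(
      weight_before = 100, weight_after = 100 - g, total_licks = licks))
    abs(res$spearman_rho) < 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.95 - 2 * sqrt(0.95 * 0.05 / n_seeds))
})

test_that("simulated intake sessions reproduce a strong lick/intake correlation", {
  # proportional volume with no noise: rho exactly 1
  clean <- simulate_intake_sessions(
    n_animals = 8, n_sessions = 1,
    lick_params = lick_gen_params(session_duration = 1800,
                                  inter_bout_interval_mean = 60),
    weighing_sd_g = 0, animal_volume_sdlog = 0, seed = 4)
  water <- clean[clean$liquid == "water", ] # one liquid: grams strictly
  res_clean <- intake_correlation(water)    # proportional to licks
  expect_equal(res_clean$spearman_rho, 1.0)

  # zero volume per lick: no weight change beyond (zero) noise
  none <- simulate_intake_sessions(
    n_animals = 3, n_sessions = 1,
    lick_params = lick_gen_params(session_duration = 600,
                                  inter_bout_interval_mean = 60),
    ul_per_lick = 0, weighing_sd_g = 0, seed = 4)
  expect_true(all(none$weight_before - none$weight_after == 0))

  # determinism
  a <- simulate_intake_sessions(n_animals = 2, n_sessions = 1,
                                lick_params = lick_gen_params(
                                  session_duration = 300), seed = 12)
  b <- simulate_intake_sessions(n_animals = 2, n_sessions = 1,
                                lick_params = lick_gen_params(
                                  session_duration = 300), seed = 12)
  expect_identical(a, b)
})

test_that("the default noisy intake generator reaches rho > 0.8 at n = 96", {
  sessions <- simulate_intake_sessions(
    n_animals = 24, n_sessions = 2,
    lick_params = lick_gen_params(session_duration = 2 * 3600,
                                  inter_bout_interval_mean = 75),
    seed = 8)
  expect_identical(nrow(sessions), 96L)
  res <- intake_correlation(sessions, by_liquid = TRUE)
  pooled <- res[res$liquid == "all", ]
  expect_gt(pooled$spearman_rho, 0.8)
  expect_lt(pooled$p_value, 1e-4)
  expect_setequal(res$liquid, c("all", "water", "ethanol"))
})

test_that("microstructure summary aggregates per channel with preference", {
  ev <- dplyr::bind_rows(
    make_events(c(0, 120, 240, 5000, 5120, 5240), 1L, "A"),
    make_events(c(0, 130, 260), 1L, "B")
  )
  ms <- microstructure_summary(ev)
  expect_identical(nrow(ms), 2L)
  a <- ms[ms$bottle_id == "A", ]
  expect_identical(a$total_licks, 6L)
  expect_identical(a$n_bouts, 2L)
  expect_equal(a$preference_A, 6 / 9)
})
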