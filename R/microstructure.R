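#' Interlick intervals
#'
#' Successive differences of lick timestamps per channel: `n - 1` ILIs for
#' `n` licks, none for a single or no lick.
#'
#' @param events A `lick_events` tibble or numeric vector of times, ms.
#' @return A tibble `cage_id`, `bottle_id`, `ili_ms` (one row per ILI), or
#'   a numeric vector when a vector was given.
#' @examples
#' interlick_intervals(c(0, 200, 400)) # 200 200
#' @export
interlick_intervals <- function(events) {
  vector_in <- is.numeric(events)
  ev <- as_events_tbl(events)
  out <- ev %>%
    dplyr::group_by(.data$cage_id, .data$bottle_id) %>%
    dplyr::arrange(.data$time_ms, .by_group = TRUE) %>%
    dplyr::reframe(ili_ms = diff(.data$time_ms))
  if (vector_in) out$ili_ms else out
}

#' Segment lick events into bouts
#'
#' A bout is a run of licks separated from other runs by a gap exceeding
#' the bout-break threshold: a new bout starts at any lick whose preceding
#' ILI is greater than `bout_break_ms`. The 1 s default is the common
#' rodent-lickometry convention; the parameter is deliberately prominent
#' because the partition depends on it.
#'
#' @param events A `lick_events` tibble or numeric vector of times, ms.
#' @param bout_break_ms Bout-break threshold, ms, > 0. Default 1000.
#' @return A tibble of class `bout_summary`, one row per bout: `cage_id`,
#'   `bottle_id`, `bout`, `onset_ms`, `offset_ms`, `n_licks`,
#'   `mean_ili_ms`, `sd_ili_ms`, and `inter_bout_interval_ms` (gap from the
#'   previous bout's offset; `NA` for the first bout of a channel).
#' @examples
#' segment_bouts(c(0, 120, 240, 5000, 5120)) # two bouts: 3 licks, 2 licks
#' @export
segment_bouts <- function(events, bout_break_ms = 1000) {
  check_number(bout_break_ms, "bout_break_ms", min = 1e-12)
  ev <- as_events_tbl(events)
  if (nrow(ev) == 0L) {
    out <- tibble::tibble(
      cage_id = integer(0), bottle_id = character(0), bout = integer(0),
      onset_ms = numeric(0), offset_ms = numeric(0), n_licks = integer(0),
      mean_ili_ms = numeric(0), sd_ili_ms = numeric(0),
      inter_bout_interval_ms = numeric(0)
    )
    return(structure(out, class = c("bout_summary", class(out)),
                     bout_break_ms = bout_break_ms))
  }
  out <- ev %>%
    dplyr::group_by(.data$cage_id, .data$bottle_id) %>%
    dplyr::arrange(.data$time_ms, .by_group = TRUE) %>%
    dplyr::mutate(bout = cumsum(c(TRUE, diff(.data$time_ms) > bout_break_ms))) %>%
    dplyr::group_by(.data$cage_id, .data$bottle_id, .data$bout) %>%
    dplyr::summarise(
      onset_ms = min(.data$time_ms),
      offset_ms = max(.data$time_ms),
      n_licks = dplyr::n(),
      mean_ili_ms = if (dplyr::n() > 1L) mean(diff(.data$time_ms)) else NA_real_,
      sd_ili_ms = if (dplyr::n() > 2L) sd(diff(.data$time_ms)) else NA_real_,
      .groups = "drop_last"
    ) %>%
    dplyr::mutate(
      inter_bout_interval_ms = .data$onset_ms - dplyr::lag(.data$offset_ms)
    ) %>%
    dplyr::ungroup()
  structure(out, class = c("bout_summary", class(out)),
            bout_break_ms = bout_break_ms)
}

#' Within-bout lick frequency
#'
#' `1000 / mean(within-bout ILI)` in licks/s, pooling the ILIs of all bouts
#' (ILIs spanning a bout break are excluded). Mouse within-bout rates
#' typically fall between 6 and 9 licks/s.
#'
#' @inheritParams segment_bouts
#' @return A tibble `cage_id`, `bottle_id`, `n_ilis`,
#'   `within_bout_rate_hz`; channels without any within-bout ILI get `NA`.
#' @export
within_bout_frequency <- function(events, bout_break_ms = 1000) {
  ev <- as_events_tbl(events)
  ev %>%
    dplyr::group_by(.data$cage_id, .data$bottle_id) %>%
    dplyr::arrange(.data$time_ms, .by_group = TRUE) %>%
    dplyr::summarise(
      n_ilis = sum(diff(.data$time_ms) <= bout_break_ms),
      within_bout_rate_hz = {
        ili <- diff(.data$time_ms)
        ili <- ili[ili <= bout_break_ms]
        if (length(ili)) 1000 / mean(ili) else NA_real_
      },
      .groups = "drop"
    )
}

#' Lick rate over fixed windows
#'
#' Counts per consecutive fixed window divided by the window duration.
#'
#' @inheritParams segment_bouts
#' @param window_ms Window length, ms, > 0.
#' @param session_ms Session length, ms; defaults to the last event time
#'   (rounded up to a whole window). Zero events give zero rates.
#' @return A tibble `cage_id`, `bottle_id`, `window`, `start_ms`,
#'   `n_licks`, `rate_hz`.
#' @examples
#' lf <- lick_frequency(seq(0, 9900, by = 10000 / 85)[1:85],
#'                      window_ms = 10000, session_ms = 10000)
#' lf$rate_hz # 8.5 licks/s
#' @export
lick_frequency <- function(events, window_ms, session_ms = NULL) {
  check_number(window_ms, "window_ms", min = 1e-12)
  ev <- as_events_tbl(events)
  if (is.null(session_ms)) {
    session_ms <- if (nrow(ev)) {
      ceiling(max(ev$time_ms) / window_ms) * window_ms
    } else {
      window_ms
    }
  }
  n_win <- max(1L, as.integer(ceiling(session_ms / window_ms)))
  chans <- dplyr::distinct(ev[, c("cage_id", "bottle_id")])
  if (nrow(chans) == 0L) chans <- tibble::tibble(cage_id = 1L, bottle_id = "A")
  grid <- tidyr::expand_grid(chans, window = seq_len(n_win))
  counts <- ev %>%
    dplyr::mutate(window = pmin(floor(.data$time_ms / window_ms) + 1L, n_win)) %>%
    dplyr::count(.data$cage_id, .data$bottle_id, .data$window, name = "n_licks")
  grid %>%
    dplyr::left_join(counts, by = c("cage_id", "bottle_id", "window")) %>%
    dplyr::mutate(
      n_licks = dplyr::coalesce(.data$n_licks, 0L),
      start_ms = (.data$window - 1L) * window_ms,
      rate_hz = .data$n_licks / (window_ms / 1000)
    ) %>%
    dplyr::select("cage_id", "bottle_id", "window", "start_ms", "n_licks",
                  "rate_hz")
}

#' Two-bottle preference index
#'
#' Fraction of total licks delivered to bottle A:
#' `licks_A / (licks_A + licks_B)`.
#'
#' @param events_A,events_B Lick events for each bottle — `lick_events`
#'   tibbles, numeric time vectors, or plain counts.
#' @return Preference for A in `[0, 1]`.
#' @examples
#' preference_index(300, 100) # 0.75
#' @export
preference_index <- function(events_A, events_B) {
  count_of <- function(x) {
    if (is.data.frame(x)) nrow(x)
    else if (length(x) == 1L && is.numeric(x) && x >= 0 && x == floor(x)) x
    else length(x)
  }
  a <- count_of(events_A)
  b <- count_of(events_B)
  if (a + b == 0) abort("Preference undefined: no licks on either bottle.")
  a / (a + b)
}

#' Time-binned lick counts with light/dark tagging
#'
#' Histograms licks over the session in fixed bins and tags each bin light
#' or dark from the housing light schedule (default lights on 07:00, 12/12
#' cycle, so dark spans 19:00-07:00). A bin takes the tag of its start
#' instant. The overnight protocol starts sessions 2 h before lights-off
#' (17:00) for 16 h, so with 60-min bins the first two bins are light.
#'
#' @inheritParams segment_bouts
#' @param bin_minutes Bin width, minutes, > 0. Default 60.
#' @param session_start_clock Session start as `"HH:MM"` local time.
#'   Default `"17:00"`.
#' @param session_minutes Session length in minutes. Default 960 (16 h).
#' @param lights_on_clock,lights_off_clock Light-cycle boundaries,
#'   `"HH:MM"`. Defaults `"07:00"` and `"19:00"`.
#' @return A tibble `cage_id`, `bottle_id`, `bin`, `start_min`,
#'   `clock_start_min`, `phase_of_day` (`"light"`/`"dark"`), `n_licks`.
#' @export
time_binned_counts <- function(events, bin_minutes = 60,
                               session_start_clock = "17:00",
                               session_minutes = 960,
                               lights_on_clock = "07:00",
                               lights_off_clock = "19:00") {
  check_number(bin_minutes, "bin_minutes", min = 1e-12)
  check_number(session_minutes, "session_minutes", min = 1e-12)
  ev <- as_events_tbl(events)
  session_start_min <- parse_clock_min(session_start_clock)
  on_min <- parse_clock_min(lights_on_clock)
  off_min <- parse_clock_min(lights_off_clock)

  n_bins <- as.integer(ceiling(session_minutes / bin_minutes))
  chans <- dplyr::distinct(ev[, c("cage_id", "bottle_id")])
  if (nrow(chans) == 0L) chans <- tibble::tibble(cage_id = 1L, bottle_id = "A")
  grid <- tidyr::expand_grid(chans, bin = seq_len(n_bins))
  counts <- ev %>%
    dplyr::filter(.data$time_ms >= 0,
                  .data$time_ms < session_minutes * 60000) %>%
    dplyr::mutate(bin = floor(.data$time_ms / (bin_minutes * 60000)) + 1L) %>%
    dplyr::count(.data$cage_id, .data$bottle_id, .data$bin, name = "n_licks")
  grid %>%
    dplyr::left_join(counts, by = c("cage_id", "bottle_id", "bin")) %>%
    dplyr::mutate(
      n_licks = dplyr::coalesce(.data$n_licks, 0L),
      start_min = (.data$bin - 1) * bin_minutes,
      clock_start_min = (session_start_min + .data$start_min) %% 1440,
      phase_of_day = ifelse(
        is_dark(.data$clock_start_min, on_min, off_min), "dark", "light"
      )
    ) %>%
    dplyr::select("cage_id", "bottle_id", "bin", "start_min",
                  "clock_start_min", "phase_of_day", "n_licks")
}

parse_clock_min <- function(x) {
  if (is.numeric(x)) return(x %% 1440)
  parts <- strsplit(x, ":", fixed = TRUE)[[1]]
  if (length(parts) != 2L) abort("Clock times must be \"HH:MM\".")
  as.numeric(parts[1]) * 60 + as.numeric(parts[2])
}

# dark = [lights_off, lights_on), possibly wrapping midnight
is_dark <- function(clock_min, on_min, off_min) {
  if (off_min > on_min) {
    clock_min >= off_min | clock_min < on_min
  } else {
    clock_min >= off_min & clock_min < on_min
  }
}

#' Correlate lick counts with bottle-weight intake
#'
#' Spearman rank correlation between consumed grams
#' (`weight_before - weight_after`) and total licks, pooled across
#' sessions and optionally split per liquid; a least-squares R-squared is
#' reported descriptively alongside. P-values use the exact permutation
#' distribution for n <= 20 and the large-sample approximation otherwise.
#'
#' @param sessions A tibble of per-session intake records with columns
#'   `weight_before`, `weight_after` (grams), `total_licks`, and `liquid`
#'   when `by_liquid = TRUE` (see [simulate_intake_sessions()]).
#' @param by_liquid Also compute per-liquid correlations. Default `FALSE`.
#' @return A tibble of class `lick_correlation`: `liquid` (`"all"` plus
#'   each liquid when requested), `n`, `spearman_rho`, `p_value`,
#'   `r_squared`.
#' @export
intake_correlation <- function(sessions, by_liquid = FALSE) {
  stopifnot(is.data.frame(sessions))
  need <- c("weight_before", "weight_after", "total_licks")
  if (!all(need %in% names(sessions))) {
    abort(sprintf("`sessions` must have columns %s.", paste(need, collapse = ", ")))
  }
  sessions <- tibble::as_tibble(sessions)
  sessions$intake_g <- sessions$weight_before - sessions$weight_after

  one <- function(df, label) {
    if (nrow(df) < 3L) abort("Correlation needs at least 3 sessions.")
    x <- df$intake_g
    y <- df$total_licks
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
      abort("Correlation undefined: a variable is constant.")
    }
    ct <- suppressWarnings(
      cor.test(x, y, method = "spearman", exact = nrow(df) <= 20)
    )
    fit <- lm(y ~ x)
    tibble::tibble(
      liquid = label, n = nrow(df),
      spearman_rho = unname(ct$estimate),
      p_value = ct$p.value,
      r_squared = summary(fit)$r.squared
    )
  }
  out <- one(sessions, "all")
  if (by_liquid) {
    if (!"liquid" %in% names(sessions)) {
      abort("`by_liquid = TRUE` requires a `liquid` column.")
    }
    per <- lapply(unname(split(sessions, sessions$liquid)), function(df) {
      one(df, df$liquid[1])
    })
    out <- dplyr::bind_rows(c(list(out), per))
  }
  structure(out, class = c("lick_correlation", class(out)), data = sessions)
}

#' @method tidy lick_correlation
#' @export
tidy.lick_correlation <- function(x, ...) {
  tibble::as_tibble(unclass(x)[names(x)])
}

#' Simulate per-session intake records (synthetic in vivo analogue)
#'
#' Generates a synthetic stand-in for an overnight two-bottle drinking
#' data set: for each animal x session x bottle a lick train is generated,
#' and consumed grams are `licks x volume-per-lick x density` plus Gaussian
#' weighing noise. Densities are 1.0 g/mL for water and 0.984 g/mL for 10%
#' v/v ethanol. Animals differ: each animal x bottle receives lognormal
#' multipliers on its drinking propensity (inter-bout interval) and its
#' per-lick volume, so totals vary across the data set the way real mice
#' vary. The device itself does not measure volume; the volume-per-lick
#' conversion is an assumption of the simulator.
#'
#' @param n_animals Number of animals. Default 24.
#' @param n_sessions Sessions per animal. Default 2.
#' @param lick_params A [lick_gen_params()] for one session; the default
#'   emulates a 16 h overnight session with a 10 min mean inter-bout gap.
#' @param ul_per_lick Mean per-lick volume, microliters. Default 1.5.
#' @param weighing_sd_g SD of bottle-weighing noise, grams. Default 0.05.
#' @param animal_ibi_sdlog,animal_volume_sdlog Lognormal SDs of the
#'   per-animal-x-bottle inter-bout-interval and volume multipliers.
#' @param bottle_fill_g Initial bottle weight, grams. Default 100.
#' @param seed Integer seed or `NULL`.
#' @return A tibble of `SessionIntake` records: `animal_id`, `session_id`,
#'   `bottle_id`, `liquid`, `weight_before`, `weight_after`, `total_licks`.
#' @export
simulate_intake_sessions <- function(n_animals = 24,
                                     n_sessions = 2,
                                     lick_params = lick_gen_params(
                                       session_duration = 16 * 3600,
                                       inter_bout_interval_mean = 600
                                     ),
                                     ul_per_lick = 1.5,
                                     weighing_sd_g = 0.05,
                                     animal_ibi_sdlog = 0.4,
                                     animal_volume_sdlog = 0.2,
                                     bottle_fill_g = 100,
                                     seed = NULL) {
  check_number(n_animals, "n_animals", min = 1)
  check_number(n_sessions, "n_sessions", min = 1)
  check_number(ul_per_lick, "ul_per_lick", min = 0)
  check_number(weighing_sd_g, "weighing_sd_g", min = 0)
  stopifnot(inherits(lick_params, "lick_gen_params"))
  local_seed(seed)

  density <- c(water = 1.0, ethanol = 0.984)
  grid <- tidyr::expand_grid(
    animal_id = seq_len(n_animals),
    bottle_id = c("A", "B")
  )
  grid$liquid <- ifelse(grid$bottle_id == "A", "water", "ethanol")
  grid$ibi_mult <- rlnorm(nrow(grid), 0, animal_ibi_sdlog)
  grid$vol_mult <- rlnorm(nrow(grid), 0, animal_volume_sdlog)

  rows <- purrr::pmap(grid, function(animal_id, bottle_id, liquid,
                                     ibi_mult, vol_mult) {
    p <- lick_params
    p$inter_bout_interval_mean <- p$inter_bout_interval_mean * ibi_mult
    p$seed <- NULL # draws come from the surrounding seeded stream
    purrr::map(seq_len(n_sessions), function(s) {
      train <- generate_lick_train(p, cage_id = ((animal_id - 1L) %% 8L) + 1L,
                                   bottle_id = bottle_id)
      licks <- nrow(train)
      grams <- licks * ul_per_lick / 1000 * vol_mult * density[[liquid]]
      tibble::tibble(
        animal_id = animal_id, session_id = s, bottle_id = bottle_id,
        liquid = liquid,
        weight_before = bottle_fill_g,
        weight_after = bottle_fill_g - grams + rnorm(1, 0, weighing_sd_g),
        total_licks = licks
      )
    }) %>% dplyr::bind_rows()
  })
  dplyr::bind_rows(rows)
}

#' Per-channel microstructure report
#'
#' One row per channel: totals, bout count, mean licks per bout, mean
#' within-bout ILI, within-bout frequency, and the cage's two-bottle
#' preference for A.
#'
#' @inheritParams segment_bouts
#' @return A tibble, one row per (cage, bottle).
#' @export
microstructure_summary <- function(events, bout_break_ms = 1000) {
  ev <- as_events_tbl(events)
  bouts <- segment_bouts(ev, bout_break_ms)
  wbf <- within_bout_frequency(ev, bout_break_ms)
  per_chan <- bouts %>%
    dplyr::group_by(.data$cage_id, .data$bottle_id) %>%
    dplyr::summarise(
      total_licks = sum(.data$n_licks),
      n_bouts = dplyr::n(),
      mean_licks_per_bout = mean(.data$n_licks),
      mean_within_bout_ili_ms = stats::weighted.mean(
        .data$mean_ili_ms, .data$n_licks - 1L, na.rm = TRUE
      ),
      .groups = "drop"
    ) %>%
    dplyr::left_join(wbf, by = c("cage_id", "bottle_id"))
  pref <- per_chan %>%
    dplyr::select("cage_id", "bottle_id", "total_licks") %>%
    tidyr::pivot_wider(names_from = "bottle_id", values_from = "total_licks",
                       values_fill = 0L)
  a <- if ("A" %in% names(pref)) pref$A else rep(0L, nrow(pref))
  b <- if ("B" %in% names(pref)) pref$B else rep(0L, nrow(pref))
  pref$preference_A <- ifelse(a + b > 0, a / (a + b), NA_real_)
  per_chan %>%
    dplyr::left_join(pref[, c("cage_id", "preference_A")], by = "cage_id")
}
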