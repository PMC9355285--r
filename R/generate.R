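#' Parameters for the synthetic mouse lick-train generator
#'
#' Bundles the knobs of the alternating-renewal lick model: drinking happens
#' in bouts; within a bout, interlick intervals (ILIs) follow a gamma
#' distribution (shape `ili_shape`) truncated below at the physiological
#' refractory floor; bout lengths (licks per bout) are geometric; gaps
#' between bouts are exponential.
#'
#' The nominal within-bout rate is the *realized* rate: the pre-truncation
#' gamma mean is calibrated at construction time so that the truncated
#' distribution's mean ILI equals `1000 / mean_within_bout_rate` ms exactly.
#' C57Bl/6 mice lick at about 8.5 licks/s within bouts, with reported means
#' ranging between 6 and 9 Hz; those two figures are the defaults for
#' `mean_within_bout_rate` and `within_bout_rate_range`.
#'
#' @param mean_within_bout_rate Target mean within-bout licking rate,
#'   licks per second. Default 8.5.
#' @param within_bout_rate_range Plausibility band for the within-bout rate,
#'   licks per second; used by validation checks, not by the sampler.
#' @param licks_per_bout_mean Mean number of licks per bout (geometric on
#'   1, 2, ...). Default 30.
#' @param inter_bout_interval_mean Mean gap between the end of one bout and
#'   the start of the next, seconds (exponential). Default 30.
#' @param session_duration Session length, seconds. Default 3600.
#' @param contact_duration_mean,contact_duration_sd Mean and SD of
#'   tongue-contact duration, ms (lognormal). Defaults 40 and 10.
#' @param refractory_ms Refractory floor: no ILI may be shorter than this,
#'   ms. Default 60 (caps the instantaneous rate below 16.7 licks/s).
#' @param ili_shape Gamma shape of the within-bout ILI distribution.
#'   Default 10.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return An object of class `lick_gen_params` (a named list).
#' @examples
#' p <- lick_gen_params(session_duration = 120, seed = 1)
#' train <- generate_lick_train(p)
#' @export
lick_gen_params <- function(mean_within_bout_rate = 8.5,
                            within_bout_rate_range = c(6, 9),
                            licks_per_bout_mean = 30,
                            inter_bout_interval_mean = 30,
                            session_duration = 3600,
                            contact_duration_mean = 40,
                            contact_duration_sd = 10,
                            refractory_ms = 60,
                            ili_shape = 10,
                            seed = NULL) {
  check_number(mean_within_bout_rate, "mean_within_bout_rate", min = 1e-6)
  check_number(licks_per_bout_mean, "licks_per_bout_mean", min = 1)
  check_number(inter_bout_interval_mean, "inter_bout_interval_mean", min = 1e-6)
  check_number(session_duration, "session_duration", min = 0)
  check_number(contact_duration_mean, "contact_duration_mean", min = 1e-6)
  check_number(contact_duration_sd, "contact_duration_sd", min = 0)
  check_number(refractory_ms, "refractory_ms", min = 0)
  check_number(ili_shape, "ili_shape", min = 1e-6)
  if (length(within_bout_rate_range) != 2L ||
      within_bout_rate_range[1] > within_bout_rate_range[2]) {
    abort("`within_bout_rate_range` must be an increasing pair of rates.")
  }
  target_ili <- 1000 / mean_within_bout_rate
  if (target_ili <= refractory_ms) {
    abort("`mean_within_bout_rate` implies a mean ILI at or below the refractory floor.")
  }
  p <- list(
    mean_within_bout_rate = mean_within_bout_rate,
    within_bout_rate_range = as.numeric(within_bout_rate_range),
    licks_per_bout_mean = licks_per_bout_mean,
    inter_bout_interval_mean = inter_bout_interval_mean,
    session_duration = session_duration,
    contact_duration_mean = contact_duration_mean,
    contact_duration_sd = contact_duration_sd,
    refractory_ms = refractory_ms,
    ili_shape = ili_shape,
    ili_raw_mean = calibrate_trunc_gamma_mean(target_ili, ili_shape, refractory_ms),
    seed = seed
  )
  structure(p, class = "lick_gen_params")
}

# Find the pre-truncation gamma mean m (shape fixed) such that
# E[X | X > floor] = target. Monotone in m, so uniroot on [eps, target].
calibrate_trunc_gamma_mean <- function(target, shape, floor_ms) {
  if (floor_ms <= 0) {
    return(target)
  }
  trunc_mean <- function(m) {
    rate <- shape / m
    p_keep <- pgamma(floor_ms, shape, rate, lower.tail = FALSE)
    # E[X 1{X>floor}] via the gamma identity E[X 1{X>a}] = m * P(G(shape+1) > a)
    m * pgamma(floor_ms, shape + 1, rate, lower.tail = FALSE) / p_keep
  }
  if (trunc_mean(target) - target < 1e-9) {
    return(target)
  }
  # walk the lower bracket down until the truncated mean drops below target
  # (tiny m makes the kept tail mass vanish numerically, so don't start at 0)
  lo <- target * 0.9
  repeat {
    v <- trunc_mean(lo)
    if (is.finite(v) && v < target) break
    lo <- lo * 0.9
    if (lo < floor_ms * 1e-3) {
      abort("Cannot calibrate the truncated ILI mean for these parameters.")
    }
  }
  uniroot(function(m) trunc_mean(m) - target, lower = lo, upper = target,
          tol = 1e-10)$root
}

# Inverse-CDF sampler for gamma truncated below at `floor_ms`.
rtrunc_gamma <- function(n, shape, mean, floor_ms) {
  if (n == 0L) return(numeric(0))
  rate <- shape / mean
  p0 <- pgamma(floor_ms, shape, rate)
  qgamma(p0 + runif(n) * (1 - p0), shape, rate)
}

#' Generate a synthetic ground-truth lick train
#'
#' Simulates one channel (cage, bottle) of licking as an alternating-renewal
#' process: exponential inter-bout gaps, geometric bout lengths, truncated
#' gamma within-bout ILIs, lognormal contact durations clipped below the
#' following ILI so contacts never overlap.
#'
#' @param params A [lick_gen_params()] object.
#' @param cage_id Cage number, 1-8. Default 1.
#' @param bottle_id Bottle, `"A"` or `"B"`. Default `"A"`.
#' @return A tibble of class `lick_train` with columns `cage_id`,
#'   `bottle_id`, `onset_ms` (strictly increasing lick-onset times, ms from
#'   session start) and `contact_ms` (tongue-contact durations, ms).
#' @examples
#' train <- generate_lick_train(lick_gen_params(session_duration = 60, seed = 42))
#' range(diff(train$onset_ms)) # all ILIs above the 60 ms refractory floor
#' @export
generate_lick_train <- function(params, cage_id = 1L, bottle_id = "A") {
  stopifnot(inherits(params, "lick_gen_params"))
  if (!bottle_id %in% c("A", "B")) abort("`bottle_id` must be \"A\" or \"B\".")
  check_number(cage_id, "cage_id", min = 1, max = 8)
  local_seed(params$seed)

  session_ms <- params$session_duration * 1000
  onsets <- vector("list", 64L)
  n_bouts <- 0L
  t <- 0
  while (TRUE) {
    t_start <- t + rexp(1, rate = 1 / (params$inter_bout_interval_mean * 1000))
    if (t_start > session_ms) break
    n_licks <- 1L + rgeom(1, prob = 1 / params$licks_per_bout_mean)
    ilis <- rtrunc_gamma(n_licks - 1L, params$ili_shape,
                         params$ili_raw_mean, params$refractory_ms)
    bout <- t_start + cumsum(c(0, ilis))
    bout <- bout[bout <= session_ms]
    if (length(bout) == 0L) break
    n_bouts <- n_bouts + 1L
    if (n_bouts > length(onsets)) onsets <- c(onsets, vector("list", length(onsets)))
    onsets[[n_bouts]] <- bout
    t <- bout[length(bout)]
  }
  onset_ms <- unlist(onsets[seq_len(n_bouts)], use.names = FALSE)
  if (is.null(onset_ms)) onset_ms <- numeric(0)

  n <- length(onset_ms)
  contact_ms <- draw_contacts(n, params$contact_duration_mean,
                              params$contact_duration_sd)
  if (n > 1L) {
    gap_after <- c(diff(onset_ms), Inf)
    contact_ms <- pmin(contact_ms, 0.9 * gap_after)
  }
  new_lick_train(cage_id, bottle_id, onset_ms, contact_ms,
                 refractory_ms = params$refractory_ms)
}

draw_contacts <- function(n, mean, sd) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) return(rep(mean, n))
  sdlog <- sqrt(log1p((sd / mean)^2))
  meanlog <- log(mean) - sdlog^2 / 2
  rlnorm(n, meanlog, sdlog)
}

new_lick_train <- function(cage_id, bottle_id, onset_ms, contact_ms,
                           refractory_ms = NA_real_) {
  out <- tibble::tibble(
    cage_id = as.integer(cage_id),
    bottle_id = as.character(bottle_id),
    onset_ms = as.numeric(onset_ms),
    contact_ms = as.numeric(contact_ms)
  )
  structure(out, class = c("lick_train", class(out)),
            refractory_ms = refractory_ms)
}

#' Describe an emulated pulse protocol
#'
#' One cell of the three-phase in-silico validation design: square digital
#' pulses standing in for licks are driven onto bottle outputs of the first
#' `active_cages` cages. Phase 1 pulses only bottle A, Phase 2 only bottle
#' B, Phase 3 both bottles alternately (B offset by half a period from A).
#'
#' @param phase Validation phase, 1, 2 or 3.
#' @param frequency_hz Pulse frequency in Hz; the validation design uses 5
#'   (typical licking, ILI 200 ms) and 10 (extreme, ILI 100 ms).
#' @param n_pulses Number of high-level pulses emitted per pulsed output.
#'   Default 12000.
#' @param active_cages Number of cages simultaneously receiving pulses,
#'   1-8.
#' @param duty High-level fraction of each period. Default 0.5.
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(phase, frequency_hz, n_pulses = 12000L,
                           active_cages = 1L, duty = 0.5) {
  check_number(phase, "phase", min = 1, max = 3)
  check_number(frequency_hz, "frequency_hz", min = 1e-9)
  check_number(n_pulses, "n_pulses", min = 1)
  check_number(active_cages, "active_cages", min = 1, max = 8)
  check_number(duty, "duty", min = 1e-9, max = 1)
  structure(
    list(phase = as.integer(phase), frequency_hz = frequency_hz,
         n_pulses = as.integer(n_pulses), active_cages = as.integer(active_cages),
         duty = duty),
    class = "pulse_protocol"
  )
}

#' Generate deterministic emulated pulse trains for one protocol cell
#'
#' Each pulsed output carries exactly `n_pulses` onsets at the exact period
#' `1000 / frequency_hz` ms; the high level lasts `duty` of a period, so 5 Hz
#' pulses are high for 100 ms and 10 Hz pulses for 50 ms at the default 50%
#' duty. In Phase 3 the B train of each cage is offset half a period after
#' the A train.
#'
#' @param protocol A [pulse_protocol()] object.
#' @return A `lick_train` tibble holding every pulsed channel; channels not
#'   pulsed in the phase carry no rows. `contact_ms` is the high duration.
#' @examples
#' trains <- generate_pulse_trains(pulse_protocol(1, 5, n_pulses = 10))
#' unique(diff(trains$onset_ms)) # exactly 200 ms
#' @export
generate_pulse_trains <- function(protocol) {
  stopifnot(inherits(protocol, "pulse_protocol"))
  period <- 1000 / protocol$frequency_hz
  high <- protocol$duty * period
  onsets <- (seq_len(protocol$n_pulses) - 1) * period
  cages <- seq_len(protocol$active_cages)

  one <- function(cage, bottle, offset) {
    new_lick_train(cage, bottle, onsets + offset, rep(high, length(onsets)))
  }
  parts <- switch(as.character(protocol$phase),
    "1" = lapply(cages, one, bottle = "A", offset = 0),
    "2" = lapply(cages, one, bottle = "B", offset = 0),
    "3" = c(lapply(cages, one, bottle = "A", offset = 0),
            lapply(cages, one, bottle = "B", offset = period / 2))
  )
  out <- dplyr::bind_rows(parts)
  out <- dplyr::arrange(out, .data$cage_id, .data$bottle_id, .data$onset_ms)
  class(out) <- unique(c("lick_train", class(out)))
  attr(out, "protocol") <- protocol
  out
}

#' Write / read ground-truth lick trains as CSV
#'
#' The ground-truth dialect is `cage_id,bottle_id,onset_ms,contact_ms`, one
#' row per lick, sorted by onset within channel.
#'
#' @param train A `lick_train` tibble.
#' @param path File path.
#' @return `write_lick_train()` returns `path` invisibly;
#'   `read_lick_train()` returns a `lick_train` tibble.
#' @export
write_lick_train <- function(train, path) {
  stopifnot(is.data.frame(train))
  out <- dplyr::arrange(tibble::as_tibble(train),
                        .data$cage_id, .data$bottle_id, .data$onset_ms)
  write.csv(out[, c("cage_id", "bottle_id", "onset_ms", "contact_ms")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_lick_train
#' @export
read_lick_train <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cage_id", "bottle_id", "onset_ms", "contact_ms")
  if (!all(need %in% names(df))) {
    abort(sprintf("Ground-truth file must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  new_lick_train(df$cage_id, df$bottle_id, df$onset_ms, df$contact_ms)
}
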