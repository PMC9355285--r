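#' Detector configuration
#'
#' Two acquisition schemes are modeled. The *prototype* polls one channel
#' every 50 ms and applies a 5 ms refractory delay after each counted lick
#' so duplicates are not counted. The *wireless* system scans 16 channels
#' (8 cages x 2 bottles) through a multiplexer once per 60 ms frame, giving
#' each channel 16.67 samples/s, and applies a threshold established from
#' the baseline capture.
#'
#' @param mode `"prototype"` or `"wireless"`.
#' @param poll_period_ms Prototype polling period, ms. Default 50.
#' @param refractory_ms Prototype post-event refractory delay, ms.
#'   Default 5.
#' @param frame_period_ms Wireless frame period, ms. Default 60.
#' @param threshold Detection threshold, a.u., or `NULL` to derive it from
#'   baseline statistics with [estimate_threshold()].
#' @param threshold_k Baseline-SD multiplier used when deriving the
#'   threshold. Default 5.
#' @return An object of class `detector_config`.
#' @export
detector_config <- function(mode = c("prototype", "wireless"),
                            poll_period_ms = 50,
                            refractory_ms = 5,
                            frame_period_ms = 60,
                            threshold = NULL,
                            threshold_k = 5) {
  mode <- match.arg(mode)
  check_number(poll_period_ms, "poll_period_ms", min = 1e-12)
  check_number(refractory_ms, "refractory_ms", min = 0)
  check_number(frame_period_ms, "frame_period_ms", min = 1e-12)
  check_number(threshold, "threshold", allow_null = TRUE)
  check_number(threshold_k, "threshold_k", min = 1e-12)
  structure(
    list(mode = mode, poll_period_ms = poll_period_ms,
         refractory_ms = refractory_ms, frame_period_ms = frame_period_ms,
         threshold = threshold, threshold_k = threshold_k),
    class = "detector_config"
  )
}

#' Establish a licking threshold from baseline statistics
#'
#' `threshold = baseline mean + k * baseline sd`. With the default sensor
#' model (baseline 100, noise SD 2, touch amplitude 50) and `k = 5` the
#' threshold sits at 110 a.u. — more than 20 noise SDs below an elevated
#' reading, so clean touches always exceed it.
#'
#' @param baseline A `baseline_stats` tibble from [capture_baseline()], or
#'   anything with `mean` and `sd` components.
#' @param k Noise-SD multiplier, > 0. Default 5.
#' @return The threshold, a.u. (single number).
#' @examples
#' estimate_threshold(list(mean = 100, sd = 2), k = 5) # 110
#' @export
estimate_threshold <- function(baseline, k = 5) {
  check_number(k, "k", min = 1e-12)
  m <- baseline$mean
  s <- baseline$sd
  check_number(m, "baseline$mean")
  check_number(s, "baseline$sd", min = 0)
  m + k * s
}

new_lick_events <- function(cage_id, bottle_id, time_ms) {
  out <- tibble::tibble(
    cage_id = as.integer(cage_id),
    bottle_id = as.character(bottle_id),
    time_ms = as.numeric(time_ms)
  )
  structure(out, class = c("lick_events", class(out)))
}

#' Prototype detector: 50 ms polling with refractory debounce
#'
#' Polls the signal every `poll_period_ms` and counts a lick on a rising
#' edge — a poll reading above threshold whose previous poll read below it
#' (the signal is taken as baseline before the first poll). Polls inside
#' the refractory window after a counted lick are ignored. Timestamps are
#' the poll instants at which counting occurred, which is all the hardware
#' can know.
#'
#' @param signal A `sensor_signal` from [render_continuous()], or a
#'   `sensor_trace` whose sampling grid the polls are snapped to.
#' @param config A [detector_config()] with a set `threshold` (or supply
#'   `threshold` directly).
#' @param threshold Overrides `config$threshold`.
#' @param phase_offset_ms Offset of the first poll relative to time 0, ms.
#'   Default 0.
#' @param duration_ms Polling horizon, ms; defaults to the signal extent.
#' @return A `lick_events` tibble.
#' @export
detect_prototype <- function(signal, config = detector_config("prototype"),
                             threshold = NULL, phase_offset_ms = 0,
                             duration_ms = NULL) {
  stopifnot(inherits(config, "detector_config"))
  threshold <- threshold %||% config$threshold
  if (is.null(threshold)) {
    abort("No threshold set: supply `threshold` or a config with one.")
  }
  period <- config$poll_period_ms

  if (inherits(signal, "sensor_signal")) {
    if (is.null(duration_ms)) duration_ms <- attr(signal, "duration_ms")
    n <- floor((duration_ms - phase_offset_ms) / period) + 1
    t <- phase_offset_ms + (seq_len(max(n, 0)) - 1) * period
    params <- attr(signal, "params")
    local_seed(params$seed)
    v <- signal_value_at(signal, t)
    if (params$baseline_noise_sd > 0 && length(t)) {
      v <- v + rnorm(length(t), 0, params$baseline_noise_sd)
    }
    cage <- attr(signal, "cage_id")
    bottle <- attr(signal, "bottle_id")
  } else if (inherits(signal, "sensor_trace") || is.data.frame(signal)) {
    t <- signal$time_ms
    v <- signal$value
    cage <- if (nrow(signal)) signal$cage_id[1] else NA_integer_
    bottle <- if (nrow(signal)) signal$bottle_id[1] else NA_character_
    keep <- t >= phase_offset_ms
    t <- t[keep]; v <- v[keep]
  } else {
    abort("`signal` must be a sensor_signal or sensor_trace.")
  }

  above <- v > threshold
  rising <- above & !c(FALSE, above[-length(above)])
  events <- t[rising]
  events <- enforce_refractory(events, config$refractory_ms)
  new_lick_events(rep(cage, length(events)), rep(bottle, length(events)), events)
}

# Drop events closer than `refractory` ms after the last kept event.
enforce_refractory <- function(times, refractory) {
  if (length(times) < 2L || refractory <= 0) return(times)
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last > refractory) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times[keep]
}

#' Multiplex channel signals into 16-channel frames
#'
#' Emulates the 16-channel multiplexer feeding the single analog input of
#' the wireless central: one frame per `frame_period_ms`, within which the
#' channels are scanned sequentially in the fixed order 1A, 1B, ..., 8B at
#' offsets `(c - 1) * frame_period_ms / 16`. At the default 60 ms frame,
#' each channel is read at 16.67 samples/s and channel 16 is read 56.25 ms
#' after channel 1.
#'
#' When given event trains rather than continuous signals, the frame also
#' records `n_latched`: the number of pulse onsets falling in the
#' read-to-read window of each channel, which is what a latch-equipped
#' front end would hand to the read. Values are then the idealized digital
#' levels (1 while high, 0 otherwise).
#'
#' @param x Either a `lick_train` tibble (event/pulse input, any number of
#'   channels; absent channels are flat), or a named list of
#'   `sensor_signal` objects keyed `"1A"`, ..., `"8B"`.
#' @param frame_period_ms Frame period, ms. Default 60.
#' @param scan_offsets Optional length-16 vector of within-frame read
#'   offsets, ms; default sequential scan.
#' @param duration_ms Horizon, ms; defaults to the signal extent plus one
#'   frame so trailing events are still read.
#' @return A tibble of class `frame_sequence` in long form: `frame`,
#'   `cage_id`, `bottle_id`, `read_time_ms`, `value`, and `n_latched` for
#'   event input. 16 rows per frame.
#' @export
multiplex <- function(x, frame_period_ms = 60, scan_offsets = NULL,
                      duration_ms = NULL) {
  check_number(frame_period_ms, "frame_period_ms", min = 1e-12)
  if (is.null(scan_offsets)) {
    scan_offsets <- (0:15) * frame_period_ms / 16
  }
  if (length(scan_offsets) != 16L) abort("`scan_offsets` must have length 16.")

  chans <- all_channels()
  chans$offset <- scan_offsets

  if (is.data.frame(x)) {
    if (anyDuplicated(paste(x$cage_id, x$bottle_id, x$onset_ms))) {
      abort("Duplicate (channel, onset) rows in event input.")
    }
    if (is.null(duration_ms)) {
      duration_ms <- if (nrow(x)) max(x$onset_ms + x$contact_ms) else 0
    }
    n_frames <- ceiling(duration_ms / frame_period_ms) + 1L
    per_chan <- purrr::pmap(chans, function(cage_id, bottle_id, offset) {
      reads <- offset + (seq_len(n_frames) - 1) * frame_period_ms
      ev <- x[x$cage_id == cage_id & x$bottle_id == bottle_id, , drop = FALSE]
      value <- rep(0, n_frames)
      for (i in seq_len(nrow(ev))) {
        k0 <- ceiling(pmax(ev$onset_ms[i] - offset, 0) / frame_period_ms) + 1L
        k1 <- ceiling((ev$onset_ms[i] + ev$contact_ms[i] - offset) /
                        frame_period_ms)
        if (k0 <= min(k1, n_frames)) {
          value[k0:min(k1, n_frames)] <- 1
        }
      }
      # latch: onset consumed at the first read instant >= onset
      fidx <- ceiling((ev$onset_ms - offset) / frame_period_ms) + 1L
      fidx <- fidx[fidx >= 1L & fidx <= n_frames]
      n_latched <- tabulate(fidx, nbins = n_frames)
      tibble::tibble(frame = seq_len(n_frames), cage_id = cage_id,
                     bottle_id = bottle_id, read_time_ms = reads,
                     value = value, n_latched = n_latched)
    })
  } else if (is.list(x)) {
    keys <- paste0(chans$cage_id, chans$bottle_id)
    if (is.null(names(x)) || !all(names(x) %in% keys)) {
      abort("List input must be named with channel keys \"1A\"...\"8B\".")
    }
    if (anyDuplicated(names(x))) abort("Duplicate channel ids in input.")
    if (is.null(duration_ms)) {
      duration_ms <- max(vapply(x, function(s) attr(s, "duration_ms"), 0))
    }
    n_frames <- ceiling(duration_ms / frame_period_ms) + 1L
    per_chan <- purrr::pmap(chans, function(cage_id, bottle_id, offset) {
      reads <- offset + (seq_len(n_frames) - 1) * frame_period_ms
      key <- paste0(cage_id, bottle_id)
      if (key %in% names(x)) {
        sig <- x[[key]]
        params <- attr(sig, "params")
        local_seed(params$seed)
        value <- signal_value_at(sig, reads)
        if (params$baseline_noise_sd > 0) {
          value <- value + rnorm(n_frames, 0, params$baseline_noise_sd)
        }
      } else {
        value <- rep(0, n_frames)
      }
      tibble::tibble(frame = seq_len(n_frames), cage_id = cage_id,
                     bottle_id = bottle_id, read_time_ms = reads,
                     value = value)
    })
  } else {
    abort("`x` must be an event tibble or a named list of sensor signals.")
  }

  out <- dplyr::arrange(dplyr::bind_rows(per_chan),
                        .data$frame, .data$read_time_ms)
  structure(out, class = c("frame_sequence", class(out)),
            frame_period_ms = frame_period_ms, scan_offsets = scan_offsets,
            n_frames = max(out$frame))
}

#' Wireless detector over multiplexed frames
#'
#' Two firmware models. *Edge* mode counts a lick at frames where a
#' channel's value crosses from at-or-below to above threshold — an
#' instantaneous 16.67 Hz read, sufficient at 5 Hz pulses (100 ms high
#' spans every 60 ms read grid) but blind to pulses shorter than a frame.
#' *Latched* mode models a front end in which each pulse sets a per-channel
#' latch that the next frame read consumes as one count, so events between
#' reads are retained; the residual acquisition failure is a per-pulse miss
#' probability.
#'
#' @param frames A `frame_sequence` from [multiplex()].
#' @param threshold Threshold, a.u.; required in edge mode. Event-derived
#'   frames use idealized 0/1 levels, so `0.5` is the natural threshold.
#' @param mode `"edge"` or `"latched"`.
#' @param miss_prob Per-pulse probability that the latch fails to capture
#'   an event (latched mode). Default 0.
#' @param seed Seed for the miss draws, or `NULL`.
#' @return A `lick_events` tibble over all 16 channels; timestamps are
#'   frame read instants.
#' @export
detect_wireless <- function(frames, threshold = NULL,
                            mode = c("edge", "latched"),
                            miss_prob = 0, seed = NULL) {
  stopifnot(inherits(frames, "frame_sequence"))
  mode <- match.arg(mode)
  check_number(miss_prob, "miss_prob", min = 0, max = 1)
  local_seed(seed)

  if (mode == "edge") {
    if (is.null(threshold)) abort("Edge mode requires a `threshold`.")
    out <- frames %>%
      dplyr::group_by(.data$cage_id, .data$bottle_id) %>%
      dplyr::arrange(.data$frame, .by_group = TRUE) %>%
      dplyr::filter(.data$value > threshold &
                      !dplyr::lag(.data$value > threshold, default = FALSE)) %>%
      dplyr::ungroup() %>%
      dplyr::select("cage_id", "bottle_id", time_ms = "read_time_ms")
  } else {
    if (!"n_latched" %in% names(frames)) {
      abort("Latched mode requires event-derived frames with `n_latched`.")
    }
    hit <- frames[frames$n_latched > 0, , drop = FALSE]
    # a latch is one bit: multiple pulses inside one read window collapse
    captured <- if (miss_prob > 0) {
      rbinom(nrow(hit), pmin(hit$n_latched, 1L), 1 - miss_prob) > 0
    } else {
      rep(TRUE, nrow(hit))
    }
    out <- hit[captured, c("cage_id", "bottle_id", "read_time_ms")]
    names(out)[3] <- "time_ms"
  }
  out <- dplyr::arrange(tibble::as_tibble(out),
                        .data$cage_id, .data$bottle_id, .data$time_ms)
  structure(out, class = c("lick_events", class(out)))
}

#' Per-channel sampling rate of a frame period
#'
#' @param frame_period_ms Frame period, ms.
#' @return Samples per second per channel (`1000 / frame_period_ms`).
#' @examples
#' per_channel_rate(60) # 16.666..., i.e. 16.67 samples/s
#' @export
per_channel_rate <- function(frame_period_ms) {
  check_number(frame_period_ms, "frame_period_ms", min = 1e-12)
  1000 / frame_period_ms
}
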