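#' Parameters of the capacitive-style sensor model
#'
#' The sensor reads a baseline level with Gaussian noise; a tongue contact
#' elevates the reading by `touch_amplitude` for the duration of the
#' contact. Optional "confuser" events — elevations not caused by licks,
#' the software analogue of an animal blocking a photoelectric beam without
#' drinking — arrive as a Poisson process and produce false positives.
#'
#' Units are abstract sensor counts (a.u.). The defaults give an
#' amplitude-to-noise ratio of 25, which makes detection essentially
#' perfect unless deliberately degraded.
#'
#' @param baseline_level Mouse-free sensor level, a.u. Default 100.
#' @param baseline_noise_sd SD of Gaussian baseline noise, a.u. Default 2.
#' @param touch_amplitude Elevation during a tongue contact, a.u. Default 50.
#' @param confuser_rate Confuser events per minute. Default 0 (capacitive
#'   simulations).
#' @param confuser_amplitude Elevation during a confuser, a.u. Default
#'   equals `touch_amplitude`.
#' @param confuser_duration_ms Duration of a confuser elevation, ms.
#'   Default 100.
#' @param sample_period_ms Default sampling period for traces, ms.
#'   Default 60 (16.67 samples/s).
#' @param seed Integer seed or `NULL`.
#' @return An object of class `sensor_params`.
#' @export
sensor_params <- function(baseline_level = 100,
                          baseline_noise_sd = 2,
                          touch_amplitude = 50,
                          confuser_rate = 0,
                          confuser_amplitude = touch_amplitude,
                          confuser_duration_ms = 100,
                          sample_period_ms = 60,
                          seed = NULL) {
  check_number(baseline_level, "baseline_level")
  check_number(baseline_noise_sd, "baseline_noise_sd", min = 0)
  check_number(touch_amplitude, "touch_amplitude", min = 1e-12)
  check_number(confuser_rate, "confuser_rate", min = 0)
  check_number(confuser_amplitude, "confuser_amplitude", min = 0)
  check_number(confuser_duration_ms, "confuser_duration_ms", min = 1e-12)
  check_number(sample_period_ms, "sample_period_ms", min = 1e-12)
  structure(
    list(baseline_level = baseline_level, baseline_noise_sd = baseline_noise_sd,
         touch_amplitude = touch_amplitude, confuser_rate = confuser_rate,
         confuser_amplitude = confuser_amplitude,
         confuser_duration_ms = confuser_duration_ms,
         sample_period_ms = sample_period_ms, seed = seed),
    class = "sensor_params"
  )
}

#' Render a lick train as a continuous-time sensor signal
#'
#' Turns ground-truth licks into a piecewise description of the sensor's
#' continuous activity: one elevated interval per lick over
#' `[onset, onset + contact)`, plus Poisson confuser intervals when
#' `confuser_rate > 0`. The noise specification travels with the signal and
#' is applied at sampling time.
#'
#' @param train A single-channel `lick_train` tibble (zero rows allowed).
#' @param params A [sensor_params()] object.
#' @param duration_ms Signal duration, ms; defaults to the end of the last
#'   contact. Needed explicitly for confusers on an empty train.
#' @return A tibble of class `sensor_signal` with columns `start_ms`,
#'   `end_ms`, `amplitude`, `source` (`"lick"` or `"confuser"`); attributes
#'   carry the channel, duration and noise spec.
#' @export
render_continuous <- function(train, params, duration_ms = NULL) {
  stopifnot(is.data.frame(train), inherits(params, "sensor_params"))
  if (length(unique(paste(train$cage_id, train$bottle_id))) > 1L) {
    abort("`render_continuous()` takes a single-channel train.")
  }
  local_seed(params$seed)
  if (is.null(duration_ms)) {
    duration_ms <- if (nrow(train)) max(train$onset_ms + train$contact_ms) else 0
  }
  check_number(duration_ms, "duration_ms", min = 0)

  lick_iv <- tibble::tibble(
    start_ms = train$onset_ms,
    end_ms = train$onset_ms + train$contact_ms,
    amplitude = rep(params$touch_amplitude, nrow(train)),
    source = rep("lick", nrow(train))
  )
  conf_iv <- tibble::tibble(start_ms = numeric(0), end_ms = numeric(0),
                            amplitude = numeric(0), source = character(0))
  if (params$confuser_rate > 0 && duration_ms > 0) {
    n_conf <- stats::rpois(1, params$confuser_rate * duration_ms / 60000)
    if (n_conf > 0) {
      starts <- sort(runif(n_conf, 0, duration_ms))
      conf_iv <- tibble::tibble(
        start_ms = starts,
        end_ms = starts + params$confuser_duration_ms,
        amplitude = rep(params$confuser_amplitude, n_conf),
        source = rep("confuser", n_conf)
      )
    }
  }
  out <- dplyr::arrange(dplyr::bind_rows(lick_iv, conf_iv), .data$start_ms)
  structure(out, class = c("sensor_signal", class(out)),
            cage_id = if (nrow(train)) train$cage_id[1] else NA_integer_,
            bottle_id = if (nrow(train)) train$bottle_id[1] else NA_character_,
            duration_ms = duration_ms, params = params)
}

# Noise-free signal value at arbitrary instants: baseline + the summed
# amplitude of every elevated interval covering the instant. Lick intervals
# never overlap by construction; a confuser over a lick adds.
signal_value_at <- function(signal, t_ms) {
  params <- attr(signal, "params")
  v <- rep(params$baseline_level, length(t_ms))
  for (i in seq_len(nrow(signal))) {
    hit <- t_ms >= signal$start_ms[i] & t_ms < signal$end_ms[i]
    v[hit] <- v[hit] + signal$amplitude[i]
  }
  v
}

#' Sample a continuous sensor signal as a uniformly spaced trace
#'
#' Instantaneous point reads every `sample_period_ms`, starting at 0:
#' sample k (k = 0, 1, ...) reads the signal at `k * sample_period_ms` and
#' adds Gaussian baseline noise. `floor(duration_ms / sample_period_ms)`
#' samples are produced, so one minute at the 60 ms default yields exactly
#' 1000 samples (16.67 samples/s).
#'
#' @param signal A `sensor_signal` from [render_continuous()].
#' @param sample_period_ms Sampling period, ms. Defaults to the signal's
#'   sensor parameter.
#' @param duration_ms Trace duration, ms; defaults to the signal duration.
#' @param start_ms Time of the first sample, ms. Default 0.
#' @return A tibble of class `sensor_trace` with columns `cage_id`,
#'   `bottle_id`, `time_ms`, `value`; attribute `sample_period_ms`.
#' @export
sample_trace <- function(signal, sample_period_ms = NULL, duration_ms = NULL,
                         start_ms = 0) {
  stopifnot(inherits(signal, "sensor_signal"))
  params <- attr(signal, "params")
  if (is.null(sample_period_ms)) sample_period_ms <- params$sample_period_ms
  if (is.null(duration_ms)) duration_ms <- attr(signal, "duration_ms")
  check_number(sample_period_ms, "sample_period_ms", min = 1e-12)
  check_number(duration_ms, "duration_ms", min = 0)
  local_seed(params$seed)

  n <- floor(duration_ms / sample_period_ms)
  t <- start_ms + (seq_len(n) - 1) * sample_period_ms
  v <- signal_value_at(signal, t)
  if (params$baseline_noise_sd > 0 && n > 0) {
    v <- v + rnorm(n, 0, params$baseline_noise_sd)
  }
  out <- tibble::tibble(
    cage_id = rep(attr(signal, "cage_id") %||% NA_integer_, n),
    bottle_id = rep(attr(signal, "bottle_id") %||% NA_character_, n),
    time_ms = t,
    value = v
  )
  structure(out, class = c("sensor_trace", class(out)),
            sample_period_ms = sample_period_ms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Capture baseline statistics from a mouse-free trace
#'
#' Samples a lick-free trace — the standard one-minute acquisition without
#' an animal — and summarizes it. The resulting mean and SD feed
#' [estimate_threshold()].
#'
#' @param params A [sensor_params()] object.
#' @param duration_ms Capture duration, ms. Default 60000 (1 min, i.e.
#'   1000 samples at the 60 ms period).
#' @param sample_period_ms Sampling period, ms; defaults to the parameter
#'   object's period.
#' @return A one-row tibble of class `baseline_stats` with columns `mean`,
#'   `sd`, `n_samples`, `sample_period_ms`.
#' @examples
#' capture_baseline(sensor_params(baseline_noise_sd = 0))
#' @export
capture_baseline <- function(params, duration_ms = 60000,
                             sample_period_ms = NULL) {
  stopifnot(inherits(params, "sensor_params"))
  check_number(duration_ms, "duration_ms", min = 1e-12)
  empty <- new_lick_train(1L, "A", numeric(0), numeric(0))
  quiet <- render_continuous(empty, params, duration_ms = duration_ms)
  tr <- sample_trace(quiet, sample_period_ms = sample_period_ms,
                     duration_ms = duration_ms)
  out <- tibble::tibble(
    mean = mean(tr$value),
    sd = if (nrow(tr) > 1L) sd(tr$value) else 0,
    n_samples = nrow(tr),
    sample_period_ms = attr(tr, "sample_period_ms")
  )
  structure(out, class = c("baseline_stats", class(out)))
}
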