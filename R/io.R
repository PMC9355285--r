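#' Write and read raw sensor-trace files
#'
#' The raw-trace dialect mirrors the acquisition software's habit of
#' storing the sensor raw input at 16.67 Hz in a text file: tab-separated
#' with header `timestamp_iso	cage_id	bottle_id	value`, one row per channel
#' per frame, ISO-8601 timestamps with millisecond precision, values
#' serialized with 3 decimal places (the writer/reader round-trip is exact
#' on that representation).
#'
#' @param traces A `sensor_trace` tibble (one or more channels stacked).
#' @param path File path.
#' @param session_start A `POSIXct` wall-clock time of `time_ms = 0`.
#'   Default `2026-01-01 17:00:00 UTC`.
#' @return `write_raw_trace()` returns `path` invisibly;
#'   `read_raw_trace()` returns a `sensor_trace` tibble with `time_ms`
#'   offsets from the earliest timestamp in the file and a
#'   `session_start` attribute.
#' @export
write_raw_trace <- function(traces, path,
                            session_start = as.POSIXct("2026-01-01 17:00:00",
                                                       tz = "UTC")) {
  stopifnot(is.data.frame(traces))
  df <- dplyr::arrange(tibble::as_tibble(traces),
                       .data$time_ms, .data$cage_id, .data$bottle_id)
  stamp <- iso_ms(session_start, df$time_ms)
  out <- data.frame(timestamp_iso = stamp, cage_id = df$cage_id,
                    bottle_id = df$bottle_id,
                    value = sprintf("%.3f", df$value))
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

# ISO-8601 timestamps with exact millisecond rendering. strftime's %OS3
# truncates the floating-point seconds, so the millisecond field is built
# by integer arithmetic instead.
iso_ms <- function(session_start, time_ms) {
  abs_ms <- round(as.numeric(session_start) * 1000 + time_ms)
  secs <- abs_ms %/% 1000
  msec <- abs_ms %% 1000
  paste0(
    format(as.POSIXct(secs, origin = "1970-01-01", tz = "UTC"),
           "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    sprintf(".%03d", msec)
  )
}

#' @rdname write_raw_trace
#' @export
read_raw_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) abort("Empty file: missing raw-trace header.")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("timestamp_iso", "cage_id", "bottle_id", "value")
  if (!identical(header, need)) {
    abort(sprintf("Raw-trace header must be %s.", paste(need, collapse = "\t")))
  }
  body <- lines[-1]
  if (length(body) == 0L) {
    out <- tibble::tibble(cage_id = integer(0), bottle_id = character(0),
                          time_ms = numeric(0), value = numeric(0))
    return(structure(out, class = c("sensor_trace", class(out))))
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 4L)
  if (length(bad)) {
    warn(sprintf("Skipping %d malformed raw-trace row(s) at line(s): %s",
                 length(bad), paste(head(bad + 1L, 10), collapse = ", ")))
    parts <- parts[lengths(parts) == 4L]
  }
  m <- do.call(rbind, parts)
  stamp <- as.POSIXct(m[, 1], format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(stamp)) {
    bad_t <- which(is.na(stamp))
    warn(sprintf("Skipping %d row(s) with unparseable timestamps.",
                 length(bad_t)))
    keep <- !is.na(stamp)
    m <- m[keep, , drop = FALSE]
    stamp <- stamp[keep]
  }
  t0 <- min(stamp)
  out <- tibble::tibble(
    cage_id = as.integer(m[, 2]),
    bottle_id = m[, 3],
    time_ms = round(as.numeric(stamp - t0, units = "secs") * 1000, 3),
    value = as.numeric(m[, 4])
  )
  mono <- out %>%
    dplyr::group_by(.data$cage_id, .data$bottle_id) %>%
    dplyr::summarise(ok = !is.unsorted(.data$time_ms, strictly = TRUE),
                     .groups = "drop")
  if (any(!mono$ok)) {
    abort(sprintf(
      "Non-monotonic timestamps within channel(s): %s",
      paste(mono$cage_id[!mono$ok], mono$bottle_id[!mono$ok],
            sep = "", collapse = ", ")
    ))
  }
  structure(out, class = c("sensor_trace", class(out)), session_start = t0)
}

#' Write and read detected lick-event files
#'
#' Events CSV dialect: header `timestamp_iso,cage_id,bottle_id`, one row
#' per detected lick, millisecond-precision ISO-8601 timestamps — the
#' per-lick record the deployed system keeps. Reading sorts each channel
#' by time (with a warning if the file was out of order).
#'
#' @param events A `lick_events` tibble.
#' @param path File path.
#' @param session_start Wall-clock time of `time_ms = 0`.
#' @return `write_events()` returns `path` invisibly; `read_events()`
#'   returns a `lick_events` tibble with ms offsets from the earliest
#'   timestamp.
#' @export
write_events <- function(events, path,
                         session_start = as.POSIXct("2026-01-01 17:00:00",
                                                    tz = "UTC")) {
  ev <- as_events_tbl(events)
  stamp <- iso_ms(session_start, ev$time_ms)
  out <- data.frame(timestamp_iso = stamp, cage_id = ev$cage_id,
                    bottle_id = ev$bottle_id)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_iso", "cage_id", "bottle_id")
  if (!all(need %in% names(df))) {
    abort(sprintf("Events file must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (nrow(df) == 0L) {
    return(new_lick_events(integer(0), character(0), numeric(0)))
  }
  stamp <- as.POSIXct(df$timestamp_iso, format = "%Y-%m-%dT%H:%M:%OS",
                      tz = "UTC")
  if (anyNA(stamp)) abort("Unparseable timestamps in events file.")
  t0 <- min(stamp)
  out <- new_lick_events(df$cage_id, df$bottle_id,
                         round(as.numeric(stamp - t0, units = "secs") * 1000, 3))
  unsorted <- out %>%
    dplyr::group_by(.data$cage_id, .data$bottle_id) %>%
    dplyr::summarise(bad = is.unsorted(.data$time_ms), .groups = "drop")
  if (any(unsorted$bad)) {
    warn("Events file out of order; sorting per channel.")
  }
  out <- dplyr::arrange(out, .data$cage_id, .data$bottle_id, .data$time_ms)
  structure(out, class = c("lick_events", class(out)), session_start = t0)
}

#' Flat key-value run configuration files
#'
#' Configuration (and the run manifest, which is the same dialect) is a
#' plain text file of `module.key = value` lines; `#` starts a comment.
#' Values are kept as character and coerced by the consumer.
#'
#' @param config A named list (names like `"lickgen.session_duration"`).
#' @param path File path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` a named character list.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    sprintf("%s = %s", k, paste(format(config[[k]], trim = TRUE),
                                collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) {
    abort(sprintf("Malformed config line(s): %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  vals <- lapply(kv, function(x) trimws(x[3]))
  names(vals) <- vapply(kv, function(x) trimws(x[2]), character(1))
  vals
}
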