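#' Match detected licks to ground truth within a tolerance window
#'
#' Greedy one-to-one matching in time order, the software analogue of
#' frame-by-frame video annotation: each detection is matched to the
#' nearest unmatched truth onset whose window contains it, ties broken
#' toward the earlier onset. Because detections are stamped at read/poll
#' instants, which trail lick onsets, the window is asymmetric: detection
#' `d` is compatible with truth onset `o` (contact duration `c`) when
#' `o - before <= d <= o + c + tolerance`. Matched pairs are true
#' positives; unmatched detections false positives; unmatched truths false
#' negatives.
#'
#' @param detected A `lick_events` tibble (or numeric vector of times, ms).
#' @param truth A `lick_train` tibble (or numeric vector of onsets; then
#'   contact durations are taken as 0).
#' @param tolerance_ms Allowance after the end of the contact, ms. Default
#'   60, one wireless frame period: a detection within the contact or the
#'   immediately following frame is the same lick.
#' @param before_ms Allowance before the onset, ms. Default 0.
#' @return A one-row tibble of class `confusion_counts` with columns `tp`,
#'   `fp`, `fn` (per channel when multi-channel input is given, plus the
#'   channel columns).
#' @examples
#' match_events(c(10, 500), c(0, 480, 900), tolerance_ms = 60)
#' @export
match_events <- function(detected, truth, tolerance_ms = 60, before_ms = 0) {
  check_number(tolerance_ms, "tolerance_ms", min = 0)
  check_number(before_ms, "before_ms", min = 0)
  det <- as_events_tbl(detected, "detected")
  if (is.numeric(truth)) {
    truth <- new_lick_train(1L, "A", truth, rep(0, length(truth)))
  }
  stopifnot(is.data.frame(truth))

  channels <- dplyr::distinct(dplyr::bind_rows(
    det[, c("cage_id", "bottle_id")],
    truth[, c("cage_id", "bottle_id")]
  ))
  rows <- purrr::pmap(channels, function(cage_id, bottle_id) {
    d <- sort(det$time_ms[det$cage_id == cage_id & det$bottle_id == bottle_id])
    idx <- truth$cage_id == cage_id & truth$bottle_id == bottle_id
    o <- truth$onset_ms[idx]
    cc <- truth$contact_ms[idx]
    if (is.unsorted(o)) abort("`truth` onsets must be sorted within channel.")
    m <- greedy_match(d, o, cc, tolerance_ms, before_ms)
    tibble::tibble(cage_id = cage_id, bottle_id = bottle_id,
                   tp = m$tp, fp = m$fp, fn = m$fn)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("confusion_counts", class(out)))
}

greedy_match <- function(d, o, contact, tol, before) {
  matched <- logical(length(o))
  tp <- 0L
  for (di in d) {
    lo <- o - before
    hi <- o + contact + tol
    ok <- which(!matched & di >= lo & di <= hi)
    if (length(ok)) {
      pick <- ok[which.min(abs(di - o[ok]))] # ties: which.min takes the first,
      matched[pick] <- TRUE                  # i.e. the earlier onset
      tp <- tp + 1L
    }
  }
  list(tp = tp, fp = length(d) - tp, fn = sum(!matched))
}

#' Precision and recall of lick detection
#'
#' Precision is the ratio of true positives among true and false positives
#' (`TP / (TP + FP)`): the fraction of counted licks that were real.
#' Recall is the ratio of true positives in relation to false negatives
#' and true positives (`TP / (TP + FN)`): the fraction of real licks that
#' were counted. Both error (rather than return 0) when their denominator
#' is zero, since "no detections at all" is not the same as "all
#' detections wrong".
#'
#' @param counts A `confusion_counts` tibble from [match_events()] (rows
#'   are summed), or anything with `tp`, `fp`, `fn` components.
#' @return A proportion in `[0, 1]`.
#' @examples
#' precision(list(tp = 91, fp = 9, fn = 9)) # 0.91
#' recall(list(tp = 90, fp = 0, fn = 9))
#' @export
precision <- function(counts) {
  tp <- sum(counts$tp); fp <- sum(counts$fp)
  if (tp + fp == 0) abort("Precision undefined: no detections (TP + FP = 0).")
  tp / (tp + fp)
}

#' @rdname precision
#' @export
recall <- function(counts) {
  tp <- sum(counts$tp); fn <- sum(counts$fn)
  if (tp + fn == 0) abort("Recall undefined: no ground-truth licks (TP + FN = 0).")
  tp / (tp + fn)
}

#' Run the three-phase in-silico validation protocol grid
#'
#' Replicates the emulated-signal validation end to end for every cell of
#' phase x frequency x active-cage-count (x replicate): generate the
#' deterministic pulse trains, acquire them at the central through the
#' 60 ms multiplexed frame scan (latched by default, with a per-pulse miss
#' probability), transmit the frame-packets through the lossy channel, and
#' score reading and transmission errors per output.
#'
#' Acquisition here uses an event-level implementation of the latched read
#' (per-pulse frame assignment), algebraically identical to running
#' [multiplex()] + [detect_wireless()] on dense frames but without
#' materializing 40,000 x 16 frame grids per cell; the equivalence is
#' exercised in the package tests. The unit of transmission loss is one
#' frame-packet carrying all 16 channel values, so the number of events
#' lost per drop depends on how many active channels had latched events in
#' that frame — which is why transmission error varies across phases and
#' cage counts while reading error does not.
#'
#' @param phases Phases to run. Default `1:3`.
#' @param frequencies_hz Pulse frequencies, Hz. Default `c(5, 10)`.
#' @param cages Active-cage counts. Default `1:8`.
#' @param replicates Replicates per cell. Default 10.
#' @param n_pulses Pulses per pulsed output. Default 12000.
#' @param frame_period_ms Wireless frame period, ms. Default 60.
#' @param miss_prob Per-pulse latch miss probability. Default `5e-4`.
#' @param loss A [loss_model()] for the frame-packet channel. Its own seed
#'   is ignored; per-cell seeds are derived from `seed`.
#' @param seed Base seed. Per-cell seeds are `seed +` a cell index, so any
#'   cell is reproducible in isolation.
#' @return A tibble of class `insilico_validation`, one row per
#'   (phase, frequency, active cages, output, replicate), with columns
#'   `emitted`, `central_detected`, `received`, `reading_error_pct`,
#'   `transmission_error_pct`, `cell_seed`.
#' @examples
#' rep <- run_insilico_protocol(cages = 1:2, replicates = 2, n_pulses = 500,
#'                              seed = 1)
#' glance(rep)
#' @export
run_insilico_protocol <- function(phases = 1:3,
                                  frequencies_hz = c(5, 10),
                                  cages = 1:8,
                                  replicates = 10,
                                  n_pulses = 12000,
                                  frame_period_ms = 60,
                                  miss_prob = 5e-4,
                                  loss = loss_model(),
                                  seed = 1) {
  stopifnot(inherits(loss, "loss_model"))
  check_number(miss_prob, "miss_prob", min = 0, max = 1)
  check_number(seed, "seed", min = 0)

  grid <- tidyr::expand_grid(
    phase = as.integer(phases),
    frequency_hz = frequencies_hz,
    active_cages = as.integer(cages),
    replicate = seq_len(replicates)
  )
  grid$cell_seed <- seed + seq_len(nrow(grid))

  rows <- purrr::pmap(grid, function(phase, frequency_hz, active_cages,
                                     replicate, cell_seed) {
    run_protocol_cell(phase, frequency_hz, active_cages, n_pulses,
                      frame_period_ms, miss_prob, loss, cell_seed) %>%
      dplyr::mutate(phase = phase, frequency_hz = frequency_hz,
                    active_cages = active_cages, replicate = replicate,
                    cell_seed = cell_seed, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("insilico_validation", class(out)),
            n_pulses = n_pulses, frame_period_ms = frame_period_ms,
            miss_prob = miss_prob, loss = loss, seed = seed)
}

# One grid cell: event-level latched acquisition + frame-packet loss,
# aggregated per output letter.
run_protocol_cell <- function(phase, frequency_hz, active_cages, n_pulses,
                              frame_period_ms, miss_prob, loss, cell_seed) {
  local_seed(cell_seed)
  proto <- pulse_protocol(phase, frequency_hz, n_pulses, active_cages)
  period <- 1000 / frequency_hz
  offsets <- (0:15) * frame_period_ms / 16
  duration <- n_pulses * period + period
  n_frames <- as.integer(ceiling(duration / frame_period_ms) + 1L)

  outputs <- switch(as.character(phase), "1" = "A", "2" = "B", "3" = c("A", "B"))
  cage_seq <- seq_len(active_cages)

  # frame-packet delivery shared by all channels in this cell
  model <- loss
  model$seed <- NULL
  n_del <- deliveries(n_frames, model)

  res <- lapply(outputs, function(bottle) {
    emitted <- 0L; detected <- 0L; received <- 0L
    b_off <- if (phase == 3 && bottle == "B") period / 2 else 0
    onsets <- (seq_len(n_pulses) - 1) * period + b_off
    for (cage in cage_seq) {
      ch_off <- offsets[channel_index(cage, bottle)]
      fidx <- ceiling((onsets - ch_off) / frame_period_ms) + 1L
      fidx <- pmax(fidx, 1L)
      captured <- if (miss_prob > 0) runif(n_pulses) >= miss_prob
                  else rep(TRUE, n_pulses)
      # latch is one bit per read window: collapse collisions (none occur
      # for pulse periods above the frame period, but keep the semantics)
      fcap <- unique(fidx[captured])
      emitted <- emitted + n_pulses
      detected <- detected + length(fcap)
      received <- received + sum(n_del[fcap])
    }
    tibble::tibble(
      output = bottle, emitted = as.integer(emitted),
      central_detected = as.integer(detected), received = as.integer(received),
      reading_error_pct = reading_error(emitted, detected),
      transmission_error_pct = transmission_error(detected, received)
    )
  })
  dplyr::bind_rows(res)
}

#' Summarize an in-silico validation report
#'
#' @param x An `insilico_validation` tibble.
#' @param ... Unused.
#' @return A one-row tibble: grand mean reading error, grand mean absolute
#'   and signed transmission error (all percent, averaged over cells), and
#'   the cell count.
#' @method glance insilico_validation
#' @export
glance.insilico_validation <- function(x, ...) {
  tibble::tibble(
    mean_reading_error_pct = mean(x$reading_error_pct),
    mean_abs_transmission_error_pct = mean(abs(x$transmission_error_pct)),
    mean_transmission_error_pct = mean(x$transmission_error_pct),
    n_cells = nrow(x)
  )
}

#' Tidy confusion counts into precision/recall
#'
#' @param x A `confusion_counts` tibble.
#' @param ... Unused.
#' @return A one-row tibble with summed counts, `precision` and `recall`.
#' @method tidy confusion_counts
#' @export
tidy.confusion_counts <- function(x, ...) {
  tibble::tibble(
    tp = sum(x$tp), fp = sum(x$fp), fn = sum(x$fn),
    precision = precision(x), recall = recall(x)
  )
}

#' Export a validation report as long-form CSV
#'
#' Columns: `phase,frequency_hz,active_cages,output,replicate,emitted,
#' central_detected,received,reading_error_pct,transmission_error_pct`.
#'
#' @param report An `insilico_validation` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  cols <- c("phase", "frequency_hz", "active_cages", "output", "replicate",
            "emitted", "central_detected", "received",
            "reading_error_pct", "transmission_error_pct")
  write.csv(as.data.frame(report)[, cols], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
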