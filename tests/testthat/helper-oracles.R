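# Independent brute-force oracles used to cross-check the production code.
# These deliberately share no code with the package internals.

# Dense-grid detector: evaluate the noise-free signal on a fine grid of
# poll instants and count rising edges above threshold, with a refractory
# window enforced by a direct scan. Operates on raw interval data.
oracle_detect <- function(starts, ends, amplitude, baseline, threshold,
                          poll_times, refractory = 0) {
  values <- vapply(poll_times, function(t) {
    baseline + amplitude * sum(t >= starts & t < ends)
  }, numeric(1))
  above <- values > threshold
  events <- numeric(0)
  last <- -Inf
  prev_above <- FALSE
  for (i in seq_along(poll_times)) {
    if (above[i] && !prev_above && poll_times[i] - last > refractory) {
      events <- c(events, poll_times[i])
      last <- poll_times[i]
    }
    prev_above <- above[i]
  }
  events
}

# Exhaustive optimal one-to-one matching: maximize TP over all assignments
# of detections to compatible truths. Recursion over detections; fine for
# <= 12 events.
oracle_optimal_tp <- function(d, o, contact, tol, before = 0) {
  compat <- lapply(d, function(di) {
    which(di >= o - before & di <= o + contact + tol)
  })
  best <- 0L
  recurse <- function(i, used, tp) {
    if (tp + (length(d) - i + 1L) <= best) return(invisible(NULL))
    if (i > length(d)) {
      best <<- max(best, tp)
      return(invisible(NULL))
    }
    recurse(i + 1L, used, tp) # leave detection i unmatched
    for (j in compat[[i]]) {
      if (!used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, tp + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(length(o)), 0L)
  best
}

# Direct-scan bout partition: walk the sorted times and cut wherever the
# gap exceeds the break.
oracle_bout_partition <- function(times, bout_break) {
  if (length(times) == 0L) return(integer(0))
  id <- integer(length(times))
  id[1] <- 1L
  for (i in seq_along(times)[-1]) {
    id[i] <- id[i - 1] + (times[i] - times[i - 1] > bout_break)
  }
  id
}

# Tiny random detector-output generator in the physiological regime:
# well-separated truths, detections jittered by less than half the window.
random_match_instance <- function(n_truth, tolerance, seed) {
  set.seed(seed)
  onsets <- cumsum(runif(n_truth, 2.5 * tolerance, 6 * tolerance))
  contact <- runif(n_truth, 20, 50)
  detected <- onsets + runif(n_truth, 0, contact + tolerance * 0.9)
  miss <- runif(n_truth) < 0.2
  spurious <- if (runif(1) < 0.5) {
    max(onsets) + contact[n_truth] + tolerance * 3 + runif(1, 0, 100)
  } else {
    numeric(0)
  }
  list(truth_onsets = onsets, truth_contacts = contact,
       detected = sort(c(detected[!miss], spurious)))
}

make_events <- function(times, cage = 1L, bottle = "A") {
  tibble::tibble(cage_id = cage, bottle_id = bottle, time_ms = times)
}

make_train <- function(onsets, contacts, cage = 1L, bottle = "A") {
  tibble::tibble(cage_id = cage, bottle_id = bottle,
                 onset_ms = onsets, contact_ms = contacts)
}
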