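#' Lossy wireless channel model
#'
#' The wireless link is UDP-style: no delivery guarantee. Two channel
#' models are available: independent Bernoulli packet loss, and a
#' two-state Gilbert-Elliott burst model (good state delivers everything;
#' the bad state drops packets with `bad_loss_prob`; transitions follow a
#' Markov chain), which captures loss clustering under busy network
#' bandwidth. Packets may additionally be duplicated.
#'
#' @param kind `"bernoulli"` or `"burst"`.
#' @param loss_prob Per-packet loss probability (Bernoulli model).
#'   Default 0.008.
#' @param duplicate_prob Probability a delivered packet arrives twice.
#'   Default 0.
#' @param p_good_bad,p_bad_good Burst-model transition probabilities
#'   good-to-bad and bad-to-good per packet.
#' @param bad_loss_prob Loss probability while in the bad state.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `loss_model`.
#' @export
loss_model <- function(kind = c("bernoulli", "burst"),
                       loss_prob = 0.008,
                       duplicate_prob = 0,
                       p_good_bad = 0.01,
                       p_bad_good = 0.3,
                       bad_loss_prob = 0.5,
                       seed = NULL) {
  kind <- match.arg(kind)
  for (nm in c("loss_prob", "duplicate_prob", "p_good_bad", "p_bad_good",
               "bad_loss_prob")) {
    check_number(get(nm), nm, min = 0, max = 1)
  }
  structure(
    list(kind = kind, loss_prob = loss_prob, duplicate_prob = duplicate_prob,
         p_good_bad = p_good_bad, p_bad_good = p_bad_good,
         bad_loss_prob = bad_loss_prob, seed = seed),
    class = "loss_model"
  )
}

# Per-unit delivery counts (0 dropped, 1 delivered, 2 duplicated).
deliveries <- function(n, model) {
  if (n == 0L) return(integer(0))
  dropped <- switch(model$kind,
    bernoulli = runif(n) < model$loss_prob,
    burst = {
      bad <- logical(n)
      state <- FALSE # start in the good state
      u <- runif(n)
      for (i in seq_len(n)) {
        state <- if (state) u[i] >= model$p_bad_good else u[i] < model$p_good_bad
        bad[i] <- state
      }
      bad & (runif(n) < model$bad_loss_prob)
    }
  )
  n_del <- as.integer(!dropped)
  if (model$duplicate_prob > 0) {
    n_del <- n_del + as.integer(n_del == 1L & runif(n) < model$duplicate_prob)
  }
  n_del
}

#' Transmit a sequence of units through the lossy channel
#'
#' Each unit (typically one frame-packet carrying all 16 channel values) is
#' independently dropped or duplicated according to the model; order is
#' preserved. The returned tibble keeps one row per *sent* unit with an
#' `n_delivered` column (0, 1 or 2), which doubles as the transmission log;
#' expand with `tidyr::uncount(n_delivered)` to obtain the received
#' sequence itself.
#'
#' @param x A tibble of units (one row per packet), or a vector.
#' @param model A [loss_model()].
#' @return A tibble of class `transmission` with the columns of `x` plus
#'   `n_delivered`; attributes `sent_count` and `received_count`.
#' @examples
#' tx <- transmit(tibble::tibble(frame = 1:1000),
#'                loss_model(loss_prob = 0.01, seed = 1))
#' attr(tx, "received_count")
#' @export
transmit <- function(x, model) {
  stopifnot(inherits(model, "loss_model"))
  if (!is.data.frame(x)) x <- tibble::tibble(unit = x)
  local_seed(model$seed)
  x <- tibble::as_tibble(x)
  x$n_delivered <- deliveries(nrow(x), model)
  structure(x, class = c("transmission", class(x)),
            sent_count = nrow(x), received_count = sum(x$n_delivered))
}

#' Transmission error (signed percent)
#'
#' `(received - sent) / sent * 100`: negative values are net loss over the
#' wireless link, positive values net duplication.
#'
#' @param sent_count Packets (or events) sent, > 0.
#' @param received_count Packets (or events) received.
#' @return Signed percent. Vectorized over both arguments.
#' @examples
#' transmission_error(12000, 11880) # -1
#' @export
transmission_error <- function(sent_count, received_count) {
  if (any(sent_count <= 0)) {
    abort("Transmission error is undefined for `sent_count` = 0.")
  }
  if (any(received_count < 0)) abort("`received_count` must be >= 0.")
  (received_count - sent_count) / sent_count * 100
}

#' Reading error (percent)
#'
#' The percentage of emitted lick events the central acquisition failed to
#' register before wireless transmission:
#' `(emitted - detected) / emitted * 100`.
#'
#' @param emitted_count Events emitted at the sensors, > 0.
#' @param detected_count Events registered by the central.
#' @return Percent. Vectorized over both arguments.
#' @examples
#' reading_error(12000, 11994) # 0.05
#' @export
reading_error <- function(emitted_count, detected_count) {
  if (any(emitted_count <= 0)) {
    abort("Reading error is undefined for `emitted_count` = 0.")
  }
  if (any(detected_count < 0)) abort("`detected_count` must be >= 0.")
  (emitted_count - detected_count) / emitted_count * 100
}
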