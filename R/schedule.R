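#' Build an IGT payoff schedule
#'
#' Defines the four-deck card-selection environment. Every selection of a deck
#' pays its fixed gain; losses occur on a subset of selections. Decks A and B
#' pay large gains (+100) but lose more than they gain over a 10-selection
#' cycle (expected value -250); decks C and D pay small gains (+50) with a
#' positive per-cycle expected value (+250). Losses are scheduled either
#' deterministically (exactly \code{loss_events} losses per 10 consecutive
#' selections of a deck, at fixed evenly spread within-cycle positions, so the
#' per-cycle expected values hold exactly) or as independent Bernoulli events
#' with probability \code{loss_events/10} per selection (the same values in
#' expectation).
#'
#' @param gain named numeric, fixed gain per selection of each deck (A-D).
#' @param loss_events named numeric, number of loss events per 10 consecutive
#'   selections of each deck (0-10).
#' @param loss_magnitude named numeric, positive loss magnitude per event;
#'   losses are recorded as negative numbers in trial tables.
#' @param loss_mode \code{"deterministic_cycle"} (default) or
#'   \code{"bernoulli"}.
#' @param cycle cycle length in selections of one deck (default 10).
#' @return An object of class \code{igt_schedule}.
#' @examples
#' sched <- igt_schedule()
#' deck_expected_value(sched, "C") # +250
#' @export
igt_schedule <- function(gain = c(A = 100, B = 100, C = 50, D = 50),
                         loss_events = c(A = 5, B = 1, C = 5, D = 1),
                         loss_magnitude = c(A = 250, B = 1250, C = 50, D = 250),
                         loss_mode = c("deterministic_cycle", "bernoulli"),
                         cycle = 10L) {
  loss_mode <- match.arg(loss_mode)
  decks <- c("A", "B", "C", "D")
  for (v in list(gain, loss_events, loss_magnitude)) {
    if (!is.numeric(v) || length(v) != 4L || !identical(sort(names(v)), decks))
      stop("each payoff field must be a numeric vector named A, B, C, D")
  }
  gain <- gain[decks]; loss_events <- loss_events[decks]
  loss_magnitude <- loss_magnitude[decks]
  if (any(gain <= 0)) stop("gain_per_selection must be positive")
  if (any(loss_events < 0 | loss_events > cycle))
    stop("loss_events must lie in [0, ", cycle, "]")
  if (any(loss_magnitude < 0)) stop("loss magnitudes are given as positive numbers")
  # Evenly spread loss positions within each deck's cycle: k events at
  # positions round(i * cycle / k), i = 1..k. k = 5 in a 10-cycle gives
  # 2,4,6,8,10; k = 1 gives 10.
  pos <- matrix(0L, nrow = 4, ncol = cycle, dimnames = list(decks, NULL))
  for (j in seq_len(4)) {
    k <- loss_events[j]
    if (k > 0) pos[j, unique(round(seq_len(k) * cycle / k))] <- 1L
  }
  structure(list(gain = gain, loss_events = loss_events,
                 loss_magnitude = loss_magnitude, loss_mode = loss_mode,
                 cycle = as.integer(cycle), loss_positions = pos),
            class = "igt_schedule")
}

#' @export
print.igt_schedule <- function(x, ...) {
  cat("IGT payoff schedule (", x$loss_mode, ", cycle = ", x$cycle, ")\n", sep = "")
  df <- data.frame(gain = x$gain, losses_per_cycle = x$loss_events,
                   loss_magnitude = x$loss_magnitude,
                   expected_value = vapply(names(x$gain), function(d)
                     deck_expected_value(x, d), numeric(1)))
  print(df, ...)
  invisible(x)
}

.check_deck <- function(deck) {
  if (length(deck) != 1L || !deck %in% c("A", "B", "C", "D"))
    stop("unknown deck id: ", paste(deck, collapse = ","),
         " (expected one of A, B, C, D)")
  deck
}

#' Draw the outcome of one deck selection
#'
#' In deterministic-cycle mode the loss falls exactly on the schedule's fixed
#' within-cycle positions, keyed by how many times this deck has been selected
#' so far; in bernoulli mode a loss occurs independently with probability
#' \code{loss_events/cycle} (uses the R RNG).
#'
#' @param schedule an \code{igt_schedule}.
#' @param deck deck id, one of \code{"A"}-\code{"D"}.
#' @param selection_count 1-based count of selections of this deck including
#'   the current one.
#' @return named numeric \code{c(gain=, loss=)}; loss is non-positive.
#' @export
draw_outcome <- function(schedule, deck, selection_count) {
  stopifnot(inherits(schedule, "igt_schedule"))
  .check_deck(deck)
  if (selection_count < 1) stop("selection_count must be >= 1")
  gain <- schedule$gain[[deck]]
  loss <- 0
  if (schedule$loss_mode == "deterministic_cycle") {
    pos <- (selection_count - 1) %% schedule$cycle + 1
    if (schedule$loss_positions[deck, pos] == 1L)
      loss <- -schedule$loss_magnitude[[deck]]
  } else {
    if (runif(1) < schedule$loss_events[[deck]] / schedule$cycle)
      loss <- -schedule$loss_magnitude[[deck]]
  }
  c(gain = gain, loss = loss)
}

#' Expected net payoff of one deck over a full selection cycle
#'
#' \code{cycle * gain - loss_events * loss_magnitude}; exact in
#' deterministic-cycle mode, the expectation in bernoulli mode. For the
#' default schedule this is -250 for decks A and B and +250 for C and D.
#'
#' @inheritParams draw_outcome
#' @return net currency units per cycle.
#' @export
deck_expected_value <- function(schedule, deck) {
  stopifnot(inherits(schedule, "igt_schedule"))
  .check_deck(deck)
  schedule$cycle * schedule$gain[[deck]] -
    schedule$loss_events[[deck]] * schedule$loss_magnitude[[deck]]
}
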