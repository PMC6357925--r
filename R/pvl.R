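#' PVL model parameters
#'
#' The Prospect Valence Learning model describes trial-by-trial deck choice
#' with four parameters: feedback sensitivity \code{a} (curvature of the
#' prospect utility, 0-1), loss aversion \code{lambda} (weight on losses
#' relative to gains, 0-5), learning/decay \code{A} (retention of prior deck
#' expectancies, 0-1) and response consistency \code{c} (0-5), which sets the
#' softmax sensitivity theta = 3^c - 1.
#'
#' @param a,lambda,A,c parameter values within their ranges.
#' @return named numeric vector of class \code{pvl_params}.
#' @examples
#' pvl_params(a = 0.25, lambda = 0.5, A = 0.45, c = 0.6)
#' @export
pvl_params <- function(a, lambda, A, c) {
  p <- c(a = a, lambda = lambda, A = A, c = c)
  validate_pvl_params(p)
  structure(p, class = "pvl_params")
}

.pvl_lower <- c(a = 0, lambda = 0, A = 0, c = 0)
.pvl_upper <- c(a = 1, lambda = 5, A = 1, c = 5)

#' @rdname pvl_params
#' @param params named numeric with entries a, lambda, A, c.
#' @export
validate_pvl_params <- function(params) {
  nm <- c("a", "lambda", "A", "c")
  if (!is.numeric(params) || !all(nm %in% names(params)))
    stop("params must be numeric with names a, lambda, A, c")
  p <- params[nm]
  if (any(!is.finite(p))) stop("PVL parameters must be finite")
  bad <- p < .pvl_lower | p > .pvl_upper
  if (any(bad))
    stop("PVL parameter(s) out of range: ",
         paste(nm[bad], collapse = ", "),
         " (a, A in [0,1]; lambda, c in [0,5])")
  invisible(p)
}

#' Prospect utility of a net outcome
#'
#' u(x) = x^a for x >= 0 and -lambda * |x|^a for x < 0. A zero outcome has
#' zero valence for any a. With a = 1, lambda = 1 the utility is the identity;
#' lambda = 0 ignores losses entirely.
#'
#' @param x signed net outcome(s) (gain + loss), already payoff-scaled.
#' @param a feedback sensitivity in [0, 1].
#' @param lambda loss aversion in [0, 5].
#' @return numeric vector of valences.
#' @export
pvl_utility <- function(x, a, lambda) {
  validate_pvl_params(c(a = a, lambda = lambda, A = 0, c = 0))
  ifelse(x >= 0, ifelse(x == 0, 0, x^a), -lambda * abs(x)^a)
}

#' Decay-rule expectancy update
#'
#' E_j <- A * E_j for every deck; the chosen deck additionally gains the
#' current utility u. A = 0 is memoryless (only the last outcome on the chosen
#' deck survives); A = 1 accumulates utilities as running sums.
#'
#' @param E numeric length-4 expectancy vector (decks A-D).
#' @param chosen deck id of the selected deck.
#' @param u utility of the current net outcome.
#' @param A learning/decay parameter in [0, 1].
#' @return updated length-4 expectancy vector.
#' @export
update_expectancies <- function(E, chosen, u, A) {
  if (length(E) != 4L || any(!is.finite(E))) stop("E must be 4 finite values")
  if (A < 0 || A > 1) stop("A must lie in [0, 1]")
  j <- match(.check_deck(chosen), c("A", "B", "C", "D"))
  E <- A * E
  E[j] <- E[j] + u
  E
}

#' Softmax sensitivity theta
#'
#' The printed rule (\code{"as_printed"}, default) is theta = 3^c - 1,
#' constant in t; c = 0 gives theta = 0 and hence uniform random choice.
#' \code{"trial_dependent"} is the classic alternative theta(t) = (t/10)^c.
#'
#' @param c response consistency in [0, 5].
#' @param t 1-based trial index (used only by the trial-dependent rule).
#' @param rule \code{"as_printed"} or \code{"trial_dependent"}.
#' @return theta >= 0.
#' @export
consistency_theta <- function(c, t = 1L, rule = c("as_printed", "trial_dependent")) {
  rule <- match.arg(rule)
  if (c < 0 || c > 5) stop("c must lie in [0, 5]")
  if (any(t < 1)) stop("t must be >= 1")
  if (rule == "as_printed") rep(3^c - 1, length(t)) else (t / 10)^c
}

.theta_rule_code <- function(rule) {
  match(match.arg(rule, c("as_printed", "trial_dependent")),
        c("as_printed", "trial_dependent")) - 1L
}

#' Softmax choice probabilities over the four decks
#'
#' Pr(deck j) proportional to exp(theta * E_j), computed with max-subtraction
#' so large theta * E cannot overflow. All-zero (or equal) expectancies give
#' 1/4 each, as does c = 0.
#'
#' @inheritParams update_expectancies
#' @inheritParams consistency_theta
#' @return numeric length-4 probability vector summing to 1.
#' @export
choice_probabilities <- function(E, c, t = 1L, rule = c("as_printed", "trial_dependent")) {
  if (length(E) != 4L || any(!is.finite(E))) stop("E must be 4 finite values")
  th <- consistency_theta(c, t, match.arg(rule))[1]
  z <- th * E
  w <- exp(z - max(z))
  w / sum(w)
}

#' Simulate one PVL agent on the IGT
#'
#' Composes the three model equations forward: on each trial a deck is
#' sampled from the softmax over current expectancies, the outcome is drawn
#' from the payoff schedule, the net outcome is payoff-scaled, passed through
#' the prospect utility and folded into the expectancies by the decay rule.
#' Optional practice trials are simulated first as a separate warm-up run
#' (own expectancies and deck cycle counters); the experimental trials then
#' start from all-zero expectancies.
#'
#' @param params a \code{pvl_params} vector (or named numeric a, lambda, A, c).
#' @param schedule an \code{igt_schedule}.
#' @param n_trials number of experimental trials (default 100).
#' @param n_practice number of practice trials prepended and flagged
#'   (default 0).
#' @param seed optional integer seed for reproducibility.
#' @param theta_rule softmax sensitivity rule, see [consistency_theta()].
#' @param payoff_scale factor applied to net outcomes before the utility
#'   (default 0.01, i.e. utilities operate on outcomes in units of 100).
#' @return data frame with columns trial, deck, gain, loss, net, is_practice;
#'   the scale and rule are recorded as attributes.
#' @export
simulate_agent <- function(params, schedule = igt_schedule(), n_trials = 100L,
                           n_practice = 0L, seed = NULL,
                           theta_rule = c("as_printed", "trial_dependent"),
                           payoff_scale = 0.01) {
  p <- validate_pvl_params(params)
  stopifnot(inherits(schedule, "igt_schedule"), n_trials >= 1)
  theta_rule <- match.arg(theta_rule)
  if (!is.null(seed)) set.seed(seed)
  run <- function(n) {
    out <- simulate_agent_cpp(p[["a"]], p[["lambda"]], p[["A"]], p[["c"]],
                              unname(schedule$gain), unname(schedule$loss_events),
                              unname(schedule$loss_magnitude),
                              if (schedule$loss_mode == "deterministic_cycle") 0L else 1L,
                              schedule$loss_positions, as.integer(n),
                              .theta_rule_code(theta_rule), payoff_scale)
    data.frame(deck = c("A", "B", "C", "D")[out$deck],
               gain = out$gain, loss = out$loss, net = out$gain + out$loss)
  }
  res <- if (n_practice > 0) {
    pr <- run(n_practice); ex <- run(n_trials)
    cbind(rbind(pr, ex),
          is_practice = rep(c(TRUE, FALSE), c(n_practice, n_trials)))
  } else cbind(run(n_trials), is_practice = FALSE)
  res <- cbind(trial = seq_len(nrow(res)), res)
  attr(res, "payoff_scale") <- payoff_scale
  attr(res, "theta_rule") <- theta_rule
  res
}

#' PVL log-likelihood of an observed choice sequence
#'
#' Sum over trials of the log probability of the observed deck under the
#' expectancy state accumulated from the preceding trials (all-zero before
#' trial 1, so the first trial always contributes log 1/4). Per-trial
#' probabilities are floored at \code{prob_floor} inside the log, so the
#' likelihood is finite for all in-range parameters.
#'
#' @param trials data frame with \code{deck} (A-D) and \code{net} columns in
#'   trial order; practice rows (\code{is_practice}) are dropped.
#' @inheritParams simulate_agent
#' @param prob_floor lower bound on per-trial choice probabilities.
#' @return scalar log-likelihood.
#' @export
pvl_loglik <- function(trials, params,
                       theta_rule = c("as_printed", "trial_dependent"),
                       payoff_scale = 0.01, prob_floor = 1e-12) {
  p <- validate_pvl_params(params)
  theta_rule <- match.arg(theta_rule)
  if (!is.data.frame(trials) || is.null(trials$deck) || is.null(trials$net))
    stop("trials must be a data frame with 'deck' and 'net' columns")
  if (!is.null(trials$is_practice)) trials <- trials[!trials$is_practice, , drop = FALSE]
  if (nrow(trials) == 0L) stop("empty choice sequence")
  deck <- match(as.character(trials$deck), c("A", "B", "C", "D"))
  if (any(is.na(deck))) stop("deck column must contain only A, B, C, D")
  pvl_loglik_cpp(deck, as.numeric(trials$net), p[["a"]], p[["lambda"]],
                 p[["A"]], p[["c"]], .theta_rule_code(theta_rule),
                 payoff_scale, prob_floor)
}
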