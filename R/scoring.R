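#' IGT net scores for one subject
#'
#' The net score is the count of advantageous selections minus disadvantageous
#' ones, (C + D) - (A + B), over all experimental trials (total net) and
#' within each consecutive block of \code{block_size} trials (block nets).
#' Rows flagged \code{is_practice} are dropped before scoring; the remaining
#' trials must number exactly 100 (five 20-trial blocks) unless
#' \code{allow_any_multiple} permits any multiple of the block size.
#'
#' @param trials data frame with a \code{deck} column (letters A-D) in trial
#'   order, optionally an \code{is_practice} logical column.
#' @param block_size trials per scoring block (default 20).
#' @param allow_any_multiple accept any trial count that is a positive
#'   multiple of \code{block_size}.
#' @return list of class \code{igt_scores}: \code{total_net},
#'   \code{block_nets}, \code{deck_counts}, \code{n_trials}.
#' @export
compute_net_scores <- function(trials, block_size = 20L,
                               allow_any_multiple = FALSE) {
  if (!is.data.frame(trials) || is.null(trials$deck))
    stop("trials must be a data frame with a 'deck' column")
  if (!is.null(trials$is_practice)) trials <- trials[!trials$is_practice, , drop = FALSE]
  deck <- as.character(trials$deck)
  if (!all(deck %in% c("A", "B", "C", "D")))
    stop("deck column must contain only A, B, C, D")
  n <- length(deck)
  if (!allow_any_multiple && n != 100L)
    stop("expected exactly 100 experimental trials, got ", n,
         " (set allow_any_multiple = TRUE for other multiples of the block size)")
  if (n == 0L || n %% block_size != 0L)
    stop("trial count (", n, ") must be a positive multiple of block_size (",
         block_size, ")")
  sgn <- ifelse(deck %in% c("C", "D"), 1L, -1L)
  block <- rep(seq_len(n %/% block_size), each = block_size)
  block_nets <- as.integer(tapply(sgn, block, sum))
  counts <- vapply(c("A", "B", "C", "D"), function(d) sum(deck == d), integer(1))
  structure(list(total_net = sum(sgn), block_nets = block_nets,
                 deck_counts = counts, n_trials = n),
            class = "igt_scores")
}

#' @export
print.igt_scores <- function(x, ...) {
  cat("IGT scores over", x$n_trials, "trials: total net =", x$total_net, "\n")
  cat("  block nets:", paste(x$block_nets, collapse = ", "), "\n")
  cat("  deck counts:", paste(names(x$deck_counts), x$deck_counts,
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Label a subject by eating-attitude screening score
#'
#' Total scores strictly above the threshold (default 22, the KEAT-26
#' cut-off for high risk of anorexia nervosa) are labelled
#' \code{"high_risk"}; all others \code{"control"}.
#'
#' @param keat26_total non-negative total score(s).
#' @param threshold cut-off; scores > threshold are high risk.
#' @return character vector of \code{"high_risk"} / \code{"control"}.
#' @export
label_risk_group <- function(keat26_total, threshold = 22) {
  if (any(!is.finite(keat26_total)) || any(keat26_total < 0))
    stop("keat26_total must be finite and non-negative")
  ifelse(keat26_total > threshold, "high_risk", "control")
}
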