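#' Per-subject IGT scores for a cohort
#'
#' Applies [compute_net_scores()] to each subject's experimental trials.
#'
#' @param trials trial table with subject_id (and optionally group) columns,
#'   or a \code{pvl_cohort}.
#' @return data frame: subject_id, group, total_net, block1..block5,
#'   count_A..count_D.
#' @export
cohort_scores <- function(trials) {
  if (inherits(trials, "pvl_cohort")) trials <- trials$trials
  ids <- unique(trials$subject_id)
  do.call(rbind, lapply(ids, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    sc <- compute_net_scores(tr)
    out <- data.frame(subject_id = id,
                      group = if (is.null(tr$group)) NA_character_
                              else as.character(tr$group[1]),
                      total_net = sc$total_net, stringsAsFactors = FALSE)
    out[paste0("block", 1:5)] <- as.list(sc$block_nets)
    out[paste0("count_", c("A", "B", "C", "D"))] <- as.list(sc$deck_counts)
    out
  }))
}

#' Run the full group-comparison battery on a cohort
#'
#' Reproduces the analysis pipeline on any cohort in the package's trial
#' layout: ANCOVA of total net score on group with depression/anxiety
#' covariates, mixed-design block-by-group ANCOVA with Bonferroni-corrected
#' follow-ups, pooled t tests on per-deck selection counts, Mann-Whitney U
#' tests on the four per-subject PVL parameter estimates, and within-group
#' plain/bootstrapped Pearson correlations between total net score, the
#' screening score and the learning/consistency estimates.
#'
#' @param cohort a \code{pvl_cohort} (or list with \code{subjects} and
#'   \code{trials} tables in the package layout).
#' @param estimates per-subject parameter table
#'   (from [fit_mle_cohort()] or [hier_point_estimates()]); NULL skips the
#'   parameter tests.
#' @param covariates names of subject columns entered as ANCOVA covariates.
#' @param n_boot bootstrap replicates for the correlations.
#' @param seed seed for the bootstrap.
#' @return list of result tables: \code{total_net}, \code{blocks} (a
#'   \code{pvl_mixed_anova}), \code{deck_counts}, \code{parameters},
#'   \code{correlations}.
#' @export
analyze_cohort <- function(cohort, estimates = NULL,
                           covariates = c("sds", "stai_state", "stai_trait"),
                           n_boot = 10000L, seed = NULL) {
  subjects <- cohort$subjects
  scores <- cohort_scores(cohort)
  scores <- scores[match(subjects$subject_id, scores$subject_id), ]
  grp <- factor(subjects$group, levels = c("high_risk", "control"))
  covs <- if (length(covariates)) subjects[, covariates, drop = FALSE] else NULL
  res <- list()
  res$total_net <- ancova_group(scores$total_net, grp, covs)
  res$blocks <- mixed_block_ancova(
    as.matrix(scores[paste0("block", 1:5)]), grp, covs, followups = TRUE)
  hr <- grp == "high_risk"
  res$deck_counts <- do.call(rbind, lapply(c("A", "B", "C", "D"), function(d) {
    r <- welch_t(scores[[paste0("count_", d)]][hr],
                 scores[[paste0("count_", d)]][!hr])
    r$test <- paste0("deck_", d, "_count")
    r
  }))
  if (!is.null(estimates)) {
    est <- estimates[match(subjects$subject_id, estimates$subject_id), ]
    res$parameters <- do.call(rbind, lapply(c("a", "lambda", "A", "c"),
      function(p) {
        r <- mann_whitney(est[[p]][hr], est[[p]][!hr])
        r$test <- paste0("param_", p)
        r
      }))
  }
  if (!is.null(seed)) set.seed(seed)
  corr_rows <- list()
  for (g in c("high_risk", "control")) {
    sel <- grp == g
    r1 <- pearson_r(scores$total_net[sel], subjects$keat26[sel])
    r1$test <- paste0("net_vs_keat26_", g)
    corr_rows[[length(corr_rows) + 1L]] <- r1
    if (!is.null(estimates)) {
      est <- estimates[match(subjects$subject_id, estimates$subject_id), ]
      for (p in c("A", "c")) {
        rb <- bootstrap_pearson(scores$total_net[sel], est[[p]][sel],
                                n_boot = n_boot)
        rb$test <- paste0("net_vs_", p, "_", g)
        corr_rows[[length(corr_rows) + 1L]] <-
          rb[, setdiff(names(rb), c("n_boot", "dropped"))]
      }
    }
  }
  res$correlations <- do.call(rbind, corr_rows)
  res
}

#' Write / read cohort tables as delimited text
#'
#' The trial table (subject_id, group, trial, deck, gain, loss, net,
#' is_practice) and the subjects table (group, covariates, true parameters)
#' are written as plain CSV with a header row; decks are single letters A-D.
#'
#' @param cohort a \code{pvl_cohort}.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "pvl_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tp <- file.path(dir, "trials.csv")
  sp <- file.path(dir, "subjects.csv")
  utils::write.csv(cohort$trials, tp, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$subjects, sp, row.names = FALSE, quote = FALSE)
  invisible(c(trials = tp, subjects = sp))
}

#' @rdname write_cohort
#' @param path path to a trials.csv written by [write_cohort()].
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial", "deck", "gain", "loss", "net")
  miss <- setdiff(need, names(tr))
  if (length(miss)) stop("trial table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(tr$is_practice)) tr$is_practice <- as.logical(tr$is_practice)
  tr
}
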