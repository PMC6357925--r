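# common one-row result layout for all tests
.stat_row <- function(test, statistic, df1 = NA_real_, df2 = NA_real_,
                      n1 = NA_integer_, n2 = NA_integer_, p = NA_real_,
                      p_one = NA_real_, effect_size = NA_real_,
                      ci_lo = NA_real_, ci_hi = NA_real_,
                      adjustment = "none", method = NA_character_) {
  data.frame(test = test, statistic = statistic, df1 = df1, df2 = df2,
             n1 = n1, n2 = n2, p = p, p_one = p_one,
             effect_size = effect_size, ci_lo = ci_lo, ci_hi = ci_hi,
             adjustment = adjustment, method = method,
             stringsAsFactors = FALSE)
}

#' Covariate-adjusted group comparison (one-way ANCOVA)
#'
#' Least-squares fit of \code{outcome ~ covariates + group}; the group effect
#' is the extra-sum-of-squares F test of dropping group from the full model
#' (equivalent to a Type-III test here, since group is the only factor and no
#' interactions are fitted). With no covariates this reduces exactly to the
#' one-way ANOVA F. Effect size is partial eta-squared,
#' SS_group / (SS_group + SS_residual).
#'
#' @param outcome numeric per-subject scores.
#' @param group two-or-more-level grouping vector.
#' @param covariates data frame of numeric covariates (or NULL).
#' @param adjustment bookkeeping tag recorded in the result.
#' @return one-row data frame (test, statistic = F, df1, df2, p,
#'   effect_size, ...).
#' @export
ancova_group <- function(outcome, group, covariates = NULL,
                         adjustment = "none") {
  group <- factor(group)
  if (nlevels(group) < 2 || any(table(group) < 2))
    stop("need >= 2 subjects in each of >= 2 groups")
  d <- data.frame(.y = outcome, .g = group)
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (any(!complete.cases(covariates))) stop("covariates must be complete")
    cov_names <- names(covariates)
    d <- cbind(d, covariates)
  }
  rhs_cov <- if (length(cov_names)) paste(cov_names, collapse = " + ") else "1"
  full <- lm(as.formula(paste(".y ~", rhs_cov, "+ .g")), data = d)
  if (full$rank < ncol(model.matrix(full)))
    stop("design is rank-deficient (collinear covariates or covariate ",
         "confounded with group)")
  reduced <- lm(as.formula(paste(".y ~", rhs_cov)), data = d)
  ss_g <- sum(residuals(reduced)^2) - sum(residuals(full)^2)
  df1 <- reduced$df.residual - full$df.residual
  df2 <- full$df.residual
  sse <- sum(residuals(full)^2)
  if (sse == 0 && ss_g == 0) {
    Fv <- 0; p <- 1
  } else {
    Fv <- (ss_g / df1) / (sse / df2)
    p <- pf(Fv, df1, df2, lower.tail = FALSE)
  }
  .stat_row("ancova_group", Fv, df1 = df1, df2 = df2,
            n1 = length(outcome), p = p,
            effect_size = if (ss_g + sse > 0) ss_g / (ss_g + sse) else 0,
            adjustment = adjustment, method = "lm extra-SS F")
}

#' Mixed-design block-by-group ANCOVA
#'
#' Five within-subject block net scores, a between-subject group factor and
#' optional covariates, analysed through the multivariate linear model route
#' (\code{car::Anova} with an intra-subject design), which reproduces the
#' SPSS-style univariate mixed-model table: between-subjects group F, the
#' within-subject block main effect and the block-by-group interaction, with
#' Greenhouse-Geisser epsilon and corrected p-values reported alongside the
#' uncorrected tests (uncorrected as primary). Optional follow-ups: per-block
#' group ANCOVAs (Bonferroni over the 5 blocks) and per-group
#' repeated-measures ANOVAs across blocks, without covariates (Bonferroni
#' over the 2 groups).
#'
#' @param block_scores n-by-5 matrix/data frame of block net scores.
#' @param group between-subject labels, length n.
#' @param covariates data frame of numeric covariates (or NULL).
#' @param followups also run the per-block and per-group contrasts.
#' @return list of class \code{pvl_mixed_anova}: \code{main} (rows group,
#'   block, block:group), \code{gg_epsilon}, and, if requested,
#'   \code{per_block} and \code{per_group} tables.
#' @export
mixed_block_ancova <- function(block_scores, group, covariates = NULL,
                               followups = FALSE) {
  Y <- as.matrix(block_scores)
  if (ncol(Y) != 5L) stop("expected exactly 5 block scores per subject")
  if (any(!is.finite(Y))) stop("missing block scores")
  group <- factor(group)
  n <- nrow(Y)
  d <- data.frame(.g = group)
  contrasts(d$.g) <- "contr.sum"
  cov_names <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    cov_names <- names(covariates)
    d <- cbind(d, covariates)
  }
  rhs <- paste(c(cov_names, ".g"), collapse = " + ")
  mlm <- lm(as.formula(paste("Y ~", rhs)), data = d)
  idata <- data.frame(block = factor(paste0("b", 1:5)))
  av <- car::Anova(mlm, idata = idata, idesign = ~block, type = 3)
  # car warns when the HF epsilon exceeds 1 (it clamps it) and when a
  # degenerate error SSP blocks the sphericity corrections; both cases are
  # handled downstream, so these notes are muffled
  smry <- withCallingHandlers(
    summary(av, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps|error SSP", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ut <- smry$univariate.tests
  find_row <- function(tab, terms) {
    i <- which(rownames(tab) %in% terms)
    if (!length(i)) stop("term not found in ANOVA table: ",
                         paste(terms, collapse = "/"))
    i[1]
  }
  pick <- function(terms) {
    i <- find_row(ut, terms)
    ss <- ut[i, "Sum Sq"]; err <- ut[i, "Error SS"]
    Fv <- ut[i, "F value"]; p <- ut[i, "Pr(>F)"]
    eta <- if (ss + err > 0) ss / (ss + err) else 0
    # no between-effect variance (e.g. constant scores): report a null effect
    if (ss <= 1e-10 * (abs(err) + 1) || !is.finite(Fv)) { Fv <- 0; p <- 1; eta <- 0 }
    .stat_row(terms[1], Fv, df1 = ut[i, "num Df"],
              df2 = ut[i, "den Df"], n1 = n, p = p,
              effect_size = eta,
              method = "mixed ANCOVA (univariate)")
  }
  inter <- c(".g:block", "block:.g")
  main <- rbind(pick(".g"), pick("block"), pick(inter))
  main$test <- c("group", "block", "block:group")
  pva <- smry$pval.adjustments
  gg <- list(epsilon = NA_real_, p_block = NA_real_, p_interaction = NA_real_)
  if (!is.null(pva) && nrow(pva) > 0) {
    gg$epsilon <- pva[find_row(pva, "block"), "GG eps"]
    gg$p_block <- pva[find_row(pva, "block"), "Pr(>F[GG])"]
    if (any(rownames(pva) %in% inter))
      gg$p_interaction <- pva[find_row(pva, inter), "Pr(>F[GG])"]
  }
  out <- list(main = main, gg = gg)
  if (followups) {
    out$per_block <- do.call(rbind, lapply(1:5, function(b) {
      r <- ancova_group(Y[, b], group, covariates, adjustment = "bonferroni_5")
      r$test <- paste0("group_block", b)
      r
    }))
    out$per_group <- do.call(rbind, lapply(levels(group), function(g) {
      Yg <- Y[group == g, , drop = FALSE]
      ng <- nrow(Yg)
      long <- data.frame(y = as.vector(Yg),
                         block = factor(rep(1:5, each = ng)),
                         id = factor(rep(seq_len(ng), 5)))
      fit <- aov(y ~ block + Error(id), data = long)
      tab <- summary(fit)[["Error: Within"]][[1]]
      ss <- tab["block", "Sum Sq"]; err <- tab["Residuals", "Sum Sq"]
      Fv <- tab["block", "F value"]; p <- tab["block", "Pr(>F)"]
      eta <- if (ss + err > 0) ss / (ss + err) else 0
      if (ss <= 1e-10 * (abs(err) + 1) || !is.finite(Fv)) { Fv <- 0; p <- 1; eta <- 0 }
      .stat_row(paste0("block_within_", g), Fv,
                df1 = tab["block", "Df"], df2 = tab["Residuals", "Df"],
                n1 = ng, p = p, effect_size = eta,
                adjustment = "bonferroni_2",
                method = "repeated-measures ANOVA")
    }))
  }
  class(out) <- "pvl_mixed_anova"
  out
}

#' @export
print.pvl_mixed_anova <- function(x, ...) {
  cat("Mixed-design block x group analysis\n")
  print(x$main[, c("test", "statistic", "df1", "df2", "p", "effect_size")],
        digits = 4)
  if (is.finite(x$gg$epsilon))
    cat("Greenhouse-Geisser epsilon =", round(x$gg$epsilon, 3),
        "; GG-corrected p(block) =", signif(x$gg$p_block, 3),
        ", p(interaction) =", signif(x$gg$p_interaction, 3), "\n")
  if (!is.null(x$per_block)) {
    cat("Per-block group contrasts (Bonferroni over 5):\n")
    print(x$per_block[, c("test", "statistic", "df1", "df2", "p", "effect_size")],
          digits = 4)
  }
  invisible(x)
}

#' Mann-Whitney U test
#'
#' U computed from midranks; the reported statistic is the smaller of U_x and
#' n1*n2 - U_x. The null distribution is enumerated exactly (via the
#' Wilcoxon rank-sum distribution) when there are no ties and n1*n2 <= 400;
#' otherwise a tie-corrected normal approximation with continuity correction
#' is used. Both two-sided and one-sided (x shifted below y) p-values are
#' reported.
#'
#' @param x,y numeric samples.
#' @return one-row data frame with statistic = min(U_x, U_y), p (two-sided),
#'   p_one, and the method used.
#' @export
mann_whitney <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  r <- rank(c(x, y))
  Ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  Uy <- n1 * n2 - Ux
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 * n2 <= 400) {
    # exact enumeration of the rank-sum null distribution
    p_less <- pwilcox(Ux, n1, n2)
    p_greater <- pwilcox(Uy, n2, n1)
    p <- min(1, 2 * min(p_less, p_greater))
    method <- "exact"
  } else {
    N <- n1 + n2
    tie_tab <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    if (sigma2 <= 0) {           # all values tied
      p <- 1; p_less <- 0.5
      method <- "degenerate"
    } else {
      z_less <- (Ux - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
      z_greater <- (Uy - n1 * n2 / 2 + 0.5) / sqrt(sigma2)
      p_less <- pnorm(z_less)
      p_greater <- pnorm(z_greater)
      p <- min(1, 2 * min(p_less, p_greater))
      method <- "normal_tie_corrected"
    }
  }
  out <- .stat_row("mann_whitney", min(Ux, Uy), n1 = n1, n2 = n2,
                   p = p, p_one = p_less, method = method)
  out$U_x <- Ux; out$U_y <- Uy
  out
}

#' Pearson product-moment correlation
#'
#' r with the two-sided p-value from the t transform t = r sqrt((n-2)/(1-r^2))
#' (via \code{stats::cor.test}).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return one-row data frame (statistic = r, df1 = n - 2, p).
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  ct <- cor.test(x, y, method = "pearson")
  .stat_row("pearson_r", unname(ct$estimate), df1 = unname(ct$parameter),
            n1 = length(x), p = ct$p.value, method = "t transform")
}

#' Case-resampling bootstrap of the Pearson correlation
#'
#' Resamples (x, y) pairs with replacement \code{n_boot} times; reports the
#' observed r, the percentile 95% CI, and a bootstrap p-value (twice the
#' smaller tail proportion of resampled r on either side of 0, capped at 1).
#' Degenerate resamples (zero variance) are redrawn up to 10 times each,
#' then dropped; the drop count is recorded.
#'
#' @param x,y numeric vectors of equal length >= 5.
#' @param n_boot bootstrap replicates (>= 1000; default 10000).
#' @param seed optional integer seed; the CI is deterministic given it.
#' @param conf confidence level of the percentile interval.
#' @return one-row data frame (statistic = observed r, ci_lo, ci_hi, p).
#' @export
bootstrap_pearson <- function(x, y, n_boot = 10000L, seed = NULL,
                              conf = 0.95) {
  if (length(x) != length(y) || length(x) < 5)
    stop("x and y must have equal length >= 5")
  if (n_boot < 1000) stop("n_boot must be >= 1000")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in x or y")
  n <- length(x)
  r_obs <- cor(x, y)
  if (!is.null(seed)) set.seed(seed)
  rb <- numeric(n_boot)
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    val <- NA_real_
    for (try in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      if (sd(x[idx]) > 0 && sd(y[idx]) > 0) { val <- cor(x[idx], y[idx]); break }
    }
    rb[b] <- val
    if (is.na(val)) dropped <- dropped + 1L
  }
  rb <- rb[!is.na(rb)]
  alpha <- (1 - conf) / 2
  ci <- unname(quantile(rb, c(alpha, 1 - alpha)))
  p <- min(1, 2 * min(mean(rb <= 0), mean(rb >= 0)))
  out <- .stat_row("bootstrap_pearson", r_obs, n1 = n, p = p,
                   ci_lo = ci[1], ci_hi = ci[2],
                   method = sprintf("percentile bootstrap (%d reps)", n_boot))
  out$n_boot <- n_boot; out$dropped <- dropped
  out
}

#' Two-sample t test
#'
#' Pooled-variance Student t by default (df = n1 + n2 - 2, matching
#' equal-df reporting for two groups); Welch's unequal-variance form by flag.
#'
#' @param x,y numeric samples of size >= 2.
#' @param pooled use the pooled-variance form (default TRUE).
#' @return one-row data frame (statistic = t, df1 = df, p).
#' @export
welch_t <- function(x, y, pooled = TRUE) {
  if (length(x) < 2 || length(y) < 2) stop("both samples must have size >= 2")
  if (sd(c(x, y)) == 0)
    return(.stat_row("t_test", 0, df1 = length(x) + length(y) - 2,
                     n1 = length(x), n2 = length(y), p = 1,
                     method = if (pooled) "pooled" else "welch"))
  tt <- t.test(x, y, var.equal = pooled)
  .stat_row("t_test", unname(tt$statistic), df1 = unname(tt$parameter),
            n1 = length(x), n2 = length(y), p = tt$p.value,
            method = if (pooled) "pooled" else "welch")
}
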