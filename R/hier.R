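#' Priors for the hierarchical PVL model
#'
#' The hierarchy is specified on an unconstrained scale: each subject's raw
#' parameter z is Normal(mu, sigma) with group mean mu ~ Normal(mu_loc,
#' mu_scale) and group SD sigma ~ half-Normal(sigma_scale). A probit link
#' maps z onto each parameter's range: a = Phi(z), A = Phi(z), lambda =
#' 5 Phi(z), c = 5 Phi(z), so every draw satisfies the range invariants by
#' construction. The defaults are weakly informative for bounded
#' reinforcement-learning parameters.
#'
#' @param mu_loc,mu_scale location and scale of the group-mean prior.
#' @param sigma_scale scale of the half-normal group-SD prior.
#' @return list of class \code{pvl_priors}.
#' @export
pvl_priors <- function(mu_loc = 0, mu_scale = 1, sigma_scale = 1) {
  stopifnot(mu_scale > 0, sigma_scale > 0)
  structure(list(mu_loc = mu_loc, mu_scale = mu_scale,
                 sigma_scale = sigma_scale), class = "pvl_priors")
}

# probit links from unconstrained z to the parameter box
.pvl_link <- function(z) {
  p <- pnorm(z)
  if (is.matrix(z)) {
    p[, c(2, 4)] <- 5 * p[, c(2, 4)]
    colnames(p) <- c("a", "lambda", "A", "c")
  } else {
    p <- p * c(1, 5, 1, 5)
    names(p) <- c("a", "lambda", "A", "c")
  }
  p
}

.split_trials_by_subject <- function(trials) {
  if (!is.null(trials$is_practice)) trials <- trials[!trials$is_practice, , drop = FALSE]
  if (is.null(trials$subject_id)) trials$subject_id <- "s1"
  if (nrow(trials) == 0L) stop("empty trial table: no experimental trials")
  ids <- unique(trials$subject_id)
  dat <- lapply(ids, function(id) {
    tr <- trials[trials$subject_id == id, , drop = FALSE]
    if (nrow(tr) == 0L) stop("subject ", id, " has no experimental trials")
    deck <- match(as.character(tr$deck), c("A", "B", "C", "D"))
    if (any(is.na(deck))) stop("invalid deck ids for subject ", id)
    list(deck = deck, net = as.numeric(tr$net),
         group = if (is.null(tr$group)) NA_character_ else as.character(tr$group[1]))
  })
  names(dat) <- as.character(ids)
  dat
}

# one adaptive Metropolis-within-Gibbs chain; returns natural-scale draws
.pvl_chain <- function(dat, priors, burnin, draws, rule, payoff_scale,
                       use_lik, thin = 1L) {
  S <- length(dat)
  z <- matrix(rnorm(S * 4, 0, 0.5), S, 4)
  mu <- rnorm(4, 0, 0.5)
  lsig <- rnorm(4, log(0.5), 0.2)
  step <- matrix(0.5, S, 4)
  sstep <- rep(0.5, 4)
  loglik_s <- function(s, zrow) {
    if (!use_lik) return(0)
    p <- .pvl_link(zrow)
    pvl_loglik_cpp(dat[[s]]$deck, dat[[s]]$net, p[["a"]], p[["lambda"]],
                   p[["A"]], p[["c"]], rule, payoff_scale, 1e-12)
  }
  cur_ll <- vapply(seq_len(S), function(s) loglik_s(s, z[s, ]), numeric(1))
  n_iter <- burnin + draws * thin
  keep <- matrix(NA_real_, draws, 8 + 4 * S)
  k <- 0L
  for (it in seq_len(n_iter)) {
    adapting <- it <= burnin
    sig <- exp(lsig)
    # subject-level raw parameters. With the likelihood disabled their full
    # conditional is exactly N(mu, sigma): draw it directly. Otherwise,
    # componentwise random-walk MH against the PVL likelihood.
    for (p in 1:4) {
      if (!use_lik) {
        z[, p] <- rnorm(S, mu[p], sig[p])
        next
      }
      prop <- z[, p] + step[, p] * rnorm(S)
      for (s in seq_len(S)) {
        znew <- z[s, ]; znew[p] <- prop[s]
        ll_new <- loglik_s(s, znew)
        lacc <- ll_new - cur_ll[s] +
          dnorm(prop[s], mu[p], sig[p], log = TRUE) -
          dnorm(z[s, p], mu[p], sig[p], log = TRUE)
        acc <- is.finite(lacc) && log(runif(1)) < lacc
        if (acc) { z[s, p] <- prop[s]; cur_ll[s] <- ll_new }
        if (adapting)
          step[s, p] <- step[s, p] * exp(0.05 * ((if (acc) 1 else 0) - 0.44))
      }
    }
    # group means: conjugate normal update
    for (p in 1:4) {
      prec <- 1 / priors$mu_scale^2 + S / sig[p]^2
      m <- (priors$mu_loc / priors$mu_scale^2 + sum(z[, p]) / sig[p]^2) / prec
      mu[p] <- rnorm(1, m, sqrt(1 / prec))
    }
    # group SDs: random-walk MH on log sigma (half-normal prior + Jacobian)
    for (p in 1:4) {
      lp <- lsig[p] + sstep[p] * rnorm(1)
      sp <- exp(lp)
      lacc <- sum(dnorm(z[, p], mu[p], sp, log = TRUE)) -
        sum(dnorm(z[, p], mu[p], sig[p], log = TRUE)) +
        dnorm(sp, 0, priors$sigma_scale, log = TRUE) -
        dnorm(sig[p], 0, priors$sigma_scale, log = TRUE) +
        lp - lsig[p]
      acc <- is.finite(lacc) && log(runif(1)) < lacc
      if (acc) lsig[p] <- lp
      if (adapting) sstep[p] <- sstep[p] * exp(0.05 * ((if (acc) 1 else 0) - 0.44))
    }
    if (it > burnin && (it - burnin) %% thin == 0L) {
      k <- k + 1L
      keep[k, ] <- c(.pvl_link(mu), exp(lsig), as.vector(t(.pvl_link(z))))
    }
  }
  pn <- c("a", "lambda", "A", "c")
  colnames(keep) <- c(paste0("group_", pn), paste0("sigma_", pn),
                      paste0(rep(names(dat), each = 4), ".", pn))
  keep
}

#' Hierarchical Bayesian PVL fit for one group of subjects
#'
#' Subject-level parameters are drawn (through probit links, see
#' [pvl_priors()]) from group-level normal distributions, and the joint
#' posterior is sampled by an adaptive Metropolis-within-Gibbs scheme:
#' componentwise random-walk updates on each subject's raw parameters against
#' the exact PVL likelihood (the same compiled routine used by [pvl_loglik()]
#' and [fit_mle()]), conjugate updates for the group means, and random-walk
#' updates on the log group SDs. Proposal scales adapt during burn-in only.
#' The default sampler configuration is 3 chains, 500 burn-in iterations and
#' 1,000 kept draws per chain. Convergence is monitored by split-chain R-hat;
#' any parameter with R-hat > 1.1 flags the fit as non-converged (returned
#' with a warning, never silently).
#'
#' @param trials trial table (one group) with subject_id, deck, net columns;
#'   practice rows are dropped.
#' @param priors a [pvl_priors()] specification.
#' @param chains,burnin,draws sampler configuration.
#' @param seed integer master seed; per-chain seeds derive from it.
#' @param likelihood set \code{FALSE} to sample the prior only (used to
#'   validate the sampler against direct prior simulation).
#' @inheritParams fit_mle
#' @return object of class \code{pvl_hfit}: \code{group} (posterior summary
#'   of the link-transformed group means, one row per parameter),
#'   \code{subjects} (per-subject posterior means/SDs/95% intervals with
#'   R-hat and ESS), \code{draws} (per-chain natural-scale draw matrices),
#'   \code{converged}, and the sampler configuration.
#' @export
fit_hierarchical <- function(trials, priors = pvl_priors(), chains = 3L,
                             burnin = 500L, draws = 1000L, seed = NULL,
                             theta_rule = c("as_printed", "trial_dependent"),
                             payoff_scale = 0.01, likelihood = TRUE) {
  theta_rule <- match.arg(theta_rule)
  stopifnot(chains >= 1, burnin >= 0, draws >= 1)
  dat <- .split_trials_by_subject(trials)
  rule <- .theta_rule_code(theta_rule)
  ch <- lapply(seq_len(chains), function(i) {
    if (!is.null(seed)) set.seed((seed + 7919L * i) %% .Machine$integer.max)
    .pvl_chain(dat, priors, burnin, draws, rule, payoff_scale, likelihood)
  })
  all_draws <- do.call(rbind, ch)
  pn <- c("a", "lambda", "A", "c")
  cols <- colnames(all_draws)
  summarise_col <- function(cn) {
    x <- all_draws[, cn]
    c(mean = mean(x), sd = sd(x),
      lo = unname(quantile(x, 0.025)), hi = unname(quantile(x, 0.975)),
      rhat = split_rhat(lapply(ch, function(m) m[, cn])),
      ess = ess_autocorr(lapply(ch, function(m) m[, cn])))
  }
  gs <- t(vapply(paste0("group_", pn), summarise_col, numeric(6)))
  group <- data.frame(parameter = pn, gs, row.names = NULL)
  ids <- names(dat)
  subj <- do.call(rbind, lapply(ids, function(id) {
    s <- t(vapply(paste0(id, ".", pn), summarise_col, numeric(6)))
    data.frame(subject_id = id, group_label = dat[[id]]$group, parameter = pn,
               s, row.names = NULL, stringsAsFactors = FALSE)
  }))
  converged <- all(is.finite(c(group$rhat, subj$rhat))) &&
    all(c(group$rhat, subj$rhat) <= 1.1)
  fit <- structure(list(group = group, subjects = subj, draws = ch,
                        converged = converged,
                        config = list(chains = chains, burnin = burnin,
                                      draws = draws, seed = seed,
                                      theta_rule = theta_rule,
                                      payoff_scale = payoff_scale,
                                      likelihood = likelihood,
                                      point_estimate = "posterior_mean")),
                   class = "pvl_hfit")
  if (!converged)
    warning("hierarchical fit flagged non-converged: some R-hat > 1.1 ",
            "(or undefined); inspect convergence_report(fit)")
  fit
}

#' @export
print.pvl_hfit <- function(x, ...) {
  cfg <- x$config
  cat("Hierarchical PVL fit:", length(unique(x$subjects$subject_id)),
      "subjects,", cfg$chains, "chains x", cfg$draws, "draws (burn-in",
      cfg$burnin, ")\n")
  if (!cfg$likelihood) cat("  [prior-only sampling]\n")
  cat("Group-level posterior (link-transformed group means):\n")
  print(cbind(parameter = x$group$parameter,
              round(x$group[, c("mean", "sd", "lo", "hi", "rhat")], 3)))
  if (!x$converged) cat("WARNING: flagged non-converged (R-hat > 1.1)\n")
  invisible(x)
}

#' Per-subject posterior-mean point estimates from a hierarchical fit
#'
#' One row per subject in the layout expected by the group statistics
#' (same columns as [fit_mle_cohort()]).
#'
#' @param fit a \code{pvl_hfit}.
#' @return data frame: subject_id, group, a, lambda, A, c, method.
#' @export
hier_point_estimates <- function(fit) {
  stopifnot(inherits(fit, "pvl_hfit"))
  s <- fit$subjects
  ids <- unique(s$subject_id)
  wide <- data.frame(subject_id = ids,
                     group = s$group_label[match(ids, s$subject_id)],
                     stringsAsFactors = FALSE)
  for (p in c("a", "lambda", "A", "c")) {
    sp <- s[s$parameter == p, ]
    wide[[p]] <- sp$mean[match(ids, sp$subject_id)]
  }
  wide$method <- "hierarchical_posterior_mean"
  wide
}

#' Split-chain R-hat (potential scale reduction)
#'
#' Each chain is split in half and the classic between/within variance ratio
#' is computed over the split chains. Returns \code{NA} for degenerate chains
#' (zero within-chain variance), which callers treat as flagged.
#'
#' @param chains list of numeric vectors (one per chain, equal lengths).
#' @return scalar R-hat, or NA if undefined.
#' @export
split_rhat <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1)
  half <- unlist(lapply(chains, function(x) {
    n <- length(x) %/% 2L
    list(x[seq_len(n)], x[n + seq_len(n)])
  }), recursive = FALSE)
  n <- length(half[[1]])
  if (n < 2L) return(NA_real_)
  m <- length(half)
  means <- vapply(half, mean, numeric(1))
  vars <- vapply(half, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Autocorrelation-based effective sample size
#'
#' Geyer-style initial-positive-sequence estimate: lag autocorrelations
#' (averaged over chains) are summed in consecutive pairs until a pair sum
#' turns negative. Returns 0 for degenerate (constant) chains.
#'
#' @inheritParams split_rhat
#' @return scalar effective sample size (capped at the total draw count).
#' @export
ess_autocorr <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 1)
  n <- length(chains[[1]])
  m <- length(chains)
  if (n < 4L) return(NA_real_)
  if (all(vapply(chains, function(x) var(x) == 0 || !is.finite(var(x)),
                 logical(1)))) return(0)
  max_lag <- min(n - 1L, 200L)
  rho <- rowMeans(vapply(chains, function(x) {
    if (var(x) == 0) rep(0, max_lag + 1L)
    else as.numeric(acf(x, lag.max = max_lag, plot = FALSE)$acf)
  }, numeric(max_lag + 1L)))
  s <- 0
  t <- 1L
  while (t + 1L <= max_lag) {
    pair <- rho[t + 1L] + rho[t + 2L]
    if (!is.finite(pair) || pair < 0) break
    s <- s + pair
    t <- t + 2L
  }
  min(m * n, m * n / (1 + 2 * s))
}

#' Convergence diagnostics for a hierarchical fit
#'
#' Split-chain R-hat and effective sample size for every group-level and
#' subject-level parameter, flagged against the R-hat > 1.1 threshold
#' (undefined R-hat, e.g. constant chains, is also flagged).
#'
#' @param fit a \code{pvl_hfit}.
#' @return data frame: level, id, parameter, rhat, ess, flagged.
#' @export
convergence_report <- function(fit) {
  stopifnot(inherits(fit, "pvl_hfit"))
  cols <- colnames(fit$draws[[1]])
  rows <- lapply(cols, function(cn) {
    series <- lapply(fit$draws, function(m) m[, cn])
    rh <- split_rhat(series)
    data.frame(level = if (grepl("^(group|sigma)_", cn)) "group" else "subject",
               id = sub("\\.[^.]+$", "", sub("^(group|sigma)_.*$", "-", cn)),
               parameter = sub("^.*[._]", "", cn),
               rhat = rh, ess = ess_autocorr(series),
               flagged = !is.finite(rh) || rh > 1.1,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
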