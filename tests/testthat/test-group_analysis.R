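test_that("group ANCOVA reduces to one-way ANOVA and handles degeneracy", {
  set.seed(15)
  y <- c(rnorm(20, 10), rnorm(20, 12))
  g <- rep(c("x", "y"), each = 20)
  # sums-of-squares oracle for the classical one-way F
  gm <- mean(y)
  ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  F_oracle <- (ss_b / 1) / (ss_w / 38)
  r0 <- ancova_group(y, g)
  expect_equal(r0$statistic, F_oracle, tolerance = 1e-10)
  expect_equal(r0$df1, 1); expect_equal(r0$df2, 38)
  expect_equal(r0$effect_size, ss_b / (ss_b + ss_w), tolerance = 1e-10)
  # a covariate orthogonal to outcome and design has exactly zero effect:
  # the group F equals the classical form with one residual df spent
  z_raw <- rnorm(40)
  z <- residuals(lm(z_raw ~ y + factor(g)))
  r1 <- ancova_group(y, g, data.frame(z = z))
  expect_equal(r1$statistic, (ss_b / 1) / (ss_w / 37), tolerance = 1e-8)
  expect_equal(r1$df2, 37)
  # identical groups: F = 0, p = 1
  r2 <- ancova_group(rep(c(1, 2), 10), rep(c("x", "y"), each = 10))
  expect_equal(r2$statistic, 0, tolerance = 1e-20)
  expect_equal(r2$p, 1)
  # covariate collinear with the group indicator is rejected
  expect_error(ancova_group(y, g, data.frame(z = as.numeric(g == "x"))),
               "rank-deficient|collinear")
})

test_that("mixed block ANCOVA has the study's df layout and tags follow-ups", {
  set.seed(16)
  n1 <- 42; n2 <- 43
  Y <- matrix(rnorm((n1 + n2) * 5), n1 + n2, 5)
  g <- rep(c("high_risk", "control"), c(n1, n2))
  covs <- data.frame(sds = rnorm(n1 + n2, 44, 8),
                     stai_state = rnorm(n1 + n2, 53, 12),
                     stai_trait = rnorm(n1 + n2, 45, 12))
  m <- mixed_block_ancova(Y, g, covs, followups = TRUE)
  expect_equal(m$main$df1, c(1, 4, 4))
  expect_equal(m$main$df2, c(80, 320, 320))
  expect_true(all(m$main$p >= 0 & m$main$p <= 1))
  expect_true(all(m$main$effect_size >= 0 & m$main$effect_size <= 1))
  expect_equal(m$per_block$adjustment, rep("bonferroni_5", 5))
  expect_equal(m$per_block$df2, rep(80, 5))
  expect_equal(m$per_group$adjustment, rep("bonferroni_2", 2))
  # per-group repeated-measures df: (4, 4*(n-1))
  expect_setequal(m$per_group$df2, c(4 * (n1 - 1), 4 * (n2 - 1)))
  expect_true(is.finite(m$gg$epsilon) && m$gg$epsilon <= 1)
  # constant scores: every effect reported null
  mc <- mixed_block_ancova(matrix(5, 20, 5), rep(c("a", "b"), 10))
  expect_equal(mc$main$statistic, rep(0, 3))
  expect_equal(mc$main$p, rep(1, 3))
  expect_error(mixed_block_ancova(Y[, 1:4], g), "5 block")
})

test_that("a group-specific block trend is detected as an interaction", {
  set.seed(18)
  hits <- 0
  for (r in 1:100) {
    n1 <- 42; n2 <- 43
    flat <- matrix(rnorm(n1 * 5, 0, 6), n1, 5)
    rising <- matrix(rnorm(n2 * 5, 0, 6), n2, 5) +
      matrix(rep(seq(0, 8, length.out = 5), each = n2), n2, 5)
    m <- mixed_block_ancova(rbind(flat, rising),
                            rep(c("high_risk", "control"), c(n1, n2)))
    if (m$main$p[m$main$test == "block:group"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 90)
})

test_that("Mann-Whitney U matches brute-force pair counting", {
  r1 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r1$statistic, 0)
  expect_equal(r1$U_x, 0)
  # brute-force count over all 4 cross-pairs of x=[1,3], y=[2,4]
  x <- c(1, 3); y <- c(2, 4)
  U_brute <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  r2 <- mann_whitney(x, y)
  expect_equal(r2$U_x, U_brute)
  expect_equal(r2$U_x, 1)
  # identical samples: U = n1*n2/2 by midrank symmetry
  r3 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r3$statistic, 4.5)
  # U_x + U_y = n1*n2 on random inputs, p-values in [0,1]
  set.seed(20)
  for (i in 1:20) {
    a <- rnorm(sample(2:30, 1)); b <- rnorm(sample(2:30, 1))
    r <- mann_whitney(a, b)
    expect_equal(r$U_x + r$U_y, length(a) * length(b))
    expect_true(r$p >= 0 && r$p <= 1)
    expect_true(r$p_one >= 0 && r$p_one <= 1)
  }
})

test_that("exact and approximate Mann-Whitney p-values agree", {
  set.seed(22)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(10, 0.5)
    r <- mann_whitney(x, y)
    expect_equal(r$method, "exact")
    # cross-check the exact p against the independent stats implementation
    w <- suppressWarnings(wilcox.test(x, y, exact = TRUE, correct = FALSE))
    expect_equal(r$p, w$p.value, tolerance = 1e-12)
    # tie-corrected normal approximation within 0.02 of exact
    big <- mann_whitney(c(x, 100 + rnorm(50)), c(y, 100 + rnorm(50)))
    expect_equal(big$method, "normal_tie_corrected")
    expect_lt(abs(r$p - {  # force the normal path on the same small sample
      rr <- rank(c(x, y))
      Ux <- sum(rr[1:10]) - 55
      sigma <- sqrt(10 * 10 * 21 / 12)
      min(1, 2 * min(pnorm((Ux - 50 + 0.5) / sigma),
                     pnorm((50 - Ux + 0.5) / sigma)))
    }), 0.02)
  }
})

test_that("Pearson r matches the covariance formula and flags degeneracy", {
  x <- c(1, 2, 4, 7, 11)
  expect_equal(pearson_r(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_r(x, -x)$statistic, -1)
  y <- c(3, 1, 4, 1, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- pearson_r(x, y)
  expect_equal(r$statistic, r_hand, tolerance = 1e-12)
  expect_equal(r$df1, 3)
  expect_error(pearson_r(x, rep(2, 5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("bootstrapped correlation is seeded and degenerate-safe", {
  x <- c(1, 2, 3, 4, 5, 6)
  b1 <- bootstrap_pearson(x, x + rnorm(6, sd = 0.1), n_boot = 1000, seed = 4)
  b2 <- bootstrap_pearson(x, x + rnorm(6, sd = 0.1), n_boot = 1000, seed = 4)
  # observed r is data-determined, invariant to seed and n_boot
  set.seed(30)
  y <- rnorm(20); z <- rnorm(20)
  o1 <- bootstrap_pearson(y, z, n_boot = 1000, seed = 1)
  o2 <- bootstrap_pearson(y, z, n_boot = 2000, seed = 99)
  expect_equal(o1$statistic, o2$statistic)
  expect_equal(o1$statistic, cor(y, z))
  o3 <- bootstrap_pearson(y, z, n_boot = 1000, seed = 1)
  expect_equal(o1$ci_lo, o3$ci_lo)
  expect_equal(o1$ci_hi, o3$ci_hi)
  # y = x exactly: every resample has r = 1
  d <- bootstrap_pearson(x, x, n_boot = 1000, seed = 2)
  expect_equal(c(d$ci_lo, d$ci_hi), c(1, 1))
  expect_error(bootstrap_pearson(y, z, n_boot = 10), "n_boot")
})

test_that("pooled t matches the hand formula and the study's df", {
  x <- c(1, 2, 3); y <- c(3, 4, 5)
  sp2 <- (2 * var(x) + 2 * var(y)) / 4
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  r <- welch_t(x, y)
  expect_equal(r$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r$df1, 4)
  set.seed(33)
  r2 <- welch_t(rnorm(42), rnorm(43))
  expect_equal(r2$df1, 83)
  expect_equal(welch_t(x, x)$statistic, 0)
  expect_equal(welch_t(x, x)$p, 1)
  rw <- welch_t(c(x, 10), y, pooled = FALSE)
  expect_equal(rw$method, "welch")
})

test_that("the full battery runs end to end on a synthetic cohort", {
  coh <- generate_cohort(cohort_config(n_high_risk = 12, n_control = 12),
                         seed = 55)
  est <- fit_mle_cohort(coh$trials, n_starts = 3, seed = 56)
  res <- analyze_cohort(coh, est, n_boot = 1000, seed = 57)
  expect_s3_class(res$total_net, "data.frame")
  expect_equal(nrow(res$deck_counts), 4)
  expect_equal(nrow(res$parameters), 4)
  expect_true(all(res$parameters$p >= 0 & res$parameters$p <= 1))
  expect_true(all(grepl("net_vs_", res$correlations$test)))
  # round-trip through the delimited-text interface
  dir <- tempfile("cohort")
  paths <- write_cohort(coh, dir)
  tr <- read_trials(paths[["trials"]])
  expect_equal(nrow(tr), nrow(coh$trials))
  expect_identical(cohort_scores(tr)$total_net, cohort_scores(coh)$total_net)
})
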