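test_that("prospect utility matches its defining cases", {
  expect_equal(pvl_utility(100, a = 1, lambda = 1), 100)
  expect_equal(pvl_utility(0, a = 0.5, lambda = 3), 0)
  # high-precision scalar evaluation at the reported high-risk group means
  expect_equal(pvl_utility(-1250, a = 0.249, lambda = 0.355),
               -0.355 * exp(0.249 * log(1250)), tolerance = 1e-12)
  # lambda = 0 ignores losses entirely
  expect_equal(pvl_utility(c(-1, -500, -1250), a = 0.7, lambda = 0),
               c(0, 0, 0))
  # a = 1, lambda = 1 is the identity
  x <- c(-1250, -50, 0, 50, 100)
  expect_equal(pvl_utility(x, 1, 1), x)
  expect_error(pvl_utility(1, a = 2, lambda = 1), "out of range")
})

test_that("utility is monotone in x and in lambda", {
  x <- seq(-20, 20, by = 0.5)
  for (pars in list(c(0.3, 0.5), c(1, 2), c(0.7, 0))) {
    u <- pvl_utility(x, pars[1], pars[2])
    expect_true(all(diff(u) >= 0))
    expect_equal(sign(u[pars[2] > 0 | x >= 0]), sign(x[pars[2] > 0 | x >= 0]))
  }
  u_lo <- pvl_utility(x, 0.5, 0.2)
  u_hi <- pvl_utility(x, 0.5, 2)
  expect_true(all(u_hi[x < 0] <= u_lo[x < 0]))
  expect_equal(u_hi[x >= 0], u_lo[x >= 0])
})

test_that("expectancy update applies decay and credits only the chosen deck", {
  expect_equal(update_expectancies(c(0, 0, 0, 0), "B", u = -2, A = 0.5),
               c(0, -2, 0, 0))
  expect_equal(update_expectancies(c(1, 2, 3, 4), "A", u = 0, A = 1),
               c(1, 2, 3, 4))
  # hand evaluation of the recursion
  expect_equal(update_expectancies(c(1, 2, 3, 4), "C", u = 10, A = 0.5),
               c(0.5, 1, 11.5, 2))
  expect_error(update_expectancies(c(1, 2, 3, 4), "E", 1, 0.5), "unknown deck")
  # A = 0 is memoryless; A = 1 accumulates running sums
  E <- c(5, 6, 7, 8)
  expect_equal(update_expectancies(E, "D", 3, A = 0), c(0, 0, 0, 3))
  expect_equal(update_expectancies(E, "D", 3, A = 1), c(5, 6, 7, 11))
})

test_that("consistency theta follows the printed and trial-dependent rules", {
  expect_equal(consistency_theta(0, 1, "as_printed"), 0)
  expect_equal(consistency_theta(1, 99, "as_printed"), 2)
  expect_equal(consistency_theta(2, 10, "trial_dependent"), 1)
  expect_equal(consistency_theta(0.5, 40, "trial_dependent"), 2)
  expect_error(consistency_theta(6, 1), "0, 5")
})

test_that("choice probabilities are a stabilized softmax", {
  expect_equal(choice_probabilities(c(9, -3, 0.5, 2), c = 0), rep(0.25, 4))
  expect_equal(choice_probabilities(c(1, 1, 1, 1), c = 3), rep(0.25, 4))
  # brute-force softmax evaluation at theta = 3^1 - 1 = 2
  expect_equal(choice_probabilities(c(1, 0, 0, 0), c = 1),
               c(exp(2), 1, 1, 1) / (exp(2) + 3), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:50) {
    E <- rnorm(4, sd = 10^runif(1, -2, 3))
    p <- choice_probabilities(E, c = runif(1, 0, 5))
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
})

test_that("the agent is reproducible and uniform at c = 0", {
  params <- pvl_params(0.3, 1, 0.6, 1)
  a1 <- simulate_agent(params, n_trials = 50, n_practice = 20, seed = 99)
  a2 <- simulate_agent(params, n_trials = 50, n_practice = 20, seed = 99)
  expect_identical(a1, a2)
  expect_equal(sum(a1$is_practice), 20)
  expect_equal(a1$net, a1$gain + a1$loss)
  expect_true(all(a1$loss <= 0) && all(a1$gain > 0))

  unif <- simulate_agent(pvl_params(0.5, 2, 0.3, 0), n_trials = 10000, seed = 4)
  freq <- table(factor(unif$deck, levels = c("A", "B", "C", "D"))) / 10000
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_true(all(abs(freq - 0.25) < 3.5 * se))
})

test_that("a consistent agent locks onto the high-expectancy deck", {
  # no-loss schedule in which deck D pays 100 and the others 1: after the
  # first selection of D its expectancy dwarfs the rest, and with c = 5
  # (theta = 242) a consistent agent should almost never leave it
  sched <- igt_schedule(gain = c(A = 1, B = 1, C = 1, D = 100),
                        loss_events = c(A = 0, B = 0, C = 0, D = 0),
                        loss_magnitude = c(A = 1, B = 1, C = 1, D = 1))
  params <- pvl_params(a = 1, lambda = 1, A = 1, c = 5)
  stick <- vapply(1:200, function(s) {
    tr <- simulate_agent(params, sched, n_trials = 50, seed = 1000 + s)
    first_d <- match("D", tr$deck)
    if (is.na(first_d) || first_d == 50) return(NA_real_)
    after <- tr$deck[(first_d + 1):50]
    mean(after == "D")
  }, numeric(1))
  expect_gt(mean(stick, na.rm = TRUE), 0.95)
})

test_that("log-likelihood matches analytic limits", {
  one <- data.frame(deck = "B", net = -1150)
  expect_equal(pvl_loglik(one, pvl_params(0.9, 4, 0.2, 3)), log(0.25))
  seq10 <- random_sequence(10)
  expect_equal(pvl_loglik(seq10, pvl_params(0.5, 1, 0.5, 0)), 10 * log(0.25))
  expect_error(pvl_loglik(seq10[0, ], pvl_params(0.5, 1, 0.5, 0.5)), "empty")
  expect_error(pvl_loglik(seq10, c(a = 2, lambda = 1, A = 0.5, c = 1)),
               "out of range")
})

test_that("log-likelihood equals a step-by-step hand recomputation", {
  # 3-trial sequence recomputed explicitly: a=0.5, lambda=1, A=0.5, c=1
  tr <- data.frame(deck = c("B", "B", "C"), net = c(100, -1150, 50))
  th <- 3^1 - 1
  s <- 0.01
  p1 <- 0.25                                  # all-zero state
  E <- 0.5 * c(0, 0, 0, 0); E[2] <- E[2] + sqrt(100 * s)
  p2 <- exp(th * E[2]) / sum(exp(th * E))
  E <- 0.5 * E; E[2] <- E[2] - sqrt(1150 * s)
  p3 <- exp(th * E[3]) / sum(exp(th * E))
  expect_equal(pvl_loglik(tr, pvl_params(0.5, 1, 0.5, 1)),
               log(p1) + log(p2) + log(p3), tolerance = 1e-12)
})

test_that("recursion-based likelihood matches the brute-force oracle", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(1:10, 1)
    seqn <- random_sequence(n)
    pars <- c(a = runif(1), lambda = runif(1, 0, 5),
              A = runif(1), c = runif(1, 0, 5))
    rule <- sample(c("as_printed", "trial_dependent"), 1)
    ll <- pvl_loglik(seqn, pars, theta_rule = rule)
    or <- oracle_loglik(match(seqn$deck, c("A", "B", "C", "D")), seqn$net,
                        pars["a"], pars["lambda"], pars["A"], pars["c"],
                        rule = rule)
    expect_lt(abs(ll - or), 1e-10)
  }
})

test_that("the generative and likelihood paths are self-consistent", {
  truth <- pvl_params(0.3, 1, 0.6, 1)
  up <- function(p, d) pmin(pmax(p + d, 0), 1)
  set.seed(21)
  diffs_A <- diffs_c <- numeric(200)
  for (i in 1:200) {
    tr <- simulate_agent(truth, n_trials = 100)
    ll0 <- pvl_loglik(tr, truth)
    llA <- pvl_loglik(tr, pvl_params(0.3, 1, up(0.6, 0.3 * sign(runif(1) - 0.5)), 1))
    llc <- pvl_loglik(tr, pvl_params(0.3, 1, 0.6, 1 + 0.3 * sign(runif(1) - 0.5)))
    diffs_A[i] <- ll0 - llA
    diffs_c[i] <- ll0 - llc
  }
  expect_gt(mean(diffs_A), 0)
  expect_gt(mean(diffs_c), 0)
})
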