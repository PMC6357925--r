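# Independent brute-force PVL log-likelihood: recomputes the expectancy state
# and softmax trial by trial with plain scalar R arithmetic. Kept deliberately
# separate from the package's compiled code path.
oracle_loglik <- function(deck, net, a, lam, A, cc,
                          rule = "as_printed", scale = 0.01,
                          floor = 1e-12) {
  E <- c(0, 0, 0, 0)
  ll <- 0
  for (t in seq_along(deck)) {
    th <- if (rule == "as_printed") 3^cc - 1 else (t / 10)^cc
    z <- th * E
    w <- exp(z - max(z))
    p <- w[deck[t]] / sum(w)
    ll <- ll + log(max(p, floor))
    x <- net[t] * scale
    u <- if (x >= 0) { if (x == 0) 0 else x^a } else -lam * (-x)^a
    E <- A * E
    E[deck[t]] <- E[deck[t]] + u
  }
  ll
}

# random choice sequence (deck indices 1-4 and net outcomes) as a data frame
random_sequence <- function(n) {
  deck_i <- sample.int(4, n, replace = TRUE)
  net <- sample(c(100, 50, -150, -1200, -200, 0, 25), n, replace = TRUE)
  data.frame(deck = c("A", "B", "C", "D")[deck_i], net = net)
}

# small cohort of simulated agents at one fixed parameter set
simulate_group <- function(n_subj, params, n_trials = 100, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_subj), function(i)
    cbind(subject_id = sprintf("S%03d", i),
          simulate_agent(params, n_trials = n_trials))))
}
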