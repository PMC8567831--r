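test_that("state space separates community nodes from their exit neighbours", {
  t1 <- toy_t1()
  ss <- build_state_space(t1$fc, t1$partition, "C")
  expect_identical(ss$s_trans, c("a", "b"))
  expect_identical(ss$s_abs, c("x", "y"))

  # community = whole graph has no absorbing states
  allc <- as_partition(stats::setNames(rep("C", 4), c("a", "b", "x", "y")))
  expect_error(build_state_space(t1$fc, allc, "C"),
               class = "fnmorph_degenerate_error")

  # exhaustive-scan oracle on a random modular graph
  inst <- random_chain_instance(n = 50, k = 8, seed = 3)
  ss50 <- build_state_space(inst$fc, inst$partition, "C")
  W <- inst$fc$weights
  outside <- setdiff(inst$fc$node_ids, ss50$s_trans)
  expected <- outside[vapply(outside,
                             function(j) any(W[ss50$s_trans, j] > 0), logical(1))]
  expect_identical(ss50$s_abs, expected)
})

test_that("terminating chain is row-stochastic with the printed block structure", {
  t1 <- toy_t1()
  ch <- terminating_chain(t1$fc, build_state_space(t1$fc, t1$partition, "C"))
  expect_equal(unname(ch$q_tt), matrix(c(0, .5, .5, 0), 2))
  expect_equal(ch$P["a", "x"], 0.5)
  expect_equal(ch$P["b", "y"], 0.5)
  expect_equal(unname(ch$P[3:4, 3:4]), diag(2))   # absorbing rows are unit vectors

  t2 <- toy_t2()
  ch2 <- terminating_chain(t2$fc, build_state_space(t2$fc, t2$partition, "C"))
  expect_equal(unname(ch2$P["a", ]), c(0, 0.9, 0.1))

  for (seed in 1:5) {
    inst <- random_chain_instance(n = 25, k = 5, seed = seed)
    ch <- terminating_chain(inst$fc, build_state_space(inst$fc, inst$partition, "C"))
    nt <- length(ch$s_trans)
    expect_equal(unname(rowSums(ch$P)[seq_len(nt)]), rep(1, nt), tolerance = 1e-10)
    expect_true(all(ch$P >= 0 & ch$P <= 1))
  }
})

test_that("zero-strength transient nodes raise an isolated-node error by name", {
  ids <- c("a", "b", "x")
  W <- matrix(0, 3, 3, dimnames = list(ids, ids))
  W["a", "x"] <- W["x", "a"] <- 1   # b has no edges at all
  fc <- as_connectome(W); fc$sanitized <- TRUE
  part <- as_partition(c(a = "C", b = "C", x = "O"))
  expect_error(terminating_chain(fc, list(community = "C", s_trans = c("a", "b"),
                                          s_abs = "x")),
               "b", class = "fnmorph_isolated_node_error")
})

test_that("absorption algebra matches the hand-solved toys", {
  t1 <- toy_t1()
  s <- absorption(t1$fc, t1$partition, "C")
  expect_equal(unname(s$Z), matrix(c(4, 2, 2, 4) / 3, 2), tolerance = 1e-12)
  expect_equal(unname(s$tau), c(2, 2), tolerance = 1e-12)
  expect_equal(unname(s$Psi), matrix(c(2, 1, 1, 2) / 3, 2), tolerance = 1e-12)
  expect_equal(s$exit_strength, 2)
  expect_equal(unname(s$psi), c(0.5, 0.5))

  t2 <- toy_t2()
  s2 <- absorption(t2$fc, t2$partition, "C")
  expect_equal(unname(s2$Z), matrix(1), tolerance = 1e-12)
  expect_equal(unname(s2$tau), 1)
  expect_equal(unname(drop(s2$Psi)), c(0.9, 0.1))
  expect_equal(s2$exit_strength, 1)
})

test_that("fundamental matrix equals the truncated Neumann series", {
  for (seed in c(2, 9)) {
    inst <- random_chain_instance(n = 30, k = 6, seed = seed)
    ch <- terminating_chain(inst$fc, build_state_space(inst$fc, inst$partition, "C"))
    s <- absorption_summary(ch)
    nt <- length(ch$s_trans)
    acc <- diag(nt); term <- diag(nt)
    for (k in seq_len(200)) {
      term <- term %*% ch$q_tt
      acc <- acc + term
    }
    expect_equal(unname(s$Z), unname(acc), tolerance = 1e-8)
  }
})

test_that("absorption quantities satisfy their normalization invariants", {
  for (seed in 1:8) {
    inst <- random_chain_instance(n = sample(10:40, 1), k = sample(2:6, 1),
                                  seed = seed)
    s <- absorption(inst$fc, inst$partition, "C")
    expect_true(all(s$tau >= 1))
    expect_equal(unname(rowSums(s$Psi)), rep(1, length(s$s_trans)),
                 tolerance = 1e-10)
    expect_equal(sum(s$psi), 1, tolerance = 1e-12)
    expect_true(all(s$Z >= -1e-12))
    # strength-weighted start is also a valid probability vector
    ch <- terminating_chain(inst$fc, build_state_space(inst$fc, inst$partition, "C"))
    psi_w <- exit_distribution(s$Psi, ch, start = "strength")
    expect_equal(sum(psi_w), 1, tolerance = 1e-12)
  }
})

test_that("node order of the input connectome does not affect tau or Psi", {
  inst <- random_chain_instance(n = 20, k = 5, seed = 13)
  s <- absorption(inst$fc, inst$partition, "C")
  set.seed(1)
  perm <- sample(inst$fc$node_ids)
  fc_p <- as_connectome(inst$fc$weights[perm, perm])
  fc_p$sanitized <- TRUE
  s_p <- absorption(fc_p, inst$partition, "C")
  expect_equal(s$tau[sort(names(s$tau))], s_p$tau[sort(names(s_p$tau))])
  expect_equal(s$Psi[sort(s$s_trans), sort(s$s_abs)],
               s_p$Psi[sort(s_p$s_trans), sort(s_p$s_abs)])
})

test_that("Monte-Carlo walkers reproduce the closed-form absorption law", {
  t2 <- toy_t2()
  ch <- terminating_chain(t2$fc, build_state_space(t2$fc, t2$partition, "C"))
  sim <- simulate_absorption(ch, n_walkers = 20000, seed = 5)
  expect_equal(unname(sim$tau_hat), 1)   # one-step absorption, exactly
  se <- sqrt(0.9 * 0.1 / 20000)
  expect_lt(abs(sim$Psi_hat[1, "x"] - 0.9), 3 * se)
  expect_equal(sim$n_exceeded, 0)

  # determinism under the seed
  sim2 <- simulate_absorption(ch, n_walkers = 20000, seed = 5)
  expect_identical(sim, sim2)
})
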