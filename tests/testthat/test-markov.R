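test_that("transition estimation cross-tabulates cell states", {
  s1 <- matrix(c(1L, 3L, 1L, 8L), 2, 2)  # core, edge / core, nonfarmland
  model <- suppressWarnings(estimate_transitions(s1, s1))
  expect_true(all(diag(model$P)[rowSums(model$C) > 0] == 1))
  expect_equal(sum(model$C), 4)
  # 2x2 toy: core,core / edge,nf  ->  core,edge / edge,nf
  t1 <- matrix(c(1L, 3L, 1L, 8L), 2, 2, byrow = TRUE)
  t2 <- matrix(c(1L, 3L, 3L, 8L), 2, 2, byrow = TRUE)
  m <- suppressWarnings(estimate_transitions(t1, t2))
  expect_equal(m$P["core", "core"], 0.5)
  expect_equal(m$P["core", "edge"], 0.5)
  expect_equal(m$P["edge", "edge"], 1)
  expect_equal(m$P["nonfarmland", "nonfarmland"], 1)
  # conservation: row sums of C equal t1 state counts
  expect_equal(unname(rowSums(m$C)[c("core", "edge", "nonfarmland")]),
               c(2, 1, 1))
  expect_error(estimate_transitions(t1, matrix(1L, 3, 2)), "shape mismatch")
  expect_error(estimate_transitions(matrix(9L, 2, 2), t2), "unknown state")
  expect_warning(estimate_transitions(t1, t2), "absent")
})

test_that("mspa maps feed the chain with the background as non-farmland", {
  fx <- generate_fixture("dumbbell")
  m <- mspa_segment(fx$landscape)
  tm <- suppressWarnings(estimate_transitions(m, m))
  expect_equal(unname(tm$C["nonfarmland", "nonfarmland"]),
               sum(m$labels == 1L))
  expect_equal(tm$P, diag(8), ignore_attr = TRUE)
})

test_that("stationary distribution satisfies pi P = pi", {
  tm <- transition_model(matrix(0.5, 2, 2))
  expect_equal(unname(stationary_distribution(tm)), c(0.5, 0.5))
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  pi <- stationary_distribution(transition_model(P))
  expect_equal(unname(pi), c(2 / 3, 1 / 3))
  expect_warning(pi_id <- stationary_distribution(transition_model(diag(2))),
                 "reducible")
  expect_equal(sum(pi_id), 1)
  expect_equal(as.numeric(pi_id %*% diag(2)), as.numeric(pi_id))
})

test_that("convergence rate is the reciprocal subdominant modulus", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  expect_equal(convergence_rate(transition_model(P)), 1 / 0.7)
  # uniform rows: lambda2 = 0, one-step convergence
  expect_equal(convergence_rate(transition_model(matrix(0.25, 4, 4))), Inf)
  expect_warning(r <- convergence_rate(transition_model(diag(2))), "modulus 1")
  expect_equal(r, 1)
})

test_that("normalized entropy matches hand evaluation and its endpoints", {
  expect_equal(suppressWarnings(
    normalized_entropy(transition_model(diag(3)))), 0)
  expect_equal(normalized_entropy(transition_model(matrix(1 / 5, 5, 5))), 1)
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  hand <- (-(2 / 3) * (0.9 * log(0.9) + 0.1 * log(0.1))
           - (1 / 3) * (0.2 * log(0.2) + 0.8 * log(0.8))) / log(2)
  expect_equal(normalized_entropy(transition_model(P)), hand)
  # spectral quantities are bit-reproducible across calls
  tm <- transition_model(P)
  expect_identical(convergence_rate(tm), convergence_rate(tm))
  expect_identical(normalized_entropy(tm), normalized_entropy(tm))
})

test_that("entropy weighting follows the stationary mass of the rows", {
  # same rows, entropy placed on a heavy vs a light state
  noisy <- c(0.5, 0.5, 0); quiet <- c(0.05, 0.9, 0.05)
  # heavy state 2 noisy:
  P1 <- rbind(c(0.9, 0.1, 0), c(0.3, 0.4, 0.3), c(0, 0.1, 0.9))
  # reverse: make state 2 nearly deterministic, put noise on state 1
  P2 <- rbind(c(0.4, 0.3, 0.3), c(0.05, 0.9, 0.05), c(0, 0.1, 0.9))
  h1 <- normalized_entropy(transition_model(P1))
  h2 <- normalized_entropy(transition_model(P2))
  pi2 <- stationary_distribution(transition_model(P2))
  # the noisy row of P2 carries little stationary mass, so H drops
  expect_lt(pi2[1], 1 / 3)
  expect_lt(h2, h1)
})

test_that("conversion sources decompose flow into a sink", {
  C <- matrix(0, 8, 8, dimnames = list(markov_states(), markov_states()))
  C["islet", "nonfarmland"] <- 30
  C["branch", "nonfarmland"] <- 45
  C["core", "nonfarmland"] <- 25
  diag(C) <- 100
  model <- fragscape:::transition_model_from_counts(C)
  sh <- conversion_sources(model, "nonfarmland")
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  expect_equal(unname(sh["islet"] + sh["branch"]), 0.75)
  C2 <- C * 0; C2["core", "edge"] <- 10; diag(C2) <- 1
  m2 <- fragscape:::transition_model_from_counts(C2)
  expect_equal(unname(conversion_sources(m2, "edge")["core"]), 1)
  expect_error(conversion_sources(m2, "islet"), "no conversion flow")
  expect_error(conversion_sources(m2, "water"), "unknown sink")
})

test_that("projection converges geometrically at rate lambda2", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  tm <- transition_model(P)
  expect_equal(project_chain(tm, c(1, 0), 0), matrix(c(1, 0), 1),
               ignore_attr = TRUE)
  traj <- project_chain(tm, c(1, 0), 20)
  pi <- stationary_distribution(tm)
  d <- apply(traj, 1, function(x) sum(abs(x - pi)))
  ratios <- d[-1] / utils::head(d, -1)
  expect_equal(unname(ratios[5:15]), rep(0.7, 11), tolerance = 1e-6)
  # uniform chain converges in one step
  u <- transition_model(matrix(0.5, 2, 2))
  expect_equal(unname(project_chain(u, c(1, 0), 1)[2, ]), c(0.5, 0.5))
  expect_error(project_chain(tm, c(1, 0), -1), ">= 0")
})

test_that("a chain simulated at known P is recovered from 100k cells", {
  states <- markov_states()
  # every row carries the same probability pattern (persistence 0.9, one
  # featured conversion 0.07, six rare moves), so the normalized entropy is
  # insensitive to the conditioning of the stationary vector and the
  # tolerance measures estimation error alone
  P <- matrix(0.005, 8, 8, dimnames = list(states, states))
  diag(P) <- 0.9
  P["core", "edge"] <- 0.07
  P["perforation", "edge"] <- 0.07
  P["edge", "nonfarmland"] <- 0.07
  P["islet", "nonfarmland"] <- 0.07
  P["bridge", "branch"] <- 0.07
  P["loop", "bridge"] <- 0.07
  P["branch", "nonfarmland"] <- 0.07
  P["nonfarmland", "islet"] <- 0.07
  P <- P / rowSums(P)
  set.seed(99)
  n <- 1e5
  # all states well represented so every row is estimated from >= 10k cells
  s1 <- sample.int(8, n, replace = TRUE, prob = rep(1 / 8, 8))
  s2 <- vapply(s1, function(i) sample.int(8, 1, prob = P[i, ]), 0L)
  dim(s1) <- dim(s2) <- c(250, 400)
  est <- estimate_transitions(s1, s2)
  expect_lt(max(abs(est$P - P)), 0.01)
  true_sum <- chain_summary(transition_model(P))
  est_sum <- chain_summary(est)
  expect_lt(abs(est_sum$rho - true_sum$rho) / true_sum$rho, 0.02)
  expect_lt(abs(est_sum$entropy - true_sum$entropy) / true_sum$entropy, 0.02)
})

test_that("probability matrices round-trip through CSV", {
  P <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  p <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(P, p)
  tm <- read_transition_matrix(p)
  expect_equal(tm$P, P)
  expect_error(transition_model(matrix(c(0.5, 0.6, 0.6, 0.4), 2, 2)),
               "row-stochastic")
})
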