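# Threshold dynamics: stepping, frozen cores, convergence classification.

test_that("single-step updates follow the sign of the local field", {
  zero_net <- threshold_network(matrix(0, 3, 3))
  expect_identical(step_state(zero_net, c(1, -1, 1)), c(0, 0, 0))
  # positive-zero variant: source nodes lock at +1 instead
  expect_identical(step_state(zero_net, c(1, -1, 1),
                              sign_variant = "positive"), c(1, 1, 1))

  diag_net <- threshold_network(diag(c(2, 1, 3)))
  s <- c(1, -1, 1)
  expect_identical(step_state(diag_net, s), s)

  ff <- fixture_flipflop()$network
  expect_identical(step_state(ff, c(1, 1)), c(1, -1))

  expect_error(step_state(ff, c(1, 1, 1)), "length")
  expect_error(step_state(ff, c(1, 2)), "entries")
})

test_that("synchronous flip-flop dynamics is a period-4 orbit, never frozen", {
  ff <- fixture_flipflop()$network
  r <- run_dynamics(ff, s0 = c(1, 1), burn_in = 0, window = 8,
                    update_fraction = 1, record = TRUE, seed = 1)
  orbit <- list(c(1, 1), c(1, -1), c(-1, -1), c(-1, 1))
  for (t in 0:8)
    expect_identical(r$trajectory[, t + 1], as.integer(orbit[[t %% 4 + 1]]))
  expect_identical(r$frozen_fraction, 0)
  expect_identical(r$classification, "none")
})

test_that("compiled simulator agrees with the pure-R step on synchronous runs", {
  set.seed(42)
  W <- matrix(rnorm(64), 8, 8) * (matrix(runif(64), 8) < 0.4)
  net <- threshold_network(W, bias = rnorm(8, sd = 0.3))
  s0 <- sample(c(-1L, 1L), 8, replace = TRUE)
  r <- run_dynamics(net, s0 = s0, burn_in = 0, window = 20,
                    update_fraction = 1, record = TRUE, seed = 7)
  s <- s0
  for (t in 1:20) {
    s <- step_state(net, s)
    expect_identical(r$trajectory[, t + 1], as.integer(s))
  }
})

test_that("strong positive self-coupling freezes the trajectory immediately", {
  net <- fixture_identity(10, w = 2)$network
  r <- run_dynamics(net, burn_in = 0, window = 50, record = TRUE, seed = 2)
  expect_identical(r$frozen_fraction, 1)
  expect_identical(r$classification, "fixed_point")
  expect_true(all(r$trajectory == r$trajectory[, 1]))
})

test_that("same seed reproduces the trajectory; spin flip negates it", {
  top <- build_binomial_topology(60, 0.1, seed = 3)
  net <- compose_network(top, seed = 4)
  s0 <- rep(c(1L, -1L), 30)
  r1 <- run_dynamics(net, s0 = s0, burn_in = 10, window = 40,
                     record = TRUE, seed = 5)
  r2 <- run_dynamics(net, s0 = s0, burn_in = 10, window = 40,
                     record = TRUE, seed = 5)
  expect_identical(r1$trajectory, r2$trajectory)
  # sign is odd: same update-set sequence, negated initial state
  r3 <- run_dynamics(net, s0 = -s0, burn_in = 10, window = 40,
                     record = TRUE, seed = 5)
  expect_identical(r3$trajectory, -r1$trajectory)
})

test_that("frozen-core fraction counts exactly the constant nodes", {
  traj <- matrix(1L, 10, 5)
  expect_identical(frozen_core_fraction(traj), 1)
  traj_toggle <- outer(rep(1L, 10), c(1L, -1L, 1L, -1L))
  expect_identical(frozen_core_fraction(traj_toggle), 0)
  traj[10, 3] <- -1L
  expect_identical(frozen_core_fraction(traj), 0.9)
  expect_error(frozen_core_fraction(traj, integer(0)), "empty")
})

test_that("frozen-core fraction is non-increasing as the window grows", {
  top <- build_binomial_topology(80, 6 / 80, seed = 6)
  net <- compose_network(top, seed = 7)
  r <- run_dynamics(net, burn_in = 200, window = 300, record = TRUE, seed = 8)
  ff <- vapply(seq(20, 300, by = 40),
               function(w) frozen_core_fraction(r, seq_len(w)), numeric(1))
  expect_true(all(diff(ff) <= 0))
})

test_that("convergence classification thresholds are respected", {
  expect_identical(classify_convergence(1), "fixed_point")
  expect_identical(classify_convergence(0.95), "qfp")
  expect_identical(classify_convergence(0.5), "none")
  expect_identical(classify_convergence(0.95, qfp_threshold = 0.96), "none")
  expect_error(classify_convergence(1.2))
})

test_that("zero-input nodes are pruned (or driven) per sign variant", {
  # nodes 4 and 5 receive no input
  W <- matrix(0, 5, 5)
  W[2, 1] <- 1; W[3, 2] <- -1; W[1, 3] <- 1
  net <- threshold_network(W)
  r <- run_dynamics(net, s0 = rep(1L, 5), burn_in = 100, window = 50,
                    record = TRUE, seed = 9)
  expect_true(all(r$state[4:5] == 0))
  r2 <- run_dynamics(net, s0 = rep(-1L, 5), burn_in = 100, window = 50,
                     sign_variant = "positive", seed = 10)
  expect_true(all(r2$state[4:5] == 1))
})

test_that("all-zero networks converge to the zero fixed point with certainty", {
  spec <- function(r) threshold_network(matrix(0, 20, 20))
  est <- estimate_convergence_probability(spec, 10, criterion = "fixed_point",
                                          burn_in = 100, window = 50,
                                          seed = 11)
  expect_identical(est$p, 1)
  expect_identical(est$n_converged, 10L)
  expect_identical(est$se, 0)
})

test_that("convergence estimates carry binomial standard errors", {
  ens <- ensemble_params(60, "binomial", p = 2 / 60)
  est <- estimate_convergence_probability(ens, 20, burn_in = 300,
                                          window = 200, seed = 12)
  expect_s3_class(est, "tbl_df")
  expect_identical(est$n_realizations, 20)
  expect_equal(est$se, sqrt(est$p * (1 - est$p) / 20))
  expect_length(est$frozen_fractions[[1]], 20)
  expect_true(all(est$frozen_fractions[[1]] >= 0 &
                  est$frozen_fractions[[1]] <= 1))
})
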