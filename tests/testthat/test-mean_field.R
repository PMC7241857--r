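# Mean-field damage-spreading theory: analytic derivative, critical line,
# time scales, and the Monte-Carlo oracle.

test_that("folded-Gaussian exceedance probability is the arctangent law", {
  expect_equal(exceedance_probability(1), 0.5)
  expect_equal(exceedance_probability(sqrt(3)), 1 / 3)
  expect_equal(exceedance_probability(0), 1)
  expect_error(exceedance_probability(-1), "non-negative")

  # Monte-Carlo check at an arbitrary eta
  eta <- 2.7
  set.seed(21)
  n <- 1e6
  freq <- mean(abs(rnorm(n)) > eta * abs(rnorm(n)))
  p <- exceedance_probability(eta)
  expect_true(abs(freq - p) < 3 * sqrt(p * (1 - p) / n))
})

test_that("the damage derivative collapses correctly in its limits", {
  # alpha = 0: hub decoupled, sigma_h irrelevant
  expect_equal(grad_d(4, 0, 0), grad_d(4, 7.3, 0))
  expect_equal(grad_d(4, 2, 0), grad_d(4, 0, 0.9)) # undriven limit unique
  # alpha = 1, overwhelming drive: every row pinned by the hub
  expect_lt(grad_d(4, 1e5, 1), 1e-4)
  # large k_b asymptote within a few percent
  full <- grad_d(25, 20, 1)
  approxim <- grad_d_asymptotic(25, 20)
  expect_true(abs(full - approxim) / full < 0.05)
  # asymptote error shrinks with k_b along a fixed-derivative path
  rel_err <- vapply(c(5, 25, 100), function(kb) {
    sig <- sqrt((2 * kb / pi)^2 - kb) # asymptotic derivative = 1
    abs(grad_d(kb, sig, 1) - grad_d_asymptotic(kb, sig)) / grad_d(kb, sig, 1)
  }, numeric(1))
  expect_true(all(diff(rel_err) < 0))
  expect_error(grad_d(-1, 1, 1), "k_b")
})

test_that("the derivative is monotone in each parameter", {
  kb <- c(1, 3, 5, 10)
  sh <- c(0, 0.5, 1, 2, 4, 8)
  al <- c(0, 0.25, 0.5, 1)
  for (a in al) for (k in kb)
    expect_true(all(diff(grad_d(k, sh, a)) <= 1e-12)) # non-increasing in sigma
  for (k in kb) for (s in sh[sh > 0])
    expect_true(all(diff(grad_d(k, s, al)) <= 1e-12)) # non-increasing in alpha
  for (a in al) for (s in sh)
    expect_true(all(diff(grad_d(kb, s, a)) >= -1e-12)) # non-decreasing in k_b
})

test_that("the critical hub strength solves grad_d = 1 or is undefined", {
  sc <- sigma_crit(5, 1)
  expect_true(abs(grad_d(5, sc, 1) - 1) < 1e-6)
  sc2 <- sigma_crit(3, 0.5)
  expect_true(abs(grad_d(3, sc2, 0.5) - 1) < 1e-6)
  # linear critical line for dense hubs at large k_b
  expect_true(abs(sigma_crit(100, 1) / 100 - 2 / pi) < 0.05 * 2 / pi)
  # sparse hubs beyond the maximal bulk degree: no strength suppresses chaos
  expect_true(is.na(sigma_crit(25, 0.1)))
  # subcritical bulk needs no drive at all
  expect_identical(sigma_crit(1, 1), 0)
})

test_that("mean-field time scales follow the printed plug-in forms", {
  expect_equal(convergence_time(0.5, 1000, 0.1), log(100) / log(2))
  expect_true(is.na(convergence_time(1, 1000, 0.1)))
  expect_gt(convergence_time(0.999, 1500, 0.1), 1e3) # diverges at criticality
  expect_lt(convergence_time(1e-6, 1500, 0.1), 1)    # instant collapse

  expect_equal(hub_flip_time(1500, 20, 0.1), 750)
  expect_equal(hub_flip_probability(0, 20, 1500), 0)
  # the arctan factor keeps the rate below the coarse delta * k_h / n bound,
  # ever more so for well-connected hubs
  expect_lt(hub_flip_probability(0.1, 20, 1500), 0.1 * 20 / 1500)
  expect_lt(hub_flip_probability(0.1, 400, 1500) / (0.1 * 400 / 1500),
            hub_flip_probability(0.1, 4, 1500) / (0.1 * 4 / 1500))

  stab <- closed_loop_stability(0.5, 1500, 20, 0.1)
  expect_identical(stab$status, "stable")
  expect_identical(stab$p_closed_factor, 0.5)
  expect_lt(stab$t_conv, stab$t_flip)
  stab2 <- closed_loop_stability(1 - 1e-9, 1500, 20, 0.1)
  expect_identical(stab2$status, "marginal")
})

test_that("the Monte-Carlo oracle vanishes in the degenerate limits", {
  # zero network, zero drive: both copies map to the all-zero state
  lh0 <- build_sparse_gaussian(lumped_hub_params(1e-9, 0, 0), 200, seed = 31)
  lh0$bulk_weights@x <- numeric(0) # force exactly empty
  lh0$bulk_weights@i <- integer(0)
  lh0$bulk_weights@p <- rep(0L, 201)
  expect_identical(grad_d_oracle(lh0, 50, seed = 32)$estimate, 0)

  # overwhelming dense drive pins every row
  lh <- build_sparse_gaussian(lumped_hub_params(3, 1e4, 1), 2000, seed = 33)
  expect_lt(grad_d_oracle(lh, 100, seed = 34)$estimate, 0.05)
})

test_that("analytic derivative matches direct damage spreading near criticality", {
  # one sparse-Gaussian system on each side of the transition at k_b = 5
  for (case in list(list(sig = 1.2, above = TRUE),
                    list(sig = 3.5, above = FALSE))) {
    lh <- build_sparse_gaussian(lumped_hub_params(5, case$sig, 1), 5000,
                                seed = 35 + case$sig)
    o <- grad_d_oracle(lh, 600, seed = 40 + case$sig)
    g <- grad_d(5, case$sig, 1)
    expect_true(abs(o$estimate - g) < 3 * o$se + 0.05 * g)
    expect_identical(g > 1, case$above)
  }
})

test_that("prediction summaries and phase boundaries are tidy tables", {
  pred <- mft_prediction(5, 3, 1, n = 1500, k_h = 20)
  expect_s3_class(pred, "tbl_df")
  expect_true(pred$converges_open_loop)
  expect_identical(pred$p_closed_loop, 0.5)
  pred2 <- mft_prediction(5, 1, 1)
  expect_false(pred2$converges_open_loop)
  expect_identical(pred2$p_closed_loop, 0)

  pb <- phase_boundary(c(2, 5, 10), alpha = c(0.5, 1))
  expect_identical(nrow(pb), 6L)
  # critical strength grows with k_b and with sparsity (smaller alpha)
  expect_true(all(diff(pb$sigma_crit[pb$alpha == 1]) > 0))
  expect_true(all(pb$sigma_crit[pb$alpha == 0.5] >=
                  pb$sigma_crit[pb$alpha == 1], na.rm = TRUE))
  p <- autoplot(pb)
  expect_s3_class(p, "ggplot")
})
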