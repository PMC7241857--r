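# Lumped-hub reduction: hub selection, parameter extraction, the three
# coarse-graining levels, and system assembly.

# 8-node toy: nodes 1, 2 are hubs; bulk is nodes 3..8 (6 nodes).
# Hub 1 targets bulk nodes {3, 4, 5}; hub 2 targets {5, 6}.
# Bulk-internal edges: 3->4, 4->5, 5->6, 6->3, 7->8, 8->7 (6 edges).
# Bulk in-neighbors of the hubs: 7 -> hub1, 8 -> hub2.
toy_topology <- function() {
  A <- matrix(0, 8, 8) # A[i, j] = 1 means j -> i
  A[3, 1] <- A[4, 1] <- A[5, 1] <- 1
  A[5, 2] <- A[6, 2] <- 1
  A[4, 3] <- A[5, 4] <- A[6, 5] <- A[3, 6] <- A[8, 7] <- A[7, 8] <- 1
  A[1, 7] <- A[2, 8] <- 1
  hubnet:::new_topology(A, "toy")
}

test_that("top-hub selection is by out-degree with deterministic ties", {
  top <- build_sfo_topology(c(5, 9, 9, 1, 0, 3, 2, 2, 1, 1), seed = 1)
  expect_identical(select_top_hubs(top, 2), c(2L, 3L)) # tie broken low
  expect_identical(sort(select_top_hubs(top, 10)), 1:10)
  expect_error(select_top_hubs(top, 11), "m must")
})

test_that("lumped parameters are extracted by moment matching", {
  top <- toy_topology()
  p <- extract_lumped_params(top, 2)
  expect_identical(attr(p, "n_bulk"), 6L)
  # bulk: 6 edges over 6 nodes
  expect_equal(p$k_b, 1)
  # targeted bulk nodes {3,4,5,6} -> alpha = 4/6
  expect_equal(p$alpha, 4 / 6)
  # hub-connection counts (1,1,2,1): sigma_h^2 = mean = 5/4
  expect_equal(p$sigma_h, sqrt(5 / 4))
  # lumped hub in-degree: edges 7->hub1, 8->hub2
  expect_equal(p$k_h, 2)
  expect_identical(p$m, 2L)

  # every targeted node hit exactly once -> sigma_h = 1
  p1 <- extract_lumped_params(top, 1)
  expect_equal(p1$sigma_h, 1)
})

test_that("exact-pattern lumping preserves the hub target pattern and variance", {
  top <- toy_topology()
  lh <- lump_exact_pattern(top, 2, seed = 2)
  expect_identical(lh$n_bulk, 6L)
  # support of u = union of hub target sets, in bulk indexing {1,2,3,4}
  expect_identical(which(lh$u != 0), 1:4)
  # hub in-vector support = bulk in-neighbours of the hubs {5, 6}
  expect_identical(which(lh$v != 0), 5:6)

  # Var(u_i) equals the hub-connection count: node 3 of the bulk is hit by
  # both hubs, the others by one
  set.seed(3)
  draws <- replicate(4000, lump_exact_pattern(top, 2)$u)
  v <- apply(draws, 1, var)
  expect_true(abs(v[3] - 2) < 0.15)
  expect_true(all(abs(v[c(1, 2, 4)] - 1) < 0.1))
  expect_true(all(draws[5:6, ] == 0))

  # variance accounting: E[sum u_i^2] = total number of hub->bulk edges (5)
  expect_true(abs(mean(colSums(draws^2)) - 5) < 0.2)
})

test_that("sparse-Gaussian hub has Bernoulli support and matched variance", {
  p <- lumped_hub_params(k_b = 3, sigma_h = 2, alpha = 0.5)
  lh <- build_sparse_gaussian(p, 1e5, seed = 4)
  frac <- mean(lh$u != 0)
  expect_true(abs(frac - 0.5) < 4 * binom_se(0.5, 1e5))
  nz <- lh$u[lh$u != 0]
  expect_true(abs(var(nz) - 4) < 4 * 4 * sqrt(2 / length(nz)))

  expect_true(all(build_sparse_gaussian(lumped_hub_params(3, 2, 0), 100,
                                        seed = 5)$u == 0))
  expect_true(all(build_sparse_gaussian(lumped_hub_params(3, 2, 1), 100,
                                        seed = 6)$u != 0))
})

test_that("dense-Gaussian hub matches the sparse total output variance", {
  p <- lumped_hub_params(k_b = 3, sigma_h = 2, alpha = 0.4)
  n <- 1e5
  dense <- build_dense_gaussian(p, n, seed = 7)
  sparse <- build_sparse_gaussian(p, n, seed = 8)
  # both have total variance n * alpha * sigma_h^2
  tv <- n * 0.4 * 4
  expect_true(abs(sum(dense$u^2) - tv) / tv < 0.05)
  expect_true(abs(sum(sparse$u^2) - tv) / tv < 0.05)
  # but the dense hub drives every node
  expect_identical(mean(dense$u != 0), 1)
})

test_that("assembled systems wire the hub as drive (open) or node (closed)", {
  p <- lumped_hub_params(k_b = 2, sigma_h = 3, alpha = 1, m = 2, k_h = 4)
  lh <- build_sparse_gaussian(p, 50, seed = 9)
  open <- assemble_system(lh, "open")
  expect_identical(open$n, 50L)
  expect_equal(open$bias, lh$u)

  closed <- assemble_system(lh, "closed")
  expect_identical(closed$n, 51L)
  expect_equal(as.vector(closed$weights[1:50, 51]), lh$u)
  expect_equal(as.vector(closed$weights[51, 1:50]), lh$v)
  expect_identical(closed$weights[51, 51], 0)

  # open loop with u = 0 is plain bulk dynamics
  lh0 <- build_sparse_gaussian(lumped_hub_params(2, 0, 0), 50, seed = 10)
  open0 <- assemble_system(lh0, "open")
  expect_true(all(open0$bias == 0))

  # hub clamped at +1 with v = 0: one synchronous closed-loop step equals
  # the open-loop step on the bulk (positive sign variant keeps h = +1)
  lh$v[] <- 0
  cl <- assemble_system(lh, "closed")
  s <- rep(c(1, -1), 25)
  bulk_next <- step_state(open, s, sign_variant = "positive")
  full_next <- step_state(cl, c(s, 1), sign_variant = "positive")
  expect_identical(full_next[1:50], bulk_next)
  expect_identical(full_next[51], 1) # zero field -> +1 under this variant
})

test_that("lumping sensitivity reports the derivative across m", {
  top <- sample_topology(ensemble_params(400, "sfo", gamma = 2.6, k_min = 1),
                         seed = 11)
  sens <- lumping_sensitivity(top, m_range = 1:5)
  expect_identical(nrow(sens), 5L)
  expect_true(all(c("m", "grad_d", "k_b", "sigma_h", "alpha") %in%
                  names(sens)))
  expect_true(all(is.finite(sens$grad_d)))
})
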