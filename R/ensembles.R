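# Directed network ensembles: scale-free-out (SFO), scale-free-in (SFI),
# binomial, and small deterministic fixtures.
#
# Orientation convention (fixed throughout the package): entry T[i, j] = 1
# means node j influences node i, so the local field is the plain product
# W %*% s. Out-degree of node j is the j-th column sum; in-degree of node i
# is the i-th row sum.

#' Ensemble parameter set
#'
#' Bundles and validates the generative parameters of a network ensemble.
#' Scale-free families (`"sfo"`, `"sfi"`) require a power-law exponent
#' `gamma > 2` (finite mean degree) and a Pareto location `k_min > 0`;
#' the `"binomial"` family requires an edge probability `p`, with `p * n`
#' the target mean degree.
#'
#' @param n Number of nodes (positive integer).
#' @param family One of `"sfo"`, `"sfi"`, `"binomial"`, `"identity"`,
#'   `"cycle"`.
#' @param gamma Power-law exponent of the out- (or in-) degree distribution.
#' @param k_min Pareto location parameter; the smallest continuous degree.
#' @param p Edge probability for the binomial family.
#'
#' @return An object of class `ensemble_params`.
#' @examples
#' ensemble_params(1500, "sfo", gamma = 2.2, k_min = 1)
#' ensemble_params(1500, "binomial", p = 5 / 1500)
#' @export
ensemble_params <- function(n, family = c("sfo", "sfi", "binomial",
                                          "identity", "cycle"),
                            gamma = NULL, k_min = NULL, p = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(n), length(n) == 1, n >= 1, n == round(n))
  if (family %in% c("sfo", "sfi")) {
    if (is.null(gamma) || gamma <= 2)
      stop("scale-free families require gamma > 2 (finite mean degree)")
    if (is.null(k_min) || k_min <= 0)
      stop("scale-free families require k_min > 0")
  }
  if (family == "binomial") {
    if (is.null(p) || p < 0 || p > 1)
      stop("binomial family requires p in [0, 1]")
  }
  structure(list(n = as.integer(n), family = family, gamma = gamma,
                 k_min = k_min, p = p),
            class = "ensemble_params")
}

#' @export
print.ensemble_params <- function(x, ...) {
  cat("<ensemble_params> family =", x$family, " n =", x$n)
  if (!is.null(x$gamma)) cat("  gamma =", x$gamma, " k_min =", x$k_min)
  if (!is.null(x$p)) cat("  p =", signif(x$p, 4))
  cat("\n")
  invisible(x)
}

new_topology <- function(adjacency, family, params = NULL) {
  adjacency <- Matrix::Matrix(adjacency, sparse = TRUE)
  adjacency <- methods::as(methods::as(adjacency, "generalMatrix"),
                           "CsparseMatrix")
  structure(list(adjacency = adjacency,
                 n = nrow(adjacency),
                 out_degrees = as.integer(Matrix::colSums(adjacency != 0)),
                 in_degrees = as.integer(Matrix::rowSums(adjacency != 0)),
                 family = family,
                 params = params),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("<topology>", x$family, " n =", x$n,
      " edges =", sum(x$out_degrees),
      " max out-degree =", max(x$out_degrees), "\n")
  invisible(x)
}

#' Sample a discretized Pareto out-degree sequence
#'
#' Draws `n` continuous Pareto variates with density
#' \eqn{P(k) = (\gamma - 1)\, k_{min}^{\gamma - 1}\, k^{-\gamma}} for
#' \eqn{k \ge k_{min}} (inverse-CDF sampling), rounds half-away-from-zero to
#' the nearest integer, and clamps the result to `[1, max_degree]`. The mean
#' of the continuous law is \eqn{k_{min} (\gamma - 1)/(\gamma - 2)}, finite
#' only for `gamma > 2`.
#'
#' @param n Number of degrees to draw.
#' @param gamma Power-law exponent (> 2).
#' @param k_min Pareto location (> 0).
#' @param max_degree Upper clamp; defaults to `n - 1` (simple directed graph).
#' @param seed Optional seed applied locally.
#'
#' @return Integer vector of length `n`, each entry in `[1, max_degree]`.
#' @examples
#' k <- sample_scale_free_degrees(1e4, gamma = 3, k_min = 2, seed = 1)
#' mean(k) # close to k_min * (gamma - 1) / (gamma - 2) = 4
#' @export
sample_scale_free_degrees <- function(n, gamma, k_min,
                                      max_degree = n - 1, seed = NULL) {
  if (gamma <= 2) stop("gamma must exceed 2 (infinite-mean degree otherwise)")
  if (k_min <= 0) stop("k_min must be positive")
  stopifnot(n >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  k <- k_min * runif(n)^(-1 / (gamma - 1))
  k <- floor(k + 0.5) # round half away from zero (all draws positive)
  as.integer(pmin(pmax(k, 1), max_degree))
}

#' Build an SFO topology from an out-degree sequence
#'
#' Each node `j` is wired to exactly `degrees[j]` distinct targets drawn
#' uniformly among the other nodes (no self-loops, no multi-edges). The
#' out-degree sequence is reproduced exactly; in-degrees are consequently
#' binomial-like.
#'
#' @param degrees Integer vector of out-degrees, each in `[0, n - 1]`.
#' @param seed Optional seed applied locally.
#' @return A `topology` object with family `"sfo"`.
#' @export
build_sfo_topology <- function(degrees, seed = NULL) {
  n <- length(degrees)
  if (any(degrees < 0 | degrees > n - 1))
    stop("each out-degree must lie in [0, n - 1]")
  if (!is.null(seed)) withr::local_seed(seed)
  total <- sum(degrees)
  ii <- integer(total); jj <- integer(total)
  pos <- 0L
  for (j in seq_len(n)) {
    k <- degrees[j]
    if (k == 0) next
    idx <- sample.int(n - 1L, k)       # targets among the other n - 1 nodes
    targets <- idx + (idx >= j)        # skip j itself
    ii[(pos + 1L):(pos + k)] <- targets
    jj[(pos + 1L):(pos + k)] <- j
    pos <- pos + k
  }
  adj <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  new_topology(adj, "sfo", list(degrees = degrees))
}

#' Transpose a topology
#'
#' Reverses every edge. An SFO network becomes an SFI network: the out-degree
#' sequence of the result equals the in-degree sequence of the input.
#'
#' @param topology A `topology` object.
#' @return The transposed `topology`.
#' @export
transpose_topology <- function(topology) {
  stopifnot(inherits(topology, "topology"))
  fam <- switch(topology$family, sfo = "sfi", sfi = "sfo", topology$family)
  new_topology(Matrix::t(topology$adjacency), fam, topology$params)
}

#' Build a binomial (Erdos-Renyi) directed topology
#'
#' Every ordered pair of distinct nodes is connected independently with
#' probability `p`; mean in- and out-degree are both `p * (n - 1)`.
#'
#' @param n Number of nodes.
#' @param p Edge probability in `[0, 1]`.
#' @param seed Optional seed applied locally.
#' @return A `topology` object with family `"binomial"`.
#' @export
build_binomial_topology <- function(n, p, seed = NULL) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  if (!is.null(seed)) withr::local_seed(seed)
  n_pairs <- as.double(n) * (n - 1)
  m <- rbinom(1, n_pairs, p)
  if (m == 0) {
    adj <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n))
    return(new_topology(adj, "binomial", list(p = p)))
  }
  q <- sample.int(n_pairs, m) - 1     # linear index over off-diagonal pairs
  jj <- q %/% (n - 1)
  r <- q %% (n - 1)
  ii <- r + (r >= jj)
  adj <- Matrix::sparseMatrix(i = ii + 1, j = jj + 1, x = 1, dims = c(n, n))
  new_topology(adj, "binomial", list(p = p))
}

#' Sample a topology from an ensemble parameter set
#'
#' @param params An `ensemble_params` object.
#' @param seed Optional seed applied locally.
#' @return A `topology`.
#' @export
sample_topology <- function(params, seed = NULL) {
  stopifnot(inherits(params, "ensemble_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  switch(params$family,
    sfo = build_sfo_topology(
      sample_scale_free_degrees(params$n, params$gamma, params$k_min)),
    sfi = transpose_topology(build_sfo_topology(
      sample_scale_free_degrees(params$n, params$gamma, params$k_min))),
    binomial = build_binomial_topology(params$n, params$p),
    identity = fixture_identity(params$n)$topology,
    cycle = fixture_cycle(params$n)$topology,
    stop("unknown family"))
}

#' Compose a weighted network from a topology
#'
#' Replaces each present edge with an independent standard-Gaussian strength:
#' `W = T * J` elementwise with `J ~ N(0, 1)` i.i.d. The sparsity pattern of
#' the topology is preserved (Gaussian draws are almost surely nonzero).
#'
#' @param topology A `topology` object.
#' @param seed Optional seed applied locally.
#' @return A `threshold_net` (see [threshold_network()]).
#' @export
compose_network <- function(topology, seed = NULL) {
  stopifnot(inherits(topology, "topology"))
  if (!is.null(seed)) withr::local_seed(seed)
  W <- topology$adjacency
  W@x <- rnorm(length(W@x))
  threshold_network(W, family = topology$family, topology = topology)
}

#' Threshold network object
#'
#' A weighted directed network plus an optional constant bias (external
#' drive) entering the threshold: the dynamics update a node to
#' `sign(sum_j W[i, j] s_j + bias[i])`. Row `i` of `W` lists the inputs of
#' node `i`.
#'
#' @param weights Square numeric matrix (dense or `Matrix` sparse).
#' @param bias Numeric drive vector (recycled scalar allowed); default 0.
#' @param family Optional ensemble tag.
#' @param topology Optional generating `topology`.
#' @return An object of class `threshold_net`.
#' @export
threshold_network <- function(weights, bias = 0, family = NULL,
                              topology = NULL) {
  W <- methods::as(methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE),
                                           "generalMatrix"),
                               "CsparseMatrix"), "dMatrix")
  n <- nrow(W)
  stopifnot(ncol(W) == n)
  bias <- rep_len(as.numeric(bias), n)
  structure(list(weights = W, bias = bias, n = n, family = family,
                 topology = topology),
            class = "threshold_net")
}

#' @export
print.threshold_net <- function(x, ...) {
  cat("<threshold_net> n =", x$n,
      " nonzeros =", length(x$weights@x),
      " drive =", if (any(x$bias != 0)) "yes" else "no", "\n")
  invisible(x)
}

# ---- deterministic fixtures ------------------------------------------------

#' Hand-checkable fixture networks
#'
#' `fixture_identity()` gives self-loops with weight `+w`; `fixture_cycle()`
#' a directed cycle 1 -> 2 -> ... -> n -> 1 with unit weights (optionally one
#' negated); `fixture_flipflop()` the 2-node cross-coupled pair
#' `W = [[0, 1], [-1, 0]]`, whose synchronous dynamics is a period-4 orbit.
#'
#' @param n Number of nodes.
#' @param w Self-loop weight (identity fixture).
#' @param negate_one If `TRUE`, the edge n -> 1 has weight -1 (cycle fixture).
#' @return A list with elements `topology` and `network`.
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
fixture_identity <- function(n, w = 1) {
  W <- Matrix::Diagonal(n, w)
  top <- new_topology(W != 0, "identity")
  list(topology = top, network = threshold_network(W, family = "identity"))
}

#' @rdname fixtures
#' @export
fixture_cycle <- function(n, negate_one = FALSE) {
  # edge j -> j + 1 (mod n): W[i, j] with i = successor of j
  jj <- seq_len(n)
  ii <- c(seq_len(n)[-1], 1L)
  x <- rep(1, n)
  if (negate_one) x[n] <- -1
  W <- Matrix::sparseMatrix(i = ii, j = jj, x = x, dims = c(n, n))
  top <- new_topology(W != 0, "cycle")
  list(topology = top, network = threshold_network(W, family = "cycle"))
}

#' @rdname fixtures
#' @export
fixture_flipflop <- function() {
  W <- matrix(c(0, -1, 1, 0), 2, 2)
  list(topology = new_topology(W != 0, "flipflop"),
       network = threshold_network(W, family = "flipflop"))
}
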