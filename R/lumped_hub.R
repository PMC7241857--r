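# The lumped-hub reduction: replace the m strongest outgoing hubs of a
# heterogeneous network by a single effective hub coupled to a homogeneous
# binomial bulk, at three coarse-graining levels:
#   exact_pattern   - hub out-connections keep the union pattern of the m
#                     hubs' targets, with variance equal to the number of
#                     lumped hubs pointing at each target;
#   sparse_gaussian - only the statistics survive: each bulk node receives a
#                     N(0, sigma_h^2) hub weight with probability alpha;
#   dense_gaussian  - sparseness is discarded: every node receives
#                     N(0, alpha * sigma_h^2).

#' Lumped-hub parameter set
#'
#' The three-parameter description of a heterogeneous network after lumping:
#' mean bulk degree `k_b`, hub strength scale `sigma_h`, hub sparseness
#' `alpha` (fraction of bulk nodes receiving hub input), plus the lumping
#' count `m` and the lumped hub's in-degree `k_h`.
#'
#' @param k_b Mean out-degree of the bulk subnetwork (>= 0).
#' @param sigma_h Hub connection-strength scale (>= 0).
#' @param alpha Fraction of bulk nodes driven by the hub, in `[0, 1]`.
#' @param m Number of lumped hubs (default 1).
#' @param k_h Hub in-degree (defaults to `m * k_b`, the typical total
#'   in-degree of the lumped hubs).
#' @return An object of class `lumped_hub_params`.
#' @export
lumped_hub_params <- function(k_b, sigma_h, alpha, m = 1, k_h = m * k_b) {
  stopifnot(k_b >= 0, sigma_h >= 0, alpha >= 0, alpha <= 1, m >= 1)
  structure(list(k_b = k_b, sigma_h = sigma_h, alpha = alpha,
                 m = as.integer(m), k_h = k_h),
            class = "lumped_hub_params")
}

#' @export
print.lumped_hub_params <- function(x, ...) {
  cat("<lumped_hub_params> k_b =", signif(x$k_b, 4),
      " sigma_h =", signif(x$sigma_h, 4),
      " alpha =", signif(x$alpha, 4),
      " m =", x$m, " k_h =", signif(x$k_h, 4), "\n")
  invisible(x)
}

#' @export
tidy.lumped_hub_params <- function(x, ...) {
  tibble::tibble(k_b = x$k_b, sigma_h = x$sigma_h, alpha = x$alpha,
                 m = x$m, k_h = x$k_h)
}

#' Indices of the m largest outgoing hubs
#'
#' Ties are broken toward the lowest index, so the selection is
#' deterministic.
#'
#' @param topology A `topology`.
#' @param m Number of hubs to select (`1 <= m <= n`).
#' @return Integer vector of node indices, ordered by decreasing out-degree.
#' @export
select_top_hubs <- function(topology, m) {
  stopifnot(inherits(topology, "topology"))
  if (m < 1 || m > topology$n) stop("m must lie in [1, n]")
  order(topology$out_degrees, seq_len(topology$n),
        decreasing = c(TRUE, FALSE), method = "radix")[seq_len(m)]
}

#' Extract lumped-hub parameters from a topology
#'
#' Computes the `(k_b, sigma_h, alpha)` description of a network for a given
#' lumping count `m`: `k_b` is the mean out-degree of the bulk subgraph
#' (edges among non-hub nodes); `alpha` the fraction of bulk nodes targeted
#' by at least one of the `m` hubs; `sigma_h^2` the mean hub-connection
#' count over targeted nodes (second-moment matching of the exact-pattern
#' hub weights to a single Gaussian, conditional on being connected); and
#' `k_h` the lumped hub's in-degree (edges from bulk into any of the `m`
#' hubs).
#'
#' @param topology A `topology`.
#' @param m Number of hubs to lump.
#' @return A `lumped_hub_params` with attribute `hub_counts` (per-bulk-node
#'   hub-connection counts) and `n_bulk`.
#' @export
extract_lumped_params <- function(topology, m) {
  stopifnot(inherits(topology, "topology"))
  hubs <- select_top_hubs(topology, m)
  bulk <- setdiff(seq_len(topology$n), hubs)
  A <- topology$adjacency
  counts <- as.vector(Matrix::rowSums(A[bulk, hubs, drop = FALSE] != 0))
  k_b <- sum(A[bulk, bulk, drop = FALSE] != 0) / length(bulk)
  alpha <- mean(counts > 0)
  sigma_h <- if (any(counts > 0)) sqrt(mean(counts[counts > 0])) else 0
  k_h <- sum(A[hubs, bulk, drop = FALSE] != 0)
  out <- lumped_hub_params(k_b, sigma_h, alpha, m = m, k_h = k_h)
  attr(out, "hub_counts") <- counts
  attr(out, "n_bulk") <- length(bulk)
  out
}

new_lumped_hub_net <- function(bulk_weights, u, v, mode, params) {
  structure(list(bulk_weights = bulk_weights, u = u, v = v,
                 n_bulk = length(u), mode = mode, params = params),
            class = "lumped_hub_net")
}

#' @export
print.lumped_hub_net <- function(x, ...) {
  cat("<lumped_hub_net>", x$mode, " bulk n =", x$n_bulk,
      " driven fraction =", signif(mean(x$u != 0), 3), "\n")
  invisible(x)
}

bulk_binomial_weights <- function(n_bulk, k_b) {
  p <- min(1, k_b / (n_bulk - 1))
  compose_network(build_binomial_topology(n_bulk, p))$weights
}

hub_in_vector <- function(n_bulk, support) {
  v <- numeric(n_bulk)
  if (length(support)) v[support] <- rnorm(length(support))
  v
}

#' Exact-pattern lumped-hub reduction
#'
#' Lumps the `m` largest outgoing hubs of `topology` into one effective hub.
#' The hub's outgoing weight onto bulk node `i` is drawn from
#' `N(0, c_i)` where `c_i` is the number of lumped hubs pointing at `i`
#' (zero where none do), so the union connection pattern is preserved
#' exactly. The bulk is replaced by an independent binomial network with the
#' original mean bulk degree; the hub's incoming weights sit on the union of
#' the `m` hubs' bulk in-neighbors with i.i.d. `N(0, 1)` strengths.
#' Hub-to-hub edges among the lumped hubs are discarded.
#'
#' @param topology A `topology` (typically SFO).
#' @param m Number of hubs to lump (default 4).
#' @param seed Optional seed applied locally.
#' @return A `lumped_hub_net` with mode `"exact_pattern"`.
#' @export
lump_exact_pattern <- function(topology, m = 4, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  params <- extract_lumped_params(topology, m)
  counts <- attr(params, "hub_counts")
  n_bulk <- attr(params, "n_bulk")
  u <- numeric(n_bulk)
  hit <- counts > 0
  u[hit] <- rnorm(sum(hit), sd = sqrt(counts[hit]))
  hubs <- select_top_hubs(topology, m)
  bulk <- setdiff(seq_len(topology$n), hubs)
  # in-neighbors of any hub, restricted to bulk, in bulk indexing
  in_nb <- which(Matrix::colSums(
    topology$adjacency[hubs, bulk, drop = FALSE] != 0) > 0)
  new_lumped_hub_net(bulk_binomial_weights(n_bulk, params$k_b),
                     u, hub_in_vector(n_bulk, in_nb),
                     "exact_pattern", params)
}

#' Sparse-Gaussian lumped-hub ensemble
#'
#' Retains the statistics of the hub connectivity rather than its pattern:
#' each bulk node independently receives a hub weight `N(0, sigma_h^2)` with
#' probability `alpha` and 0 otherwise; the bulk is binomial with mean
#' degree `k_b`. The hub's in-connections sit on `round(k_h)` random bulk
#' nodes with `N(0, 1)` strengths.
#'
#' @param params A `lumped_hub_params`.
#' @param n_bulk Number of bulk nodes.
#' @param seed Optional seed applied locally.
#' @return A `lumped_hub_net` with mode `"sparse_gaussian"`.
#' @export
build_sparse_gaussian <- function(params, n_bulk, seed = NULL) {
  stopifnot(inherits(params, "lumped_hub_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  u <- numeric(n_bulk)
  hit <- runif(n_bulk) < params$alpha
  u[hit] <- rnorm(sum(hit), sd = params$sigma_h)
  k_in <- min(n_bulk, max(1L, as.integer(round(params$k_h))))
  new_lumped_hub_net(bulk_binomial_weights(n_bulk, params$k_b),
                     u, hub_in_vector(n_bulk, sample.int(n_bulk, k_in)),
                     "sparse_gaussian", params)
}

#' Dense-Gaussian lumped-hub ensemble
#'
#' The coarsest level: hub sparseness is discarded and every bulk node
#' receives a hub weight `N(0, alpha * sigma_h^2)`. Total hub output
#' variance matches the sparse variant (`n * alpha * sigma_h^2`), but
#' convergence probabilities are systematically overestimated relative to
#' the sparse and exact-pattern levels.
#'
#' @inheritParams build_sparse_gaussian
#' @return A `lumped_hub_net` with mode `"dense_gaussian"`.
#' @export
build_dense_gaussian <- function(params, n_bulk, seed = NULL) {
  stopifnot(inherits(params, "lumped_hub_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  u <- rnorm(n_bulk, sd = sqrt(params$alpha) * params$sigma_h)
  k_in <- min(n_bulk, max(1L, as.integer(round(params$k_h))))
  new_lumped_hub_net(bulk_binomial_weights(n_bulk, params$k_b),
                     u, hub_in_vector(n_bulk, sample.int(n_bulk, k_in)),
                     "dense_gaussian", params)
}

#' Assemble a lumped-hub system for simulation
#'
#' Open loop: the hub is clamped at +1 and acts as a constant external
#' drive, giving bulk dynamics `s'(t+1) = sign(W' s'(t) + u)`; its incoming
#' connections are discarded. Closed loop: the hub is restored as dynamic
#' node `n_bulk + 1` with outgoing column `u` and incoming row `v`.
#'
#' @param lh A `lumped_hub_net`.
#' @param loop `"open"` or `"closed"`.
#' @return A `threshold_net`; for the closed loop, the hub is the last node.
#' @export
assemble_system <- function(lh, loop = c("open", "closed")) {
  stopifnot(inherits(lh, "lumped_hub_net"))
  loop <- match.arg(loop)
  if (loop == "open") {
    net <- threshold_network(lh$bulk_weights, bias = lh$u,
                             family = paste0("lumped_", lh$mode, "_open"))
  } else {
    n <- lh$n_bulk
    Wb <- lh$bulk_weights
    W <- rbind(cbind(Wb, Matrix::Matrix(lh$u, n, 1, sparse = TRUE)),
               c(lh$v, 0))
    net <- threshold_network(W,
                             family = paste0("lumped_", lh$mode, "_closed"))
  }
  net$loop <- loop
  net
}

#' Specification of a lumped-hub ensemble for convergence experiments
#'
#' A recipe consumed by [estimate_convergence_probability()]: each
#' realization builds a fresh lumped-hub network and assembles it in the
#' requested loop mode. For modes `"sparse_gaussian"`/`"dense_gaussian"`,
#' supply `params`; for `"exact_pattern"`, supply the generating
#' `ensemble_params` in `source` (a fresh heterogeneous topology is drawn
#' and lumped each realization).
#'
#' @param mode Coarse-graining level.
#' @param loop `"open"` or `"closed"`.
#' @param n_bulk Bulk size (Gaussian modes).
#' @param params A `lumped_hub_params` (Gaussian modes).
#' @param source An `ensemble_params` (exact-pattern mode).
#' @param m Lumping count (exact-pattern mode, default 4).
#' @return An object of class `lumped_hub_spec`.
#' @export
lumped_hub_spec <- function(mode = c("sparse_gaussian", "dense_gaussian",
                                     "exact_pattern"),
                            loop = c("open", "closed"),
                            n_bulk = NULL, params = NULL, source = NULL,
                            m = 4) {
  mode <- match.arg(mode)
  loop <- match.arg(loop)
  if (mode == "exact_pattern") {
    if (!inherits(source, "ensemble_params"))
      stop("exact_pattern mode requires `source` ensemble_params")
  } else {
    if (!inherits(params, "lumped_hub_params") || is.null(n_bulk))
      stop("Gaussian modes require `params` and `n_bulk`")
  }
  structure(list(mode = mode, loop = loop, n_bulk = n_bulk,
                 params = params, source = source, m = m),
            class = "lumped_hub_spec")
}

realize_lumped_hub <- function(spec) {
  lh <- switch(spec$mode,
    exact_pattern = lump_exact_pattern(sample_topology(spec$source), spec$m),
    sparse_gaussian = build_sparse_gaussian(spec$params, spec$n_bulk),
    dense_gaussian = build_dense_gaussian(spec$params, spec$n_bulk))
  assemble_system(lh, spec$loop)
}

#' Sensitivity of the damage-spreading derivative to the lumping count
#'
#' Diagnostic for the stability of the lumped-hub reduction: extracts
#' `(k_b, sigma_h, alpha)` and the mean-field derivative [grad_d()] for each
#' `m` in `m_range` on the same topology. A flat profile indicates the
#' lumping is well defined; strong `m`-dependence (typical for very heavy
#' tails, e.g. power-law exponent near 2.2) signals the approximation's
#' limit.
#'
#' @param topology A `topology`.
#' @param m_range Integer vector of lumping counts (default `1:8`).
#' @return A tibble with one row per `m`: the extracted parameters and
#'   `grad_d`.
#' @export
lumping_sensitivity <- function(topology, m_range = 1:8) {
  purrr::map_dfr(m_range, function(m) {
    p <- extract_lumped_params(topology, m)
    dplyr::mutate(tidy(p), grad_d = grad_d(p$k_b, p$sigma_h, p$alpha),
                  .before = 1)
  })
}
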