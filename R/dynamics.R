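# Binary threshold dynamics with asynchronous random updates, frozen-core
# detection and convergence classification.

sign_variant_code <- function(sign_variant = c("zero", "positive")) {
  match(match.arg(sign_variant), c("zero", "positive")) - 1L
}

apply_sign <- function(x, sign_variant = c("zero", "positive")) {
  sign_variant <- match.arg(sign_variant)
  if (sign_variant == "zero") sign(x) else ifelse(x >= 0, 1, -1)
}

#' One update step of the threshold dynamics
#'
#' Reference (pure R) implementation of a single step: every node in
#' `update` is set to the sign of its local field
#' `sum_j W[i, j] s_j + bias[i]`, simultaneously, based on the state at the
#' start of the step; all other nodes are unchanged. The default sign
#' convention maps a zero field to 0, so nodes with no inputs are pruned
#' from the dynamics; the `"positive"` variant maps it to +1, turning such
#' source nodes into a constant drive.
#'
#' @param net A `threshold_net`.
#' @param s State vector with entries in `{-1, 0, +1}`.
#' @param update Indices of nodes to update (default: all, i.e. synchronous).
#' @param sign_variant `"zero"` (default) or `"positive"`.
#' @return The next state vector.
#' @examples
#' ff <- fixture_flipflop()$network
#' step_state(ff, c(1, 1)) # c(1, -1)
#' @export
step_state <- function(net, s, update = NULL,
                       sign_variant = c("zero", "positive")) {
  stopifnot(inherits(net, "threshold_net"))
  if (length(s) != net$n) stop("state length does not match network size")
  if (!all(s %in% c(-1, 0, 1))) stop("state entries must be in {-1, 0, +1}")
  if (is.null(update)) update <- seq_len(net$n)
  x <- as.vector(net$weights %*% s) + net$bias
  s_next <- s
  s_next[update] <- apply_sign(x[update], match.arg(sign_variant))
  s_next
}

#' Run asynchronous threshold dynamics
#'
#' Simulates `burn_in + window` steps. At each step a fresh uniformly random
#' subset of `round(update_fraction * n)` distinct nodes is updated
#' simultaneously; `update_fraction = 1` is the synchronous map. After the
#' burn-in, a node is *frozen* iff its value is identical at every step of
#' the measurement window.
#'
#' @param net A `threshold_net`.
#' @param s0 Initial state; default uniform i.i.d. over `{-1, +1}`.
#' @param burn_in Steps before the measurement window (default 4000).
#' @param window Measurement window length in steps (default 1000).
#' @param update_fraction Fraction of nodes updated per step (default 0.1).
#' @param sign_variant `"zero"` (default) or `"positive"`.
#' @param record If `TRUE`, keep the window states (`n x (window + 1)`
#'   integer matrix, first column = state when the window opens).
#' @param qfp_threshold Frozen-core fraction above which a state counts as a
#'   quasi-fixed point (default 0.9).
#' @param seed Optional seed applied locally.
#'
#' @return An object of class `dynamics_result`: final `state`, logical
#'   `frozen` vector, `frozen_fraction`, `classification` (`"fixed_point"`,
#'   `"qfp"` or `"none"`), and `trajectory` when recorded.
#' @export
run_dynamics <- function(net, s0 = NULL, burn_in = 4000, window = 1000,
                         update_fraction = 0.1,
                         sign_variant = c("zero", "positive"),
                         record = FALSE, qfp_threshold = 0.9, seed = NULL) {
  stopifnot(inherits(net, "threshold_net"))
  stopifnot(update_fraction > 0, update_fraction <= 1, window >= 1,
            burn_in >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- net$n
  if (is.null(s0)) s0 <- sample(c(-1L, 1L), n, replace = TRUE)
  if (length(s0) != n) stop("s0 length does not match network size")
  n_update <- max(1L, as.integer(round(update_fraction * n)))
  W <- net$weights
  res <- cpp_run_dynamics(W@Dim, W@p, W@i, W@x, net$bias,
                          as.integer(s0), as.integer(burn_in),
                          as.integer(window), n_update,
                          sign_variant_code(sign_variant), record)
  structure(list(state = res$state,
                 frozen = res$frozen,
                 frozen_fraction = res$frozen_fraction,
                 classification = classify_convergence(res$frozen_fraction,
                                                       qfp_threshold),
                 trajectory = if (record) res$trajectory else NULL,
                 s0 = as.integer(s0),
                 burn_in = burn_in, window = window,
                 update_fraction = update_fraction,
                 qfp_threshold = qfp_threshold),
            class = "dynamics_result")
}

#' @export
print.dynamics_result <- function(x, ...) {
  cat("<dynamics_result> frozen core =",
      signif(x$frozen_fraction, 4), "->", x$classification, "\n")
  invisible(x)
}

#' @export
tidy.dynamics_result <- function(x, ...) {
  tibble::tibble(frozen_fraction = x$frozen_fraction,
                 classification = x$classification,
                 burn_in = x$burn_in, window = x$window,
                 update_fraction = x$update_fraction)
}

#' Frozen-core fraction of a recorded trajectory
#'
#' Fraction of nodes whose value is identical at every recorded step of the
#' chosen window. Non-increasing as the window is extended.
#'
#' @param trajectory Either a `dynamics_result` with a recorded trajectory or
#'   an `n x T` state matrix (columns = time).
#' @param window Optional column indices delimiting the window (default: all
#'   recorded columns).
#' @return A number in `[0, 1]`.
#' @export
frozen_core_fraction <- function(trajectory, window = NULL) {
  if (inherits(trajectory, "dynamics_result")) {
    trajectory <- trajectory$trajectory
    if (is.null(trajectory))
      stop("dynamics_result has no recorded trajectory; rerun with record = TRUE")
  }
  if (is.null(window)) window <- seq_len(ncol(trajectory))
  if (length(window) == 0) stop("empty window")
  seg <- trajectory[, window, drop = FALSE]
  mean(rows_constant(seg))
}

# rows identical across all columns
rows_constant <- function(m) {
  if (ncol(m) == 1) return(rep(TRUE, nrow(m)))
  rowSums(m[, -1, drop = FALSE] != m[, -ncol(m), drop = FALSE]) == 0
}

#' Classify a frozen-core fraction
#'
#' A frozen core of exactly 1 is a fixed point; at or above `qfp_threshold`
#' (default 0.9) a quasi-fixed point; otherwise unconverged.
#'
#' @param frozen_fraction Number in `[0, 1]`.
#' @param qfp_threshold Quasi-fixed-point threshold.
#' @return `"fixed_point"`, `"qfp"` or `"none"`.
#' @export
classify_convergence <- function(frozen_fraction, qfp_threshold = 0.9) {
  stopifnot(frozen_fraction >= 0, frozen_fraction <= 1)
  if (frozen_fraction == 1) "fixed_point"
  else if (frozen_fraction >= qfp_threshold) "qfp"
  else "none"
}

#' Estimate the ensemble convergence probability
#'
#' Draws independent realizations (topology, strengths, initial state), runs
#' the asynchronous dynamics under the standard protocol (4000-step burn-in,
#' 1000-step window, 10% of nodes updated per step), and reports the
#' fraction reaching the requested criterion, with its binomial standard
#' error.
#'
#' @param spec What to realize each round: an `ensemble_params`, a
#'   `lumped_hub_spec` (see [lumped_hub_spec()]), or a function taking the
#'   realization index and returning a `threshold_net`.
#' @param n_realizations Number of independent realizations.
#' @param criterion `"qfp"` (frozen core >= threshold, default) or
#'   `"fixed_point"` (frozen core = 1).
#' @param seed Optional master seed applied locally; realizations consume a
#'   single sequential RNG stream.
#' @inheritParams run_dynamics
#' @return A one-row tibble with columns `criterion`, `n_realizations`,
#'   `n_converged`, `p`, `se`, and a list-column `frozen_fractions`.
#' @export
estimate_convergence_probability <- function(spec, n_realizations,
                                             criterion = c("qfp", "fixed_point"),
                                             burn_in = 4000, window = 1000,
                                             update_fraction = 0.1,
                                             sign_variant = c("zero", "positive"),
                                             qfp_threshold = 0.9,
                                             seed = NULL) {
  criterion <- match.arg(criterion)
  sign_variant <- match.arg(sign_variant)
  stopifnot(n_realizations >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  realize <- realizer(spec)
  ff <- vapply(seq_len(n_realizations), function(r) {
    net <- realize(r)
    run_dynamics(net, burn_in = burn_in, window = window,
                 update_fraction = update_fraction,
                 sign_variant = sign_variant,
                 qfp_threshold = qfp_threshold)$frozen_fraction
  }, numeric(1))
  hit <- if (criterion == "fixed_point") ff == 1 else ff >= qfp_threshold
  p <- mean(hit)
  tibble::tibble(criterion = criterion,
                 n_realizations = n_realizations,
                 n_converged = sum(hit),
                 p = p,
                 se = sqrt(p * (1 - p) / n_realizations),
                 frozen_fractions = list(ff))
}

realizer <- function(spec) {
  if (is.function(spec)) return(spec)
  if (inherits(spec, "ensemble_params"))
    return(function(r) compose_network(sample_topology(spec)))
  if (inherits(spec, "lumped_hub_spec"))
    return(function(r) realize_lumped_hub(spec))
  if (inherits(spec, "threshold_net"))
    return(function(r) spec) # fixed network, random initial conditions only
  stop("spec must be ensemble_params, lumped_hub_spec, threshold_net, ",
       "or a function(index) -> threshold_net")
}
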