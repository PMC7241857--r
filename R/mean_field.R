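# Damage-spreading mean-field theory for the open-loop lumped-hub system.
#
# The order parameter is the normalized Hamming distance d(t) between two
# trajectories; its one-step map has derivative grad_d at the origin, and
# single-bit damage heals iff grad_d < 1. The analytic expression averages,
# over the Poisson in-degree of a bulk row, the probability that flipping
# one input flips the row's sign -- a two-Gaussian exceedance that reduces
# to an arctangent.

#' Exceedance probability of two folded Gaussians
#'
#' For independent standard normals `z1`, `z2` and a positive scalar `eta`,
#' `Pr(|z1| > eta * |z2|) = (2 / pi) * atan(1 / eta)`: in the
#' `(|z1|, |z2|)` plane the probability mass depends only on the angle, so
#' the event is the wedge below the line of slope `1 / eta`.
#'
#' @param eta Non-negative scalar or vector; `eta = 0` gives 1 (the limit).
#' @return Probability in `[0, 1]`.
#' @examples
#' exceedance_probability(1) # 1/2 by symmetry
#' exceedance_probability(sqrt(3)) # 1/3
#' @export
exceedance_probability <- function(eta) {
  if (any(eta < 0)) stop("eta must be non-negative")
  (2 / pi) * atan2(1, eta)
}

#' Damage-spreading derivative of the open-loop mean-field map
#'
#' Evaluates
#' \deqn{\nabla d = \frac{2 k_b}{\pi} \sum_{k' \ge 0} P_{Pois}(k'; k_b)
#'   \left[\alpha \arctan\frac{1}{\sqrt{k' + \sigma_h^2}}
#'   + (1 - \alpha) \arctan\frac{1}{\sqrt{k'}}\right],}
#' the expected number of bulk nodes whose sign flips after a single-bit
#' perturbation, in the large-`n` limit. The `k' = 0` undriven term takes
#' its limiting value \eqn{\arctan(\infty) = \pi/2}. The Poisson series is
#' truncated where the residual tail mass drops below `tail_tol`.
#'
#' The system converges under the clamped hub iff the returned value is
#' below 1.
#'
#' @param k_b Mean bulk degree (> 0). Vectorized over `k_b`, `sigma_h`,
#'   `alpha`.
#' @param sigma_h Hub strength scale (>= 0).
#' @param alpha Hub sparseness in `[0, 1]`.
#' @param tail_tol Poisson tail mass below which the series is cut
#'   (default 1e-12).
#' @return The derivative (non-negative real).
#' @export
grad_d <- function(k_b, sigma_h, alpha, tail_tol = 1e-12) {
  if (any(k_b <= 0)) stop("k_b must be positive")
  if (any(sigma_h < 0)) stop("sigma_h must be non-negative")
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  args <- vctrs_recycle(k_b = k_b, sigma_h = sigma_h, alpha = alpha)
  vapply(seq_along(args$k_b), function(q) {
    kb <- args$k_b[q]; sh <- args$sigma_h[q]; al <- args$alpha[q]
    kmax <- qpois(tail_tol, kb, lower.tail = FALSE) + 1
    kp <- 0:kmax
    w <- dpois(kp, kb)
    term <- al * atan2(1, sqrt(kp + sh^2)) + (1 - al) * atan2(1, sqrt(kp))
    (2 * kb / pi) * sum(w * term)
  }, numeric(1))
}

# minimal common-length recycling
vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, n)
}

#' Large-k_b asymptote of the damage-spreading derivative
#'
#' For a dense hub (`alpha = 1`) and large `k_b`, replacing the Poisson sum
#' by its mean and the arctangent by its argument gives
#' `2 k_b / (pi * sqrt(k_b + sigma_h^2))`, hence an asymptotically linear
#' critical line `sigma_crit ~ (2 / pi) k_b`.
#'
#' @param k_b Mean bulk degree.
#' @param sigma_h Hub strength scale.
#' @return Approximate derivative.
#' @export
grad_d_asymptotic <- function(k_b, sigma_h) {
  2 * k_b / (pi * sqrt(k_b + sigma_h^2))
}

#' Critical hub strength
#'
#' Solves `grad_d(k_b, sigma, alpha) = 1` for `sigma` by bracketing and
#' bisection (`|grad_d - 1| < tol`). Returns 0 when the undriven bulk is
#' already subcritical, and `NA` when even an infinitely strong hub cannot
#' suppress chaos (`lim_{sigma -> Inf} grad_d >= 1`, which happens for
#' sparse hubs above a maximal bulk degree).
#'
#' @param k_b Mean bulk degree (> 0).
#' @param alpha Hub sparseness in `[0, 1]`.
#' @param tol Convergence tolerance on `|grad_d - 1|` (default 1e-8).
#' @return Critical `sigma_h`, 0, or `NA` (undefined).
#' @export
sigma_crit <- function(k_b, alpha, tol = 1e-8) {
  if (length(k_b) > 1 || length(alpha) > 1)
    return(mapply(sigma_crit, k_b, alpha, MoreArgs = list(tol = tol)))
  f <- function(sig) grad_d(k_b, sig, alpha) - 1
  if (f(0) < 0) return(0)
  # sigma -> Inf limit: driven term vanishes, undriven term survives
  lim <- grad_d(k_b, 0, 0) * (1 - alpha)
  if (lim >= 1) return(NA_real_)
  hi <- 1
  while (f(hi) > 0) hi <- hi * 2
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm > 0) lo <- mid else hi <- mid
    if (hi - lo < .Machine$double.eps * max(1, hi)) return(mid)
  }
}

#' Monte-Carlo damage-spreading oracle
#'
#' Direct estimate of the damage-spreading derivative on a concrete
#' open-loop system: repeatedly draw a random `{-1, +1}` state, flip one
#' uniformly chosen bit, advance both copies one synchronous step, and
#' count differing bits. The mean count estimates the derivative (the
#' expected damage after one step); the standard error of the mean is
#' attached.
#'
#' @param system A `threshold_net` (e.g. from
#'   `assemble_system(lh, "open")`) or a `lumped_hub_net` (assembled open
#'   loop automatically).
#' @param n_trials Number of (state, flip) trials.
#' @param sign_variant Sign convention, as in [run_dynamics()].
#' @param seed Optional seed applied locally.
#' @return A one-row tibble: `estimate`, `se`, `n_trials`.
#' @export
grad_d_oracle <- function(system, n_trials = 400,
                          sign_variant = c("zero", "positive"),
                          seed = NULL) {
  if (inherits(system, "lumped_hub_net"))
    system <- assemble_system(system, "open")
  stopifnot(inherits(system, "threshold_net"), n_trials >= 2)
  if (!is.null(seed)) withr::local_seed(seed)
  W <- system$weights
  d <- cpp_damage_trials(W@Dim, W@p, W@i, W@x, system$bias,
                         as.integer(n_trials),
                         sign_variant_code(sign_variant))
  out <- tibble::tibble(estimate = mean(d),
                        se = sd(d) / sqrt(n_trials),
                        n_trials = n_trials)
  attr(out, "raw") <- as.integer(d) # per-trial damage counts, for pooling
  out
}

#' Convergence time under the mean-field map
#'
#' Steps for a perturbation of size `delta` to contract below one node
#' (`d < 1/n`) at rate `grad_d`: `-log(n * delta) / log(grad_d)` (natural
#' logarithms). Undefined (`NA`) for `grad_d >= 1`.
#'
#' @param grad_d Derivative of the distance map, in `(0, 1)`.
#' @param n Network size.
#' @param delta Initial perturbed fraction, in `(0, 1)`.
#' @return Estimated number of steps.
#' @export
convergence_time <- function(grad_d, n, delta) {
  stopifnot(delta > 0, delta < 1)
  ifelse(grad_d >= 1 | grad_d <= 0, NA_real_,
         -log(n * delta) / log(grad_d))
}

#' Hub flip statistics in the perturbed closed loop
#'
#' With `k_h` incoming hub connections and a perturbed fraction `delta`,
#' the per-step probability that the hub flips is
#' `(delta * k_h / n) * (2 / pi) * arctan(1 / sqrt(k_h))`;
#' the coarse characteristic flip time drops the arctangent factor:
#' `T_flip = n / (k_h * delta)`.
#'
#' @param delta Perturbed fraction in `(0, 1)`.
#' @param k_h Hub in-degree (>= 1).
#' @param n Network size.
#' @return `hub_flip_probability()`: probability per step;
#'   `hub_flip_time()`: steps.
#' @export
hub_flip_probability <- function(delta, k_h, n) {
  stopifnot(all(delta >= 0 & delta < 1), all(k_h >= 1))
  (delta * k_h / n) * exceedance_probability(sqrt(k_h))
}

#' @rdname hub_flip_probability
#' @export
hub_flip_time <- function(n, k_h, delta) {
  stopifnot(all(delta > 0 & delta < 1), all(k_h >= 1))
  n / (k_h * delta)
}

#' Closed-loop stability margin
#'
#' A stable open-loop fixed point survives closing the loop when the bulk
#' converges before the hub flips: `T_conv < T_flip`. Near criticality this
#' is the margin condition `1 - grad_d > (k_h * delta / n) * log(delta * n)`
#' (natural log). When stable, the predicted closed-loop convergence
#' probability is half the open-loop one (the hub's input is
#' sign-consistent with its clamped value with probability 1/2).
#'
#' @param grad_d Open-loop derivative (< 1 for a convergent system).
#' @param n Network size.
#' @param k_h Hub in-degree.
#' @param delta Perturbed fraction.
#' @return A one-row tibble: `grad_d`, `t_conv`, `t_flip`, `margin`
#'   (`1 - grad_d`), `bound` (the near-critical requirement), `status`
#'   (`"stable"`/`"marginal"`), and `p_closed_factor` (1/2 when stable).
#' @export
closed_loop_stability <- function(grad_d, n, k_h, delta) {
  stopifnot(grad_d < 1)
  t_conv <- convergence_time(grad_d, n, delta)
  t_flip <- hub_flip_time(n, k_h, delta)
  bound <- (k_h * delta / n) * log(delta * n)
  stable <- t_conv < t_flip && (1 - grad_d) > bound
  tibble::tibble(grad_d = grad_d, t_conv = t_conv, t_flip = t_flip,
                 margin = 1 - grad_d, bound = bound,
                 status = if (stable) "stable" else "marginal",
                 p_closed_factor = if (stable) 0.5 else NA_real_)
}

#' Mean-field prediction summary
#'
#' Ties the pieces together for one parameter point: the derivative, the
#' critical hub strength, open-loop convergence (derivative below 1), and
#' the closed-loop factor-of-half prediction with its stability margin.
#'
#' @inheritParams grad_d
#' @param n Network size used for the time-scale estimates.
#' @param k_h Hub in-degree (default `k_b`, a single lumped hub).
#' @param delta Perturbed fraction (default 0.1).
#' @return A one-row tibble.
#' @export
mft_prediction <- function(k_b, sigma_h, alpha, n = 1500, k_h = k_b,
                           delta = 0.1) {
  gd <- grad_d(k_b, sigma_h, alpha)
  sc <- sigma_crit(k_b, alpha)
  conv <- gd < 1
  stab <- if (conv) closed_loop_stability(gd, n, k_h, delta) else NULL
  tibble::tibble(k_b = k_b, sigma_h = sigma_h, alpha = alpha,
                 grad_d = gd, sigma_crit = sc,
                 converges_open_loop = conv,
                 p_closed_loop = if (conv && stab$status == "stable") 0.5
                                 else if (conv) NA_real_ else 0,
                 t_conv = if (conv) stab$t_conv else NA_real_,
                 t_flip = hub_flip_time(n, k_h, delta))
}

#' Convergence/chaos phase boundary
#'
#' Tabulates the critical hub strength over a grid of bulk degrees for one
#' or more sparseness values; rows where no finite critical strength exists
#' carry `NA`.
#'
#' @param k_b Vector of bulk degrees.
#' @param alpha Vector of sparseness values.
#' @return A tibble of class `phase_boundary` with columns `k_b`, `alpha`,
#'   `sigma_crit`.
#' @export
phase_boundary <- function(k_b, alpha = 1) {
  grid <- tidyr_crossing(k_b = k_b, alpha = alpha)
  grid$sigma_crit <- sigma_crit(grid$k_b, grid$alpha)
  class(grid) <- c("phase_boundary", class(grid))
  grid
}

tidyr_crossing <- function(...) {
  args <- list(...)
  grid <- expand.grid(rev(args), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  tibble::as_tibble(grid[, rev(seq_along(args)), drop = FALSE])
}

#' @export
autoplot.phase_boundary <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$k_b, y = .data$sigma_crit,
                               colour = factor(.data$alpha))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "mean bulk degree k_b",
                  y = expression(sigma[crit]),
                  colour = expression(alpha),
                  title = "Convergence/chaos phase boundary") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
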