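# Statistics of non-converging trajectories: effective dimensionality
# (participation ratio of the state covariance) and temporal
# autocorrelation with short-lag exponential fits. Used to compare original
# heterogeneous ensembles with their lumped-hub reductions beyond
# convergence probabilities.

#' Participation ratio of a trajectory segment
#'
#' Effective dimensionality `(tr C)^2 / tr(C^2)` of the state covariance
#' `C` over the segment: 1 for rank-one dynamics, `k` for isotropic
#' `k`-dimensional motion, at most `n`. A fully frozen segment has `C = 0`
#' and the ratio is undefined (`NA`).
#'
#' @param states `n x T` state matrix (rows = nodes, columns = recorded
#'   steps, `T >= 2`) or a `dynamics_result` with a recorded trajectory.
#' @return A number in `[1, n]`, or `NA` for a constant segment.
#' @export
participation_ratio <- function(states) {
  states <- as_state_matrix(states)
  stopifnot(ncol(states) >= 2)
  X <- t(states)
  X <- sweep(X, 2, colMeans(X))
  G <- crossprod(X) / (nrow(X) - 1)  # node covariance
  tr <- sum(diag(G))
  if (tr == 0) return(NA_real_)
  tr^2 / sum(G^2)
}

as_state_matrix <- function(states) {
  if (inherits(states, "dynamics_result")) {
    if (is.null(states$trajectory))
      stop("dynamics_result has no recorded trajectory; rerun with record = TRUE")
    states <- states$trajectory
  }
  states
}

#' Node-averaged temporal autocorrelation of a trajectory
#'
#' For each node, the temporal autocovariance at lags `0..max_lag`
#' (after subtracting the node's temporal mean by default), summed over
#' nodes and normalized so the lag-0 value is 1. Set `demean = FALSE` for
#' the raw product (no mean subtraction), in which case a frozen node
#' contributes a constant 1.
#'
#' @param states `n x T` state matrix or a recorded `dynamics_result`.
#' @param max_lag Largest lag (must leave a positive averaging window).
#' @param demean Subtract each node's temporal mean (default `TRUE`).
#' @return A tibble of class `autocorr_profile` with columns `lag`,
#'   `autocorrelation`.
#' @export
autocorrelation_profile <- function(states, max_lag = 20, demean = TRUE) {
  states <- as_state_matrix(states)
  Tn <- ncol(states)
  stopifnot(max_lag < Tn)
  X <- states
  if (demean) X <- X - rowMeans(X)
  ac <- vapply(0:max_lag, function(l) {
    a <- X[, 1:(Tn - l), drop = FALSE]
    b <- X[, (1 + l):Tn, drop = FALSE]
    sum(a * b) / (Tn - l)
  }, numeric(1))
  if (ac[1] == 0) ac <- rep(ifelse(demean, NA_real_, 0), max_lag + 1)
  else ac <- ac / ac[1]
  if (!demean && all(states == states[, 1])) ac <- rep(1, max_lag + 1)
  out <- tibble::tibble(lag = 0:max_lag, autocorrelation = ac)
  class(out) <- c("autocorr_profile", class(out))
  out
}

#' Asymptotic autocorrelation of a profile
#'
#' Mean autocorrelation over the last quarter of computed lags; used with
#' the 0.3 threshold to filter out frozen or near-frozen trajectories
#' before ensemble averaging.
#'
#' @param profile An `autocorr_profile`.
#' @return A number (or `NA` for a degenerate profile).
#' @export
asymptotic_autocorrelation <- function(profile) {
  k <- nrow(profile)
  tail_idx <- seq.int(ceiling(3 * k / 4), k)
  mean(profile$autocorrelation[tail_idx])
}

#' Exponential decay rate of the short-lag autocorrelation
#'
#' Log-linear least-squares fit `log A(l) ~ l` over lags `0..lag_max`
#' (default 5); the decay rate is minus the slope. Non-positive
#' autocorrelation values inside the fit range are dropped; if fewer than
#' two usable points remain the rate is `NA`.
#'
#' @param profile An `autocorr_profile`.
#' @param lag_max Largest lag entering the fit (default 5).
#' @return Decay rate (per step).
#' @export
fit_autocorr_decay <- function(profile, lag_max = 5) {
  d <- profile[profile$lag <= lag_max & profile$autocorrelation > 0, ]
  if (nrow(d) < 2 || anyNA(d$autocorrelation)) return(NA_real_)
  fit <- lm(log(autocorrelation) ~ lag, data = d)
  -unname(coef(fit)[2])
}

#' Summary statistics of one trajectory
#'
#' @param states `n x T` state matrix or recorded `dynamics_result`.
#' @param max_lag Largest autocorrelation lag.
#' @return A one-row tibble: `participation_ratio`, `asymptotic_autocorr`,
#'   `decay_rate`.
#' @export
trajectory_statistics <- function(states, max_lag = 20) {
  states <- as_state_matrix(states)
  prof <- autocorrelation_profile(states, max_lag = max_lag)
  tibble::tibble(participation_ratio = participation_ratio(states),
                 asymptotic_autocorr = asymptotic_autocorrelation(prof),
                 decay_rate = fit_autocorr_decay(prof))
}
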