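# Exhaustive fixed-point enumeration for small dense threshold networks,
# ensemble censuses, and Poisson reference laws.
#
# Undriven networks have fixed points in +-s pairs (the sign map is odd), so
# the pair count M/2 is the natural object; a symmetry-breaking drive
# unpairs them.

#' Enumerate all fixed points of a small threshold network
#'
#' Checks every state `s` in `{-1, +1}^n` for `s = sign(W s + drive)`
#' elementwise, by Gray-code traversal (one column update per state), so
#' the enumeration is exact. States whose field has a zero component cannot
#' be `{-1, +1}` fixed points and are counted as non-fixed (measure zero
#' for continuous weights). Guarded at `n <= 24`.
#'
#' @param W Square numeric matrix of weights (dense).
#' @param drive Optional drive vector added inside the threshold; scaled by
#'   `sigma_h`.
#' @param sigma_h Scale applied to `drive` (default 1).
#' @param return_states If `TRUE`, also return the fixed states.
#' @return A list: `count`, and (if requested) `states`, an
#'   `n x count` matrix of `{-1, +1}` columns.
#' @examples
#' W <- diag(3)
#' enumerate_fixed_points(W)$count # 8: every +-1 state is fixed
#' @export
enumerate_fixed_points <- function(W, drive = NULL, sigma_h = 1,
                                   return_states = FALSE) {
  W <- as.matrix(W)
  n <- ncol(W)
  stopifnot(nrow(W) == n)
  if (n > 24)
    stop("n > 24: exhaustive enumeration over 2^n states refused; ",
         "use sampling-based search instead")
  if (is.null(drive)) drive <- numeric(n)
  stopifnot(length(drive) == n)
  res <- cpp_enumerate_fixed_points(W, sigma_h * drive, return_states)
  out <- list(count = res$count)
  if (return_states) {
    codes <- res$codes
    states <- matrix(1L, n, length(codes))
    for (b in seq_len(n)) {
      neg <- bitwAnd(codes, bitwShiftL(1L, b - 1L)) != 0L
      states[b, neg] <- -1L
    }
    out$states <- states
  }
  out
}

#' Fixed-point census over a dense Gaussian ensemble
#'
#' For each realization draws a fully connected network with i.i.d.
#' `N(0, 1/n)` weights (all entries, self-couplings included) and, when
#' `sigma_h > 0`, a dense drive vector `u` with i.i.d. standard-Gaussian
#' entries scaled by `sigma_h`; counts the fixed points of
#' `s = sign(W s + sigma_h u)` by exhaustive enumeration. The `1/n` weight
#' normalization puts the recurrent input on unit scale, so `sigma_h`
#' measures the drive against it.
#'
#' @param n Network size (<= 24; default 16).
#' @param n_realizations Number of independent `(W, u)` draws.
#' @param sigma_h Drive scale (0 = undriven).
#' @param seed Optional seed applied locally.
#' @return An object of class `fp_census`: the integer vector `M` of
#'   per-realization counts plus metadata. Use [tidy()] for the empirical
#'   distribution and [glance()] or [mean_fixed_point_count()] for the
#'   mean.
#' @export
fixed_point_census <- function(n = 16, n_realizations = 1e4, sigma_h = 0,
                               seed = NULL) {
  stopifnot(n <= 24, n_realizations >= 1, sigma_h >= 0)
  if (!is.null(seed)) withr::local_seed(seed)
  sdw <- 1 / sqrt(n)
  M <- integer(n_realizations)
  for (r in seq_len(n_realizations)) {
    W <- matrix(rnorm(n * n, sd = sdw), n, n)
    drive <- if (sigma_h > 0) sigma_h * rnorm(n) else numeric(n)
    M[r] <- cpp_enumerate_fixed_points(W, drive, FALSE)$count
  }
  structure(list(M = M, n = n, n_realizations = n_realizations,
                 sigma_h = sigma_h),
            class = "fp_census")
}

#' @export
print.fp_census <- function(x, ...) {
  cat("<fp_census> n =", x$n, " realizations =", x$n_realizations,
      " sigma_h =", x$sigma_h, "\n")
  print(tidy(x), n = 8)
  invisible(x)
}

#' @describeIn fixed_point_census Empirical distribution `P(M = m)` with
#'   binomial standard errors, as a tibble.
#' @param x,object An `fp_census`.
#' @param max_m Largest count to tabulate (default: observed maximum).
#' @param ... Unused.
#' @export
tidy.fp_census <- function(x, max_m = max(x$M), ...) {
  m <- 0:max_m
  p <- vapply(m, function(k) mean(x$M == k), numeric(1))
  tibble::tibble(m = m, probability = p,
                 se = sqrt(p * (1 - p) / x$n_realizations),
                 sigma_h = x$sigma_h)
}

#' @describeIn fixed_point_census One-row summary: mean count and its
#'   standard error.
#' @export
glance.fp_census <- function(x, ...) {
  tibble::tibble(n = x$n, n_realizations = x$n_realizations,
                 sigma_h = x$sigma_h,
                 mean_M = mean(x$M),
                 se_mean_M = sd(x$M) / sqrt(x$n_realizations))
}

#' Mean fixed-point count of a census
#'
#' The ensemble expectation of the number of fixed points is exactly 1 for
#' this model class; the sample mean should sit within sampling error of it.
#'
#' @param census An `fp_census`.
#' @return A one-row tibble: `mean_M`, `se`.
#' @export
mean_fixed_point_count <- function(census) {
  stopifnot(inherits(census, "fp_census"))
  tibble::tibble(mean_M = mean(census$M),
                 se = sd(census$M) / sqrt(census$n_realizations))
}

#' Poisson reference distribution for fixed-point counts
#'
#' Undriven networks: fixed points come in `+-s` pairs and the pair count is
#' asymptotically `Poisson(1/2)`, so `P(M = 2j) = e^(-lambda) lambda^j / j!`
#' and odd counts have probability 0 (`paired = TRUE`, `lambda = 1/2`).
#' Weakly driven networks: single fixed points, `M ~ Poisson(1)`
#' (`paired = FALSE`, `lambda = 1`). Both references have mean count 1.
#'
#' @param lambda Poisson rate.
#' @param paired If `TRUE`, `M/2 ~ Poisson(lambda)`; otherwise
#'   `M ~ Poisson(lambda)`.
#' @param max_m Largest count to tabulate.
#' @return A tibble with columns `m`, `probability`.
#' @examples
#' poisson_reference(1 / 2, paired = TRUE, max_m = 4)
#' @export
poisson_reference <- function(lambda, paired = TRUE, max_m = 10) {
  stopifnot(lambda > 0)
  m <- 0:max_m
  p <- if (paired) ifelse(m %% 2 == 0, dpois(m %/% 2, lambda), 0)
       else dpois(m, lambda)
  tibble::tibble(m = m, probability = p)
}

#' @export
autoplot.fp_census <- function(object, reference = NULL, max_m = 6, ...) {
  emp <- tidy(object, max_m = max_m)
  p <- ggplot2::ggplot(emp, ggplot2::aes(x = .data$m,
                                         y = .data$probability)) +
    ggplot2::geom_col(fill = "steelblue", alpha = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$probability - .data$se,
                                        ymax = .data$probability + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = "number of fixed points M", y = "P(M)",
                  title = sprintf("Fixed-point census (n = %d, sigma_h = %g)",
                                  object$n, object$sigma_h)) +
    ggplot2::theme_minimal()
  if (!is.null(reference))
    p <- p + ggplot2::geom_point(data = head(reference, max_m + 1),
                                 ggplot2::aes(x = .data$m,
                                              y = .data$probability),
                                 colour = "red", shape = 3, size = 3)
  p
}
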