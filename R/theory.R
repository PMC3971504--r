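## Exact order-statistic theory of the L1 distance between uniformly placed
## test points and the optimum cocktail on the (T+1)^n index lattice.
##
## Per axis, with both the test coordinate and the optimum coordinate uniform
## on {0..T}, the signed difference Z has a triangular pmf and its absolute
## value W a folded version; the L1 distance of one random point is the n-fold
## convolution of W, and the distance of the closest of m points follows from
## the minimum order statistic.

new_distance_pmf <- function(support, pmf, provenance) {
  stopifnot(length(support) == length(pmf))
  structure(list(support = support, pmf = pmf, provenance = provenance),
            class = "distance_pmf")
}

#' @export
print.distance_pmf <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("Distance pmf [%s] on %d..%d; mean %.4f\n",
              paste(names(p), unlist(p), sep = "=", collapse = ", "),
              min(x$support), max(x$support),
              sum(x$support * x$pmf)))
  invisible(x)
}

check_T <- function(T) {
  if (!is.numeric(T) || length(T) != 1L || T < 1 || T != round(T))
    stop("`T` must be a single integer >= 1")
  as.integer(T)
}

#' Per-axis signed difference distribution
#'
#' Pmf of \code{Z = V(i) - Vmax(i)} when both coordinates are independent and
#' uniform on \code{0..T}: the discrete triangular law
#' \code{f(z) = (T + 1 - |z|) / (T + 1)^2} on \code{-T..T}.
#'
#' @param T maximum discretization index.
#' @return a \code{"distance_pmf"} on support \code{-T..T}.
#' @export
axis_difference_pmf <- function(T) {
  T <- check_T(T)
  z <- (-T):T
  new_distance_pmf(z, (T + 1 - abs(z)) / (T + 1)^2, list(kind = "Z", T = T))
}

#' Per-axis absolute distance distribution
#'
#' Pmf of \code{W = |Z|}, the per-drug distance between a uniform test
#' coordinate and a uniform optimum coordinate:
#' \code{f(0) = 1/(T+1)} and \code{f(w) = 2 (T + 1 - w) / (T + 1)^2} for
#' \code{w = 1..T}.
#'
#' @param T maximum discretization index.
#' @return a \code{"distance_pmf"} on support \code{0..T}.
#' @export
axis_distance_pmf <- function(T) {
  T <- check_T(T)
  w <- 0:T
  p <- 2 * (T + 1 - w) / (T + 1)^2
  p[1] <- 1 / (T + 1)
  new_distance_pmf(w, p, list(kind = "W", T = T))
}

## exact linear convolution of two pmfs given as plain vectors (supports
## starting at 0); direct O(k^2) sum, no FFT round-off
convolve_pmf <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    idx <- i:(i + length(b) - 1L)
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

#' L1 distance of one uniformly placed point from the optimum
#'
#' Distribution of \code{R1 = sum_i |V(i) - Vmax(i)|} for one point placed
#' uniformly on the grid, with the optimum also uniform: the n-fold
#' self-convolution of [axis_distance_pmf()].
#'
#' @param n number of drugs.
#' @param T maximum discretization index.
#' @return a \code{"distance_pmf"} on support \code{0..n*T}.
#' @export
l1_distance_pmf <- function(n, T) {
  if (n < 1 || n != round(n)) stop("`n` must be a single integer >= 1")
  w <- axis_distance_pmf(T)$pmf
  p <- w
  if (n > 1) for (i in 2:n) p <- convolve_pmf(p, w)
  new_distance_pmf(0:(n * T), p, list(kind = "R1", n = n, T = T))
}

#' Minimum L1 distance among m uniformly placed points
#'
#' Distribution of \code{R2 = min(X1, ..., Xm)} with the \code{Xj} i.i.d.
#' copies of the single-point distance \code{R1}:
#' \code{CDF(x) = 1 - (1 - CDF_R1(x))^m}, with the pmf recovered by first
#' differences.
#'
#' @param n number of drugs.
#' @param T maximum discretization index.
#' @param m number of independently placed points.
#' @return a \code{"distance_pmf"} on support \code{0..n*T}.
#' @export
min_l1_distance_pmf <- function(n, T, m) {
  if (m < 1 || m != round(m)) stop("`m` must be a single integer >= 1")
  r1 <- l1_distance_pmf(n, T)
  cdf <- 1 - (1 - cumsum(r1$pmf))^m
  new_distance_pmf(r1$support, diff(c(0, cdf)),
                   list(kind = "R2", n = n, T = T, m = m))
}

pmf_mean <- function(d) sum(d$support * d$pmf)
pmf_var <- function(d) sum(d$support^2 * d$pmf) - pmf_mean(d)^2

#' Moments of the minimum L1 distance from the optimum
#'
#' Exact mean and variance of [min_l1_distance_pmf()]: how close the best of
#' \code{m} uniformly placed cocktails is expected to land to the optimum.
#'
#' @inheritParams min_l1_distance_pmf
#' @return list with elements \code{mean} and \code{variance}.
#' @examples
#' min_distance_moments(5, 10, 40)$mean  # 6.86
#' @export
min_distance_moments <- function(n, T, m) {
  d <- min_l1_distance_pmf(n, T, m)
  list(mean = pmf_mean(d), variance = pmf_var(d))
}

#' Moments of the minimum distance to any of k well-separated optima
#'
#' With \code{k} optima in diverse locations the minimum is taken over
#' \code{k * m} point-to-optimum distances, so the moments equal those of a
#' single optimum with \code{k * m} points.
#'
#' @inheritParams min_l1_distance_pmf
#' @param k number of well-separated optimal points (>= 1).
#' @return list with elements \code{mean} and \code{variance}.
#' @export
multi_optimum_moments <- function(n, T, m, k) {
  if (k < 1 || k != round(k)) stop("`k` must be a single integer >= 1")
  min_distance_moments(n, T, m * k)
}

#' Density of a product of independent uniforms
#'
#' Density of \code{G1 * G2 * ... * Gr} with each factor uniform on
#' \code{(0, 1)}: \code{(log(1/x))^(r-1) / (r-1)!}. This models the per-
#' refinement shrinkage of the distance to the optimum during focused search.
#'
#' @param x evaluation points in \code{(0, 1]}.
#' @param r number of uniform factors (integer >= 1).
#' @return density values at \code{x}.
#' @export
product_uniform_pdf <- function(x, r) {
  if (r < 1 || r != round(r)) stop("`r` must be a single integer >= 1")
  if (any(x <= 0) || any(x > 1)) stop("`x` must lie in (0, 1]")
  log(1 / x)^(r - 1) / factorial(r - 1)
}

#' Expected distance after focused refinements
#'
#' Each focused refinement multiplies the expected distance to the optimum by
#' the mean of a uniform factor (1/2), so after \code{rho1} refinements an
#' initial expected distance \code{D} shrinks to \code{D / 2^rho1}.
#'
#' @param D initial expected distance (>= 0).
#' @param rho1 number of focused refinements near the optimum (>= 0).
#' @return \code{D / 2^rho1}.
#' @examples
#' expected_distance_after_focus(19.7, 6)  # 0.3078125
#' @export
expected_distance_after_focus <- function(D, rho1) {
  if (D < 0) stop("`D` must be >= 0")
  if (rho1 < 0) stop("`rho1` must be >= 0")
  D / 2^rho1
}

#' Analytic expected minimum-distance trajectory
#'
#' Expected minimum L1 distance from the optimum after each experiment of a
#' run: during the initialization phase (iterations \code{1..m}) the curve is
#' the exact mean of the minimum over the points placed so far; beyond
#' \code{m} it decays by the focused-refinement model with an expected
#' \code{(iter - m) * p_focus} refinements.
#'
#' @inheritParams min_l1_distance_pmf
#' @param p_focus probability of a focused step per iteration.
#' @param iters total number of iterations (>= m).
#' @return numeric vector of length \code{iters}.
#' @export
theoretical_trajectory <- function(n, T, m, p_focus = 0.3, iters) {
  if (iters < m) stop("`iters` must be >= m")
  means <- vapply(seq_len(m), function(mm) min_distance_moments(n, T, mm)$mean,
                  numeric(1))
  D <- means[m]
  out <- c(means,
           if (iters > m)
             D / 2^((seq_len(iters - m)) * p_focus))
  out
}

#' Table of minimum-distance moments over a parameter lattice
#'
#' Convenience wrapper evaluating [min_distance_moments()] on the cross
#' product of the supplied parameter vectors.
#'
#' @param n,T,m integer vectors of parameter values.
#' @return data frame with columns \code{n}, \code{T}, \code{m}, \code{mean},
#'   \code{variance}.
#' @export
min_distance_table <- function(n, T, m) {
  tab <- expand.grid(m = m, T = T, n = n)[, c("n", "T", "m")]
  mom <- mapply(function(ni, Ti, mi) unlist(min_distance_moments(ni, Ti, mi)),
                tab$n, tab$T, tab$m)
  tab$mean <- mom["mean", ]
  tab$variance <- mom["variance", ]
  tab
}
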