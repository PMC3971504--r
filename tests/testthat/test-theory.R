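test_that("per-axis signed and absolute distance pmfs match their closed forms", {
  z <- axis_difference_pmf(10)
  expect_equal(sum(z$pmf), 1, tolerance = 1e-14)
  expect_equal(z$pmf[z$support == 0], 11 / 121)
  expect_equal(z$pmf[z$support == 10], 1 / 121)
  expect_equal(z$pmf[z$support == -10], 1 / 121)
  expect_equal(z$pmf, rev(z$pmf))  # symmetry

  w <- axis_distance_pmf(10)
  expect_equal(sum(w$pmf), 1, tolerance = 1e-14)
  expect_equal(w$pmf[w$support == 0], 1 / 11)
  expect_equal(w$pmf[w$support == 1], 20 / 121)

  ## folding |Z| about 0 reproduces the absolute-distance pmf
  folded <- vapply(0:10, function(v)
    sum(z$pmf[abs(z$support) == v]), numeric(1))
  expect_equal(w$pmf, folded)
  expect_error(axis_distance_pmf(0), ">= 1")
})

test_that("single-point L1 distance is the n-fold convolution with exact moments", {
  expect_equal(l1_distance_pmf(1, 10)$pmf, axis_distance_pmf(10)$pmf)
  for (n in c(2, 5, 9)) {
    r1 <- l1_distance_pmf(n, 10)
    expect_equal(length(r1$pmf), n * 10 + 1)
    expect_equal(sum(r1$pmf), 1, tolerance = 1e-12)
    w <- axis_distance_pmf(10)
    expect_equal(sum(r1$support * r1$pmf), n * sum(w$support * w$pmf),
                 tolerance = 1e-12)  # mean is n * E[W]
  }
})

test_that("single-point distance pmf agrees with direct simulation", {
  set.seed(1)
  n <- 5; T <- 10; reps <- 1e5
  v <- matrix(sample(0:T, n * reps, TRUE), ncol = n)
  vmax <- matrix(sample(0:T, n * reps, TRUE), ncol = n)
  emp <- tabulate(rowSums(abs(v - vmax)) + 1L, nbins = n * T + 1) / reps
  tv <- sum(abs(emp - l1_distance_pmf(n, T)$pmf)) / 2
  expect_lt(tv, 0.02)
})

test_that("minimum-of-m distribution follows the order-statistic identity", {
  expect_equal(min_l1_distance_pmf(3, 10, 1)$pmf, l1_distance_pmf(3, 10)$pmf)
  r2 <- min_l1_distance_pmf(5, 10, 40)
  cdf <- cumsum(r2$pmf)
  expect_true(all(diff(cdf) >= -1e-14))
  expect_equal(cdf[length(cdf)], 1, tolerance = 1e-12)
  expect_equal(sum(r2$pmf), 1, tolerance = 1e-12)

  ## Monte-Carlo minimum over m independent single-point draws
  set.seed(2)
  r1 <- l1_distance_pmf(5, 10)
  draws <- matrix(sample(r1$support, 40 * 1e4, TRUE, prob = r1$pmf), ncol = 40)
  mins <- apply(draws, 1, min)
  mom <- min_distance_moments(5, 10, 40)
  se <- sqrt(mom$variance / 1e4)
  expect_lt(abs(mean(mins) - mom$mean), 3 * se)
})

test_that("minimum-distance moments reproduce the reference lattice to 2 decimals", {
  expected <- data.frame(
    n = rep(c(5, 10, 15), each = 6),
    T = rep(rep(c(5, 10), each = 3), 3),
    m = rep(c(20, 40, 60), 6),
    mean = c(4.15, 3.42, 3.04, 8.15, 6.86, 6.21,
             11.35, 10.20, 9.59, 21.75, 19.70, 18.62,
             19.16, 17.69, 16.92, 36.45, 33.83, 32.45),
    variance = c(1.77, 1.29, 1.09, 5.25, 3.71, 3.06,
                 4.29, 3.32, 2.90, 13.35, 10.21, 8.83,
                 6.88, 5.43, 4.79, 21.76, 17.02, 14.94))
  got <- min_distance_table(c(5, 10, 15), c(5, 10), c(20, 40, 60))
  got <- got[order(got$n, got$T, got$m), ]
  expected <- expected[order(expected$n, expected$T, expected$m), ]
  expect_equal(round(got$mean, 2), expected$mean)
  expect_equal(round(got$variance, 2), expected$variance)
})

test_that("moments shift monotonically with m, n and T", {
  means_m <- vapply(c(20, 40, 60),
                    function(m) min_distance_moments(5, 5, m)$mean, numeric(1))
  expect_true(all(diff(means_m) < 0))
  means_n <- vapply(c(5, 10, 15),
                    function(n) min_distance_moments(n, 10, 40)$mean, numeric(1))
  expect_true(all(diff(means_n) > 0))
  means_T <- vapply(c(5, 10),
                    function(T) min_distance_moments(10, T, 40)$mean, numeric(1))
  expect_true(all(diff(means_T) > 0))
})

test_that("multiple diverse optima act like a single optimum with k*m points", {
  expect_equal(multi_optimum_moments(5, 5, 20, 1),
               min_distance_moments(5, 5, 20))
  expect_equal(round(multi_optimum_moments(5, 5, 20, 2)$mean, 2), 3.42)
  expect_equal(round(multi_optimum_moments(5, 5, 20, 3)$mean, 2), 3.04)
})

test_that("product-of-uniforms density is a proper density with mean 2^-r", {
  x <- seq(0.01, 1, by = 0.01)
  expect_equal(product_uniform_pdf(x, 1), rep(1, length(x)))
  for (r in 1:6) {
    total <- integrate(product_uniform_pdf, 0, 1, r = r,
                       rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-8)
    mn <- integrate(function(x) x * product_uniform_pdf(x, r), 0, 1,
                    rel.tol = 1e-10)$value
    expect_equal(mn, 2^-r, tolerance = 1e-8)
  }
  expect_error(product_uniform_pdf(0, 2), "\\(0, 1\\]")
  expect_error(product_uniform_pdf(1.2, 2), "\\(0, 1\\]")
})

test_that("focused-refinement decay halves the expected distance per step", {
  expect_equal(expected_distance_after_focus(19.7, 6), 19.7 / 64)
  expect_equal(round(expected_distance_after_focus(19.7, 6), 4), 0.3078)
  expect_equal(expected_distance_after_focus(7.3, 0), 7.3)
  ## composition in the exponent
  expect_equal(
    expected_distance_after_focus(expected_distance_after_focus(12, 2), 3),
    expected_distance_after_focus(12, 5))
})

test_that("the analytic trajectory stitches the two phases consistently", {
  tr <- theoretical_trajectory(10, 10, 40, p_focus = 0.3, iters = 60)
  expect_length(tr, 60)
  expect_equal(tr[40], min_distance_moments(10, 10, 40)$mean)
  expect_equal(tr[60], min_distance_moments(10, 10, 40)$mean / 2^6)
  expect_equal(round(tr[60], 4), 0.3078)
  expect_true(all(diff(tr) <= 1e-12))  # non-increasing
  expect_error(theoretical_trajectory(2, 5, 10, iters = 5), ">= m")
})
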