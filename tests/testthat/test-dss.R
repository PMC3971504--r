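test_that("normalization rescales to [0,1] and powering preserves ranks", {
  expect_equal(normalize_and_power(c(2, 4, 6), n = 2), c(0, 0.5, 1))
  expect_equal(normalize_and_power(c(0, 0.5, 1), n = 3), c(0, 0.25, 1))
  expect_equal(normalize_and_power(c(0.3, 0.3), n = 4), c(1, 1))  # degenerate
  set.seed(1)
  for (rep in 1:20) {
    v <- runif(15)
    w <- normalize_and_power(v, n = sample(2:6, 1))
    expect_equal(order(w), order(v))  # monotone transform
    expect_true(all(w >= 0 & w <= 1))
  }
})

test_that("path choice is a Bernoulli draw with the requested probability", {
  set.seed(2)
  expect_true(all(replicate(50, dosesearch:::choose_path(0)) == "diverse"))
  expect_true(all(replicate(50, dosesearch:::choose_path(1)) == "focused"))
  draws <- replicate(10000, dosesearch:::choose_path(0.3))
  frac <- mean(draws == "focused")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 10000))
})

test_that("steepest ascent terminates at local maxima found by a reference climber", {
  g <- search_grid(2, 6)
  ## local max returns itself
  s <- hill_surface(g, c(3, 3), 2, 1)
  expect_equal(ascent_path(s$values, g, c(3, 3)), rbind(c(3, 3)),
               ignore_attr = TRUE)
  ## monotone ramp climbs to the top end
  g1 <- search_grid(1, 10)
  expect_equal(as.vector(ascent_path(seq(0, 1, length.out = 11), g1, 0)), 10)
  ## random surfaces vs the independent climber (continuous values: no ties)
  for (seed in 1:5) {
    set.seed(seed)
    vals <- runif(grid_size(g))
    start <- c(sample(0:6, 1), sample(0:6, 1))
    expect_equal(as.vector(ascent_path(vals, g, start)),
                 oracle_hill_climb(vals, g, start))
  }
})

test_that("Gibbs sampling reproduces point masses and uniform distributions", {
  ## point mass
  pmf <- numeric(25); pmf[13] <- 1
  set.seed(3)
  s <- gibbs_sample(pmf, c(5, 5), count = 50)
  expect_true(all(s[, 1] == 2 & s[, 2] == 2))  # 0-based (2,2) = linear 13

  ## uniform on 11^2: per-cell frequency within 4 sigma of the binomial
  set.seed(4)
  n_samp <- 10000
  s <- gibbs_sample(rep(1, 121), c(11, 11), count = n_samp)
  lin <- s[, 1] + 11 * s[, 2] + 1
  counts <- tabulate(lin, nbins = 121)
  p <- 1 / 121
  bound <- 4 * sqrt(n_samp * p * (1 - p))
  expect_true(all(abs(counts - n_samp * p) <= bound))

  expect_error(gibbs_sample(numeric(9), c(3, 3), 10), "degenerate")
})

test_that("Gibbs sampling recovers the mass ratio of a two-hill distribution", {
  g <- search_grid(2, 10)
  s <- hill_surface(g, rbind(c(2, 5), c(8, 5)), widths = 2.5,
                    heights = c(1, 0.6))
  pmf <- s$values
  left_mass <- sum(pmf[dosesearch:::grid_points(g)[, 1] <= 5])
  true_ratio <- left_mass / sum(pmf)
  set.seed(5)
  draws <- gibbs_sample(pmf, c(11, 11), count = 10000)
  emp_ratio <- mean(draws[, 1] <= 5)
  expect_lt(abs(emp_ratio - true_ratio) / true_ratio, 0.10)

  ## direct multinomial sampling as the independent oracle for the same check
  set.seed(6)
  direct <- sample.int(121, 10000, TRUE, prob = pmf)
  dir_ratio <- mean((dosesearch:::grid_points(g)[direct, 1]) <= 5)
  expect_lt(abs(emp_ratio - dir_ratio), 0.05)
})

test_that("focused search returns the top estimated point and respects hills", {
  ## two-hill 1-D fixture: hill A peaks at position 2 (0.9), hill B at
  ## position 7 (0.25); positions 2,3,4 are A's three highest points
  g1 <- search_grid(1, 10)
  vals <- c(0.05, 0.2, 0.9, 0.5, 0.3, 0.1, 0.12, 0.25, 0.2, 0.15, 0.05)

  ## top point estimated -> returned immediately
  res <- dosesearch:::focused_step(vals, exp_lin = c(1L, 2L), grid = g1,
                                   cluster_threshold = 2, cluster_break = 11,
                                   cluster_sphere_fraction = 1 / 500)
  expect_equal(res$type, "candidate")
  expect_equal(res$lin, 3L)  # 0-based position 2, the global peak

  ## top-2 experimental on hill A, third estimated on the same hill,
  ## threshold > 2 -> the third point is the candidate
  res <- dosesearch:::focused_step(vals, exp_lin = c(3L, 4L), grid = g1,
                                   cluster_threshold = 3, cluster_break = 11,
                                   cluster_sphere_fraction = 1 / 500)
  expect_equal(res$type, "candidate")
  expect_equal(res$lin, 5L)  # position 4, still on hill A

  ## with threshold 2, hill A is discovered after its top-2 points and the
  ## candidate comes from hill B instead
  res <- dosesearch:::focused_step(vals, exp_lin = c(3L, 4L), grid = g1,
                                   cluster_threshold = 2, cluster_break = 11,
                                   cluster_sphere_fraction = 1 / 500)
  expect_equal(res$type, "candidate")
  expect_equal(res$lin, 8L)  # position 7, hill B's peak
  hill_of_cand <- dosesearch:::ascend_lin(vals, 11L, 1L, g1, res$lin, NULL)
  expect_equal(hill_of_cand, 8L)
})

test_that("an over-explored peak triggers suppression that restores losslessly", {
  g1 <- search_grid(1, 10)
  vals <- c(0.05, 0.2, 0.9, 0.5, 0.3, 0.1, 0.12, 0.25, 0.2, 0.15, 0.05)
  ## every inspected point experimental within a tiny walk budget
  res <- dosesearch:::focused_step(vals, exp_lin = c(3L, 4L, 5L), grid = g1,
                                   cluster_threshold = 5, cluster_break = 3,
                                   cluster_sphere_fraction = 1 / 500)
  expect_equal(res$type, "break")
  expect_equal(res$center, 3L)  # the current highest point
  expect_true(res$center %in% res$sphere)

  ## suppress-then-restore round trip is exact
  archived <- vals[res$sphere]
  suppressed <- vals
  suppressed[res$sphere] <- 0
  restored <- suppressed
  restored[res$sphere] <- archived
  expect_identical(restored, vals)
})

test_that("diverse search proposes untested points weighted by the estimate", {
  g <- search_grid(2, 4)
  ## concentrated estimate -> that point is returned
  vals <- numeric(25); vals[17] <- 1
  set.seed(7)
  expect_equal(dosesearch:::diverse_step(vals, exp_lin = 1L, g,
                                         gibbs_points = 20, burn_in = 5), 17L)
  ## never repeats an experimental point
  set.seed(8)
  vals <- runif(25)
  tested <- c(1L, 5L, 13L, 25L)
  picks <- replicate(200, dosesearch:::diverse_step(vals, tested, g, 30, 5))
  expect_true(!any(picks %in% tested))
  ## candidate frequency increases with estimate height
  freq <- tabulate(picks, nbins = 25)[-tested]
  expect_gt(cor(freq, vals[-tested], method = "spearman"), 0)
})

test_that("with uniform weights the diverse path is uniform over untested points", {
  g <- search_grid(2, 4)
  tested <- c(2L, 12L, 23L)
  set.seed(9)
  picks <- replicate(3000, dosesearch:::diverse_step(rep(1, 25), tested, g,
                                                     gibbs_points = 10,
                                                     burn_in = 2))
  counts <- tabulate(picks, nbins = 25)[-tested]
  p <- 1 / 22
  expect_true(all(abs(counts - 3000 * p) <= 4 * sqrt(3000 * p * (1 - p))))
})

test_that("a full search logs every query once and never repeats a point", {
  s <- builtin_sphere_surface()
  fit <- dss_search(s, m = 5, max_steps = 40, seed = 11)
  expect_equal(nrow(fit$trajectory), 40)
  expect_equal(n_queries(s), 40L)
  pts <- as.matrix(fit$trajectory[, c("d1", "d2")])
  expect_equal(anyDuplicated(pts), 0)
  expect_true(all(fit$trajectory$path[1:5] == "lhs"))
  expect_true(all(fit$trajectory$path[-(1:5)] %in% c("focused", "diverse")))
  ## the logged sensitivities match the surface
  expect_equal(fit$trajectory$sensitivity,
               s$values[dosesearch:::point_to_linear(s$grid, pts)])
  expect_error(dss_search(s, m = 10, max_steps = 5), "at least m")
})

test_that("identical seeds give bit-identical trajectories", {
  s1 <- builtin_sphere_surface()
  s2 <- builtin_sphere_surface()
  f1 <- dss_search(s1, m = 5, max_steps = 30, seed = 21)
  f2 <- dss_search(s2, m = 5, max_steps = 30, seed = 21)
  expect_identical(f1$trajectory, f2$trajectory)
})

test_that("minimum distance to the optimum is non-increasing along a run", {
  for (seed in c(31, 32, 33)) {
    s <- builtin_sphere_surface()
    fit <- dss_search(s, m = 5, max_steps = 50, seed = seed)
    md <- min_distance_trajectory(
      as.matrix(fit$trajectory[, c("d1", "d2")]), s$optima)
    expect_true(all(diff(md) <= 0))
  }
})

test_that("initial-phase minimum distances agree with the analytic band", {
  ## conditions with m large enough for the uniform-placement approximation:
  ## 4 drugs, levels 0..10, m = 40, optimum placed uniformly per run
  g <- search_grid(4, 10)
  runs <- 100
  d <- numeric(runs)
  for (r in seq_len(runs)) {
    set.seed(5000 + r)
    center <- sample(0:10, 4, replace = TRUE)
    s <- inverted_sphere_surface(g, center)
    fit <- dss_search(s, m = 40, max_steps = 40, seed = r)
    d[r] <- min(min_distance_trajectory(
      as.matrix(fit$trajectory[, paste0("d", 1:4)]), s$optima))
  }
  mom <- min_distance_moments(4, 10, 40)
  expect_lt(abs(mean(d) - mom$mean), 3 * sqrt(mom$variance) / sqrt(runs))
})

test_that("search parameter defaults follow the dimension and grid-size rules", {
  p2 <- dosesearch:::resolve_params(dss_params(), search_grid(2, 20))
  expect_equal(p2$power_exponent, 1L)
  expect_equal(p2$cluster_threshold, 3L)       # 2n - 1
  expect_equal(p2$cluster_break, 5L)           # ceil(1% of 441)
  expect_equal(p2$gibbs_points, 882L)          # 2 x grid size below 7500
  p5 <- dosesearch:::resolve_params(dss_params(), search_grid(5, 10))
  expect_equal(p5$cluster_threshold, 7L)       # fixed at 7 for n >= 5
  expect_equal(p5$gibbs_points, 15000L)
  expect_equal(default_m(builtin_sphere_surface()), 5L)
  g9 <- search_grid(2, 8)
  tab <- dosesearch:::new_response_surface(g9, runif(81), source = "tabulated")
  expect_equal(default_m(tab), 3L)
})
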