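## Diverse stochastic search: maximin Latin-hypercube initialization followed
## by an iterative segment that, per experiment, re-estimates the sensitivity
## surface from all measurements and then either refines the current peaks
## (focused search) or explores the estimated distribution by Gibbs sampling
## (diverse search).

#' Search parameters for the diverse stochastic search
#'
#' Parameters left \code{NULL} are resolved from the grid at run time with
#' the package defaults: \code{power_exponent = n - 1} (emphasizes peaks of
#' the normalized measurements before surface estimation);
#' \code{cluster_threshold = 2n - 1} when \code{n < 5}, else 7 (experimental
#' points allowed on one hill before it counts as discovered);
#' \code{cluster_break = ceiling(1\%} of the grid) (sorted points inspected
#' before an over-explored peak is suppressed); \code{gibbs_points = 2 *}
#' grid size when the grid has fewer than 7500 points, else 15000.
#'
#' @param p_focus probability of a focused step per iteration (default 0.3).
#' @param power_exponent exponent applied to the min-max normalized
#'   measurements; \code{NULL} = \code{n - 1}.
#' @param cluster_threshold experimental points on a hill before it is
#'   labelled discovered; \code{NULL} = \code{2n - 1} if \code{n < 5} else 7.
#' @param cluster_break sorted-walk length triggering peak suppression;
#'   \code{NULL} = \code{ceiling(0.01 * grid size)}.
#' @param cluster_sphere_fraction volume of the suppression sphere as a
#'   fraction of the search-space volume (default 1/500).
#' @param gibbs_points Gibbs samples drawn per diverse step; \code{NULL} =
#'   twice the grid size below 7500 points, else 15000.
#' @param gibbs_burn_in Gibbs sweeps discarded before sampling (default 10).
#' @param lhs_iterations swap budget for the maximin optimization of the
#'   initial design (default 1000).
#' @param smoothing smoothing parameter \code{s} of the surface estimator
#'   (default 1e-3: small, so the estimate passes through the measurements).
#' @param smoother_iterations iteration budget of the surface estimator
#'   (default 100).
#' @return an object of class \code{"dss_params"}.
#' @export
dss_params <- function(p_focus = 0.3, power_exponent = NULL,
                       cluster_threshold = NULL, cluster_break = NULL,
                       cluster_sphere_fraction = 1 / 500,
                       gibbs_points = NULL, gibbs_burn_in = 10,
                       lhs_iterations = 1000, smoothing = 1e-3,
                       smoother_iterations = 100) {
  if (p_focus < 0 || p_focus > 1) stop("`p_focus` must lie in [0, 1]")
  if (cluster_sphere_fraction <= 0 || cluster_sphere_fraction >= 1)
    stop("`cluster_sphere_fraction` must lie in (0, 1)")
  structure(list(p_focus = p_focus, power_exponent = power_exponent,
                 cluster_threshold = cluster_threshold,
                 cluster_break = cluster_break,
                 cluster_sphere_fraction = cluster_sphere_fraction,
                 gibbs_points = gibbs_points, gibbs_burn_in = gibbs_burn_in,
                 lhs_iterations = lhs_iterations, smoothing = smoothing,
                 smoother_iterations = smoother_iterations),
            class = "dss_params")
}

resolve_params <- function(params, grid) {
  N <- grid_size(grid)
  n <- grid$n
  p <- unclass(params)
  if (is.null(p$power_exponent)) p$power_exponent <- n - 1L
  if (is.null(p$cluster_threshold))
    p$cluster_threshold <- if (n < 5) 2L * n - 1L else 7L
  if (is.null(p$cluster_break)) p$cluster_break <- ceiling(0.01 * N)
  if (is.null(p$gibbs_points))
    p$gibbs_points <- if (N < 7500) 2L * N else 15000L
  if (p$cluster_threshold < 1) stop("`cluster_threshold` must be >= 1")
  if (p$gibbs_points < 1) stop("`gibbs_points` must be >= 1")
  structure(p, class = "dss_params")
}

#' Default number of initialization experiments
#'
#' 5 for synthetic two-drug surfaces, 3 for tabulated two-drug surfaces, 10
#' otherwise.
#'
#' @param surface a \code{response_surface}.
#' @return an integer.
#' @export
default_m <- function(surface) {
  n <- surface$grid$n
  if (n == 2L) {
    if (identical(surface$source, "tabulated")) 3L else 5L
  } else 10L
}

#' Min-max normalize measured sensitivities and emphasize peaks
#'
#' Rescales the measurements to \code{[0, 1]} and raises them to
#' \code{power} (default \code{n - 1}), which sharpens the peaks relative to
#' average values so the diverse-search sampling concentrates around hills.
#' The transform is monotone, so the ranking of measurements is preserved.
#' A constant input (no spread yet) maps to all ones.
#'
#' @param values measured sensitivities (>= 1 value).
#' @param n number of drugs (>= 2).
#' @param power exponent; defaults to \code{n - 1}.
#' @return weights in \code{[0, 1]}.
#' @export
normalize_and_power <- function(values, n, power = n - 1) {
  if (length(values) < 1L) stop("need at least one value")
  if (n < 2) stop("`n` must be >= 2")
  rng <- max(values) - min(values)
  if (rng == 0) return(rep(1, length(values)))
  ((values - min(values)) / rng)^power
}

choose_path <- function(p_focus) {
  if (stats::runif(1) < p_focus) "focused" else "diverse"
}

## axis neighbours (2n at most) of a 1-based linear index, with coordinates
axis_neighbours <- function(lin, shape, strides) {
  out <- integer(0)
  for (ax in seq_along(shape)) {
    coord <- ((lin - 1L) %/% strides[ax]) %% shape[ax]
    if (coord > 0) out <- c(out, lin - strides[ax])
    if (coord < shape[ax] - 1L) out <- c(out, lin + strides[ax])
  }
  out
}

## lexicographic rank of grid points (first coordinate most significant)
lex_rank <- function(grid, lin) {
  pts <- linear_to_point(grid, lin)
  as.numeric(pts %*% (grid$T + 1)^(rev(seq_len(grid$n)) - 1))
}

#' Steepest-ascent walk on an estimated surface
#'
#' From \code{start}, repeatedly moves to the strictly highest axis
#' neighbour (ties broken toward the lexicographically smallest index
#' vector) until no neighbour is strictly higher. The terminal point
#' identifies the hill that \code{start} belongs to.
#'
#' @param values full-grid value vector (flattened, first axis fastest).
#' @param grid a [search_grid()].
#' @param start 0-based index vector.
#' @return the terminal 0-based index vector (a local maximum).
#' @export
ascent_path <- function(values, grid, start) {
  start <- assert_on_grid(grid, start, "start")
  shape <- grid_dims(grid)
  strides <- cumprod(c(1L, shape[-length(shape)]))
  lin <- point_to_linear(grid, start)
  lin <- ascend_lin(values, shape, strides, grid, lin)
  linear_to_point(grid, lin)
}

ascend_lin <- function(values, shape, strides, grid, lin, memo = NULL) {
  path <- integer(0)
  repeat {
    if (!is.null(memo) && !is.null(memo[[as.character(lin)]])) {
      lin <- memo[[as.character(lin)]]
      break
    }
    nb <- axis_neighbours(lin, shape, strides)
    higher <- nb[values[nb] > values[lin]]
    if (!length(higher)) break
    best <- higher[values[higher] == max(values[higher])]
    if (length(best) > 1L) best <- best[order(lex_rank(grid, best))[1L]]
    path <- c(path, lin)
    lin <- best[1L]
  }
  if (!is.null(memo)) for (p in c(path, lin)) memo[[as.character(p)]] <- lin
  lin
}

#' Gibbs sampler over a gridded probability mass function
#'
#' Systematic-scan Gibbs sampling of the (unnormalized, non-negative) pmf
#' tensor: each sweep redraws every coordinate exactly from its conditional
#' given the others. The chain starts at a uniformly chosen positive-mass
#' point and discards \code{burn_in} sweeps; afterwards one sample is
#' recorded per sweep. Uses the current RNG state.
#'
#' @param pmf non-negative vector over the full grid (flattened, first axis
#'   fastest), with at least one strictly positive entry.
#' @param shape integer vector of axis sizes.
#' @param count number of samples to return.
#' @param burn_in sweeps discarded before recording (default 10).
#' @return \code{count x n} matrix of 0-based index vectors.
#' @export
gibbs_sample <- function(pmf, shape, count, burn_in = 10) {
  pmf <- as.numeric(pmf)
  if (length(pmf) != prod(shape)) stop("`pmf` length must equal prod(shape)")
  if (any(pmf < 0)) stop("`pmf` must be non-negative")
  pos <- which(pmf > 0)
  if (!length(pos)) stop("degenerate distribution: pmf has no positive mass")
  if (count < 1) stop("`count` must be >= 1")
  n <- length(shape)
  strides <- cumprod(c(1L, shape[-n]))
  lin <- pos[sample.int(length(pos), 1L)]
  cur <- as.integer(arrayInd(lin, .dim = shape) - 1L)
  samples <- matrix(0L, nrow = count, ncol = n)
  for (sweep in seq_len(burn_in + count)) {
    for (ax in seq_len(n)) {
      base <- lin - cur[ax] * strides[ax]
      idx <- base + (0:(shape[ax] - 1L)) * strides[ax]
      newc <- sample.int(shape[ax], 1L, prob = pmf[idx]) - 1L
      lin <- base + newc * strides[ax]
      cur[ax] <- newc
    }
    if (sweep > burn_in) samples[sweep - burn_in, ] <- cur
  }
  samples
}

## Focused search (path a): walk the sorted sensitivities from the top.
## Returns either the first estimated (untested) point not on a discovered
## hill, or a suppression action when `cluster_break` points pass without a
## candidate. Experimental points are labelled with the hill (ascent
## terminal) they belong to and their rank on that hill.
focused_step <- function(values, exp_lin, grid, cluster_threshold,
                         cluster_break, cluster_sphere_fraction) {
  shape <- grid_dims(grid)
  strides <- cumprod(c(1L, shape[-length(shape)]))
  ord <- order(-values, lex_rank(grid, seq_along(values)))
  is_exp <- logical(length(values))
  is_exp[exp_lin] <- TRUE
  memo <- new.env(parent = emptyenv())
  hill_of <- integer(0)          # terminal lin per named hill id
  hill_exp_count <- integer(0)   # experimental points seen per hill
  discovered <- logical(0)
  labels <- list()               # lin -> c(hill, rank)
  inspected <- 0L
  for (lin in ord) {
    inspected <- inspected + 1L
    if (inspected > cluster_break) break
    term <- ascend_lin(values, shape, strides, grid, lin, memo)
    key <- match(term, hill_of)
    if (is.na(key)) {
      hill_of <- c(hill_of, term)
      hill_exp_count <- c(hill_exp_count, 0L)
      discovered <- c(discovered, FALSE)
      key <- length(hill_of)
    }
    if (is_exp[lin]) {
      hill_exp_count[key] <- hill_exp_count[key] + 1L
      labels[[as.character(lin)]] <- c(hill = key, rank = hill_exp_count[key])
      if (hill_exp_count[key] >= cluster_threshold) discovered[key] <- TRUE
    } else if (!discovered[key]) {
      return(list(type = "candidate", lin = lin, hill = key, labels = labels))
    }
  }
  ## over-explored: suppress a small sphere around the current highest point
  center <- ord[1L]
  r <- sphere_radius(grid$n, grid$T, cluster_sphere_fraction)
  pts <- grid_points(grid)
  cpt <- linear_to_point(grid, center)
  inside <- which(rowSums(sweep(pts, 2, as.numeric(cpt))^2) <= r^2 + 1e-12)
  list(type = "break", center = center, radius = r, sphere = inside,
       labels = labels)
}

## radius of an L2 ball holding `fraction` of the search-space volume
sphere_radius <- function(n, T, fraction) {
  (fraction * (T + 1)^n * gamma(n / 2 + 1) / pi^(n / 2))^(1 / n)
}

## Diverse search (path b): Gibbs-sample the estimated surface treated as an
## unnormalized pmf and pick one untested sample uniformly; falls back to a
## uniform draw over untested points when every sample is already tested.
diverse_step <- function(values, exp_lin, grid, gibbs_points, burn_in) {
  shape <- grid_dims(grid)
  if (all(values <= 0)) return(uniform_untested(grid, exp_lin))
  samples <- gibbs_sample(values, shape, gibbs_points, burn_in)
  lins <- point_to_linear(grid, samples)
  cand <- lins[!(lins %in% exp_lin)]
  if (!length(cand)) return(uniform_untested(grid, exp_lin))
  cand[sample.int(length(cand), 1L)]
}

uniform_untested <- function(grid, exp_lin) {
  untested <- setdiff(seq_len(grid_size(grid)), exp_lin)
  if (!length(untested)) stop("entire grid has been tested")
  untested[sample.int(length(untested), 1L)]
}

#' Run the diverse stochastic search on a response surface
#'
#' Executes the full two-phase search: \code{m} maximin Latin-hypercube
#' initialization experiments snapped to the grid, then sequential
#' experiments chosen per iteration by re-estimating the sensitivity surface
#' (penalized DCT least squares on the normalized, peak-emphasized
#' measurements) and following the focused path with probability
#' \code{p_focus} or the diverse Gibbs-sampling path otherwise. No grid
#' point is ever measured twice.
#'
#' @param surface a \code{response_surface} oracle; every measurement
#'   increments its query counter.
#' @param m number of initialization experiments; default [default_m()].
#' @param params a [dss_params()] object.
#' @param max_steps total experiment budget (>= m); default
#'   \code{10 * (T + 1) * n}.
#' @param seed integer seed for the single run-level RNG stream (ordered:
#'   initial design, path choices, Gibbs draws, candidate selection).
#' @param stop_at optional absolute sensitivity; the run stops early once a
#'   measurement reaches it (used by the benchmark harness).
#' @return an object of class \code{"dss"}: the experiment trajectory (one
#'   row per oracle query: indices, sensitivity, path, hill label), the
#'   resolved parameters, the best cocktail found, and bookkeeping fields.
#' @examples
#' s <- builtin_sphere_surface()
#' fit <- dss_search(s, m = 5, max_steps = 60, seed = 1)
#' coef(fit)          # best cocktail found (0-based indices)
#' summary(fit)
#' @export
dss_search <- function(surface, m = default_m(surface), params = dss_params(),
                       max_steps = NULL, seed = 1, stop_at = NULL) {
  grid <- surface$grid
  n <- grid$n
  if (n < 2) stop("the search requires at least 2 drugs")
  N <- grid_size(grid)
  shape <- grid_dims(grid)
  p <- resolve_params(params, grid)
  if (is.null(max_steps)) max_steps <- 10L * (grid$T + 1L) * n
  if (max_steps < m) stop("`max_steps` must be at least m")
  if (m < 1) stop("`m` must be >= 1")

  set.seed(as.integer(seed))

  ## --- Step 1: approximate Latin hypercube initialization -----------------
  design <- generate_maximin_lhs(m, n, p$lhs_iterations)
  init_pts <- snap_to_grid(design, grid)
  exp_lin <- integer(0)
  measured <- numeric(0)
  path_log <- character(0)
  for (i in seq_len(nrow(init_pts))) {
    lin <- point_to_linear(grid, init_pts[i, ])
    exp_lin <- c(exp_lin, lin)
    measured <- c(measured, query_surface(surface, init_pts[i, ]))
    path_log <- c(path_log, "lhs")
  }
  stopped <- !is.null(stop_at) && any(measured >= stop_at - 1e-12)

  ## --- Step 2: iterative segment ------------------------------------------
  spheres <- list()      # active suppressions: center, radius, lins, archived
  hill_labels <- new.env(parent = emptyenv())
  while (!stopped && length(exp_lin) < max_steps && length(exp_lin) < N) {
    w <- normalize_and_power(measured, n, p$power_exponent)
    y <- numeric(N); y[exp_lin] <- w
    mask <- numeric(N); mask[exp_lin] <- 1
    est <- estimate_surface(y, mask, shape, s = p$smoothing,
                            n_iters = p$smoother_iterations)
    vals <- pmax(est$values, 0)
    vals[exp_lin] <- w
    for (sp in spheres) vals[sp$lins] <- 0

    cand <- NULL
    path <- NULL
    attempts <- 0L
    while (is.null(cand)) {
      attempts <- attempts + 1L
      path <- choose_path(p$p_focus)
      if (path == "diverse" || attempts > 50L) {
        path <- "diverse"
        cand <- diverse_step(vals, exp_lin, grid, p$gibbs_points,
                             p$gibbs_burn_in)
      } else {
        res <- focused_step(vals, exp_lin, grid, p$cluster_threshold,
                            p$cluster_break, p$cluster_sphere_fraction)
        for (k in names(res$labels)) hill_labels[[k]] <- res$labels[[k]]
        if (res$type == "candidate") {
          cand <- res$lin
        } else {
          spheres <- c(spheres, list(list(
            center = res$center, radius = res$radius, lins = res$sphere,
            archived = vals[res$sphere])))
          vals[res$sphere] <- 0
        }
      }
    }

    pt <- linear_to_point(grid, cand)
    exp_lin <- c(exp_lin, cand)
    val <- query_surface(surface, pt)
    measured <- c(measured, val)
    path_log <- c(path_log, path)

    ## restore any suppressed sphere the new measurement lands in
    if (length(spheres)) {
      hit <- vapply(spheres, function(sp) cand %in% sp$lins, logical(1))
      spheres <- spheres[!hit]
    }
    if (!is.null(stop_at) && val >= stop_at - 1e-12) stopped <- TRUE
  }

  pts <- linear_to_point(grid, exp_lin)
  colnames(pts) <- paste0("d", seq_len(n))
  hills <- vapply(exp_lin, function(l) {
    lab <- hill_labels[[as.character(l)]]
    if (is.null(lab)) NA_integer_ else as.integer(lab["hill"])
  }, integer(1))
  traj <- data.frame(iteration = seq_along(exp_lin), pts,
                     sensitivity = measured, path = path_log, hill = hills)
  best <- which.max(measured)
  structure(list(trajectory = traj, grid = grid, params = p, m = m,
                 seed = seed, max_steps = max_steps,
                 best_index = pts[best, ], best_value = measured[best],
                 surface_max = surface$max, optima = surface$optima,
                 n_queries = length(exp_lin)),
            class = "dss")
}

#' @export
print.dss <- function(x, ...) {
  cat(sprintf("Diverse stochastic search: %d experiments on a %d-drug grid (levels 0..%d)\n",
              x$n_queries, x$grid$n, x$grid$T))
  cat(sprintf("  best sensitivity %.4f (surface max %.4f) at cocktail [%s]\n",
              x$best_value, x$surface_max,
              paste(x$best_index, collapse = ", ")))
  invisible(x)
}

#' @export
summary.dss <- function(object, threshold = 0.95, ...) {
  traj <- object$trajectory
  fp <- first_passage(traj$sensitivity, threshold * object$surface_max)
  md <- min_distance_trajectory(as.matrix(traj[, paste0("d", seq_len(object$grid$n))]),
                                object$optima)
  out <- list(n_queries = object$n_queries, m = object$m,
              best_value = object$best_value, surface_max = object$surface_max,
              threshold = threshold, first_passage = fp,
              final_min_l1 = md[length(md)],
              paths = table(traj$path))
  class(out) <- "summary.dss"
  out
}

#' @export
print.summary.dss <- function(x, ...) {
  cat(sprintf("%d experiments (%d initialization + %d sequential)\n",
              x$n_queries, x$m, x$n_queries - x$m))
  cat(sprintf("  best sensitivity %.4f of max %.4f; final min L1 distance to optimum: %d\n",
              x$best_value, x$surface_max, x$final_min_l1))
  if (is.na(x$first_passage)) {
    cat(sprintf("  %.0f%% of max not reached within the budget\n", 100 * x$threshold))
  } else {
    cat(sprintf("  reached %.0f%% of max at experiment %d\n",
                100 * x$threshold, x$first_passage))
  }
  cat("  steps by path:\n")
  print(x$paths)
  invisible(x)
}

#' @export
coef.dss <- function(object, ...) object$best_index

#' @export
plot.dss <- function(x, ...) {
  traj <- x$trajectory
  md <- min_distance_trajectory(
    as.matrix(traj[, paste0("d", seq_len(x$grid$n))]), x$optima)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(seq_along(md), md, type = "s", xlab = "experiment",
                 ylab = "min L1 distance to optimum",
                 main = "Distance to optimum", ...)
  graphics::abline(v = x$m, col = "red", lty = 2)
  graphics::plot(traj$iteration, cummax(traj$sensitivity), type = "s",
                 xlab = "experiment", ylab = "best sensitivity so far",
                 main = "Best sensitivity", ylim = c(0, 1), ...)
  graphics::abline(h = 0.95 * x$surface_max, col = "gray", lty = 3)
  invisible(x)
}

first_passage <- function(values, level) {
  hit <- which(values >= level - 1e-12)
  if (length(hit)) hit[1L] else NA_integer_
}
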