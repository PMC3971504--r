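#' Maximin Latin hypercube design in the unit hypercube
#'
#' Draws an initial Latin hypercube sample (via \code{lhs::randomLHS}) and
#' improves its maximin criterion by random within-column swaps: a swap of two
#' rows' values in one column is kept only when it strictly increases the
#' minimum pairwise Euclidean distance. Swapping within columns preserves the
#' Latin hypercube stratification, so the result remains a Latin hypercube
#' while the points spread out.
#'
#' Uses the current RNG state; seed with \code{set.seed()} (or let
#' [dss_search()] seed its single run-level stream).
#'
#' @param m number of design points (>= 1).
#' @param n number of dimensions (drugs).
#' @param max_iterations number of candidate swaps to try (default 1000; past
#'   roughly this budget further gains in the minimum distance are negligible
#'   for the design sizes used here).
#' @return an \code{m x n} matrix of points in \code{[0, 1]^n}, with
#'   attributes \code{min_dist_initial} (criterion of the unoptimized draw)
#'   and \code{objective_trace} (criterion after each accepted swap).
#' @export
generate_maximin_lhs <- function(m, n, max_iterations = 1000) {
  if (m < 1) stop("`m` must be >= 1")
  if (n < 1) stop("`n` must be >= 1")
  pts <- lhs::randomLHS(m, n)
  if (m == 1L) {
    attr(pts, "min_dist_initial") <- Inf
    attr(pts, "objective_trace") <- numeric(0)
    return(pts)
  }
  d0 <- min_pairwise_distance(pts)
  cur <- d0
  trace <- numeric(0)
  for (it in seq_len(max_iterations)) {
    j <- sample.int(n, 1L)
    rows <- sample.int(m, 2L)
    cand <- pts
    cand[rows, j] <- cand[rev(rows), j]
    dc <- min_pairwise_distance(cand)
    if (dc > cur) {
      pts <- cand
      cur <- dc
      trace <- c(trace, dc)
    }
  }
  attr(pts, "min_dist_initial") <- d0
  attr(pts, "objective_trace") <- trace
  pts
}

#' Minimum pairwise Euclidean distance of a point set
#'
#' @param points matrix, one point per row (>= 2 rows).
#' @return the smallest pairwise L2 distance.
#' @export
min_pairwise_distance <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 2L)
    stop("minimum pairwise distance is undefined for fewer than 2 points")
  min(stats::dist(points))
}

#' Snap continuous unit-hypercube points to the nearest grid points
#'
#' Each coordinate \code{x} maps to the index \code{round(x * T)}. When two
#' continuous points collide on the same grid cell, the later point is
#' re-assigned to the nearest unoccupied cell (L1-nearest; ties broken by the
#' lexicographically smallest index vector), so the snapped design keeps one
#' distinct cocktail per input point.
#'
#' @param points matrix of continuous points in \code{[0, 1]^n}.
#' @param grid a [search_grid()].
#' @return matrix of distinct 0-based grid index vectors, one row per input
#'   point (fewer only if the grid is smaller than the design).
#' @export
snap_to_grid <- function(points, grid) {
  points <- rbind(points)
  if (ncol(points) != grid$n) stop("points must have n columns")
  if (any(points < 0) || any(points > 1)) stop("points must lie in [0, 1]^n")
  idx <- round(points * grid$T)
  occupied <- integer(0)
  out <- matrix(0L, nrow = 0, ncol = grid$n)
  N <- grid_size(grid)
  for (i in seq_len(nrow(idx))) {
    lin <- point_to_linear(grid, idx[i, ])
    if (lin %in% occupied) {
      if (length(occupied) >= N) break  # grid exhausted
      lin <- nearest_free_cell(grid, idx[i, ], occupied)
    }
    occupied <- c(occupied, lin)
    out <- rbind(out, linear_to_point(grid, lin))
  }
  out
}

## nearest unoccupied cell by L1 distance; lexicographic tie-break on the
## index vector (most significant coordinate first)
nearest_free_cell <- function(grid, point, occupied) {
  pts <- grid_points(grid)
  d <- rowSums(abs(sweep(pts, 2, as.numeric(point))))
  d[occupied] <- Inf
  best <- which(d == min(d))
  if (length(best) > 1L) {
    ord <- do.call(order, as.data.frame(pts[best, , drop = FALSE]))
    best <- best[ord[1L]]
  }
  best[1L]
}
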