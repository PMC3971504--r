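#' Discretized drug-concentration search grid
#'
#' Defines the lattice of candidate drug cocktails. Each of the \code{n}
#' drugs is discretized into levels \code{0..T}, so the search space holds
#' \code{(T+1)^n} cocktails. A cocktail is represented by its integer index
#' vector; real concentrations are an affine view derived from \code{bounds}.
#'
#' @param n number of drugs (integer, >= 1).
#' @param T maximum discretization index per drug; levels run \code{0..T}.
#' @param bounds per-drug concentration interval, an \code{n x 2} matrix (or
#'   a vector \code{c(low, high)} recycled to all drugs). Defaults to
#'   \code{[0, 1]} for every drug. Used only by [index_to_concentration()].
#' @return an object of class \code{"search_grid"} with elements \code{n},
#'   \code{T} and \code{bounds}.
#' @examples
#' g <- search_grid(2, 20)
#' grid_size(g)  # 441
#' @export
search_grid <- function(n, T, bounds = NULL) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    stop("`n` must be a single integer >= 1")
  if (!is.numeric(T) || length(T) != 1L || is.na(T) || T < 1 || T != round(T))
    stop("`T` must be a single integer >= 1")
  n <- as.integer(n); T <- as.integer(T)
  if (is.null(bounds)) bounds <- matrix(rep(c(0, 1), each = n), ncol = 2)
  if (is.vector(bounds) && length(bounds) == 2L)
    bounds <- matrix(rep(bounds, each = n), ncol = 2)
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != n || ncol(bounds) != 2L)
    stop("`bounds` must be an n x 2 matrix of (low, high) intervals")
  if (!is.numeric(bounds) || anyNA(bounds) || any(bounds[, 1] >= bounds[, 2]))
    stop("each bounds row must satisfy low < high")
  dimnames(bounds) <- list(paste0("drug", seq_len(n)), c("low", "high"))
  structure(list(n = n, T = T, bounds = bounds), class = "search_grid")
}

#' @export
print.search_grid <- function(x, ...) {
  cat(sprintf("Search grid: %d drug(s), levels 0..%d, %s points\n",
              x$n, x$T, format(grid_size(x), big.mark = ",")))
  invisible(x)
}

#' Number of points in a search grid
#' @param grid a [search_grid()].
#' @return \code{(T+1)^n}.
#' @export
grid_size <- function(grid) (grid$T + 1)^grid$n

grid_dims <- function(grid) rep(grid$T + 1L, grid$n)

## all grid points as an N x n matrix of 0-based index vectors, in the
## same (first-axis-fastest) order as the flattened value vector
grid_points <- function(grid) {
  arrayInd(seq_len(grid_size(grid)), .dim = grid_dims(grid)) - 1L
}

## 0-based index vectors (rows of a matrix) -> 1-based linear positions
point_to_linear <- function(grid, points) {
  points <- rbind(points)
  strides <- (grid$T + 1)^(seq_len(grid$n) - 1)
  as.integer(points %*% strides) + 1L
}

linear_to_point <- function(grid, lin) {
  arrayInd(lin, .dim = grid_dims(grid)) - 1L
}

assert_on_grid <- function(grid, points, what = "point") {
  points <- rbind(points)
  if (ncol(points) != grid$n)
    stop(sprintf("%s must have %d coordinates", what, grid$n))
  if (anyNA(points) || any(points != round(points)) ||
      any(points < 0) || any(points > grid$T))
    stop(sprintf("%s coordinates must be integers in [0, %d]", what, grid$T))
  invisible(points)
}

#' Map grid index vectors to real concentrations
#'
#' @param grid a [search_grid()].
#' @param points matrix of 0-based index vectors (one row per cocktail), or
#'   a single index vector.
#' @return matrix of real concentrations, one row per cocktail.
#' @export
index_to_concentration <- function(grid, points) {
  points <- assert_on_grid(grid, points)
  lo <- grid$bounds[, 1]; hi <- grid$bounds[, 2]
  sweep(sweep(points / grid$T, 2, hi - lo, "*"), 2, lo, "+")
}

## ---------------------------------------------------------------------------
## Response surfaces: the oracle f mapping a cocktail to a sensitivity in [0,1]
## with an experiment (query) counter.
## ---------------------------------------------------------------------------

new_response_surface <- function(grid, values, source = "synthetic") {
  values <- as.numeric(values)
  stopifnot(length(values) == grid_size(grid))
  if (anyNA(values) || any(values < -1e-12) || any(values > 1 + 1e-12))
    stop("sensitivities must lie in [0, 1]")
  values <- pmin(pmax(values, 0), 1)
  vmax <- max(values)
  opt_lin <- which(values >= vmax - 1e-12)
  env <- new.env(parent = emptyenv())
  env$queries <- 0L
  structure(list(grid = grid, values = values, max = vmax,
                 optima = linear_to_point(grid, opt_lin),
                 source = source, counter = env),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf(
    "Response surface (%s) on a %d-drug grid, levels 0..%d\n",
    x$source, x$grid$n, x$grid$T))
  cat(sprintf("  max sensitivity %.4g at %d optimum point(s); %d oracle queries so far\n",
              x$max, nrow(x$optima), n_queries(x)))
  invisible(x)
}

#' Query a response surface (one experiment)
#'
#' Returns the sensitivity of a cocktail and increments the surface's query
#' counter by exactly one. Each call stands for one wet-lab experiment; the
#' counter is the search cost.
#'
#' @param surface a \code{response_surface}.
#' @param point a 0-based index vector (or one-row matrix).
#' @return the sensitivity in \code{[0, 1]}.
#' @export
query_surface <- function(surface, point) {
  point <- assert_on_grid(surface$grid, point)
  surface$counter$queries <- surface$counter$queries + 1L
  surface$values[point_to_linear(surface$grid, point)]
}

#' Number of oracle queries made so far
#' @param surface a \code{response_surface}.
#' @export
n_queries <- function(surface) surface$counter$queries

reset_queries <- function(surface) {
  surface$counter$queries <- 0L
  invisible(surface)
}

#' Synthetic multi-hill response surface
#'
#' Builds a sensitivity surface as a floor plus a sum of Gaussian hills,
#' clipped at 1. This emulates multi-modal drug-interaction surfaces with a
#' controllable number of near-optimal points: narrow single hills give an
#' isolated optimum, several wide hills give broad high-sensitivity regions.
#'
#' @param grid a [search_grid()].
#' @param centers matrix of hill centers (0-based index vectors, one row per
#'   hill), or a single index vector.
#' @param widths per-hill width in index units (recycled).
#' @param heights per-hill height in \code{(0, 1]} (recycled).
#' @param floor baseline sensitivity added everywhere (default 0).
#' @return a \code{response_surface}; its optimum set is found by full
#'   enumeration of the grid.
#' @examples
#' g <- search_grid(2, 10)
#' s <- hill_surface(g, centers = c(3, 7), widths = 2, heights = 1)
#' s$optima  # the single hill center
#' @export
hill_surface <- function(grid, centers, widths, heights, floor = 0) {
  centers <- assert_on_grid(grid, centers, "hill center")
  k <- nrow(centers)
  widths <- rep_len(widths, k); heights <- rep_len(heights, k)
  if (any(widths <= 0)) stop("hill widths must be positive")
  if (any(heights <= 0) || any(heights > 1)) stop("hill heights must be in (0, 1]")
  if (floor < 0 || floor >= 1) stop("floor must be in [0, 1)")
  pts <- grid_points(grid)
  vals <- rep(floor, nrow(pts))
  for (j in seq_len(k)) {
    d2 <- rowSums(sweep(pts, 2, centers[j, ])^2)
    vals <- vals + heights[j] * exp(-d2 / widths[j]^2)
  }
  new_response_surface(grid, pmin(vals, 1))
}

#' Inverted-sphere (unimodal) response surface
#'
#' A smooth unimodal test surface: sensitivity falls off quadratically with
#' Euclidean distance from the peak, scaled so the peak has sensitivity 1 and
#' the farthest grid corner has sensitivity 0.
#'
#' @param grid a [search_grid()].
#' @param center 0-based index vector of the unique optimum.
#' @return a \code{response_surface} with a single optimum at \code{center}.
#' @export
inverted_sphere_surface <- function(grid, center) {
  center <- assert_on_grid(grid, center, "center")
  pts <- grid_points(grid)
  d2 <- rowSums(sweep(pts, 2, as.numeric(center))^2)
  new_response_surface(grid, 1 - d2 / max(d2))
}

#' Built-in two-drug demonstration surface
#'
#' The canonical 21 x 21 unimodal surface used in the package examples and
#' benchmarks: an inverted sphere on a 2-drug grid with levels 0..20 and its
#' peak at (10, 10).
#'
#' @return a \code{response_surface}.
#' @export
builtin_sphere_surface <- function() {
  inverted_sphere_surface(search_grid(2, 20), c(10, 10))
}

#' Points within a fraction of the maximum sensitivity
#'
#' @param surface a \code{response_surface}.
#' @param fraction scalar in \code{(0, 1]}; default 0.95, the usual
#'   near-optimality criterion for combination screens.
#' @return matrix of 0-based index vectors whose sensitivity is at least
#'   \code{fraction * max}.
#' @export
points_within_fraction <- function(surface, fraction = 0.95) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must be a scalar in (0, 1]")
  lin <- which(surface$values >= fraction * surface$max - 1e-12)
  linear_to_point(surface$grid, lin)
}

## ---------------------------------------------------------------------------
## Tabulated surfaces (delimited text), e.g. measured inhibition matrices
## ---------------------------------------------------------------------------

#' Read a tabulated response surface from a delimited text file
#'
#' Two layouts are supported. \emph{Matrix} layout (2 drugs only): a dense
#' numeric table whose rows are drug-1 indices ascending and columns drug-2
#' indices ascending. \emph{Long} layout: a header \code{d1,...,dn,sensitivity}
#' followed by one row per grid point with 0-based indices. Raw responses
#' (e.g. percent inhibition) are rescaled to \code{[0, 1]} by dividing by the
#' file maximum whenever any value exceeds 1.
#'
#' @param path file path.
#' @param grid optional [search_grid()]; inferred from the file when omitted
#'   (matrix layout infers \code{n = 2}, \code{T = nrow - 1}).
#' @param format \code{"auto"} (default; long layout is detected by a header
#'   naming a sensitivity column), \code{"matrix"} or \code{"long"}.
#' @param sep field separator; default guesses comma vs whitespace.
#' @return a \code{response_surface} with \code{source = "tabulated"}.
#' @export
read_surface <- function(path, grid = NULL,
                         format = c("auto", "matrix", "long"), sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl(",", first)) "," else ""
  if (format == "auto")
    format <- if (grepl("sensitivity", first, ignore.case = TRUE)) "long" else "matrix"

  if (format == "long") {
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
    n <- ncol(tab) - 1L
    if (n < 1L) stop("long-format file needs >= 1 index column plus a value column")
    for (j in seq_len(ncol(tab))) {
      bad <- which(!is.finite(suppressWarnings(as.numeric(tab[[j]]))))
      if (length(bad))
        stop(sprintf("non-numeric cell in column %d, data row %d of %s",
                     j, bad[1], path))
      tab[[j]] <- as.numeric(tab[[j]])
    }
    if (is.null(grid)) grid <- search_grid(n, max(tab[, seq_len(n)]))
    if (nrow(tab) != grid_size(grid))
      stop(sprintf("expected %d rows (one per grid point), found %d",
                   grid_size(grid), nrow(tab)))
    idx <- as.matrix(tab[, seq_len(n), drop = FALSE])
    bad <- which(idx < 0 | idx > grid$T | idx != round(idx), arr.ind = TRUE)
    if (nrow(rbind(bad)) && length(bad))
      stop(sprintf("index out of range in data row %d of %s", bad[1], path))
    vals <- tab[[n + 1L]]
    neg <- which(vals < 0)
    if (length(neg))
      stop(sprintf("negative sensitivity in data row %d of %s", neg[1], path))
    lin <- point_to_linear(grid, idx)
    if (anyDuplicated(lin)) stop("duplicate grid points in ", path)
    values <- numeric(grid_size(grid))
    values[lin] <- vals
  } else {
    m <- as.matrix(utils::read.table(path, header = FALSE, sep = sep))
    suppressWarnings(storage.mode(m) <- "numeric")
    bad <- which(!is.finite(m), arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell at row %d, column %d of %s",
                   bad[1, 1], bad[1, 2], path))
    if (is.null(grid)) {
      if (nrow(m) != ncol(m))
        stop("matrix layout requires a square table (T+1 x T+1) unless `grid` is given")
      grid <- search_grid(2, nrow(m) - 1L)
    }
    if (grid$n != 2L) stop("matrix layout is only defined for 2-drug grids")
    if (nrow(m) != grid$T + 1L || ncol(m) != grid$T + 1L)
      stop(sprintf("expected a %d x %d table, found %d x %d",
                   grid$T + 1L, grid$T + 1L, nrow(m), ncol(m)))
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
      stop(sprintf("negative sensitivity at row %d, column %d of %s",
                   neg[1, 1], neg[1, 2], path))
    values <- as.vector(m)  # column-major: drug-1 index fastest
  }
  if (max(values) > 1) values <- values / max(values)
  new_response_surface(grid, values, source = "tabulated")
}

#' Write a response surface to a delimited text file
#'
#' Inverse of [read_surface()]; the long layout round-trips exactly for any
#' number of drugs, the matrix layout for two drugs.
#'
#' @param surface a \code{response_surface}.
#' @param path output file path.
#' @param format \code{"long"} (default) or \code{"matrix"} (2 drugs only).
#' @param sep field separator (default comma).
#' @return \code{path}, invisibly.
#' @export
write_surface <- function(surface, path, format = c("long", "matrix"), sep = ",") {
  format <- match.arg(format)
  grid <- surface$grid
  vals <- sprintf("%.17g", surface$values)  # full precision: exact round trip
  if (format == "long") {
    tab <- as.data.frame(grid_points(grid))
    names(tab) <- paste0("d", seq_len(grid$n))
    tab$sensitivity <- vals
    utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  } else {
    if (grid$n != 2L) stop("matrix layout is only defined for 2-drug grids")
    m <- matrix(vals, nrow = grid$T + 1L)
    utils::write.table(m, path, sep = sep, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' L1 distance between grid points
#'
#' @param a,b 0-based index vectors or matrices of them (rows recycled).
#' @return integer L1 distances.
#' @export
l1_distance <- function(a, b) {
  a <- rbind(a); b <- rbind(b)
  if (nrow(a) == 1L && nrow(b) > 1L) a <- a[rep(1L, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1L && nrow(a) > 1L) b <- b[rep(1L, nrow(a)), , drop = FALSE]
  as.integer(rowSums(abs(a - b)))
}
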