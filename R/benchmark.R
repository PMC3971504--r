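## Repeated seeded evaluation: search cost (experiments to reach a fraction
## of the maximum sensitivity), success rate within a budget, and
## minimum-distance trajectories.

#' Minimum L1 distance trajectory of a search
#'
#' Element \code{t} is the smallest L1 distance between any of the first
#' \code{t} tested points and any optimum; by construction the sequence is
#' non-increasing.
#'
#' @param points matrix of tested 0-based index vectors, in test order.
#' @param optima matrix of optimum index vectors.
#' @return integer vector, one entry per tested point.
#' @export
min_distance_trajectory <- function(points, optima) {
  points <- rbind(points); optima <- rbind(optima)
  if (!nrow(points) || !nrow(optima)) stop("need nonempty points and optima")
  per <- vapply(seq_len(nrow(points)), function(i)
    min(l1_distance(points[i, , drop = FALSE], optima)), integer(1))
  as.integer(cummin(per))
}

new_benchmark <- function(first_passage, n_runs, budget, threshold, method) {
  ok <- !is.na(first_passage)
  structure(list(
    cost = if (any(ok)) mean(first_passage[ok]) else NA_real_,
    std = if (sum(ok) > 1) stats::sd(first_passage[ok]) else NA_real_,
    worst_case = if (any(ok)) max(first_passage[ok]) else NA_integer_,
    success_rate = mean(ok),
    n_runs = n_runs, budget = budget, threshold = threshold,
    first_passage = first_passage, method = method),
    class = "dss_benchmark")
}

#' @export
print.dss_benchmark <- function(x, ...) {
  cat(sprintf("%s benchmark: %d runs, budget %d, threshold %.2f x max\n",
              x$method, x$n_runs, x$budget, x$threshold))
  cat(sprintf("  cost %.2f (sd %.2f), worst case %d, success rate %.0f%%\n",
              x$cost, x$std, x$worst_case, 100 * x$success_rate))
  invisible(x)
}

#' Benchmark the diverse stochastic search over repeated seeded runs
#'
#' Runs [dss_search()] \code{n_runs} times with seeds
#' \code{base_seed, base_seed + 1, ...} and records, per run, the first
#' experiment whose measured sensitivity reaches
#' \code{threshold * max(surface)}. Initialization experiments count toward
#' the cost. Results are deterministic given \code{base_seed}.
#'
#' @param surface a \code{response_surface}.
#' @param n_runs number of repeated runs (default 100).
#' @param budget experiment budget per run; default \code{10 * (T + 1) * n}.
#' @param threshold near-optimality fraction (default 0.95).
#' @param m initialization experiments per run; default [default_m()].
#' @param params a [dss_params()] object.
#' @param base_seed first seed (default 1).
#' @param keep_runs if TRUE, attach the individual \code{"dss"} objects.
#' @return an object of class \code{"dss_benchmark"} with fields
#'   \code{cost}, \code{std}, \code{worst_case}, \code{success_rate},
#'   \code{first_passage} (per-run vector, NA = budget exhausted).
#' @export
dss_benchmark <- function(surface, n_runs = 100, budget = NULL,
                          threshold = 0.95, m = default_m(surface),
                          params = dss_params(), base_seed = 1,
                          keep_runs = FALSE) {
  if (n_runs < 1) stop("`n_runs` must be >= 1")
  grid <- surface$grid
  if (is.null(budget)) budget <- 10L * (grid$T + 1L) * grid$n
  if (budget < m) stop("`budget` must be at least m")
  level <- threshold * surface$max
  fp <- integer(n_runs)
  runs <- if (keep_runs) vector("list", n_runs) else NULL
  for (r in seq_len(n_runs)) {
    fit <- dss_search(surface, m = m, params = params, max_steps = budget,
                      seed = base_seed + r - 1L, stop_at = level)
    fp[r] <- first_passage(fit$trajectory$sensitivity, level)
    if (keep_runs) runs[[r]] <- fit
  }
  out <- new_benchmark(fp, n_runs, budget, threshold, "DSS")
  if (keep_runs) out$runs <- runs
  out
}

#' Uniform random-search control
#'
#' Samples untested points uniformly without replacement and reports the
#' same cost/success metrics as [dss_benchmark()]. With \code{q} qualifying
#' points among \code{N}, the expected cost of this control is
#' \code{(N + 1) / (q + 1)} (see [expected_random_search_cost()]).
#'
#' @inheritParams dss_benchmark
#' @return a \code{"dss_benchmark"} object.
#' @export
random_search_baseline <- function(surface, n_runs = 100, budget = NULL,
                                   threshold = 0.95, base_seed = 1) {
  grid <- surface$grid
  if (is.null(budget)) budget <- 10L * (grid$T + 1L) * grid$n
  N <- grid_size(grid)
  level <- threshold * surface$max
  qualifies <- surface$values >= level - 1e-12
  fp <- integer(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(base_seed + r - 1L)
    ord <- sample.int(N)
    hit <- which(qualifies[ord])[1L]
    fp[r] <- if (!is.na(hit) && hit <= budget) hit else NA_integer_
  }
  new_benchmark(fp, n_runs, budget, threshold, "random search")
}

#' Closed-form expected cost of uniform sampling without replacement
#'
#' With \code{q} qualifying points among \code{N} grid points, the expected
#' draw at which the first qualifying point appears is
#' \code{(N + 1) / (q + 1)}.
#'
#' @param N total number of grid points.
#' @param q number of qualifying points (1 <= q <= N).
#' @return the expected first-passage draw.
#' @export
expected_random_search_cost <- function(N, q) {
  if (q < 1 || q > N) stop("`q` must lie in 1..N")
  (N + 1) / (q + 1)
}

#' Serialize a benchmark result to JSON
#'
#' Writes a machine-readable summary (cost, std, worst case, success rate,
#' per-run first-passage list). Identical inputs produce byte-identical
#' files.
#'
#' @param result a \code{"dss_benchmark"}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_benchmark_json <- function(result, path) {
  obj <- list(method = result$method, n_runs = result$n_runs,
              budget = result$budget, threshold = result$threshold,
              cost = result$cost, std = result$std,
              worst_case = result$worst_case,
              success_rate = result$success_rate,
              first_passage = result$first_passage)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Export a search trajectory as TSV
#'
#' One row per experiment: iteration, cocktail indices, measured
#' sensitivity, path taken (lhs / focused / diverse) and hill label.
#'
#' @param fit a \code{"dss"} object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_tsv <- function(fit, path) {
  utils::write.table(fit$trajectory, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
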