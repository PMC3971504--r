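## shared fixture builders; all randomness is seeded inside the tests

random_values_surface <- function(grid, seed) {
  set.seed(seed)
  vals <- stats::runif(dosesearch::grid_size(grid))
  dosesearch:::new_response_surface(grid, vals)
}

## independent steepest-ascent climber working on explicit index vectors
oracle_hill_climb <- function(values, grid, start) {
  T <- grid$T; n <- grid$n
  cur <- as.integer(start)
  val_at <- function(p) values[dosesearch:::point_to_linear(grid, p)]
  repeat {
    best <- NULL; best_val <- val_at(cur)
    for (ax in seq_len(n)) for (step in c(-1L, 1L)) {
      nb <- cur; nb[ax] <- nb[ax] + step
      if (nb[ax] < 0 || nb[ax] > T) next
      if (val_at(nb) > best_val) { best <- nb; best_val <- val_at(nb) }
    }
    if (is.null(best)) return(cur)
    cur <- best
  }
}
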