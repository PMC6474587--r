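# shared helpers: independent oracles and small constructors

# evidence config rating every qualitative rubric topic "acceptable"
all_acceptable_evidence <- function() {
  tp <- rubric_topics()
  keys <- tp$topic[!tp$computed]
  stats::setNames(as.list(rep("acceptable", length(keys))), keys)
}

# brute-force maximum independent set size over all 2^n subsets (bitmask
# enumeration); independent of the package's branch-and-bound
brute_force_mis_size <- function(xy, min_dist) {
  n <- nrow(xy)
  stopifnot(n <= 14)
  d <- as.matrix(stats::dist(xy))
  conflict_mask <- integer(n)
  for (i in seq_len(n)) {
    conflict_mask[i] <- sum(2L^(which(d[i, ] < min_dist & seq_len(n) != i) - 1L))
  }
  subsets <- 0:(2^n - 1)
  feasible <- rep(TRUE, length(subsets))
  for (i in seq_len(n)) {
    has_i <- bitwAnd(subsets, 2L^(i - 1L)) > 0L
    feasible[has_i & bitwAnd(subsets, conflict_mask[i]) > 0L] <- FALSE
  }
  popcount <- vapply(subsets, function(s) sum(bitwAnd(s, 2L^(0:(n - 1))) > 0L),
                     numeric(1))
  max(popcount[feasible])
}

# Moran's I with rook contiguity on a matrix (permutation oracle support)
morans_i <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  z <- m - mean(m)
  num <- 0; w_sum <- 0
  # horizontal and vertical neighbour products
  num <- sum(z[, -nc] * z[, -1]) + sum(z[-nr, ] * z[-1, ])
  w_sum <- nr * (nc - 1) + (nr - 1) * nc
  (length(m) / w_sum) * (num / sum(z^2))
}

# a tiny single-ring model on an n x n grid with given values
tiny_model <- function(values, res = 100, id = "m1", ...) {
  suitability_model(id, hs_grid(values, xmin = 0, ymax = nrow(values) * res,
                                res = res), ...)
}

# occurrence records from bare centre points (circular class-1 polygons)
records_from_points <- function(x, y, species = "sp", class = 1L,
                                year = 2000L, radius = 40) {
  n <- length(x)
  occurrence_records(
    data.frame(record_id = sprintf("R%03d", seq_len(n)), species = species,
               accuracy_class = class, year = year, occ_rank = "Good",
               source = "test"),
    lapply(seq_len(n), function(i) circle_poly(x[i], y[i], radius))
  )
}

# shared seeded synthetic inputs for ensemble-level tests (memoized per session)
t1_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_species_config(seed = 1)
      inp <- simulate_species_inputs(cfg, n_eval_points = 60)
      rubs <- lapply(inp$models, function(m) {
        evaluate_model(m$model_id, inp$eval_records,
                       evidence = all_acceptable_evidence())
      })
      prob <- build_probable(inp$models, rubs, inp$eval_points,
                             species = cfg$species,
                             independent_points = inp$independent_points)
      cache <<- list(cfg = cfg, inputs = inp, rubrics = rubs, probable = prob)
    }
    cache
  }
})
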