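#' Maximal spatial thinning of evaluation centroids
#'
#' Selects as many centroids as possible subject to a minimum pairwise
#' separation distance. This is a maximum-independent-set problem on the
#' distance ("conflict") graph; the heuristic mode runs a seeded randomized
#' greedy with restarts and returns the best subset found, the exact mode
#' solves each connected component of the conflict graph by branch and bound.
#' Every returned subset is maximal: no excluded centroid can be re-added
#' without violating the separation distance.
#'
#' @param points data.frame with columns `record_id`, `x`, `y` (metres).
#' @param min_dist_m minimum pairwise separation in metres (default 430).
#' @param seed integer seed driving the randomized restarts; a fixed seed gives
#'   a bit-identical result.
#' @param exact if `TRUE`, return a maximum-cardinality subset (permitted for
#'   n <= 15 points only).
#' @param restarts number of random greedy restarts in heuristic mode.
#' @param species,window optional labels stored on the result.
#' @return an object of class `evaluation_set`: list with `species`, `window`,
#'   `points` (the retained rows), `min_separation_m`, `seed`, `n_input`.
#' @export
thin_maximal <- function(points, min_dist_m = 430, seed = 1L, exact = FALSE,
                         restarts = 100L, species = NA_character_,
                         window = c(NA_integer_, NA_integer_)) {
  if (!is.numeric(min_dist_m) || min_dist_m <= 0) {
    stop("`min_dist_m` must be positive", call. = FALSE)
  }
  points <- as.data.frame(points, stringsAsFactors = FALSE)
  stopifnot(all(c("record_id", "x", "y") %in% names(points)))
  n <- nrow(points)
  if (n == 0L) {
    return(new_evaluation_set(points, min_dist_m, seed, species, window, 0L))
  }
  # order by record_id so greedy tie-breaking is reproducible
  points <- points[order(points$record_id), , drop = FALSE]
  rownames(points) <- NULL
  d <- as.matrix(stats::dist(points[, c("x", "y")]))
  conflict <- d < min_dist_m
  diag(conflict) <- FALSE

  keep <- if (exact) {
    if (n > 15L) {
      stop("exact mode is limited to 15 points or fewer (got ", n, ")",
           call. = FALSE)
    }
    mis_exact(conflict)
  } else {
    best <- greedy_pass(conflict, seq_len(n))  # deterministic record_id order
    with_seed(seed, {
      for (r in seq_len(restarts)) {
        cand <- greedy_pass(conflict, sample.int(n))
        if (length(cand) > length(best)) best <- cand
      }
    })
    sort(best)
  }
  new_evaluation_set(points[keep, , drop = FALSE], min_dist_m, seed,
                     species, window, n)
}

new_evaluation_set <- function(points, min_dist_m, seed, species, window,
                               n_input) {
  rownames(points) <- NULL
  structure(
    list(species = species, window = window, points = points,
         min_separation_m = min_dist_m, seed = seed, n_input = n_input),
    class = "evaluation_set"
  )
}

#' @export
print.evaluation_set <- function(x, ...) {
  cat(sprintf(
    "<evaluation_set> %d of %d centroids retained (min separation %g m, seed %s)\n",
    nrow(x$points), x$n_input, x$min_separation_m, format(x$seed)
  ))
  invisible(x)
}

# one feasibility-greedy pass over candidates in the given order
greedy_pass <- function(conflict, order) {
  kept <- integer(0)
  for (i in order) {
    if (!any(conflict[i, kept])) kept <- c(kept, i)
  }
  kept
}

# exact maximum independent set, solved per connected component by
# branch and bound on the highest-degree vertex
mis_exact <- function(conflict) {
  n <- nrow(conflict)
  comp <- components_of(conflict)
  out <- integer(0)
  for (verts in comp) out <- c(out, mis_bb(conflict, verts))
  sort(out)
}

components_of <- function(conflict) {
  n <- nrow(conflict)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    queue <- s; seen[s] <- TRUE; members <- integer(0)
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      members <- c(members, v)
      nb <- which(conflict[v, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

mis_bb <- function(conflict, verts) {
  best <- integer(0)
  recurse <- function(remaining, chosen) {
    if (length(chosen) + length(remaining) <= length(best)) return()
    if (!length(remaining)) {
      if (length(chosen) > length(best)) best <<- chosen
      return()
    }
    deg <- colSums(conflict[remaining, remaining, drop = FALSE])
    v <- remaining[which.max(deg)]
    # include v
    recurse(setdiff(remaining, c(v, remaining[conflict[v, remaining]])),
            c(chosen, v))
    # exclude v
    recurse(setdiff(remaining, v), chosen)
  }
  recurse(verts, integer(0))
  best
}

#' Verify the separation and maximality invariants of a thinned set
#'
#' @param eval_set an [thin_maximal()] result.
#' @param points the original candidate points.
#' @return `TRUE` invisibly; errors if either invariant fails.
#' @export
check_thinning <- function(eval_set, points) {
  kept <- eval_set$points
  if (nrow(kept) > 1) {
    dmin <- min(stats::dist(kept[, c("x", "y")]))
    if (dmin < eval_set$min_separation_m) {
      stop("separation invariant violated: min pairwise distance ", dmin,
           call. = FALSE)
    }
  }
  dropped <- points[!points$record_id %in% kept$record_id, , drop = FALSE]
  if (nrow(dropped) && nrow(kept)) {
    for (i in seq_len(nrow(dropped))) {
      dd <- sqrt((kept$x - dropped$x[i])^2 + (kept$y - dropped$y[i])^2)
      if (all(dd >= eval_set$min_separation_m)) {
        stop("maximality invariant violated: record ", dropped$record_id[i],
             " could be re-added", call. = FALSE)
      }
    }
  }
  invisible(TRUE)
}

#' Export an evaluation set
#'
#' Writes the retained points as GeoJSON point features and as CSV
#' (`record_id, x, y`).
#'
#' @param eval_set an `evaluation_set`.
#' @param geojson,csv output paths (either may be `NULL` to skip).
#' @param crs_name CRS label recorded in the GeoJSON.
#' @return invisibly, a list of the paths written.
#' @export
export_evaluation_set <- function(eval_set, geojson = NULL, csv = NULL,
                                  crs_name = "local-metre") {
  pts <- eval_set$points
  if (!is.null(geojson)) {
    write_geojson(
      geometry = lapply(seq_len(nrow(pts)), function(i) c(pts$x[i], pts$y[i])),
      properties = pts[, "record_id", drop = FALSE],
      path = geojson, crs_name = crs_name
    )
  }
  if (!is.null(csv)) {
    utils::write.csv(pts[, c("record_id", "x", "y")], csv, row.names = FALSE)
  }
  invisible(list(geojson = geojson, csv = csv))
}
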