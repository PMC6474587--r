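#' Trace boundary polygons of a binary grid
#'
#' Converts the suitable region of a logical grid into closed rings by
#' following pixel edges (region kept on the left, so outer rings are
#' counter-clockwise and holes clockwise; even-odd filling reproduces the
#' region exactly). Deterministic.
#'
#' @param grid a logical [hs_grid()].
#' @return list of rings (two-column matrices of x, y vertices, unclosed).
#' @export
boundary_polygons <- function(grid) {
  v <- grid$values != 0
  v[is.na(v)] <- FALSE
  nr <- nrow(v); nc <- ncol(v)
  res <- grid$res
  suit <- function(i, j) i >= 1 && i <= nr && j >= 1 && j <= nc && v[i, j]
  # directed edges with the region on the left, keyed by start vertex
  # vertex (a, b) = corner at x = xmin + b*res, y = ymax - a*res (a, b 0-based)
  edges <- list()
  add_edge <- function(from, to) {
    key <- paste(from, collapse = ",")
    edges[[key]] <<- c(edges[[key]], list(list(from = from, to = to)))
  }
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!v[i, j]) next
      # corners (row index a grows south, col index b grows east)
      tl <- c(i - 1L, j - 1L); tr <- c(i - 1L, j)
      bl <- c(i, j - 1L); br <- c(i, j)
      if (!suit(i + 1L, j)) add_edge(bl, br)  # south edge, eastward
      if (!suit(i, j + 1L)) add_edge(br, tr)  # east edge, northward
      if (!suit(i - 1L, j)) add_edge(tr, tl)  # north edge, westward
      if (!suit(i, j - 1L)) add_edge(tl, bl)  # west edge, southward
    }
  }
  rings <- list()
  take_edge <- function(key, prev_dir) {
    cand <- edges[[key]]
    if (is.null(cand) || !length(cand)) return(NULL)
    k <- 1L
    if (length(cand) > 1L && !is.null(prev_dir)) {
      # at a checkerboard corner prefer the sharpest left turn, keeping the
      # traced ring simple
      turns <- vapply(cand, function(e) {
        d <- e$to - e$from
        # cross product of prev_dir and d: positive = left turn
        prev_dir[1] * d[2] - prev_dir[2] * d[1]
      }, numeric(1))
      k <- which.max(turns)
    }
    e <- cand[[k]]
    edges[[key]] <<- cand[-k]
    e
  }
  repeat {
    keys <- names(edges)[vapply(edges, length, integer(1)) > 0]
    if (!length(keys)) break
    start_key <- sort(keys)[1]
    e <- take_edge(start_key, NULL)
    ring <- list(e$from)
    repeat {
      ring <- c(ring, list(e$to))
      if (all(e$to == ring[[1]])) break
      e <- take_edge(paste(e$to, collapse = ","), e$to - e$from)
      if (is.null(e)) stop("boundary tracing failed: open ring", call. = FALSE)
    }
    ring <- ring[-length(ring)]  # drop closing vertex
    ab <- do.call(rbind, ring)
    rings[[length(rings) + 1L]] <- cbind(
      x = grid$xmin + ab[, 2] * res,
      y = grid$ymax - ab[, 1] * res
    )
  }
  rings
}

#' Export a habitat product
#'
#' Writes the product's grids as ESRI ASCII bands (`boundary.asc`,
#' `model_count.asc`, `mean_score.asc`), the boundary rings as GeoJSON, the
#' area/capture report as CSV, and a JSON run manifest recording inputs,
#' thresholds, and capture statistics. Products are emitted on the common grid;
#' the manifest notes that results should be used at no finer a resolution than
#' the coarsest contributing model.
#'
#' @param product a `habitat_product`.
#' @param dir output directory (created if missing).
#' @param overlays overlay layers forwarded to [area_summary()].
#' @param coarsest_input_res_m optional coarsest native input resolution,
#'   recorded in the manifest as the recommended minimum resolution of use.
#' @return invisibly, named list of the files written.
#' @export
export_product <- function(product, dir, overlays = list(),
                           coarsest_input_res_m = NA_real_) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  b <- product$boundary
  write_asc(hs_grid(b$values * 1, b$xmin, b$ymax, b$res, b$crs),
            p("boundary.asc"))
  write_asc(product$model_count, p("model_count.asc"))
  write_asc(product$mean_score, p("mean_score.asc"))
  rings <- boundary_polygons(b)
  if (length(rings)) {
    write_geojson(
      geometry = lapply(rings, function(r) list(r)),
      properties = data.frame(ring = seq_along(rings)),
      path = p("boundary.geojson"), crs_name = b$crs
    )
  }
  areas <- area_summary(product, overlays, csv = p("areas.csv"))
  manifest <- list(
    species = product$species,
    kind = product$kind,
    pixel_size_m = product$pixel_size_m,
    recommended_min_use_resolution_m = coarsest_input_res_m,
    thresholds_used = as.list(product$thresholds_used),
    boundary_model_ids = product$boundary_model_ids,
    capture_eval = product$capture_eval,
    capture_independent = product$capture_independent,
    compliant = product$compliant,
    notes = product$notes,
    total_km2 = areas$km2[areas$zone == "total"],
    total_acres = areas$acres[areas$zone == "total"]
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(
    boundary = p("boundary.asc"), model_count = p("model_count.asc"),
    mean_score = p("mean_score.asc"), areas = p("areas.csv"),
    manifest = p("manifest.json")
  ))
}
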