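#' Occurrence records
#'
#' Element-occurrence records are held in a data frame of class `occ_records`
#' with one row per record and columns:
#' `record_id`, `species`, `accuracy_class` (1-10), `year`, `occ_rank`
#' (Excellent/Good/Fair/Poor/X/Unknown), `source`, `area_m2`, and a `geometry`
#' list-column of polygons (lists of ring matrices) in a projected metre CRS.
#'
#' @name occ_records
NULL

OCC_RANKS <- c("Excellent", "Good", "Fair", "Poor", "X", "Unknown")
OCC_REQUIRED <- c("record_id", "species", "accuracy_class", "year",
                  "occ_rank", "source")

new_occ_records <- function(df) {
  class(df) <- c("occ_records", "data.frame")
  df
}

validate_occ <- function(df, where = "input") {
  for (col in OCC_REQUIRED) {
    if (is.null(df[[col]])) {
      stop("schema error in ", where, ": missing required column `", col, "`",
           call. = FALSE)
    }
  }
  ac <- df$accuracy_class
  if (any(is.na(ac)) || any(ac < 1 | ac > 10) || any(ac != round(ac))) {
    stop("schema error in ", where,
         ": `accuracy_class` must be an integer in [1, 10]", call. = FALSE)
  }
  if (any(is.na(df$year)) || any(df$year < 1800)) {
    stop("schema error in ", where, ": `year` must be a calendar year >= 1800",
         call. = FALSE)
  }
  bad_rank <- !df$occ_rank %in% OCC_RANKS
  if (any(bad_rank)) {
    stop("schema error in ", where, ": unknown `occ_rank` value(s): ",
         paste(unique(df$occ_rank[bad_rank]), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

#' Build an occurrence-record table from attributes and polygons
#'
#' @param attributes data.frame with columns `record_id`, `species`,
#'   `accuracy_class`, `year`, `occ_rank`, `source`.
#' @param geometry list of polygons (each a list of ring matrices, metres).
#' @return an `occ_records` data frame with a computed `area_m2` column.
#' @export
occurrence_records <- function(attributes, geometry) {
  stopifnot(nrow(attributes) == length(geometry))
  df <- as.data.frame(attributes, stringsAsFactors = FALSE)
  df$accuracy_class <- as.integer(df$accuracy_class)
  df$year <- as.integer(df$year)
  validate_occ(df)
  geometry <- lapply(geometry, as_polygon)
  df$area_m2 <- vapply(geometry, poly_area, numeric(1))
  if (any(df$area_m2 < 0)) stop("negative polygon area", call. = FALSE)
  df$geometry <- geometry
  new_occ_records(df)
}

#' Read occurrence records from a GeoJSON file
#'
#' Reads polygon features with the documented attribute schema
#' (`record_id, species, accuracy_class, year, occ_rank, source`), keeps the
#' requested species, and validates attributes. Files in geographic
#' (degree-unit) coordinates are projected to a local metre plane via
#' [lonlat_to_local()]; this requires `working_crs`.
#'
#' @param path GeoJSON FeatureCollection of polygon features.
#' @param species species name to select.
#' @param working_crs `NULL` for files already in a projected metre CRS
#'   (declared by a `crs` member naming a metre CRS); for geographic files,
#'   either `"auto"` (origin at the mean vertex of the selected records) or a
#'   list with `lon0` and `lat0`.
#' @return an `occ_records` data frame in the working metre CRS.
#' @export
read_occurrences <- function(path, species, working_crs = NULL) {
  gj <- read_geojson(path)
  if (any(gj$type != "Polygon")) {
    stop("schema error in ", path, ": all features must be polygons",
         call. = FALSE)
  }
  props <- gj$properties
  for (col in OCC_REQUIRED) {
    if (is.null(props[[col]])) {
      stop("schema error in ", path, ": missing required column `", col, "`",
           call. = FALSE)
    }
  }
  keep <- props$species == species
  props <- props[keep, , drop = FALSE]
  geoms <- gj$geometry[keep]
  geographic <- is.na(gj$crs_name) ||
    grepl("4326|CRS84", gj$crs_name, ignore.case = TRUE)
  projected_tag <- !is.na(gj$crs_name) &&
    grepl("metre|meter|local|326\\d\\d|269\\d\\d", gj$crs_name, ignore.case = TRUE)
  if (geographic && !projected_tag) {
    if (is.null(working_crs)) {
      stop("CRS error: ", path, " is in geographic (degree) coordinates and ",
           "no working CRS was configured; pass `working_crs`", call. = FALSE)
    }
    all_xy <- do.call(rbind, lapply(geoms, function(g) do.call(rbind, g)))
    if (identical(working_crs, "auto")) {
      working_crs <- list(lon0 = mean(all_xy[, 1]), lat0 = mean(all_xy[, 2]))
    }
    geoms <- lapply(geoms, function(g) {
      lapply(g, lonlat_to_local, lon0 = working_crs$lon0, lat0 = working_crs$lat0)
    })
  }
  occurrence_records(props, geoms)
}

#' Filter occurrence records for evaluation use
#'
#' Retains records whose year falls in the inclusive window and whose mapped
#' location is precise: accuracy class in `precise_classes`, or class 3 with a
#' polygon no larger than a circle of radius `class3_max_radius_m` (equivalent
#' radius `sqrt(area / pi)`).
#'
#' @param records an `occ_records` data frame.
#' @param window inclusive year range, `c(start, end)`.
#' @param precise_classes accuracy classes accepted regardless of polygon size.
#' @param class3_max_radius_m maximum equivalent radius (m) for class-3 records.
#' @return the retained subset, same class. Idempotent; empty in, empty out.
#' @export
filter_records <- function(records, window = c(1981, 2012),
                           precise_classes = c(1L, 2L, 4L),
                           class3_max_radius_m = 150) {
  if (nrow(records) == 0L) return(records)
  r_equiv <- sqrt(records$area_m2 / pi)
  keep <- records$year >= window[1] & records$year <= window[2] &
    (records$accuracy_class %in% precise_classes |
       (records$accuracy_class == 3L & r_equiv <= class3_max_radius_m))
  new_occ_records(records[keep, , drop = FALSE])
}

#' Internal centroids of occurrence records
#'
#' @param records an `occ_records` data frame.
#' @return data.frame with `record_id`, `x`, `y`; each point lies inside its
#'   parent polygon (see [internal_centroid()]).
#' @export
occurrence_centroids <- function(records) {
  pts <- t(vapply(records$geometry, internal_centroid, numeric(2)))
  data.frame(record_id = records$record_id,
             x = pts[, 1], y = pts[, 2],
             stringsAsFactors = FALSE)
}
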