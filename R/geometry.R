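#' Planar polygon primitives
#'
#' Polygons are stored as a list of rings; each ring is a two-column numeric
#' matrix of x, y vertices in a projected metre CRS (closing vertex optional).
#' The first ring is the outer boundary, subsequent rings are holes; containment
#' uses the even-odd rule, so ring orientation does not matter.
#'
#' @name polygon-geometry
NULL

# drop a duplicated closing vertex
normalize_ring <- function(ring) {
  ring <- as.matrix(ring)[, 1:2, drop = FALSE]
  n <- nrow(ring)
  if (n >= 2 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  if (nrow(ring) < 3) stop("ring has fewer than 3 distinct vertices", call. = FALSE)
  storage.mode(ring) <- "double"
  ring
}

as_polygon <- function(geom) {
  if (is.matrix(geom) || is.data.frame(geom)) geom <- list(geom)
  lapply(geom, normalize_ring)
}

shoelace <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area of a planar polygon
#'
#' Shoelace area of the outer ring minus the area of any holes, in the square
#' of the coordinate unit (m^2 for metre CRSs).
#'
#' @param poly a polygon (list of rings, or a single ring matrix).
#' @return non-negative area.
#' @export
poly_area <- function(poly) {
  rings <- as_polygon(poly)
  a <- abs(shoelace(rings[[1]]))
  if (length(rings) > 1) {
    a <- a - sum(vapply(rings[-1], function(r) abs(shoelace(r)), numeric(1)))
  }
  max(a, 0)
}

#' Point-in-polygon test (even-odd rule)
#'
#' @param x,y point coordinates (vectors of equal length).
#' @param poly a polygon (list of rings, or a single ring matrix).
#' @return logical vector; points on an edge may return either value.
#' @export
point_in_poly <- function(x, y, poly) {
  rings <- as_polygon(poly)
  inside <- rep(FALSE, length(x))
  for (ring in rings) {
    px <- ring[, 1]; py <- ring[, 2]
    n <- nrow(ring)
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      xi <- px[k]; yi <- py[k]; xj <- px[j[k]]; yj <- py[j[k]]
      cross <- ((yi > y) != (yj > y)) &
        (x < (xj - xi) * (y - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross & !is.na(cross))
    }
  }
  inside
}

#' Geometric centroid of a planar polygon
#'
#' Signed-area-weighted centroid over all rings (holes subtract). May fall
#' outside a non-convex polygon; see [internal_centroid()].
#'
#' @param poly a polygon.
#' @return numeric length-2 vector (x, y).
#' @export
poly_centroid <- function(poly) {
  rings <- as_polygon(poly)
  A_tot <- 0; cx <- 0; cy <- 0
  for (i in seq_along(rings)) {
    r <- rings[[i]]
    a <- shoelace(r)
    # force outer ring positive, holes negative
    sign_i <- if (i == 1) 1 else -1
    a <- sign_i * abs(a)
    x <- r[, 1]; y <- r[, 2]
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    f <- x * yn - xn * y
    if (shoelace(r) < 0) f <- -f  # orient CCW before the centroid sum
    cx <- cx + sign_i * sum((x + xn) * f) / 6
    cy <- cy + sign_i * sum((y + yn) * f) / 6
    A_tot <- A_tot + a
  }
  if (A_tot == 0) stop("degenerate polygon: zero area", call. = FALSE)
  c(cx, cy) / A_tot
}

#' Internal centroid of a polygon
#'
#' A deterministic representative point guaranteed to lie inside the polygon.
#' Returns the geometric centroid whenever that point is interior; otherwise
#' scans horizontal chords (starting at the median vertex y, then at y
#' quantiles) and returns the midpoint of the widest interior interval.
#'
#' @param poly a polygon (list of rings, or a single ring matrix).
#' @return numeric length-2 vector (x, y), strictly inside the polygon.
#' @export
internal_centroid <- function(poly) {
  rings <- as_polygon(poly)
  if (poly_area(rings) <= 0) stop("empty or degenerate polygon", call. = FALSE)
  ctr <- poly_centroid(rings)
  if (point_in_poly(ctr[1], ctr[2], rings)) return(ctr)
  ys <- rings[[1]][, 2]
  # candidate scan lines: median vertex y first, then interior quantiles
  y_cand <- unique(c(stats::median(ys),
                     stats::quantile(ys, probs = seq(0.1, 0.9, by = 0.1),
                                     names = FALSE)))
  rng <- range(ys)
  y_cand <- y_cand[y_cand > rng[1] & y_cand < rng[2]]
  for (y0 in y_cand) {
    xs <- chord_crossings(rings, y0)
    if (length(xs) >= 2) {
      xs <- sort(xs)
      # even-odd: intervals [x1,x2], [x3,x4], ... are interior
      starts <- xs[seq(1, length(xs) - 1, by = 2)]
      ends <- xs[seq(2, length(xs), by = 2)]
      w <- ends - starts
      k <- which.max(w)
      pt <- c((starts[k] + ends[k]) / 2, y0)
      if (point_in_poly(pt[1], pt[2], rings)) return(pt)
    }
  }
  stop("could not locate an interior point", call. = FALSE)
}

# x coordinates where the horizontal line y = y0 crosses polygon edges
chord_crossings <- function(rings, y0) {
  xs <- numeric(0)
  for (ring in rings) {
    n <- nrow(ring)
    j <- c(n, seq_len(n - 1L))
    for (k in seq_len(n)) {
      yi <- ring[k, 2]; yj <- ring[j[k], 2]
      if ((yi > y0) != (yj > y0)) {
        xi <- ring[k, 1]; xj <- ring[j[k], 1]
        xs <- c(xs, xi + (y0 - yi) * (xj - xi) / (yj - yi))
      }
    }
  }
  xs
}

#' Regular polygon approximating a circle
#'
#' @param cx,cy centre coordinates.
#' @param r radius (same unit as coordinates).
#' @param n number of vertices.
#' @return a one-ring polygon whose area is within `1 - n/(2*pi) * sin(2*pi/n)`
#'   of the true disc area (< 0.2% for the default `n`).
#' @export
circle_poly <- function(cx, cy, r, n = 72L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  list(cbind(cx + r * cos(th), cy + r * sin(th)))
}

## ---- local projection ------------------------------------------------------

# metres per degree of latitude/longitude on the WGS84 ellipsoid at `lat`
meters_per_degree <- function(lat) {
  rad <- lat * pi / 180
  list(
    lat = 111132.92 - 559.82 * cos(2 * rad) + 1.175 * cos(4 * rad) -
      0.0023 * cos(6 * rad),
    lon = 111412.84 * cos(rad) - 93.5 * cos(3 * rad) + 0.118 * cos(5 * rad)
  )
}

#' Project geographic coordinates to a local metre plane
#'
#' Equirectangular (tangent-plane) projection about a reference point, using
#' ellipsoidal metres-per-degree scale factors at the reference latitude.
#' Intended for desk-scale working windows (tens of kilometres), where the
#' area distortion is far below the 0.5% tolerance used in validation.
#'
#' @param lonlat two-column matrix of longitude, latitude (degrees, WGS84).
#' @param lon0,lat0 reference (origin) point in degrees.
#' @return two-column matrix of x, y in metres (origin at `lon0, lat0`).
#' @export
lonlat_to_local <- function(lonlat, lon0, lat0) {
  lonlat <- as.matrix(lonlat)[, 1:2, drop = FALSE]
  s <- meters_per_degree(lat0)
  cbind(x = (lonlat[, 1] - lon0) * s$lon,
        y = (lonlat[, 2] - lat0) * s$lat)
}

## ---- GeoJSON I/O -----------------------------------------------------------

#' Read a GeoJSON FeatureCollection
#'
#' Parses Polygon and Point features into package geometry (lists of ring
#' matrices; points as length-2 vectors) plus a properties data frame.
#'
#' @param path path to a GeoJSON file.
#' @return list with `geometry` (list, one element per feature), `type`
#'   (character vector of geometry types), `properties` (data.frame), and
#'   `crs_name` (the optional `crs` member's name, or `NA`).
#' @export
read_geojson <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection in ", path, call. = FALSE)
  }
  crs_name <- tryCatch(gj$crs$properties$name, error = function(e) NULL) %||% NA_character_
  feats <- gj$features
  geometry <- vector("list", length(feats))
  type <- character(length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    type[i] <- f$geometry$type
    coords <- f$geometry$coordinates
    geometry[[i]] <- switch(
      f$geometry$type,
      Point = unlist(coords)[1:2],
      Polygon = lapply(coords, function(ring) {
        do.call(rbind, lapply(ring, function(p) unlist(p)[1:2]))
      }),
      stop("unsupported GeoJSON geometry type: ", f$geometry$type, call. = FALSE)
    )
    props[[i]] <- lapply(f$properties, function(v) if (is.null(v)) NA else v)
  }
  keys <- unique(unlist(lapply(props, names)))
  pdf <- as.data.frame(
    lapply(stats::setNames(keys, keys), function(k) {
      vals <- lapply(props, function(p) p[[k]] %||% NA)
      unlist(vals)
    }),
    stringsAsFactors = FALSE
  )
  list(geometry = geometry, type = type, properties = pdf, crs_name = crs_name)
}

#' Write features to GeoJSON
#'
#' @param geometry list of geometries: polygons (lists of ring matrices) or
#'   points (length-2 numeric vectors).
#' @param properties data.frame of feature attributes (one row per feature).
#' @param path output path.
#' @param crs_name optional CRS name to record in a `crs` member (omitted when
#'   `NULL`, implying RFC 7946 WGS84).
#' @return `path`, invisibly.
#' @export
write_geojson <- function(geometry, properties, path, crs_name = NULL) {
  stopifnot(nrow(properties) == length(geometry))
  feats <- lapply(seq_along(geometry), function(i) {
    g <- geometry[[i]]
    geom <- if (is.numeric(g) && length(g) == 2) {
      list(type = "Point", coordinates = as.numeric(g))
    } else {
      rings <- as_polygon(g)
      list(type = "Polygon", coordinates = lapply(rings, function(r) {
        r <- rbind(r, r[1, ])  # GeoJSON rings are closed
        lapply(seq_len(nrow(r)), function(k) as.numeric(r[k, ]))
      }))
    }
    list(
      type = "Feature",
      geometry = geom,
      properties = as.list(properties[i, , drop = FALSE])
    )
  })
  out <- list(type = "FeatureCollection", features = feats)
  if (!is.null(crs_name)) {
    out$crs <- list(type = "name", properties = list(name = crs_name))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  invisible(path)
}
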