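#' Lightweight single-band raster grid
#'
#' A minimal in-memory raster: a numeric matrix whose rows run north to south,
#' an upper-left origin, a square pixel size in metres, and `NA` as nodata.
#' All package rasters (suitability surfaces, binary habitat maps, standardized
#' scores, model counts) are `hs_grid` objects. On-disk exchange uses the ESRI
#' ASCII grid format (see [read_asc()] / [write_asc()]).
#'
#' @param values numeric (or logical/integer) matrix; row 1 is the northernmost
#'   row, column 1 the westernmost column. `NA` marks nodata.
#' @param xmin x coordinate of the west (left) edge, metres.
#' @param ymax y coordinate of the north (top) edge, metres.
#' @param res pixel edge length in metres (> 0, square pixels).
#' @param crs label for the projected CRS the coordinates live in. Purely
#'   informational; all geometry is planar.
#' @return an object of class `hs_grid`.
#' @export
hs_grid <- function(values, xmin, ymax, res, crs = "local-metre") {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(res) || length(res) != 1L || is.na(res) || res <= 0) {
    stop("pixel size `res` must be a single positive number", call. = FALSE)
  }
  structure(
    list(values = values, xmin = xmin, ymax = ymax, res = res, crs = crs),
    class = "hs_grid"
  )
}

#' @export
print.hs_grid <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf(
    "<hs_grid> %d x %d pixels @ %g m | extent x [%g, %g] y [%g, %g] | crs: %s\n",
    nrow(x$values), ncol(x$values), x$res,
    x$xmin, grid_xmax(x), grid_ymin(x), x$ymax, x$crs
  ))
  if (length(v)) {
    cat(sprintf("  valid: %d pixels, range [%g, %g]\n",
                length(v), min(v), max(v)))
  } else {
    cat("  all nodata\n")
  }
  invisible(x)
}

grid_xmax <- function(g) g$xmin + ncol(g$values) * g$res
grid_ymin <- function(g) g$ymax - nrow(g$values) * g$res

#' Coordinates of pixel centres
#' @param g an `hs_grid`.
#' @return list with `x` (west to east) and `y` (north to south) centre vectors.
#' @keywords internal
grid_centers <- function(g) {
  list(
    x = g$xmin + (seq_len(ncol(g$values)) - 0.5) * g$res,
    y = g$ymax - (seq_len(nrow(g$values)) - 0.5) * g$res
  )
}

#' Extract grid values at point locations
#'
#' Returns the value of the pixel containing each point; points outside the
#' grid extent return `NA`. Points exactly on the east/south outer edge fall in
#' the last pixel.
#'
#' @param g an `hs_grid`.
#' @param xy two-column matrix or data.frame of x, y coordinates (metres, grid CRS).
#' @return numeric vector of length `nrow(xy)`.
#' @export
grid_extract <- function(g, xy) {
  xy <- as.matrix(xy[, 1:2, drop = FALSE])
  col <- floor((xy[, 1] - g$xmin) / g$res) + 1L
  row <- floor((g$ymax - xy[, 2]) / g$res) + 1L
  # points on the outer max edge belong to the final row/column
  col[xy[, 1] == grid_xmax(g)] <- ncol(g$values)
  row[xy[, 2] == grid_ymin(g)] <- nrow(g$values)
  ok <- col >= 1L & col <= ncol(g$values) & row >= 1L & row <= nrow(g$values) &
    !is.na(col) & !is.na(row)
  out <- rep(NA_real_, nrow(xy))
  if (any(ok)) out[ok] <- g$values[cbind(row[ok], col[ok])]
  out
}

#' Read an ESRI ASCII grid
#'
#' @param path path to a `.asc` file (6-line header, rows north to south).
#' @param crs CRS label to attach (the format itself carries none).
#' @return an [hs_grid()].
#' @export
read_asc <- function(path, crs = "local-metre") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "r")
  on.exit(close(con))
  hdr <- character(0)
  vals <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) break
    if (grepl("^\\s*[A-Za-z]", line)) hdr <- c(hdr, line) else {
      vals[[length(vals) + 1L]] <- line
    }
  }
  vals <- c(vals, as.list(readLines(con)))
  kv <- do.call(rbind, strsplit(trimws(hdr), "\\s+"))
  key <- tolower(kv[, 1])
  val <- as.numeric(kv[, 2])
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% key)) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  ncols <- as.integer(val[key == "ncols"])
  nrows <- as.integer(val[key == "nrows"])
  res <- val[key == "cellsize"]
  xll <- if ("xllcorner" %in% key) val[key == "xllcorner"] else
    val[key == "xllcenter"] - res / 2
  yll <- if ("yllcorner" %in% key) val[key == "yllcorner"] else
    val[key == "yllcenter"] - res / 2
  nodata <- if ("nodata_value" %in% key) val[key == "nodata_value"] else NA
  nums <- scan(text = paste(unlist(vals), collapse = " "), quiet = TRUE)
  if (length(nums) != nrows * ncols) {
    stop("ASCII grid body has ", length(nums), " values, expected ",
         nrows * ncols, call. = FALSE)
  }
  m <- matrix(nums, nrow = nrows, ncol = ncols, byrow = TRUE)
  if (!is.na(nodata)) m[m == nodata] <- NA
  hs_grid(m, xmin = xll, ymax = yll + nrows * res, res = res, crs = crs)
}

#' Write an ESRI ASCII grid
#'
#' @param g an [hs_grid()].
#' @param path output path.
#' @param nodata value used to encode `NA` pixels.
#' @return `path`, invisibly.
#' @export
write_asc <- function(g, path, nodata = -9999) {
  m <- g$values
  m[is.na(m)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(m)),
    sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %.10g", g$xmin),
    sprintf("yllcorner %.10g", grid_ymin(g)),
    sprintf("cellsize %.10g", g$res),
    sprintf("NODATA_value %g", nodata)
  )
  body <- apply(m, 1, function(r) paste(format(r, trim = TRUE, scientific = FALSE),
                                        collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resample a grid to a target lattice by nearest neighbour
#'
#' Each target pixel takes the value of the source pixel containing its centre;
#' no interpolation is performed, so no new values are created. Target pixels
#' whose centre falls outside the source extent are nodata.
#'
#' @param g source [hs_grid()].
#' @param xmin,ymax target origin (west edge, north edge).
#' @param res target pixel size (m).
#' @param nrow,ncol target dimensions.
#' @return an [hs_grid()] on the target lattice.
#' @export
resample_nn <- function(g, xmin, ymax, res, nrow, ncol) {
  cx <- xmin + (seq_len(ncol) - 0.5) * res
  cy <- ymax - (seq_len(nrow) - 0.5) * res
  src_col <- floor((cx - g$xmin) / g$res) + 1L
  src_row <- floor((g$ymax - cy) / g$res) + 1L
  col_ok <- src_col >= 1L & src_col <= ncol(g$values)
  row_ok <- src_row >= 1L & src_row <= nrow(g$values)
  out <- matrix(NA_real_, nrow = nrow, ncol = ncol)
  if (any(row_ok) && any(col_ok)) {
    out[row_ok, col_ok] <- g$values[src_row[row_ok], src_col[col_ok], drop = FALSE]
  }
  hs_grid(out, xmin = xmin, ymax = ymax, res = res, crs = g$crs)
}

#' Aggregate a grid by block mean
#'
#' Coarsens a grid by an integer factor, averaging valid pixels in each block.
#' Used by the synthetic contractor-model generator to emulate coarser
#' deliveries.
#'
#' @param g an [hs_grid()].
#' @param factor integer block edge (>= 1).
#' @return an [hs_grid()] at `factor` times the pixel size.
#' @export
aggregate_mean <- function(g, factor) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(g)
  nr <- nrow(g$values) %/% factor
  nc <- ncol(g$values) %/% factor
  if (nr < 1L || nc < 1L) stop("grid too small for aggregation factor", call. = FALSE)
  v <- g$values[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  # mean over factor x factor blocks, ignoring nodata
  arr <- array(v, dim = c(factor, nr, factor * nc))
  colsum <- apply(arr, c(2, 3), function(z) sum(z, na.rm = TRUE))
  colcnt <- apply(arr, c(2, 3), function(z) sum(!is.na(z)))
  arr2 <- array(colsum, dim = c(nr, factor, nc))
  cnt2 <- array(colcnt, dim = c(nr, factor, nc))
  s <- apply(arr2, c(1, 3), sum)
  n <- apply(cnt2, c(1, 3), sum)
  out <- s / n
  out[n == 0] <- NA_real_
  hs_grid(out, xmin = g$xmin, ymax = g$ymax, res = g$res * factor, crs = g$crs)
}

#' Align suitability models to a shared grid
#'
#' Puts every model on one lattice: the union of the input extents, at the
#' finest native resolution among the inputs (or `target_res_m`), snapped to
#' the lattice of the finest-resolution model so that its pixels transfer
#' one-to-one. Resampling is nearest neighbour, so each model's set of distinct
#' valid values is unchanged; pixels outside a model's native extent become
#' nodata.
#'
#' @param models list of [suitability_model()] objects in one projected CRS.
#' @param target_res_m optional target pixel size (m); defaults to the finest
#'   native resolution among the inputs.
#' @return list of models on the shared grid (same order, metadata preserved).
#' @export
align_to_common_grid <- function(models, target_res_m = NULL) {
  stopifnot(length(models) >= 1L)
  crs <- unique(vapply(models, function(m) m$grid$crs, character(1)))
  if (length(crs) > 1L) {
    stop("models are in different CRSs (", paste(crs, collapse = ", "),
         "); reproject before aligning", call. = FALSE)
  }
  res_native <- vapply(models, function(m) m$grid$res, numeric(1))
  res <- target_res_m %||% min(res_native)
  ref <- models[[which.min(res_native)]]$grid
  xmin <- min(vapply(models, function(m) m$grid$xmin, numeric(1)))
  ymax <- max(vapply(models, function(m) m$grid$ymax, numeric(1)))
  xmax <- max(vapply(models, function(m) grid_xmax(m$grid), numeric(1)))
  ymin <- min(vapply(models, function(m) grid_ymin(m$grid), numeric(1)))
  # snap the union origin outward onto the reference lattice
  xmin <- ref$xmin - ceiling((ref$xmin - xmin) / res) * res
  ymax <- ref$ymax + ceiling((ymax - ref$ymax) / res) * res
  nc <- as.integer(ceiling((xmax - xmin) / res - 1e-9))
  nr <- as.integer(ceiling((ymax - ymin) / res - 1e-9))
  lapply(models, function(m) {
    m$grid <- resample_nn(m$grid, xmin = xmin, ymax = ymax, res = res,
                          nrow = nr, ncol = nc)
    m
  })
}

same_lattice <- function(a, b, tol = 1e-6) {
  abs(a$xmin - b$xmin) < tol && abs(a$ymax - b$ymax) < tol &&
    abs(a$res - b$res) < tol &&
    all(dim(a$values) == dim(b$values))
}
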