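#' Overlay layers
#'
#' Named vector or raster layers (managed lands, development focus areas,
#' developed land cover, water masks, ...) used either to mask products (water)
#' or to slice area summaries. Vector geometry is a list of polygons; raster
#' geometry is an [hs_grid()] where nonzero/valid pixels are "in".
#'
#' @param name label, e.g. `"managed_lands"`, `"development_focus"`,
#'   `"developed_landcover"`, `"water_mask"`, or any custom label.
#' @param geometry list of polygons or an [hs_grid()].
#' @return object of class `overlay_layer`.
#' @export
overlay_layer <- function(name, geometry) {
  structure(list(name = name, geometry = geometry), class = "overlay_layer")
}

#' Rasterize an overlay layer onto a grid
#'
#' @param layer an [overlay_layer()].
#' @param grid the target [hs_grid()] lattice.
#' @return logical matrix (`TRUE` = inside the overlay).
#' @export
rasterize_overlay <- function(layer, grid) {
  g <- layer$geometry
  if (inherits(g, "hs_grid")) {
    r <- resample_nn(g, grid$xmin, grid$ymax, grid$res,
                     nrow(grid$values), ncol(grid$values))
    return(!is.na(r$values) & r$values != 0)
  }
  ctr <- grid_centers(grid)
  xy <- expand.grid(y = ctr$y, x = ctr$x)  # column-major like the matrix
  inside <- rep(FALSE, nrow(xy))
  polys <- if (is.matrix(g) || (is.list(g) && is.matrix(g[[1]]))) list(g) else g
  for (p in polys) inside <- inside | point_in_poly(xy$x, xy$y, p)
  matrix(inside, nrow = nrow(grid$values), ncol = ncol(grid$values))
}

product_unavailable <- function(message, class) {
  stop(structure(
    class = c(class, "hsmeval_product_unavailable", "error", "condition"),
    list(message = message, call = NULL)
  ))
}

rubric_by_id <- function(models, rubrics) {
  ids <- vapply(rubrics, function(r) r$model_id, character(1))
  out <- lapply(models, function(m) {
    k <- match(m$model_id, ids)
    if (is.na(k)) stop("no rubric evaluation for model ", m$model_id,
                       call. = FALSE)
    rubrics[[k]]
  })
  out
}

union_map <- function(models, thresholds, template) {
  u <- matrix(FALSE, nrow(template$values), ncol(template$values))
  for (m in models) {
    u <- u | binary_map(m, thresholds[[m$model_id]])$grid$values
  }
  structure(list(model_id = "union", threshold_used = NA_real_,
                 grid = hs_grid(u, template$xmin, template$ymax, template$res,
                                template$crs),
                 pixel_size_m = template$res),
            class = "binary_habitat_map")
}

new_habitat_product <- function(species, kind, boundary, model_count,
                                mean_score, thresholds_used, boundary_model_ids,
                                capture_eval, capture_independent, pixel_size_m,
                                compliant = TRUE, notes = character(0)) {
  structure(
    list(species = species, kind = kind, boundary = boundary,
         model_count = model_count, mean_score = mean_score,
         thresholds_used = thresholds_used,
         boundary_model_ids = boundary_model_ids,
         capture_eval = capture_eval,
         capture_independent = capture_independent,
         pixel_size_m = pixel_size_m, compliant = compliant, notes = notes),
    class = "habitat_product"
  )
}

#' @export
print.habitat_product <- function(x, ...) {
  npix <- sum(x$boundary$values, na.rm = TRUE)
  cat(sprintf(
    "<habitat_product> %s suitable habitat for %s\n  %d pixels @ %g m (%.2f km^2, %.0f acres)\n",
    x$kind, x$species, npix, x$pixel_size_m,
    npix * x$pixel_size_m^2 / 1e6, m2_to_acres(npix * x$pixel_size_m^2)
  ))
  if (!is.na(x$capture_eval)) {
    cat(sprintf("  capture rate (evaluation points): %.3f\n", x$capture_eval))
  }
  if (!is.na(x$capture_independent)) {
    cat(sprintf("  capture rate (independent points): %.3f\n",
                x$capture_independent))
  }
  cat(sprintf("  boundary models: %s\n",
              paste(x$boundary_model_ids, collapse = ", ")))
  if (!x$compliant) cat("  NOTE: capture-rate requirement not met; see notes\n")
  invisible(x)
}

# per-pixel model count and average standardized score over a footprint
overlay_statistics <- function(models, thresholds, footprint, template,
                               score_average) {
  count <- matrix(0L, nrow(template$values), ncol(template$values))
  score_sum <- matrix(0, nrow(template$values), ncol(template$values))
  score_n <- matrix(0L, nrow(template$values), ncol(template$values))
  for (m in models) {
    suit <- binary_map(m, thresholds[[m$model_id]])$grid$values
    count <- count + (suit & footprint)
    s <- standardize_scores(m)$grid$values
    contrib <- if (score_average == "suitable_only") {
      !is.na(s) & suit
    } else {
      !is.na(s)
    }
    contrib <- contrib & footprint
    score_sum[contrib] <- score_sum[contrib] + s[contrib]
    score_n <- score_n + contrib
  }
  mean_score <- score_sum / score_n
  mean_score[score_n == 0 | !footprint] <- NA_real_
  count[!footprint] <- 0L
  list(
    model_count = hs_grid(count, template$xmin, template$ymax, template$res,
                          template$crs),
    mean_score = hs_grid(mean_score, template$xmin, template$ymax,
                         template$res, template$crs)
  )
}

#' Map probable suitable habitat
#'
#' Builds the probable-suitable-habitat product from models that (1) pass all
#' three rubric exclusion gates ("acceptable") and (2) capture, or can be
#' recalibrated to capture, each model's per-model capture target (0.80 by
#' default; 0.78 for contractors flagged with that relaxed target). The outer
#' boundary is the union of the qualifying binary maps. If the union captures
#' less than `boundary_target` (0.90, relaxed to 0.89 when a flagged model is
#' in the union), thresholds of lowerable (full-surface) qualifying models are
#' decreased by a greedy rule — repeatedly capture the uncaptured evaluation
#' point with the highest suitability under any lowerable model — until the
#' requirement is met or no lowering remains. With a single qualifying model,
#' its threshold is instead set as close to `boundary_target` as possible.
#' Inside the boundary, *all* acceptable models (including those that failed
#' per-model calibration) are overlaid at their thresholds to produce the
#' per-pixel model count and the per-pixel average standardized (1-100)
#' suitability score. Masked model variants are preferred here; a water mask,
#' when supplied, is applied before capture statistics are computed.
#'
#' @param models list of [suitability_model()] objects on one CRS (aligned to a
#'   common grid internally if needed). Pass masked/unmasked variants as
#'   separate models; the masked one is used here when both exist for a
#'   contractor.
#' @param rubrics list of [evaluate_model()] results covering every model.
#' @param points evaluation `evaluation_set` (or data.frame with `x`, `y`).
#' @param species species label for the product.
#' @param boundary_target union capture requirement; default 0.90, or 0.89 when
#'   any flagged (relaxed-target) model is in the qualifying set.
#' @param water optional [overlay_layer()] masked out of the final product.
#' @param score_average `"all_valid"` (average every acceptable model with a
#'   valid score at the pixel) or `"suitable_only"` (average only models
#'   predicting suitable there).
#' @param independent_points optional later-window points for an independent
#'   capture rate.
#' @param target_res_m optional common-grid resolution override.
#' @return a `habitat_product` of kind `"probable"`. Signals a classed error
#'   (`hsmeval_no_acceptable_model` / `hsmeval_no_qualifying_model`, both
#'   inheriting `hsmeval_product_unavailable`) when no probable map is
#'   possible; emits a warning and sets `compliant = FALSE` when the boundary
#'   target is unreachable with every threshold at its minimum.
#' @export
build_probable <- function(models, rubrics, points, species = NA_character_,
                           boundary_target = NULL, water = NULL,
                           score_average = c("all_valid", "suitable_only"),
                           independent_points = NULL, target_res_m = NULL) {
  score_average <- match.arg(score_average)
  rub <- rubric_by_id(models, rubrics)

  # prefer masked variants for probable mapping
  masked_contractors <- unique(vapply(
    Filter(function(m) m$mask_variant == "masked", models),
    function(m) m$contractor, character(1)))
  use <- vapply(models, function(m) {
    !(m$mask_variant == "unmasked" && m$contractor %in% masked_contractors)
  }, logical(1))
  models <- models[use]; rub <- rub[use]

  models <- align_to_common_grid(models, target_res_m)
  template <- models[[1]]$grid

  acceptable <- vapply(rub, function(r) r$acceptable, logical(1))
  if (!any(acceptable)) {
    product_unavailable(
      sprintf("no model passed all three exclusion gates for %s", species),
      "hsmeval_no_acceptable_model")
  }
  acc_models <- models[acceptable]

  # per-model calibration to each model's own capture target
  thresholds <- list()
  qualifying <- list()
  notes <- character(0)
  for (m in acc_models) {
    cal <- calibrate_threshold(m, points, target = m$capture_target,
                               mode = "at_least")
    if (cal$eligible) {
      thresholds[[m$model_id]] <- cal$threshold
      qualifying[[length(qualifying) + 1L]] <- m
    } else {
      notes <- c(notes, sprintf("%s excluded from boundary: %s",
                                m$model_id, cal$reason))
    }
  }
  if (!length(qualifying)) {
    product_unavailable(
      sprintf("no acceptable model met or could be recalibrated to its capture target for %s",
              species),
      "hsmeval_no_qualifying_model")
  }

  flagged <- any(vapply(qualifying, function(m) m$capture_target < 0.80,
                        logical(1)))
  if (is.null(boundary_target)) boundary_target <- if (flagged) 0.89 else 0.90

  if (length(qualifying) == 1L) {
    # single-model rule: get as close to the boundary target as possible
    m <- qualifying[[1]]
    cal <- calibrate_threshold(m, points, target = boundary_target,
                               mode = "closest")
    thresholds[[m$model_id]] <- cal$threshold
    union <- union_map(qualifying, thresholds, template)
  } else {
    union <- union_map(qualifying, thresholds, template)
    cap <- capture_rate(union, points)
    xy <- eval_points_xy(points)
    point_vals <- lapply(qualifying, function(m) grid_extract(m$grid, xy))
    names(point_vals) <- vapply(qualifying, `[[`, character(1), "model_id")
    lowerable <- vapply(qualifying, function(m) {
      m$delivery_kind == "full_surface"
    }, logical(1))
    while (cap < boundary_target) {
      cv <- grid_extract(union$grid, xy)
      captured <- !is.na(cv) & cv != 0
      best_val <- -Inf; best_model <- NULL
      for (k in which(lowerable)) {
        mid <- qualifying[[k]]$model_id
        v <- point_vals[[mid]]
        # values that would require lowering this model's threshold
        idx <- which(!captured & !is.na(v) & v < thresholds[[mid]])
        if (length(idx) && max(v[idx]) > best_val) {
          best_val <- max(v[idx])
          best_model <- mid
        }
      }
      if (is.null(best_model)) break
      thresholds[[best_model]] <- best_val
      new_union <- union_map(qualifying, thresholds, template)
      stopifnot(all(new_union$grid$values >= union$grid$values))  # monotone
      union <- new_union
      new_cap <- capture_rate(union, points)
      stopifnot(new_cap >= cap)
      cap <- new_cap
    }
    if (cap < boundary_target) {
      warning(sprintf(
        "boundary capture target %.2f unreachable for %s; best achieved %.3f",
        boundary_target, species, cap))
      notes <- c(notes, sprintf("non-compliant: boundary capture %.3f < %.2f",
                                cap, boundary_target))
    }
  }

  boundary <- union$grid
  # overlay thresholds for acceptable models that did not qualify
  for (m in acc_models) {
    if (is.null(thresholds[[m$model_id]])) {
      thresholds[[m$model_id]] <- overlay_threshold(m, points)
    }
  }

  if (!is.null(water)) {
    wet <- rasterize_overlay(water, boundary)
    boundary$values <- boundary$values & !wet
  }
  stats <- overlay_statistics(acc_models, thresholds, boundary$values,
                              template, score_average)

  bmap <- structure(list(grid = boundary), class = "binary_habitat_map")
  cap_eval <- capture_rate(bmap, points)
  cap_ind <- if (!is.null(independent_points)) {
    capture_rate(bmap, independent_points)
  } else NA_real_

  compliant <- !any(grepl("non-compliant", notes))
  new_habitat_product(
    species = species, kind = "probable", boundary = boundary,
    model_count = stats$model_count, mean_score = stats$mean_score,
    thresholds_used = unlist(thresholds),
    boundary_model_ids = vapply(qualifying, `[[`, character(1), "model_id"),
    capture_eval = cap_eval, capture_independent = cap_ind,
    pixel_size_m = template$res, compliant = compliant, notes = notes
  )
}

# threshold used when an acceptable model is overlaid inside the boundary
# without having passed per-model calibration
overlay_threshold <- function(m, points) {
  if (!is.na(m$delivered_threshold)) return(m$delivered_threshold)
  cal <- calibrate_threshold(m, points, target = m$capture_target,
                             mode = "closest")
  if (cal$eligible) cal$threshold else min(m$grid$values, na.rm = TRUE)
}

#' Map potential suitable habitat
#'
#' The complementary product, intended only to guide future field surveys: the
#' union of the models *not* used for the probable boundary (models failing an
#' exclusion gate, or that could not be recalibrated to the per-model capture
#' target), with unmasked variants substituted for masked deliveries, each
#' thresholded as close to `target` (default 0.80) as possible (the delivered
#' threshold is kept when recalibration is impossible), clipped to the area
#' outside the probable boundary.
#'
#' @param models full list of aligned [suitability_model()] objects, including
#'   any unmasked variants.
#' @param rubrics list of [evaluate_model()] results covering every model.
#' @param probable the species' probable `habitat_product`, or `NULL` when no
#'   probable map exists.
#' @param points evaluation points.
#' @param species species label.
#' @param target capture target for potential-model recalibration.
#' @param score_average see [build_probable()].
#' @return a `habitat_product` of kind `"potential"`; an all-empty product when
#'   no leftover models exist.
#' @export
build_potential <- function(models, rubrics, probable, points,
                            species = NA_character_, target = 0.80,
                            score_average = c("all_valid", "suitable_only")) {
  score_average <- match.arg(score_average)
  rubric_by_id(models, rubrics)  # validates coverage
  models <- align_to_common_grid(models)
  template <- models[[1]]$grid
  if (!is.null(probable) && !same_lattice(template, probable$boundary)) {
    stop("models and probable product are on different grids; align first",
         call. = FALSE)
  }
  used <- if (is.null(probable)) character(0) else probable$boundary_model_ids

  unmasked_contractors <- unique(vapply(
    Filter(function(m) m$mask_variant == "unmasked", models),
    function(m) m$contractor, character(1)))
  leftover <- Filter(function(m) {
    if (m$model_id %in% used) return(FALSE)
    # a masked delivery is represented by its unmasked variant here
    if (m$mask_variant == "masked" && m$contractor %in% unmasked_contractors) {
      return(FALSE)
    }
    TRUE
  }, models)

  empty <- hs_grid(matrix(FALSE, nrow(template$values), ncol(template$values)),
                   template$xmin, template$ymax, template$res, template$crs)
  if (!length(leftover)) {
    return(new_habitat_product(
      species = species, kind = "potential", boundary = empty,
      model_count = hs_grid(matrix(0L, nrow(empty$values), ncol(empty$values)),
                            empty$xmin, empty$ymax, empty$res, empty$crs),
      mean_score = hs_grid(matrix(NA_real_, nrow(empty$values),
                                  ncol(empty$values)),
                           empty$xmin, empty$ymax, empty$res, empty$crs),
      thresholds_used = numeric(0), boundary_model_ids = character(0),
      capture_eval = NA_real_, capture_independent = NA_real_,
      pixel_size_m = template$res,
      notes = "no leftover models; empty potential product"))
  }

  thresholds <- list()
  for (m in leftover) {
    cal <- tryCatch(
      calibrate_threshold(m, points, target = target, mode = "closest"),
      error = function(e) list(eligible = FALSE, reason = conditionMessage(e))
    )
    thresholds[[m$model_id]] <- if (cal$eligible) cal$threshold else {
      if (!is.na(m$delivered_threshold)) m$delivered_threshold
      else min(m$grid$values, na.rm = TRUE)
    }
  }
  union <- union_map(leftover, thresholds, template)
  footprint <- union$grid$values
  if (!is.null(probable)) footprint <- footprint & !probable$boundary$values
  fp_grid <- hs_grid(footprint, template$xmin, template$ymax, template$res,
                     template$crs)
  stats <- overlay_statistics(leftover, thresholds, footprint, template,
                              score_average)
  cap <- capture_rate(structure(list(grid = fp_grid),
                                class = "binary_habitat_map"), points)
  new_habitat_product(
    species = species, kind = "potential", boundary = fp_grid,
    model_count = stats$model_count, mean_score = stats$mean_score,
    thresholds_used = unlist(thresholds),
    boundary_model_ids = vapply(leftover, `[[`, character(1), "model_id"),
    capture_eval = cap, capture_independent = NA_real_,
    pixel_size_m = template$res
  )
}

#' Multispecies richness stack
#'
#' Per-pixel count of species whose probable-suitable-habitat boundary covers
#' the pixel.
#'
#' @param products list of probable `habitat_product`s on one shared grid.
#' @return an [hs_grid()] of integer species counts.
#' @export
multispecies_count <- function(products) {
  stopifnot(length(products) >= 1L)
  g0 <- products[[1]]$boundary
  out <- matrix(0L, nrow(g0$values), ncol(g0$values))
  for (p in products) {
    if (!same_lattice(p$boundary, g0)) {
      stop("alignment error: products are on different grids", call. = FALSE)
    }
    out <- out + (p$boundary$values != 0)
  }
  hs_grid(out, g0$xmin, g0$ymax, g0$res, g0$crs)
}

#' Area summary of a habitat product
#'
#' Suitable area in total and within each overlay layer. Overlays may overlap,
#' so overlay rows need not partition the total. Area = suitable-pixel count
#' times pixel area.
#'
#' @param product a `habitat_product`.
#' @param overlays list of [overlay_layer()] objects (possibly empty).
#' @param csv optional output path.
#' @return data.frame with `zone`, `pixels`, `km2`, `acres`.
#' @export
area_summary <- function(product, overlays = list(), csv = NULL) {
  b <- product$boundary
  px_m2 <- product$pixel_size_m^2
  suitable <- b$values != 0
  rows <- data.frame(zone = "total", pixels = sum(suitable),
                     stringsAsFactors = FALSE)
  for (ov in overlays) {
    inside <- rasterize_overlay(ov, b)
    rows <- rbind(rows, data.frame(zone = ov$name,
                                   pixels = sum(suitable & inside)))
  }
  rows$km2 <- rows$pixels * px_m2 / 1e6
  rows$acres <- m2_to_acres(rows$pixels * px_m2)
  if (!is.null(csv)) utils::write.csv(rows, csv, row.names = FALSE)
  rows
}
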