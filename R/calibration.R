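#' Contractor suitability model
#'
#' Wraps one delivered continuous habitat-suitability raster with its delivery
#' metadata. `delivery_kind = "above_threshold_only"` marks models delivered
#' with everything below the contractor's threshold removed, which can only be
#' recalibrated upward; `mask_variant` distinguishes masked deliveries (e.g.
#' clipped to watersheds with known occurrences) from their unmasked
#' counterparts. `capture_target` is the per-model capture-rate requirement for
#' probable-habitat mapping — 0.80 by default, relaxed to 0.78 for contractors
#' whose modelling style cannot match capture rates closely.
#'
#' @param model_id unique identifier.
#' @param grid an [hs_grid()] of continuous suitability values.
#' @param contractor contractor label.
#' @param delivered_threshold the contractor's own suitability threshold, or
#'   `NA` if none was delivered.
#' @param delivery_kind `"full_surface"` or `"above_threshold_only"`.
#' @param mask_variant `"none"`, `"masked"`, or `"unmasked"`.
#' @param capture_target per-model capture-rate requirement (fraction).
#' @param native_resolution_m native pixel size; defaults to the grid's.
#' @return an object of class `suitability_model`.
#' @export
suitability_model <- function(model_id, grid, contractor = "unknown",
                              delivered_threshold = NA_real_,
                              delivery_kind = c("full_surface",
                                                "above_threshold_only"),
                              mask_variant = c("none", "masked", "unmasked"),
                              capture_target = 0.80,
                              native_resolution_m = grid$res) {
  delivery_kind <- match.arg(delivery_kind)
  mask_variant <- match.arg(mask_variant)
  if (delivery_kind == "above_threshold_only") {
    if (is.na(delivered_threshold)) {
      stop("above_threshold_only delivery requires `delivered_threshold`",
           call. = FALSE)
    }
    v <- grid$values[!is.na(grid$values)]
    if (length(v) && min(v) < delivered_threshold) {
      stop("above_threshold_only delivery contains values below the delivered ",
           "threshold", call. = FALSE)
    }
  }
  structure(
    list(model_id = model_id, contractor = contractor, grid = grid,
         native_resolution_m = native_resolution_m,
         delivered_threshold = delivered_threshold,
         delivery_kind = delivery_kind, mask_variant = mask_variant,
         capture_target = capture_target),
    class = "suitability_model"
  )
}

#' @export
print.suitability_model <- function(x, ...) {
  cat(sprintf(
    "<suitability_model> %s (%s) | %s, %s | native %g m | delivered threshold %s | target %g\n",
    x$model_id, x$contractor, x$delivery_kind, x$mask_variant,
    x$native_resolution_m,
    if (is.na(x$delivered_threshold)) "none" else format(x$delivered_threshold),
    x$capture_target
  ))
  invisible(x)
}

#' Threshold a suitability model into a binary habitat map
#'
#' A pixel is suitable when its value is valid and greater than or equal to the
#' threshold (closed comparison, so a delivered threshold reproduces the
#' contractor's above-threshold footprint exactly); nodata pixels are
#' unsuitable.
#'
#' @param model a [suitability_model()].
#' @param threshold suitability cut value.
#' @return object of class `binary_habitat_map`: list with `model_id`,
#'   `threshold_used`, `grid` (logical [hs_grid()]), `pixel_size_m`.
#' @export
binary_map <- function(model, threshold) {
  v <- model$grid$values
  suit <- !is.na(v) & v >= threshold
  structure(
    list(model_id = model$model_id, threshold_used = threshold,
         grid = hs_grid(suit, model$grid$xmin, model$grid$ymax,
                        model$grid$res, model$grid$crs),
         pixel_size_m = model$grid$res),
    class = "binary_habitat_map"
  )
}

eval_points_xy <- function(points) {
  if (inherits(points, "evaluation_set")) points <- points$points
  as.data.frame(points)[, c("x", "y"), drop = FALSE]
}

#' Capture rate of a binary habitat map
#'
#' Fraction of evaluation points whose containing pixel is suitable. Points
#' outside the grid extent or on nodata pixels count in the denominator but
#' never in the numerator.
#'
#' @param map a [binary_map()] result (or any logical `hs_grid` wrapped in a
#'   list with a `grid` element).
#' @param points an `evaluation_set` or a data.frame with `x`, `y`.
#' @return fraction in `[0, 1]`.
#' @export
capture_rate <- function(map, points) {
  xy <- eval_points_xy(points)
  if (nrow(xy) == 0L) {
    stop("capture rate undefined: empty evaluation point set", call. = FALSE)
  }
  g <- if (inherits(map, "hs_grid")) map else map$grid
  v <- grid_extract(g, xy)
  sum(!is.na(v) & v != 0) / nrow(xy)
}

#' Recalibrate a model threshold to a target capture rate
#'
#' Candidate thresholds are the model's suitability values sampled at the
#' evaluation points (the capture rate only changes there). Because the capture
#' rate is non-increasing in the threshold, `at_least` mode — the largest
#' threshold whose rate is at least `target` — also attains the smallest
#' achievable rate that is >= target, so the `closest_above` reading of
#' "approximately the target" selects the same threshold; both mode names are
#' accepted. `closest` mode instead minimizes `|rate - target|` (ties resolved
#' upward), used when a product must get *as close as possible* to a target.
#' Models delivered only above their threshold can never be lowered: if the
#' delivered footprint already captures less than `target`, the model is
#' ineligible.
#'
#' @param model a [suitability_model()].
#' @param points an `evaluation_set` or data.frame with `x`, `y`.
#' @param target required capture rate in `(0, 1]`; defaults to the model's
#'   `capture_target`.
#' @param mode `"at_least"`, `"closest_above"` (identical), or `"closest"`.
#' @return list with `eligible` (logical); when eligible, also `threshold` and
#'   `achieved_rate`; when not, a `reason` string.
#' @export
calibrate_threshold <- function(model, points,
                                target = model$capture_target,
                                mode = c("at_least", "closest_above",
                                         "closest")) {
  mode <- match.arg(mode)
  if (!is.numeric(target) || target <= 0 || target > 1) {
    stop("`target` must be in (0, 1]", call. = FALSE)
  }
  xy <- eval_points_xy(points)
  if (nrow(xy) == 0L) stop("empty evaluation point set", call. = FALSE)
  vals <- grid_extract(model$grid, xy)
  n <- length(vals)
  cand <- sort(unique(vals[!is.na(vals)]), decreasing = TRUE)
  restricted <- model$delivery_kind == "above_threshold_only"
  if (restricted) {
    delivered_rate <- sum(!is.na(vals) & vals >= model$delivered_threshold) / n
    if (delivered_rate < target && mode != "closest") {
      return(list(eligible = FALSE,
                  reason = sprintf(
                    "delivered footprint captures %.3f < target %.3f and the threshold cannot be decreased",
                    delivered_rate, target)))
    }
    cand <- cand[cand >= model$delivered_threshold]
    if (!length(cand)) cand <- model$delivered_threshold
  }
  if (!length(cand)) {
    return(list(eligible = FALSE,
                reason = "no evaluation point falls on a valid pixel"))
  }
  rates <- vapply(cand, function(t) sum(!is.na(vals) & vals >= t) / n,
                  numeric(1))
  if (mode == "closest") {
    err <- abs(rates - target)
    k <- which(err == min(err))
    k <- k[which.max(rates[k])]  # ties: prefer the higher capture rate
    return(list(eligible = TRUE, threshold = cand[k], achieved_rate = rates[k]))
  }
  ok <- which(rates >= target)
  if (!length(ok)) {
    return(list(eligible = FALSE,
                reason = sprintf("best achievable capture rate %.3f < target %.3f",
                                 max(rates), target)))
  }
  k <- ok[1]  # candidates sorted decreasing: first feasible = largest threshold
  list(eligible = TRUE, threshold = cand[k], achieved_rate = rates[k])
}

#' Standardize a suitability surface to the 1-100 scale
#'
#' Linear min-max rescale of the model's valid values:
#' `s = 1 + 99 * (x - min) / (max - min)`. A constant-valued surface maps to
#' 100 everywhere valid. Affine transforms of the input (`a*x + b`, `a > 0`)
#' give identical output.
#'
#' @param model a [suitability_model()].
#' @return object of class `standardized_grid`: list with `model_id` and
#'   `grid` (an [hs_grid()] whose valid values lie in `[1, 100]`).
#' @export
standardize_scores <- function(model) {
  v <- model$grid$values
  if (all(is.na(v))) stop("cannot standardize an all-nodata grid", call. = FALSE)
  lo <- min(v, na.rm = TRUE); hi <- max(v, na.rm = TRUE)
  s <- if (hi > lo) 1 + 99 * (v - lo) / (hi - lo) else {
    out <- v; out[!is.na(out)] <- 100; out
  }
  structure(
    list(model_id = model$model_id,
         grid = hs_grid(s, model$grid$xmin, model$grid$ymax, model$grid$res,
                        model$grid$crs)),
    class = "standardized_grid"
  )
}

#' Calibration report for a set of models
#'
#' @param models list of [suitability_model()] objects (aligned or not).
#' @param points evaluation points.
#' @param csv optional output path.
#' @param mode calibration mode passed to [calibrate_threshold()].
#' @return data.frame: `model_id`, `delivered_threshold`, `calibrated_threshold`,
#'   `achieved_rate`, `eligible`, `reason`.
#' @export
calibration_report <- function(models, points, csv = NULL, mode = "at_least") {
  rows <- lapply(models, function(m) {
    res <- calibrate_threshold(m, points, mode = mode)
    data.frame(
      model_id = m$model_id,
      delivered_threshold = m$delivered_threshold,
      calibrated_threshold = if (res$eligible) res$threshold else NA_real_,
      achieved_rate = if (res$eligible) res$achieved_rate else NA_real_,
      eligible = res$eligible,
      reason = if (res$eligible) "" else res$reason,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE)
  out
}
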