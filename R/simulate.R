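#' Synthetic species configuration
#'
#' Bundles the study conditions for one synthetic species: the landscape
#' window, the truth-surface resolution, the occurrence sample, and the
#' contractor styles. Defaults emulate the structure of a desert rare-plant
#' case: a 10 km working window, a 100 m truth surface, 150 element-occurrence
#' polygons concentrated on high-suitability ground with a mix of accuracy
#' classes and record years (mostly 1981-2012, a few older, a few 2013-2018
#' for independent validation), and three full-surface contractor models with
#' distinct resolutions and noise levels.
#'
#' @param seed integer seed; all downstream generation is deterministic in it.
#' @param window_km landscape edge length (km).
#' @param truth_res_m truth-surface pixel size (m).
#' @param n_occurrences number of occurrence polygons to draw.
#' @param species species label attached to records.
#' @param accuracy_mix named numeric vector of probabilities over accuracy
#'   classes `"1"`-`"10"` (must sum to 1).
#' @param year_mix named numeric vector of probabilities over year bins; names
#'   are `"start:end"` ranges.
#' @param rank_mix named numeric vector of probabilities over occurrence ranks.
#' @param contractor_styles list of style descriptors; see
#'   [default_contractor_styles()].
#' @return list of class `synthetic_species_config`.
#' @export
synthetic_species_config <- function(
    seed = 1L, window_km = 10, truth_res_m = 100, n_occurrences = 150L,
    species = "Eriastrum synthetica",
    accuracy_mix = c(`1` = 0.25, `2` = 0.20, `3` = 0.20, `4` = 0.15,
                     `5` = 0.05, `7` = 0.10, `8` = 0.05),
    year_mix = c(`1960:1980` = 0.05, `1981:2012` = 0.85, `2013:2018` = 0.10),
    rank_mix = c(Excellent = 0.30, Good = 0.40, Fair = 0.20, Poor = 0.05,
                 X = 0.02, Unknown = 0.03),
    contractor_styles = default_contractor_styles()) {
  stopifnot(window_km > 0, truth_res_m > 0, n_occurrences >= 0)
  if (abs(sum(accuracy_mix) - 1) > 1e-8) stop("accuracy_mix must sum to 1",
                                              call. = FALSE)
  if (abs(sum(year_mix) - 1) > 1e-8) stop("year_mix must sum to 1",
                                          call. = FALSE)
  structure(
    list(seed = as.integer(seed), window_km = window_km,
         truth_res_m = truth_res_m, n_occurrences = as.integer(n_occurrences),
         species = species, accuracy_mix = accuracy_mix, year_mix = year_mix,
         rank_mix = rank_mix, contractor_styles = contractor_styles),
    class = "synthetic_species_config"
  )
}

#' Default contractor styles: three full-surface models
#'
#' Distinct resolutions and noise levels, all delivered as full continuous
#' surfaces with a recommended threshold at the given quantile of their values.
#'
#' @return list of style descriptors with fields `contractor`, `resolution_m`,
#'   `noise_sd`, `delivery_kind`, `mask_variant`, `threshold_quantile`,
#'   `capture_target`.
#' @export
default_contractor_styles <- function() {
  list(
    list(contractor = "A", resolution_m = 100, noise_sd = 0.05,
         delivery_kind = "full_surface", mask_variant = "none",
         threshold_quantile = 0.50, capture_target = 0.80),
    list(contractor = "B", resolution_m = 300, noise_sd = 0.15,
         delivery_kind = "full_surface", mask_variant = "none",
         threshold_quantile = 0.55, capture_target = 0.80),
    list(contractor = "C", resolution_m = 200, noise_sd = 0.10,
         delivery_kind = "full_surface", mask_variant = "none",
         threshold_quantile = 0.60, capture_target = 0.80)
  )
}

#' Extended contractor styles covering every delivery quirk
#'
#' One clean full-surface model, one masked/unmasked pair from a contractor
#' with the relaxed 0.78 capture target, and one values-above-threshold-only
#' delivery — so a workspace built from these exercises every eligibility
#' branch of the pipeline.
#'
#' @return list of style descriptors.
#' @export
extended_contractor_styles <- function() {
  list(
    list(contractor = "A", resolution_m = 100, noise_sd = 0.05,
         delivery_kind = "full_surface", mask_variant = "none",
         threshold_quantile = 0.50, capture_target = 0.80),
    list(contractor = "B", resolution_m = 300, noise_sd = 0.15,
         delivery_kind = "full_surface", mask_variant = "masked",
         threshold_quantile = 0.55, capture_target = 0.78),
    list(contractor = "B", resolution_m = 300, noise_sd = 0.15,
         delivery_kind = "full_surface", mask_variant = "unmasked",
         threshold_quantile = 0.55, capture_target = 0.78),
    list(contractor = "C", resolution_m = 200, noise_sd = 0.10,
         delivery_kind = "above_threshold_only", mask_variant = "none",
         threshold_quantile = 0.65, capture_target = 0.80)
  )
}

# dense row-normalized Gaussian smoothing matrix (reflecting tails into the
# normalization keeps edge rows unbiased)
smoothing_matrix <- function(n, sigma) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) stats::dnorm(j - i, sd = sigma))
  K / rowSums(K)
}

# smooth, standardized (mean 0, sd 1) spatially autocorrelated field
smooth_field <- function(n, sigma) {
  K <- smoothing_matrix(n, sigma)
  z <- K %*% matrix(stats::rnorm(n * n), n, n) %*% t(K)
  (z - mean(z)) / stats::sd(z)
}

#' Simulate a synthetic landscape
#'
#' Generates smooth spatially autocorrelated covariate fields (Gaussian-
#' smoothed white noise with a correlation length of about 1 km) and a truth
#' suitability surface: a logistic function of a linear covariate combination,
#' so truth values lie strictly in (0, 1). Deterministic in `config$seed`.
#'
#' @param config a [synthetic_species_config()].
#' @return list with `truth` (an [hs_grid()]) and `covariates` (list of three
#'   [hs_grid()] fields).
#' @export
simulate_landscape <- function(config) {
  n <- as.integer(round(config$window_km * 1000 / config$truth_res_m))
  if (n < 2L) stop("non-positive or degenerate landscape dimensions",
                   call. = FALSE)
  sigma <- max(2, 1000 / config$truth_res_m)  # ~1 km correlation length
  with_seed(config$seed, {
    z1 <- smooth_field(n, sigma)
    z2 <- smooth_field(n, sigma)
    z3 <- smooth_field(n, sigma * 0.5)
    truth <- stats::plogis(-0.4 + 1.3 * z1 + 0.9 * z2 - 0.6 * z3)
    mk <- function(m) hs_grid(m, xmin = 0, ymax = n * config$truth_res_m,
                              res = config$truth_res_m)
    list(truth = mk(truth), covariates = list(mk(z1), mk(z2), mk(z3)))
  })
}

# class -> polygon radius (m); class 3 spans both sides of the 150 m rule
class_radius <- function(class) {
  lo <- c(30, 40, 50, 50, 150, 500, 500, 500, 500, 500)
  hi <- c(60, 80, 400, 80, 500, 5000, 5000, 5000, 5000, 5000)
  stats::runif(length(class), lo[class], hi[class])
}

sample_from_mix <- function(n, mix) {
  sample(names(mix), n, replace = TRUE, prob = mix)
}

#' Simulate occurrence records on a truth surface
#'
#' Occurrence centres are drawn without replacement with probability
#' proportional to the truth suitability of each pixel (then jittered within
#' the pixel), so records cluster on high-suitability ground. Each centre
#' becomes a circular polygon with a radius drawn for its accuracy class
#' (classes 1, 2, 4 well under 150 m equivalent radius; class 3 spanning both
#' sides of 150 m; classes 6-10 well over). Years and ranks are drawn from the
#' configured mixes. Deterministic in `config$seed`.
#'
#' @param truth the truth [hs_grid()] from [simulate_landscape()].
#' @param config a [synthetic_species_config()].
#' @return an `occ_records` data frame.
#' @export
simulate_occurrences <- function(truth, config) {
  n <- config$n_occurrences
  if (n == 0L) {
    return(occurrence_records(
      data.frame(record_id = character(0), species = character(0),
                 accuracy_class = integer(0), year = integer(0),
                 occ_rank = character(0), source = character(0)),
      list()))
  }
  v <- truth$values
  ok <- which(!is.na(v))
  if (n > length(ok)) {
    warning("n_occurrences exceeds the number of valid pixels; sampling all")
    n <- length(ok)
  }
  with_seed(config$seed + 1L, {
    cells <- sample(ok, n, prob = v[ok])
    rc <- arrayInd(cells, dim(v))
    cx <- truth$xmin + (rc[, 2] - 1 + stats::runif(n)) * truth$res
    cy <- truth$ymax - (rc[, 1] - 1 + stats::runif(n)) * truth$res
    classes <- as.integer(sample_from_mix(n, config$accuracy_mix))
    radii <- class_radius(classes)
    bins <- sample_from_mix(n, config$year_mix)
    years <- vapply(strsplit(bins, ":"), function(b) {
      rng <- as.integer(b[1]):as.integer(b[2])
      rng[sample.int(length(rng), 1L)]
    }, integer(1))
    ranks <- sample_from_mix(n, config$rank_mix)
    attrs <- data.frame(
      record_id = sprintf("EO%04d", seq_len(n)),
      species = config$species,
      accuracy_class = classes,
      year = years,
      occ_rank = ranks,
      source = "synthetic",
      stringsAsFactors = FALSE
    )
    geoms <- lapply(seq_len(n), function(i) {
      circle_poly(cx[i], cy[i], radii[i], n = 36L)
    })
    occurrence_records(attrs, geoms)
  })
}

#' Simulate contractor-style suitability models
#'
#' Each style degrades the truth surface with smooth noise of the style's
#' standard deviation, aggregates it to the style's resolution (block mean),
#' then applies the style's delivery quirks: masked variants are clipped to
#' synthetic 2-km "watersheds" containing at least one occurrence centroid;
#' above-threshold-only deliveries discard everything below the delivered
#' threshold (set at the style's value quantile). Deterministic in `seed`.
#'
#' @param truth the truth [hs_grid()].
#' @param styles list of style descriptors (see [default_contractor_styles()]).
#' @param seed integer seed.
#' @param occurrences optional `occ_records`, required for masked styles.
#' @return list of [suitability_model()] objects (native grids, unaligned).
#' @export
simulate_contractor_models <- function(truth, styles, seed,
                                       occurrences = NULL) {
  stopifnot(length(styles) >= 1L)
  n <- nrow(truth$values)
  lapply(seq_along(styles), function(k) {
    st <- styles[[k]]
    with_seed(seed + 100L + k, {
      vals <- truth$values
      if (st$noise_sd > 0) {
        vals <- vals + st$noise_sd * smooth_field(n, max(2, 500 / truth$res))
      }
      g <- hs_grid(vals, truth$xmin, truth$ymax, truth$res, truth$crs)
      fct <- as.integer(round(st$resolution_m / truth$res))
      if (fct > 1L) g <- aggregate_mean(g, fct)
      if (identical(st$mask_variant, "masked")) {
        if (is.null(occurrences)) {
          stop("masked style requires `occurrences`", call. = FALSE)
        }
        g <- mask_to_watersheds(g, occurrences, block_m = 2000)
      }
      thr <- stats::quantile(g$values, st$threshold_quantile, na.rm = TRUE,
                             names = FALSE)
      if (identical(st$delivery_kind, "above_threshold_only")) {
        g$values[!is.na(g$values) & g$values < thr] <- NA_real_
      }
      suitability_model(
        model_id = sprintf("%s-%s%s", st$contractor,
                           substr(st$delivery_kind, 1, 4),
                           if (st$mask_variant == "none") "" else
                             paste0("-", st$mask_variant)),
        grid = g, contractor = st$contractor, delivered_threshold = thr,
        delivery_kind = st$delivery_kind, mask_variant = st$mask_variant,
        capture_target = st$capture_target %||% 0.80,
        native_resolution_m = st$resolution_m
      )
    })
  })
}

# clip a grid to 2-km blocks ("watersheds") containing >= 1 occurrence centroid
mask_to_watersheds <- function(g, occurrences, block_m = 2000) {
  pts <- occurrence_centroids(occurrences)
  bx <- floor((pts$x - g$xmin) / block_m)
  by <- floor((g$ymax - pts$y) / block_m)
  keep_blocks <- unique(paste(bx, by))
  ctr <- grid_centers(g)
  colb <- floor((ctr$x - g$xmin) / block_m)
  rowb <- floor((g$ymax - ctr$y) / block_m)
  keep <- outer(rowb, colb, function(r, c) paste(c, r) %in% keep_blocks)
  g$values[!keep] <- NA_real_
  g
}

#' Build the full synthetic evaluation inputs for one species
#'
#' Convenience wrapper running the whole generator: landscape, occurrences,
#' QC (window filter, internal centroids, maximal thinning), contractor
#' models, and independent (post-window) evaluation points.
#'
#' @param config a [synthetic_species_config()].
#' @param n_eval_points optional cap on the number of thinned evaluation
#'   points (a seeded subsample is taken when more are available).
#' @param styles contractor styles; defaults to the config's.
#' @return list with `landscape`, `records` (all), `eval_records` (QC-passed,
#'   1981-2012), `eval_points` (an `evaluation_set`), `independent_points`
#'   (2013-2018 centroids, possibly empty), and `models`.
#' @export
simulate_species_inputs <- function(config, n_eval_points = NULL,
                                    styles = config$contractor_styles) {
  land <- simulate_landscape(config)
  records <- simulate_occurrences(land$truth, config)
  eval_records <- filter_records(records, window = c(1981, 2012))
  centroids <- occurrence_centroids(eval_records)
  eval_points <- thin_maximal(centroids, min_dist_m = 430,
                              seed = config$seed + 2L,
                              species = config$species, window = c(1981, 2012))
  if (!is.null(n_eval_points) && nrow(eval_points$points) > n_eval_points) {
    pts <- eval_points$points
    keep <- with_seed(config$seed + 3L,
                      sort(sample.int(nrow(pts), n_eval_points)))
    eval_points$points <- pts[keep, , drop = FALSE]
    rownames(eval_points$points) <- NULL
  }
  ind_records <- filter_records(records, window = c(2013, 2018))
  independent_points <- if (nrow(ind_records)) {
    thin_maximal(occurrence_centroids(ind_records), min_dist_m = 430,
                 seed = config$seed + 4L, species = config$species,
                 window = c(2013, 2018))
  } else NULL
  models <- simulate_contractor_models(land$truth, styles, config$seed,
                                       occurrences = records)
  list(landscape = land, records = records, eval_records = eval_records,
       eval_points = eval_points, independent_points = independent_points,
       models = models)
}

#' Write a complete synthetic species workspace to disk
#'
#' Emits everything the pipeline reads: contractor model rasters as ESRI ASCII
#' grids with a JSON metadata manifest, occurrence polygons as GeoJSON (in the
#' local metre CRS), a rubric evidence YAML rating every qualitative topic
#' `acceptable`, plus a second, data-poor species (six records) whose audit
#' fails the occurrence-count exclusion gate. Uses the extended contractor
#' styles, so the workspace contains an acceptable model, a masked/unmasked
#' pair, and an above-threshold-only delivery.
#'
#' @param dir output directory.
#' @param config a [synthetic_species_config()]; styles are overridden by
#'   [extended_contractor_styles()].
#' @return invisibly, a list of the paths written.
#' @export
simulate_species_workspace <- function(dir, config = synthetic_species_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  styles <- extended_contractor_styles()
  inputs <- simulate_species_inputs(config, styles = styles)

  occ_path <- file.path(dir, "occurrences.geojson")
  rec <- inputs$records
  sparse_cfg <- synthetic_species_config(
    seed = config$seed + 10L, window_km = config$window_km,
    truth_res_m = config$truth_res_m, n_occurrences = 6L,
    species = paste(config$species, "minor"))
  sparse <- simulate_occurrences(inputs$landscape$truth, sparse_cfg)
  all_rec <- rbind(rec, sparse)
  write_geojson(
    geometry = all_rec$geometry,
    properties = all_rec[, c("record_id", "species", "accuracy_class", "year",
                             "occ_rank", "source")],
    path = occ_path, crs_name = "local-metre"
  )

  model_meta <- list()
  for (m in inputs$models) {
    f <- file.path(dir, paste0(m$model_id, ".asc"))
    write_asc(m$grid, f)
    model_meta[[m$model_id]] <- list(
      model_id = m$model_id, contractor = m$contractor,
      file = basename(f), delivered_threshold = m$delivered_threshold,
      delivery_kind = m$delivery_kind, mask_variant = m$mask_variant,
      capture_target = m$capture_target,
      native_resolution_m = m$native_resolution_m
    )
  }
  models_path <- file.path(dir, "models.json")
  jsonlite::write_json(model_meta, models_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  evidence_path <- file.path(dir, "evidence.yaml")
  qual <- rubric_topics()
  qual <- qual$topic[!qual$computed]
  yaml::write_yaml(
    stats::setNames(as.list(rep("acceptable", length(qual))), qual),
    evidence_path
  )
  invisible(list(occurrences = occ_path, models = models_path,
                 evidence = evidence_path, dir = dir))
}

#' Read a model workspace written by [simulate_species_workspace()]
#'
#' @param dir workspace directory containing `models.json` and the `.asc` grids.
#' @return list of [suitability_model()] objects.
#' @export
read_model_workspace <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "models.json"))
  lapply(meta, function(mm) {
    suitability_model(
      model_id = mm$model_id,
      grid = read_asc(file.path(dir, mm$file)),
      contractor = mm$contractor,
      delivered_threshold = mm$delivered_threshold %||% NA_real_,
      delivery_kind = mm$delivery_kind, mask_variant = mm$mask_variant,
      capture_target = mm$capture_target,
      native_resolution_m = mm$native_resolution_m
    )
  })
}
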