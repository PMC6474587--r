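# rubric evaluations that pass / fail the gates, for wiring ensemble fixtures
ok_rubric <- function(id) {
  evaluate_model(id, records_from_points(seq(0, 30000, by = 1000), rep(0, 31)),
                 evidence = all_acceptable_evidence())
}
bad_rubric <- function(id) {
  evaluate_model(id, records_from_points(seq(0, 4000, by = 1000), rep(0, 5)),
                 evidence = all_acceptable_evidence())
}

strip_points <- function(n = 10) {
  data.frame(record_id = sprintf("P%02d", seq_len(n)),
             x = seq(50, by = 100, length.out = n), y = rep(50, n))
}

# 1 x 10 strip with the given values
strip <- function(vals, id, ...) {
  suitability_model(id, hs_grid(matrix(vals, nrow = 1), 0, 100, 100), ...)
}

test_that("disjoint 50/50 models union to full capture with no lowering", {
  m1 <- strip(c(rep(1, 5), rep(0, 5)), "m1", capture_target = 0.5)
  m2 <- strip(c(rep(0, 5), rep(1, 5)), "m2", capture_target = 0.5)
  prob <- build_probable(list(m1, m2), list(ok_rubric("m1"), ok_rubric("m2")),
                         strip_points(), species = "sp")
  expect_equal(prob$capture_eval, 1)
  # thresholds never moved below the calibrated value of 1
  expect_equal(unname(prob$thresholds_used[c("m1", "m2")]), c(1, 1))
  expect_true(all(prob$boundary$values))
})

test_that("under-capturing unions are lowered until the 90% requirement holds", {
  vals <- (10:1) / 10
  m1 <- strip(vals, "m1"); m2 <- strip(vals, "m2")
  prob <- build_probable(list(m1, m2), list(ok_rubric("m1"), ok_rubric("m2")),
                         strip_points(), species = "sp")
  expect_gte(prob$capture_eval, 0.9)
  # at least one threshold moved below the per-model calibration value (0.3)
  expect_true(any(prob$thresholds_used[c("m1", "m2")] < 0.3))
})

test_that("a single qualifying model is calibrated as close to 90% as possible", {
  m <- strip(seq(0.9, 0, by = -0.1), "solo")
  prob <- build_probable(list(m), list(ok_rubric("solo")), strip_points(),
                         species = "sp")
  expect_equal(prob$capture_eval, 0.9)
  expect_equal(prob$boundary_model_ids, "solo")
})

test_that("union capture is at least the best individual capture", {
  set.seed(61)
  pts <- data.frame(record_id = sprintf("P%02d", 1:20),
                    x = runif(20, 0, 1000), y = runif(20, 0, 1000))
  m1 <- tiny_model(matrix(runif(100), 10, 10), res = 100, id = "m1")
  m2 <- tiny_model(matrix(runif(100), 10, 10), res = 100, id = "m2")
  prob <- build_probable(list(m1, m2), list(ok_rubric("m1"), ok_rubric("m2")),
                         pts, species = "sp")
  for (id in c("m1", "m2")) {
    ind <- capture_rate(binary_map(if (id == "m1") m1 else m2,
                                   prob$thresholds_used[[id]]), pts)
    expect_gte(prob$capture_eval, ind)
  }
})

test_that("acceptable models failing calibration are overlaid inside the boundary only", {
  m1 <- strip((10:1) / 10, "full")
  # above-threshold-only delivery capturing 50% that cannot be lowered
  v <- (10:1) / 10; v[v < 0.6] <- NA
  m2 <- strip(v, "ato", delivered_threshold = 0.6,
              delivery_kind = "above_threshold_only")
  prob <- build_probable(list(m1, m2), list(ok_rubric("full"), ok_rubric("ato")),
                         strip_points(), species = "sp")
  # boundary comes from the full-surface model alone
  expect_equal(prob$boundary_model_ids, "full")
  # inside the boundary both models count where both are suitable
  expect_equal(max(prob$model_count$values), 2)
  cnt <- prob$model_count$values[1, ]
  expect_true(all(cnt[1:5] == 2))   # ato suitable on the first five pixels
  expect_true(all(cnt[!prob$boundary$values[1, ]] == 0))
})

test_that("missing or non-qualifying model sets signal classed conditions", {
  m <- strip((10:1) / 10, "m")
  expect_error(
    build_probable(list(m), list(bad_rubric("m")), strip_points(), "sp"),
    class = "hsmeval_no_acceptable_model")
  # acceptable but uncalibratable: above-threshold-only capturing too little
  v <- (10:1) / 10; v[v < 0.8] <- NA
  ato <- strip(v, "ato", delivered_threshold = 0.8,
               delivery_kind = "above_threshold_only")
  expect_error(
    build_probable(list(ato), list(ok_rubric("ato")), strip_points(), "sp"),
    class = "hsmeval_no_qualifying_model")
  # both classes inherit the umbrella condition
  expect_error(
    build_probable(list(m), list(bad_rubric("m")), strip_points(), "sp"),
    class = "hsmeval_product_unavailable")
})

test_that("an unreachable boundary target yields a flagged, best-effort product", {
  # two points sit on nodata for both models: max union capture = 0.8
  v1 <- c((10:3) / 10, NA, NA)
  m1 <- strip(v1, "m1"); m2 <- strip(v1, "m2")
  expect_warning(
    prob <- build_probable(list(m1, m2), list(ok_rubric("m1"), ok_rubric("m2")),
                           strip_points(), species = "sp"),
    "unreachable")
  expect_false(prob$compliant)
  expect_equal(prob$capture_eval, 0.8)
})

test_that("water masking removes pixels before capture statistics", {
  m <- strip((10:1) / 10, "m")
  # water polygon over the first two pixels
  water <- overlay_layer("water_mask",
                         list(rbind(c(0, 0), c(200, 0), c(200, 100), c(0, 100))))
  prob <- build_probable(list(m), list(ok_rubric("m")), strip_points(),
                         species = "sp", water = water)
  expect_true(all(!prob$boundary$values[1, 1:2]))
  expect_true(all(prob$model_count$values[1, 1:2] == 0))
  # the two masked points no longer count as captured
  expect_lte(prob$capture_eval, 0.8)
})

test_that("mean scores stay on the 1-100 scale and model counts within bounds", {
  fx <- t1_fixture()
  prob <- fx$probable
  ms <- prob$mean_score$values[prob$boundary$values]
  ms <- ms[!is.na(ms)]
  expect_true(all(ms >= 1 & ms <= 100))
  cnt <- prob$model_count$values[prob$boundary$values]
  expect_true(all(cnt >= 1 & cnt <= length(fx$inputs$models)))
  expect_true(all(prob$model_count$values[!prob$boundary$values] == 0))
})

test_that("potential habitat uses leftover models outside the probable boundary", {
  m1 <- strip((10:1) / 10, "full")
  v <- (10:1) / 10; v[v < 0.6] <- NA
  m2 <- strip(v, "ato", delivered_threshold = 0.6,
              delivery_kind = "above_threshold_only")
  rubs <- list(ok_rubric("full"), bad_rubric("ato"))
  prob <- build_probable(list(m1, m2), rubs, strip_points(), species = "sp")
  pot <- build_potential(align_to_common_grid(list(m1, m2)), rubs, prob,
                         strip_points(), species = "sp")
  # leftover above-threshold-only model mapped at its delivered threshold
  expect_equal(unname(pot$thresholds_used["ato"]), 0.6)
  expect_true(all(!(pot$boundary$values & prob$boundary$values)))
  # potential = ato footprint minus probable boundary
  ato_suit <- binary_map(align_to_common_grid(list(m1, m2))[[2]], 0.6)$grid$values
  expect_equal(pot$boundary$values, ato_suit & !prob$boundary$values)
})

test_that("unmasked variants supply potential habitat when masked models were used", {
  vals <- (10:1) / 10
  vm <- vals; vm[9:10] <- NA  # masked delivery misses the eastern pixels
  masked <- strip(vm, "b-masked", contractor = "B", mask_variant = "masked")
  unmasked <- strip(vals, "b-unmasked", contractor = "B",
                    mask_variant = "unmasked")
  rubs <- list(ok_rubric("b-masked"), ok_rubric("b-unmasked"))
  prob <- build_probable(list(masked, unmasked), rubs, strip_points(),
                         species = "sp")
  expect_equal(prob$boundary_model_ids, "b-masked")  # masked preferred
  pot <- build_potential(align_to_common_grid(list(masked, unmasked)), rubs,
                         prob, strip_points(), species = "sp")
  expect_equal(pot$boundary_model_ids, "b-unmasked")
  expect_true(all(!(pot$boundary$values & prob$boundary$values)))
})

test_that("no leftover models yields an empty potential product", {
  m <- strip((10:1) / 10, "m")
  rubs <- list(ok_rubric("m"))
  prob <- build_probable(list(m), rubs, strip_points(), species = "sp")
  pot <- build_potential(list(m), rubs, prob, strip_points(), species = "sp")
  expect_equal(sum(pot$boundary$values), 0)
  expect_equal(area_summary(pot)$km2[1], 0)
})

test_that("multispecies counts equal the elementwise sum of boolean boundaries", {
  g <- function(v) hs_grid(matrix(v, 2, 2), 0, 200, 100)
  mk <- function(v) structure(list(boundary = g(v)), class = "habitat_product")
  p1 <- mk(c(TRUE, TRUE, FALSE, FALSE))
  p2 <- mk(c(TRUE, FALSE, TRUE, FALSE))
  p3 <- mk(c(TRUE, TRUE, TRUE, FALSE))
  stack <- multispecies_count(list(p1, p2, p3))
  expected <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2) +
    matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2) +
    matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(stack$values, expected)
  # identical boundaries -> 2 inside, 0 outside; disjoint -> max 1
  both <- multispecies_count(list(p1, p1))
  expect_setequal(unique(as.vector(both$values)), c(0L, 2L))
  disj <- multispecies_count(list(mk(c(TRUE, FALSE, FALSE, FALSE)),
                                  mk(c(FALSE, FALSE, FALSE, TRUE))))
  expect_equal(max(disj$values), 1)
  # mixed grids are an alignment error
  p_off <- structure(list(boundary = hs_grid(matrix(TRUE, 3, 3), 0, 300, 100)),
                     class = "habitat_product")
  expect_error(multispecies_count(list(p1, p_off)), "alignment")
})

test_that("area summaries convert pixel counts to km2 and acres", {
  vals <- matrix(FALSE, 40, 25)
  vals[1:40, 1:25] <- TRUE  # 1,000 pixels
  prod <- structure(list(boundary = hs_grid(vals, 0, 400, 10),
                         pixel_size_m = 10),
                    class = "habitat_product")
  a <- area_summary(prod)
  expect_equal(a$pixels, 1000)
  expect_equal(a$km2, 0.1)
  expect_equal(a$acres, 24.7105381)
  # an overlay over 12 of the 25 columns covers 480 pixels;
  # overlapping overlays may sum to more than the total
  left <- overlay_layer("left", list(rbind(c(0, 0), c(125, 0), c(125, 400),
                                           c(0, 400))))
  most <- overlay_layer("most", list(rbind(c(0, 0), c(200, 0), c(200, 400),
                                           c(0, 400))))
  a2 <- area_summary(prod, list(left, most))
  expect_equal(a2$pixels[a2$zone == "left"], 480)
  expect_gt(sum(a2$pixels[a2$zone != "total"]), a2$pixels[a2$zone == "total"])
})

# signed ring area; outer rings CCW (+), holes CW (-)
shoelace_test <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
}

test_that("products export grids, boundary polygons and a manifest", {
  fx <- t1_fixture()
  d <- tempfile()
  files <- export_product(fx$probable, d, coarsest_input_res_m = 300)
  expect_true(all(file.exists(unlist(files))))
  b <- read_asc(files$boundary)
  expect_equal(sum(b$values == 1, na.rm = TRUE),
               sum(fx$probable$boundary$values))
  man <- jsonlite::read_json(files$manifest)
  expect_equal(man$recommended_min_use_resolution_m, 300)
  expect_equal(man$capture_eval, fx$probable$capture_eval)
  # boundary rings reproduce the suitable area exactly
  rings <- boundary_polygons(fx$probable$boundary)
  ring_area <- sum(vapply(rings, function(r) shoelace_test(r), numeric(1)))
  expect_equal(ring_area,
               sum(fx$probable$boundary$values) * fx$probable$pixel_size_m^2)
})
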