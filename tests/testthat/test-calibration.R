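# a 1 x 10 strip model whose pixel values are 0.9, 0.8, ..., 0.0 west to east,
# with one evaluation point in each pixel
strip_fixture <- function() {
  vals <- matrix((9:0) / 10, nrow = 1)  # exact decimal doubles
  model <- tiny_model(vals, res = 100, id = "strip")
  pts <- data.frame(record_id = sprintf("P%02d", 1:10),
                    x = seq(50, 950, by = 100), y = rep(50, 10))
  list(model = model, points = pts)
}

test_that("capture rate counts points in suitable pixels over all points", {
  fx <- strip_fixture()
  expect_equal(capture_rate(binary_map(fx$model, 0.95), fx$points), 0)
  expect_equal(capture_rate(binary_map(fx$model, 0.0), fx$points), 1)
  # 8 of 10 points at or above 0.2
  expect_equal(capture_rate(binary_map(fx$model, 0.2), fx$points), 0.8)
  expect_error(capture_rate(binary_map(fx$model, 0.5), fx$points[0, ]),
               "empty")
})

test_that("points outside the extent or on nodata stay in the denominator", {
  fx <- strip_fixture()
  fx$model$grid$values[1, 1] <- NA  # the 0.9 pixel becomes nodata
  pts <- rbind(fx$points, data.frame(record_id = "OUT", x = -500, y = 50))
  expect_equal(capture_rate(binary_map(fx$model, 0.0), pts), 9 / 11)
})

test_that("at_least calibration returns the largest threshold meeting the target", {
  fx <- strip_fixture()
  cal <- calibrate_threshold(fx$model, fx$points, target = 0.8,
                             mode = "at_least")
  expect_true(cal$eligible)
  expect_equal(cal$threshold, 0.2)
  expect_equal(cal$achieved_rate, 0.8)
  # brute-force sweep: every strictly larger candidate under-captures
  for (t in seq(0.3, 0.9, by = 0.1)) {
    expect_lt(capture_rate(binary_map(fx$model, t), fx$points), 0.8)
  }
  # target 1.0 on a full surface: threshold = minimum point value
  cal1 <- calibrate_threshold(fx$model, fx$points, target = 1)
  expect_equal(cal1$threshold, 0)
  expect_equal(cal1$achieved_rate, 1)
})

test_that("capture rate is non-increasing over the full candidate sweep", {
  set.seed(31)
  model <- tiny_model(matrix(runif(400), 20, 20), res = 100)
  pts <- data.frame(record_id = sprintf("P%02d", 1:30),
                    x = runif(30, 0, 2000), y = runif(30, 0, 2000))
  cand <- sort(unique(grid_extract(model$grid, pts[, c("x", "y")])))
  rates <- vapply(cand, function(t) capture_rate(binary_map(model, t), pts),
                  numeric(1))
  expect_true(all(diff(rates) <= 0))
})

test_that("above-threshold-only deliveries can only be recalibrated upward", {
  fx <- strip_fixture()
  v <- fx$model$grid$values
  v[v < 0.4] <- NA  # delivered footprint = values >= 0.4 (6 of 10 points)
  ato <- suitability_model("ato", hs_grid(v, 0, 100, 100),
                           delivered_threshold = 0.4,
                           delivery_kind = "above_threshold_only")
  res <- calibrate_threshold(ato, fx$points, target = 0.8)
  expect_false(res$eligible)
  expect_match(res$reason, "cannot be decreased")
  # but a reachable (lower) target can still be tightened upward
  res2 <- calibrate_threshold(ato, fx$points, target = 0.5)
  expect_true(res2$eligible)
  expect_equal(res2$threshold, 0.5)
  expect_equal(res2$achieved_rate, 0.5)
  # constructor enforces the delivery invariant
  expect_error(
    suitability_model("bad", hs_grid(matrix(c(0.1, 0.9), 1), 0, 100, 100),
                      delivered_threshold = 0.5,
                      delivery_kind = "above_threshold_only"),
    "below the delivered")
})

test_that("ineligibility is reported when no target is achievable", {
  g <- hs_grid(matrix(NA_real_, 2, 2), 0, 200, 100)
  g$values[1, 1] <- 0.5
  model <- suitability_model("m", g)
  pts <- data.frame(record_id = c("a", "b"), x = c(150, 150), y = c(50, 150))
  res <- calibrate_threshold(model, pts, target = 0.9)
  expect_false(res$eligible)
})

test_that("closest mode lands on the capture rate nearest the target", {
  fx <- strip_fixture()
  # achievable rates are 0.1, 0.2, ..., 1.0; closest to 0.87 (ties upward) is 0.9
  cal <- calibrate_threshold(fx$model, fx$points, target = 0.87,
                             mode = "closest")
  expect_equal(cal$achieved_rate, 0.9)
  # float-exact tie: 4 points, achievable rates 0.25/0.5/0.75/1; target 0.625
  # is equidistant from 0.5 and 0.75 and ties resolve to the higher rate
  m4 <- tiny_model(matrix((4:1) / 10, nrow = 1), res = 100)
  p4 <- data.frame(record_id = sprintf("Q%d", 1:4),
                   x = seq(50, 350, by = 100), y = 50)
  cal2 <- calibrate_threshold(m4, p4, target = 0.625, mode = "closest")
  expect_equal(cal2$achieved_rate, 0.75)
})

test_that("standardization maps the value range onto [1, 100] exactly", {
  vals <- matrix(c(2, 4, 6, NA), 2, 2)
  s <- standardize_scores(tiny_model(vals))
  expect_equal(s$grid$values[1, 1], 1)     # minimum -> 1
  expect_equal(s$grid$values[1, 2], 100)   # maximum -> 100
  expect_equal(s$grid$values[2, 1], 50.5)  # midrange -> 50.5
  expect_true(is.na(s$grid$values[2, 2]))
  # constant surface -> 100 everywhere valid
  s0 <- standardize_scores(tiny_model(matrix(0.3, 2, 2)))
  expect_true(all(s0$grid$values == 100))
  expect_error(standardize_scores(tiny_model(matrix(NA_real_, 2, 2))),
               "all-nodata")
})

test_that("standardization is invariant to positive affine transforms", {
  set.seed(13)
  vals <- matrix(runif(36), 6, 6)
  a <- standardize_scores(tiny_model(vals))
  b <- standardize_scores(tiny_model(3.7 * vals + 11))
  expect_equal(a$grid$values, b$grid$values)
})

test_that("calibration reports collect per-model eligibility", {
  fx <- strip_fixture()
  rep <- calibration_report(list(fx$model), fx$points, mode = "at_least")
  expect_equal(rep$calibrated_threshold, 0.2)
  expect_true(rep$eligible)
  cs <- tempfile(fileext = ".csv")
  calibration_report(list(fx$model), fx$points, csv = cs)
  expect_true(file.exists(cs))
})
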