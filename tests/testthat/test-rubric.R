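test_that("occurrence-count gate flips exactly at n = 10", {
  expect_false(rate_occurrence_count(9)$gate_pass)
  expect_true(rate_occurrence_count(10)$gate_pass)
  expect_equal(rate_occurrence_count(55), list(rating = "ideal", gate_pass = TRUE))
  expect_equal(rate_occurrence_count(30)$rating, "acceptable")
  expect_equal(rate_occurrence_count(0), list(rating = "caution", gate_pass = FALSE))
  # small-range override upgrades <25 to acceptable without touching the gate
  expect_equal(rate_occurrence_count(15, small_range_flag = TRUE)$rating,
               "acceptable")
  expect_false(rate_occurrence_count(5, small_range_flag = TRUE)$gate_pass)
  expect_error(rate_occurrence_count(-1), "non-negative")
})

test_that("occurrence-age gate and ratings follow the majority/20%/2000 rules", {
  expect_equal(rate_occurrence_age(rep(2005, 12)),
               list(rating = "ideal", gate_pass = TRUE))
  expect_false(rate_occurrence_age(c(rep(1949, 6), rep(1995, 4)))$gate_pass)
  # exactly half old still passes the gate ("majority" is strict)
  expect_true(rate_occurrence_age(c(rep(1950, 5), rep(1995, 5)))$gate_pass)
  expect_equal(rate_occurrence_age(c(rep(1975, 3), rep(1995, 7)))$rating,
               "caution")
  # exactly 20% old is not "more than 20%"
  expect_equal(rate_occurrence_age(c(rep(1975, 2), rep(1995, 8)))$rating,
               "acceptable")
  expect_error(rate_occurrence_age(integer(0)), "non-empty")
})

test_that("age rating never improves when post-1981 records are removed", {
  years <- c(rep(1975, 2), rep(1995, 8))  # acceptable
  rank_of <- function(r) match(r, c("caution", "acceptable", "ideal"))
  base <- rank_of(rate_occurrence_age(years)$rating)
  for (k in which(years >= 1981)) {
    expect_lte(rank_of(rate_occurrence_age(years[-k])$rating), base)
  }
})

test_that("accuracy gate and precision ratings follow the class rules", {
  expect_false(rate_occurrence_accuracy(c(rep(7, 6), rep(1, 4)))$gate_pass)
  expect_equal(rate_occurrence_accuracy(rep(1, 8))$rating, "ideal")
  res <- rate_occurrence_accuracy(c(rep(8, 3), rep(2, 17)))
  expect_equal(res$rating, "acceptable")  # 85% precise
  expect_true(res$gate_pass)
  # class 3 precision flips at a 150 m equivalent radius
  expect_equal(rate_occurrence_accuracy(c(3, 3),
                                        class3_radii_m = c(150, 151))$rating,
               "caution")  # 50% precise
  expect_equal(rate_occurrence_accuracy(rep(3, 5),
                                        class3_radii_m = c(100, 100, 100, 100, 200))$rating,
               "acceptable")  # 80% precise
  expect_error(rate_occurrence_accuracy(c(0, 5)), "\\[1, 10\\]")
})

test_that("evaluate_model covers exactly the rubric topics and applies defaults", {
  topics <- rubric_topics()
  expect_equal(nrow(topics), 23)
  expect_equal(sum(topics$computed), 3)

  recs <- records_from_points(seq(0, 66000, by = 1000), rep(0, 67),
                              year = 2001L)
  ev <- evaluate_model("m", recs, evidence = all_acceptable_evidence())
  expect_true(ev$acceptable)
  expect_setequal(ev$ratings$topic, topics$topic)
  expect_equal(nrow(ev$ratings), 23)

  # empty evidence: every qualitative topic defaults to caution
  ev0 <- evaluate_model("m", recs)
  qual <- ev0$ratings[!ev0$ratings$topic %in%
                        topics$topic[topics$computed], ]
  expect_true(all(qual$rating == "caution"))
  expect_true(ev0$acceptable)  # gates are data-driven, not evidence-driven

  expect_error(evaluate_model("m", recs, evidence = list(bogus = "ideal")),
               "unknown rubric topic")
})

test_that("the count gate dominates otherwise ideal models", {
  recs <- records_from_points(seq(0, 4000, by = 1000), rep(0, 5), year = 2005L)
  ev <- evaluate_model("tiny", recs, evidence = all_acceptable_evidence())
  expect_false(ev$gate_count_pass)
  expect_false(ev$acceptable)
  expect_true(ev$gate_age_pass && ev$gate_accuracy_pass)
})

test_that("acceptable=true implies all three gate conditions", {
  cfg <- synthetic_species_config(seed = 21, n_occurrences = 80)
  land <- simulate_landscape(cfg)
  recs <- simulate_occurrences(land$truth, cfg)
  ev <- evaluate_model("m", recs)
  if (ev$acceptable) {
    expect_gte(nrow(recs), 10)
    expect_lte(mean(recs$year <= 1950), 0.5)
    expect_lte(mean(recs$accuracy_class %in% 6:10), 0.5)
  }
  expect_equal(ev$acceptable,
               ev$gate_count_pass && ev$gate_age_pass && ev$gate_accuracy_pass)
})

test_that("evidence configs read from YAML and reports write out", {
  yml <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(absence_data = "ideal",
                        covariate_correlation = list(rating = "caution",
                                                     note = "not assessed")),
                   yml)
  ev_cfg <- read_evidence(yml)
  recs <- records_from_points(seq(0, 29000, by = 1000), rep(0, 30))
  ev <- evaluate_model("m", recs, evidence = ev_cfg)
  r <- ev$ratings
  expect_equal(r$rating[r$topic == "absence_data"], "ideal")
  expect_equal(r$rating[r$topic == "covariate_correlation"], "caution")
  expect_equal(r$evidence[r$topic == "covariate_correlation"], "not assessed")

  cs <- tempfile(fileext = ".csv"); md <- tempfile(fileext = ".md")
  rubric_report(ev, csv = cs, markdown = md)
  expect_equal(nrow(read.csv(cs)), 23)
  expect_true(any(grepl("\\| absence_data \\| ideal", readLines(md))))
})
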