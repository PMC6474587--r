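#' Model-construction audit rubric
#'
#' Pre-existing habitat models are audited against a fixed rubric of 23 topics
#' in five categories (occurrence data, environmental covariates, modelling
#' algorithm, extent and resolution, model selection and thresholds). Each
#' topic receives one of three ratings: `ideal`, `acceptable`, or `caution`
#' ("interpret with caution"). Three occurrence-data topics additionally carry
#' hard exclusion gates — number, age, and spatial accuracy of the occurrences
#' used to build the model — and a model is *acceptable* for probable-habitat
#' mapping only if it passes all three gates. The three gated topics are
#' computed from the occurrence records; the remaining 20 are judgement calls
#' rated from an evidence config, defaulting to `caution` when no evidence is
#' supplied.
#'
#' @name rubric
NULL

RATING_LEVELS <- c("caution", "acceptable", "ideal")

#' The fixed rubric topic list
#'
#' @return data.frame with columns `category`, `topic`, and `computed`
#'   (`TRUE` for the three data-derived gate topics).
#' @export
rubric_topics <- function() {
  df <- rbind(
    data.frame(category = "occurrence_data", topic = c(
      "occurrence_number", "occurrence_age", "occurrence_accuracy",
      "occurrence_status", "occurrence_identification",
      "occurrence_spatial_bias", "occurrence_spatial_distribution",
      "absence_data")),
    data.frame(category = "covariates", topic = c(
      "covariate_relevance", "covariate_comprehensiveness",
      "covariate_resolution_scale", "covariate_accuracy", "covariate_count",
      "covariate_currency", "covariate_selection", "covariate_correlation")),
    data.frame(category = "algorithm", topic = c(
      "algorithm_literature", "algorithm_interactions",
      "algorithm_nonlinearity")),
    data.frame(category = "extent_resolution", topic = c(
      "model_extent", "output_resolution")),
    data.frame(category = "selection_thresholds", topic = c(
      "model_selection", "threshold_selection"))
  )
  df$computed <- df$topic %in% c("occurrence_number", "occurrence_age",
                                 "occurrence_accuracy")
  df
}

#' Rate the number of occurrences used to build a model
#'
#' Gate: at least 10 occurrences. Rating: `ideal` above 50, `acceptable` for
#' 25-50, otherwise `caution` — unless `small_range_flag` documents a species
#' with a very small, well-understood range, in which case fewer than 25
#' occurrences is still `acceptable`.
#'
#' @param n number of occurrences (>= 0).
#' @param small_range_flag manual override for small-range species.
#' @return list with `rating` and `gate_pass`.
#' @export
rate_occurrence_count <- function(n, small_range_flag = FALSE) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != round(n)) {
    stop("`n` must be a single non-negative integer", call. = FALSE)
  }
  rating <- if (n > 50) "ideal"
    else if (n >= 25) "acceptable"
    else if (small_range_flag) "acceptable"
    else "caution"
  list(rating = rating, gate_pass = n >= 10)
}

#' Rate the age of the occurrence records
#'
#' Gate: no more than half the records date from 1950 or earlier. Rating:
#' `ideal` if every record is from 2000 onward; `caution` if more than 20%
#' are from 1980 or earlier; otherwise `acceptable`.
#'
#' @param years integer vector of record years (non-empty).
#' @return list with `rating` and `gate_pass`.
#' @export
rate_occurrence_age <- function(years) {
  if (!length(years) || any(is.na(years))) {
    stop("`years` must be a non-empty vector of record years", call. = FALSE)
  }
  gate_pass <- mean(years <= 1950) <= 0.5
  rating <- if (all(years >= 2000)) "ideal"
    else if (mean(years <= 1980) > 0.20) "caution"
    else "acceptable"
  list(rating = rating, gate_pass = gate_pass)
}

#' Rate the spatial accuracy of the occurrence records
#'
#' A record is *precise* when its accuracy class is 1, 2, or 4, or it is class
#' 3 with an equivalent radius (`sqrt(area/pi)`) of at most 150 m. Gate: no
#' more than half the records in the imprecise classes 6-10. Rating: `ideal`
#' if all records are precise, `acceptable` if at least 80% are, otherwise
#' `caution`.
#'
#' @param classes integer vector of accuracy classes (1-10, non-empty).
#' @param class3_radii_m equivalent radii (m) aligned with `classes`; only the
#'   entries where `classes == 3` are used (`NA` elsewhere is fine).
#' @return list with `rating` and `gate_pass`.
#' @export
rate_occurrence_accuracy <- function(classes, class3_radii_m = NULL) {
  if (!length(classes)) stop("`classes` must be non-empty", call. = FALSE)
  if (any(is.na(classes)) || any(classes < 1 | classes > 10)) {
    stop("accuracy classes must be integers in [1, 10]", call. = FALSE)
  }
  if (is.null(class3_radii_m)) class3_radii_m <- rep(NA_real_, length(classes))
  precise <- classes %in% c(1L, 2L, 4L) |
    (classes == 3L & !is.na(class3_radii_m) & class3_radii_m <= 150)
  gate_pass <- mean(classes %in% 6:10) <= 0.5
  frac <- mean(precise)
  rating <- if (frac == 1) "ideal" else if (frac >= 0.80) "acceptable" else "caution"
  list(rating = rating, gate_pass = gate_pass)
}

#' Audit one model's construction against the full rubric
#'
#' Computes the three gated occurrence-data topics from the records available
#' for the model-building window, takes the 20 qualitative topic ratings from
#' the evidence config (topic key -> rating, optionally with a note), and
#' assigns `caution` to any topic with no evidence. The model is `acceptable`
#' exactly when all three exclusion gates pass.
#'
#' @param model_id identifier of the audited model.
#' @param records `occ_records` for the model-building window (pre-thinning).
#' @param evidence named list (or path handled by [read_evidence()]) mapping
#'   qualitative topic keys to a rating string or a
#'   `list(rating = , note = )`; unknown keys are an error.
#' @param small_range_flag see [rate_occurrence_count()].
#' @return object of class `rubric_evaluation`: list with `model_id`,
#'   `ratings` (data.frame: category, topic, rating, evidence), `gate_count_pass`,
#'   `gate_age_pass`, `gate_accuracy_pass`, `acceptable`.
#' @export
evaluate_model <- function(model_id, records, evidence = list(),
                           small_range_flag = FALSE) {
  topics <- rubric_topics()
  qual_keys <- topics$topic[!topics$computed]
  unknown <- setdiff(names(evidence), qual_keys)
  if (length(unknown)) {
    stop("config error: unknown rubric topic key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  cnt <- rate_occurrence_count(n, small_range_flag)
  if (n > 0) {
    age <- rate_occurrence_age(records$year)
    acc <- rate_occurrence_accuracy(records$accuracy_class,
                                    sqrt(records$area_m2 / pi))
  } else {
    age <- list(rating = "caution", gate_pass = FALSE)
    acc <- list(rating = "caution", gate_pass = FALSE)
  }
  rating <- character(nrow(topics))
  note <- character(nrow(topics))
  for (i in seq_len(nrow(topics))) {
    key <- topics$topic[i]
    if (key == "occurrence_number") {
      rating[i] <- cnt$rating
      note[i] <- sprintf("computed from %d records", n)
    } else if (key == "occurrence_age") {
      rating[i] <- age$rating
      note[i] <- sprintf("computed from record years (%d records)", n)
    } else if (key == "occurrence_accuracy") {
      rating[i] <- acc$rating
      note[i] <- sprintf("computed from accuracy classes (%d records)", n)
    } else {
      ev <- evidence[[key]]
      if (is.null(ev)) {
        rating[i] <- "caution"
        note[i] <- "no evidence provided"
      } else if (is.character(ev)) {
        rating[i] <- match.arg(ev, RATING_LEVELS)
        note[i] <- ""
      } else {
        rating[i] <- match.arg(ev$rating, RATING_LEVELS)
        note[i] <- ev$note %||% ""
      }
    }
  }
  ratings <- data.frame(category = topics$category, topic = topics$topic,
                        rating = rating, evidence = note,
                        stringsAsFactors = FALSE)
  structure(
    list(model_id = model_id, ratings = ratings,
         gate_count_pass = cnt$gate_pass,
         gate_age_pass = age$gate_pass,
         gate_accuracy_pass = acc$gate_pass,
         acceptable = cnt$gate_pass && age$gate_pass && acc$gate_pass),
    class = "rubric_evaluation"
  )
}

#' @export
print.rubric_evaluation <- function(x, ...) {
  cat(sprintf("<rubric_evaluation> model %s: %s\n", x$model_id,
              if (x$acceptable) "ACCEPTABLE" else "NOT acceptable"))
  cat(sprintf("  gates: count %s | age %s | accuracy %s\n",
              x$gate_count_pass, x$gate_age_pass, x$gate_accuracy_pass))
  tab <- table(factor(x$ratings$rating, levels = RATING_LEVELS))
  cat(sprintf("  ratings: %d caution, %d acceptable, %d ideal\n",
              tab[["caution"]], tab[["acceptable"]], tab[["ideal"]]))
  invisible(x)
}

#' Read a rubric evidence config
#'
#' @param path YAML or JSON file mapping qualitative topic keys to a rating
#'   string or a mapping with `rating` and `note`.
#' @return named list usable as the `evidence` argument of [evaluate_model()].
#' @export
read_evidence <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path)
  } else {
    yaml::read_yaml(path)
  }
}

#' Write a rubric evaluation report
#'
#' @param evaluation a `rubric_evaluation`.
#' @param csv,markdown output paths (`NULL` to skip either).
#' @return invisibly, the ratings data.frame.
#' @export
rubric_report <- function(evaluation, csv = NULL, markdown = NULL) {
  df <- evaluation$ratings
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(markdown)) {
    lines <- c(
      sprintf("# Model construction audit: %s", evaluation$model_id),
      "",
      sprintf("Acceptable for probable-habitat mapping: **%s** (gates: count %s, age %s, accuracy %s)",
              evaluation$acceptable, evaluation$gate_count_pass,
              evaluation$gate_age_pass, evaluation$gate_accuracy_pass),
      "",
      "| Category | Topic | Rating | Evidence |",
      "| --- | --- | --- | --- |",
      sprintf("| %s | %s | %s | %s |", df$category, df$topic, df$rating,
              df$evidence)
    )
    writeLines(lines, markdown)
  }
  invisible(df)
}
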