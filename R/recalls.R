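# Repeated 24-h recall data: participants, recall days, meal occasions.

occasion_levels <- function() {
  c("breakfast", "lunch", "dinner", "snack1", "snack2", "snack3", "snack4")
}

#' Construct a recall dataset
#'
#' Bundles participant attributes with their consumption events from
#' repeated 24-hour recalls. Events are kept long: one row per consumed
#' food per meal occasion per recall day. Events with `grams = 0` are
#' retained (they contribute nothing but preserve provenance of
#' replacements).
#'
#' @param participants Tibble `pid, sex, age_years, weight_kg, height_cm,
#'   education, survey_weight`.
#' @param events Tibble `pid, day_index, occasion, event_id, item_id, grams`.
#' @param provenance Free-text origin note.
#' @param foods Optional food table; when supplied, `item_id`s are checked
#'   against it.
#' @return A `recall_dataset` object (list of the two validated tibbles).
#' @export
recall_dataset <- function(participants, events, provenance = "unspecified",
                           foods = NULL) {
  ds <- structure(
    list(participants = as_tibble(participants),
         events = as_tibble(events),
         provenance = provenance),
    class = "recall_dataset"
  )
  validate_recalls(ds, foods = foods)
  ds
}

#' @export
print.recall_dataset <- function(x, ...) {
  cat("<recall_dataset> ", x$provenance, "\n", sep = "")
  cat(sprintf("  %d participants, %d recall days, %d consumption events\n",
              nrow(x$participants),
              nrow(distinct(x$events, .data$pid, .data$day_index)),
              nrow(x$events)))
  invisible(x)
}

#' Validate a recall dataset
#'
#' Checks participant invariants (positive weight and survey weight, age in
#' range, known sex/education levels), event invariants (non-negative grams,
#' occasions within the 7-slot vocabulary, no orphan days), and, when a food
#' table is given, that every `item_id` resolves.
#'
#' @param ds A `recall_dataset`.
#' @param foods Optional food table for foreign-key checks.
#' @param age_range Permitted age interval, inclusive.
#' @return `ds`, invisibly.
#' @export
validate_recalls <- function(ds, foods = NULL, age_range = c(65, 79)) {
  p <- ds$participants
  e <- ds$events
  fail <- function(msg, class = "dietshift_validation_error") {
    abort(msg, class = class)
  }
  if (anyDuplicated(p$pid)) fail("duplicated participant pid")
  if (any(p$weight_kg <= 0)) fail("participant weight_kg must be positive")
  if (any(p$survey_weight <= 0)) fail("survey_weight must be positive")
  if (any(p$age_years < age_range[1] | p$age_years > age_range[2])) {
    fail(sprintf("age_years outside configured range [%d, %d]",
                 age_range[1], age_range[2]))
  }
  if (any(!p$sex %in% c("male", "female"))) fail("sex must be male/female")
  if (nrow(e) == 0) {
    warn("recall dataset has participants but no consumption events")
    return(invisible(ds))
  }
  if (any(is.na(e$grams) | e$grams < 0)) {
    fail(paste0("negative grams in event row(s): ",
                paste(which(is.na(e$grams) | e$grams < 0), collapse = ", ")))
  }
  bad_occ <- unique(e$occasion[!e$occasion %in% occasion_levels()])
  if (length(bad_occ) > 0) {
    fail(paste0("unknown meal occasion label(s): ",
                paste(bad_occ, collapse = ", "),
                " (occasions are never silently re-binned)"))
  }
  orphans <- setdiff(unique(e$pid), p$pid)
  if (length(orphans) > 0) {
    fail(paste0("recall day(s) reference unknown participant(s): ",
                paste(orphans, collapse = ", ")),
         class = "dietshift_referential_error")
  }
  if (anyDuplicated(e$event_id)) fail("duplicated event_id")
  if (!is.null(foods)) {
    unknown <- !e$item_id %in% foods$item_id
    if (any(unknown)) {
      rows <- which(unknown)
      fail(paste0("event(s) reference unknown item_id: ",
                  paste(sprintf("%s (row %d)", e$item_id[rows], rows),
                        collapse = ", ")))
    }
  }
  invisible(ds)
}

#' Load a recall dataset from participant and event CSV files
#'
#' @param participants_path CSV `pid, sex, age_years, weight_kg, height_cm,
#'   education, survey_weight`.
#' @param events_path Long CSV `pid, day_index, occasion, event_id,
#'   item_id, grams`.
#' @param foods Food table used to resolve `item_id` foreign keys.
#' @param provenance Free-text origin note.
#' @return A validated `recall_dataset`.
#' @export
load_recalls <- function(participants_path, events_path, foods,
                         provenance = NULL) {
  p <- readr::read_csv(participants_path, show_col_types = FALSE,
                       progress = FALSE)
  e <- readr::read_csv(events_path, show_col_types = FALSE, progress = FALSE)
  recall_dataset(
    p, e,
    provenance = provenance %||%
      paste0("loaded from ", basename(participants_path), " + ",
             basename(events_path)),
    foods = foods
  )
}

#' Write a recall dataset to a pair of CSV files
#'
#' @param ds A `recall_dataset`.
#' @param participants_path,events_path Output CSV paths.
#' @return `ds`, invisibly.
#' @export
write_recalls <- function(ds, participants_path, events_path) {
  readr::write_csv(ds$participants, participants_path)
  readr::write_csv(ds$events, events_path)
  invisible(ds)
}

#' Descriptive summary of a recall dataset, stratified by sex
#'
#' The descriptive block of a survey characteristics table: per-sex counts,
#' median (p25-p75) age, mean (SD) body-mass index, and education-level
#' counts. Sexes absent from the data are reported with `n = 0` and `NA`
#' statistics.
#'
#' @param ds A `recall_dataset`.
#' @return A tibble with one row per sex.
#' @export
dataset_summary <- function(ds) {
  p <- ds$participants
  if (nrow(p) == 0) {
    abort("cannot summarise an empty dataset", class = "dietshift_empty_error")
  }
  p %>%
    mutate(sex = factor(.data$sex, levels = c("male", "female")),
           bmi = .data$weight_kg / (.data$height_cm / 100)^2) %>%
    group_by(sex, .drop = FALSE) %>%
    summarise(
      n = n(),
      age_median = median(.data$age_years),
      age_p25 = unname(quantile(.data$age_years, 0.25)),
      age_p75 = unname(quantile(.data$age_years, 0.75)),
      bmi_mean = mean(.data$bmi),
      bmi_sd = sd(.data$bmi),
      edu_low = sum(.data$education == "low"),
      edu_middle = sum(.data$education == "middle"),
      edu_high = sum(.data$education == "high"),
      .groups = "drop"
    ) %>%
    mutate(pct = 100 * .data$n / sum(.data$n),
           sex = as.character(.data$sex)) %>%
    select("sex", "n", "pct", dplyr::everything())
}
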