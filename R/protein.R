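# Protein scoring: total (amino-acid mass), digestible, and utilizable
# (per-meal limiting amino-acid score) protein.
#
# All amino-acid bookkeeping is in mg; grams appear only at reporting.
# Scoring is pool-then-score within a meal occasion: amino acids eaten in
# the same occasion can complement each other, amino acids eaten at
# different occasions cannot.

dig_cols <- function() paste0("dig_", iaa_cols())

#' Per-event protein and digestible amino acid content
#'
#' For each consumption event: total protein in grams (amino-acid mass
#' basis, `grams/100 * total_aa_mg / 1000`), digestible protein, and the
#' digestible amount of each indispensable amino acid in mg
#' (`grams/100 * content_per_100g * digestibility`). All quantities are
#' linear in consumed grams.
#'
#' @param events Tibble with at least `item_id` and `grams` (one row per
#'   consumption event; additional columns are carried through).
#' @param foods Validated food table with complete amino-acid profiles.
#' @return `events` augmented with `total_g`, `digestible_g`, and
#'   `dig_his` ... `dig_val` (mg, after digestibility).
#' @export
event_protein <- function(events, foods) {
  unknown <- setdiff(unique(events$item_id), foods$item_id)
  if (length(unknown) > 0) {
    abort(paste0("event(s) reference unresolvable item(s): ",
                 paste(unknown, collapse = ", ")),
          class = "dietshift_validation_error")
  }
  cols <- c("item_id", "digestibility", "plant_fraction", "kcal_per_100g",
            "total_aa_mg", iaa_cols())
  ev <- left_join(events, select(foods, all_of(cols)), by = "item_id")
  scale <- ev$grams / 100
  out <- mutate(
    ev,
    total_g = scale * .data$total_aa_mg / 1000,
    digestible_g = .data$total_g * .data$digestibility,
    kcal = scale * .data$kcal_per_100g,
    plant_g = .data$total_g * .data$plant_fraction
  )
  for (a in iaa_cols()) {
    out[[paste0("dig_", a)]] <- scale * out[[a]] * out$digestibility
  }
  select(out, -all_of(c(iaa_cols(), "total_aa_mg", "digestibility",
                        "plant_fraction", "kcal_per_100g")))
}

#' Similarity factor of a meal's digestible amino acids to a reference
#'
#' The amino-acid score of a pooled meal: for each IAA group, the
#' digestible density (mg per g digestible protein) is divided by the
#' reference pattern density; the similarity factor is the smallest of the
#' nine ratios, capped at 1. When no amino acid is limiting the factor is
#' 100% and no limiting amino acid is reported. A protein-free meal
#' (`digestible_g = 0`) is assigned similarity 1 by convention — its
#' utilizable protein is 0 by multiplication, so the convention cannot
#' affect any aggregate.
#'
#' @param dig_iaa_mg Named numeric vector over [iaa_names()]: digestible mg
#'   of each IAA in the meal.
#' @param digestible_g Digestible protein of the meal, grams.
#' @param ref A `reference_pattern` (mg per g protein).
#' @return List with `similarity` (in \[0, 1\]) and `limiting_iaa`
#'   (IAA name, or `NA` when nothing is limiting).
#' @export
meal_similarity <- function(dig_iaa_mg, digestible_g, ref = who_reference_pattern()) {
  stopifnot(length(digestible_g) == 1, digestible_g >= 0)
  dig_iaa_mg <- dig_iaa_mg[iaa_names()]
  if (any(is.na(dig_iaa_mg))) {
    abort("digestible IAA vector must cover all nine scoring groups",
          class = "dietshift_validation_error")
  }
  if (any(dig_iaa_mg < 0)) {
    abort("negative amino acid mass", class = "dietshift_validation_error")
  }
  if (digestible_g == 0) {
    return(list(similarity = 1, limiting_iaa = NA_character_))
  }
  ratios <- (dig_iaa_mg / digestible_g) / as.numeric(ref)
  i <- which.min(ratios)
  if (ratios[[i]] >= 1) {
    list(similarity = 1, limiting_iaa = NA_character_)
  } else {
    list(similarity = unname(ratios[[i]]), limiting_iaa = iaa_names()[[i]])
  }
}

# vectorised similarity over a tibble holding digestible_g and dig_* columns
similarity_cols <- function(tb, ref) {
  dens <- as.matrix(tb[, dig_cols()]) / tb$digestible_g
  ratios <- sweep(dens, 2, as.numeric(ref), "/")
  min_i <- max.col(-ratios, ties.method = "first")
  min_r <- ratios[cbind(seq_len(nrow(ratios)), min_i)]
  sim <- pmin(1, min_r)
  lim <- ifelse(min_r < 1, iaa_names()[min_i], NA_character_)
  zero <- tb$digestible_g == 0
  sim[zero] <- 1
  lim[zero] <- NA_character_
  tb$similarity <- sim
  tb$limiting_iaa <- lim
  tb
}

#' Score one meal occasion
#'
#' Pools all events of the occasion (amino acids are summed before
#' scoring), then applies the similarity factor to the digestible protein:
#' `utilizable_g = similarity * digestible_g`.
#'
#' @param meal Tibble of consumption events for a single occasion
#'   (`item_id`, `grams`, optionally `occasion`).
#' @param foods Food table.
#' @param ref Reference pattern.
#' @return One-row tibble: `occasion, total_g, digestible_g, similarity,
#'   limiting_iaa, utilizable_g`.
#' @export
meal_summary <- function(meal, foods, ref = who_reference_pattern()) {
  occ <- if ("occasion" %in% names(meal) && nrow(meal) > 0) {
    unique(meal$occasion)[1]
  } else {
    NA_character_
  }
  ev <- event_protein(meal, foods)
  pooled <- tibble(
    occasion = occ,
    total_g = sum(ev$total_g),
    digestible_g = sum(ev$digestible_g)
  )
  for (a in iaa_cols()) {
    pooled[[paste0("dig_", a)]] <- sum(ev[[paste0("dig_", a)]])
  }
  pooled <- similarity_cols(pooled, ref)
  pooled %>%
    mutate(utilizable_g = .data$similarity * .data$digestible_g) %>%
    select("occasion", "total_g", "digestible_g", "similarity",
           "limiting_iaa", "utilizable_g")
}

#' Score every meal occasion in a recall dataset
#'
#' @param ds A `recall_dataset` (or a bare events tibble with `pid,
#'   day_index, occasion, item_id, grams`).
#' @param foods Food table.
#' @param ref Reference pattern.
#' @return Tibble with one row per `pid x day_index x occasion`:
#'   `total_g, digestible_g, similarity, limiting_iaa, utilizable_g, kcal`.
#' @export
meal_summaries <- function(ds, foods, ref = who_reference_pattern()) {
  events <- if (inherits(ds, "recall_dataset")) ds$events else ds
  ev <- event_protein(events, foods)
  pooled <- ev %>%
    group_by(.data$pid, .data$day_index, .data$occasion) %>%
    summarise(
      total_g = sum(.data$total_g),
      digestible_g = sum(.data$digestible_g),
      kcal = sum(.data$kcal),
      plant_g = sum(.data$plant_g),
      across(all_of(dig_cols()), sum),
      .groups = "drop"
    )
  pooled <- similarity_cols(pooled, ref)
  pooled %>%
    mutate(utilizable_g = .data$similarity * .data$digestible_g) %>%
    select("pid", "day_index", "occasion", "total_g", "digestible_g",
           "similarity", "limiting_iaa", "utilizable_g", "kcal", "plant_g")
}

#' Daily protein summaries per person-day
#'
#' Sums the per-occasion summaries within each recall day (daily utilizable
#' protein is the sum of the per-occasion utilizable amounts, not a daily
#' re-score), and expresses each figure per kg body weight.
#'
#' @param ds A `recall_dataset`.
#' @param foods Food table.
#' @param ref Reference pattern.
#' @return Tibble with one row per person-day: `pid, day_index, total_g,
#'   digestible_g, utilizable_g, kcal`, the `_per_kg` variants, and the
#'   participant's `sex`, `weight_kg`, `survey_weight`.
#' @export
daily_summaries <- function(ds, foods, ref = who_reference_pattern()) {
  stopifnot(inherits(ds, "recall_dataset"))
  if (any(is.na(ds$participants$weight_kg))) {
    abort("participant body weight missing", class = "dietshift_data_error")
  }
  meals <- meal_summaries(ds, foods, ref)
  daily <- meals %>%
    group_by(.data$pid, .data$day_index) %>%
    summarise(
      total_g = sum(.data$total_g),
      digestible_g = sum(.data$digestible_g),
      utilizable_g = sum(.data$utilizable_g),
      kcal = sum(.data$kcal),
      plant_g = sum(.data$plant_g),
      .groups = "drop"
    ) %>%
    inner_join(select(ds$participants, "pid", "sex", "weight_kg",
                      "survey_weight"),
               by = "pid") %>%
    mutate(
      total_g_per_kg = .data$total_g / .data$weight_kg,
      digestible_g_per_kg = .data$digestible_g / .data$weight_kg,
      utilizable_g_per_kg = .data$utilizable_g / .data$weight_kg
    )
  daily
}

#' Plant-based share of total protein, per sex
#'
#' Protein-mass-weighted plant fraction over all consumption events:
#' `sum(event_total_g * plant_fraction) / sum(event_total_g)`, stratified
#' by sex.
#'
#' @param ds A `recall_dataset`.
#' @param foods Food table.
#' @return Tibble `sex, plant_share` (fraction in \[0, 1\]).
#' @export
plant_protein_share <- function(ds, foods) {
  stopifnot(inherits(ds, "recall_dataset"))
  event_protein(ds$events, foods) %>%
    inner_join(select(ds$participants, "pid", "sex"), by = "pid") %>%
    group_by(.data$sex) %>%
    summarise(plant_share = sum(.data$plant_g) / sum(.data$total_g),
              .groups = "drop")
}
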