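# Food composition tables: ingestion, validation, replacement tables.
#
# A food table is a tibble with one row per food item:
#   item_id, name, group, kcal_per_100g, digestibility, plant_fraction,
#   total_aa_mg, his..val (mg IAA per 100 g edible portion),
#   conform_pescetarian, conform_vegetarian, conform_vegan
#     (each "conforming" or "non_conforming").
# Protein mass is the amino-acid mass (total_aa_mg), not nitrogen x 6.25:
# the nitrogen factor overestimates protein for most food groups.

#' Supported dietary scenario identifiers
#'
#' @return Character vector of the six scenarios, from least to most
#'   plant-based: `original`, `flexitarian40`, `flexitarian80`,
#'   `pescetarian`, `vegetarian`, `vegan`.
#' @export
scenario_ids <- function() {
  c("original", "flexitarian40", "flexitarian80",
    "pescetarian", "vegetarian", "vegan")
}

conformity_keys <- function() {
  c("conform_pescetarian", "conform_vegetarian", "conform_vegan")
}

food_table_cols <- function() {
  c("item_id", "name", "group", "kcal_per_100g", "digestibility",
    "plant_fraction", "total_aa_mg", iaa_cols(), conformity_keys())
}

#' Load and validate a food composition table
#'
#' Reads a CSV with one row per food item and validates it: strictly
#' positive digestibility not exceeding 1, plant fraction in \[0, 1\],
#' non-negative amino acid content whose IAA sum does not exceed the total
#' amino acid mass, and conformity flags in
#' `{conforming, non_conforming}` for every supported scenario.
#' Rows with missing amino-acid data are admitted (to be repaired with
#' [resolve_missing_profiles()]), but rows violating range invariants abort.
#'
#' @param path CSV file with columns `item_id, name, group, kcal_per_100g,
#'   digestibility, plant_fraction, total_aa_mg, his, ile, leu, lys, saa,
#'   aaa, thr, trp, val, conform_pescetarian, conform_vegetarian,
#'   conform_vegan`.
#' @param schema Optional named character vector mapping the canonical
#'   column names above to the names actually used in the file.
#' @param groups Optional character vector restricting the food-group
#'   vocabulary; groups outside it are a validation error.
#' @return A tibble of validated food items, in file order, with a message
#'   reporting the number loaded.
#' @export
load_food_table <- function(path, schema = NULL, groups = NULL) {
  if (!file.exists(path)) {
    abort(paste0("food table file not found: ", path),
          class = "dietshift_schema_error")
  }
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    tb <- rename(tb, !!!setNames(unname(schema), names(schema)))
  }
  missing <- setdiff(food_table_cols(), names(tb))
  if (length(missing) > 0) {
    abort(paste0("food table is missing required column(s): ",
                 paste(missing, collapse = ", ")),
          class = "dietshift_schema_error")
  }
  tb <- select(tb, all_of(food_table_cols()))
  validate_food_table(tb, groups = groups)
  message(sprintf("loaded %d food items from %s", nrow(tb), basename(path)))
  tb
}

#' Validate a food composition table
#'
#' @param foods A food table tibble (see [load_food_table()]).
#' @param groups Optional allowed food-group vocabulary.
#' @param require_complete If `TRUE`, rows with missing amino-acid profiles
#'   are an error rather than being tolerated.
#' @return `foods`, invisibly, if valid; otherwise aborts with a
#'   validation error naming the offending `item_id`s.
#' @export
validate_food_table <- function(foods, groups = NULL, require_complete = FALSE) {
  stopifnot(is.data.frame(foods))
  fail <- function(msg, ids) {
    abort(paste0(msg, ": ", paste(ids, collapse = ", ")),
          class = "dietshift_validation_error")
  }
  if (anyDuplicated(foods$item_id)) {
    fail("duplicated item_id", unique(foods$item_id[duplicated(foods$item_id)]))
  }
  bad <- foods$item_id[is.na(foods$digestibility) |
                         foods$digestibility <= 0 | foods$digestibility > 1]
  if (length(bad) > 0) fail("digestibility must lie in (0, 1]", bad)
  bad <- foods$item_id[is.na(foods$plant_fraction) |
                         foods$plant_fraction < 0 | foods$plant_fraction > 1]
  if (length(bad) > 0) fail("plant_fraction must lie in [0, 1]", bad)
  if (!is.null(groups)) {
    bad <- foods$item_id[!foods$group %in% groups]
    if (length(bad) > 0) fail("food group outside configured vocabulary", bad)
  }
  for (key in conformity_keys()) {
    bad <- foods$item_id[!foods[[key]] %in% c("conforming", "non_conforming")]
    if (length(bad) > 0) {
      fail(paste0(key, " must be 'conforming' or 'non_conforming'"), bad)
    }
  }
  aa <- as.matrix(foods[, c("total_aa_mg", iaa_cols())])
  complete <- stats::complete.cases(aa)
  if (require_complete && any(!complete)) {
    fail("incomplete amino acid profile", foods$item_id[!complete])
  }
  aa_ok <- aa[complete, , drop = FALSE]
  ids_ok <- foods$item_id[complete]
  bad <- ids_ok[apply(aa_ok < 0, 1, any)]
  if (length(bad) > 0) fail("negative amino acid content", bad)
  iaa_sum <- rowSums(aa_ok[, iaa_cols(), drop = FALSE])
  # small numeric slack: the IAA sum may equal the total
  bad <- ids_ok[iaa_sum > aa_ok[, "total_aa_mg"] * (1 + 1e-9)]
  if (length(bad) > 0) fail("IAA sum exceeds total amino acid mass", bad)
  invisible(foods)
}

#' Write a food table to CSV
#'
#' Inverse of [load_food_table()]; `load_food_table(write_food_table(x, f))`
#' round-trips field-for-field.
#'
#' @param foods Food table tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(foods, path) {
  readr::write_csv(select(foods, all_of(food_table_cols())), path)
  invisible(path)
}

#' Fill in missing amino acid profiles from donor items
#'
#' Food items lacking amino-acid information inherit the full profile
#' (all IAA values, `total_aa_mg`) and digestibility of a mapped donor
#' item, mirroring the practice of substituting comparable products for
#' the handful of items absent from an amino-acid database. Items with
#' complete profiles are untouched; the operation is idempotent.
#'
#' @param items Food table tibble, possibly with `NA` amino-acid columns.
#' @param mapping Named character vector: `names()` are item_ids lacking a
#'   profile, values are donor item_ids with complete profiles.
#' @return The repaired food table; the substitutions performed are
#'   attached as a tibble in `attr(, "resolutions")`.
#' @export
resolve_missing_profiles <- function(items, mapping = character()) {
  aa_cols <- c("total_aa_mg", iaa_cols())
  incomplete <- !stats::complete.cases(items[, aa_cols])
  need <- items$item_id[incomplete]
  uncovered <- setdiff(need, names(mapping))
  if (length(uncovered) > 0) {
    abort(paste0("item(s) lack an amino acid profile and are not covered ",
                 "by the donor mapping: ", paste(uncovered, collapse = ", ")),
          class = "dietshift_unresolved_item_error")
  }
  resolutions <- tibble(item_id = character(), donor_id = character())
  for (id in need) {
    donor_id <- unname(mapping[[id]])
    donor <- items[items$item_id == donor_id, ]
    if (nrow(donor) != 1 ||
        !stats::complete.cases(donor[, aa_cols])) {
      abort(paste0("donor item '", donor_id, "' for '", id,
                   "' is absent or itself incomplete"),
            class = "dietshift_unresolved_item_error")
    }
    items[items$item_id == id, c(aa_cols, "digestibility")] <-
      donor[, c(aa_cols, "digestibility")]
    resolutions <- bind_rows(resolutions,
                             tibble(item_id = id, donor_id = donor_id))
  }
  validate_food_table(items, require_complete = TRUE)
  attr(items, "resolutions") <- resolutions
  items
}

#' Load a scenario replacement table
#'
#' Reads the long CSV `scenario, group, rank, item_id` listing, per food
#' group, the ranked alternatives a dietitian selected for that scenario
#' (at most 12 per group). Every alternative must exist in the food table
#' and be conforming under the table's scenario.
#'
#' @param path CSV path.
#' @param scenario One of `"pescetarian"`, `"vegetarian"`, `"vegan"` (the
#'   scenarios with conformity criteria; flexitarian diets reuse the
#'   vegetarian alternatives).
#' @param items Validated food table the alternatives must resolve against.
#' @return A tibble `scenario, group, rank, item_id` ordered by group and
#'   rank.
#' @export
load_replacement_table <- function(path, scenario, items) {
  if (!file.exists(path)) {
    abort(paste0("replacement table file not found: ", path),
          class = "dietshift_schema_error")
  }
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c("scenario", "group", "rank", "item_id"), names(tb))
  if (length(missing) > 0) {
    abort(paste0("replacement table is missing column(s): ",
                 paste(missing, collapse = ", ")),
          class = "dietshift_schema_error")
  }
  tb <- tb %>%
    filter(.data$scenario == !!scenario) %>%
    arrange(.data$group, .data$rank)
  validate_replacement_table(tb, scenario, items)
}

#' Validate a replacement table against a food table
#'
#' @inheritParams load_replacement_table
#' @param tb Tibble `scenario, group, rank, item_id`.
#' @return `tb`, if valid.
#' @export
validate_replacement_table <- function(tb, scenario, items) {
  key <- paste0("conform_", scenario)
  if (!key %in% conformity_keys()) {
    abort(paste0("no conformity criteria exist for scenario '", scenario, "'"),
          class = "dietshift_validation_error")
  }
  unknown <- setdiff(tb$item_id, items$item_id)
  if (length(unknown) > 0) {
    abort(paste0("replacement table references unknown item(s): ",
                 paste(unknown, collapse = ", ")),
          class = "dietshift_validation_error")
  }
  flags <- items[[key]][match(tb$item_id, items$item_id)]
  bad <- tb$item_id[flags != "conforming"]
  if (length(bad) > 0) {
    abort(paste0("alternative(s) not conforming under ", scenario, ": ",
                 paste(unique(bad), collapse = ", ")),
          class = "dietshift_validation_error")
  }
  sizes <- count(tb, .data$group)
  over <- sizes$group[sizes$n > 12]
  if (length(over) > 0) {
    abort(paste0("more than 12 alternatives listed for group(s): ",
                 paste(over, collapse = ", ")),
          class = "dietshift_validation_error")
  }
  tb
}
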