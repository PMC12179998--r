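# Scenario engine: rule-based classification of consumption events and
# seeded, gram-for-gram random replacement with dietitian-chosen
# alternatives.

#' Scenario specification
#'
#' Defines one of the six supported dietary scenarios. `original` performs
#' no replacement. The flexitarian scenarios replace a random 40% or 80% of
#' meat-and-fish consumption events and draw their alternatives from the
#' vegetarian replacement table; conformity of an event under a flexitarian
#' scenario is therefore governed by the vegetarian flag.
#'
#' @param scenario_id One of `"original"`, `"flexitarian40"`,
#'   `"flexitarian80"`, `"pescetarian"`, `"vegetarian"`, `"vegan"`.
#' @return A `scenario_spec`: list with `scenario_id`, `replace_fraction`,
#'   `conformity_key` (`NA` for `original`), and `replacement_source` (the
#'   scenario whose replacement table supplies the alternatives).
#' @export
scenario_spec <- function(scenario_id = scenario_ids()) {
  scenario_id <- match.arg(scenario_id)
  spec <- switch(
    scenario_id,
    original      = list(replace_fraction = 1.0, conformity_key = NA_character_,
                         replacement_source = NA_character_),
    flexitarian40 = list(replace_fraction = 0.4,
                         conformity_key = "conform_vegetarian",
                         replacement_source = "vegetarian"),
    flexitarian80 = list(replace_fraction = 0.8,
                         conformity_key = "conform_vegetarian",
                         replacement_source = "vegetarian"),
    pescetarian   = list(replace_fraction = 1.0,
                         conformity_key = "conform_pescetarian",
                         replacement_source = "vegetarian"),
    vegetarian    = list(replace_fraction = 1.0,
                         conformity_key = "conform_vegetarian",
                         replacement_source = "vegetarian"),
    vegan         = list(replace_fraction = 1.0,
                         conformity_key = "conform_vegan",
                         replacement_source = "vegan")
  )
  structure(c(list(scenario_id = scenario_id), spec), class = "scenario_spec")
}

is_flexitarian <- function(spec) spec$replace_fraction < 1

#' Classify food items under a scenario
#'
#' Pure lookup of the scenario's conformity flag; under the `original`
#' scenario every item is conforming.
#'
#' @param items Food table rows (one or more items).
#' @param spec A `scenario_spec`.
#' @return Character vector, `"conforming"` or `"non_conforming"`, one per
#'   item.
#' @export
classify_event <- function(items, spec) {
  if (spec$scenario_id == "original") {
    return(rep("conforming", nrow(items)))
  }
  flags <- items[[spec$conformity_key]]
  if (is.null(flags) || any(is.na(flags))) {
    abort(paste0("item(s) lack the ", spec$conformity_key, " flag"),
          class = "dietshift_data_error")
  }
  flags
}

# deterministic event ordering used before any RNG consumption
ordered_events <- function(events) {
  arrange(events, .data$pid, .data$day_index,
          match(.data$occasion, occasion_levels()), .data$event_id)
}

round_half_up <- function(x) floor(x + 0.5)

#' Randomly select meat-and-fish events for flexitarian replacement
#'
#' Samples uniformly, without replacement, from all meat-and-fish
#' consumption events pooled across the dataset (events whose item is
#' non-conforming under the vegetarian criteria). The sample size is
#' `round(fraction * n_eligible)` with half-up rounding. Deterministic
#' given `seed`.
#'
#' @param ds A `recall_dataset`.
#' @param foods Food table.
#' @param fraction Fraction of eligible events to select, in \[0, 1\].
#' @param seed Integer seed.
#' @return Character vector of selected `event_id`s.
#' @export
select_flexitarian_events <- function(ds, foods, fraction, seed) {
  stopifnot(fraction >= 0, fraction <= 1)
  events <- ordered_events(ds$events)
  flags <- foods$conform_vegetarian[match(events$item_id, foods$item_id)]
  eligible <- events$event_id[flags == "non_conforming"]
  k <- round_half_up(fraction * length(eligible))
  if (k == 0) return(character(0))
  withr::with_seed(seed, sample(eligible, k))
}

#' Apply a dietary scenario to a recall dataset
#'
#' Replaces each targeted consumption event's food with an alternative
#' drawn uniformly at random from its food group's list in the replacement
#' table, gram-for-gram (consumed grams are never altered). Under full
#' scenarios (`replace_fraction = 1`) every non-conforming event is
#' targeted; under flexitarian scenarios only the randomly pre-selected
#' subset of meat-and-fish events is. Draws are independent per event, so
#' the same product consumed twice may map to different alternatives. The
#' input dataset is not mutated.
#'
#' A single seeded generator drives the whole call: the flexitarian event
#' selection consumes the stream first, then one uniform draw per targeted
#' event in dataset order (pid, day, occasion, event id).
#'
#' @param ds A `recall_dataset`.
#' @param foods Food table.
#' @param repl Replacement table (`scenario, group, rank, item_id`) for the
#'   spec's `replacement_source` scenario.
#' @param spec A `scenario_spec`.
#' @param seed Integer seed.
#' @return List with `dataset` (the transformed `recall_dataset`) and
#'   `log`, a tibble of replacement records `(pid, day_index, occasion,
#'   event_id, old_item, new_item, grams)`.
#' @export
apply_scenario <- function(ds, foods, repl = NULL, spec, seed) {
  stopifnot(inherits(ds, "recall_dataset"), inherits(spec, "scenario_spec"))
  empty_log <- tibble(pid = character(), day_index = integer(),
                      occasion = character(), event_id = character(),
                      old_item = character(), new_item = character(),
                      grams = double())
  if (spec$scenario_id == "original" || nrow(ds$events) == 0) {
    return(list(dataset = ds, log = empty_log))
  }
  events <- ordered_events(ds$events)
  items <- foods[match(events$item_id, foods$item_id), ]
  flags <- classify_event(items, spec)

  withr::with_seed(seed, {
    if (is_flexitarian(spec)) {
      eligible <- events$event_id[flags == "non_conforming"]
      k <- round_half_up(spec$replace_fraction * length(eligible))
      selected <- if (k > 0) sample(eligible, k) else character(0)
      target <- events$event_id %in% selected
    } else {
      target <- flags == "non_conforming"
    }
    if (!any(target)) {
      out <- list(dataset = ds, log = empty_log)
    } else {
      groups <- items$group[target]
      alt_list <- split(repl$item_id, repl$group)
      uncovered <- setdiff(unique(groups), names(alt_list))
      if (length(uncovered) > 0) {
        abort(paste0("no replacement alternatives for non-conforming ",
                     "group(s): ", paste(uncovered, collapse = ", ")),
              class = "dietshift_coverage_error")
      }
      k_alt <- lengths(alt_list)[groups]
      # one uniform draw per targeted event, in dataset order
      draw <- floor(runif(length(groups)) * k_alt) + 1
      new_items <- purrr::map2_chr(groups, draw, function(g, i) alt_list[[g]][[i]])
      log <- tibble(
        pid = events$pid[target],
        day_index = events$day_index[target],
        occasion = events$occasion[target],
        event_id = events$event_id[target],
        old_item = events$item_id[target],
        new_item = new_items,
        grams = events$grams[target]
      )
      new_events <- ds$events
      idx <- match(log$event_id, new_events$event_id)
      new_events$item_id[idx] <- log$new_item
      out <- list(
        dataset = recall_dataset(ds$participants, new_events,
                                 provenance = paste0(ds$provenance, " | ",
                                                     spec$scenario_id),
                                 foods = foods),
        log = log
      )
    }
  })
  out
}

#' Count food replacements per sex
#'
#' @param log Replacement log from [apply_scenario()].
#' @param participants Participants tibble (for the sex of each `pid`).
#' @return Tibble `sex, n_replacements` covering both sexes; the counts sum
#'   to `nrow(log)`.
#' @export
replacement_counts <- function(log, participants) {
  sexes <- tibble(sex = c("male", "female"))
  if (nrow(log) == 0) {
    return(mutate(sexes, n_replacements = 0L))
  }
  log %>%
    inner_join(select(participants, "pid", "sex"), by = "pid") %>%
    count(.data$sex, name = "n_replacements") %>%
    right_join(sexes, by = "sex") %>%
    mutate(n_replacements = dplyr::coalesce(.data$n_replacements, 0L)) %>%
    select("sex", "n_replacements")
}
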