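# Synthetic survey generator: food tables, replacement tables and recall
# datasets with the statistical structure of a national food consumption
# survey of community-dwelling adults aged 65-79 (two non-consecutive 24-h
# recalls per participant, 7 meal occasions per day, ~62% animal protein,
# median habitual intake ~0.95 g/kg bw/day).
#
# Daily protein is generated on the log scale (person effect + day noise),
# allocated to occasions by fixed protein shares, and realised as grams of
# archetype foods; amounts are derived from protein targets, so realised
# intake and the animal-protein share are calibrated by construction.

#' Configuration for the synthetic survey generator
#'
#' Defaults are calibrated to the study conditions the package emulates:
#' ~51% men, ages 65-79, ~62% of protein animal-based, per-sex median
#' habitual protein intake of 0.96 (men) / 0.94 (women) g/kg bw/day,
#' dinner carrying the largest protein share, and between-/within-person
#' coefficients of variation of daily protein of 0.22 / 0.30.
#'
#' @param n_participants Number of participants.
#' @param seed Integer seed; every generator draw is derived from it.
#' @param sex_ratio Fraction of participants that are male.
#' @param age_range Inclusive age interval (years).
#' @param weight_mean,weight_sd Named per-sex (`male`, `female`) body-weight
#'   normal parameters, kg.
#' @param height_mean,height_sd Named per-sex height normal parameters, cm.
#' @param target_animal_protein_share Fraction of total protein mass from
#'   animal sources the generated diets are calibrated to.
#' @param target_intake_g_per_kg Named per-sex median habitual protein
#'   intake, g/kg bw/day.
#' @param occasion_protein_shares Named fractions over the 7 meal occasions
#'   (must sum to 1).
#' @param between_person_cv,within_person_cv Coefficients of variation of
#'   daily protein intake between persons and within person across days.
#' @param fish_share Probability that a dinner's meat-or-fish item is fish.
#' @param composition_jitter SD of the log-normal day-to-day jitter on the
#'   within-occasion category protein fractions (meals differ from day to
#'   day around the calibrated composition; 0 disables).
#' @param weight_variation SD of log survey weights; 0 (default) makes the
#'   synthetic population self-representative (all weights 1).
#' @param education_probs Named per-sex list of `(low, middle, high)`
#'   probabilities.
#' @return A `generator_config` list.
#' @export
generator_config <- function(
    n_participants = 600,
    seed = 1L,
    sex_ratio = 0.51,
    age_range = c(65L, 79L),
    weight_mean = c(male = 86, female = 72),
    weight_sd = c(male = 12, female = 11),
    height_mean = c(male = 177, female = 163),
    height_sd = c(male = 7, female = 6.5),
    target_animal_protein_share = 0.62,
    target_intake_g_per_kg = c(male = 0.96, female = 0.94),
    occasion_protein_shares = c(breakfast = 0.16, lunch = 0.22, dinner = 0.40,
                                snack1 = 0.07, snack2 = 0.07, snack3 = 0.05,
                                snack4 = 0.03),
    between_person_cv = 0.22,
    within_person_cv = 0.30,
    fish_share = 0.25,
    composition_jitter = 0.25,
    weight_variation = 0,
    education_probs = list(male = c(low = 0.31, middle = 0.29, high = 0.40),
                           female = c(low = 0.45, middle = 0.28, high = 0.27))) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$occasion_protein_shares) - 1) > 1e-8) {
    abort("occasion_protein_shares must sum to 1",
          class = "dietshift_config_error")
  }
  if (any(names(cfg$occasion_protein_shares) != occasion_levels())) {
    abort("occasion_protein_shares must be named by the 7 occasions",
          class = "dietshift_config_error")
  }
  if (cfg$between_person_cv <= 0 || cfg$within_person_cv < 0) {
    abort("between_person_cv must be > 0 and within_person_cv >= 0",
          class = "dietshift_config_error")
  }
  fracs <- c(cfg$sex_ratio, cfg$target_animal_protein_share, cfg$fish_share)
  if (any(fracs < 0 | fracs > 1)) {
    abort("fractions must lie in [0, 1]", class = "dietshift_config_error")
  }
  structure(cfg, class = "generator_config")
}

# Archetype food items. IAA densities are mg per g protein and are turned
# into per-100 g contents via the protein content; the cereal archetype is
# deliberately lysine-poor (bread-like), legumes lysine-rich but
# SAA-limited, meat/dairy complete.
synthetic_iaa_densities <- function() {
  tibble::tribble(
    ~archetype, ~his, ~ile, ~leu, ~lys, ~saa, ~aaa, ~thr, ~trp, ~val,
    "meat",      32,  47,   80,   88,   38,   76,   44,   12,   50,
    "fish",      29,  46,   81,   91,   40,   75,   44,   11,   52,
    "dairy",     27,  49,   95,   78,   33,   93,   44,   14,   63,
    "cheese",    30,  50,   92,   75,   30,  100,   36,   13,   66,
    "egg",       24,  53,   86,   72,   52,   93,   47,   13,   61,
    "cereal",    22,  36,   68,   26,   39,   77,   29,   11,   44,
    "rice",      24,  40,   79,   36,   42,   86,   34,   12,   55,
    "potato",    19,  36,   60,   52,   30,   76,   36,   10,   50,
    "legume",    26,  42,   76,   64,   21,   84,   37,    9,   45,
    "soy",       26,  46,   78,   62,   26,   88,   38,   13,   47,
    "nut",       25,  34,   65,   36,   25,   90,   29,   10,   42,
    "vegetable", 21,  39,   62,   50,   25,   67,   39,   12,   48
  )
}

synthetic_items <- function() {
  tibble::tribble(
    ~item_id, ~name, ~group, ~archetype, ~protein_g, ~kcal_per_100g,
    ~digestibility, ~plant_fraction,
    "beef_steak",    "beef steak",          "meat_or_fish",   "meat",   26.0, 190, 0.93, 0,
    "chicken_breast","chicken breast",      "meat_or_fish",   "meat",   27.0, 150, 0.94, 0,
    "pork_chop",     "pork chop",           "meat_or_fish",   "meat",   24.0, 230, 0.93, 0,
    "salmon_fillet", "salmon fillet",       "meat_or_fish",   "fish",   25.0, 200, 0.94, 0,
    "white_fish",    "white fish fillet",   "meat_or_fish",   "fish",   22.0, 110, 0.94, 0,
    "cold_cuts",     "meat cold cuts",      "meat_or_fish",   "meat",   20.0, 250, 0.92, 0,
    "milk_semi",     "semi-skimmed milk",   "dairy_drink",    "dairy",   3.5,  47, 0.95, 0,
    "yogurt_plain",  "plain yogurt",        "dairy_dessert",  "dairy",   4.0,  60, 0.95, 0,
    "custard",       "custard dessert",     "dairy_dessert",  "dairy",   3.3,  95, 0.95, 0,
    "gouda_cheese",  "gouda cheese 48+",    "cheese",         "cheese", 24.9, 356, 0.95, 0,
    "aged_cheese",   "aged cheese",         "cheese",         "cheese", 28.0, 375, 0.95, 0,
    "chicken_egg",   "chicken egg",         "egg",            "egg",    12.3, 128, 0.95, 0,
    "bread_whole",   "wholemeal bread",     "bread",          "cereal", 10.5, 235, 0.85, 1,
    "bread_roll",    "white roll",          "bread",          "cereal",  9.7, 262, 0.86, 1,
    "rice_boiled",   "boiled rice",         "cereal_side",    "rice",    2.8, 130, 0.86, 1,
    "potato_boiled", "boiled potatoes",     "cereal_side",    "potato",  2.0,  90, 0.84, 1,
    "pasta_cooked",  "cooked pasta",        "cereal_side",    "cereal",  5.5, 160, 0.86, 1,
    "veg_mixed",     "mixed vegetables",    "vegetable",      "vegetable", 2.5, 30, 0.80, 1,
    "lentils",       "boiled lentils",      "legume",         "legume", 21.0, 306, 0.80, 1,
    "chickpeas",     "boiled chickpeas",    "legume",         "legume",  8.0, 130, 0.80, 1,
    "veg_burger",    "vegetarian burger",   "meat_replacer",  "soy",    15.0, 220, 0.86, 1,
    "veg_schnitzel", "vegetarian schnitzel","meat_replacer",  "soy",    15.2, 226, 0.86, 1,
    "pb_burger",     "plant-based burger",  "meat_replacer",  "soy",    17.0, 252, 0.86, 1,
    "tofu",          "tofu (soy curd)",     "meat_replacer",  "soy",    11.6, 113, 0.88, 1,
    "vegan_chicken", "vegan chicken pieces","meat_replacer",  "soy",    15.0, 166, 0.86, 1,
    "falafel",       "falafel",             "meat_replacer",  "legume",  6.8, 208, 0.80, 1,
    "vegan_luncheon","vegan luncheon meat", "meat_replacer",  "soy",     8.2, 156, 0.86, 1,
    "vegan_bacon",   "vegan bacon strips",  "meat_replacer",  "soy",     5.0, 170, 0.86, 1,
    "vegan_cheese",  "vegan cheese slices", "cheese_replacer","soy",     8.3, 270, 0.86, 1,
    "soy_drink",     "soy drink",           "dairy_replacer", "soy",     3.0,  39, 0.88, 1,
    "soy_yogurt",    "soy yogurt",          "dairy_replacer", "soy",     4.0,  47, 0.88, 1,
    "soy_dessert",   "soy dessert",         "dairy_replacer", "soy",     3.1,  85, 0.88, 1,
    "tea",           "tea",                 "beverage",       "vegetable", 0.0,  0, 1.00, 1,
    "coffee",        "coffee",              "beverage",       "vegetable", 0.0,  0, 1.00, 1,
    "peanut_butter", "peanut butter",       "spread",         "nut",    20.0, 651, 0.85, 1,
    "hummus",        "hummus",              "spread",         "legume",  7.7, 322, 0.82, 1,
    "biscuit",       "biscuit",             "bakery",         "cereal",  6.0, 450, 0.88, 0.92,
    "currant_bread", "currant bread",       "bakery",         "cereal",  7.8, 273, 0.86, 0.92,
    "mixed_nuts",    "mixed nuts",          "nuts",           "nut",    25.0, 600, 0.85, 1
  )
}

animal_groups <- function() {
  c("meat_or_fish", "dairy_drink", "dairy_dessert", "cheese", "egg")
}

#' Generate a synthetic food table and scenario replacement tables
#'
#' Builds an archetype-based food table (meat/fish with high digestibility
#' and complete IAA profiles, dairy/egg, lysine-poor cereals, lysine-rich
#' but SAA-limited legumes, soy-based processed alternatives) together with
#' vegetarian and vegan replacement tables that satisfy all composition
#' invariants. Bakery items with trace animal ingredients keep
#' `conform_vegan = "conforming"` (replacing them would have minimal
#' impact), which is why a vegan-scenario diet retains a plant-protein
#' share slightly below 100%.
#'
#' @param cfg A `generator_config`.
#' @return List with `foods` (food table tibble) and `replacements` (named
#'   list of replacement tables: `vegetarian`, `vegan`).
#' @export
generate_food_table <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  dens <- synthetic_iaa_densities()
  foods <- synthetic_items() %>%
    left_join(dens, by = "archetype") %>%
    mutate(
      total_aa_mg = .data$protein_g * 1000,
      across(all_of(iaa_cols()), ~ .x * .data$protein_g),
      conform_pescetarian = ifelse(
        .data$archetype == "meat" & .data$group == "meat_or_fish",
        "non_conforming", "conforming"),
      conform_vegetarian = ifelse(.data$group == "meat_or_fish",
                                  "non_conforming", "conforming"),
      conform_vegan = ifelse(.data$group %in% animal_groups(),
                             "non_conforming", "conforming")
    ) %>%
    select(all_of(food_table_cols()))
  validate_food_table(foods, require_complete = TRUE)

  repl <- bind_rows(
    tibble(scenario = "vegetarian", group = "meat_or_fish",
           item_id = c("chicken_egg", "gouda_cheese", "veg_burger",
                       "veg_schnitzel", "pb_burger", "vegan_chicken")),
    tibble(scenario = "vegan", group = "meat_or_fish",
           item_id = c("lentils", "veg_burger", "pb_burger", "tofu",
                       "vegan_chicken", "falafel", "vegan_luncheon",
                       "vegan_bacon")),
    tibble(scenario = "vegan", group = "dairy_drink",
           item_id = c("tea", "coffee", "soy_drink")),
    tibble(scenario = "vegan", group = "dairy_dessert",
           item_id = c("soy_yogurt", "soy_dessert")),
    tibble(scenario = "vegan", group = "cheese",
           item_id = c("peanut_butter", "hummus", "vegan_cheese")),
    tibble(scenario = "vegan", group = "egg",
           item_id = "tofu")
  ) %>%
    group_by(.data$scenario, .data$group) %>%
    mutate(rank = row_number()) %>%
    ungroup() %>%
    select("scenario", "group", "rank", "item_id")

  replacements <- list(
    vegetarian = validate_replacement_table(
      filter(repl, .data$scenario == "vegetarian"), "vegetarian", foods),
    vegan = validate_replacement_table(
      filter(repl, .data$scenario == "vegan"), "vegan", foods)
  )
  list(foods = foods, replacements = replacements)
}

# occasion composition: per occasion, protein fraction per category.
# pool = items drawn from uniformly; af = animal (1 - plant) fraction of
# the category's items, used for calibration.
occasion_composition <- function() {
  tibble::tribble(
    ~occasion,  ~category,      ~frac, ~pool,
    "breakfast", "bread",        0.68, list(c("bread_whole", "bread_roll")),
    "breakfast", "dairy",        0.32, list(c("milk_semi", "yogurt_plain")),
    "lunch",     "bread",        0.45, list(c("bread_whole", "bread_roll")),
    "lunch",     "cheese",       0.35, list(c("gouda_cheese", "aged_cheese")),
    "lunch",     "cold_cuts",    0.20, list("cold_cuts"),
    "dinner",    "meat_or_fish", 0.78, list(c("beef_steak", "chicken_breast", "pork_chop")),
    "dinner",    "side",         0.16, list(c("rice_boiled", "potato_boiled", "pasta_cooked")),
    "dinner",    "vegetable",    0.06, list("veg_mixed"),
    "snack1",    "dairy",        0.60, list(c("custard", "yogurt_plain")),
    "snack1",    "bakery",       0.40, list(c("biscuit", "currant_bread")),
    "snack2",    "dairy",        0.60, list(c("custard", "milk_semi")),
    "snack2",    "bakery",       0.40, list(c("biscuit", "currant_bread")),
    "snack3",    "nuts",         1.00, list("mixed_nuts"),
    "snack4",    "bakery",       1.00, list("biscuit")
  ) %>%
    mutate(pool = purrr::map(.data$pool, 1))
}

# Rescale animal-category protein fractions by a common multiplier so the
# overall animal-protein share hits the target; plant categories absorb the
# complement proportionally within each occasion.
calibrate_composition <- function(comp, foods, shares, target) {
  pf <- vapply(comp$pool, function(ids) {
    mean(foods$plant_fraction[match(ids, foods$item_id)])
  }, numeric(1))
  comp$animal_frac <- 1 - pf
  is_animal <- comp$animal_frac >= 0.999

  scaled <- function(m) {
    out <- comp
    for (occ in unique(out$occasion)) {
      i <- out$occasion == occ
      a <- is_animal & i
      p <- !is_animal & i
      a_tot <- sum(out$frac[a])
      if (a_tot == 0) next
      new_a <- min(m * a_tot, 0.95)
      out$frac[a] <- out$frac[a] * new_a / a_tot
      out$frac[p] <- out$frac[p] * (1 - new_a) / sum(out$frac[p])
    }
    out
  }
  realized <- function(m) {
    out <- scaled(m)
    sum(shares[out$occasion] * out$frac * out$animal_frac)
  }
  lo <- realized(0)
  hi <- realized(1e3)
  if (target < lo - 1e-9 || target > hi + 1e-9) {
    abort(sprintf(paste0("target animal protein share %.3f is infeasible ",
                         "for the configured foods (attainable range ",
                         "%.3f-%.3f)"), target, lo, hi),
          class = "dietshift_calibration_error")
  }
  m <- uniroot(function(m) realized(m) - target, c(0, 1e3),
               tol = 1e-10)$root
  scaled(m)
}

#' Generate a synthetic recall dataset
#'
#' Draws participants (sex, age, body weight, height, education, survey
#' weight), assigns each a habitual protein intake on the log scale
#' (between-person variation) and each recall day a multiplicative day
#' deviation (within-person variation), allocates the day's protein to the
#' 7 meal occasions by the configured shares, and realises each occasion as
#' grams of archetype foods whose mix is calibrated so the animal-protein
#' share matches the configured target. Deterministic given `cfg$seed`.
#'
#' @param cfg A `generator_config`.
#' @param foods Food table from [generate_food_table()] (regenerated from
#'   `cfg` when omitted).
#' @return A validated `recall_dataset` with `n_participants * 2` recall
#'   days.
#' @export
generate_recalls <- function(cfg = generator_config(), foods = NULL) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.null(foods)) foods <- generate_food_table(cfg)$foods
  comp <- calibrate_composition(occasion_composition(), foods,
                                cfg$occasion_protein_shares,
                                cfg$target_animal_protein_share)
  n <- cfg$n_participants
  withr::with_seed(cfg$seed, {
    sex <- ifelse(runif(n) < cfg$sex_ratio, "male", "female")
    participants <- tibble(
      pid = sprintf("p%04d", seq_len(n)),
      sex = sex,
      age_years = sample(seq(cfg$age_range[1], cfg$age_range[2]), n,
                         replace = TRUE),
      weight_kg = pmax(40, rnorm(n, cfg$weight_mean[sex], cfg$weight_sd[sex])),
      height_cm = rnorm(n, cfg$height_mean[sex], cfg$height_sd[sex]),
      education = vapply(sex, function(s) {
        sample(c("low", "middle", "high"), 1,
               prob = cfg$education_probs[[s]])
      }, character(1)),
      survey_weight = if (cfg$weight_variation > 0) {
        exp(rnorm(n, -cfg$weight_variation^2 / 2, cfg$weight_variation))
      } else {
        rep(1, n)
      }
    )
    sigma_b <- sqrt(log(1 + cfg$between_person_cv^2))
    sigma_w <- sqrt(log(1 + cfg$within_person_cv^2))
    person_log_gkg <- log(cfg$target_intake_g_per_kg[sex]) +
      rnorm(n, 0, sigma_b)

    days <- tidyr::expand_grid(i = seq_len(n), day_index = 1:2)
    day_gkg <- exp(person_log_gkg[days$i] +
                     rnorm(nrow(days), 0, sigma_w))
    day_protein <- day_gkg * participants$weight_kg[days$i]

    # one event per occasion-category per person-day
    ev <- tidyr::expand_grid(d = seq_len(nrow(days)),
                             c = seq_len(nrow(comp)))
    shares <- cfg$occasion_protein_shares
    occ <- comp$occasion[ev$c]
    # day-to-day variation in what a meal is made of: jitter the category
    # fractions, renormalised so each occasion keeps its protein share
    # (daily total protein is untouched)
    w <- comp$frac[ev$c] *
      exp(rnorm(nrow(ev), 0, cfg$composition_jitter))
    w <- w / stats::ave(w, paste(ev$d, occ), FUN = sum)
    target_protein <- day_protein[ev$d] * shares[occ] * w
    # item choice: uniform within the category pool; dinner meat-or-fish
    # switches to a fish pool with probability fish_share
    fish_pool <- c("salmon_fillet", "white_fish")
    pools <- comp$pool[ev$c]
    is_mf <- comp$category[ev$c] == "meat_or_fish"
    use_fish <- is_mf & (runif(nrow(ev)) < cfg$fish_share)
    pools[use_fish] <- list(fish_pool)
    pick <- floor(runif(nrow(ev)) * lengths(pools)) + 1
    item_id <- purrr::map2_chr(pools, pick, function(p, i) p[[i]])
    protein_per_g <- foods$total_aa_mg[match(item_id, foods$item_id)] / 1e5
    events <- tibble(
      pid = participants$pid[days$i[ev$d]],
      day_index = as.integer(days$day_index[ev$d]),
      occasion = occ,
      item_id = item_id,
      grams = target_protein / protein_per_g
    ) %>%
      arrange(.data$pid, .data$day_index,
              match(.data$occasion, occasion_levels()), .data$item_id) %>%
      mutate(event_id = sprintf("e%06d", row_number())) %>%
      select("pid", "day_index", "occasion", "event_id", "item_id", "grams")
  })
  recall_dataset(participants, events,
                 provenance = sprintf("synthetic survey (n=%d, seed=%d)",
                                      n, cfg$seed),
                 foods = foods)
}
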