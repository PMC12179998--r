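# Shared fixtures: a small hand-built food table, recall builders, and an
# independent brute-force re-implementation of the per-meal scoring used
# as the oracle in equivalence tests.

ref_default <- who_reference_pattern()

# hand-built five-item table spanning the scoring regimes:
#  - meat: complete profile, high digestibility, animal
#  - milk: complete, animal
#  - bread: lysine-poor cereal (ratio vs reference < 1)
#  - lentil: lysine-rich, SAA-limited legume
#  - biscuit: trace-animal bakery item, conforming under vegan
tiny_foods <- function() {
  dens <- list(
    meat   = c(his = 32, ile = 47, leu = 80, lys = 88, saa = 38, aaa = 76,
               thr = 44, trp = 12, val = 50),
    dairy  = c(his = 27, ile = 49, leu = 95, lys = 78, saa = 33, aaa = 93,
               thr = 44, trp = 14, val = 63),
    cereal = c(his = 22, ile = 36, leu = 68, lys = 26, saa = 39, aaa = 77,
               thr = 29, trp = 11, val = 44),
    legume = c(his = 26, ile = 42, leu = 76, lys = 64, saa = 21, aaa = 84,
               thr = 37, trp = 9, val = 45),
    soy    = c(his = 26, ile = 46, leu = 78, lys = 62, saa = 26, aaa = 88,
               thr = 38, trp = 13, val = 47)
  )
  base <- tibble::tribble(
    ~item_id, ~name, ~group, ~arch, ~protein_g, ~kcal_per_100g,
    ~digestibility, ~plant_fraction, ~conform_pescetarian,
    ~conform_vegetarian, ~conform_vegan,
    "meat",    "roast meat",  "meat_or_fish", "meat",   25, 200, 0.93, 0,
    "non_conforming", "non_conforming", "non_conforming",
    "milk",    "milk",        "dairy_drink",  "dairy",  3.5, 47, 0.95, 0,
    "conforming", "conforming", "non_conforming",
    "bread",   "bread",       "bread",        "cereal", 10, 240, 0.85, 1,
    "conforming", "conforming", "conforming",
    "lentil",  "lentils",     "legume",       "legume", 21, 306, 0.80, 1,
    "conforming", "conforming", "conforming",
    "biscuit", "biscuit",     "bakery",       "cereal",  6, 450, 0.88, 0.92,
    "conforming", "conforming", "conforming"
  )
  for (a in names(dens$meat)) {
    base[[a]] <- vapply(seq_len(nrow(base)), function(i) {
      dens[[base$arch[i]]][[a]] * base$protein_g[i]
    }, numeric(1))
  }
  base$total_aa_mg <- base$protein_g * 1000
  dplyr::select(base, dplyr::all_of(dietshift:::food_table_cols()))
}

tiny_participants <- function(n = 2, sex = rep(c("male", "female"),
                                               length.out = n)) {
  tibble::tibble(
    pid = sprintf("p%02d", seq_len(n)),
    sex = sex,
    age_years = 70L,
    weight_kg = 75,
    height_cm = 170,
    education = "middle",
    survey_weight = 1
  )
}

# one event per row: (pid, day, occasion, item, grams)
tiny_events <- function(...) {
  rows <- list(...)
  if (length(rows) == 0) {
    return(tibble::tibble(pid = character(), day_index = integer(),
                          occasion = character(), event_id = character(),
                          item_id = character(), grams = double()))
  }
  tb <- purrr::map_dfr(rows, function(r) {
    tibble::tibble(pid = r[[1]], day_index = as.integer(r[[2]]),
                   occasion = r[[3]], item_id = r[[4]],
                   grams = as.numeric(r[[5]]))
  })
  tb$event_id <- sprintf("e%03d", seq_len(nrow(tb)))
  dplyr::select(tb, "pid", "day_index", "occasion", "event_id",
                "item_id", "grams")
}

# Independent oracle: explicit loops over events and the nine IAA ratios.
# Kept deliberately naive; must not share code with the implementation.
oracle_meal <- function(meal, foods, ref = ref_default) {
  total <- 0
  dig <- 0
  iaa <- stats::setNames(numeric(length(iaa_names())), iaa_names())
  for (r in seq_len(nrow(meal))) {
    it <- foods[foods$item_id == meal$item_id[r], ]
    g <- meal$grams[r]
    total <- total + g / 100 * it$total_aa_mg / 1000
    dig <- dig + g / 100 * it$total_aa_mg / 1000 * it$digestibility
    for (a in iaa_names()) {
      iaa[[a]] <- iaa[[a]] + g / 100 * it[[tolower(a)]] * it$digestibility
    }
  }
  if (dig == 0) {
    sim <- 1
    lim <- NA_character_
  } else {
    ratios <- numeric(0)
    for (a in iaa_names()) {
      ratios[[a]] <- (iaa[[a]] / dig) / ref[[a]]
    }
    if (min(ratios) >= 1) {
      sim <- 1
      lim <- NA_character_
    } else {
      sim <- min(ratios)
      lim <- names(ratios)[which.min(ratios)]
    }
  }
  list(total_g = total, digestible_g = dig, similarity = sim,
       limiting_iaa = lim, utilizable_g = sim * dig)
}

# random <= 3-item meals over a food table, for equivalence sweeps
random_meal <- function(foods, max_items = 3) {
  n <- sample.int(max_items, 1)
  tibble::tibble(
    pid = "p01", day_index = 1L, occasion = "lunch",
    event_id = sprintf("e%03d", seq_len(n)),
    item_id = sample(foods$item_id, n, replace = TRUE),
    grams = round(runif(n, 5, 300), 1)
  )
}
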