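make_repl <- function(scenario, group, ids, foods) {
  validate_replacement_table(
    tibble::tibble(scenario = scenario, group = group,
                   rank = seq_along(ids), item_id = ids),
    scenario, foods)
}

test_that("classification is a pure conformity lookup", {
  foods <- tiny_foods()
  fishy <- foods[1, ]
  fishy$item_id <- "fish"
  fishy$conform_pescetarian <- "conforming"
  foods2 <- dplyr::bind_rows(foods, fishy)

  expect_equal(classify_event(foods2[foods2$item_id == "fish", ],
                              scenario_spec("pescetarian")), "conforming")
  expect_equal(classify_event(foods2[foods2$item_id == "milk", ],
                              scenario_spec("vegan")), "non_conforming")
  expect_equal(classify_event(foods2, scenario_spec("original")),
               rep("conforming", nrow(foods2)))
  broken <- foods
  broken$conform_vegan[1] <- NA
  expect_error(classify_event(broken[1, ], scenario_spec("vegan")),
               class = "dietshift_data_error")
})

test_that("flexitarian selection samples the exact rounded count", {
  foods <- tiny_foods()
  p <- tiny_participants(2)
  # 10 meat events, plus plant events that must never be selected
  rows <- c(
    lapply(1:5, function(i) list("p01", 1, "dinner", "meat", 50 + i)),
    lapply(1:5, function(i) list("p02", 1, "dinner", "meat", 50 + i)),
    list(list("p01", 2, "lunch", "bread", 80),
         list("p02", 2, "lunch", "lentil", 80))
  )
  ds <- recall_dataset(p, do.call(tiny_events, rows), foods = foods)

  expect_identical(select_flexitarian_events(ds, foods, 0, 1), character(0))
  all_ids <- select_flexitarian_events(ds, foods, 1, 1)
  expect_setequal(all_ids, sprintf("e%03d", 1:10))
  expect_length(select_flexitarian_events(ds, foods, 0.4, 1), 4)
  # half-up rounding of fraction * eligible
  expect_length(select_flexitarian_events(ds, foods, 0.45, 1), 5)
  # deterministic under a fixed seed
  expect_identical(select_flexitarian_events(ds, foods, 0.4, 99),
                   select_flexitarian_events(ds, foods, 0.4, 99))
})

test_that("selection frequency matches the hypergeometric inclusion rate", {
  foods <- tiny_foods()
  p <- tiny_participants(2)
  rows <- lapply(1:10, function(i) {
    list(if (i <= 5) "p01" else "p02", 1, "dinner", "meat", 100)
  })
  ds <- recall_dataset(p, do.call(tiny_events, rows), foods = foods)
  n_seeds <- 2000
  hits <- integer(10)
  for (s in seq_len(n_seeds)) {
    sel <- select_flexitarian_events(ds, foods, 0.4, s)
    hits <- hits + (sprintf("e%03d", 1:10) %in% sel)
  }
  freq <- hits / n_seeds
  se <- sqrt(0.4 * 0.6 / n_seeds)
  expect_true(all(abs(freq - 0.4) <= 3 * se))
})

test_that("scenario application replaces gram-for-gram with uniform draws", {
  foods <- tiny_foods()
  p <- tiny_participants(2)
  e <- tiny_events(
    list("p01", 1, "dinner", "meat", 150),
    list("p01", 1, "breakfast", "milk", 200),
    list("p02", 2, "lunch", "bread", 80)
  )
  ds <- recall_dataset(p, e, foods = foods)
  veg_repl <- make_repl("vegetarian", "meat_or_fish", "lentil", foods)

  # forced single alternative, identical grams, untouched events identical
  res <- apply_scenario(ds, foods, veg_repl, scenario_spec("vegetarian"), 5)
  expect_equal(res$log$old_item, "meat")
  expect_equal(res$log$new_item, "lentil")
  expect_equal(res$log$grams, 150)
  expect_identical(res$dataset$events$grams, ds$events$grams)
  expect_identical(res$dataset$events$item_id[-1], ds$events$item_id[-1])
  # input dataset is not mutated
  expect_equal(ds$events$item_id[1], "meat")

  # fixed point: vegan scenario on an all-conforming dataset
  plant <- recall_dataset(p, tiny_events(
    list("p01", 1, "lunch", "bread", 80),
    list("p02", 1, "lunch", "lentil", 90)), foods = foods)
  res2 <- apply_scenario(plant, foods, NULL, scenario_spec("vegan"), 5)
  expect_identical(res2$dataset$events, plant$events)
  expect_equal(nrow(res2$log), 0)

  # coverage error names the uncovered group
  vegan_repl <- make_repl("vegan", "meat_or_fish", "lentil", foods)
  expect_error(
    apply_scenario(ds, foods, vegan_repl, scenario_spec("vegan"), 5),
    "dairy_drink", class = "dietshift_coverage_error")
})

test_that("alternative choice is uniform over the group list", {
  foods <- dplyr::bind_rows(
    tiny_foods(),
    within(as.data.frame(tiny_foods()[4, ]), {
      item_id <- "chickpea"
    }),
    within(as.data.frame(tiny_foods()[4, ]), {
      item_id <- "tofu"
    })
  ) |> tibble::as_tibble()
  p <- tiny_participants(1)
  ds <- recall_dataset(p, tiny_events(list("p01", 1, "dinner", "meat", 100)),
                       foods = foods)
  repl <- make_repl("vegetarian", "meat_or_fish",
                    c("lentil", "chickpea", "tofu"), foods)
  n_seeds <- 3000
  picks <- character(n_seeds)
  for (s in seq_len(n_seeds)) {
    picks[s] <- apply_scenario(ds, foods, repl,
                               scenario_spec("vegetarian"), s)$log$new_item
  }
  freq <- table(factor(picks, levels = c("lentil", "chickpea", "tofu"))) /
    n_seeds
  se <- sqrt((1 / 3) * (2 / 3) / n_seeds)
  expect_true(all(abs(freq - 1 / 3) <= 3 * se))
})

test_that("replacement counts stratify by sex and conserve totals", {
  p <- tiny_participants(3, sex = c("male", "male", "female"))
  log <- tibble::tibble(
    pid = c("p01", "p02", "p03", "p01", "p02"),
    day_index = 1L, occasion = "dinner",
    event_id = sprintf("e%03d", 1:5),
    old_item = "meat", new_item = "lentil", grams = 100
  )
  counts <- replacement_counts(log, p)
  expect_equal(counts$n_replacements[counts$sex == "male"], 4L)
  expect_equal(counts$n_replacements[counts$sex == "female"], 1L)
  expect_equal(sum(counts$n_replacements), nrow(log))
  empty <- replacement_counts(log[0, ], p)
  expect_equal(empty$n_replacements, c(0L, 0L))
})

test_that("full scenarios leave no non-conforming events and conserve mass", {
  cfg <- generator_config(n_participants = 40, seed = 3)
  ft <- generate_food_table(cfg)
  ds <- generate_recalls(cfg, ft$foods)
  per_day <- function(d) {
    d$events |>
      dplyr::group_by(pid, day_index) |>
      dplyr::summarise(g = sum(grams), .groups = "drop")
  }
  base <- per_day(ds)
  for (sc in c("pescetarian", "vegetarian", "vegan")) {
    spec <- scenario_spec(sc)
    repl <- ft$replacements[[spec$replacement_source]]
    res <- apply_scenario(ds, ft$foods, repl, spec, 11)
    expect_equal(per_day(res$dataset), base) # gram-for-gram conservation
    flags <- classify_event(
      ft$foods[match(res$dataset$events$item_id, ft$foods$item_id), ], spec)
    expect_true(all(flags == "conforming"))
  }
})

test_that("replacement effort is ordered across scenarios", {
  cfg <- generator_config(n_participants = 40, seed = 9)
  ft <- generate_food_table(cfg)
  ds <- generate_recalls(cfg, ft$foods)
  n_repl <- vapply(
    c("flexitarian40", "flexitarian80", "pescetarian", "vegetarian", "vegan"),
    function(sc) {
      spec <- scenario_spec(sc)
      nrow(apply_scenario(ds, ft$foods,
                          ft$replacements[[spec$replacement_source]],
                          spec, 13)$log)
    }, numeric(1))
  expect_true(n_repl[["flexitarian40"]] <= n_repl[["flexitarian80"]])
  expect_true(n_repl[["flexitarian80"]] <= n_repl[["vegetarian"]])
  expect_true(n_repl[["pescetarian"]] <= n_repl[["vegetarian"]])
  expect_true(n_repl[["vegetarian"]] <= n_repl[["vegan"]])
})
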