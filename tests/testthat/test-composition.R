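test_that("food tables load, validate and round-trip", {
  foods <- tiny_foods()
  path <- withr::local_tempfile(fileext = ".csv")
  write_food_table(foods, path)

  suppressMessages(loaded <- load_food_table(path))
  expect_equal(as.data.frame(loaded), as.data.frame(foods))
  expect_equal(loaded$item_id, foods$item_id) # order preserved

  # a kcal/protein pairing as printed in replacement listings
  egg_like <- loaded[loaded$item_id == "meat", ]
  expect_equal(egg_like$kcal_per_100g, 200)
  expect_equal(egg_like$total_aa_mg / 1000, 25)

  # missing column -> schema error naming the column
  crippled <- dplyr::select(foods, -"digestibility")
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(crippled, path2)
  expect_error(suppressMessages(load_food_table(path2)),
               "digestibility", class = "dietshift_schema_error")

  # digestibility at the open boundary is rejected, with the item named
  bad <- foods
  bad$digestibility[2] <- 0
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(bad, path3)
  expect_error(suppressMessages(load_food_table(path3)), "milk",
               class = "dietshift_validation_error")

  # schema remapping of non-canonical headers
  renamed <- dplyr::rename(foods, energy = "kcal_per_100g")
  path4 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(renamed, path4)
  suppressMessages(
    re <- load_food_table(path4, schema = c(kcal_per_100g = "energy")))
  expect_equal(re$kcal_per_100g, foods$kcal_per_100g)
})

test_that("food table invariants catch bad amino acid data", {
  foods <- tiny_foods()
  foods$lys[1] <- -1
  expect_error(validate_food_table(foods), "negative",
               class = "dietshift_validation_error")

  foods <- tiny_foods()
  foods$total_aa_mg[1] <- 100 # IAA sum now exceeds the total
  expect_error(validate_food_table(foods), "exceeds",
               class = "dietshift_validation_error")

  foods <- tiny_foods()
  foods$plant_fraction[3] <- 1.2
  expect_error(validate_food_table(foods), "plant_fraction",
               class = "dietshift_validation_error")

  expect_error(validate_food_table(tiny_foods(), groups = "meat_or_fish"),
               class = "dietshift_validation_error")
})

test_that("missing profiles inherit donor profile and digestibility", {
  foods <- tiny_foods()
  aa <- c("total_aa_mg", dietshift:::iaa_cols())
  foods[foods$item_id == "biscuit", aa] <- NA_real_

  fixed <- resolve_missing_profiles(foods, c(biscuit = "bread"))
  donor <- foods[foods$item_id == "bread", ]
  got <- fixed[fixed$item_id == "biscuit", ]
  expect_equal(got[[aa[1]]], donor[[aa[1]]])
  expect_equal(got$lys, donor$lys)
  expect_equal(got$digestibility, donor$digestibility)
  expect_equal(nrow(attr(fixed, "resolutions")), 1L)
  # untouched items stay untouched
  expect_equal(fixed[fixed$item_id != "biscuit", ],
               foods[foods$item_id != "biscuit", ], ignore_attr = TRUE)

  # identity on complete tables, and idempotence
  complete <- tiny_foods()
  expect_equal(resolve_missing_profiles(complete, character()), complete,
               ignore_attr = TRUE)
  expect_equal(resolve_missing_profiles(fixed, c(biscuit = "bread")), fixed,
               ignore_attr = TRUE)
})

test_that("uncovered profile-less items are reported by id", {
  foods <- tiny_foods()
  aa <- c("total_aa_mg", dietshift:::iaa_cols())
  foods[foods$item_id %in% c("biscuit", "lentil"), aa] <- NA_real_
  # brute-force enumeration of what should be left uncovered:
  incomplete <- foods$item_id[!stats::complete.cases(foods[, aa])]
  mapping <- c(biscuit = "bread")
  uncovered <- setdiff(incomplete, names(mapping))
  expect_equal(uncovered, "lentil")
  expect_error(resolve_missing_profiles(foods, mapping), "lentil",
               class = "dietshift_unresolved_item_error")
})

test_that("replacement tables enforce conformity and the 12-item cap", {
  foods <- tiny_foods()
  path <- withr::local_tempfile(fileext = ".csv")

  # dairy conforms under vegetarian rules but not under vegan rules
  tb <- tibble::tibble(scenario = c("vegetarian", "vegan"),
                       group = "meat_or_fish", rank = 1L,
                       item_id = "milk")
  readr::write_csv(tb, path)
  veg <- load_replacement_table(path, "vegetarian", foods)
  expect_equal(veg$item_id, "milk")
  expect_error(load_replacement_table(path, "vegan", foods), "milk",
               class = "dietshift_validation_error")

  # 13 alternatives in one group exceed the cap
  big <- tibble::tibble(scenario = "vegetarian", group = "meat_or_fish",
                        rank = 1:13,
                        item_id = rep(c("bread", "lentil"), length.out = 13))
  readr::write_csv(big, path)
  expect_error(load_replacement_table(path, "vegetarian", foods), "12",
               class = "dietshift_validation_error")

  # unknown alternative ids are named
  ghost <- tibble::tibble(scenario = "vegan", group = "meat_or_fish",
                          rank = 1L, item_id = "tofuburger")
  readr::write_csv(ghost, path)
  expect_error(load_replacement_table(path, "vegan", foods), "tofuburger",
               class = "dietshift_validation_error")
})

test_that("reference patterns validate their nine keys", {
  ref <- who_reference_pattern()
  expect_named(as.vector(ref) |> setNames(names(ref)), iaa_names())
  expect_true(all(ref > 0))
  expect_equal(ref[["Lys"]], 45)

  shipped <- system.file("extdata", "who2007_adult_pattern.yaml",
                         package = "dietshift")
  expect_equal(as.numeric(load_reference_pattern(shipped)), as.numeric(ref))

  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("His: 15", "Ile: 30", "Leu: 59", "Lys: 45", "SAA: 22",
               "AAA: 38", "Thr: 23", "Trp: 6"), path) # Val missing
  expect_error(load_reference_pattern(path), "Val",
               class = "dietshift_config_error")

  writeLines(c("His: 15", "Ile: 30", "Leu: 59", "Lys: 0", "SAA: 22",
               "AAA: 38", "Thr: 23", "Trp: 6", "Val: 39"), path)
  expect_error(load_reference_pattern(path), "Lys",
               class = "dietshift_validation_error")
})
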