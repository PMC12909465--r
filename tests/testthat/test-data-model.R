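# Readers, writers and invariant checks of the shared table contracts.

test_that("consumption reader parses rows identically and rejects bad input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("person_id,day_index,food_id,amount_g",
               "p1,1,meat1,100.5", "p1,2,meat1,80", "p2,1,bread1,42.25"),
             path)
  rec <- read_consumption(path)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$amount_g, c(100.5, 80, 42.25))
  expect_equal(rec$person_id, c("p1", "p1", "p2"))

  writeLines("person_id,day_index,food_id,amount_g", path)
  expect_equal(nrow(read_consumption(path)), 0)

  writeLines(c("person_id,day_index,food_id,amount_g", "p1,1,meat1,-5"),
             path)
  expect_error(read_consumption(path), "amount_g")

  writeLines(c("person_id,day_index,amount_g", "p1,1,5"), path)
  expect_error(read_consumption(path), "food_id")
})

test_that("person table invariants are enforced", {
  p <- mini_persons(4)
  expect_silent(validate_persons(p))
  expect_error(validate_persons(dplyr::mutate(p, sex = "other")),
               "unknown sex")
  expect_error(validate_persons(dplyr::mutate(p, age = 17)), "age")
  expect_error(validate_persons(dplyr::mutate(p, weight_factor = 0)),
               "weight_factor")
  expect_error(
    validate_persons(dplyr::mutate(p, person_id = "dup")), "unique")
})

test_that("food table join checks protein split and id consistency", {
  food <- mini_food()
  dir <- withr::local_tempdir()
  comp <- file.path(dir, "comp.csv")
  foot <- file.path(dir, "foot.csv")
  grp <- file.path(dir, "grp.csv")
  readr::write_csv(
    dplyr::select(food, dplyr::all_of(c("food_id", "name",
                                        tracked_nutrients()))), comp)
  readr::write_csv(
    dplyr::select(food, dplyr::all_of(c("food_id",
                                        footprint_indicators()))), foot)
  readr::write_csv(
    dplyr::select(food, dplyr::all_of(c("food_id", "consumed_group",
                                        "group_category", "is_red_meat"))),
    grp)

  joined <- read_food_table(comp, foot, grp)
  expect_equal(nrow(joined), nrow(food))
  # plant fraction 1 means all protein is plant protein
  expect_equal(joined$plant_protein_g[joined$food_id == "ra1"], 10)
  expect_equal(joined$animal_protein_g[joined$food_id == "ra1"], 0)

  # protein split violation
  bad <- dplyr::mutate(food,
                       total_protein_g = .data$total_protein_g +
                         ifelse(.data$food_id == "meat1", 1, 0))
  readr::write_csv(
    dplyr::select(bad, dplyr::all_of(c("food_id", "name",
                                       tracked_nutrients()))), comp)
  expect_error(read_food_table(comp, foot, grp), "meat1")

  # mismatched id sets
  readr::write_csv(
    dplyr::select(food[-1, ], dplyr::all_of(c("food_id", "name",
                                              tracked_nutrients()))), comp)
  expect_error(read_food_table(comp, foot, grp), "differ")
})

test_that("mapping and EAR validation catch contract violations", {
  food <- mini_food()
  expect_silent(validate_mapping(mini_mapping(), food))
  expect_error(validate_mapping(
    tibble::tibble(consumed_group = "meat_a", food_id = "nope"), food),
    "unknown food_id")
  # a replacement with animal protein needs the mixed flag
  expect_error(validate_mapping(
    tibble::tibble(consumed_group = "meat_a", food_id = "dairy1"), food),
    "mixed")
  expect_silent(validate_mapping(
    tibble::tibble(consumed_group = "meat_a", food_id = "dairy1"), food,
    allow_mixed = "dairy1"))

  expect_error(validate_ear_table(
    tibble::tibble(nutrient = "energy_kcal", sex = "female",
                   ear_value = 1)), "unsupported")
  expect_error(validate_ear_table(
    tibble::tibble(nutrient = "calcium_mg", sex = "female",
                   ear_value = 0)), "ear_value")
})

test_that("records referencing unknown foods are rejected", {
  rec <- tibble::tibble(person_id = "p1", day_index = 1L,
                        food_id = "ghost", amount_g = 10)
  expect_error(validate_consumption(rec, mini_food()), "ghost")
})

test_that("survey bundle round-trips through CSV losslessly", {
  survey <- tiny_survey()
  dir <- withr::local_tempdir()
  write_survey(survey, dir)
  back <- read_survey(dir)
  expect_equal(back$persons, survey$persons, tolerance = 1e-12)
  expect_equal(back$records, survey$records, tolerance = 1e-12)
  expect_equal(
    dplyr::select(back$food, dplyr::all_of(names(back$food))),
    dplyr::select(survey$food, dplyr::all_of(names(back$food))),
    tolerance = 1e-12
  )
  expect_equal(back$mapping, survey$mapping)
  expect_equal(back$ear[c("nutrient", "sex", "ear_value")],
               survey$ear[c("nutrient", "sex", "ear_value")],
               tolerance = 1e-12)
})
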