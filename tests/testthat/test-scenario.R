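# Replacement engine: conservation laws, seeded allocation, enumeration
# oracle and allocation-stability replicates.

test_that("nutrient totals are linear, additive and complete over days", {
  food <- mini_food()
  rec <- tibble::tibble(person_id = c("p1", "p1", "p1"),
                        day_index = c(1L, 1L, 2L),
                        food_id = c("bread1", "bread1", "meat1"),
                        amount_g = c(200, 100, 50))
  tot <- nutrient_totals(rec, food)
  d1 <- tot[tot$day_index == 1, ]
  # 300 g of bread at 9 g protein / 100 g, two records summing additively
  expect_equal(d1$plant_protein_g, 27)
  expect_equal(d1$energy_kcal, 300 * 2.5)
  d2 <- tot[tot$day_index == 2, ]
  expect_equal(d2$animal_protein_g, 10)

  # a person-day with no record yields an all-zero row
  rec2 <- tibble::tibble(person_id = c("p1", "p2"), day_index = c(1L, 2L),
                         food_id = "bread1", amount_g = c(100, 100))
  tot2 <- nutrient_totals(rec2, food)
  expect_equal(nrow(tot2), 4)
  empty <- tot2[tot2$person_id == "p2" & tot2$day_index == 1, ]
  expect_true(all(as.matrix(empty[tracked_nutrients()]) == 0))
})

test_that("half replacement splits each targeted record in two", {
  food <- mini_food()
  rec <- tibble::tibble(person_id = "p1", day_index = 1L,
                        food_id = "meat1", amount_g = 100)
  spec <- scenario_spec("half_meat", "meat_a", 0.5, "quantity",
                        allocation_seed = 3)
  out <- apply_scenario(rec, food, mini_mapping(), spec)
  expect_equal(nrow(out$records), 2)
  expect_equal(out$records$amount_g[out$records$food_id == "meat1"], 50)
  repl <- out$records[out$records$food_id != "meat1", ]
  expect_equal(repl$amount_g, 50)
  expect_true(repl$food_id %in% c("ra1", "ra2", "ra3"))
  expect_equal(out$events$replaced_g, 50)
})

test_that("energy replacement conserves kilocalories exactly", {
  food <- mini_food()
  rec <- tibble::tibble(person_id = "p1", day_index = 1L,
                        food_id = "meat1", amount_g = 100)
  # single candidate at 1.25 kcal/g forces 200 g (energy 250 kcal)
  mapping <- tibble::tibble(consumed_group = "meat_a", food_id = "ra1")
  spec <- scenario_spec("no_meat", "meat_a", 1, "energy",
                        allocation_seed = 3)
  out <- apply_scenario(rec, food, mapping, spec)
  expect_equal(nrow(out$records), 1)
  expect_equal(out$records$food_id, "ra1")
  expect_equal(out$records$amount_g, 200)
})

test_that("reference scenario returns the input untouched", {
  survey <- tiny_survey()
  spec <- scenario_spec("reference", character(), 1, "quantity", 1)
  out <- apply_scenario(survey$records, survey$food, survey$mapping, spec)
  expect_identical(out$records, survey$records)
  expect_equal(nrow(out$events), 0)
})

test_that("scenario errors name the offending group", {
  food <- mini_food()
  rec <- tibble::tibble(person_id = "p1", day_index = 1L,
                        food_id = "meat1", amount_g = 100)
  no_map <- tibble::tibble(consumed_group = "dairy_a", food_id = "rd1")
  spec <- scenario_spec("no_meat", "meat_a", 1, "quantity", 1)
  expect_error(apply_scenario(rec, food, no_map, spec), "meat_a")

  # all candidates under the energy-density floor
  thin <- food
  thin$energy_kcal[thin$food_id %in% c("ra1", "ra2", "ra3")] <- 1
  spec_e <- scenario_spec("no_meat", "meat_a", 1, "energy", 1)
  expect_error(apply_scenario(rec, thin, mini_mapping(), spec_e), "meat_a")
})

test_that("conservation invariants hold on a full synthetic survey", {
  survey <- tiny_survey()
  sc <- default_scenarios(survey$food, "quantity", 101, "no_meat")$no_meat
  out <- apply_scenario(survey$records, survey$food, survey$mapping, sc)
  # equal-weight replacement: replaced grams == added grams, and dataset
  # total grams are conserved
  expect_equal(sum(out$events$replaced_g), sum(out$events$replacement_g))
  expect_equal(sum(out$records$amount_g), sum(survey$records$amount_g))

  sce <- default_scenarios(survey$food, "energy", 101, "no_meat")$no_meat
  oute <- apply_scenario(survey$records, survey$food, survey$mapping, sce)
  en <- function(r) sum(nutrient_totals(r, survey$food)$energy_kcal)
  expect_equal(en(oute$records), en(survey$records), tolerance = 1e-9)

  sch <- default_scenarios(survey$food, "quantity", 101,
                           "half_meat")$half_meat
  outh <- apply_scenario(survey$records, survey$food, survey$mapping, sch)
  meat_g <- function(r) {
    grp <- survey$food$group_category[match(r$food_id,
                                            survey$food$food_id)]
    sum(r$amount_g[grp == "meat"])
  }
  expect_equal(meat_g(outh$records), 0.5 * meat_g(survey$records),
               tolerance = 1e-12)
})

test_that("allocation is seeded: same seed identical, seeds differ only in draws", {
  survey <- tiny_survey()
  sc <- default_scenarios(survey$food, "quantity", 101, "no_meat")$no_meat
  a <- apply_scenario(survey$records, survey$food, survey$mapping, sc)
  b <- apply_scenario(survey$records, survey$food, survey$mapping, sc)
  expect_identical(a, b)

  sc2 <- sc
  sc2$allocation_seed <- sc$allocation_seed + 1L
  c <- apply_scenario(survey$records, survey$food, survey$mapping, sc2)
  expect_equal(a$events$replaced_g, c$events$replaced_g)
  expect_equal(a$events$record_index, c$events$record_index)
  expect_false(identical(a$events$replacement_food_id,
                         c$events$replacement_food_id))
})

test_that("seeded outcomes lie within the exhaustively enumerated set", {
  food <- mini_food()
  rec <- tibble::tibble(
    person_id = "p1", day_index = 1L,
    food_id = c("meat1", "meat2", "meat1", "meat2", "meat1"),
    amount_g = c(100, 50, 80, 60, 40)
  )
  mapping <- mini_mapping()[mini_mapping()$consumed_group == "meat_a", ]
  cand <- mapping$food_id
  protein <- function(r) sum(nutrient_totals(r, food)$total_protein_g)

  # enumerate all 3^5 allocations by hand
  grids <- do.call(expand.grid, rep(list(seq_along(cand)), nrow(rec)))
  enumerated <- apply(grids, 1, function(pick) {
    repl <- tibble::tibble(person_id = "p1", day_index = 1L,
                           food_id = cand[pick], amount_g = rec$amount_g)
    protein(repl)
  })

  for (seed in 1:10) {
    spec <- scenario_spec("no_meat", "meat_a", 1, "quantity", seed)
    out <- apply_scenario(rec, food, mapping, spec)
    val <- protein(out$records)
    expect_gte(val, min(enumerated) - 1e-9)
    expect_lte(val, max(enumerated) + 1e-9)
    expect_true(any(abs(enumerated - val) < 1e-9))
  }
})

test_that("plant-protein share increases with replacement extent", {
  survey <- tiny_survey()
  share_of <- function(records) {
    v <- weighted_mean_intake_fn(survey$food, survey$persons,
                                 c("plant_protein_g",
                                   "total_protein_g"))(records)
    unname(v[1] / v[2])
  }
  shares <- c(reference = share_of(survey$records))
  for (nm in c("half_meat", "no_meat", "no_meat_and_dairy")) {
    sc <- default_scenarios(survey$food, "quantity", 101, nm)[[nm]]
    out <- apply_scenario(survey$records, survey$food, survey$mapping, sc)
    shares[nm] <- share_of(out$records)
  }
  expect_true(all(diff(shares) > 0))
})

test_that("allocation CV is zero without randomness and NA for zero means", {
  food <- mini_food()
  rec <- tibble::tibble(person_id = "p1", day_index = 1L,
                        food_id = "meat1", amount_g = 100)
  single <- tibble::tibble(consumed_group = "meat_a", food_id = "ra1")
  spec <- scenario_spec("no_meat", "meat_a", 1, "quantity", 5)
  cv <- replicate_allocation_cv(
    rec, food, single, spec, n_replicates = 4,
    outcome_fn = function(r) c(
      protein = sum(nutrient_totals(r, food)$total_protein_g),
      b12 = sum(nutrient_totals(r, food)$vitb12_ug)
    )
  )
  expect_equal(cv$cv[cv$outcome == "protein"], 0)
  expect_true(is.na(cv$cv[cv$outcome == "b12"]))
})
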