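# Shared fixtures, built in code and memoised per test run.

# small synthetic survey for structural tests
tiny_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_survey(
        synthetic_spec(n_women = 40, n_men = 40, master_seed = 101)
      )
    }
    cache
  }
})

# the default study-scale survey (600 women, 585 men), shared by the
# acceptance checks
default_survey <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_survey(synthetic_spec(master_seed = 20191))
    }
    cache
  }
})

# hand-built minimal food table + mapping for exact scenario oracles:
# one meat group (2.5 kcal/g foods), one dairy group, one staple, and
# replacement candidates with known energy densities
mini_food <- function() {
  nut0 <- stats::setNames(as.list(rep(0, 13)), tracked_nutrients())
  mk <- function(food_id, group, category, kcal, plant, animal,
                 red = FALSE, ghg = 1, land = 1, water = 100) {
    row <- tibble::as_tibble(nut0)
    row$energy_kcal <- kcal
    row$plant_protein_g <- plant
    row$animal_protein_g <- animal
    row$total_protein_g <- plant + animal
    tibble::tibble(food_id = food_id, name = food_id,
                   consumed_group = group, group_category = category,
                   is_red_meat = red) %>%
      dplyr::bind_cols(row) %>%
      dplyr::mutate(ghg_kgco2eq_per_kg = ghg, land_m2yr_per_kg = land,
                    water_l_per_kg = water)
  }
  dplyr::bind_rows(
    mk("meat1", "meat_a", "meat", 250, 0, 20, red = TRUE,
       ghg = 20, land = 12, water = 120),
    mk("meat2", "meat_a", "meat", 200, 0, 18, red = FALSE,
       ghg = 10, land = 8, water = 110),
    mk("dairy1", "dairy_a", "dairy", 60, 0, 3.5, ghg = 1.5, land = 1.1,
       water = 60),
    mk("bread1", "bread", "plant_staple", 250, 9, 0, ghg = 1, land = 1.2,
       water = 150),
    mk("ra1", "repl_meat_a", "replacement", 125, 10, 0, ghg = 2.5,
       land = 3, water = 300),
    mk("ra2", "repl_meat_a", "replacement", 150, 12, 0, ghg = 2.5,
       land = 3, water = 310),
    mk("ra3", "repl_meat_a", "replacement", 300, 14, 0, ghg = 2.6,
       land = 3, water = 320),
    mk("rd1", "repl_dairy_a", "replacement", 45, 2, 0, ghg = 0.5,
       land = 0.4, water = 120)
  )
}

mini_mapping <- function() {
  tibble::tibble(
    consumed_group = c("meat_a", "meat_a", "meat_a", "dairy_a"),
    food_id = c("ra1", "ra2", "ra3", "rd1")
  )
}

mini_persons <- function(n = 2) {
  tibble::tibble(
    person_id = sprintf("p%02d", seq_len(n)),
    sex = rep(c("female", "male"), length.out = n),
    age = rep(40, n),
    weight_factor = rep(1, n)
  )
}

# daily-intake table from explicit per-person-day values of one nutrient
daily_from_values <- function(values_by_person, nutrient = "energy_kcal") {
  df <- purrr::imap(values_by_person, function(v, id) {
    tibble::tibble(person_id = id, day_index = seq_along(v), value = v)
  }) %>% dplyr::bind_rows()
  names(df)[names(df) == "value"] <- nutrient
  df
}

persons_for <- function(ids, sex = "female", age = 40, weight = 1) {
  tibble::tibble(person_id = ids, sex = sex,
                 age = rep(age, length.out = length(ids)),
                 weight_factor = rep(weight, length.out = length(ids)))
}
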