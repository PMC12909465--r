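# Default parameterisation of the synthetic two-recall survey.  The group
# table below is the generator's picture of a Dutch-style adult diet: five
# consumed meat subgroups, seven dairy subgroups, plant staples and a mixed
# fish/egg group, each with an eating-occasion rate (occasions/day), a mean
# occasion portion (g) and mean nutrient densities (per 100 g) plus
# footprint factors (per kg).  Values are order-of-magnitude realistic for
# the food categories named; they are not measurements from any composition
# or LCA database.

#' Default food-group parameters for the synthetic survey
#'
#' One row per food group.  Categories: `plant_staple` and `other_animal`
#' groups form the untouched backbone of the diet (staple groups are eaten
#' at least once per day so every tracked nutrient is consumed daily, as the
#' one-part habitual-intake model assumes); `meat` and `dairy` groups are
#' the replacement targets; `replacement` groups are the plant-based
#' alternatives, linked to the consumed group they replace via `replaces`.
#'
#' Replacement groups follow the systematic contrasts of real plant-based
#' alternatives: all-plant protein, zero vitamin B12 (unless fortification
#' is switched on in [synthetic_spec()]), more fiber, less saturated fat,
#' lower greenhouse-gas and land footprints, higher water footprints.
#'
#' @return A tibble with group parameters; see source for columns.
#' @export
default_group_params <- function() {
  cols <- c("group", "category", "replaces", "staple", "rate", "amount_g",
            "energy_kcal", "plant_protein_g", "animal_protein_g",
            "total_lipid_g", "safa_g", "fiber_g", "vita_ug", "vitb12_ug",
            "vitb6_mg", "vitb2_mg", "calcium_mg", "sodium_mg",
            "ghg_kgco2eq_per_kg", "land_m2yr_per_kg", "water_l_per_kg")
  rows <- list(
    # group, category, replaces, staple, rate, amount,
    #   kcal, pl_prot, an_prot, lipid, safa, fiber, vitA, B12, B6, B2,
    #   Ca, Na, ghg, land, water
    list("bread", "plant_staple", NA, TRUE, 2.0, 85,
         250, 10.5, 0, 3, 0.6, 5, 0, 0, 0.10, 0.05, 30, 450, 1.0, 1.2, 150),
    list("cereals_potatoes", "plant_staple", NA, TRUE, 1.4, 180,
         110, 3.2, 0, 1, 0.2, 2, 1, 0, 0.25, 0.03, 10, 5, 0.6, 0.7, 100),
    list("vegetables", "plant_staple", NA, TRUE, 1.5, 150,
         30, 1.5, 0, 0.3, 0.05, 2.5, 150, 0, 0.15, 0.06, 40, 20,
         0.7, 0.4, 60),
    list("fruit", "plant_staple", NA, FALSE, 1.2, 120,
         55, 0.7, 0, 0.2, 0.05, 2, 20, 0, 0.08, 0.03, 10, 2, 0.6, 0.5, 90),
    list("snacks_sweets", "plant_staple", NA, FALSE, 1.5, 60,
         450, 6, 0, 20, 8, 2, 10, 0, 0.05, 0.05, 40, 300, 2.5, 2.0, 250),
    list("fats_oils", "plant_staple", NA, TRUE, 1.0, 20,
         720, 0.2, 0, 80, 25, 0, 600, 0, 0, 0, 5, 100, 3.0, 3.5, 200),
    list("fish_eggs", "other_animal", NA, TRUE, 1.0, 70,
         160, 0, 13, 10, 2.5, 0, 120, 2.0, 0.30, 0.30, 50, 300,
         5.0, 4.0, 150),
    # meat subgroups
    list("meat_unprocessed", "meat", NA, FALSE, 0.8, 100,
         180, 0, 22, 10, 4, 0, 10, 1.5, 0.40, 0.20, 10, 80, 18, 12, 120),
    list("meat_processed", "meat", NA, FALSE, 0.7, 60,
         250, 0, 16, 20, 8, 0, 10, 1.0, 0.25, 0.18, 15, 900, 12, 9, 110),
    list("meat_warm_snacks", "meat", NA, FALSE, 0.3, 70,
         280, 0, 12, 18, 7, 1, 15, 0.8, 0.15, 0.12, 20, 700, 8, 6, 130),
    list("cold_meat_cut", "meat", NA, FALSE, 0.6, 30,
         210, 0, 18, 14, 5.5, 0, 5, 1.2, 0.30, 0.18, 10, 1000, 11, 8, 110),
    list("cold_meat_spread", "meat", NA, FALSE, 0.3, 15,
         260, 0, 13, 22, 8, 0, 400, 1.5, 0.20, 0.60, 15, 800, 10, 7, 100),
    # dairy subgroups
    list("milk_unsweetened", "dairy", NA, FALSE, 0.8, 200,
         50, 0, 3.5, 2, 1.2, 0, 20, 0.40, 0.04, 0.18, 120, 40,
         1.5, 1.1, 60),
    list("milk_sweetened", "dairy", NA, FALSE, 0.4, 200,
         80, 0, 3.3, 2, 1.2, 0, 20, 0.35, 0.04, 0.16, 110, 45,
         1.6, 1.2, 70),
    list("dairy_dessert", "dairy", NA, FALSE, 0.5, 130,
         120, 0, 3.5, 4, 2.5, 0, 30, 0.30, 0.04, 0.15, 110, 50,
         2.0, 1.5, 80),
    list("fermented_dairy", "dairy", NA, FALSE, 0.8, 150,
         70, 0, 4.5, 3, 1.9, 0, 25, 0.40, 0.05, 0.20, 130, 50,
         1.7, 1.2, 65),
    list("cheese", "dairy", NA, FALSE, 0.8, 30,
         360, 0, 24, 29, 18, 0, 250, 1.5, 0.07, 0.30, 750, 800, 9, 7, 250),
    list("cheese_spread", "dairy", NA, FALSE, 0.3, 20,
         250, 0, 12, 20, 13, 0, 180, 0.8, 0.05, 0.25, 400, 900,
         7, 5, 200),
    list("cream", "dairy", NA, FALSE, 0.3, 30,
         290, 0, 2.5, 30, 19, 0, 250, 0.2, 0.03, 0.12, 80, 40, 4, 3, 120),
    # plant-based replacement groups (one per targeted consumed group)
    list("repl_meat_unprocessed", "replacement", "meat_unprocessed",
         FALSE, 0, 100,
         150, 14, 0, 7, 1, 5, 5, 0, 0.15, 0.10, 100, 400, 2.5, 3.0, 300),
    list("repl_meat_processed", "replacement", "meat_processed",
         FALSE, 0, 60,
         200, 15, 0, 10, 1.5, 4, 0, 0, 0.10, 0.10, 80, 700, 2.8, 3.2, 320),
    list("repl_meat_warm_snacks", "replacement", "meat_warm_snacks",
         FALSE, 0, 70,
         230, 10, 0, 12, 2, 4, 0, 0, 0.10, 0.08, 60, 600, 2.5, 3.0, 280),
    list("repl_cold_meat_cut", "replacement", "cold_meat_cut",
         FALSE, 0, 30,
         180, 16, 0, 9, 1.2, 3, 0, 0, 0.10, 0.08, 60, 900, 2.6, 3.0, 300),
    list("repl_cold_meat_spread", "replacement", "cold_meat_spread",
         FALSE, 0, 15,
         350, 12, 0, 28, 4, 6, 0, 0, 0.20, 0.10, 50, 500, 2.2, 3.5, 900),
    list("repl_milk_unsweetened", "replacement", "milk_unsweetened",
         FALSE, 0, 200,
         40, 2.0, 0, 1.5, 0.2, 0.5, 0, 0, 0.02, 0.10, 90, 40,
         0.5, 0.4, 120),
    list("repl_milk_sweetened", "replacement", "milk_sweetened",
         FALSE, 0, 200,
         60, 2.0, 0, 1.5, 0.2, 0.5, 0, 0, 0.02, 0.08, 90, 45,
         0.55, 0.45, 130),
    list("repl_dairy_dessert", "replacement", "dairy_dessert",
         FALSE, 0, 130,
         100, 2.5, 0, 3.5, 1.5, 1, 0, 0, 0.02, 0.05, 80, 50,
         0.9, 0.8, 150),
    list("repl_fermented_dairy", "replacement", "fermented_dairy",
         FALSE, 0, 150,
         55, 3.5, 0, 2.5, 0.4, 1, 0, 0, 0.03, 0.05, 100, 40,
         0.6, 0.5, 130),
    list("repl_cheese", "replacement", "cheese", FALSE, 0, 30,
         330, 10, 0, 28, 9, 3, 10, 0, 0.15, 0.10, 120, 600, 3, 4, 1200),
    list("repl_cheese_spread", "replacement", "cheese_spread",
         FALSE, 0, 20,
         320, 11, 0, 26, 4, 5, 0, 0, 0.20, 0.10, 60, 450, 2.2, 3.5, 900),
    list("repl_cream", "replacement", "cream", FALSE, 0, 30,
         160, 1.5, 0, 15, 5, 0.5, 0, 0, 0.02, 0.03, 20, 40,
         1.2, 1.0, 150)
  )
  out <- purrr::map(rows, ~ setNames(.x, cols)) %>%
    purrr::map(as_tibble) %>%
    bind_rows()
  out$replaces <- as.character(out$replaces)
  # every consumed group is eaten at least once per day by default: the
  # habitual model is a one-part model for components consumed daily
  out$staple <- out$category != "replacement"
  out
}

#' Specification of the synthetic two-recall survey
#'
#' Collects every knob of the synthetic-data generator.  Defaults emulate
#' the study conditions the pipeline is validated under: 600 women and 585
#' men with two recall days each; an average of 12 replacement alternatives
#' per targeted group (range 1-31); a log-scale (`lambda = 0`) habitual
#' intake process with between-person SD 0.30 and within-person SD 0.50 on
#' the transformed scale and a mild linear age trend; per-food nutrient
#' densities scattered around their group means with relative SD 0.2; 80%
#' of meat foods flagged as red meat.
#'
#' @param n_women,n_men Number of persons per sex.
#' @param master_seed Integer master seed; every generator stage derives
#'   its own child stream from it.
#' @param sigma_b,sigma_w Between-/within-person SD of transformed daily
#'   intake (dimensionless on the Box-Cox scale).
#' @param lambda Box-Cox power of the latent intake process (0 = log).
#' @param age_slope Linear age trend of transformed intake, per year,
#'   centred at age 40.
#' @param mean_energy_kcal Named vector (`female`, `male`): target mean
#'   habitual daily energy on the original scale.
#' @param groups Group-parameter table, see [default_group_params()].
#' @param foods_per_group Number of distinct foods generated per consumed
#'   group.
#' @param alternatives_mean,alternatives_max Mean and maximum of the
#'   per-group replacement-list size distribution
#'   (`1 + Binomial(alternatives_max - 1, p)` with `p` set from the mean;
#'   support `[1, alternatives_max]`).
#' @param red_meat_prob Probability that a meat-group food is flagged as
#'   red meat.
#' @param density_rel_sd Relative SD of per-food nutrient densities and
#'   footprint factors around their group mean (must be <= 0.3).
#' @param amount_sdlog Log-scale SD of raw occasion portion sizes.
#' @param fortified_b12 If `TRUE`, replacement foods carry the vitamin B12
#'   density of the group they replace (fortification); default off.
#' @param ear_quantile Latent-habitual quantile at which
#'   [generate_ear_table()] plants each EAR (recycled over nutrients).
#' @return An object of class `synthetic_spec` (a list).
#' @export
#' @examples
#' spec <- synthetic_spec(n_women = 20, n_men = 20, master_seed = 1)
#' spec$n_women
synthetic_spec <- function(n_women = 600, n_men = 585, master_seed = 20191,
                           sigma_b = 0.30, sigma_w = 0.50, lambda = 0,
                           age_slope = -0.003,
                           mean_energy_kcal = c(female = 2000, male = 2600),
                           groups = default_group_params(),
                           foods_per_group = 8,
                           alternatives_mean = 12, alternatives_max = 31,
                           red_meat_prob = 0.8, density_rel_sd = 0.2,
                           amount_sdlog = 0.4, fortified_b12 = FALSE,
                           ear_quantile = 0.10) {
  stopifnot(
    n_women >= 0, n_men >= 0, n_women + n_men > 0,
    sigma_b >= 0, sigma_w >= 0, lambda >= 0, lambda <= 1,
    foods_per_group >= 1,
    alternatives_mean >= 1, alternatives_mean <= alternatives_max,
    alternatives_max >= 1, alternatives_max <= 31,
    red_meat_prob >= 0, red_meat_prob <= 1,
    density_rel_sd >= 0, density_rel_sd <= 0.3,
    all(c("female", "male") %in% names(mean_energy_kcal)),
    all(groups$rate >= 0),
    ear_quantile >= 0, ear_quantile <= 1
  )
  structure(
    list(
      n_women = n_women, n_men = n_men, master_seed = master_seed,
      sigma_b = sigma_b, sigma_w = sigma_w, lambda = lambda,
      age_slope = age_slope, mean_energy_kcal = mean_energy_kcal,
      groups = groups, foods_per_group = foods_per_group,
      alternatives_mean = alternatives_mean,
      alternatives_max = alternatives_max,
      red_meat_prob = red_meat_prob, density_rel_sd = density_rel_sd,
      amount_sdlog = amount_sdlog, fortified_b12 = fortified_b12,
      ear_quantile = ear_quantile
    ),
    class = "synthetic_spec"
  )
}
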