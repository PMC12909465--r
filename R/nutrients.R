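#' Tracked nutrient vocabulary
#'
#' The thirteen dietary components followed through every stage of the
#' pipeline: energy plus twelve macro- and micro-nutrients prioritised for
#' monitoring during a protein transition.  Food-composition tables carry one
#' column per component, expressed per 100 g of food; intake tables carry the
#' same columns as per-day totals.
#'
#' Units are encoded in the names: `_kcal` kilocalories, `_g` grams,
#' `_ug` micrograms (vitamin A as retinol activity equivalents),
#' `_mg` milligrams.
#'
#' @return Character vector of the 13 component column names.
#' @export
#' @examples
#' tracked_nutrients()
tracked_nutrients <- function() {
  c(
    "energy_kcal",
    "total_protein_g",
    "plant_protein_g",
    "animal_protein_g",
    "total_lipid_g",
    "safa_g",
    "fiber_g",
    "vita_ug",
    "vitb12_ug",
    "vitb6_mg",
    "vitb2_mg",
    "calcium_mg",
    "sodium_mg"
  )
}

#' Nutrients with an Estimated Average Requirement
#'
#' The micronutrients for which population inadequacy is assessed with the
#' EAR cut-point method: vitamin A, B12, B6, B2 and calcium.
#'
#' @return Character vector, a subset of [tracked_nutrients()].
#' @export
ear_nutrients <- function() {
  c("vita_ug", "vitb12_ug", "vitb6_mg", "vitb2_mg", "calcium_mg")
}

#' Environmental footprint indicators
#'
#' Per-kg life-cycle factors carried on the food table: greenhouse-gas
#' emissions (kg CO2-equivalents), land use (m2 \eqn{\times} year) and
#' freshwater consumption (litres).
#'
#' @return Character vector of the three factor column names.
#' @export
footprint_indicators <- function() {
  c("ghg_kgco2eq_per_kg", "land_m2yr_per_kg", "water_l_per_kg")
}

# column names of per-day footprint totals (per kg factors applied to grams)
footprint_day_cols <- function() {
  c("ghg_kgco2eq", "land_m2yr", "water_l")
}
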