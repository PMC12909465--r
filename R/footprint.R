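# Diet environmental footprints: per-kg life-cycle factors applied to
# consumed grams, averaged per person across recall days, then
# survey-weighted across persons.

#' Per-person per-day environmental footprint
#'
#' For each (person, day): `sum(amount_g / 1000 * factor_per_kg)` for each
#' of the three indicators (GHG in kg CO2-eq, land use in m2-year, water
#' in litres).
#'
#' @param records Consumption records.
#' @param food Food table carrying [footprint_indicators()].
#' @return A tibble with `person_id`, `day_index`, `ghg_kgco2eq`,
#'   `land_m2yr`, `water_l`.
#' @export
person_day_footprint <- function(records, food) {
  validate_consumption(records, food)
  if (nrow(records) == 0) {
    return(bind_cols(
      tibble(person_id = character(), day_index = integer()),
      as_tibble(setNames(rep(list(double()), 3), footprint_day_cols()))
    ))
  }
  fac <- food[match(records$food_id, food$food_id), footprint_indicators()]
  totals <- records$amount_g / 1000 * fac
  names(totals) <- footprint_day_cols()
  bind_cols(records[c("person_id", "day_index")], totals) %>%
    group_by(.data$person_id, .data$day_index) %>%
    summarise(across(all_of(footprint_day_cols()), sum),
              .groups = "drop") %>%
    tidyr::complete(!!!rlang::syms(c("person_id", "day_index")),
                    fill = setNames(as.list(rep(0, 3)),
                                    footprint_day_cols()))
}

#' Survey-weighted per-capita daily footprint of a population slice
#'
#' Each person's footprints are first averaged across their recall days,
#' then weighted by the survey weight across the persons of the slice
#' (`total`, `women` or `men`).
#'
#' @param pd Per-person-day footprints from [person_day_footprint()].
#' @param persons Person table.
#' @param slice `"total"`, `"women"` or `"men"`.
#' @return A one-row tibble with `slice` and the three per-day indicators.
#' @export
population_footprint <- function(pd, persons,
                                 slice = c("total", "women", "men")) {
  slice <- match.arg(slice)
  keep <- switch(slice,
                 total = persons,
                 women = filter(persons, .data$sex == "female"),
                 men = filter(persons, .data$sex == "male"))
  if (nrow(keep) == 0) abort(sprintf("slice '%s' contains no persons", slice))
  pm <- pd %>%
    group_by(.data$person_id) %>%
    summarise(across(all_of(footprint_day_cols()), mean),
              .groups = "drop") %>%
    inner_join(select(keep, "person_id", "weight_factor"),
               by = "person_id")
  if (nrow(pm) == 0) abort(sprintf("slice '%s' has no footprint rows", slice))
  out <- tibble(slice = slice)
  for (cn in footprint_day_cols()) {
    out[[paste0(cn, "_per_day")]] <- wmean(pm[[cn]], pm$weight_factor)
  }
  out
}

#' Relative footprint difference versus the reference diet
#'
#' `100 * (scenario - reference) / reference`, per indicator, on matching
#' slices.
#'
#' @param scenario_fp,reference_fp One-row outputs of
#'   [population_footprint()] for the same slice.
#' @return A one-row tibble of percentage differences, columns suffixed
#'   `_rel_diff_pct`.
#' @export
footprint_relative_diff <- function(scenario_fp, reference_fp) {
  stopifnot(scenario_fp$slice == reference_fp$slice)
  out <- tibble(slice = scenario_fp$slice)
  for (cn in paste0(footprint_day_cols(), "_per_day")) {
    out[[sub("_per_day$", "_rel_diff_pct", cn)]] <-
      100 * (scenario_fp[[cn]] - reference_fp[[cn]]) / reference_fp[[cn]]
  }
  out
}

#' Food-group contribution shares per indicator
#'
#' Share of each consumed group in the population total of each indicator
#' (shares sum to one per indicator).  Groups absent from the food table's
#' vocabulary fall into their own `consumed_group` value as carried on the
#' food table.  If the population total of an indicator is zero its shares
#' are `NA`.
#'
#' @param records Consumption records.
#' @param food Food table.
#' @return A tibble with `consumed_group`, `indicator`, `share`.
#' @export
group_contributions <- function(records, food) {
  validate_consumption(records, food)
  finfo <- food[match(records$food_id, food$food_id), ]
  fac <- finfo[footprint_indicators()]
  totals <- records$amount_g / 1000 * fac
  names(totals) <- footprint_day_cols()
  df <- bind_cols(tibble(consumed_group = finfo$consumed_group), totals) %>%
    group_by(.data$consumed_group) %>%
    summarise(across(all_of(footprint_day_cols()), sum),
              .groups = "drop") %>%
    tidyr::pivot_longer(all_of(footprint_day_cols()),
                        names_to = "indicator", values_to = "total") %>%
    group_by(.data$indicator) %>%
    mutate(share = .data$total / sum(.data$total)) %>%
    ungroup() %>%
    mutate(share = ifelse(is.nan(.data$share), NA_real_, .data$share)) %>%
    select("consumed_group", "indicator", "share")
  df
}
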