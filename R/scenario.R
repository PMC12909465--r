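# Replacement-scenario engine: apply a scenario to a consumption dataset
# under the quantity (equal grams) or energy (equal kcal) strategy, with a
# seeded uniform draw of the replacement food per consumption record.

#' Define a replacement scenario
#'
#' The scenario vocabulary: `reference` (no change), `no_meat_and_dairy`,
#' `no_meat`, `half_meat` (fraction 0.5), `no_red_meat` (only foods flagged
#' as red meat).  `target` is the set of consumed groups acted on; for the
#' named scenarios it can be derived from a food table with
#' [default_scenarios()].
#'
#' @param name One of `reference`, `no_meat_and_dairy`, `no_meat`,
#'   `half_meat`, `no_red_meat`.
#' @param target Character vector of consumed groups to replace (empty for
#'   `reference`).
#' @param fraction_replaced Fraction of each targeted record's grams
#'   replaced, in (0, 1]; 1 except for `half_meat` (0.5).
#' @param strategy `"quantity"` (equal grams) or `"energy"` (equal kcal).
#' @param allocation_seed Integer seed of the uniform allocation stream.
#' @param red_meat_only If `TRUE`, only records of red-meat-flagged foods
#'   in the target groups are replaced.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, target, fraction_replaced = 1,
                          strategy = c("quantity", "energy"),
                          allocation_seed = 1L, red_meat_only = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(fraction_replaced > 0, fraction_replaced <= 1)
  if (name == "reference" && length(target) > 0) {
    abort("the reference scenario must have an empty target")
  }
  structure(
    list(name = name, target = as.character(target),
         fraction_replaced = fraction_replaced, strategy = strategy,
         allocation_seed = as.integer(allocation_seed),
         red_meat_only = red_meat_only),
    class = "scenario_spec"
  )
}

#' Build the standard scenario set from a food table
#'
#' Derives the meat and dairy group sets from the food table's
#' `group_category` column and returns the reference plus the four
#' replacement scenarios, each with a child allocation seed stably hashed
#' from the master seed, the scenario name and the strategy (one fixed seed
#' per scenario, independent across scenarios).
#'
#' @param food Food table with `consumed_group` and `group_category`.
#' @param strategy `"quantity"` or `"energy"`.
#' @param master_seed Integer master seed.
#' @param names Which scenarios to build (default all five).
#' @return Named list of [scenario_spec()] objects.
#' @export
default_scenarios <- function(food, strategy = c("quantity", "energy"),
                              master_seed = 1L,
                              names = c("reference", "no_meat_and_dairy",
                                        "no_meat", "half_meat",
                                        "no_red_meat")) {
  strategy <- match.arg(strategy)
  meat <- unique(food$consumed_group[food$group_category == "meat"])
  dairy <- unique(food$consumed_group[food$group_category == "dairy"])
  build <- function(nm) {
    seed <- child_seed(master_seed, paste("scenario", nm, strategy))
    switch(
      nm,
      reference = scenario_spec("reference", character(), 1, strategy, seed),
      no_meat_and_dairy = scenario_spec("no_meat_and_dairy",
                                        c(meat, dairy), 1, strategy, seed),
      no_meat = scenario_spec("no_meat", meat, 1, strategy, seed),
      half_meat = scenario_spec("half_meat", meat, 0.5, strategy, seed),
      no_red_meat = scenario_spec("no_red_meat", meat, 1, strategy, seed,
                                  red_meat_only = TRUE),
      abort(sprintf("unknown scenario name '%s'", nm))
    )
  }
  setNames(purrr::map(names, build), names)
}

#' Apply a replacement scenario to consumption records
#'
#' For every targeted record, `fraction_replaced` of its grams is removed
#' and handed to one replacement food drawn uniformly (with replacement)
#' from the candidate list of the record's consumed group, using a stream
#' seeded by `spec$allocation_seed`.  Under the quantity strategy the
#' replacement amount equals the replaced grams; under the energy strategy
#' it is scaled so the replacement supplies the same kilocalories as the
#' replaced grams did.  Candidates with energy density below `ed_min`
#' kcal/g are excluded in energy mode (guards against unbounded gram
#' inflation); the exclusion count is recorded in the `log` attribute.
#' Non-targeted records pass through bit-identical and in input order;
#' replacement records are appended in the order of the records that
#' spawned them.
#'
#' @param records Consumption records.
#' @param food Food table.
#' @param mapping Replacement mapping (`consumed_group`, `food_id`).
#' @param spec A [scenario_spec()].
#' @param ed_min Minimum energy density (kcal/g) of energy-mode candidates.
#' @return A list with `records` (the new dataset) and `events` (one row
#'   per replacement: original record index, food, replaced grams,
#'   replacement food, replacement grams).
#' @export
apply_scenario <- function(records, food, mapping, spec, ed_min = 0.05) {
  validate_consumption(records, food)
  empty_events <- tibble(
    record_index = integer(), person_id = character(),
    day_index = integer(), food_id = character(), replaced_g = double(),
    replacement_food_id = character(), replacement_g = double()
  )
  attr(empty_events, "log") <- tibble(
    event = "energy_candidates_excluded", count = 0L
  )
  if (length(spec$target) == 0) {
    return(list(records = records, events = empty_events))
  }

  finfo <- food[match(records$food_id, food$food_id), ]
  targeted <- finfo$consumed_group %in% spec$target
  if (spec$red_meat_only) targeted <- targeted & finfo$is_red_meat
  if (!any(targeted)) {
    return(list(records = records, events = empty_events))
  }

  groups_hit <- unique(finfo$consumed_group[targeted])
  unmapped <- setdiff(groups_hit, unique(mapping$consumed_group))
  if (length(unmapped) > 0) {
    abort(sprintf("targeted group(s) without replacement mapping: %s",
                  paste(unmapped, collapse = ", ")))
  }

  cand <- mapping %>%
    filter(.data$consumed_group %in% groups_hit) %>%
    mutate(ed = food$energy_kcal[match(.data$food_id,
                                       food$food_id)] / 100)
  n_excluded <- 0L
  if (spec$strategy == "energy") {
    n_excluded <- sum(cand$ed < ed_min)
    kept <- cand %>% filter(.data$ed >= ed_min)
    starved <- setdiff(groups_hit, unique(kept$consumed_group))
    if (length(starved) > 0) {
      abort(sprintf(
        "energy strategy: no candidate with energy density >= %g kcal/g in group(s): %s",
        ed_min, paste(starved, collapse = ", ")
      ))
    }
    cand <- kept
  }
  cand_split <- split(cand$food_id, cand$consumed_group)
  cand_ed <- split(cand$ed, cand$consumed_group)

  idx <- which(targeted)
  grp_of <- finfo$consumed_group[idx]
  replaced_g <- spec$fraction_replaced * records$amount_g[idx]

  # one uniform draw per targeted consumption record, in record order
  pick <- withr::with_seed(spec$allocation_seed, {
    k <- lengths(cand_split)[grp_of]
    as.integer(ceiling(runif(length(idx)) * k))
  })
  repl_food <- purrr::map2_chr(grp_of, pick, ~ cand_split[[.x]][.y])

  if (spec$strategy == "quantity") {
    repl_g <- replaced_g
  } else {
    ed_orig <- finfo$energy_kcal[idx] / 100
    ed_repl <- purrr::map2_dbl(grp_of, pick, ~ cand_ed[[.x]][.y])
    repl_g <- replaced_g * ed_orig / ed_repl
  }

  events <- tibble(
    record_index = idx,
    person_id = records$person_id[idx],
    day_index = records$day_index[idx],
    food_id = records$food_id[idx],
    replaced_g = replaced_g,
    replacement_food_id = repl_food,
    replacement_g = repl_g
  )

  out <- records
  out$amount_g[idx] <- out$amount_g[idx] - replaced_g
  if (spec$fraction_replaced >= 1) {
    out <- out[-idx, , drop = FALSE]
  }
  new_rows <- tibble(
    person_id = events$person_id,
    day_index = events$day_index,
    food_id = events$replacement_food_id,
    amount_g = events$replacement_g
  )
  out <- bind_rows(out, new_rows)
  attr(events, "log") <- tibble(
    event = "energy_candidates_excluded", count = n_excluded
  )
  list(records = as_tibble(out), events = events)
}

#' Per-person per-day nutrient totals
#'
#' Intake of each tracked component per (person, day):
#' `sum(amount_g * density_per_100g / 100)`.  Person-days present in the
#' data's person and day sets but without any record yield zero rows.
#'
#' @param records Consumption records.
#' @param food Food table.
#' @return A tibble with `person_id`, `day_index` and one column per
#'   [tracked_nutrients()].
#' @export
nutrient_totals <- function(records, food) {
  validate_consumption(records, food)
  if (nrow(records) == 0) {
    return(bind_cols(
      tibble(person_id = character(), day_index = integer()),
      as_tibble(setNames(rep(list(double()), 13), tracked_nutrients()))
    ))
  }
  dens <- food[match(records$food_id, food$food_id), tracked_nutrients()]
  bind_cols(records[c("person_id", "day_index")],
            records$amount_g * dens / 100) %>%
    group_by(.data$person_id, .data$day_index) %>%
    summarise(across(all_of(tracked_nutrients()), sum), .groups = "drop") %>%
    tidyr::complete(!!!rlang::syms(c("person_id", "day_index")),
                    fill = setNames(as.list(rep(0, 13)),
                                    tracked_nutrients()))
}

#' Allocation variability across replicate runs
#'
#' Re-runs [apply_scenario()] `n_replicates` times with allocation seeds
#' `spec$allocation_seed + 1, ..., + n_replicates` and summarises the
#' stability of user-chosen outcomes as a coefficient of variation
#' (sd/mean) per outcome.  Outcomes whose replicate mean is zero get
#' `NA` (CV undefined).
#'
#' @param records,food,mapping,spec As for [apply_scenario()].
#' @param n_replicates Number of replicate allocations (default 10).
#' @param outcome_fn Function mapping a records tibble to a named numeric
#'   vector of positive scalars (e.g. survey-weighted population mean
#'   intake per nutrient); see [weighted_mean_intake_fn()].
#' @return A tibble with `outcome`, `mean`, `sd`, `cv`.
#' @export
replicate_allocation_cv <- function(records, food, mapping, spec,
                                    n_replicates = 10, outcome_fn) {
  stopifnot(n_replicates >= 2)
  vals <- purrr::map(seq_len(n_replicates), function(r) {
    spec_r <- spec
    spec_r$allocation_seed <- spec$allocation_seed + r
    outcome_fn(apply_scenario(records, food, mapping, spec_r)$records)
  })
  m <- do.call(rbind, vals)
  mu <- unname(colMeans(m))
  sdev <- unname(apply(m, 2, sd))
  tibble(
    outcome = colnames(m),
    mean = mu,
    sd = sdev,
    cv = ifelse(mu == 0, NA_real_, sdev / mu)
  )
}

#' Survey-weighted population mean intake as an outcome function
#'
#' Builds a closure suitable for [replicate_allocation_cv()]: for a records
#' tibble it computes per-person across-day mean daily intakes and returns
#' their weighted mean over persons, per requested nutrient.
#'
#' @param food Food table.
#' @param persons Person table (for survey weights).
#' @param nutrients Nutrient columns to report.
#' @return A function `records -> named numeric`.
#' @export
weighted_mean_intake_fn <- function(food, persons,
                                    nutrients = "total_protein_g") {
  force(food); force(persons); force(nutrients)
  function(records) {
    pm <- nutrient_totals(records, food) %>%
      group_by(.data$person_id) %>%
      summarise(across(all_of(nutrients), mean), .groups = "drop") %>%
      inner_join(select(persons, "person_id", "weight_factor"),
                 by = "person_id")
    vapply(nutrients,
           function(nm) wmean(pm[[nm]], pm$weight_factor),
           numeric(1))
  }
}
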