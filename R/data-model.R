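# CSV readers/writers and table validators shared by all pipeline stages.
# Contract: composition per 100 g, footprints per kg, consumption in grams;
# UTF-8, "." decimal separator, no missing values in numeric columns.

read_csv_quiet <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

check_columns <- function(df, required, what, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s file '%s' is missing required column(s): %s",
      what, path, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Read a person (survey-weight) table
#'
#' Expects columns `person_id`, `sex` (`female`/`male`), `age` (integer
#' years, 18-65) and `weight_factor` (positive survey weight).
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per person.
#' @export
read_persons <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    person_id = readr::col_character(),
    .default = readr::col_guess()
  ))
  check_columns(df, c("person_id", "sex", "age", "weight_factor"),
                "Person", path)
  validate_persons(df)
}

#' Validate a person table
#'
#' Enforces the person invariants: unique ids, sex in `female`/`male`, age
#' in 18-65, strictly positive survey weights.
#'
#' @param persons Tibble with `person_id`, `sex`, `age`, `weight_factor`.
#' @return The validated tibble, invisibly coerced to canonical types.
#' @export
validate_persons <- function(persons) {
  bad_sex <- setdiff(unique(persons$sex), c("female", "male"))
  if (length(bad_sex) > 0) {
    abort(sprintf("unknown sex token(s): %s", paste(bad_sex, collapse = ", ")))
  }
  if (anyDuplicated(persons$person_id) > 0) {
    abort("person_id values must be unique")
  }
  if (any(!is.finite(persons$age) | persons$age < 18 | persons$age > 65)) {
    abort("age must lie in [18, 65]")
  }
  if (any(!is.finite(persons$weight_factor) | persons$weight_factor <= 0)) {
    abort("weight_factor must be finite and > 0")
  }
  as_tibble(persons)
}

#' Read a consumption-record table
#'
#' One row per food eaten by one person on one recall day, in grams.
#' Columns: `person_id`, `day_index` (1 or 2), `food_id`, `amount_g`.
#' Duplicate (person, day, food) rows are legitimate separate eating
#' occasions and are kept apart.  Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A tibble of consumption records.
#' @export
read_consumption <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    person_id = readr::col_character(),
    food_id = readr::col_character(),
    .default = readr::col_guess()
  ))
  check_columns(df, c("person_id", "day_index", "food_id", "amount_g"),
                "Consumption", path)
  bad <- which(!is.finite(df$amount_g) | df$amount_g < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "amount_g must be finite and >= 0; offending row(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  as_tibble(df)
}

#' Read and join the food table
#'
#' Joins the three per-food inputs into one table: composition (energy and
#' the 12 further tracked nutrients per 100 g), environmental footprint
#' factors (per kg) and group membership (consumed subgroup, category,
#' red-meat flag).  The protein-split invariant
#' `plant_protein_g + animal_protein_g == total_protein_g` is checked.
#'
#' @param path_composition CSV with `food_id`, `name` and the
#'   [tracked_nutrients()] columns (per 100 g).
#' @param path_footprints CSV with `food_id` and the
#'   [footprint_indicators()] columns (per kg).
#' @param path_groups CSV with `food_id`, `consumed_group`,
#'   `group_category` and `is_red_meat`.
#' @return A tibble with one row per food.
#' @export
read_food_table <- function(path_composition, path_footprints, path_groups) {
  comp <- read_csv_quiet(path_composition, readr::cols(
    food_id = readr::col_character(), name = readr::col_character(),
    .default = readr::col_double()
  ))
  check_columns(comp, c("food_id", "name", tracked_nutrients()),
                "Composition", path_composition)
  foot <- read_csv_quiet(path_footprints, readr::cols(
    food_id = readr::col_character(), .default = readr::col_double()
  ))
  check_columns(foot, c("food_id", footprint_indicators()),
                "Footprint", path_footprints)
  grp <- read_csv_quiet(path_groups, readr::cols(
    food_id = readr::col_character(),
    consumed_group = readr::col_character(),
    group_category = readr::col_character(),
    is_red_meat = readr::col_logical()
  ))
  check_columns(grp, c("food_id", "consumed_group", "group_category",
                       "is_red_meat"), "Group", path_groups)

  ids <- list(comp$food_id, foot$food_id, grp$food_id)
  all_ids <- unique(unlist(ids))
  missing <- purrr::map(ids, ~ setdiff(all_ids, .x))
  if (any(lengths(missing) > 0)) {
    abort(sprintf(
      "food_id sets differ across the three files; e.g. missing: %s",
      paste(utils::head(unique(unlist(missing)), 5), collapse = ", ")
    ))
  }
  food <- comp %>%
    inner_join(foot, by = "food_id") %>%
    inner_join(grp, by = "food_id")
  validate_food_table(food)
}

#' Validate a food table
#'
#' Checks non-negative densities and footprint factors, the protein-split
#' identity, and that red-meat flags only occur in meat groups.
#'
#' @param food Tibble as produced by [read_food_table()].
#' @param tol Absolute tolerance for the protein split identity.
#' @return The validated tibble.
#' @export
validate_food_table <- function(food, tol = 1e-9) {
  num_cols <- c(tracked_nutrients(), footprint_indicators())
  for (cn in num_cols) {
    if (any(!is.finite(food[[cn]]) | food[[cn]] < 0)) {
      abort(sprintf("column '%s' must be finite and >= 0 for every food", cn))
    }
  }
  split_err <- abs(food$plant_protein_g + food$animal_protein_g -
                     food$total_protein_g)
  if (any(split_err > tol)) {
    bad <- food$food_id[split_err > tol]
    abort(sprintf(
      "plant + animal protein must equal total protein; offending food(s): %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  if (any(food$is_red_meat & food$group_category != "meat")) {
    abort("is_red_meat may only be set for foods in a meat group")
  }
  as_tibble(food)
}

#' Read a replacement mapping
#'
#' Maps each consumed subgroup to its ordered list of candidate replacement
#' foods, one row per (consumed_group, replacement food).
#'
#' @param path CSV with columns `consumed_group`, `food_id`.
#' @return A tibble with columns `consumed_group`, `food_id`.
#' @export
read_replacement_mapping <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    consumed_group = readr::col_character(),
    food_id = readr::col_character()
  ))
  check_columns(df, c("consumed_group", "food_id"), "Mapping", path)
  as_tibble(df)
}

#' Validate a replacement mapping against a food table
#'
#' Every mapped food must exist; every mapped group must have at least one
#' candidate; candidates must be fully plant-based (zero animal protein)
#' unless listed in `allow_mixed` (e.g. vegetarian cheese containing dairy).
#'
#' @param mapping Tibble with `consumed_group`, `food_id`.
#' @param food Food table.
#' @param allow_mixed Character vector of food_ids exempt from the
#'   plant-only rule.
#' @return The validated mapping.
#' @export
validate_mapping <- function(mapping, food, allow_mixed = character()) {
  unknown <- setdiff(mapping$food_id, food$food_id)
  if (length(unknown) > 0) {
    abort(sprintf("mapping lists unknown food_id(s): %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  if (any(table(mapping$consumed_group) < 1)) {
    abort("every mapped group needs at least one replacement food")
  }
  joined <- mapping %>% inner_join(select(food, "food_id",
                                          "animal_protein_g"), by = "food_id")
  bad <- joined$food_id[joined$animal_protein_g > 0 &
                          !(joined$food_id %in% allow_mixed)]
  if (length(bad) > 0) {
    abort(sprintf(
      "replacement food(s) with animal protein not flagged as mixed: %s",
      paste(utils::head(unique(bad), 5), collapse = ", ")
    ))
  }
  as_tibble(mapping)
}

#' Read an EAR reference table
#'
#' One Estimated Average Requirement per (nutrient, sex), in the nutrient's
#' own unit.  Covered nutrients must be a subset of [ear_nutrients()].
#'
#' @param path CSV with columns `nutrient`, `sex`, `ear_value`.
#' @return A tibble.
#' @export
read_ear_table <- function(path) {
  df <- read_csv_quiet(path, readr::cols(
    nutrient = readr::col_character(), sex = readr::col_character(),
    ear_value = readr::col_double()
  ))
  check_columns(df, c("nutrient", "sex", "ear_value"), "EAR", path)
  validate_ear_table(df)
}

#' @rdname read_ear_table
#' @param ear Tibble with `nutrient`, `sex`, `ear_value`.
#' @export
validate_ear_table <- function(ear) {
  extra <- setdiff(unique(ear$nutrient), ear_nutrients())
  if (length(extra) > 0) {
    abort(sprintf("EAR table covers unsupported nutrient(s): %s",
                  paste(extra, collapse = ", ")))
  }
  if (any(!is.finite(ear$ear_value) | ear$ear_value <= 0)) {
    abort("ear_value must be finite and > 0")
  }
  as_tibble(ear)
}

#' Check that every consumed food resolves in the food table
#'
#' @param records Consumption records.
#' @param food Food table.
#' @return `records`, invisibly.
#' @export
validate_consumption <- function(records, food) {
  unknown <- setdiff(unique(records$food_id), food$food_id)
  if (length(unknown) > 0) {
    abort(sprintf("consumption references unknown food_id(s): %s",
                  paste(utils::head(unknown, 5), collapse = ", ")))
  }
  invisible(records)
}

#' Flatten a scenario report to one tidy table
#'
#' Serialisation used by [write_report()]: one row per
#' (section, sex/slice, scenario, strategy, metric), with `value`, `lower`,
#' `upper` columns (`NA` where an interval does not apply).
#'
#' @param report A `scenario_report` as returned by [run_pipeline()], or an
#'   already-flat tibble (returned unchanged).
#' @return A tibble in deterministic column and row order.
#' @export
report_table <- function(report) {
  if (!inherits(report, "scenario_report")) return(as_tibble(report))
  sect <- function(df, section, slice_col, metric_cols) {
    if (is.null(df) || nrow(df) == 0) return(NULL)
    df %>%
      tidyr::pivot_longer(all_of(metric_cols), names_to = "metric",
                          values_to = "value") %>%
      mutate(section = section, slice = .data[[slice_col]]) %>%
      select(any_of(c("section", "slice", "scenario", "strategy",
                      "nutrient", "consumed_group", "metric", "value",
                      "lower", "upper")))
  }
  out <- bind_rows(
    report$habitual %>%
      rename(value = "mean") %>%
      mutate(section = "habitual", metric = "habitual_mean",
             slice = .data$sex) %>%
      select(all_of(c("section", "slice", "scenario", "strategy",
                      "nutrient", "metric", "value", "lower", "upper"))),
    report$adequacy %>%
      rename(value = "prop_below_ear") %>%
      mutate(section = "adequacy", metric = "prop_below_ear",
             slice = .data$sex) %>%
      select(all_of(c("section", "slice", "scenario", "strategy",
                      "nutrient", "metric", "value", "lower", "upper"))),
    report$plant_protein %>%
      rename(value = "share") %>%
      mutate(section = "plant_protein", metric = "plant_protein_share",
             slice = .data$sex) %>%
      select(all_of(c("section", "slice", "scenario", "strategy",
                      "metric", "value"))),
    report$footprints %>%
      tidyr::pivot_longer(-c("scenario", "strategy", "slice"),
                          names_to = "metric", values_to = "value") %>%
      mutate(section = "footprint") %>%
      select(all_of(c("section", "slice", "scenario", "strategy",
                      "metric", "value"))),
    report$contributions %>%
      rename(value = "share") %>%
      mutate(section = "contribution", metric = .data$indicator,
             slice = "total") %>%
      select(all_of(c("section", "slice", "scenario", "strategy",
                      "consumed_group", "metric", "value")))
  )
  out %>% arrange(.data$section, .data$slice, .data$scenario,
                  .data$strategy, .data$metric)
}

#' Write / read a flattened scenario report
#'
#' @param report A `scenario_report` or a flat report tibble.
#' @param path CSV destination.
#' @return `write_report()` returns `path` invisibly; `read_report()`
#'   returns the flat tibble (round-trips [report_table()] losslessly).
#' @export
write_report <- function(report, path) {
  readr::write_csv(report_table(report), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    section = readr::col_character(), slice = readr::col_character(),
    scenario = readr::col_character(), strategy = readr::col_character(),
    metric = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  as_tibble(df)
}

#' Write all tables of a (synthetic or real) survey bundle to a directory
#'
#' Emits `persons.csv`, `consumption.csv`, `food_composition.csv`,
#' `food_footprints.csv`, `food_groups.csv`, `replacement_mapping.csv`,
#' `ear.csv` and, when present, `ground_truth.csv`.
#'
#' @param data List with elements `persons`, `records`, `food`, `mapping`,
#'   `ear` and optionally `ground_truth` (as from [simulate_survey()]).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(data, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, f) readr::write_csv(df, file.path(dir, f),
                                        progress = FALSE)
  w(data$persons, "persons.csv")
  w(data$records, "consumption.csv")
  w(select(data$food, all_of(c("food_id", "name", tracked_nutrients()))),
    "food_composition.csv")
  w(select(data$food, all_of(c("food_id", footprint_indicators()))),
    "food_footprints.csv")
  w(select(data$food, all_of(c("food_id", "consumed_group",
                               "group_category", "is_red_meat"))),
    "food_groups.csv")
  w(data$mapping, "replacement_mapping.csv")
  w(data$ear, "ear.csv")
  if (!is.null(data$ground_truth)) {
    w(data$ground_truth$persons, "ground_truth.csv")
  }
  invisible(dir)
}

#' Read a survey bundle written by [write_survey()]
#'
#' @param dir Directory containing the CSV files.
#' @return A list with `persons`, `records`, `food`, `mapping`, `ear`.
#' @export
read_survey <- function(dir) {
  food <- read_food_table(file.path(dir, "food_composition.csv"),
                          file.path(dir, "food_footprints.csv"),
                          file.path(dir, "food_groups.csv"))
  records <- read_consumption(file.path(dir, "consumption.csv"))
  validate_consumption(records, food)
  list(
    persons = read_persons(file.path(dir, "persons.csv")),
    records = records,
    food = food,
    mapping = validate_mapping(
      read_replacement_mapping(file.path(dir, "replacement_mapping.csv")),
      food),
    ear = read_ear_table(file.path(dir, "ear.csv"))
  )
}
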