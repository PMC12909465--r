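# End-to-end orchestration: scenarios -> daily totals -> habitual models
# -> EAR adequacy -> plant-protein share -> footprints, with stratified
# person bootstrap CIs and CI-non-overlap flags versus the reference diet.

#' Pipeline run configuration
#'
#' @param scenarios Scenario names to run (reference is always included
#'   once, independent of strategy).
#' @param strategies Replacement strategies to run each scenario under.
#' @param master_seed Master seed; allocation and bootstrap streams are
#'   derived from it per (scenario, strategy) by stable hashing.
#' @param n_boot Bootstrap iterations for 95% CIs (default 200); `0`
#'   disables the bootstrap (point estimates only).
#' @param n_replicates_cv Replicates for the allocation-stability CV check
#'   (default 10); `0` disables it.
#' @param nutrients Nutrients to model habitually.
#' @param ear_threshold Inadequacy proportion above which a nutrient is
#'   flagged a potential public-health concern (default 0.10).
#' @param share_targets Plant-protein share reporting targets: current,
#'   short-term and long-term policy levels.
#' @return An object of class `run_config`.
#' @export
run_config <- function(scenarios = c("no_meat_and_dairy", "no_meat",
                                     "half_meat", "no_red_meat"),
                       strategies = c("quantity", "energy"),
                       master_seed = 1L, n_boot = 200,
                       n_replicates_cv = 10,
                       nutrients = tracked_nutrients(),
                       ear_threshold = 0.10,
                       share_targets = c(current = 0.40, short_term = 0.50,
                                         long_term = 0.60)) {
  stopifnot(ear_threshold > 0, ear_threshold < 1,
            all(share_targets > 0), all(share_targets < 1),
            all(strategies %in% c("quantity", "energy")),
            n_boot == 0 || n_boot >= 2)
  structure(
    list(scenarios = setdiff(scenarios, "reference"),
         strategies = strategies,
         master_seed = master_seed, n_boot = n_boot,
         n_replicates_cv = n_replicates_cv, nutrients = nutrients,
         ear_threshold = ear_threshold, share_targets = share_targets),
    class = "run_config"
  )
}

#' Plant-protein share of total protein
#'
#' Ratio of weighted-mean habitual plant protein to weighted-mean habitual
#' total protein (ratio of means, matching population-level reporting).
#'
#' @param plant,total Either [habitual_distribution()] objects for plant
#'   and total protein, or the two weighted means directly.
#' @return The share in `[0, 1]`.
#' @export
#' @examples
#' plant_protein_share(40, 100)
plant_protein_share <- function(plant, total) {
  val <- function(x) {
    if (inherits(x, "habitual_distribution")) x$summary$mean else x
  }
  p <- val(plant); t <- val(total)
  if (t == 0) abort("total protein is zero; share undefined")
  p / t
}

#' Classify a plant-protein share against policy targets
#'
#' @param share Share(s) in `[0, 1]`.
#' @param short_term,long_term Policy targets (defaults 0.50 and 0.60).
#' @return A tibble with `share`, `meets_short_term`, `meets_long_term`
#'   and a text `label`.
#' @export
#' @examples
#' classify_against_targets(c(0.40, 0.52, 0.61))
classify_against_targets <- function(share, short_term = 0.50,
                                     long_term = 0.60) {
  stopifnot(all(share >= 0), all(share <= 1))
  tibble(
    share = share,
    meets_short_term = share >= short_term,
    meets_long_term = share >= long_term,
    label = case_when(
      share >= long_term ~ "meets long-term target",
      share >= short_term ~ "meets short-term target",
      TRUE ~ "below short-term target"
    )
  )
}

# statistics for one bootstrap resample of one scenario dataset:
# per sex, habitual means for all nutrients, %<EAR for EAR nutrients and
# the plant-protein share.
combo_statistics <- function(daily, persons, config, ear) {
  out <- c()
  for (sx in intersect(c("female", "male"), unique(persons$sex))) {
    dists <- list()
    for (nm in unique(c(config$nutrients,
                        "plant_protein_g", "total_protein_g"))) {
      model <- suppressWarnings(
        fit_habitual_model(daily, persons, nm, sx))
      dists[[nm]] <- suppressWarnings(
        habitual_distribution(model, persons, daily))
    }
    means <- vapply(config$nutrients,
                    function(nm) dists[[nm]]$summary$mean, numeric(1))
    names(means) <- paste0(sx, ".mean_", config$nutrients)
    props <- c()
    ear_sx <- ear[ear$sex == sx, ]
    for (nm in intersect(ear_nutrients(), ear_sx$nutrient)) {
      props[paste0(sx, ".prop_below_", nm)] <-
        proportion_below(dists[[nm]],
                         ear_sx$ear_value[ear_sx$nutrient == nm])
    }
    share <- c()
    share[paste0(sx, ".plant_protein_share")] <-
      plant_protein_share(dists[["plant_protein_g"]],
                          dists[["total_protein_g"]])
    out <- c(out, means, props, share)
  }
  out
}

# full per-combo result: point estimates with percentiles, plus CIs
run_combo <- function(recs, data, config, combo_label, boot_seed) {
  daily <- nutrient_totals(recs, data$food)
  persons <- data$persons

  habitual <- list(); adequacy <- list(); shares <- list()
  for (sx in c("female", "male")) {
    dists <- list()
    for (nm in unique(c(config$nutrients,
                        "plant_protein_g", "total_protein_g"))) {
      model <- suppressWarnings(fit_habitual_model(daily, persons, nm, sx))
      dists[[nm]] <- suppressWarnings(
        habitual_distribution(model, persons, daily))
    }
    habitual[[sx]] <- purrr::map(config$nutrients, function(nm) {
      dists[[nm]]$summary %>% mutate(sex = sx)
    }) %>% bind_rows()
    ear_sx <- data$ear[data$ear$sex == sx, ]
    adequacy[[sx]] <- purrr::map(
      intersect(ear_nutrients(), ear_sx$nutrient), function(nm) {
        p <- proportion_below(dists[[nm]],
                              ear_sx$ear_value[ear_sx$nutrient == nm])
        tibble(sex = sx, nutrient = nm, prop_below_ear = p,
               flag_concern = p > config$ear_threshold)
      }) %>% bind_rows()
    shares[[sx]] <- tibble(
      sex = sx,
      share = plant_protein_share(dists[["plant_protein_g"]],
                                  dists[["total_protein_g"]])
    )
  }

  ci <- NULL
  if (config$n_boot >= 2) {
    ci <- bootstrap_ci(
      daily, persons,
      function(d, p) combo_statistics(d, p, config, data$ear),
      n_boot = config$n_boot, seed = boot_seed
    )
  }

  pd <- person_day_footprint(recs, data$food)
  footprints <- bind_rows(
    population_footprint(pd, persons, "total"),
    population_footprint(pd, persons, "women"),
    population_footprint(pd, persons, "men")
  )

  list(
    habitual = bind_rows(habitual), adequacy = bind_rows(adequacy),
    shares = bind_rows(shares), ci = ci, footprints = footprints,
    contributions = group_contributions(recs, data$food)
  )
}

attach_ci <- function(df, ci, stat_fn) {
  if (is.null(ci)) {
    df$lower <- NA_real_
    df$upper <- NA_real_
    df$differs_from_reference <- NA
    return(df)
  }
  key <- stat_fn(df)
  df$lower <- ci$lower[match(key, ci$statistic)]
  df$upper <- ci$upper[match(key, ci$statistic)]
  df
}

#' Run the full dietary-transition pipeline
#'
#' Applies every configured (scenario, strategy) combination plus the
#' reference to the consumption data; estimates sex-specific habitual
#' intake distributions for all configured nutrients; derives EAR
#' inadequacy with concern flags; computes plant-protein shares against
#' policy targets; computes survey-weighted footprints with relative
#' differences versus the reference; attaches stratified bootstrap 95% CIs
#' and CI-non-overlap flags versus the reference.  Fully deterministic
#' given `config$master_seed`.
#'
#' @param data Survey bundle: a list with `persons`, `records`, `food`,
#'   `mapping`, `ear` (e.g. from [simulate_survey()] or [read_survey()]),
#'   or a directory path understood by [read_survey()].
#' @param config A [run_config()].
#' @return An object of class `scenario_report`: a list of tibbles
#'   `habitual`, `adequacy`, `plant_protein`, `footprints`,
#'   `contributions`, `allocation_cv`, `log`.
#' @export
run_pipeline <- function(data, config = run_config()) {
  if (is.character(data)) data <- read_survey(data)
  validate_persons(data$persons)
  validate_food_table(data$food)
  validate_consumption(data$records, data$food)

  combos <- bind_rows(
    tibble(scenario = "reference", strategy = "none"),
    tidyr::expand_grid(scenario = config$scenarios,
                       strategy = config$strategies)
  )

  log <- list()
  results <- list()
  cv_rows <- list()
  for (i in seq_len(nrow(combos))) {
    sc <- combos$scenario[i]
    st <- combos$strategy[i]
    label <- paste(sc, st, sep = ".")
    spec <- default_scenarios(
      data$food,
      strategy = if (st == "none") "quantity" else st,
      master_seed = config$master_seed, names = sc
    )[[sc]]
    applied <- apply_scenario(data$records, data$food, data$mapping, spec)
    log[[label]] <- attr(applied$events, "log") %>%
      mutate(scenario = sc, strategy = st)

    res <- run_combo(applied$records, data, config, label,
                     boot_seed = child_seed(config$master_seed,
                                            paste("boot", label)))
    res$scenario <- sc
    res$strategy <- st
    results[[label]] <- res

    if (config$n_replicates_cv >= 2 && sc != "reference") {
      cv <- replicate_allocation_cv(
        data$records, data$food, data$mapping, spec,
        n_replicates = config$n_replicates_cv,
        outcome_fn = weighted_mean_intake_fn(data$food, data$persons,
                                             "total_protein_g")
      )
      cv_rows[[label]] <- cv %>% mutate(scenario = sc, strategy = st)
    }
  }

  ref <- results[["reference.none"]]

  habitual <- purrr::map(results, function(res) {
    attach_ci(res$habitual, res$ci,
              function(df) paste0(df$sex, ".mean_", df$nutrient)) %>%
      mutate(scenario = res$scenario, strategy = res$strategy)
  }) %>% bind_rows()
  adequacy <- purrr::map(results, function(res) {
    attach_ci(res$adequacy, res$ci,
              function(df) paste0(df$sex, ".prop_below_", df$nutrient)) %>%
      mutate(scenario = res$scenario, strategy = res$strategy)
  }) %>% bind_rows()

  if (!is.null(ref$ci)) {
    flags <- purrr::map(results, function(res) {
      compare_scenarios(res$ci, ref$ci) %>%
        mutate(scenario = res$scenario, strategy = res$strategy)
    }) %>% bind_rows()
    add_flag <- function(df, stat_fn) {
      key <- paste(stat_fn(df), df$scenario, df$strategy)
      fk <- paste(flags$statistic, flags$scenario, flags$strategy)
      df$differs_from_reference <- flags$different[match(key, fk)]
      df
    }
    habitual <- add_flag(habitual,
                         function(df) paste0(df$sex, ".mean_", df$nutrient))
    adequacy <- add_flag(adequacy, function(df)
      paste0(df$sex, ".prop_below_", df$nutrient))
  }

  plant_protein <- purrr::map(results, function(res) {
    res$shares %>%
      bind_cols(classify_against_targets(
        res$shares$share,
        short_term = config$share_targets[["short_term"]],
        long_term = config$share_targets[["long_term"]]
      ) %>% select(-"share")) %>%
      mutate(scenario = res$scenario, strategy = res$strategy)
  }) %>% bind_rows()

  ref_fp <- ref$footprints
  footprints <- purrr::map(results, function(res) {
    rel <- purrr::map(seq_len(nrow(res$footprints)), function(j) {
      footprint_relative_diff(res$footprints[j, ],
                              ref_fp[ref_fp$slice ==
                                       res$footprints$slice[j], ])
    }) %>% bind_rows()
    res$footprints %>%
      inner_join(rel, by = "slice") %>%
      mutate(scenario = res$scenario, strategy = res$strategy)
  }) %>% bind_rows()

  contributions <- purrr::map(results, function(res) {
    res$contributions %>%
      mutate(scenario = res$scenario, strategy = res$strategy)
  }) %>% bind_rows()

  structure(
    list(
      habitual = habitual %>%
        select(all_of(c("sex", "scenario", "strategy", "nutrient", "mean",
                        "lower", "upper", "p5", "p25", "p50", "p75", "p95",
                        "differs_from_reference"))),
      adequacy = adequacy %>%
        select(all_of(c("sex", "scenario", "strategy", "nutrient",
                        "prop_below_ear", "lower", "upper", "flag_concern",
                        "differs_from_reference"))),
      plant_protein = plant_protein %>%
        select(all_of(c("sex", "scenario", "strategy", "share",
                        "meets_short_term", "meets_long_term", "label"))),
      footprints = footprints %>%
        select(all_of(c("scenario", "strategy", "slice",
                        paste0(footprint_day_cols(), "_per_day"),
                        paste0(footprint_day_cols(), "_rel_diff_pct")))),
      contributions = contributions %>%
        select(all_of(c("scenario", "strategy", "consumed_group",
                        "indicator", "share"))),
      allocation_cv = bind_rows(cv_rows),
      log = bind_rows(log),
      config = config
    ),
    class = "scenario_report"
  )
}

#' @export
print.scenario_report <- function(x, ...) {
  n_sc <- n_distinct(paste(x$habitual$scenario, x$habitual$strategy))
  cat(sprintf(
    "Scenario report: %d scenario block(s), %d nutrients, bootstrap B = %d\n",
    n_sc, n_distinct(x$habitual$nutrient), x$config$n_boot))
  cat("Plant-protein shares:\n")
  print(x$plant_protein)
  invisible(x)
}
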