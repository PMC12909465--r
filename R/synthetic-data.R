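# Synthetic survey generator.  Every stage draws from its own child stream
# of the master seed, so regenerating any one table is deterministic and
# independent of the others.
#
# Generative model for intake: each person i carries a latent habitual
# level on the Box-Cox transformed scale,
#   H_i = mu_sex + age_slope * (age_i - 40) + b_i,    b_i ~ N(0, sigma_b^2)
# and each recall day j realises
#   T_ij = invBoxCox(H_i + e_ij, lambda),             e_ij ~ N(0, sigma_w^2)
# as the day's total energy intake.  A raw basket of eating occasions
# (Poisson occasion counts per group, uniform food choice within group,
# lognormal portions) is drawn once per person; each day consumes the same
# basket with all gram amounts rescaled so the day's energy equals T_ij
# exactly.  Energy therefore follows the assumed one-part
# measurement-error model exactly, and every other nutrient follows it too
# up to the person's fixed basket nutrient-to-energy ratio, which adds a
# small extra between-person variance component.

#' Generate the survey population
#'
#' Ages are uniform over 18-65 (integer years); survey weights are
#' lognormal and normalised to mean 1 within each sex, mimicking a
#' sociodemographic weighting factor.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble of persons (`person_id`, `sex`, `age`,
#'   `weight_factor`), deterministic given `spec$master_seed`.
#' @export
generate_population <- function(spec) {
  withr::with_seed(child_seed(spec$master_seed, "population"), {
    n <- spec$n_women + spec$n_men
    sex <- c(rep("female", spec$n_women), rep("male", spec$n_men))
    id <- c(sprintf("F%04d", seq_len(spec$n_women)),
            sprintf("M%04d", seq_len(spec$n_men)))
    persons <- tibble(
      person_id = id,
      sex = sex,
      age = sample(18:65, n, replace = TRUE),
      weight_factor = rlnorm(n, meanlog = 0, sdlog = 0.3)
    ) %>%
      group_by(.data$sex) %>%
      mutate(weight_factor = .data$weight_factor /
               mean(.data$weight_factor)) %>%
      ungroup()
    validate_persons(persons)
  })
}

#' Generate the food database and replacement mapping
#'
#' Emits `foods_per_group` foods per consumed group plus the plant-based
#' replacement groups.  Per-food densities and footprint factors scatter
#' around their group means with relative SD `spec$density_rel_sd`
#' (lognormal, mean-preserving); structural zeros (e.g. B12 in unfortified
#' plant foods) stay exactly zero.  Replacement-list sizes are drawn from
#' `1 + Binomial(alternatives_max - 1, p)` with mean `alternatives_mean`;
#' meat foods are flagged red meat with probability `spec$red_meat_prob`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `food` (one row per food, see [read_food_table()]
#'   for columns) and `mapping` (`consumed_group`, `food_id`).
#' @export
generate_food_database <- function(spec) {
  withr::with_seed(child_seed(spec$master_seed, "foods"), {
    grp <- spec$groups
    dens_cols <- c("energy_kcal", "plant_protein_g", "animal_protein_g",
                   "total_lipid_g", "safa_g", "fiber_g", "vita_ug",
                   "vitb12_ug", "vitb6_mg", "vitb2_mg", "calcium_mg",
                   "sodium_mg", footprint_indicators())

    repl <- grp[grp$category == "replacement", ]
    consumed <- grp[grp$category != "replacement", ]

    # replacement-list sizes: support [1, alternatives_max], mean target
    p_alt <- if (spec$alternatives_max > 1) {
      (spec$alternatives_mean - 1) / (spec$alternatives_max - 1)
    } else {
      0
    }
    n_per_group <- ifelse(
      grp$category == "replacement",
      1L + rbinom(nrow(grp), spec$alternatives_max - 1L, p_alt),
      spec$foods_per_group
    )

    food <- purrr::map2(seq_len(nrow(grp)), n_per_group, function(g, k) {
      row <- grp[g, ]
      out <- tibble(
        food_id = sprintf("%s_%02d", row$group, seq_len(k)),
        name = sprintf("%s item %d", gsub("_", " ", row$group), seq_len(k)),
        consumed_group = row$group,
        group_category = row$category
      )
      for (cn in dens_cols) {
        mu <- row[[cn]]
        if (spec$fortified_b12 && cn == "vitb12_ug" &&
            row$category == "replacement") {
          mu <- grp[[cn]][grp$group == row$replaces]
        }
        sdlog <- sqrt(log(1 + spec$density_rel_sd^2))
        out[[cn]] <- if (mu > 0) {
          rlnorm(k, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
        } else {
          rep(0, k)
        }
      }
      out$is_red_meat <- if (row$category == "meat") {
        runif(k) < spec$red_meat_prob
      } else {
        rep(FALSE, k)
      }
      out
    }) %>% bind_rows()

    food$total_protein_g <- food$plant_protein_g + food$animal_protein_g
    food <- select(food, all_of(c("food_id", "name", "consumed_group",
                                  "group_category", "is_red_meat",
                                  tracked_nutrients(),
                                  footprint_indicators())))

    mapping <- food %>%
      filter(.data$group_category == "replacement") %>%
      inner_join(select(grp, "group", "replaces"),
                 by = c("consumed_group" = "group")) %>%
      mutate(consumed_group = .data$replaces) %>%
      select(all_of(c("consumed_group", "food_id")))

    list(food = validate_food_table(food),
         mapping = validate_mapping(mapping, food))
  })
}

# Transformed-scale intercept mu so the population mean latent habitual
# energy invBoxCox(mu + age_slope*(age-40) + b) equals the target, with
# ages discrete-uniform on 18:65.  Closed form for lambda = 0; otherwise a
# Gauss-Hermite + age-average root-find.
solve_mu <- function(target, spec) {
  ages <- 18:65
  if (spec$lambda == 0) {
    log(target) - spec$sigma_b^2 / 2 -
      log(mean(exp(spec$age_slope * (ages - 40))))
  } else {
    gh <- gauss_hermite_std(30)
    f <- function(mu) {
      m <- outer(mu + spec$age_slope * (ages - 40), spec$sigma_b * gh$x, "+")
      mean(inv_box_cox(m, spec$lambda) %*% gh$w) - target
    }
    stats::uniroot(f, interval = box_cox(target, spec$lambda) + c(-5, 5),
                   extendInt = "yes")$root
  }
}

#' Generate two-recall consumption records with ground truth
#'
#' Each person's food basket — eating occasions per group (Poisson occasion
#' counts, at least one for staple groups so daily consumption of every
#' nutrient holds), uniform food choice within group, lognormal raw
#' portions — is drawn once and consumed on both recall days, with all of a
#' day's gram amounts rescaled so the day's total energy equals the latent
#' model's realisation exactly (see the file header for the model).
#' Because both days scale the same basket, every nutrient's transformed
#' daily intake carries exactly the within-person variance `sigma_w^2`; the
#' between-person variance of non-energy nutrients picks up a small extra
#' component from basket-composition differences between persons.
#'
#' @param population From [generate_population()].
#' @param food_db From [generate_food_database()].
#' @param spec The same [synthetic_spec()].
#' @return A list with `records` (consumption tibble) and `ground_truth`
#'   (list: `persons` tibble with the latent habitual intake of every
#'   tracked nutrient per person — the person's basket nutrient-to-energy
#'   ratio times the latent habitual energy — and `params` with the
#'   latent-model parameters).
#' @export
generate_consumption <- function(population, food_db, spec) {
  food <- food_db$food
  withr::with_seed(child_seed(spec$master_seed, "consumption"), {
    mu <- c(female = solve_mu(spec$mean_energy_kcal[["female"]], spec),
            male = solve_mu(spec$mean_energy_kcal[["male"]], spec))

    pers <- population %>%
      mutate(b = rnorm(n(), 0, spec$sigma_b),
             h = unname(mu[.data$sex]) +
               spec$age_slope * (.data$age - 40) + .data$b)

    days <- tidyr::expand_grid(person_id = pers$person_id,
                               day_index = 1:2) %>%
      inner_join(select(pers, "person_id", "h"), by = "person_id") %>%
      mutate(e = rnorm(n(), 0, spec$sigma_w),
             target_energy = inv_box_cox(.data$h + .data$e, spec$lambda))

    grp <- spec$groups %>% filter(.data$category != "replacement")
    basket <- tidyr::expand_grid(
      person_id = pers$person_id,
      grp %>% select("group", "staple", "rate", "amount_g")
    ) %>%
      mutate(n_occ = rpois(n(), .data$rate),
             n_occ = ifelse(.data$staple, pmax(.data$n_occ, 1L),
                            .data$n_occ)) %>%
      filter(.data$n_occ > 0) %>%
      tidyr::uncount(.data$n_occ)

    fpg <- spec$foods_per_group
    basket <- basket %>%
      mutate(
        food_id = sprintf("%s_%02d", .data$group,
                          as.integer(ceiling(runif(n()) * fpg))),
        amount_raw = rlnorm(n(),
                            meanlog = log(.data$amount_g) -
                              spec$amount_sdlog^2 / 2,
                            sdlog = spec$amount_sdlog)
      )

    # pin each person's group-level energy composition at its expected
    # share: the latent model carries no diet-composition heterogeneity,
    # so between-person variation lives in the overall scale (b_i), the
    # food choices within groups and the survey design, not in how much
    # of the diet each group supplies
    ed_food <- setNames(food$energy_kcal / 100, food$food_id)
    group_ed <- food %>%
      filter(.data$group_category != "replacement") %>%
      group_by(.data$consumed_group) %>%
      summarise(mean_ed = mean(.data$energy_kcal) / 100, .groups = "drop")
    target_w <- grp %>%
      inner_join(group_ed, by = c("group" = "consumed_group")) %>%
      mutate(w_energy = .data$rate * .data$amount_g * .data$mean_ed) %>%
      select("group", "w_energy")
    basket <- basket %>%
      mutate(kcal_raw = .data$amount_raw * ed_food[.data$food_id]) %>%
      inner_join(target_w, by = "group") %>%
      group_by(.data$person_id, .data$group) %>%
      mutate(amount_raw = .data$amount_raw * .data$w_energy /
               sum(.data$kcal_raw)) %>%
      ungroup()

    dens <- food[match(basket$food_id, food$food_id), tracked_nutrients()]
    basket_tot <- bind_cols(basket["person_id"],
                            basket$amount_raw * dens / 100) %>%
      group_by(.data$person_id) %>%
      summarise(across(all_of(tracked_nutrients()), sum), .groups = "drop")

    scale_tbl <- days %>%
      inner_join(select(basket_tot, "person_id", raw = "energy_kcal"),
                 by = "person_id") %>%
      mutate(scale = .data$target_energy / .data$raw)

    records <- tidyr::expand_grid(day_index = 1:2, basket) %>%
      inner_join(select(scale_tbl, "person_id", "day_index", "scale"),
                 by = c("person_id", "day_index")) %>%
      mutate(amount_g = .data$amount_raw * .data$scale) %>%
      arrange(.data$person_id, .data$day_index) %>%
      select(all_of(c("person_id", "day_index", "food_id", "amount_g")))

    latent_energy <- setNames(inv_box_cox(pers$h, spec$lambda),
                              pers$person_id)
    gt_persons <- select(pers, "person_id", "sex", "age", "b")
    bt <- basket_tot[match(gt_persons$person_id, basket_tot$person_id), ]
    for (nm in tracked_nutrients()) {
      gt_persons[[paste0("habitual_", nm)]] <-
        (bt[[nm]] / bt$energy_kcal) *
        latent_energy[gt_persons$person_id]
    }

    list(
      records = records,
      ground_truth = list(
        persons = gt_persons,
        params = list(mu = mu, sigma_b = spec$sigma_b,
                      sigma_w = spec$sigma_w, lambda = spec$lambda,
                      age_slope = spec$age_slope)
      )
    )
  })
}

#' Plant an EAR table at known quantiles of the latent habitual distribution
#'
#' For each EAR nutrient and sex, the EAR is set to the empirical
#' `quantile` of the generator's latent habitual intakes, so the expected
#' population inadequacy is the quantile itself, by construction.
#'
#' @param ground_truth The `ground_truth` element of
#'   [generate_consumption()].
#' @param quantile Target latent quantile(s), recycled over
#'   [ear_nutrients()].
#' @return An EAR tibble (`nutrient`, `sex`, `ear_value`, `quantile`).
#' @export
generate_ear_table <- function(ground_truth, quantile = 0.10) {
  qs <- rep_len(quantile, length(ear_nutrients()))
  gt <- ground_truth$persons
  purrr::map2(ear_nutrients(), qs, function(nm, q) {
    gt %>%
      group_by(.data$sex) %>%
      summarise(
        ear_value = stats::quantile(.data[[paste0("habitual_", nm)]], q,
                                    names = FALSE, type = 7),
        .groups = "drop"
      ) %>%
      mutate(nutrient = nm, quantile = q)
  }) %>%
    bind_rows() %>%
    select(all_of(c("nutrient", "sex", "ear_value", "quantile")))
}

#' Generate a complete synthetic survey bundle
#'
#' Convenience wrapper running [generate_population()],
#' [generate_food_database()], [generate_consumption()] and
#' [generate_ear_table()] from one spec.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `persons`, `food`, `mapping`, `records`,
#'   `ground_truth`, `ear` and the `spec` itself.
#' @export
#' @examples
#' survey <- simulate_survey(synthetic_spec(n_women = 30, n_men = 30,
#'                                          master_seed = 7))
#' nrow(survey$persons)
simulate_survey <- function(spec) {
  persons <- generate_population(spec)
  food_db <- generate_food_database(spec)
  cons <- generate_consumption(persons, food_db, spec)
  ear <- generate_ear_table(cons$ground_truth, spec$ear_quantile)
  list(persons = persons, food = food_db$food, mapping = food_db$mapping,
       records = cons$records, ground_truth = cons$ground_truth,
       ear = ear, spec = spec)
}
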