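# Usual-intake model: degenerate cases, closed-form oracles, shrinkage
# and the bootstrap.

test_that("zero within-person variation gives sigma_w = 0 and no shrinkage", {
  vals <- list(a = c(10, 10), b = c(20, 20), c = c(16, 16), d = c(12, 12))
  daily <- daily_from_values(vals)
  persons <- persons_for(names(vals), age = c(20, 30, 40, 50))
  fit <- fit_habitual_model(daily, persons, "energy_kcal", "female")
  expect_equal(fit$sigma_w, 0)
  dist <- habitual_distribution(fit, persons, daily)
  expect_equal(dist$persons$habitual[match(names(vals),
                                           dist$persons$person_id)],
               vapply(vals, mean, numeric(1)), ignore_attr = TRUE,
               tolerance = 1e-9)
})

test_that("constant intakes collapse to a degenerate model", {
  vals <- list(a = c(5, 5), b = c(5, 5), c = c(5, 5))
  daily <- daily_from_values(vals)
  persons <- persons_for(names(vals), age = c(25, 40, 55))
  fit <- suppressWarnings(
    fit_habitual_model(daily, persons, "energy_kcal", "female"))
  expect_equal(fit$sigma_b, 0)
  expect_equal(fit$sigma_w, 0)
  expect_equal(unname(fit$age_fn[["age"]]), 0, tolerance = 1e-12)
})

test_that("lambda = 1 preserves the weighted grand mean exactly", {
  set.seed(61)
  n <- 60
  ids <- sprintf("p%03d", seq_len(n))
  vals <- lapply(stats::setNames(ids, ids),
                 function(i) 100 + stats::rnorm(2, sd = 8))
  daily <- daily_from_values(vals)
  persons <- persons_for(ids, age = sample(18:65, n, replace = TRUE),
                         weight = stats::runif(n, 0.5, 2))
  # no between-person component in these values, so the truncation at
  # zero is expected; mean preservation must hold regardless
  fit <- suppressWarnings(
    fit_habitual_model(daily, persons, "energy_kcal", "female",
                       lambda = 1))
  dist <- habitual_distribution(fit, persons, daily)
  joined <- dplyr::inner_join(daily, persons, by = "person_id")
  grand <- sum(joined$weight_factor * joined$energy_kcal) /
    sum(joined$weight_factor)
  expect_equal(dist$summary$mean, grand, tolerance = 1e-9)
})

test_that("lognormal truth: habitual mean matches exp(mu + sigma_b^2/2)", {
  set.seed(71)
  n <- 8000
  mu <- log(2000)
  sb <- 0.3
  sw <- 0.5
  ids <- sprintf("p%04d", seq_len(n))
  b <- stats::rnorm(n, 0, sb)
  daily <- daily_from_values(stats::setNames(
    lapply(seq_len(n), function(i) exp(mu + b[i] + stats::rnorm(2, 0, sw))),
    ids))
  persons <- persons_for(ids)
  fit <- fit_habitual_model(daily, persons, "energy_kcal", "female")
  dist <- habitual_distribution(fit, persons, daily)
  expect_equal(dist$summary$mean, exp(mu + sb^2 / 2), tolerance = 0.02)

  # cutoff below the smallest / above the largest habitual value
  expect_equal(proportion_below(dist, min(dist$values$value) / 2), 0)
  expect_equal(proportion_below(dist, max(dist$values$value) * 2), 1)
})

test_that("cut-point proportions match the normal CDF and are monotone", {
  set.seed(81)
  n <- 4000
  ids <- sprintf("p%04d", seq_len(n))
  h <- stats::rnorm(n, 20, 5)
  daily <- daily_from_values(stats::setNames(
    lapply(seq_len(n), function(i) h[i] + stats::rnorm(2, 0, 4)), ids))
  daily$energy_kcal <- pmax(daily$energy_kcal, 0.1)
  persons <- persons_for(ids)
  fit <- fit_habitual_model(daily, persons, "energy_kcal", "female",
                            lambda = 1)
  dist <- habitual_distribution(fit, persons, daily)
  # habitual ~ Normal(20, 5): P(X < 14) = pnorm(-1.2) = 0.1151
  expect_equal(proportion_below(dist, 14), stats::pnorm(-1.2),
               tolerance = 0.01 / 0.1151)

  ears <- c(10, 14, 18, 22)
  props <- vapply(ears, function(e) proportion_below(dist, e), numeric(1))
  expect_true(all(diff(props) >= 0))
})

test_that("habitual distribution is never wider than person means", {
  survey <- tiny_survey()
  daily <- nutrient_totals(survey$records, survey$food)
  wv <- function(x, w) {
    m <- sum(w * x) / sum(w)
    sum(w * (x - m)^2) / sum(w)
  }
  for (nm in c("energy_kcal", "total_protein_g", "calcium_mg")) {
    for (sx in c("female", "male")) {
      fit <- suppressWarnings(
        fit_habitual_model(daily, survey$persons, nm, sx))
      dist <- habitual_distribution(fit, survey$persons, daily)
      pm <- dplyr::inner_join(daily, survey$persons, by = "person_id") %>%
        dplyr::filter(.data$sex == sx) %>%
        dplyr::group_by(.data$person_id) %>%
        dplyr::summarise(m = mean(.data[[nm]]),
                         w = dplyr::first(.data$weight_factor),
                         .groups = "drop")
      var_habitual <- wv(dist$values$value, dist$values$weight)
      var_pm <- wv(pm$m, pm$w)
      expect_lte(var_habitual, var_pm * (1 + 1e-9))
    }
  }
})

test_that("bootstrap collapses for identical persons and is seeded", {
  vals <- rep(list(c(10, 14)), 8)
  names(vals) <- sprintf("p%02d", 1:8)
  daily <- daily_from_values(vals)
  persons <- persons_for(names(vals))
  stat_fn <- function(d, p) {
    fit <- suppressWarnings(
      fit_habitual_model(d, p, "energy_kcal", "female"))
    c(mean = habitual_distribution(fit, p, d)$summary$mean)
  }
  ci <- bootstrap_ci(daily, persons, stat_fn, n_boot = 20, seed = 9)
  point <- stat_fn(daily, persons)
  expect_equal(ci$lower, unname(point["mean"]), tolerance = 1e-12)
  expect_equal(ci$upper, unname(point["mean"]), tolerance = 1e-12)

  # deterministic given the seed
  survey <- tiny_survey()
  daily2 <- nutrient_totals(survey$records, survey$food)
  stat2 <- function(d, p) {
    fit <- suppressWarnings(
      fit_habitual_model(d, p, "total_protein_g", "female"))
    c(mean = habitual_distribution(fit, p, d)$summary$mean)
  }
  ci_a <- bootstrap_ci(daily2, survey$persons, stat2, n_boot = 15,
                       seed = 3)
  ci_b <- bootstrap_ci(daily2, survey$persons, stat2, n_boot = 15,
                       seed = 3)
  expect_identical(ci_a, ci_b)
  expect_lt(ci_a$lower, ci_a$upper)
})

test_that("bootstrap defaults to 200 iterations and aborts after redraws", {
  expect_equal(formals(bootstrap_ci)$n_boot, 200)
  n_calls <- 0L
  counter <- function(d, p) {
    n_calls <<- n_calls + 1L
    c(s = 1)
  }
  vals <- list(a = c(1, 2), b = c(2, 3))
  daily <- daily_from_values(vals)
  persons <- persons_for(names(vals))
  ci <- bootstrap_ci(daily, persons, counter, seed = 1)
  expect_equal(n_calls, 200L)

  fail_fn <- function(d, p) stop("always fails")
  expect_error(bootstrap_ci(daily, persons, fail_fn, n_boot = 20,
                            seed = 1),
               "resamples failed")
})

test_that("CI non-overlap flags scenario differences", {
  a <- tibble::tibble(statistic = "m", lower = 1, upper = 2)
  b <- tibble::tibble(statistic = "m", lower = 3, upper = 4)
  expect_true(compare_scenarios(a, b)$different)
  c <- tibble::tibble(statistic = "m", lower = 1, upper = 3)
  d <- tibble::tibble(statistic = "m", lower = 2, upper = 4)
  expect_false(compare_scenarios(c, d)$different)
  expect_false(compare_scenarios(a, a)$different)
})

test_that("persons with a single recall day are dropped with a warning", {
  vals <- list(a = c(10, 12), b = c(11, 13), c = 9)
  daily <- daily_from_values(vals)
  persons <- persons_for(names(vals))
  suppressWarnings(expect_warning(
    fit <- fit_habitual_model(daily, persons, "energy_kcal", "female"),
    "fewer than 2"
  ))
  expect_equal(fit$n_persons, 2)
  expect_equal(fit$n_dropped, 1L)
})
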