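# One-part usual-intake model for components consumed daily by everyone.
#
# Daily intakes Y_ij (person i, recall day j) are Box-Cox transformed with
# a power chosen on the grid {0, 0.05, ..., 1}; on the transformed scale
#   g(Y_ij) = beta0 + beta1 * age_i + b_i + e_ij,
#   b_i ~ N(0, sigma_b^2)  (between persons),
#   e_ij ~ N(0, sigma_w^2) (within person, day-to-day),
# with survey weights entering both the fit and all population summaries.
# The transform is normalised by the weighted geometric mean gm of the
# intakes, t = ((y^lambda - 1)/lambda) / gm^lambda, so that variance
# components are on a comparable (log-like) scale for every lambda on the
# grid and the profile log-likelihood reduces to -0.5*W*log(sigma2(lambda)).
# Variance components come from weighted moments: sigma_w^2 from
# within-person residual scatter, sigma_b^2 from person-mean residual
# variance minus its within-person share (truncated at zero).
#
# The habitual (usual) intake distribution is reconstructed per person by
# shrinking the person-mean residual towards the age trend,
#   h_i = age_fn(age_i) + k_i * rbar_i,  k_i = sigma_b^2 / (sigma_b^2 +
#                                               sigma_w^2 / d_i),
# and re-expanding with the variance the shrinkage removed,
# s_i^2 = sigma_b^2 (1 - k_i), via fixed 30-node Gauss-Hermite quadrature
# before inverse transformation.  The resulting weighted node values have
# transformed-scale marginal distribution N(age_fn, sigma_b^2), so the
# population mean on the original scale is unbiased and tail proportions
# (the EAR cut-point method) are not shrunken.

bc_grid <- function() seq(0, 1, by = 0.05)

# base-R fast path: this runs inside every bootstrap resample
prepare_daily <- function(daily_intakes, persons, nutrient, sex) {
  stopifnot(nutrient %in% names(daily_intakes))
  pidx <- match(daily_intakes$person_id, persons$person_id)
  keep <- !is.na(pidx) & persons$sex[pidx] == sex
  pidx <- pidx[keep]
  df <- list(
    person_id = daily_intakes$person_id[keep],
    day_index = daily_intakes$day_index[keep],
    age = persons$age[pidx],
    weight_factor = persons$weight_factor[pidx],
    intake = daily_intakes[[nutrient]][keep]
  )
  mk_f <- function(ids) factor(ids, levels = unique(ids))
  f <- mk_f(df$person_id)
  cnt <- tabulate(f, nbins = nlevels(f))
  short <- cnt[as.integer(f)] < 2
  n_dropped <- sum(cnt < 2)
  if (n_dropped > 0) {
    warn(sprintf("%d person(s) with fewer than 2 recall days dropped",
                 n_dropped))
    df <- lapply(df, function(col) col[!short])
    f <- mk_f(df$person_id)
  }
  if (length(df$person_id) == 0) {
    abort(sprintf("no %s persons with >= 2 recall days for %s",
                  sex, nutrient))
  }
  df$pf <- f
  df$n_dropped <- n_dropped
  df
}

# per-person aggregates of a prepared daily list: days, residual means,
# within-person residual sum of squares, first age/weight.  Levels of
# df$pf are in first-appearance order, so tabulate/rowsum/match align.
person_aggregate <- function(df, resid) {
  f <- df$pf
  d <- tabulate(f, nbins = nlevels(f))
  sum_r <- rowsum(resid, f, reorder = FALSE)[, 1]
  sum_r2 <- rowsum(resid^2, f, reorder = FALSE)[, 1]
  first <- match(levels(f), df$person_id)
  list(
    person_id = levels(f),
    d = d,
    rbar = sum_r / d,
    ss_within = sum_r2 - (sum_r^2) / d,
    age = df$age[first],
    weight_factor = df$weight_factor[first]
  )
}

#' Fit the one-part habitual-intake model
#'
#' Estimates, for one nutrient and one sex: the Box-Cox power `lambda`
#' (grid 0 to 1 in steps of 0.05, chosen by the weighted profile
#' log-likelihood), a linear age trend on the transformed scale (weighted
#' least squares), and the between-/within-person standard deviations
#' `sigma_b`, `sigma_w` from weighted moments of the residuals.  Zero
#' intakes are handled by shifting all values up by half the smallest
#' positive intake (recorded in the fit).  Persons with fewer than two
#' recall days are dropped with a warning; a negative between-person
#' variance estimate is truncated at zero with a warning.
#'
#' @param daily_intakes Per-person-day intake table as from
#'   [nutrient_totals()] (columns `person_id`, `day_index`, nutrients).
#' @param persons Person table (`person_id`, `sex`, `age`,
#'   `weight_factor`).
#' @param nutrient Column of `daily_intakes` to model.
#' @param sex `"female"` or `"male"`.
#' @param lambda Optional fixed Box-Cox power in `[0, 1]`; by default the
#'   power is chosen from the grid by profile likelihood.
#' @return An object of class `habitual_model`; see [tidy()] and
#'   [glance()] methods.
#' @export
#' @examples
#' survey <- simulate_survey(synthetic_spec(n_women = 60, n_men = 0,
#'                                          master_seed = 3))
#' daily <- nutrient_totals(survey$records, survey$food)
#' fit <- fit_habitual_model(daily, survey$persons, "energy_kcal", "female")
#' glance(fit)
fit_habitual_model <- function(daily_intakes, persons, nutrient, sex,
                               lambda = NULL) {
  df <- prepare_daily(daily_intakes, persons, nutrient, sex)

  shift <- 0
  if (any(df$intake <= 0)) {
    pos <- df$intake[df$intake > 0]
    if (length(pos) == 0) abort("all intakes are zero; nothing to model")
    shift <- min(pos) / 2
  }
  y <- df$intake + shift
  w <- df$weight_factor
  x <- cbind(1, df$age)
  gm <- exp(wmean(log(y), w))

  grid <- if (is.null(lambda)) bc_grid() else lambda
  sw <- sqrt(w)
  xs <- x * sw
  profile <- vapply(grid, function(lam) {
    t <- box_cox(y, lam) / gm^lam
    r <- stats::.lm.fit(xs, t * sw)$residuals
    -0.5 * sum(w) * log(sum(r^2) / sum(w))
  }, numeric(1))
  lambda <- grid[which.max(profile)]

  t <- box_cox(y, lambda) / gm^lambda
  fit <- stats::.lm.fit(xs, t * sw)
  beta <- numeric(ncol(xs))
  beta[fit$pivot] <- fit$coefficients
  resid <- as.vector(t - x %*% beta)

  per <- person_aggregate(df, as.vector(resid))

  sigma_w2 <- sum(per$weight_factor * per$ss_within / (per$d - 1)) /
    sum(per$weight_factor)
  vb_raw <- wvar(per$rbar, per$weight_factor) -
    wmean(sigma_w2 / per$d, per$weight_factor)
  truncated <- vb_raw < 0
  if (truncated) {
    warn(sprintf("between-person variance truncated at 0 for %s (%s)",
                 nutrient, sex))
  }
  sigma_b2 <- max(0, vb_raw)

  structure(
    list(
      nutrient = nutrient, sex = sex, lambda = lambda,
      age_fn = c(intercept = beta[1], age = beta[2]),
      sigma_b = sqrt(max(0, sigma_b2)), sigma_w = sqrt(sigma_w2),
      gm = gm, zero_shift = shift, truncated_sigma_b = truncated,
      n_persons = length(per$person_id), n_obs = length(y),
      n_dropped = df$n_dropped,
      log_lik = max(profile)
    ),
    class = "habitual_model"
  )
}

#' @export
print.habitual_model <- function(x, ...) {
  cat(sprintf(
    "Habitual-intake model: %s (%s)\n  lambda = %.2f, sigma_b = %.4f, sigma_w = %.4f\n  age trend: %.4f + %.5f * age (transformed scale)\n  %d persons, %d recall days%s\n",
    x$nutrient, x$sex, x$lambda, x$sigma_b, x$sigma_w,
    x$age_fn[["intercept"]], x$age_fn[["age"]], x$n_persons, x$n_obs,
    if (x$zero_shift > 0) sprintf(", zero-shift %.3g", x$zero_shift) else ""
  ))
  invisible(x)
}

#' @describeIn fit_habitual_model Tidy the fitted parameters
#'   (broom-style: one row per parameter).
#' @param x A `habitual_model`.
#' @param ... Unused.
#' @method tidy habitual_model
#' @export
tidy.habitual_model <- function(x, ...) {
  tibble(
    term = c("lambda", "intercept", "age_slope", "sigma_b", "sigma_w"),
    estimate = c(x$lambda, x$age_fn[["intercept"]], x$age_fn[["age"]],
                 x$sigma_b, x$sigma_w)
  )
}

#' @describeIn fit_habitual_model One-row model summary.
#' @method glance habitual_model
#' @export
glance.habitual_model <- function(x, ...) {
  tibble(
    nutrient = x$nutrient, sex = x$sex, lambda = x$lambda,
    sigma_b = x$sigma_b, sigma_w = x$sigma_w, zero_shift = x$zero_shift,
    truncated_sigma_b = x$truncated_sigma_b, n_persons = x$n_persons,
    n_obs = x$n_obs, n_dropped = x$n_dropped, log_lik = x$log_lik
  )
}

#' Reconstruct the habitual-intake distribution
#'
#' Applies the fitted model to the observed persons: shrinks each person's
#' mean residual towards the age trend, re-expands the removed variance
#' through fixed 30-node Gauss-Hermite quadrature, back-transforms, and
#' weights by the survey weight.  The returned object carries both the
#' per-person habitual values (conditional means) and the full weighted
#' node expansion that represents the estimated population distribution;
#' quantiles and EAR cut-point proportions are read from the latter.
#' Back-transform bases that would be negative (possible when
#' `lambda > 0`) are clamped at zero and counted in `n_clamped`.
#'
#' @param model A fitted [fit_habitual_model()].
#' @param persons Person table.
#' @param daily_intakes The same per-person-day intake table used for the
#'   fit.
#' @param n_nodes Number of Gauss-Hermite nodes.
#' @return An object of class `habitual_distribution` with elements
#'   `persons` (person-level habitual means), `values` (node-expanded
#'   weighted distribution values), `summary` (weighted mean and
#'   percentiles p5, p25, p50, p75, p95).
#' @export
habitual_distribution <- function(model, persons, daily_intakes,
                                  n_nodes = 30L) {
  df <- prepare_daily(daily_intakes, persons, model$nutrient, model$sex)
  t <- box_cox(df$intake + model$zero_shift, model$lambda) /
    model$gm^model$lambda
  resid <- t - (model$age_fn[["intercept"]] +
                  model$age_fn[["age"]] * df$age)

  per <- person_aggregate(df, resid)

  vb <- model$sigma_b^2
  vw <- model$sigma_w^2
  denom <- vb + vw / per$d
  k <- ifelse(denom > 0, vb / denom, 1)
  per$h <- model$age_fn[["intercept"]] + model$age_fn[["age"]] * per$age +
    k * per$rbar
  per$s <- sqrt(vb * (1 - k))

  gh <- gauss_hermite_std(n_nodes)
  n_per <- length(per$person_id)
  tmat <- (outer(per$h, rep(1, n_nodes)) + outer(per$s, gh$x)) *
    model$gm^model$lambda
  n_clamped <- n_neg_base(tmat, model$lambda)
  vmat <- pmax(inv_box_cox(tmat, model$lambda) - model$zero_shift, 0)

  per$habitual <- as.vector(vmat %*% gh$w)
  values <- tibble(
    person_id = rep(per$person_id, times = n_nodes),
    value = as.vector(vmat),
    weight = rep(per$weight_factor, times = n_nodes) *
      rep(gh$w, each = n_per)
  )

  summary <- tibble(
    nutrient = model$nutrient, sex = model$sex,
    mean = wmean(values$value, values$weight),
    p5 = wquantile(values$value, values$weight, 0.05),
    p25 = wquantile(values$value, values$weight, 0.25),
    p50 = wquantile(values$value, values$weight, 0.50),
    p75 = wquantile(values$value, values$weight, 0.75),
    p95 = wquantile(values$value, values$weight, 0.95)
  )

  structure(
    list(
      nutrient = model$nutrient, sex = model$sex, model = model,
      persons = tibble(person_id = per$person_id, age = per$age,
                       weight_factor = per$weight_factor, d = per$d,
                       habitual = per$habitual),
      values = values, summary = summary, n_clamped = n_clamped
    ),
    class = "habitual_distribution"
  )
}

#' @export
print.habitual_distribution <- function(x, ...) {
  cat(sprintf("Habitual-intake distribution: %s (%s), %d persons\n",
              x$nutrient, x$sex, nrow(x$persons)))
  print(x$summary)
  invisible(x)
}

#' Weighted proportion of the habitual distribution below a cutoff
#'
#' The EAR cut-point method: the weighted fraction of habitual-intake
#' distribution values strictly below the cutoff.
#'
#' @param distribution A [habitual_distribution()].
#' @param ear Positive cutoff in the nutrient's unit.
#' @return A proportion in `[0, 1]`.
#' @export
proportion_below <- function(distribution, ear) {
  stopifnot(ear > 0)
  v <- distribution$values
  wmean(as.numeric(v$value < ear), v$weight)
}

#' Person-level stratified bootstrap confidence intervals
#'
#' Resamples persons with replacement within sex strata — both recall days
#' of a resampled person travel together — re-runs `pipeline_fn` on each
#' resample and returns percentile 95% intervals per statistic.  A
#' resample on which `pipeline_fn` fails is redrawn (at most 5% of
#' `n_boot` redraws, then an error).
#'
#' @param records Consumption records (post-scenario).
#' @param persons Person table.
#' @param pipeline_fn Function `(records, persons) -> named numeric`
#'   recomputing the statistics from scratch (refit included).
#' @param n_boot Number of bootstrap iterations (default 200).
#' @param seed Integer seed; results are deterministic given it.
#' @return A tibble with `statistic`, `lower`, `upper` and attribute
#'   `n_redrawn`.
#' @export
bootstrap_ci <- function(records, persons, pipeline_fn, n_boot = 200,
                         seed = 1L) {
  stopifnot(n_boot >= 2)
  rec_by_person <- split(seq_len(nrow(records)), records$person_id)
  strata <- split(seq_len(nrow(persons)), persons$sex)
  max_redraw <- ceiling(0.05 * n_boot)

  draw_one <- function() {
    pick <- unlist(purrr::map(strata, ~ .x[sample.int(length(.x),
                                                      length(.x),
                                                      replace = TRUE)]),
                   use.names = FALSE)
    boot_persons <- persons[pick, , drop = FALSE]
    orig_id <- boot_persons$person_id
    boot_persons$person_id <- sprintf("b%05d", seq_along(pick))
    rows <- rec_by_person[orig_id]
    boot_records <- records[unlist(rows, use.names = FALSE), ,
                            drop = FALSE]
    boot_records$person_id <- rep(boot_persons$person_id,
                                  times = lengths(rows))
    pipeline_fn(boot_records, boot_persons)
  }

  withr::with_seed(seed, {
    n_redrawn <- 0L
    stats <- vector("list", n_boot)
    for (i in seq_len(n_boot)) {
      repeat {
        res <- tryCatch(draw_one(), error = function(e) e)
        if (!inherits(res, "error")) break
        n_redrawn <- n_redrawn + 1L
        if (n_redrawn > max_redraw) {
          abort(sprintf(
            "bootstrap: more than %d resamples failed; last error: %s",
            max_redraw, conditionMessage(res)
          ))
        }
      }
      stats[[i]] <- res
    }
    m <- do.call(rbind, stats)
    out <- tibble(
      statistic = colnames(m),
      lower = unname(apply(m, 2, quantile, probs = 0.025, names = FALSE)),
      upper = unname(apply(m, 2, quantile, probs = 0.975, names = FALSE))
    )
    attr(out, "n_redrawn") <- n_redrawn
    out
  })
}

#' Flag statistically distinguishable estimates by CI non-overlap
#'
#' Two estimates are flagged `different` exactly when their 95% bootstrap
#' intervals are disjoint.
#'
#' @param estimates_a,estimates_b Tibbles with `statistic`, `lower`,
#'   `upper` (as from [bootstrap_ci()]), matched on `statistic`.
#' @return A tibble with `statistic` and logical `different`.
#' @export
compare_scenarios <- function(estimates_a, estimates_b) {
  inner_join(estimates_a, estimates_b, by = "statistic",
             suffix = c("_a", "_b")) %>%
    mutate(different = .data$upper_a < .data$lower_b |
             .data$upper_b < .data$lower_a) %>%
    select("statistic", "different")
}
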