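# Marginal ratios, national totals via the separate ratio estimator,
# crude and truncated age-standardized rates, and period summaries.

# Fixed-effect design rows for a prediction grid, using the basis and
# year coding of the fit.
fixed_design_rows <- function(fit, grid) {
  b <- natural_cubic_basis(age_centers(grid$age_cat), fit$internal_knots,
                           fit$boundary_knots)
  sex2 <- as.numeric(grid$sex == 2)
  x <- cbind(1, sex2, grid$year - fit$year_origin, b, sex2 * b[, 3])
  colnames(x) <- names(fit$coefficients)
  x
}

#' Marginal expected HLIs per stay
#'
#' The expectation of the stratum ratio averaged over the random-effects
#' distribution.  With normal random intercepts at the two levels, the
#' moment generating function gives the lognormal correction, so
#' `alpha_hat = exp(x'beta + sigma1^2/2 + sigma2^2/2)`.
#'
#' @param fit An `hli_fit`.
#' @param grid Data frame with columns `sex`, `age_cat`, `year`;
#'   `NULL` for the full 2 x 15 grid over `years`.
#' @param years Years for the default grid (default: the fitting years).
#'   Years outside the fitting range trigger an extrapolation warning.
#' @return Data frame `sex`, `age_cat`, `year`, `alpha_hat`, with the
#'   fixed-effect design rows in attribute `X`.
#' @export
marginal_ratio <- function(fit, grid = NULL, years = NULL) {
  if (!inherits(fit, "hli_fit"))
    hli_error("fit must come from fit_pql()", "hli_validation_error")
  if (is.null(grid)) {
    if (is.null(years)) years <- fit$years
    grid <- expand.grid(sex = 1:2, age_cat = 1:15, year = years)
  }
  out_window <- grid$year < min(fit$years) | grid$year > max(fit$years)
  if (any(out_window))
    hli_warn(sprintf("%d grid year(s) outside the fitting window %d-%d (extrapolation)",
                     length(unique(grid$year[out_window])),
                     min(fit$years), max(fit$years)),
             "hli_extrapolation_warning")
  x <- fixed_design_rows(fit, grid)
  alpha <- exp(drop(x %*% fit$coefficients) +
                 fit$sigma1^2 / 2 + fit$sigma2^2 / 2)
  if (any(!is.finite(alpha)))
    hli_error("non-finite marginal ratio", "hli_validation_error")
  out <- data.frame(sex = grid$sex, age_cat = grid$age_cat,
                    year = grid$year, alpha_hat = alpha)
  attr(out, "X") <- x
  out
}

#' National totals from marginal ratios and national stay counts
#'
#' The separate ratio estimator: the stratum total is
#' `I_hat = alpha_hat * S_national`, and aggregates are sums of stratum
#' totals, so sex totals add up to the overall total exactly.
#'
#' @param ratios Output of [marginal_ratio()].
#' @param national A `national_stays` table covering the grid.
#' @return List with `strata` (per sex/age/year totals), `by_sex_year`
#'   and `by_year` aggregate data frames.
#' @export
national_totals <- function(ratios, national) {
  national <- as_hli_table(national, "national_stays")
  key <- c("sex", "age_cat", "year")
  m <- merge(ratios, national, by = key, all.x = TRUE)
  if (any(is.na(m$national_stay_count))) {
    gaps <- m[is.na(m$national_stay_count), key]
    hli_error(paste("national table misses strata:",
                    paste(utils::head(apply(gaps, 1, paste, collapse = "/"),
                                      5), collapse = ", ")),
              "hli_integrity_error")
  }
  m$total <- m$alpha_hat * m$national_stay_count
  strata <- m[c(key, "alpha_hat", "national_stay_count", "total")]
  by_sex_year <- stats::aggregate(total ~ sex + year, data = m, FUN = sum)
  by_year <- stats::aggregate(total ~ year, data = m, FUN = sum)
  list(strata = strata, by_sex_year = by_sex_year, by_year = by_year)
}

#' Crude rates per 1,000 person-years
#'
#' @param totals Data frame with columns `sex`, `age_cat`, `year`,
#'   `total` (stratum totals, e.g. `national_totals(...)$strata`).
#' @param population A `population` table on the same grid.
#' @return List with `strata` (stratum-level rates), `by_sex_year` and
#'   `by_year` rates computed with summed populations.
#' @export
crude_rates <- function(totals, population) {
  population <- as_hli_table(population, "population")
  key <- c("sex", "age_cat", "year")
  m <- merge(totals, population, by = key, all.x = TRUE)
  if (any(is.na(m$population)) || any(m$population <= 0))
    hli_error("population missing or non-positive on the estimation grid",
              "hli_validation_error")
  m$rate <- 1000 * m$total / m$population
  agg <- function(formula_lhs, by) {
    tot <- stats::aggregate(m["total"], by = m[by], FUN = sum)
    pop <- stats::aggregate(m["population"], by = m[by], FUN = sum)
    out <- merge(tot, pop, by = by)
    out$rate <- 1000 * out$total / out$population
    out
  }
  list(strata = m[c(key, "total", "population", "rate")],
       by_sex_year = agg("total", c("sex", "year")),
       by_year = agg("total", "year"))
}

#' Directly age-standardized rate
#'
#' Weighted average of age-specific rates with external standard weights
#' (direct standardization).  Standardization is applied within each
#' combination of the non-age columns of `age_rates` (e.g. sex and
#' year).
#'
#' @param age_rates Data frame with columns `age_cat`, `rate` and any
#'   grouping columns; all 15 bands must be present per group.
#' @param weights A `standard_weights` table (weights sum to 1).
#' @return Data frame of the grouping columns plus `std_rate`.
#' @export
standardized_rates <- function(age_rates,
                               weights = european_standard_weights()) {
  weights <- as_hli_table(weights, "standard_weights")
  if (!all(c("age_cat", "rate") %in% names(age_rates)))
    hli_error("age_rates needs columns age_cat and rate",
              "hli_validation_error")
  by <- setdiff(names(age_rates), c("age_cat", "rate"))
  m <- merge(age_rates, weights, by = "age_cat")
  if (length(by) == 0) {
    if (nrow(m) != 15)
      hli_error("need exactly one rate per age band", "hli_validation_error")
    return(data.frame(std_rate = sum(m$weight * m$rate)))
  }
  cnt <- stats::aggregate(list(n = m$age_cat), by = m[by], FUN = length)
  if (any(cnt$n != 15))
    hli_error("each group needs rates for all 15 age bands",
              "hli_validation_error")
  m$wr <- m$weight * m$rate
  out <- stats::aggregate(list(std_rate = m$wr), by = m[by], FUN = sum)
  out
}

#' Period summary of yearly values
#'
#' The period value over the study years is the unweighted mean of the
#' yearly values (totals as well as rates).
#'
#' @param x Numeric vector of yearly values (at least 2).
#' @return The period value.
#' @export
period_summary <- function(x) {
  if (length(x) < 2 || any(!is.finite(x)))
    hli_error("need at least two finite yearly values",
              "hli_validation_error")
  mean(x)
}

# ---- full estimation pipeline -----------------------------------------

#' National totals and rates with delta-method uncertainty
#'
#' Runs the full estimation stage: marginal ratios on the national grid,
#' stratum totals `alpha_hat * S_national`, totals, crude rates and
#' truncated age-standardized rates by sex and overall, per year and for
#' the whole period (unweighted mean of yearly values), each with a
#' delta-method variance and a Wald confidence interval (floored at 0).
#' Every reported quantity is a linear combination of the stratum totals,
#' so one gradient computation per aggregate covers totals and both
#' kinds of rate, and the men/women/overall totals are exactly additive.
#' The men-to-women ratio of period standardized rates is reported with
#' a log-scale interval that carries the full parameter covariance
#' (both rates share the same fitted parameters).
#'
#' @param fit An `hli_fit`.
#' @param national A `national_stays` table.
#' @param population A `population` table on the same grid.
#' @param weights Standard weights for direct standardization.
#' @param level Confidence level.
#' @param age_period One of `"mean"` (period age-specific rates are
#'   means of yearly rates) or `"pooled"` (pooled person-years).
#' @return An `hli_estimates` object: `table` (scope x year/period rows
#'   with totals and rates plus variances and CI bounds), `age_specific`
#'   (sex x age band x year/period totals and rates with CIs),
#'   `rate_ratio` (men/women period standardized rate ratio), `level`.
#' @export
estimate_national <- function(fit, national, population,
                              weights = european_standard_weights(),
                              level = 0.95,
                              age_period = c("mean", "pooled")) {
  age_period <- match.arg(age_period)
  national <- as_hli_table(national, "national_stays")
  population <- as_hli_table(population, "population")
  weights <- as_hli_table(weights, "standard_weights")
  years <- sort(unique(national$year))

  ratios <- marginal_ratio(fit, years = years)
  x_fixed <- attr(ratios, "X")
  key <- c("sex", "age_cat", "year")
  m <- merge(merge(ratios, national, by = key), population, by = key)
  # merge re-sorts; rebuild the design rows in the merged row order
  x_fixed <- fixed_design_rows(fit, m)
  x_ext <- augment_design_rows(x_fixed)
  m$total <- m$alpha_hat * m$national_stay_count
  wtab <- weights$weight[match(m$age_cat, weights$age_cat)]

  aug <- assemble_cov(fit)
  z <- stats::qnorm(1 - (1 - level) / 2)

  scopes <- list(men = m$sex == 1, women = m$sex == 2,
                 all = rep(TRUE, nrow(m)))
  n_yrs <- length(years)

  # weight vectors over strata for each reported aggregate
  w_total <- function(inc) as.numeric(inc)
  w_crude <- function(inc) as.numeric(inc) * 1000 / sum(m$population[inc])
  w_std <- function(inc) {
    w <- numeric(nrow(m))
    pop_age <- tapply(m$population[inc], m$age_cat[inc], sum)
    w[inc] <- 1000 * wtab[inc] / pop_age[as.character(m$age_cat[inc])]
    w
  }

  one_row <- function(scope_name, year_label, w) {
    val <- sum(w * m$total)
    v <- delta_var_total(aug, x_ext, m$total, w)
    ci <- wald_ci(val, v, level = level)
    data.frame(scope = scope_name, year = year_label, estimate = val,
               variance = v, se = sqrt(v), ci_low = ci[1], ci_high = ci[2])
  }

  build_block <- function(maker, what) {
    rows <- list()
    grads <- list()
    for (sn in names(scopes)) {
      yearly_w <- lapply(years, function(y)
        maker(scopes[[sn]] & m$year == y))
      for (i in seq_along(years))
        rows[[paste(sn, years[i])]] <-
          cbind(one_row(sn, as.character(years[i]), yearly_w[[i]]),
                quantity = what)
      w_per <- Reduce(`+`, yearly_w) / n_yrs
      rows[[paste(sn, "period")]] <-
        cbind(one_row(sn, "period", w_per), quantity = what)
      grads[[sn]] <- drop(crossprod(x_ext, w_per * m$total))
    }
    list(rows = do.call(rbind, rows), period_grads = grads)
  }

  tot <- build_block(w_total, "total")
  cru <- build_block(w_crude, "crude_rate")
  std <- build_block(w_std, "std_rate")
  tab <- rbind(tot$rows, cru$rows, std$rows)
  rownames(tab) <- NULL
  tab <- tab[c("quantity", "scope", "year", "estimate", "variance", "se",
               "ci_low", "ci_high")]

  per_std <- function(scope)
    tab$estimate[tab$quantity == "std_rate" & tab$scope == scope &
                   tab$year == "period"]
  rr <- rate_ratio(per_std("men"), per_std("women"), aug,
                   std$period_grads$men, std$period_grads$women,
                   level = level)

  # age-specific totals and rates (per sex), yearly and period
  age_rows <- list()
  for (s in 1:2) for (j in 1:15) {
    sel <- m$sex == s & m$age_cat == j
    yearly_w <- lapply(years, function(y) {
      w <- numeric(nrow(m)); idx <- sel & m$year == y
      w[idx] <- 1000 / m$population[idx]; w
    })
    for (i in seq_along(years)) {
      idx <- sel & m$year == years[i]
      v <- delta_var_total(aug, x_ext, m$total, yearly_w[[i]])
      rate <- sum(yearly_w[[i]] * m$total)
      ci <- wald_ci(rate, v, level = level)
      age_rows[[length(age_rows) + 1]] <- data.frame(
        sex = s, age_cat = j, year = as.character(years[i]),
        total = sum(m$total[idx]), rate = rate, se = sqrt(v),
        ci_low = ci[1], ci_high = ci[2])
    }
    w_per <- if (age_period == "mean") {
      Reduce(`+`, yearly_w) / n_yrs
    } else {
      w <- numeric(nrow(m)); w[sel] <- 1000 / sum(m$population[sel]); w
    }
    v <- delta_var_total(aug, x_ext, m$total, w_per)
    rate <- sum(w_per * m$total)
    ci <- wald_ci(rate, v, level = level)
    age_rows[[length(age_rows) + 1]] <- data.frame(
      sex = s, age_cat = j, year = "period",
      total = sum(m$total[sel]) / n_yrs, rate = rate, se = sqrt(v),
      ci_low = ci[1], ci_high = ci[2])
  }
  age_specific <- do.call(rbind, age_rows)

  structure(list(
    table = tab, age_specific = age_specific, rate_ratio = rr,
    strata = m[c(key, "alpha_hat", "national_stay_count", "total",
                 "population")],
    level = level, years = years
  ), class = "hli_estimates")
}

#' @export
print.hli_estimates <- function(x, digits = 1, ...) {
  cat("National HLI estimates (separate ratio estimator)\n\n")
  fmt <- function(q, scale = 1, d = digits) {
    t <- x$table[x$table$quantity == q, ]
    out <- data.frame(year = t$year[t$scope == "men"])
    for (s in c("men", "women", "all")) {
      ts <- t[t$scope == s, ]
      out[[s]] <- sprintf(paste0("%.", d, "f (%.", d, "f-%.", d, "f)"),
                          ts$estimate / scale, ts$ci_low / scale,
                          ts$ci_high / scale)
    }
    out
  }
  cat("Numbers (x 1,000):\n")
  print(fmt("total", scale = 1000, d = 0), row.names = FALSE)
  cat("\nCrude rates (per 1,000):\n")
  print(fmt("crude_rate"), row.names = FALSE)
  cat("\nStandardized rates (per 1,000, truncated ESP):\n")
  print(fmt("std_rate"), row.names = FALSE)
  cat(sprintf("\nPeriod standardized rate ratio (men/women): %.2f (%.2f-%.2f)\n",
              x$rate_ratio$ratio, x$rate_ratio$ci_low,
              x$rate_ratio$ci_high))
  invisible(x)
}
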