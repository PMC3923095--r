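# Leave-one-hospital-out cross-validation of the national estimates.

#' Drop one hospital from a strata count table
#'
#' @param counts A `strata_counts` table.
#' @param hospital_id Hospital to exclude; excluding a hospital that is
#'   not present is an error, not a no-op.
#' @return The reduced table.
#' @export
drop_hospital <- function(counts, hospital_id) {
  counts <- as_hli_table(counts, "strata_counts")
  if (!hospital_id %in% counts$hospital_id)
    hli_error(sprintf("hospital '%s' not present in the counts",
                      hospital_id), "hli_validation_error")
  as_hli_table(counts[counts$hospital_id != hospital_id, ],
               "strata_counts")
}

#' Leave-one-hospital-out cross-validation
#'
#' Refits the full model with each hospital excluded in turn (reusing
#' the full-sample knots and year origin, so the estimand is identical
#' across rows) and recomputes the period national estimates on the
#' unchanged national grid.  A reduced fit that fails is reported as a
#' flagged row, not dropped, and does not stop the run.
#'
#' @param counts A `strata_counts` table (at least 3 hospitals).
#' @param national,population,weights National auxiliary tables.
#' @param control A [pql_control()].
#' @param internal_knots,boundary_knots,year_origin Design settings,
#'   shared by the full and all reduced fits.
#' @param level Confidence level.
#' @return An `hli_cv` object: `results` (one row per excluded
#'   hospital), `full` (the full-sample reference row) and `level`.
#' @export
leave_one_hospital_out <- function(counts, national, population,
                                   weights = european_standard_weights(),
                                   control = pql_control(),
                                   internal_knots = c(40, 64),
                                   boundary_knots = c(17.5, 87.5),
                                   year_origin = 2006,
                                   level = 0.95) {
  counts <- as_hli_table(counts, "strata_counts")
  hospitals <- sort(unique(counts$hospital_id))
  if (length(hospitals) < 3)
    hli_error("need at least 3 hospitals for cross-validation",
              "hli_validation_error")

  run_one <- function(tab) {
    design <- build_design(tab, internal_knots, boundary_knots,
                           year_origin)
    fit <- fit_pql(design, control)
    est <- estimate_national(fit, national, population, weights,
                             level = level)
    per <- est$table[est$table$year == "period" &
                       est$table$scope == "all", ]
    data.frame(
      sigma1 = fit$sigma1, sigma2 = fit$sigma2, rho = fit$rho,
      period_total = per$estimate[per$quantity == "total"],
      std_rate = per$estimate[per$quantity == "std_rate"],
      ci_low = per$ci_low[per$quantity == "std_rate"],
      ci_high = per$ci_high[per$quantity == "std_rate"])
  }

  full <- cbind(excluded = "none (full sample)", run_one(counts),
                failed = FALSE)
  rows <- lapply(hospitals, function(h) {
    res <- tryCatch(
      cbind(excluded = h, run_one(drop_hospital(counts, h)),
            failed = FALSE),
      error = function(e) data.frame(
        excluded = h, sigma1 = NA_real_, sigma2 = NA_real_,
        rho = NA_real_, period_total = NA_real_, std_rate = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, failed = TRUE))
    res
  })
  results <- do.call(rbind, rows)
  results$rel_diff_pct <- 100 * (results$std_rate - full$std_rate) /
    full$std_rate
  full$rel_diff_pct <- 0
  rownames(results) <- NULL
  structure(list(results = results, full = full, level = level),
            class = "hli_cv")
}

#' Forest-plot table of the cross-validation results
#'
#' Machine-readable table mirroring a forest plot: one row per excluded
#' hospital, the full-sample reference row last.  Failed reduced fits
#' appear with missing-value markers.
#'
#' @param cv An `hli_cv` from [leave_one_hospital_out()].
#' @return Data frame with columns `excluded`, `sigma1`, `sigma2`,
#'   `rho`, `period_total`, `std_rate`, `ci_low`, `ci_high`,
#'   `rel_diff_pct`, `failed`.
#' @export
forest_table <- function(cv) {
  if (!inherits(cv, "hli_cv") || nrow(cv$results) == 0)
    hli_error("cv must be a non-empty hli_cv", "hli_validation_error")
  cols <- c("excluded", "sigma1", "sigma2", "rho", "period_total",
            "std_rate", "ci_low", "ci_high", "rel_diff_pct", "failed")
  out <- rbind(cv$results[cols], cv$full[cols])
  rownames(out) <- NULL
  out
}

#' @export
print.hli_cv <- function(x, ...) {
  cat("Leave-one-hospital-out cross-validation\n")
  tab <- forest_table(x)
  tab[2:9] <- lapply(tab[2:9], function(v) round(v, 3))
  print(tab, row.names = FALSE)
  invisible(x)
}
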