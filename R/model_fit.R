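# Design construction and penalized quasi-likelihood fitting of the
# two-level quasi-Poisson mixed model with natural cubic spline age
# effect, linear year trend and AR(1) within-unit correlation.

#' Center of a five-year age category
#'
#' Category j covers ages `[10 + 5j, 15 + 5j)` for j = 1..14; category 15
#' is the open band 85+, whose nominal center is set to 87.5 (the
#' smallest-width convention, consistent with the neighboring bands).
#'
#' @param age_cat Integer vector in 1..15.
#' @return Age in years at the band center: 17.5, 22.5, ..., 82.5, 87.5.
#' @export
age_centers <- function(age_cat) {
  if (any(!age_cat %in% 1:15))
    hli_error("age_cat must be in 1..15", "hli_validation_error")
  ifelse(age_cat == 15, 87.5, 12.5 + 5 * age_cat)
}

#' Natural cubic spline basis for the age effect
#'
#' Three-column natural cubic regression spline basis (two internal
#' knots): piecewise cubic, C2-continuous, with second derivative zero at
#' and beyond the boundary knots (linear extrapolation).
#'
#' @param ages Numeric vector of evaluation ages.
#' @param internal_knots Internal knots, default ages 40 and 64.
#' @param boundary_knots Boundary knots, default the extreme age-band
#'   centers 17.5 and 87.5.
#' @return Matrix with columns `B1`, `B2`, `B3` (one per spline degree of
#'   freedom).
#' @export
natural_cubic_basis <- function(ages, internal_knots = c(40, 64),
                                boundary_knots = c(17.5, 87.5)) {
  kn <- c(boundary_knots[1], internal_knots, boundary_knots[2])
  if (any(diff(kn) <= 0))
    hli_error("knots must be strictly increasing and bracketed by the boundary knots",
              "hli_validation_error")
  b <- splines::ns(ages, knots = internal_knots,
                   Boundary.knots = boundary_knots)
  b <- unclass(b)
  attributes(b)[setdiff(names(attributes(b)), "dim")] <- NULL
  colnames(b) <- paste0("B", seq_len(ncol(b)))
  b
}

#' Build the model design from a strata count table
#'
#' Response `y = hli_count`, offset `log(stay_count)`, fixed-effect
#' columns (intercept, women indicator, centered year, the three spline
#' basis columns, women x third basis column), hospital and sex-age-unit
#' grouping factors.  Rows with zero stays are dropped (the offset is
#' undefined) with a warning.
#'
#' @param counts A `strata_counts` table.
#' @param internal_knots,boundary_knots Spline knots (ages).
#' @param year_origin Year subtracted from calendar time; centering
#'   decouples the intercept and the trend.
#' @return An `hli_design` object.
#' @export
build_design <- function(counts, internal_knots = c(40, 64),
                         boundary_knots = c(17.5, 87.5),
                         year_origin = 2006) {
  counts <- as_hli_table(counts, "strata_counts")
  drop <- counts$stay_count == 0
  if (any(drop))
    hli_warn(sprintf("dropping %d row(s) with zero stays (offset undefined)",
                     sum(drop)), "hli_zero_stay_warning")
  counts <- counts[!drop, , drop = FALSE]
  if (nrow(counts) == 0)
    hli_error("no rows left after dropping zero-stay strata",
              "hli_empty_design_error")

  b <- natural_cubic_basis(age_centers(counts$age_cat), internal_knots,
                           boundary_knots)
  df <- data.frame(
    y = counts$hli_count,
    log_stays = log(counts$stay_count),
    sex2 = as.numeric(counts$sex == 2),
    t = counts$year - year_origin,
    B1 = b[, 1], B2 = b[, 2], B3 = b[, 3],
    sex2B3 = as.numeric(counts$sex == 2) * b[, 3],
    hospital = factor(counts$hospital_id),
    unit = factor(paste(counts$sex, counts$age_cat, sep = ".")),
    sex = counts$sex, age_cat = counts$age_cat, year = counts$year,
    stay_count = counts$stay_count)
  x <- cbind("(Intercept)" = 1, sex2 = df$sex2, t = df$t,
             B1 = df$B1, B2 = df$B2, B3 = df$B3, sex2B3 = df$sex2B3)
  structure(list(
    data = df, X = x,
    internal_knots = internal_knots, boundary_knots = boundary_knots,
    year_origin = year_origin, n_dropped = sum(drop)
  ), class = "hli_design")
}

#' Fitting control for the PQL iteration
#'
#' @param niter Maximum outer PQL iterations (the iteration stops earlier
#'   once the linear predictor is stable).
#' @param ar1 Fit the AR(1) within-unit correlation (set `FALSE` for the
#'   plain two-level model, e.g. when inspecting residual
#'   autocorrelation).
#' @param verbose Print iteration progress.
#' @return List of control values.
#' @export
pql_control <- function(niter = 50, ar1 = TRUE, verbose = FALSE) {
  list(niter = niter, ar1 = ar1, verbose = verbose)
}

# Map from design-matrix column names to the reported parameter names.
.coef_map <- c("(Intercept)" = "beta0", "sex2" = "alpha2", "t" = "delta",
               "B1" = "beta1", "B2" = "beta2", "B3" = "beta3",
               "sex2B3" = "gamma2")

#' Fit the quasi-Poisson GLMM by penalized quasi-likelihood
#'
#' Iterates weighted linear mixed model fits (REML) on the working
#' response `z = eta - offset + (y - mu)/mu` with weights `mu`, random
#' intercepts for hospital and sex-age unit within hospital, and an AR(1)
#' correlation over years within unit.  The residual variance of the
#' final working fit is the quasi-likelihood dispersion `phi`, which
#' inflates the fixed-effect covariance.  Variance-component confidence
#' intervals are Wald intervals on the log-sigma scale, back-transformed.
#'
#' @param design An `hli_design` from [build_design()].
#' @param control A [pql_control()] list.
#' @return An `hli_fit` with coefficients (beta0, alpha2, delta, beta1,
#'   beta2, beta3, gamma2), standard errors and p-values (Wald),
#'   dispersion-inflated covariance, `sigma1`, `sigma2` with CIs and
#'   log-scale variances, AR(1) `rho` with CI, dispersion `phi`, the
#'   knots and year origin of the design, and the underlying working
#'   `lme` fit.
#' @export
fit_pql <- function(design, control = pql_control()) {
  if (!inherits(design, "hli_design"))
    hli_error("design must come from build_design()", "hli_validation_error")
  df <- design$data
  n_hosp <- nlevels(df$hospital)
  units_per_hosp <- tapply(df$unit, df$hospital,
                           function(u) length(unique(u)))
  if (n_hosp < 2 || sum(units_per_hosp >= 2) < 2)
    hli_error("need at least 2 hospitals with at least 2 sex-age units each",
              "hli_degenerate_error")
  if (qr(design$X)$rank < ncol(design$X))
    hli_error("fixed-effect design is rank deficient", "hli_rank_error")

  corr <- if (isTRUE(control$ar1)) nlme::corAR1(form = ~ t) else NULL
  fit <- tryCatch(
    MASS::glmmPQL(
      y ~ sex2 + t + B1 + B2 + B3 + sex2B3 + offset(log_stays),
      random = ~ 1 | hospital / unit,
      family = stats::quasipoisson(), data = df,
      correlation = corr, niter = control$niter,
      verbose = isTRUE(control$verbose)),
    error = function(e) hli_error(
      paste("PQL iteration failed:", conditionMessage(e)),
      "hli_convergence_error"))

  tt <- summary(fit)$tTable
  beta <- fixef(fit)
  names(beta) <- .coef_map[names(beta)]
  se <- tt[, "Std.Error"]
  pval <- tt[, "p-value"]
  names(se) <- names(pval) <- names(beta)
  vcov_fixed <- fit$varFix
  dimnames(vcov_fixed) <- list(names(beta), names(beta))

  vc <- nlme::VarCorr(fit)
  sds <- suppressWarnings(as.numeric(vc[, "StdDev"]))
  ok <- which(!is.na(sds))
  sigma1 <- sds[ok[1]]
  sigma2 <- sds[ok[2]]
  phi <- sds[ok[3]]^2

  rho <- if (isTRUE(control$ar1))
    as.numeric(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  else 0
  # intervals() may fail when a variance component sits on the boundary;
  # the fit is kept and the interval reported as missing.
  iv <- tryCatch(nlme::intervals(fit, which = "var-cov"),
                 error = function(e) NULL)
  z95 <- stats::qnorm(0.975)
  ci_and_var <- function(tab) {
    if (is.null(tab)) return(list(ci = c(NA_real_, NA_real_), v = NA_real_))
    lo <- as.numeric(tab["lower"]); up <- as.numeric(tab["upper"])
    list(ci = c(lo, up), v = ((log(up) - log(lo)) / (2 * z95))^2)
  }
  s1 <- ci_and_var(if (!is.null(iv)) iv$reStruct$hospital[1, ] else NULL)
  s2 <- ci_and_var(if (!is.null(iv)) iv$reStruct$unit[1, ] else NULL)
  rho_ci <- if (!is.null(iv) && isTRUE(control$ar1))
    as.numeric(iv$corStruct["Phi", c("lower", "upper")])
  else c(NA_real_, NA_real_)

  boundary <- (sigma1 < 1e-4) || (sigma2 < 1e-4)
  if (boundary)
    hli_warn("a variance component is estimated at (or near) zero",
             "hli_boundary_warning")

  structure(list(
    coefficients = beta, se = se, p = pval, vcov_fixed = vcov_fixed,
    sigma1 = sigma1, sigma2 = sigma2,
    sigma1_ci = s1$ci, sigma2_ci = s2$ci,
    var_log_sigma1 = s1$v, var_log_sigma2 = s2$v,
    rho = rho, rho_ci = rho_ci, phi = phi,
    internal_knots = design$internal_knots,
    boundary_knots = design$boundary_knots,
    year_origin = design$year_origin,
    years = sort(unique(df$year)),
    n_obs = nrow(df), n_hospitals = n_hosp,
    ar1 = isTRUE(control$ar1), boundary = boundary, converged = TRUE,
    lme = fit
  ), class = "hli_fit")
}

#' @export
print.hli_fit <- function(x, ...) {
  cat("Two-level quasi-Poisson mixed model (PQL",
      if (x$ar1) "with AR(1))\n" else "without AR(1))\n")
  tab <- data.frame(Estimate = x$coefficients, Std.Error = x$se,
                    p.value = signif(x$p, 3))
  print(round(tab, 4))
  cat(sprintf("sigma1 (hospital): %.3f [%.3f - %.3f]\n", x$sigma1,
              x$sigma1_ci[1], x$sigma1_ci[2]))
  cat(sprintf("sigma2 (unit):     %.3f [%.3f - %.3f]\n", x$sigma2,
              x$sigma2_ci[1], x$sigma2_ci[2]))
  if (x$ar1)
    cat(sprintf("rho (lag 1):       %.3f [%.3f - %.3f]\n", x$rho,
                x$rho_ci[1], x$rho_ci[2]))
  cat(sprintf("dispersion phi:    %.3f   (n = %d, hospitals = %d)\n",
              x$phi, x$n_obs, x$n_hospitals))
  invisible(x)
}

#' Assess the shape of the calendar-time effect
#'
#' Refits the two-level model with year as an ordered factor under
#' orthogonal polynomial contrasts (degrees 1 to number of years minus
#' one) and reports a Wald test per degree.  Following the study design,
#' the linear trend is recommended for retention regardless of its
#' p-value; higher-degree contrasts indicate departures from linearity.
#'
#' @param design An `hli_design` (needs at least 3 distinct years).
#' @param control A [pql_control()]; the contrast model is fitted without
#'   the AR(1) term.
#' @return Data frame (class `hli_time_contrasts`) with one row per
#'   polynomial degree: estimate, standard error, p-value; attribute
#'   `recommended` = "linear".
#' @export
assess_time_effect <- function(design, control = pql_control()) {
  df <- design$data
  yrs <- sort(unique(df$year))
  if (length(yrs) < 3)
    hli_error("need at least 3 distinct years to assess the time effect",
              "hli_validation_error")
  df$yearf <- ordered(df$year)
  fit <- tryCatch(
    MASS::glmmPQL(
      y ~ sex2 + yearf + B1 + B2 + B3 + sex2B3 + offset(log_stays),
      random = ~ 1 | hospital / unit,
      family = stats::quasipoisson(), data = df,
      correlation = NULL, niter = control$niter, verbose = FALSE),
    error = function(e) hli_error(
      paste("time-contrast fit failed:", conditionMessage(e)),
      "hli_convergence_error"))
  tt <- summary(fit)$tTable
  rows <- grep("^yearf", rownames(tt))
  out <- data.frame(
    degree = seq_along(rows),
    contrast = sub("^yearf", "", rownames(tt)[rows]),
    estimate = tt[rows, "Value"],
    se = tt[rows, "Std.Error"],
    p = tt[rows, "p-value"])
  rownames(out) <- NULL
  attr(out, "recommended") <- "linear"
  class(out) <- c("hli_time_contrasts", "data.frame")
  out
}

#' Model diagnostics as plot-ready tables
#'
#' Returns the material for the standard checking plots: observed versus
#' fitted ratios, Pearson residuals against fitted values, the
#' autocorrelation of hospital-level Pearson residuals by lag (computed
#' over within-unit year pairs; decay with lag signals serial
#' correlation), normal-quantile data for the predicted random effects at
#' both levels, and per-hospital residual summaries with the hospital
#' intercept predictions.
#'
#' @param fit An `hli_fit`.
#' @param design The `hli_design` the fit was computed from.
#' @return An `hli_diagnostics` list of data frames.
#' @export
model_diagnostics <- function(fit, design) {
  if (!inherits(fit, "hli_fit") || !inherits(design, "hli_design"))
    hli_error("need an hli_fit and its hli_design", "hli_validation_error")
  df <- design$data
  # fitted values of the working fit are on the linear-predictor scale,
  # offset included
  eta <- as.numeric(fitted(fit$lme))
  mu <- exp(eta)
  pearson <- (df$y - mu) / sqrt(fit$phi * mu)

  fitted_tab <- data.frame(
    hospital = as.character(df$hospital), sex = df$sex,
    age_cat = df$age_cat, year = df$year,
    observed = df$y, fitted = mu,
    observed_ratio = df$y / df$stay_count,
    fitted_ratio = mu / df$stay_count,
    pearson = pearson)

  # Pooled within-unit autocorrelation by lag, computed on hospital-level
  # residuals (unit intercept and serial noise left in): a flat profile
  # across lags reflects the unit intercept alone, decay with lag
  # indicates serial correlation of the repeated counts.
  mu1 <- exp(as.numeric(fitted(fit$lme, level = 1)))
  p1 <- (df$y - mu1) / sqrt(fit$phi * mu1)
  key <- interaction(df$hospital, df$unit, drop = TRUE)
  max_lag <- min(4, diff(range(df$t)))
  acf_tab <- do.call(rbind, lapply(seq_len(max(max_lag, 1)), function(l) {
    a <- numeric(0); b <- numeric(0)
    for (g in split(seq_len(nrow(df)), key)) {
      tt <- df$t[g]
      for (i in seq_along(g)) {
        j <- g[which(tt == tt[i] + l)]
        if (length(j)) { a <- c(a, p1[g[i]]); b <- c(b, p1[j]) }
      }
    }
    data.frame(lag = l, acf = if (length(a) > 2) stats::cor(a, b) else NA,
               n_pairs = length(a))
  }))

  re <- nlme::ranef(fit$lme)
  qq <- function(v) {
    v <- sort(as.numeric(v))
    data.frame(theoretical = stats::qnorm(stats::ppoints(length(v))),
               observed = v)
  }
  hosp_ranef <- re$hospital[, 1]
  names(hosp_ranef) <- rownames(re$hospital)
  hosp_sum <- do.call(rbind, lapply(levels(df$hospital), function(h) {
    r <- pearson[df$hospital == h]
    data.frame(hospital = h, n = length(r),
               q1 = stats::quantile(r, .25), median = stats::median(r),
               q3 = stats::quantile(r, .75), mean = mean(r),
               ranef = hosp_ranef[[h]])
  }))
  rownames(hosp_sum) <- NULL

  structure(list(
    fitted = fitted_tab, acf = acf_tab,
    qq_hospital = qq(re$hospital[, 1]), qq_unit = qq(re$unit[, 1]),
    qq_pearson = qq(pearson), hospital_summary = hosp_sum
  ), class = "hli_diagnostics")
}

#' @export
print.hli_diagnostics <- function(x, ...) {
  cat("HLI model diagnostics\n")
  cat(sprintf("  mean Pearson residual: %.4f (n = %d)\n",
              mean(x$fitted$pearson), nrow(x$fitted)))
  cat("  residual autocorrelation by lag:\n")
  print(round(x$acf, 3))
  invisible(x)
}
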