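# Small, fast synthetic configurations shared across tests.

# 4 hospitals, 3 years (participation 3/3/2/1): 270 strata rows, fits in
# a fraction of a second.
fast_config <- function(...) {
  simulation_config(n_hospitals = 4, years = 2004:2006, ...)
}

fast_fit <- function(seed = 11, cfg = fast_config(), ...) {
  study <- simulate_network(cfg, seed = seed)
  design <- build_design(study$counts,
                         internal_knots = cfg$internal_knots,
                         boundary_knots = cfg$boundary_knots,
                         year_origin = cfg$year_origin)
  fit <- suppressWarnings(fit_pql(design, ...))
  list(study = study, design = design, fit = fit)
}

# Minimal hand-made fit object for closed-form checks of the estimation
# stage (marginal ratios, totals) without running the PQL machinery.
toy_fit <- function(beta = c(beta0 = 0, alpha2 = 0, delta = 0, beta1 = 0,
                             beta2 = 0, beta3 = 0, gamma2 = 0),
                    sigma1 = 0, sigma2 = 0, vcov = matrix(0, 7, 7),
                    var_log_sigma1 = 0, var_log_sigma2 = 0,
                    years = 2004:2008, phi = 1) {
  dimnames(vcov) <- list(names(beta), names(beta))
  structure(list(
    coefficients = beta, se = sqrt(diag(vcov)), p = rep(NA_real_, 7),
    vcov_fixed = vcov, sigma1 = sigma1, sigma2 = sigma2,
    sigma1_ci = c(NA, NA), sigma2_ci = c(NA, NA),
    var_log_sigma1 = var_log_sigma1, var_log_sigma2 = var_log_sigma2,
    rho = 0, rho_ci = c(NA, NA), phi = phi,
    internal_knots = c(40, 64), boundary_knots = c(17.5, 87.5),
    year_origin = 2006, years = years, n_obs = 0L, n_hospitals = 0L,
    ar1 = FALSE, boundary = FALSE, converged = TRUE, lme = NULL
  ), class = "hli_fit")
}
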