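# Delta-method variances for aggregated totals and rates, Wald
# confidence intervals and the standardized rate ratio.
#
# Every reported aggregate is a linear combination of stratum totals
# I_hat = exp(X theta) * S with theta = (beta, sigma1^2, sigma2^2) and
# extended design rows X = (x, 1/2, 1/2); its gradient with respect to
# component m is sum_s X_sm * w_s * I_hat_s, and the variance the
# quadratic form of that gradient in the assembled covariance.

#' Extend fixed-effect design rows with the variance-component slots
#'
#' Appends the two columns of constant 1/2 that multiply `sigma1^2` and
#' `sigma2^2` in the log marginal ratio.
#'
#' @param x Fixed-effect design matrix (7 columns).
#' @return Matrix with 9 columns.
#' @export
augment_design_rows <- function(x) {
  out <- cbind(x, sigma1_sq = 0.5, sigma2_sq = 0.5)
  out
}

#' Assemble the augmented parameter covariance
#'
#' Block-diagonal covariance of `(beta, sigma1^2, sigma2^2)`: the
#' dispersion-inflated fixed-effect block from the PQL working fit, and
#' variances of the squared scale parameters obtained from the log-sigma
#' scale by the univariate delta method (`Var(sigma^2) = 4 sigma^4
#' Var(log sigma)`).  The cross block between fixed effects and variance
#' components is set to zero (REML orthogonality approximation).
#'
#' @param fit An `hli_fit`.
#' @param dispersion `"inflate"` keeps the quasi-likelihood inflation of
#'   the fixed-effect covariance (the default); `"none"` divides it back
#'   out.
#' @return An `hli_augmented_cov`: list with the 9 x 9 matrix `V` and
#'   parameter `names`.
#' @export
assemble_cov <- function(fit, dispersion = c("inflate", "none")) {
  dispersion <- match.arg(dispersion)
  if (!inherits(fit, "hli_fit"))
    hli_error("fit must come from fit_pql()", "hli_validation_error")
  vb <- fit$vcov_fixed
  if (dispersion == "none") vb <- vb / fit$phi
  v1 <- fit$var_log_sigma1
  v2 <- fit$var_log_sigma2
  if (is.na(v1) || is.na(v2)) {
    hli_warn("variance-component uncertainty unavailable (boundary fit); treated as 0",
             "hli_boundary_warning")
    if (is.na(v1)) v1 <- 0
    if (is.na(v2)) v2 <- 0
  }
  v <- matrix(0, 9, 9)
  v[1:7, 1:7] <- (vb + t(vb)) / 2
  v[8, 8] <- 4 * fit$sigma1^4 * v1
  v[9, 9] <- 4 * fit$sigma2^4 * v2
  nm <- c(names(fit$coefficients), "sigma1_sq", "sigma2_sq")
  dimnames(v) <- list(nm, nm)

  ev <- eigen(v, symmetric = TRUE, only.values = TRUE)$values
  scale_ref <- max(abs(ev), 1e-12)
  if (min(ev) < -1e-4 * scale_ref)
    hli_error("assembled covariance is far from positive semi-definite",
              "hli_validation_error")
  if (min(ev) < -1e-10 * scale_ref) {
    hli_warn("projecting assembled covariance to the nearest PSD matrix",
             "hli_psd_warning")
    es <- eigen(v, symmetric = TRUE)
    v <- es$vectors %*% diag(pmax(es$values, 0)) %*% t(es$vectors)
    dimnames(v) <- list(nm, nm)
  }
  structure(list(V = v, names = nm), class = "hli_augmented_cov")
}

#' Delta-method variance of a linear aggregate of stratum totals
#'
#' For an aggregate `A = sum_s w_s I_hat_s` (w = 1 gives totals;
#' 1000/population-type weights give crude or standardized rates), the
#' gradient in parameter component m is `sum_s X_sm w_s I_hat_s`, and
#' the variance `g' V g`.
#'
#' @param aug An `hli_augmented_cov` from [assemble_cov()].
#' @param x_ext Extended design rows (9 columns), one per stratum.
#' @param totals Stratum totals `I_hat`.
#' @param w Aggregation weights (scalar or per-stratum vector).
#' @return The approximate variance of the aggregate.
#' @export
delta_var_total <- function(aug, x_ext, totals, w = 1) {
  if (!inherits(aug, "hli_augmented_cov"))
    hli_error("aug must come from assemble_cov()", "hli_validation_error")
  if (ncol(x_ext) != 9 || nrow(x_ext) != length(totals))
    hli_error("extended design rows do not match the totals",
              "hli_dimension_error")
  if (!length(w) %in% c(1, length(totals)))
    hli_error("weights must be scalar or one per stratum",
              "hli_dimension_error")
  g <- drop(crossprod(x_ext, w * totals))
  drop(t(g) %*% aug$V %*% g)
}

#' Wald confidence interval
#'
#' Symmetric interval on the natural scale, `estimate +/- z * sqrt(var)`,
#' with the lower bound floored (at 0 by default, as counts and rates
#' are non-negative).
#'
#' @param estimate Point estimate(s).
#' @param variance Variance(s), non-negative.
#' @param level Confidence level.
#' @param floor Lower floor for the interval; `NULL` for none.
#' @return For scalar input a length-2 vector `(lower, upper)`;
#'   otherwise a two-column matrix.
#' @export
wald_ci <- function(estimate, variance, level = 0.95, floor = 0) {
  if (any(variance < 0))
    hli_error("variance must be non-negative", "hli_validation_error")
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(variance)
  lo <- estimate - half
  if (!is.null(floor)) lo <- pmax(floor, lo)
  out <- cbind(lower = lo, upper = estimate + half)
  if (length(estimate) == 1) drop(out) else out
}

#' Standardized rate ratio with a log-scale interval
#'
#' Men-to-women ratio of standardized rates.  Both rates are functions
#' of the same fitted parameters, so the variance of the log ratio is
#' computed from the difference of the relative gradients in the common
#' covariance: `Var(log R) = (g_m/r_m - g_w/r_w)' V (g_m/r_m - g_w/r_w)`.
#' The interval is built on the log scale (and is therefore asymmetric
#' about the ratio).
#'
#' @param rate_men,rate_women Standardized rates (> 0).
#' @param aug An `hli_augmented_cov`.
#' @param gradient_men,gradient_women Length-9 gradients of the two
#'   rates (as produced inside [estimate_national()], i.e.
#'   `crossprod(x_ext, w * totals)`).
#' @param level Confidence level.
#' @return List with `ratio`, `se_log`, `ci_low`, `ci_high`, `level`.
#' @export
rate_ratio <- function(rate_men, rate_women, aug, gradient_men,
                       gradient_women, level = 0.95) {
  if (rate_women <= 0 || rate_men <= 0)
    hli_error("rates must be strictly positive", "hli_validation_error")
  g <- gradient_men / rate_men - gradient_women / rate_women
  v <- drop(t(g) %*% aug$V %*% g)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ratio <- rate_men / rate_women
  list(ratio = ratio, se_log = sqrt(v),
       ci_low = exp(log(ratio) - z * sqrt(v)),
       ci_high = exp(log(ratio) + z * sqrt(v)),
       level = level)
}
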