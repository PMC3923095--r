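test_that("age band centers follow the five-year convention", {
  expect_equal(age_centers(1), 17.5)
  expect_equal(age_centers(6), 42.5)
  expect_equal(age_centers(14), 82.5)
  expect_equal(age_centers(15), 87.5)   # open 85+ band
  expect_error(age_centers(16), class = "hli_validation_error")
})

test_that("the age basis is a natural cubic spline with three columns", {
  kb <- c(17.5, 87.5)
  grid <- seq(10, 95, by = 0.25)
  b <- natural_cubic_basis(grid, c(40, 64), kb)
  expect_equal(ncol(b), 3)

  # C2 continuity everywhere and zero curvature at/beyond the boundary
  d2 <- function(col, at) {
    h <- 0.25
    i <- which.min(abs(grid - at))
    (col[i + 1] - 2 * col[i] + col[i - 1]) / h^2
  }
  for (j in 1:3) {
    # at the boundary knot the finite difference straddles the kink in
    # the third derivative, so allow O(h) error there
    expect_lt(abs(d2(b[, j], kb[1])), 1e-4)
    expect_lt(abs(d2(b[, j], kb[2])), 1e-4)
    expect_lt(abs(d2(b[, j], 12)), 1e-6)   # linear outside the boundary
    expect_lt(abs(d2(b[, j], 93)), 1e-6)
  }

  # span equals an independently built truncated-power natural basis
  tp <- local({
    kn <- c(17.5, 40, 64, 87.5)
    dk <- function(x, k) (pmax(x - k, 0)^3 - pmax(x - kn[4], 0)^3) /
      (kn[4] - k)
    cbind(grid, dk(grid, kn[1]) - dk(grid, kn[3]),
          dk(grid, kn[2]) - dk(grid, kn[3]))
  })
  for (j in 1:3) {
    res <- residuals(lm(b[, j] ~ tp))
    expect_lt(max(abs(res)), 1e-8)
  }

  expect_error(natural_cubic_basis(grid, c(64, 40), kb),
               class = "hli_validation_error")
})

test_that("the design matrix encodes the model terms", {
  st <- simulate_network(simulation_config(), seed = 4)
  d <- build_design(st$counts)
  expect_equal(dim(d$X), c(900, 7))
  expect_true(all(d$X[d$data$sex == 1, "sex2B3"] == 0))
  expect_equal(sort(unique(d$data$t)), -2:2)

  # zero-stay rows are dropped with a warning
  cts <- st$counts
  cts$stay_count[3] <- 0L
  expect_warning(d2 <- build_design(cts), class = "hli_zero_stay_warning")
  expect_equal(nrow(d2$data), 899)
  all_zero <- cts
  all_zero$stay_count <- 0L
  expect_error(suppressWarnings(build_design(all_zero)),
               class = "hli_empty_design_error")
})

test_that("rescaling the auxiliary stays only shifts the intercept", {
  res <- fast_fit(seed = 21)
  cts <- res$study$counts
  cts$stay_count <- 10L * cts$stay_count
  fit2 <- suppressWarnings(fit_pql(build_design(
    cts, year_origin = 2006)))
  b1 <- res$fit$coefficients
  b2 <- fit2$coefficients
  expect_equal(unname(b2["beta0"] - b1["beta0"]), -log(10),
               tolerance = 1e-6)
  expect_equal(b1[-1], b2[-1], tolerance = 1e-6)
  # fitted marginal ratios scale by exactly 1/10
  a1 <- marginal_ratio(res$fit, years = 2005)$alpha_hat
  a2 <- marginal_ratio(fit2, years = 2005)$alpha_hat
  expect_equal(a1 / a2, rep(10, length(a1)), tolerance = 1e-5)
})

test_that("the fit is invariant to the row order of the input", {
  st <- simulate_network(fast_config(), seed = 22)
  f1 <- suppressWarnings(fit_pql(build_design(st$counts)))
  perm <- st$counts[rev(seq_len(nrow(st$counts))), ]
  f2 <- suppressWarnings(fit_pql(build_design(perm)))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
  expect_equal(f1$sigma1, f2$sigma1, tolerance = 1e-8)
})

test_that("fits report calibrated structure on well-specified data", {
  res <- fast_fit(seed = 23)
  fit <- res$fit
  expect_true(all(fit$se > 0))
  v <- fit$vcov_fixed
  expect_equal(v, t(v), tolerance = 1e-10)
  expect_true(min(eigen(v, symmetric = TRUE,
                        only.values = TRUE)$values) > -1e-12)
  expect_gt(fit$phi, 1)            # overdispersion picked up
  expect_true(abs(fit$rho) < 1)
  # log-scale Wald intervals are asymmetric about the point estimate
  expect_true(fit$sigma1_ci[1] < fit$sigma1 &&
                fit$sigma1 < fit$sigma1_ci[2])
  mid_log <- sqrt(fit$sigma1_ci[1] * fit$sigma1_ci[2])
  expect_equal(mid_log, fit$sigma1, tolerance = 0.02)
})

test_that("degenerate grouping is rejected", {
  st <- simulate_network(fast_config(), seed = 24)
  one <- st$counts[st$counts$hospital_id == "H1", ]
  expect_error(fit_pql(build_design(one)), class = "hli_degenerate_error")
})

test_that("time contrasts expose nonlinear year effects", {
  st <- simulate_network(simulation_config(sigma_e = 0.03), seed = 25)
  d <- build_design(st$counts)
  tc <- assess_time_effect(d)
  expect_equal(nrow(tc), 4)        # 5 years -> contrasts up to degree 4
  # the generated trend is linear: at most a chance significance among
  # the three higher-order contrasts
  expect_lte(sum(tc$p[tc$degree >= 2] < 0.05), 1)
  expect_identical(attr(tc, "recommended"), "linear")

  # inject a strong quadratic year effect and expect to detect it
  cts <- st$counts
  tt <- cts$year - 2006
  cts$hli_count <- as.integer(round(cts$hli_count * exp(0.12 * tt^2)))
  tc2 <- assess_time_effect(build_design(cts))
  expect_lt(tc2$p[tc2$degree == 2], 0.05)

  st3 <- simulate_network(simulation_config(n_hospitals = 4,
                                            years = 2004:2005), seed = 26)
  expect_error(assess_time_effect(build_design(st3$counts)),
               class = "hli_validation_error")
})

test_that("diagnostics expose unmodelled residual autocorrelation", {
  cfg <- simulation_config(rho = 0.8, sigma_e = 0.25)
  st <- simulate_network(cfg, seed = 27)
  d <- build_design(st$counts)
  f0 <- suppressWarnings(fit_pql(d, pql_control(ar1 = FALSE)))
  diag0 <- model_diagnostics(f0, d)
  expect_gt(diag0$acf$acf[diag0$acf$lag == 1], 0.1)
  # serial correlation decays with lag
  expect_gt(diag0$acf$acf[diag0$acf$lag == 1],
            diag0$acf$acf[diag0$acf$lag == 4])

  # well-specified fit: residuals centred, random-effect QQ data sane
  res <- fast_fit(seed = 28)
  dg <- model_diagnostics(res$fit, res$design)
  expect_lt(abs(mean(dg$fitted$pearson)), 0.15)
  expect_equal(nrow(dg$qq_hospital), 4)
  expect_equal(nrow(dg$hospital_summary), 4)
  expect_true(all(is.finite(dg$fitted$fitted_ratio)))
})
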