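test_that("marginal ratio collapses to the conditional ratio without random effects", {
  beta <- c(beta0 = 1.59, alpha2 = 0.068, delta = 0.009, beta1 = -0.680,
            beta2 = -1.37, beta3 = -0.394, gamma2 = -0.227)
  f0 <- toy_fit(beta = beta)
  grid <- expand.grid(sex = 1:2, age_cat = 1:15, year = 2006)
  a0 <- marginal_ratio(f0, grid)
  b <- natural_cubic_basis(age_centers(grid$age_cat))
  eta <- beta["beta0"] + beta["alpha2"] * (grid$sex == 2) +
    beta["beta1"] * b[, 1] + beta["beta2"] * b[, 2] +
    (beta["beta3"] + beta["gamma2"] * (grid$sex == 2)) * b[, 3]
  expect_equal(a0$alpha_hat, unname(exp(eta)), tolerance = 1e-12)

  # lognormal correction is a uniform multiplicative factor
  f1 <- toy_fit(beta = beta, sigma1 = 0.27, sigma2 = 0.10)
  a1 <- marginal_ratio(f1, grid)
  expect_equal(a1$alpha_hat / a0$alpha_hat,
               rep(exp((0.27^2 + 0.10^2) / 2), nrow(grid)),
               tolerance = 1e-12)
  expect_equal(exp((0.27^2 + 0.10^2) / 2), 1.0424, tolerance = 1e-4)
})

test_that("marginal ratio equals Monte-Carlo integration over the effects", {
  res <- fast_fit(seed = 31)
  fit <- res$fit
  grid <- expand.grid(sex = 1:2, age_cat = c(2, 8, 15), year = 2005)
  a <- marginal_ratio(fit, grid)
  x <- attr(a, "X")
  set.seed(99)
  n <- 2e5
  z <- exp(fit$sigma1 * rnorm(n)) * exp(fit$sigma2 * rnorm(n))
  for (i in seq_len(nrow(grid))) {
    cond <- exp(sum(x[i, ] * fit$coefficients))
    mc <- cond * mean(z)
    mc_se <- cond * sd(z) / sqrt(n)
    expect_lt(abs(a$alpha_hat[i] - mc), 3 * mc_se)
  }
})

test_that("prediction outside the fitting window warns", {
  res <- fast_fit(seed = 32)
  expect_warning(marginal_ratio(res$fit, years = 2015),
                 class = "hli_extrapolation_warning")
})

test_that("totals are additive, linear in the auxiliary stays, and identity at unit ratio", {
  st <- simulate_network(fast_config(), seed = 33)
  f <- toy_fit(years = 2004:2006)
  ratios <- marginal_ratio(f, years = 2004:2006)
  ratios$alpha_hat <- 1
  tot <- national_totals(ratios, st$national)
  expect_equal(sum(tot$strata$total), sum(st$national$national_stay_count))

  set.seed(7)
  ratios$alpha_hat <- runif(nrow(ratios), 0.5, 3)
  t1 <- national_totals(ratios, st$national)
  by_sex <- aggregate(total ~ year, t1$by_sex_year, sum)
  expect_equal(by_sex$total, t1$by_year$total)   # men + women = all, exact

  nat2 <- st$national
  nat2$national_stay_count <- 2L * nat2$national_stay_count
  t2 <- national_totals(ratios, nat2)
  expect_equal(t2$strata$total, 2 * t1$strata$total)

  gap <- st$national[-1, ]
  expect_error(suppressWarnings(national_totals(ratios,
                                                as.data.frame(gap))),
               class = "hli_integrity_error")
})

test_that("crude rates scale with population as rates must", {
  st <- simulate_network(fast_config(), seed = 34)
  f <- toy_fit(years = 2004:2006)
  ratios <- marginal_ratio(f, years = 2004:2006)
  tot <- national_totals(ratios, st$national)$strata
  r1 <- crude_rates(tot, st$population)
  pop2 <- st$population
  pop2$population <- 2 * pop2$population
  r2 <- crude_rates(tot, pop2)
  expect_equal(r2$strata$rate, r1$strata$rate / 2)
  expect_equal(r2$by_year$rate, r1$by_year$rate / 2)

  tot0 <- tot
  tot0$total <- 0
  expect_true(all(crude_rates(tot0, st$population)$strata$rate == 0))
})

test_that("direct standardization is a convex combination of age rates", {
  w <- european_standard_weights()
  const <- data.frame(sex = rep(1:2, each = 15), age_cat = rep(1:15, 2),
                      rate = 7.5)
  s <- standardized_rates(const, w)
  expect_equal(s$std_rate, c(7.5, 7.5))

  set.seed(5)
  rnd <- data.frame(age_cat = 1:15, rate = runif(15, 10, 200))
  s2 <- standardized_rates(rnd, w)
  expect_true(s2$std_rate >= min(rnd$rate) && s2$std_rate <= max(rnd$rate))

  # near-degenerate weights reproduce the loaded band's rate
  eps <- 1e-9
  wconc <- data.frame(age_cat = 1:15, weight = rep(eps, 15))
  wconc$weight[3] <- 1 - 14 * eps
  s3 <- standardized_rates(rnd, wconc)
  expect_equal(s3$std_rate, rnd$rate[3], tolerance = 1e-5)

  expect_error(standardized_rates(rnd[-1, ], w),
               class = "hli_validation_error")
})

test_that("period summaries are unweighted means of yearly values", {
  expect_equal(period_summary(c(4, 4, 4)), 4)
  expect_equal(period_summary(c(1, 2, 3, 4)), 2.5)
  expect_error(period_summary(5), class = "hli_validation_error")
})

test_that("the estimation table is internally consistent", {
  res <- fast_fit(seed = 36)
  est <- estimate_national(res$fit, res$study$national,
                           res$study$population, res$study$weights)
  tab <- est$table
  for (q in unique(tab$quantity)) {
    for (y in unique(tab$year)) {
      g <- tab[tab$quantity == q & tab$year == y, ]
      if (q == "total")
        expect_equal(g$estimate[g$scope == "men"] +
                       g$estimate[g$scope == "women"],
                     g$estimate[g$scope == "all"], tolerance = 1e-9)
      expect_true(all(g$ci_low <= g$estimate & g$estimate <= g$ci_high))
      expect_true(all(g$variance >= 0))
    }
  }
  # standardized rates sit between the extreme age-specific rates
  age <- est$age_specific
  for (s in 1:2) {
    per <- age[age$sex == s & age$year == "period", ]
    scope <- c("men", "women")[s]
    sr <- tab$estimate[tab$quantity == "std_rate" & tab$scope == scope &
                         tab$year == "period"]
    expect_true(sr >= min(per$rate) && sr <= max(per$rate))
  }
  # period estimates are the means of the yearly ones
  for (scope in c("men", "women", "all")) {
    g <- tab[tab$quantity == "std_rate" & tab$scope == scope, ]
    expect_equal(g$estimate[g$year == "period"],
                 mean(g$estimate[g$year != "period"]), tolerance = 1e-9)
  }
  expect_gt(est$rate_ratio$ratio, 0)
  expect_true(est$rate_ratio$ci_low < est$rate_ratio$ratio &&
                est$rate_ratio$ratio < est$rate_ratio$ci_high)
})
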