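test_that("datasets are bit-reproducible under a fixed seed", {
  a <- simulate_network(fast_config(), seed = 42)
  b <- simulate_network(fast_config(), seed = 42)
  expect_identical(a$counts, b$counts)
  expect_identical(a$national, b$national)
  expect_identical(a$random_effects, b$random_effects)
  c <- simulate_network(fast_config(), seed = 43)
  expect_false(identical(a$counts$hli_count, c$counts$hli_count))
})

test_that("degenerate variances give zero effects and fixed-effect ratios", {
  cfg <- fast_config(sigma1 = 0, sigma2 = 0, sigma_e = 0)
  re <- simulate_random_effects(cfg, seed = 1)
  expect_true(all(re$b_hospital == 0))
  expect_true(all(re$b_unit$value == 0))
  expect_true(all(re$e$value == 0))

  # with huge offsets the empirical ratios converge to exp(x'beta)
  cfg2 <- simulation_config(n_hospitals = 2, years = 2006,
                            participation = list(2006, 2006),
                            sigma1 = 0, sigma2 = 0, sigma_e = 0,
                            base_stays = 2e4, size_spread = 1)
  st <- simulate_network(cfg2, seed = 2)
  x <- st$counts
  b <- natural_cubic_basis(age_centers(x$age_cat))
  eta <- 1.59 + 0.068 * (x$sex == 2) - 0.680 * b[, 1] - 1.37 * b[, 2] +
    (-0.394 - 0.227 * (x$sex == 2)) * b[, 3]
  mu <- x$stay_count * exp(eta)
  z <- (x$hli_count - mu) / sqrt(mu)   # Poisson standardized
  expect_lt(max(abs(z)), 5)
  expect_lt(abs(mean(z)), 3 / sqrt(nrow(x)))
})

test_that("random-effect draws match their nominal moments", {
  cfg <- simulation_config(n_hospitals = 2000, years = 2004,
                           participation = lapply(1:2000, function(k) 2004))
  re <- simulate_random_effects(cfg, seed = 10)
  # sd of the sample sd is about sigma/sqrt(2n)
  expect_lt(abs(sd(re$b_hospital) - 0.27), 3 * 0.27 / sqrt(2 * 2000))
  expect_lt(abs(sd(re$b_unit$value) - 0.10),
            3 * 0.10 / sqrt(2 * nrow(re$b_unit)))
  expect_lt(abs(mean(re$b_hospital)), 3 * 0.27 / sqrt(2000))

  # long series: pooled lag-1 autocorrelation close to rho = .38
  cfg2 <- simulation_config(n_hospitals = 2, years = 2001:2300,
                            participation = list(2001:2300, 2001:2300))
  e <- simulate_random_effects(cfg2, seed = 11)$e
  e <- e[order(e$hospital, e$sex, e$age_cat, e$year), ]
  x <- matrix(e$value, nrow = 300)
  r1 <- cor(as.vector(x[-300, ]), as.vector(x[-1, ]))
  expect_lt(abs(r1 - 0.38), 0.03)
  expect_lt(abs(sd(e$value) - 0.05), 0.005)

  expect_error(simulation_config(rho = 1), class = "hli_parameter_error")
  expect_error(simulation_config(sigma1 = -1),
               class = "hli_parameter_error")
})

test_that("the default study matches the sentinel participation pattern", {
  st <- simulate_network(simulation_config(), seed = 1)
  # 2 sexes x 15 ages x (4 x 5 + 4 + 3 + 2 + 1) hospital-years
  expect_equal(nrow(st$counts), 900)
  expect_equal(length(unique(st$counts$hospital_id)), 8)
  yrs <- table(st$counts$hospital_id) / 30
  expect_setequal(as.integer(yrs), c(5, 5, 5, 5, 4, 3, 2, 1))
  # national grid is complete and dominates the network counts
  expect_equal(nrow(st$national), 2 * 15 * 5)
  net <- aggregate(stay_count ~ sex + age_cat + year, data = st$counts,
                   FUN = sum)
  m <- merge(net, st$national, by = c("sex", "age_cat", "year"))
  expect_true(all(m$stay_count <= m$national_stay_count))
})

test_that("zero stays force zero HLI counts", {
  cfg <- fast_config(base_stays = 0.2)  # many empty cells
  st <- simulate_network(cfg, seed = 6)
  expect_gt(sum(st$counts$stay_count == 0), 0)
  expect_true(all(st$counts$hli_count[st$counts$stay_count == 0] == 0))
})

test_that("level-1 noise induces overdispersion in the counts", {
  cfg <- simulation_config(n_hospitals = 2, years = 2006,
                           participation = list(2006, 2006),
                           sigma1 = 0, sigma2 = 0, base_stays = 400,
                           size_spread = 1)
  # fixed offsets across replicates for a clean variance comparison
  st0 <- simulate_network(cfg, seed = 100)
  stays <- st0$counts[c("hospital_id", "sex", "age_cat", "year",
                        "stay_count")]
  draws <- sapply(1:60, function(r) {
    st <- simulate_network(cfg, seed = 200 + r, stays = stays)
    st$counts$hli_count[1]
  })
  expect_gt(var(draws) / mean(draws), 1.3)
})

test_that("stay records realize prescribed counts with known margins", {
  st <- simulate_network(fast_config(), seed = 8)
  stays <- st$counts[c("hospital_id", "sex", "age_cat", "year",
                       "stay_count")]
  stays <- stays[stays$hospital_id == "H1" & stays$year == 2004, ]
  stays$stay_count <- pmin(stays$stay_count, 10L)

  recs <- simulate_stay_records(stays, seed = 9)
  got <- select_injury_stays(recs, 1)
  m <- merge(stays, got, by = c("hospital_id", "sex", "age_cat", "year"))
  expect_equal(m$stay_count.y, m$stay_count.x)

  recs2 <- simulate_stay_records(stays, seed = 9, algo2_only_frac = 0.5,
                                 under15_frac = 0.5)
  n1 <- select_injury_stays(recs2, 1)
  n2 <- select_injury_stays(recs2, 2)
  key <- c("hospital_id", "sex", "age_cat", "year")
  mm <- merge(merge(n1, n2, by = key), stays, by = key)
  expect_equal(mm$stay_count.x, mm$stay_count)             # under-15 excluded
  expect_equal(mm$stay_count.y - mm$stay_count.x,
               round(0.5 * mm$stay_count))                 # constructed margin

  expect_error(simulate_stay_records(stays, algo2_only_frac = -1),
               class = "hli_parameter_error")
})
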