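# Generation of complete synthetic sentinel studies with known ground
# truth: network HLI/stay counts, noise-free national auxiliary totals,
# population denominators and (optionally) line-level stay records.

#' Configuration of a synthetic sentinel study
#'
#' Default parameter values are the point estimates of the fitted
#' two-level quasi-Poisson mixed model for the French 2004-2008 adult HLI
#' study: intercept `beta0 = 1.59`, sex effect (women) `alpha2 = .068`,
#' yearly trend `delta = .009`, spline coefficients `beta1 = -.680`,
#' `beta2 = -1.37`, `beta3 = -.394`, sex-by-third-basis interaction
#' `gamma2 = -.227`, hospital-level standard deviation `sigma1 = .27`,
#' unit-level (sex-age within hospital) standard deviation
#' `sigma2 = .10` and AR(1) lag-one correlation `rho = .38`.
#'
#' `sigma_e` is the marginal standard deviation of the level-1 log-scale
#' AR(1) noise.  It is a free generator choice (a quasi-likelihood fit
#' reports a dispersion, not a generative noise scale).  The default
#' 0.05 produces clearly overdispersed counts (quasi-dispersion around
#' 2 to 3 at realistic stratum sizes) while keeping the induced
#' mean-variance relationship close to the quasi-Poisson law the fitted
#' model assumes, emulating data for which that model is adequate.
#' The noise is normalized to unit mean on the count scale, so the
#' marginal expected ratio in a stratum stays
#' `exp(x'beta + sigma1^2/2 + sigma2^2/2)`.
#'
#' The default participation pattern mirrors an unbalanced sentinel
#' panel: with 8 hospitals and 5 study years, four hospitals contribute
#' all five years and the others 4, 3, 2 and 1 most recent years.
#'
#' Baseline stay counts follow a log-quadratic age profile rising
#' steeply with age (injury admissions are dominated by falls in the
#' elderly) with a sex offset, scaled by hospital sizes spread evenly on
#' the log scale over
#' one order of magnitude (`base_stays` to `size_spread * base_stays`
#' expected stays per cell at the profile minimum).  National auxiliary
#' totals are `national_scale` times the expected (noise-free) stay
#' counts summed over all hospitals; the default scale of 40 corresponds
#' to a network covering roughly 2.5% of national stays.
#'
#' @param n_hospitals Number of sentinel hospitals.
#' @param years Calendar study years.
#' @param participation List of length `n_hospitals`; element k holds the
#'   years contributed by hospital k.  `NULL` for the default unbalanced
#'   pattern.
#' @param beta0,alpha2,delta,beta1,beta2,beta3,gamma2 Fixed effects.
#' @param sigma1,sigma2 Random-intercept standard deviations (hospital,
#'   sex-age unit within hospital).
#' @param rho AR(1) lag-one correlation of the level-1 noise.
#' @param sigma_e Marginal standard deviation of the level-1 noise.
#' @param internal_knots,boundary_knots Natural cubic spline knots (ages).
#' @param year_origin Year subtracted from calendar time before it enters
#'   the linear predictor.
#' @param base_stays Expected stays per cell in the smallest hospital at
#'   the profile minimum.
#' @param size_spread Ratio of largest to smallest hospital size.
#' @param stay_shape Named vector `c(curv, slope, sex)` for the
#'   log-quadratic baseline stay profile in `z = (age - 55)/15`.
#' @param national_scale National-to-network stay scale factor (>= 1).
#' @param population_profile Person-years per age band (same for both
#'   sexes), length 15; `NULL` for a default adult population of about
#'   49 million.
#' @return A `simulation_config` object (list).
#' @export
simulation_config <- function(n_hospitals = 8,
                              years = 2004:2008,
                              participation = NULL,
                              beta0 = 1.59, alpha2 = 0.068, delta = 0.009,
                              beta1 = -0.680, beta2 = -1.37,
                              beta3 = -0.394, gamma2 = -0.227,
                              sigma1 = 0.27, sigma2 = 0.10,
                              rho = 0.38, sigma_e = 0.05,
                              internal_knots = c(40, 64),
                              boundary_knots = c(17.5, 87.5),
                              year_origin = 2006,
                              base_stays = 40, size_spread = 10,
                              stay_shape = c(curv = 0.15, slope = 0.55,
                                             sex = -0.2),
                              national_scale = 40,
                              population_profile = NULL) {
  if (sigma1 < 0 || sigma2 < 0 || sigma_e < 0)
    hli_error("standard deviations must be non-negative",
              "hli_parameter_error")
  if (abs(rho) >= 1)
    hli_error("|rho| must be < 1", "hli_parameter_error")
  if (national_scale < 1)
    hli_error("national_scale must be >= 1", "hli_parameter_error")
  if (is.null(participation)) {
    ny <- pmax(1L, length(years) -
                 pmax(0L, seq_len(n_hospitals) - ceiling(n_hospitals / 2)))
    participation <- lapply(ny, function(k) tail(years, k))
  }
  if (length(participation) != n_hospitals)
    hli_error("participation must have one element per hospital",
              "hli_parameter_error")
  if (!all(unlist(participation) %in% years))
    hli_error("participation years must lie within the study years",
              "hli_parameter_error")
  if (is.null(population_profile))
    population_profile <- 1000 * c(1950, 1900, 1950, 2050, 2100, 2150,
                                   2100, 2050, 1900, 1700, 1300, 1100,
                                   900, 650, 550)
  if (length(population_profile) != 15 || any(population_profile <= 0))
    hli_error("population_profile must be 15 positive values",
              "hli_parameter_error")
  structure(list(
    n_hospitals = n_hospitals, years = years,
    participation = participation,
    fixed = c(beta0 = beta0, alpha2 = alpha2, delta = delta,
              beta1 = beta1, beta2 = beta2, beta3 = beta3,
              gamma2 = gamma2),
    sigma1 = sigma1, sigma2 = sigma2, rho = rho, sigma_e = sigma_e,
    internal_knots = internal_knots, boundary_knots = boundary_knots,
    year_origin = year_origin,
    base_stays = base_stays, size_spread = size_spread,
    stay_shape = stay_shape, national_scale = national_scale,
    population_profile = population_profile
  ), class = "simulation_config")
}

hospital_sizes <- function(config) {
  k <- config$n_hospitals
  if (k == 1) return(config$base_stays)
  sizes <- config$base_stays * config$size_spread^((seq_len(k) - 1) / (k - 1))
  # Interleave sizes across the participation order so hospital size is
  # not confounded with entry time (late joiners span the size range,
  # as in real sentinel networks).
  stride <- 3
  while (stride < k && gcd2(stride, k) != 1) stride <- stride + 1
  if (stride >= k) stride <- 1
  ranks <- ((seq_len(k) - 1) * stride) %% k + 1
  sizes[ranks]
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Expected stays per cell: log-quadratic in age with a sex offset.
stay_profile <- function(config, sex, age_cat, hospital) {
  z <- (age_centers(age_cat) - 55) / 15
  sh <- config$stay_shape
  hospital_sizes(config)[hospital] *
    exp(sh[["curv"]] * z^2 + sh[["slope"]] * z + sh[["sex"]] * (sex == 2))
}

# Canonical stratum frame for the observed network (participation years
# only), in fixed (hospital, sex, age_cat, year) order so that random
# draws are reproducible.
network_frame <- function(config) {
  rows <- do.call(rbind, lapply(seq_len(config$n_hospitals), function(k) {
    g <- expand.grid(year = config$participation[[k]], age_cat = 1:15,
                     sex = 1:2, hospital = k)
    g[order(g$sex, g$age_cat, g$year), c("hospital", "sex", "age_cat",
                                         "year")]
  }))
  rownames(rows) <- NULL
  rows
}

#' Draw the random effects of a synthetic study
#'
#' Hospital intercepts `b_k ~ N(0, sigma1^2)`, unit intercepts
#' `b_ijk ~ N(0, sigma2^2)` for every sex-age unit within hospital, and a
#' stationary Gaussian AR(1) series per unit over its hospital's
#' participation years, with lag-one correlation `rho` and marginal
#' standard deviation `sigma_e`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed.
#' @return List with `b_hospital` (length `n_hospitals`), `b_unit`
#'   (data frame hospital/sex/age_cat/value) and `e` (data frame
#'   hospital/sex/age_cat/year/value).
#' @export
simulate_random_effects <- function(config, seed = NULL) {
  if (!inherits(config, "simulation_config"))
    hli_error("config must come from simulation_config()",
              "hli_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  k <- config$n_hospitals
  b_hospital <- stats::rnorm(k, 0, config$sigma1)

  units <- expand.grid(age_cat = 1:15, sex = 1:2, hospital = seq_len(k))
  units <- units[order(units$hospital, units$sex, units$age_cat),
                 c("hospital", "sex", "age_cat")]
  rownames(units) <- NULL
  units$value <- stats::rnorm(nrow(units), 0, config$sigma2)

  # one stationary AR(1) series per unit, drawn hospital by hospital as a
  # units-by-years matrix (innovation variance sigma_e^2 (1 - rho^2))
  e <- do.call(rbind, lapply(seq_len(k), function(h) {
    yrs <- sort(config$participation[[h]])
    tt <- length(yrs)
    uh <- units[units$hospital == h, c("hospital", "sex", "age_cat")]
    s <- matrix(0, nrow(uh), tt)
    s[, 1] <- stats::rnorm(nrow(uh), 0, config$sigma_e)
    if (tt > 1)
      for (j in 2:tt)
        s[, j] <- config$rho * s[, j - 1] +
          stats::rnorm(nrow(uh), 0,
                       config$sigma_e * sqrt(1 - config$rho^2))
    data.frame(uh[rep(seq_len(nrow(uh)), tt), ],
               year = rep(yrs, each = nrow(uh)),
               value = as.vector(s))
  }))
  rownames(e) <- NULL
  list(b_hospital = b_hospital, b_unit = units, e = e)
}

#' Simulate a complete synthetic sentinel study
#'
#' Stay counts are drawn as Poisson around the baseline profile (or
#' reused from `stays`), and HLI counts as Poisson with conditional mean
#' `S * exp(x'beta + b_k + b_ijk + e - sigma_e^2/2)`, where `e` is the
#' level-1 AR(1) log-scale noise (mean-corrected so the noise has unit
#' mean on the count scale).  National auxiliary totals are noise-free:
#' `national_scale` times the expected stays summed over all hospitals,
#' on the full sex x age x year grid.  The realized random effects and
#' all ground-truth parameters are stored with the dataset.
#'
#' @param config A [simulation_config()].
#' @param seed Optional integer seed; with a fixed seed the dataset is
#'   bit-reproducible.
#' @param stays Optional `strata_stays` table to reuse as the stay counts
#'   (e.g. to condition a parametric bootstrap on the observed offsets).
#' @return A `synthetic_hli_study`: list with `counts`
#'   (`strata_counts`), `national` (`national_stays`), `population`
#'   (`population`), `weights` (`standard_weights`), `truth` and
#'   `random_effects`.
#' @export
simulate_network <- function(config, seed = NULL, stays = NULL) {
  if (!inherits(config, "simulation_config"))
    hli_error("config must come from simulation_config()",
              "hli_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  re <- simulate_random_effects(config)
  rows <- network_frame(config)

  m <- stay_profile(config, rows$sex, rows$age_cat, rows$hospital)
  if (is.null(stays)) {
    rows$stay_count <- stats::rpois(nrow(rows), m)
  } else {
    stays <- as_hli_table(stays, "strata_stays")
    stays$hospital <- match(stays$hospital_id,
                            sprintf("H%d", seq_len(config$n_hospitals)))
    idx <- match(interaction(rows$hospital, rows$sex, rows$age_cat,
                             rows$year),
                 interaction(stays$hospital, stays$sex, stays$age_cat,
                             stays$year))
    if (any(is.na(idx)))
      hli_error("supplied stays do not cover the network frame",
                "hli_parameter_error")
    rows$stay_count <- stays$stay_count[idx]
  }

  bx <- natural_cubic_basis(age_centers(rows$age_cat),
                            config$internal_knots, config$boundary_knots)
  fx <- config$fixed
  t_c <- rows$year - config$year_origin
  eta_fix <- fx[["beta0"]] + fx[["alpha2"]] * (rows$sex == 2) +
    fx[["delta"]] * t_c + fx[["beta1"]] * bx[, 1] +
    fx[["beta2"]] * bx[, 2] +
    (fx[["beta3"]] + fx[["gamma2"]] * (rows$sex == 2)) * bx[, 3]

  uix <- match(interaction(rows$hospital, rows$sex, rows$age_cat),
               interaction(re$b_unit$hospital, re$b_unit$sex,
                           re$b_unit$age_cat))
  eix <- match(interaction(rows$hospital, rows$sex, rows$age_cat,
                           rows$year),
               interaction(re$e$hospital, re$e$sex, re$e$age_cat,
                           re$e$year))
  eta <- eta_fix + re$b_hospital[rows$hospital] +
    re$b_unit$value[uix] + re$e$value[eix] - config$sigma_e^2 / 2
  mu <- rows$stay_count * exp(eta)
  if (any(!is.finite(mu))) {
    bad <- which(!is.finite(mu))[1]
    hli_error(sprintf(
      "non-finite conditional mean at hospital %d, sex %d, age %d, year %d",
      rows$hospital[bad], rows$sex[bad], rows$age_cat[bad],
      rows$year[bad]), "hli_simulation_error")
  }
  rows$hli_count <- stats::rpois(nrow(rows), mu)

  counts <- data.frame(
    hospital_id = sprintf("H%d", rows$hospital),
    sex = rows$sex, age_cat = rows$age_cat, year = rows$year,
    hli_count = rows$hli_count, stay_count = rows$stay_count)
  counts <- as_hli_table(counts, "strata_counts")

  nat <- expand.grid(sex = 1:2, age_cat = 1:15, year = config$years)
  exp_network <- rowSums(vapply(seq_len(config$n_hospitals), function(k)
    stay_profile(config, nat$sex, nat$age_cat, k),
    numeric(nrow(nat))))
  nat$national_stay_count <- as.integer(round(config$national_scale *
                                                exp_network))
  national <- as_hli_table(nat, "national_stays")

  pop <- expand.grid(sex = 1:2, age_cat = 1:15, year = config$years)
  pop$population <- config$population_profile[pop$age_cat]
  population <- as_hli_table(pop, "population")

  structure(list(
    counts = counts, national = national, population = population,
    weights = european_standard_weights(),
    truth = config, random_effects = re
  ), class = "synthetic_hli_study")
}

#' @export
print.synthetic_hli_study <- function(x, ...) {
  cat("Synthetic sentinel HLI study\n")
  cat(sprintf("  %d hospitals, years %s-%s, %d strata rows\n",
              x$truth$n_hospitals, min(x$truth$years), max(x$truth$years),
              nrow(x$counts)))
  cat(sprintf("  truth: sigma1 = %.3g, sigma2 = %.3g, rho = %.3g, sigma_e = %.3g\n",
              x$truth$sigma1, x$truth$sigma2, x$truth$rho,
              x$truth$sigma_e))
  invisible(x)
}

#' Emit line-level stay records realizing prescribed stay counts
#'
#' Constructs one record per prescribed algorithm-1 stay (chapter 19
#' principal diagnosis), so that `select_injury_stays(records, 1)`
#' reproduces `stay_counts` exactly.  Optional fractions add, per cell,
#' records carrying only algorithm-2-specific codes, non-qualifying
#' records, and under-15 records (excluded by both algorithms); the added
#' numbers are deterministic (`round(frac * n)`), so the margin between
#' the two algorithms is known by construction.  A tenth of the
#' qualifying records carry their injury code as an associated (not
#' principal) diagnosis, exercising the principal-or-associated rule.
#'
#' @param stay_counts A `strata_stays` table of prescribed counts.
#' @param seed Optional seed (codes and ages are sampled).
#' @param algo2_only_frac,nonqualifying_frac,under15_frac Added record
#'   fractions relative to each cell's prescribed count.
#' @return Data frame of stay records with a `diagnosis_codes` list
#'   column (first element = principal diagnosis).
#' @export
simulate_stay_records <- function(stay_counts, seed = NULL,
                                  algo2_only_frac = 0,
                                  nonqualifying_frac = 0,
                                  under15_frac = 0) {
  stay_counts <- as_hli_table(stay_counts, "strata_stays")
  if (algo2_only_frac < 0 || nonqualifying_frac < 0 || under15_frac < 0)
    hli_error("record fractions must be non-negative",
              "hli_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  chap19 <- icd10_code_set(1)
  extra2 <- setdiff(icd10_code_set(2), chap19)
  benign <- c("Z000", "I10", "M545", "E119")
  one_cell <- function(row) {
    n <- row$stay_count
    n2 <- round(algo2_only_frac * n)
    nz <- round(nonqualifying_frac * n)
    nu <- round(under15_frac * n)
    age <- age_centers(row$age_cat)
    mk <- function(m, codes, ages) {
      if (m == 0) return(NULL)
      data.frame(hospital_id = row$hospital_id, sex = row$sex,
                 age = ages, year = row$year,
                 diagnosis_codes = I(codes))
    }
    q_codes <- lapply(paste0(sample(chap19, n, replace = TRUE),
                             sample(0:9, n, replace = TRUE)), identity)
    # associated-position injury codes for a tenth of qualifying stays
    n_assoc <- floor(n / 10)
    if (n_assoc > 0)
      for (i in seq_len(n_assoc))
        q_codes[[i]] <- c(benign[1], q_codes[[i]])
    rbind(
      mk(n, q_codes, rep(age, n)),
      mk(n2, lapply(paste0(sample(extra2, max(n2, 1), replace = TRUE),
                           sample(0:9, max(n2, 1), replace = TRUE)),
                    identity)[seq_len(n2)], rep(age, n2)),
      mk(nz, as.list(sample(benign, max(nz, 1),
                            replace = TRUE))[seq_len(nz)], rep(age, nz)),
      mk(nu, lapply(paste0(sample(chap19, max(nu, 1), replace = TRUE),
                           "0"), identity)[seq_len(nu)],
         sample(5:14, nu, replace = TRUE))
    )
  }
  recs <- do.call(rbind, lapply(seq_len(nrow(stay_counts)), function(i)
    one_cell(stay_counts[i, ])))
  if (is.null(recs))
    recs <- data.frame(hospital_id = character(0), sex = integer(0),
                       age = numeric(0), year = integer(0),
                       diagnosis_codes = I(list()))
  rownames(recs) <- NULL
  recs
}
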