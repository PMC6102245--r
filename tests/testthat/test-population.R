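make_vitals <- function(Y = 4, hs_f = 0.85, hs_m = 0.77, ns = 0.95,
                        rep_f = 0.98, rep_m = 0.98,
                        PR = c(0.003, 0.25, 0.53, 0.48),
                        LS = c(2, 2, 2, 2.74), lhr = c(0, 0, 0),
                        A = 10, hs_year = matrix(0, 2, Y)) {
  vital_rates(LS = LS, PR = PR, SP_f = 0.46, CubSa = 0.84, CubSb = 0.71,
              hs_mu = c(F = cloglog_mortality(hs_f),
                        M = cloglog_mortality(hs_m)),
              hs_year = hs_year,
              ns_mu = cloglog_mortality(ns), ns_year = rep(0, Y),
              rep = c(F = rep_f, M = rep_m), lhr = lhr, n_age_classes = A)
}

test_that("fecundity, harvest_rate and annual_survival follow their formulas", {
  expect_equal(fecundity(2.74, 0.48), 1.3152)
  expect_equal(fecundity(3.1, 0), 0)
  expect_equal(fecundity(2, 1), 2)
  expect_error(fecundity(-1, 0.5), "LS")

  expect_equal(harvest_rate(1, 0.98), 0)
  expect_equal(harvest_rate(0.773, 0.98), 0.22246)
  expect_equal(harvest_rate(0, 1), 1)
  expect_error(harvest_rate(1.2, 0.5), "\\[0,1\\]")

  expect_equal(annual_survival(0.77, 0.95), 0.7315)
  expect_equal(annual_survival(1, 1), 1)
  expect_equal(annual_survival(0, 0.4), 0)
})

test_that("mortality partitions exactly into reported, unreported, survived", {
  set.seed(1)
  HS <- runif(50); Rep <- runif(50)
  expect_equal(harvest_rate(HS, Rep) + (1 - HS) * (1 - Rep) + HS,
               rep(1, 50))
})

test_that("cloglog survival link round-trips and is monotone decreasing", {
  s <- c(1e-6, 0.25, 0.77, 0.85, 1 - 1e-9)
  expect_equal(survival_from_link(cloglog_mortality(s)), s,
               tolerance = 1e-12)
  mu <- cloglog_mortality(0.77)
  expect_equal(survival_from_effects(mu, 0, 0), 0.77)
  eta <- seq(-3, 3, length.out = 30)
  expect_true(all(diff(survival_from_effects(eta)) < 0))
  expect_equal(survival_from_effects(mu, 1e4, 0), 0)   # mortality limit
  expect_equal(survival_from_effects(-1e4, 0, 0), 1)   # survival limit
})

test_that("projection conserves animals under perfect survival, no recruitment", {
  v <- make_vitals(hs_f = 1 - 1e-12, hs_m = 1 - 1e-12, ns = 1 - 1e-12,
                   PR = c(0, 0, 0, 0))
  init <- matrix(100, 10, 2)
  N <- project_abundance(init, v, n_years = 4)
  for (y in 2:4) {
    expect_equal(sum(N$values[2:10, , y]), sum(N$values[, , y - 1]),
                 tolerance = 1e-8)
    expect_equal(N$values[1, , y], c(0, 0), ignore_attr = TRUE)
  }
  # terminal class accumulates its survivors plus the aging 9.5 cohort
  expect_equal(N$values[10, 1, 2], init[9, 1] + init[10, 1],
               tolerance = 1e-8)
})

test_that("projection with zero survival leaves only recruits", {
  v <- make_vitals(hs_f = 1e-15, hs_m = 1e-15)
  init <- matrix(50, 10, 2)
  N <- project_abundance(init, v, n_years = 3)
  expect_equal(N$values[2:10, , 2], matrix(0, 9, 2), ignore_attr = TRUE,
               tolerance = 1e-10)
  expect_gt(N$values[1, 1, 2], 0)   # recruits from lagged females
})

test_that("three-class toy matches hand-computed projection", {
  # S = 0.5 everywhere, 2 recruits per female before sex split and cub
  # survival; recruitment equation: SP_s * CubSa * CubSb * sum(N_F * Fec)
  v <- vital_rates(LS = c(4, 4, 4, 4), PR = c(0.5, 0.5, 0.5, 0.5),
                   SP_f = 0.5, CubSa = 1 - 1e-12, CubSb = 1 - 1e-12,
                   hs_mu = rep(cloglog_mortality(0.5), 2) |>
                     stats::setNames(c("F", "M")),
                   hs_year = matrix(0, 2, 2),
                   ns_mu = cloglog_mortality(1 - 1e-12), ns_year = c(0, 0),
                   rep = c(F = 1, M = 1), lhr = numeric(0), n_age_classes = 3)
  # all animals start in class 2 (class 1, the new recruits, never breeds)
  init <- matrix(c(0, 100, 0, 0, 100, 0), 3, 2)
  N <- project_abundance(init, v, n_years = 2)
  # recruits: 100 class-2 females produce 100 * 4 * 0.5 = 200 cubs, split
  # 50/50 by sex; the class-2 cohort survives into class 3 at S = 0.5
  expect_equal(N$values[, 1, 2], c(100, 0, 50), ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(N$values[, 2, 2], c(100, 0, 50), ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("projection matches the dense matrix oracle on random instances", {
  set.seed(77)
  for (rep_i in 1:5) {
    Y <- sample(3:6, 1)
    v <- make_vitals(Y = Y, hs_f = runif(1, 0.6, 0.95),
                     hs_m = runif(1, 0.6, 0.95), ns = runif(1, 0.85, 0.99),
                     PR = runif(4), LS = runif(4, 1, 3),
                     lhr = rnorm(3, 0, 0.3),
                     hs_year = matrix(rnorm(2 * Y, 0, 0.2), 2, Y))
    init <- matrix(runif(20, 0, 500), 10, 2)
    got <- project_abundance(init, v, n_years = Y + 1)$values
    want <- project_oracle(init, v, n_years = Y + 1)
    expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("totals are non-increasing with zero recruitment and survival <= 1", {
  set.seed(5)
  v <- make_vitals(PR = c(0, 0, 0, 0), hs_year = matrix(rnorm(8, 0, 0.3), 2, 4))
  N <- project_abundance(matrix(runif(20, 10, 100), 10, 2), v, n_years = 5)
  totals <- apply(N$values, 3, sum)
  expect_true(all(diff(totals) <= 1e-9))
})

test_that("cub back-calculation inverts cub survival", {
  expect_equal(back_calculate_cubs(100, 1), 100)
  expect_equal(back_calculate_cubs(100, 0.71), 100 / 0.71)
  expect_equal(back_calculate_cubs(0, 0.5), 0)
  expect_error(back_calculate_cubs(10, 0), "CubSb")
  x <- runif(20, 0, 1e4)
  expect_equal(back_calculate_cubs(x * 0.71, 0.71), x)
})

test_that("initialize_abundance allocates the initial total", {
  ip <- initial_population_prior(21450, matrix(1 / 20, 10, 2))
  slice <- initialize_abundance(ip)
  expect_true(all(slice == 1072.5))
  degenerate <- matrix(0, 10, 2); degenerate[1, 1] <- 1
  slice2 <- initialize_abundance(initial_population_prior(500, degenerate))
  expect_equal(slice2[1, 1], 500)
  expect_equal(sum(slice2), 500)
  packaged <- default_priors_cached()$initial_population
  expect_equal(sum(initialize_abundance(packaged)), 21450, tolerance = 1e-9)
})

test_that("projection rejects invalid inputs", {
  v <- make_vitals()
  expect_error(project_abundance(matrix(1, 10, 2), v, n_years = 1), "n_years")
  expect_error(project_abundance(matrix(-1, 10, 2), v, n_years = 3),
               "nonnegative")
  expect_error(project_abundance(matrix(1, 8, 2), v, n_years = 3), "classes")
})

test_that("abundance arrays export tidily", {
  v <- make_vitals()
  N <- project_abundance(matrix(10, 10, 2), v, n_years = 3, start_year = 2009)
  df <- as.data.frame(N)
  expect_equal(nrow(df), 10 * 2 * 3)
  expect_named(df, c("year", "sex", "age_class", "N"))
  expect_equal(sum(df$N), sum(N$values))
  expect_equal(sort(unique(df$year)), 2009:2011)
})
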