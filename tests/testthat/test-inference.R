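test_that("mcmc_config validates and desk config matches its contract", {
  full <- mcmc_config()
  expect_equal(full$n_iterations, 220000L)
  expect_equal(full$n_chains, 3L)
  expect_equal(full$burn_in, 20000L)
  expect_equal(full$thin, 4L)
  desk <- desk_mcmc_config(seed = 5)
  expect_equal(desk$n_iterations, 20000L)
  expect_equal(desk$burn_in, 2000L)
  expect_equal(desk$seed, 5L)
  expect_error(mcmc_config(n_iterations = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_config(n_chains = 1), "chains")
  expect_error(mcmc_config(thin = 0), "thin")
})

test_that("parameter codec round-trips", {
  Y <- 5
  set.seed(8)
  th <- rnorm(attr(harvestssm:::param_index(Y, 3), "d"))
  p <- theta_to_params(th, Y)
  expect_equal(params_to_theta(p, Y), th, tolerance = 1e-10)
  expect_true(all(p$PR > 0 & p$PR < 1))
  expect_equal(sum(c(p$SP_f, 1 - p$SP_f)), 1)
})

test_that("R and compiled log-posteriors agree (dual-route check)", {
  w <- quick_world(seed = 55, n_years = 4)
  pr <- default_priors_cached()
  model <- harvestssm:::pack_model(w$data, pr)
  Y <- length(w$data$years)
  set.seed(99)
  for (i in 1:12) {
    th <- harvestssm:::init_theta_from_priors(pr, Y, 3)
    lp_r <- log_posterior(th, w$data, pr, is_theta = TRUE)
    lp_c <- harvestssm:::bear_logpost_cpp(th, model)
    expect_equal(lp_r, lp_c, tolerance = 1e-8)
  }
})

test_that("log-posterior is finite at prior means, -Inf out of support", {
  w <- quick_world(seed = 66)
  pr <- default_priors_cached()
  Y <- length(w$data$years)
  params <- list(LS = vapply(pr$LS, prior_mean, 0),
                 PR = vapply(pr$PR, prior_mean, 0),
                 SP_f = 0.46, CubSa = 0.84, CubSb = 0.71,
                 Rep = c(F = 0.98, M = 0.98),
                 hs_mu = c(F = cloglog_mortality(0.85),
                           M = cloglog_mortality(0.77)),
                 hs_year = matrix(0, 2, Y), ns_mu = cloglog_mortality(0.95),
                 ns_year = rep(0, Y), tau_ns = 40,
                 tau_hs = c(F = 40, M = 40), lhr = c(0, 0, 0),
                 N0_total = 4000)
  expect_true(is.finite(log_posterior(params, w$data, pr)))
  th <- params_to_theta(params, Y)
  th[1] <- Inf
  expect_identical(log_posterior(th, w$data, pr, is_theta = TRUE), -Inf)
})

test_that("sampler recovers a conjugate beta-binomial posterior", {
  # y = 12 successes in n = 30, Beta(3, 5) prior -> posterior Beta(15, 23)
  lp <- function(p) {
    if (p[1] <= 0 || p[1] >= 1) return(-Inf)
    dbeta(p[1], 3, 5, log = TRUE) + dbinom(12, 30, p[1], log = TRUE)
  }
  post_mean <- 15 / 38
  chains <- lapply(1:4, function(ch)
    amwg_sample(lp, init = 0.5, n_iterations = 5000, burn_in = 1000,
                step = 0.2, seed = 100 + ch)$draws[, 1])
  pooled <- unlist(chains)
  mcse <- sqrt(mean(vapply(chains, function(x) mcse_batch(x)^2, 0)) / 4)
  expect_lt(abs(mean(pooled) - post_mean), 3 * mcse)
  # posterior sd should also be near the closed form
  expect_equal(stats::sd(pooled), sqrt(15 * 23 / (38^2 * 39)),
               tolerance = 0.15)
  # and the closed-form mode matches the maximizer of the toy posterior
  opt <- stats::optimize(function(p) lp(p), c(0.01, 0.99), maximum = TRUE)
  expect_equal(opt$maximum, (15 - 1) / (38 - 2), tolerance = 1e-4)
})

test_that("amwg draws are seed-deterministic", {
  lp <- function(x) -0.5 * sum(x^2)
  a <- amwg_sample(lp, c(0, 0), 500, 100, step = c(1, 1), seed = 12)
  b <- amwg_sample(lp, c(0, 0), 500, 100, step = c(1, 1), seed = 12)
  expect_identical(a$draws, b$draws)
})

test_that("gelman_rubin follows the classic between/within formulation", {
  set.seed(4)
  x <- rnorm(200)
  # exact duplicate chains: B = 0, Rhat = sqrt((n-1)/n)
  expect_equal(gelman_rubin(cbind(x, x)), sqrt(199 / 200))
  # grossly separated chains
  expect_gt(gelman_rubin(cbind(rnorm(100), rnorm(100, 10))), 5)
  # independent transcription of the formula on random draws
  draws <- matrix(rnorm(3 * 250), 250, 3)
  n <- nrow(draws); m <- ncol(draws)
  W <- mean(apply(draws, 2, var))
  B <- n / (m - 1) * sum((colMeans(draws) - mean(draws))^2)
  expect_equal(gelman_rubin(draws),
               sqrt(((n - 1) / n * W + B / n) / W), tolerance = 1e-6)
  expect_error(gelman_rubin(matrix(x, ncol = 1)), "2 chains")
  expect_error(gelman_rubin(matrix(rnorm(10), 5, 2)), "10 draws")
})

test_that("run_mcmc bookkeeping, determinism and diagnostics", {
  w <- quick_world(seed = 70, n_years = 4, initial_total = 3000)
  pr <- default_priors_cached()
  pr$initial_population$n_total <- 3000
  cfg <- mcmc_config(n_iterations = 900, n_chains = 2, burn_in = 300,
                     thin = 4, seed = 42)
  fit <- run_mcmc(w$data, pr, cfg)
  expect_equal(dim(fit$draws)[1], (900 - 300) %/% 4)
  expect_equal(dim(fit$draws)[2], 2)
  expect_equal(length(fit$years), length(w$data$years) + 1)
  # probability-valued monitors stay in [0, 1], abundance nonnegative
  prob_vars <- grep("^(PR|SP|CubS|Rep|HS|NS)", dimnames(fit$draws)[[3]])
  expect_true(all(fit$draws[, , prob_vars] >= 0 &
                    fit$draws[, , prob_vars] <= 1))
  expect_true(all(fit$abundance >= 0))
  # same seed twice: bit-identical draws
  fit2 <- run_mcmc(w$data, pr, cfg)
  expect_identical(fit$draws, fit2$draws)
  # N_total is the sum of the abundance cells, draw by draw
  A <- fit$A; YY <- length(fit$years)
  nt1 <- fit$draws[, 1, paste0("N_total[", fit$years[1], "]")]
  expect_equal(nt1, rowSums(fit$abundance[, 1, seq_len(A * 2)]),
               ignore_attr = TRUE)
})

test_that("initialization failure names a data year", {
  w <- quick_world(seed = 71, n_years = 4)
  pr <- default_priors_cached()
  # impossible support: a class with positive observed harvest but zero
  # prior allocation (abundance identically zero there)
  props <- pr$initial_population$age_sex_proportions
  props[, 1] <- 0
  props <- props / sum(props)
  pr$initial_population <- initial_population_prior(21450, props)
  has_f <- any(w$data$C[, 1, ] > 0)
  expect_true(has_f)
  expect_error(run_mcmc(w$data, pr, mcmc_config(500, 2, 100, 1, seed = 3)),
               "initialization|year", ignore.case = TRUE)
})

test_that("posterior summaries use the standard percentile rule", {
  w <- quick_world(seed = 72, n_years = 4, initial_total = 3000)
  pr <- default_priors_cached()
  pr$initial_population$n_total <- 3000
  fit <- run_mcmc(w$data, pr, mcmc_config(600, 2, 200, 2, seed = 9))
  s <- posterior_summary(fit)
  expect_named(s, c("variable", "mean", "sd", "q2.5", "q97.5", "rhat"))
  expect_equal(nrow(s), dim(fit$draws)[3])
  v <- dimnames(fit$draws)[[3]][1]
  pooled <- as.vector(fit$draws[, , v])
  expect_equal(s$mean[s$variable == v], mean(pooled))
  expect_equal(s$q2.5[s$variable == v],
               unname(quantile(pooled, 0.025)))
  # constant draws degenerate cleanly; draws 1..100 give the documented CrI
  expect_equal(unname(quantile(1:100, c(0.025, 0.975))), c(3.475, 97.525))
  ab <- abundance_summary(fit)
  expect_equal(nrow(ab), fit$A * 2 * length(fit$years))
  expect_true(all(ab$q2.5 <= ab$q97.5))
  tr <- ntotal_trajectory(fit)
  expect_length(tr, length(fit$years))
  expect_true(all(tr > 0))
})
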