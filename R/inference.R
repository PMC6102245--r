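## MCMC inference: parameter vector codec, model packing for the C++ core,
## the reference R log-posterior, the adaptive Metropolis-within-Gibbs driver,
## Gelman-Rubin diagnostics and posterior summaries.

#' MCMC configuration
#'
#' Defaults match the published full-length analysis (220,000 iterations,
#' 3 chains, 20,000 burn-in, thinning 4). [desk_mcmc_config()] is the scaled
#' testing configuration (20,000 / 3 / 2,000 / 4) used by the simulation
#' studies and tests. Step-size adaptation runs during burn-in only, in
#' batches of 50 updates, targeting per-coordinate acceptance
#' `target_accept`; retained draws therefore form a valid Markov chain.
#'
#' @param n_iterations total iterations per chain.
#' @param n_chains number of chains (>= 2 for Gelman-Rubin).
#' @param burn_in discarded initial iterations (< `n_iterations`).
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed integer; all chain seeds derive from it.
#' @param rhat_threshold convergence threshold (values below indicate
#'   convergence; 1.1 by convention).
#' @param target_accept adaptation target acceptance rate.
#' @param adapt logical; adapt step sizes during burn-in.
#' @return object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 220000, n_chains = 3,
                        burn_in = 20000, thin = 4, seed = 1L,
                        rhat_threshold = 1.1, target_accept = 0.44,
                        adapt = TRUE) {
  if (burn_in >= n_iterations) stop_domain("burn_in must be < n_iterations")
  if (thin < 1) stop_domain("thin must be >= 1")
  if (n_chains < 2) stop_domain("n_chains must be >= 2 for Gelman-Rubin")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_chains = as.integer(n_chains),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed), rhat_threshold = rhat_threshold,
                 target_accept = target_accept, adapt = adapt),
            class = "mcmc_config")
}

#' @rdname mcmc_config
#' @param ... overrides passed to [mcmc_config()].
#' @export
desk_mcmc_config <- function(...) {
  args <- list(n_iterations = 20000, n_chains = 3, burn_in = 2000, thin = 4)
  override <- list(...)
  args[names(override)] <- override
  do.call(mcmc_config, args)
}

## ---- parameter vector codec ------------------------------------------------

param_index <- function(Y, K = 3) {
  i <- list(
    log_LS = 1:4, logit_PR = 5:8, logit_SP = 9L,
    eta_CubSa = 10L, eta_CubSb = 11L,
    eta_Rep_F = 12L, eta_Rep_M = 13L,
    mu_HS_F = 14L, mu_HS_M = 15L,
    eps_HS_F = 15L + seq_len(Y), eps_HS_M = 15L + Y + seq_len(Y),
    ltau_HS_F = 16L + 2L * Y, ltau_HS_M = 17L + 2L * Y,
    mu_NS = 18L + 2L * Y, eps_NS = 18L + 2L * Y + seq_len(Y),
    ltau_NS = 19L + 3L * Y,
    LHR = 19L + 3L * Y + seq_len(K),
    log_N0 = 20L + 3L * Y + K)
  attr(i, "d") <- 20L + 3L * Y + K
  i
}

#' Convert a natural-scale parameter list to the sampling-scale vector
#'
#' @param params named list with elements `LS` (4), `PR` (4), `SP_f`, `CubSa`,
#'   `CubSb`, `Rep` (`c(F=,M=)`), `hs_mu` (`c(F=,M=)`, link scale), `hs_year`
#'   (2 x Y link-scale deviations), `tau_hs` (`c(F=,M=)`), `ns_mu`, `ns_year`
#'   (length Y), `tau_ns`, `lhr` (length K), `N0_total`.
#' @param Y number of data years; `K` number of free age offsets.
#' @param K number of free age-class offsets.
#' @return numeric vector on the unconstrained sampling scale.
#' @export
params_to_theta <- function(params, Y, K = 3) {
  ix <- param_index(Y, K)
  th <- numeric(attr(ix, "d"))
  th[ix$log_LS] <- log(params$LS)
  th[ix$logit_PR] <- stats::qlogis(params$PR)
  th[ix$logit_SP] <- stats::qlogis(params$SP_f)
  th[ix$eta_CubSa] <- cloglog_mortality(params$CubSa)
  th[ix$eta_CubSb] <- cloglog_mortality(params$CubSb)
  th[ix$eta_Rep_F] <- cloglog_mortality(params$Rep[["F"]])
  th[ix$eta_Rep_M] <- cloglog_mortality(params$Rep[["M"]])
  th[ix$mu_HS_F] <- params$hs_mu[["F"]]
  th[ix$mu_HS_M] <- params$hs_mu[["M"]]
  th[ix$eps_HS_F] <- params$hs_year[1, ]
  th[ix$eps_HS_M] <- params$hs_year[2, ]
  th[ix$ltau_HS_F] <- log(params$tau_hs[["F"]])
  th[ix$ltau_HS_M] <- log(params$tau_hs[["M"]])
  th[ix$mu_NS] <- params$ns_mu
  th[ix$eps_NS] <- params$ns_year
  th[ix$ltau_NS] <- log(params$tau_ns)
  th[ix$LHR] <- params$lhr[seq_len(K)]
  th[ix$log_N0] <- log(params$N0_total)
  th
}

#' @rdname params_to_theta
#' @param theta sampling-scale vector.
#' @export
theta_to_params <- function(theta, Y, K = 3) {
  ix <- param_index(Y, K)
  list(LS = exp(theta[ix$log_LS]),
       PR = stats::plogis(theta[ix$logit_PR]),
       SP_f = stats::plogis(theta[ix$logit_SP]),
       CubSa = survival_from_link(theta[ix$eta_CubSa]),
       CubSb = survival_from_link(theta[ix$eta_CubSb]),
       Rep = c(F = survival_from_link(theta[ix$eta_Rep_F]),
               M = survival_from_link(theta[ix$eta_Rep_M])),
       hs_mu = c(F = theta[ix$mu_HS_F], M = theta[ix$mu_HS_M]),
       hs_year = rbind(F = theta[ix$eps_HS_F], M = theta[ix$eps_HS_M]),
       tau_hs = c(F = exp(theta[ix$ltau_HS_F]), M = exp(theta[ix$ltau_HS_M])),
       ns_mu = theta[ix$mu_NS], ns_year = theta[ix$eps_NS],
       tau_ns = exp(theta[ix$ltau_NS]),
       lhr = theta[ix$LHR],
       N0_total = exp(theta[ix$log_N0]))
}

params_to_vitals <- function(params, n_age_classes = 10) {
  vital_rates(LS = params$LS, PR = params$PR, SP_f = params$SP_f,
              CubSa = params$CubSa, CubSb = params$CubSb,
              hs_mu = params$hs_mu, hs_year = params$hs_year,
              ns_mu = params$ns_mu, ns_year = params$ns_year,
              rep = params$Rep, lhr = params$lhr,
              n_age_classes = n_age_classes)
}

## ---- model packing for the C++ core ---------------------------------------

pack_model <- function(data, priors, K = NULL) {
  stopifnot(inherits(data, "harvest_data"),
            inherits(priors, "demographic_priors"))
  A <- dim(data$C)[1]
  K <- K %||% priors$n_age_offsets
  ip <- priors$initial_population
  if (nrow(ip$age_sex_proportions) != A)
    stop_domain("initial-population prior has ", nrow(ip$age_sex_proportions),
                " age classes; data have ", A)
  hyper <- function(sp) c(sp$hyper_a, sp$hyper_b)
  app <- priors$HSf$annual_precision_prior %||% list(shape = 20, rate = 0.5)
  appn <- priors$NS$annual_precision_prior %||% app
  list(A = A, Y = length(data$years), K = as.integer(K),
       O = unname(data$O), n_aged = unname(data$n_aged),
       C = as.numeric(data$C),
       props = as.numeric(ip$age_sex_proportions),
       ls_shape = vapply(priors$LS, function(s) s$hyper_a, 0),
       ls_rate = vapply(priors$LS, function(s) s$hyper_b, 0),
       pr_a = vapply(priors$PR, function(s) s$hyper_a, 0),
       pr_b = vapply(priors$PR, function(s) s$hyper_b, 0),
       sp_a = priors$SP$hyper_a, sp_b = priors$SP$hyper_b,
       cubsa_mu = priors$CubSa$hyper_a,
       cubsa_sd = 1 / sqrt(priors$CubSa$long_term_precision),
       cubsb_mu = priors$CubSb$hyper_a,
       cubsb_sd = 1 / sqrt(priors$CubSb$long_term_precision),
       rep_mu = priors$Rep$hyper_a,
       rep_sd = 1 / sqrt(priors$Rep$long_term_precision),
       hsf_mu0 = priors$HSf$hyper_a,
       hsf_sd = 1 / sqrt(priors$HSf$long_term_precision),
       hsm_mu0 = priors$HSm$hyper_a,
       hsm_sd = 1 / sqrt(priors$HSm$long_term_precision),
       ns_mu0 = priors$NS$hyper_a,
       ns_sd = 1 / sqrt(priors$NS$long_term_precision),
       tauhs_shape = app$shape, tauhs_rate = app$rate,
       taun_shape = appn$shape, taun_rate = appn$rate,
       lhr_sd = priors$age_offset_sd,
       logn0_mu = log(ip$n_total), logn0_sd = ip$dispersion)
}

#' Joint log-posterior on the sampling scale (reference implementation)
#'
#' Pure-R reference for the compiled log-posterior used by [run_mcmc()]:
#' the sum of [joint_loglik()] at the implied abundance trajectory and all
#' prior log-densities (including Jacobians of the log/logit/cloglog sampling
#' transformations and the gamma hyperpriors on annual link-scale precisions).
#' Out-of-support or numerically impossible values yield `-Inf`, never an
#' error. Used as the independent cross-check of the compiled path.
#'
#' @param params natural-scale parameter list (see [params_to_theta()]), or a
#'   sampling-scale vector if `is_theta = TRUE`.
#' @param data a [harvest_data()].
#' @param priors a [demographic_priors()][build_default_priors()].
#' @param is_theta interpret `params` as the sampling-scale vector.
#' @return scalar log-posterior density (sampling scale).
#' @export
log_posterior <- function(params, data, priors, is_theta = FALSE) {
  Y <- length(data$years)
  K <- priors$n_age_offsets
  th <- if (is_theta) params else params_to_theta(params, Y, K)
  if (!all(is.finite(th))) return(-Inf)
  p <- theta_to_params(th, Y, K)
  m <- pack_model(data, priors, K)
  lp <- 0
  lp <- lp + sum(dgamma(p$LS, m$ls_shape, rate = m$ls_rate, log = TRUE) +
                   log(p$LS))
  lp <- lp + sum(dbeta(p$PR, m$pr_a, m$pr_b, log = TRUE) +
                   log(p$PR) + log1p(-p$PR))
  lp <- lp + dbeta(p$SP_f, m$sp_a, m$sp_b, log = TRUE) +
    log(p$SP_f) + log1p(-p$SP_f)
  ix <- param_index(Y, K)
  lp <- lp + dnorm(th[ix$eta_CubSa], m$cubsa_mu, m$cubsa_sd, log = TRUE) +
    dnorm(th[ix$eta_CubSb], m$cubsb_mu, m$cubsb_sd, log = TRUE) +
    dnorm(th[ix$eta_Rep_F], m$rep_mu, m$rep_sd, log = TRUE) +
    dnorm(th[ix$eta_Rep_M], m$rep_mu, m$rep_sd, log = TRUE) +
    dnorm(th[ix$mu_HS_F], m$hsf_mu0, m$hsf_sd, log = TRUE) +
    dnorm(th[ix$mu_HS_M], m$hsm_mu0, m$hsm_sd, log = TRUE) +
    dnorm(th[ix$mu_NS], m$ns_mu0, m$ns_sd, log = TRUE)
  lp <- lp + sum(dgamma(p$tau_hs, m$tauhs_shape, rate = m$tauhs_rate,
                        log = TRUE) + log(p$tau_hs)) +
    dgamma(p$tau_ns, m$taun_shape, rate = m$taun_rate, log = TRUE) +
    log(p$tau_ns)
  lp <- lp + sum(dnorm(p$hs_year[1, ], 0, 1 / sqrt(p$tau_hs[["F"]]), log = TRUE)) +
    sum(dnorm(p$hs_year[2, ], 0, 1 / sqrt(p$tau_hs[["M"]]), log = TRUE)) +
    sum(dnorm(p$ns_year, 0, 1 / sqrt(p$tau_ns), log = TRUE)) +
    sum(dnorm(p$lhr, 0, m$lhr_sd, log = TRUE)) +
    dnorm(th[ix$log_N0], m$logn0_mu, m$logn0_sd, log = TRUE)
  if (!is.finite(lp)) return(-Inf)
  vitals <- params_to_vitals(p, n_age_classes = m$A)
  initial <- p$N0_total * priors$initial_population$age_sex_proportions
  N <- project_abundance(initial, vitals, n_years = Y,
                         start_year = data$years[1])
  ll <- joint_loglik(data, N, vitals)
  if (!is.finite(ll)) return(-Inf)
  lp + ll
}

## ---- sampling --------------------------------------------------------------

init_theta_from_priors <- function(priors, Y, K) {
  ix <- param_index(Y, K)
  th <- numeric(attr(ix, "d"))
  th[ix$log_LS] <- log(vapply(priors$LS, function(s)
    rgamma(1, s$hyper_a, rate = s$hyper_b), 0))
  th[ix$logit_PR] <- stats::qlogis(vapply(priors$PR, function(s)
    rbeta(1, s$hyper_a, s$hyper_b), 0))
  th[ix$logit_SP] <- stats::qlogis(rbeta(1, priors$SP$hyper_a, priors$SP$hyper_b))
  hdraw <- function(sp) rnorm(1, sp$hyper_a, 1 / sqrt(sp$long_term_precision))
  th[ix$eta_CubSa] <- hdraw(priors$CubSa)
  th[ix$eta_CubSb] <- hdraw(priors$CubSb)
  th[ix$eta_Rep_F] <- hdraw(priors$Rep)
  th[ix$eta_Rep_M] <- hdraw(priors$Rep)
  th[ix$mu_HS_F] <- hdraw(priors$HSf)
  th[ix$mu_HS_M] <- hdraw(priors$HSm)
  app <- priors$HSf$annual_precision_prior %||% list(shape = 20, rate = 0.5)
  tauF <- rgamma(1, app$shape, rate = app$rate)
  tauM <- rgamma(1, app$shape, rate = app$rate)
  th[ix$ltau_HS_F] <- log(tauF); th[ix$ltau_HS_M] <- log(tauM)
  th[ix$eps_HS_F] <- rnorm(Y, 0, 1 / sqrt(tauF))
  th[ix$eps_HS_M] <- rnorm(Y, 0, 1 / sqrt(tauM))
  th[ix$mu_NS] <- hdraw(priors$NS)
  appn <- priors$NS$annual_precision_prior %||% app
  tauN <- rgamma(1, appn$shape, rate = appn$rate)
  th[ix$ltau_NS] <- log(tauN)
  th[ix$eps_NS] <- rnorm(Y, 0, 1 / sqrt(tauN))
  th[ix$LHR] <- rnorm(K, 0, min(priors$age_offset_sd, 0.5))
  ip <- priors$initial_population
  th[ix$log_N0] <- rnorm(1, log(ip$n_total), ip$dispersion)
  th
}

default_step_sizes <- function(priors, Y, K) {
  ix <- param_index(Y, K)
  st <- numeric(attr(ix, "d"))
  st[ix$log_LS] <- 1 / sqrt(vapply(priors$LS, function(s) s$hyper_a, 0))
  st[ix$logit_PR] <- sqrt(vapply(priors$PR, function(s)
    trigamma(s$hyper_a) + trigamma(s$hyper_b), 0))
  st[ix$logit_SP] <- sqrt(trigamma(priors$SP$hyper_a) +
                            trigamma(priors$SP$hyper_b))
  st[ix$eta_CubSa] <- 1 / sqrt(priors$CubSa$long_term_precision)
  st[ix$eta_CubSb] <- 1 / sqrt(priors$CubSb$long_term_precision)
  st[c(ix$eta_Rep_F, ix$eta_Rep_M)] <- 1 / sqrt(priors$Rep$long_term_precision)
  st[ix$mu_HS_F] <- 1 / sqrt(priors$HSf$long_term_precision)
  st[ix$mu_HS_M] <- 1 / sqrt(priors$HSm$long_term_precision)
  app <- priors$HSf$annual_precision_prior %||% list(shape = 20, rate = 0.5)
  st[c(ix$eps_HS_F, ix$eps_HS_M)] <- 1 / sqrt(app$shape / app$rate)
  st[c(ix$ltau_HS_F, ix$ltau_HS_M, ix$ltau_NS)] <- 1 / sqrt(app$shape)
  st[ix$mu_NS] <- 1 / sqrt(priors$NS$long_term_precision)
  st[ix$eps_NS] <- st[ix$eps_HS_F[1]]
  st[ix$LHR] <- 0.3
  st[ix$log_N0] <- priors$initial_population$dispersion
  st * 0.5
}

# directions along known posterior ridges, proposed jointly after each
# coordinate sweep: (1) population scale vs harvest mortality (raising log N0
# while lowering both sexes' link-scale harvest mortality leaves expected
# kills nearly unchanged); (2-4) long-term mean vs annual deviations of HS
# (each sex) and NS (the decomposition is only prior-identified); (5-7)
# recruitment-product ridges -- the data identify the total recruitment
# LS * PR * CubSa * CubSb far better than its factors, so pair each factor
# with a compensating move that holds the product fixed at the prior means.
# On the cloglog-mortality link, d log(s) / d eta = log(s); on the logit,
# d log(p) / d logit = 1 - p.
ridge_directions <- function(Y, K, priors) {
  ix <- param_index(Y, K)
  d <- attr(ix, "d")
  dirs <- matrix(0, d, 7)
  dirs[ix$log_N0, 1] <- 1
  dirs[c(ix$mu_HS_F, ix$mu_HS_M), 1] <- -1
  dirs[ix$mu_HS_F, 2] <- 1; dirs[ix$eps_HS_F, 2] <- -1
  dirs[ix$mu_HS_M, 3] <- 1; dirs[ix$eps_HS_M, 3] <- -1
  dirs[ix$mu_NS, 4] <- 1; dirs[ix$eps_NS, 4] <- -1
  sl_a <- log(prior_mean(priors$CubSa))      # d log CubSa / d eta
  sl_b <- log(prior_mean(priors$CubSb))
  dirs[ix$eta_CubSa, 5] <- 1
  dirs[ix$eta_CubSb, 5] <- -sl_a / sl_b      # CubSa * CubSb constant
  ls4 <- ix$log_LS[4]; pr4 <- ix$logit_PR[4]
  dirs[ls4, 6] <- 1                          # LS[5.5+] vs CubSb
  dirs[ix$eta_CubSb, 6] <- -1 / sl_b
  dirs[pr4, 7] <- 1                          # PR[5.5+] vs LS[5.5+]
  dirs[ls4, 7] <- -(1 - prior_mean(priors$PR[[4]]))
  dirs
}

monitor_names <- function(priors, years_all, Y, K) {
  g <- priors$fecundity_groups
  c(paste0("LS[", g, "]"), paste0("PR[", g, "]"), "SP",
    "CubSa", "CubSb", "Rep[F]", "Rep[M]", "HS[F]", "HS[M]", "NS",
    "tau_HS[F]", "tau_HS[M]", "tau_NS",
    paste0("HS[F,", years_all[seq_len(Y)], "]"),
    paste0("HS[M,", years_all[seq_len(Y)], "]"),
    paste0("NS[", years_all[seq_len(Y)], "]"),
    paste0("LHR[", seq_len(K), "]"), "N0_total",
    paste0("N_total[", years_all, "]"))
}

monitor_from_theta <- function(theta_mat, ntot_mat, Y, K) {
  ix <- param_index(Y, K)
  cbind(exp(theta_mat[, ix$log_LS, drop = FALSE]),
        stats::plogis(theta_mat[, ix$logit_PR, drop = FALSE]),
        stats::plogis(theta_mat[, ix$logit_SP]),
        survival_from_link(theta_mat[, ix$eta_CubSa]),
        survival_from_link(theta_mat[, ix$eta_CubSb]),
        survival_from_link(theta_mat[, ix$eta_Rep_F]),
        survival_from_link(theta_mat[, ix$eta_Rep_M]),
        survival_from_link(theta_mat[, ix$mu_HS_F]),
        survival_from_link(theta_mat[, ix$mu_HS_M]),
        survival_from_link(theta_mat[, ix$mu_NS]),
        exp(theta_mat[, ix$ltau_HS_F]), exp(theta_mat[, ix$ltau_HS_M]),
        exp(theta_mat[, ix$ltau_NS]),
        survival_from_link(theta_mat[, ix$mu_HS_F] +
                             theta_mat[, ix$eps_HS_F, drop = FALSE]),
        survival_from_link(theta_mat[, ix$mu_HS_M] +
                             theta_mat[, ix$eps_HS_M, drop = FALSE]),
        survival_from_link(theta_mat[, ix$mu_NS] +
                             theta_mat[, ix$eps_NS, drop = FALSE]),
        theta_mat[, ix$LHR, drop = FALSE],
        exp(theta_mat[, ix$log_N0]),
        ntot_mat)
}

#' Run MCMC for the age-at-harvest state-space model
#'
#' Samples the joint posterior of all modelled parameters with per-coordinate
#' adaptive random-walk Metropolis-within-Gibbs (compiled core). Chains are
#' initialized from independent prior draws (retrying, up to 100 times per
#' chain, if a draw has non-finite posterior density); adaptation is frozen
#' after burn-in. Latent abundance is a deterministic function of the initial
#' total and the vital-rate trajectory, so it is derived per retained draw
#' rather than sampled; the abundance horizon is one year beyond the data
#' (pre-season abundance for the year following the last harvest).
#'
#' @param data a [harvest_data()].
#' @param priors a demographic prior set, see [build_default_priors()].
#' @param config an [mcmc_config()].
#' @param keep_theta keep raw sampling-scale draws (for diagnostics/tests).
#' @return object of class `posterior_samples` with elements `draws`
#'   (array draw x chain x variable, natural-scale monitors incl. annual
#'   `N_total`), `abundance` (array draw x chain x cell for all
#'   age/sex/year abundances), `diagnostics` (`rhat`, `accept`), `config`,
#'   `years` (abundance years) and `data_years`.
#' @export
run_mcmc <- function(data, priors, config = desk_mcmc_config(),
                     keep_theta = FALSE) {
  stopifnot(inherits(config, "mcmc_config"))
  Y <- length(data$years)
  K <- priors$n_age_offsets
  A <- dim(data$C)[1]
  model <- pack_model(data, priors, K)
  step <- default_step_sizes(priors, Y, K)
  dirs <- ridge_directions(Y, K, priors)
  years_all <- c(data$years, data$years[Y] + 1)
  n_keep <- (config$n_iterations - config$burn_in) %/% config$thin
  vars <- monitor_names(priors, years_all, Y, K)
  draws <- array(NA_real_, dim = c(n_keep, config$n_chains, length(vars)),
                 dimnames = list(NULL, NULL, vars))
  abund <- array(NA_real_, dim = c(n_keep, config$n_chains, A * 2 * (Y + 1)))
  accept <- matrix(NA_real_, config$n_chains,
                   attr(param_index(Y, K), "d") + ncol(dirs))
  theta_keep <- if (keep_theta) vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    seed_ch <- derive_seed(config$seed, ch)
    res <- with_seed(seed_ch, {
      init <- NULL
      for (try in 1:100) {
        cand <- init_theta_from_priors(priors, Y, K)
        if (is.finite(bear_logpost_cpp(cand, model))) { init <- cand; break }
      }
      if (is.null(init)) {
        first_bad <- data$years[which.max(data$O)]
        stop_domain("run_mcmc: no finite initialization in 100 prior draws; ",
                    "check data around year ", first_bad)
      }
      bear_mcmc_cpp(model, init, config$n_iterations, config$burn_in,
                    config$thin, step, config$target_accept, config$adapt,
                    dirs, rep(0.1, ncol(dirs)))
    })
    ncells <- bear_project_draws_cpp(model, res$draws)
    ix <- param_index(Y, K)
    ntot <- sapply(seq_len(Y + 1), function(y)
      rowSums(ncells[, (y - 1) * A * 2 + seq_len(A * 2), drop = FALSE]))
    draws[, ch, ] <- monitor_from_theta(res$draws, ntot, Y, K)
    abund[, ch, ] <- ncells
    accept[ch, ] <- res$accept
    if (keep_theta) theta_keep[[ch]] <- res$draws
  }
  rhat <- apply(draws, 3, function(m) gelman_rubin(m))
  out <- structure(list(draws = draws, abundance = abund,
                        diagnostics = list(rhat = rhat, accept = accept),
                        config = config, years = years_all,
                        data_years = data$years, A = A, K = K,
                        age_class = dimnames(data$C)[[1]]),
                   class = "posterior_samples")
  if (keep_theta) attr(out, "theta") <- theta_keep
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("<posterior_samples>", dim(x$draws)[1], "draws x", dim(x$draws)[2],
      "chains x", dim(x$draws)[3], "variables\n")
  cat("  max Rhat:", round(max(x$diagnostics$rhat), 4), "\n")
  invisible(x)
}

#' Generic adaptive Metropolis-within-Gibbs sampler
#'
#' The same compiled per-coordinate random-walk updater used by [run_mcmc()],
#' driven by an arbitrary R log-density. Used for sampler-correctness oracles
#' (conjugate models with closed-form posteriors).
#'
#' @param logpost function taking a numeric vector, returning a log-density
#'   (may be `-Inf` out of support).
#' @param init initial value (finite log-density required).
#' @param n_iterations,burn_in,thin,target_accept,adapt as in [mcmc_config()].
#' @param step initial per-coordinate proposal standard deviations.
#' @param seed integer seed.
#' @return list with `draws` (matrix retained x dim) and `accept`.
#' @export
amwg_sample <- function(logpost, init, n_iterations, burn_in, thin = 1,
                        step = rep(1, length(init)), target_accept = 0.44,
                        adapt = TRUE, seed = 1L) {
  with_seed(seed,
    amwg_generic_cpp(function(th) logpost(th), init, n_iterations, burn_in,
                     thin, step, target_accept, adapt))
}

## ---- diagnostics and summaries --------------------------------------------

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic (non-split) formulation: with `m` chains of `n` draws, within-chain
#' variance `W` = mean of the chain variances, between-chain variance
#' `B = n * var(chain means)`, pooled `V = (n-1)/n * W + B/n`, and
#' `Rhat = sqrt(V / W)`. Exactly duplicated chains give
#' `sqrt((n-1)/n) <= 1`; well-mixed chains give values near 1, and values
#' below 1.1 are conventionally taken to indicate convergence.
#'
#' @param draws matrix of draws, one column per chain (>= 2 columns,
#'   >= 10 rows).
#' @return scalar potential scale reduction factor.
#' @export
gelman_rubin <- function(draws) {
  draws <- as.matrix(draws)
  m <- ncol(draws); n <- nrow(draws)
  if (m < 2) stop_domain("gelman_rubin: need >= 2 chains")
  if (n < 10) stop_domain("gelman_rubin: need >= 10 draws per chain")
  W <- mean(apply(draws, 2, stats::var))
  B <- n * stats::var(colMeans(draws))
  if (W == 0) return(if (B == 0) 1 else Inf)
  V <- (n - 1) / n * W + B / n
  sqrt(V / W)
}

#' Posterior summary table
#'
#' Per monitored variable: posterior mean, standard deviation, central 95%
#' credible interval (2.5 and 97.5 percentiles, default quantile definition)
#' and the Gelman-Rubin statistic.
#'
#' @param samples a `posterior_samples` object from [run_mcmc()].
#' @return data frame with columns `variable`, `mean`, `sd`, `q2.5`, `q97.5`,
#'   `rhat`.
#' @export
posterior_summary <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  vars <- dimnames(samples$draws)[[3]]
  pooled <- apply(samples$draws, 3, identity)      # draws*chains x var
  data.frame(variable = vars,
             mean = colMeans(pooled),
             sd = apply(pooled, 2, stats::sd),
             q2.5 = apply(pooled, 2, stats::quantile, probs = 0.025),
             q97.5 = apply(pooled, 2, stats::quantile, probs = 0.975),
             rhat = samples$diagnostics$rhat,
             row.names = NULL)
}

#' Tidy posterior summary of latent abundance
#'
#' @param samples a `posterior_samples` object.
#' @return data frame with `year`, `sex`, `age_class`, `mean`, `sd`, `q2.5`,
#'   `q97.5` for every abundance cell (including the projection year beyond
#'   the data).
#' @export
abundance_summary <- function(samples) {
  stopifnot(inherits(samples, "posterior_samples"))
  A <- samples$A
  YY <- length(samples$years)
  pooled <- apply(samples$abundance, 3, identity)
  grid <- expand.grid(age_class = samples$age_class, sex = SEX_LABELS,
                      year = samples$years, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  cbind(grid[, c("year", "sex", "age_class")],
        mean = colMeans(pooled),
        sd = apply(pooled, 2, stats::sd),
        q2.5 = apply(pooled, 2, stats::quantile, probs = 0.025),
        q97.5 = apply(pooled, 2, stats::quantile, probs = 0.975))
}

#' Posterior-mean total abundance trajectory
#'
#' @param samples a `posterior_samples` object.
#' @return named numeric vector, one entry per abundance year.
#' @export
ntotal_trajectory <- function(samples) {
  vars <- paste0("N_total[", samples$years, "]")
  pooled <- apply(samples$draws[, , vars, drop = FALSE], 3, mean)
  stats::setNames(pooled, samples$years)
}
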