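## Synthetic harvest-registry generator: a stochastic forward run of the
## population process with known truth, standing in for the real registry.

#' Simulation design for the synthetic harvest registry
#'
#' Defaults state the emulated world: 8 harvest years, an initial population
#' of 21,450 animals (aged 1.5+) allocated by the packaged proportions,
#' vital-rate centres at the prior means, annual link-scale survival
#' deviations with standard deviation `annual_sd_link` (default
#' `1/sqrt(40)`, the mean of the Gamma(20, 0.5) annual-precision hyperprior),
#' near-complete reporting (0.98) and an aged/sexed fraction of 0.859 of the
#' registered harvest.
#'
#' @param n_years number of harvest years (>= 3; the recruitment lag needs
#'   history).
#' @param initial_total year-1 total abundance.
#' @param vitals_center named list overriding any of `LS`, `PR`, `SP_f`,
#'   `CubSa`, `CubSb`, `HS_f`, `HS_m`, `NS`, `Rep_f`, `Rep_m`, `lhr`.
#' @param annual_sd_link sd of annual link-scale survival deviations (0 gives
#'   the deterministic projection).
#' @param aging_rate fraction of the registered harvest successfully
#'   aged/sexed, in (0, 1].
#' @param seed integer seed.
#' @param start_year first calendar year.
#' @param priors demographic priors supplying centres and the initial
#'   allocation (default: packaged set).
#' @return object of class `simulation_design`.
#' @export
simulation_design <- function(n_years = 8, initial_total = 21450,
                              vitals_center = list(),
                              annual_sd_link = 1 / sqrt(40),
                              aging_rate = 0.859, seed = 1L,
                              start_year = 2009, priors = NULL) {
  if (n_years < 3) stop_domain("simulation_design: n_years must be >= 3")
  if (aging_rate <= 0 || aging_rate > 1)
    stop_domain("simulation_design: aging_rate must be in (0,1]")
  if (annual_sd_link < 0) stop_domain("annual_sd_link must be >= 0")
  priors <- priors %||% build_default_priors()
  center <- list(
    LS = vapply(priors$LS, prior_mean, 0),
    PR = vapply(priors$PR, prior_mean, 0),
    SP_f = prior_mean(priors$SP),
    CubSa = prior_mean(priors$CubSa), CubSb = prior_mean(priors$CubSb),
    HS_f = prior_mean(priors$HSf), HS_m = prior_mean(priors$HSm),
    NS = prior_mean(priors$NS),
    Rep_f = prior_mean(priors$Rep), Rep_m = prior_mean(priors$Rep),
    lhr = rep(0, priors$n_age_offsets))
  center[names(vitals_center)] <- vitals_center
  structure(list(n_years = as.integer(n_years),
                 initial_total = initial_total,
                 vitals_center = center,
                 annual_sd_link = annual_sd_link,
                 aging_rate = aging_rate, seed = as.integer(seed),
                 start_year = start_year, priors = priors),
            class = "simulation_design")
}

#' Simulate the latent truth of a harvest system
#'
#' Draws annual survival deviations on the cloglog link scale, builds the full
#' vital-rate set at the design centres, projects abundance for
#' `n_years + 1` years from the allocated initial population, and records
#' expected registered kills `H = N * HR` for the harvest years. The
#' projected abundance satisfies the population-process equations exactly.
#'
#' @param design a [simulation_design()].
#' @return object of class `simulation_truth` with `vitals`, `abundance`,
#'   `expected_kills`, `params` (natural-scale truth incl. `N0_total`) and
#'   `seed`.
#' @export
simulate_truth <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  ct <- design$vitals_center
  Y <- design$n_years
  eff <- with_seed(derive_seed(design$seed, 101L), list(
    hs = matrix(rnorm(2 * Y, 0, design$annual_sd_link), nrow = 2,
                dimnames = list(SEX_LABELS, NULL)),
    ns = rnorm(Y, 0, design$annual_sd_link)))
  vitals <- vital_rates(
    LS = ct$LS, PR = ct$PR, SP_f = ct$SP_f,
    CubSa = ct$CubSa, CubSb = ct$CubSb,
    hs_mu = c(F = cloglog_mortality(ct$HS_f), M = cloglog_mortality(ct$HS_m)),
    hs_year = eff$hs,
    ns_mu = cloglog_mortality(ct$NS), ns_year = eff$ns,
    rep = c(F = ct$Rep_f, M = ct$Rep_m), lhr = ct$lhr)
  ip <- design$priors$initial_population
  initial <- design$initial_total * ip$age_sex_proportions
  N <- project_abundance(initial, vitals, n_years = Y + 1,
                         start_year = design$start_year)
  H <- array(0, dim = c(nrow(initial), 2, Y),
             dimnames = dimnames(vitals$HR))
  for (y in seq_len(Y))
    H[, , y] <- expected_harvest(N$values[, , y], vitals$HR[, , y])
  stopifnot(all(N$values >= 0))
  structure(list(vitals = vitals, abundance = N, expected_kills = H,
                 params = c(ct, list(N0_total = design$initial_total)),
                 seed = design$seed),
            class = "simulation_truth")
}

#' Simulate a harvest registry from a known truth
#'
#' Annual totals are Poisson around the total expected kills; the aged subset
#' size is binomial in the total with the design aging rate (aging failure
#' independent of age and sex), and the aged counts are multinomial across
#' age-sex classes with probabilities proportional to expected kills. The
#' result always satisfies the registry invariants (`sum(C) <= O`).
#'
#' @param truth a [simulate_truth()] result.
#' @param design the [simulation_design()] that produced it.
#' @return a [harvest_data()].
#' @export
simulate_harvest <- function(truth, design) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(design, "simulation_design"))
  Y <- design$n_years
  A <- dim(truth$expected_kills)[1]
  with_seed(derive_seed(design$seed, 202L), {
    C <- array(0L, dim = c(A, 2, Y))
    O <- numeric(Y)
    for (y in seq_len(Y)) {
      H <- truth$expected_kills[, , y]
      O[y] <- rpois(1, sum(H))
      n_aged <- rbinom(1, O[y], design$aging_rate)
      if (n_aged > 0)
        C[, , y] <- array(rmultinom(1, n_aged, as.vector(H / sum(H))),
                          dim = c(A, 2))
    }
    harvest_data(design$start_year + seq_len(Y) - 1, O, C)
  })
}

#' Write a named synthetic fixture to disk
#'
#' Fixtures with a fixed registry shape, used by tests and examples:
#' \describe{
#'   \item{`paper_shape`}{8 years at the default design with the initial
#'     population calibrated (24,200) so that the expected annual kills lie in
#'     the 3952--5133 range characteristic of the published registry; realized
#'     Poisson totals scatter around those expectations.}
#'   \item{`tiny_3class`}{3 collapsed age classes, 3 years, totals below 100;
#'     the oracle-test workhorse.}
#'   \item{`no_noise`}{deterministic expected kills, rounded, aging rate 1.}
#' }
#' Emits `<name>_registry.csv` (long-format registry) and `<name>_truth.json`
#' (vital-rate truth and per-year abundance).
#'
#' @param name fixture identifier.
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @return list with `data`, `truth`, `design` and the written `paths`,
#'   invisibly.
#' @export
make_fixture <- function(name, dir = ".", seed = 1L) {
  known <- c("paper_shape", "tiny_3class", "no_noise")
  if (!name %in% known)
    stop_domain("unknown fixture '", name, "'; available: ",
                paste(known, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (name == "paper_shape") {
    design <- simulation_design(initial_total = 24200, seed = seed)
    truth <- simulate_truth(design)
    data <- simulate_harvest(truth, design)
  } else if (name == "no_noise") {
    design <- simulation_design(annual_sd_link = 0, aging_rate = 1,
                                seed = seed)
    truth <- simulate_truth(design)
    Y <- design$n_years
    C <- round(truth$expected_kills)
    O <- apply(C, 3, sum)
    data <- harvest_data(design$start_year + seq_len(Y) - 1, O, C)
  } else { # tiny_3class
    design <- simulation_design(n_years = 3, initial_total = 400,
                                aging_rate = 1, seed = seed)
    tiny <- tiny_3class_truth(design)
    truth <- tiny$truth
    data <- tiny$data
  }
  reg_path <- file.path(dir, paste0(name, "_registry.csv"))
  truth_path <- file.path(dir, paste0(name, "_truth.json"))
  write_harvest_registry(data, reg_path)
  jsonlite::write_json(list(
    seed = seed, name = name,
    params = truth$params,
    years = truth$abundance$years,
    n_total = as.numeric(apply(truth$abundance$values, 3, sum)),
    abundance = as.numeric(truth$abundance$values)),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(data = data, truth = truth, design = design,
                 paths = c(registry = reg_path, truth = truth_path)))
}

# small 3-age-class world used by oracle tests: collapsed fecundity (classes
# 2 and 3 reproduce), deterministic kills rounded into a tiny registry
tiny_3class_truth <- function(design) {
  Y <- design$n_years
  hs_year <- matrix(0, 2, Y)
  vitals <- vital_rates(LS = c(2, 2, 2, 2), PR = c(0.1, 0.4, 0.5, 0.5),
                        SP_f = 0.5, CubSa = 0.8, CubSb = 0.7,
                        hs_mu = c(F = cloglog_mortality(0.85),
                                  M = cloglog_mortality(0.77)),
                        hs_year = hs_year,
                        ns_mu = cloglog_mortality(0.95),
                        ns_year = rep(0, Y),
                        rep = c(F = 0.98, M = 0.98), lhr = numeric(0),
                        n_age_classes = 3)
  initial <- matrix(design$initial_total / 6, 3, 2)
  N <- project_abundance(initial, vitals, n_years = Y + 1,
                         start_year = design$start_year)
  H <- array(0, dim = c(3, 2, Y))
  for (y in seq_len(Y))
    H[, , y] <- expected_harvest(N$values[, , y], vitals$HR[, , y])
  C <- round(H)
  O <- apply(C, 3, sum)
  truth <- structure(list(vitals = vitals, abundance = N, expected_kills = H,
                          params = list(N0_total = design$initial_total),
                          seed = design$seed),
                     class = "simulation_truth")
  list(truth = truth,
       data = harvest_data(design$start_year + seq_len(Y) - 1, O, C))
}
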