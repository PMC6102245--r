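#' Prior specification for one demographic parameter
#'
#' A `prior_spec` captures one row of the demographic prior table: a named
#' distribution family with hyperparameters, the real-scale mean it implies,
#' and (for hierarchical survival parameters) fixed long-term precision plus
#' an optional gamma hyperprior on the annual link-scale precision.
#'
#' Families:
#' \describe{
#'   \item{`beta`}{`hyper_a` = alpha, `hyper_b` = beta; used for probabilities
#'     (pregnancy rate, newborn sex proportion).}
#'   \item{`gamma`}{`hyper_a` = shape, `hyper_b` = rate; used for litter size.}
#'   \item{`hierarchical-link-normal`}{a normal prior on the complementary
#'     log-log (mortality) link scale: `hyper_a` is the link-scale mean implied
#'     by `real_scale_mean`, `long_term_precision` is the fixed 1/variance of
#'     the long-term mean, and `annual_precision_prior` (if present) is the
#'     (shape, rate) gamma hyperprior on the precision of annual deviations.}
#' }
#'
#' @param name identifier, e.g. `"LS[5.5+]"`.
#' @param family one of `"beta"`, `"gamma"`, `"hierarchical-link-normal"`.
#' @param hyper_a,hyper_b family hyperparameters (see Details); `hyper_b` is
#'   unused for the hierarchical family.
#' @param real_scale_mean the mean on the parameter's natural scale. For beta
#'   and gamma it is derived from the hyperparameters when omitted.
#' @param long_term_precision fixed link-scale precision (hierarchical only).
#' @param annual_precision_prior `list(shape=, rate=)` or `NULL`.
#' @param link `"identity"` or `"cloglog"`.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(name, family,
                       hyper_a = NULL, hyper_b = NULL,
                       real_scale_mean = NULL,
                       long_term_precision = NULL,
                       annual_precision_prior = NULL,
                       link = c("identity", "cloglog")) {
  link <- match.arg(link)
  family <- match.arg(family, c("beta", "gamma", "hierarchical-link-normal"))
  if (family %in% c("beta", "gamma")) {
    if (is.null(hyper_a) || is.null(hyper_b) || hyper_a <= 0 || hyper_b <= 0)
      stop_domain("prior_spec '", name, "': ", family,
                  " family requires positive hyper_a and hyper_b")
    analytic <- if (family == "beta") hyper_a / (hyper_a + hyper_b)
                else hyper_a / hyper_b
    if (is.null(real_scale_mean)) real_scale_mean <- analytic
  } else {
    if (is.null(real_scale_mean) || real_scale_mean <= 0 || real_scale_mean >= 1)
      stop_domain("prior_spec '", name,
                  "': hierarchical-link-normal requires real_scale_mean in (0,1)")
    if (is.null(long_term_precision) || long_term_precision <= 0)
      stop_domain("prior_spec '", name, "': missing positive long_term_precision")
    if (link != "cloglog")
      stop_domain("prior_spec '", name, "': hierarchical family uses link='cloglog'")
    if (is.null(hyper_a)) hyper_a <- cloglog_mortality(real_scale_mean)
  }
  if (!is.null(annual_precision_prior)) {
    ok <- is.list(annual_precision_prior) &&
      all(c("shape", "rate") %in% names(annual_precision_prior)) &&
      annual_precision_prior$shape > 0 && annual_precision_prior$rate > 0
    if (!ok) stop_domain("prior_spec '", name,
                         "': annual_precision_prior must be list(shape>0, rate>0)")
  }
  structure(list(name = name, family = family,
                 hyper_a = hyper_a, hyper_b = hyper_b,
                 real_scale_mean = real_scale_mean,
                 long_term_precision = long_term_precision,
                 annual_precision_prior = annual_precision_prior,
                 link = link),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("<prior_spec %s: %s, mean %.4g>\n", x$name, x$family,
              prior_mean(x)))
  invisible(x)
}

#' Analytic moments of a prior specification
#'
#' `prior_mean()` returns the real-scale analytic mean of the family
#' (beta: a/(a+b); gamma: shape/rate; hierarchical-link-normal: the stated
#' real-scale centre, i.e. the inverse-link of the link-scale mean).
#' `prior_sd()` returns the analytic standard deviation; for the hierarchical
#' family it is a delta-method approximation on the real scale using the
#' long-term precision.
#'
#' @param spec a [prior_spec()].
#' @return a single numeric value.
#' @export
prior_mean <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  switch(spec$family,
    beta  = spec$hyper_a / (spec$hyper_a + spec$hyper_b),
    gamma = spec$hyper_a / spec$hyper_b,
    `hierarchical-link-normal` = spec$real_scale_mean,
    stop_domain("unsupported prior family: ", spec$family))
}

#' @rdname prior_mean
#' @export
prior_sd <- function(spec) {
  stopifnot(inherits(spec, "prior_spec"))
  switch(spec$family,
    beta = {
      a <- spec$hyper_a; b <- spec$hyper_b
      sqrt(a * b / ((a + b)^2 * (a + b + 1)))
    },
    gamma = sqrt(spec$hyper_a) / spec$hyper_b,
    `hierarchical-link-normal` = {
      # delta method: d/d eta exp(-exp(eta)) = -s log(s) at s = mean
      s <- spec$real_scale_mean
      abs(s * log(s)) / sqrt(spec$long_term_precision)
    },
    stop_domain("unsupported prior family: ", spec$family))
}

#' Draw from a prior specification
#'
#' Draws are on the real parameter scale. For hierarchical-link-normal priors
#' the draw is of the long-term mean: a normal draw on the cloglog-mortality
#' link scale with the fixed long-term precision, back-transformed. Annual
#' deviations are the sampler's business, not the prior's.
#'
#' @param spec a [prior_spec()].
#' @param n number of draws (`n = 0` gives an empty vector).
#' @param seed integer seed; draws are deterministic given the seed and the
#'   caller's RNG state is left untouched.
#' @return numeric vector of length `n`.
#' @export
sample_prior <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "prior_spec"), n >= 0)
  if (n == 0) return(numeric(0))
  with_seed(seed, switch(spec$family,
    beta  = rbeta(n, spec$hyper_a, spec$hyper_b),
    gamma = rgamma(n, shape = spec$hyper_a, rate = spec$hyper_b),
    `hierarchical-link-normal` =
      survival_from_link(rnorm(n, mean = spec$hyper_a,
                               sd = 1 / sqrt(spec$long_term_precision))),
    stop_domain("unsupported prior family: ", spec$family)))
}

#' Shift a prior's real-scale mean by a relative bias
#'
#' Used to build the prior-bias sensitivity scenarios. The perturbed prior has
#' real-scale mean `(1 + relative_bias)` times the original:
#' beta priors preserve the concentration `alpha + beta`; gamma priors
#' preserve the rate and rescale the shape; hierarchical priors shift the
#' link-scale mean and leave all precisions unchanged. If the perturbed mean
#' of a probability-valued parameter leaves (0,1), the scenario is infeasible
#' and an `infeasible_prior` object is returned instead of a spec (mirroring
#' N/A rows in a sensitivity table).
#'
#' @param spec a [prior_spec()].
#' @param relative_bias signed fraction, e.g. `-0.10` for a 10\% underestimate.
#' @return a perturbed `prior_spec`, or an `infeasible_prior` object.
#' @export
perturb_prior <- function(spec, relative_bias) {
  stopifnot(inherits(spec, "prior_spec"))
  if (relative_bias <= -1)
    stop_domain("relative_bias must be > -1")
  if (relative_bias == 0) return(spec)
  m_new <- prior_mean(spec) * (1 + relative_bias)
  is_prob <- spec$family == "beta" || spec$family == "hierarchical-link-normal"
  if (is_prob && (m_new >= 1 || m_new <= 0))
    return(structure(list(name = spec$name, relative_bias = relative_bias,
                          perturbed_mean = m_new,
                          reason = "perturbed mean outside (0,1)"),
                     class = "infeasible_prior"))
  out <- spec
  switch(spec$family,
    gamma = {
      out$hyper_a <- spec$hyper_a * (1 + relative_bias)
      out$real_scale_mean <- m_new
    },
    beta = {
      conc <- spec$hyper_a + spec$hyper_b
      out$hyper_a <- conc * m_new
      out$hyper_b <- conc * (1 - m_new)
      out$real_scale_mean <- m_new
    },
    `hierarchical-link-normal` = {
      out$real_scale_mean <- m_new
      out$hyper_a <- cloglog_mortality(m_new)
    })
  out
}

#' @rdname perturb_prior
#' @param x object returned by [perturb_prior()].
#' @export
is_feasible <- function(x) !inherits(x, "infeasible_prior")

## ---- full demographic prior set -------------------------------------------

spec_from_config <- function(node, name, where) {
  need <- function(field) {
    if (is.null(node[[field]]))
      stop_domain("prior config error at '", where, "': missing field '",
                  field, "'")
    node[[field]]
  }
  fam <- need("family")
  if (fam == "gamma") {
    prior_spec(name, "gamma", hyper_a = need("shape"), hyper_b = need("rate"))
  } else if (fam == "beta") {
    prior_spec(name, "beta", hyper_a = need("alpha"), hyper_b = need("beta"))
  } else if (fam == "hierarchical-link-normal") {
    prior_spec(name, "hierarchical-link-normal",
               real_scale_mean = need("mean"),
               long_term_precision = need("long_term_precision"),
               annual_precision_prior = node$annual_precision_prior,
               link = "cloglog")
  } else {
    stop_domain("prior config error at '", where, "': unknown family '",
                fam, "'")
  }
}

#' Build the packaged demographic prior set
#'
#' Reads the packaged prior configuration (or a user-supplied JSON file with
#' the same schema) into a `demographic_priors` object holding: four litter
#' size (LS) gamma priors and four pregnancy rate (PR) beta priors for the
#' fecundity age groups 2.5, 3.5, 4.5 and 5.5+; a beta prior on the female
#' newborn sex proportion (SP); hierarchical cloglog-link survival priors for
#' male/female harvest-season survival (HSm, HSf), non-harvest survival (NS),
#' the two cub survival periods (CubSa: birth to first harvest season, CubSb:
#' first to second harvest season) and the reporting rate (Rep); the age-class
#' offset prior; and the initial-population allocation prior.
#'
#' @param config_path path to a JSON config; `NULL` uses the packaged default.
#' @return an object of class `demographic_priors`.
#' @export
build_default_priors <- function(config_path = NULL) {
  if (is.null(config_path))
    config_path <- system.file("extdata", "priors_default.json",
                               package = "harvestssm")
  if (!file.exists(config_path))
    stop_domain("prior config file not found: ", config_path)
  cfg <- jsonlite::read_json(config_path, simplifyVector = FALSE)
  need <- function(lst, field, where) {
    if (is.null(lst[[field]]))
      stop_domain("prior config error at '", where, "': missing field '",
                  field, "'")
    lst[[field]]
  }
  rec <- need(cfg, "recruitment", "$")
  sur <- need(cfg, "survival", "$")
  ls_nodes <- need(rec, "LS", "recruitment")
  pr_nodes <- need(rec, "PR", "recruitment")
  if (length(ls_nodes) != 4 || length(pr_nodes) != 4)
    stop_domain("prior config error: LS and PR must each have 4 age-group entries")
  groups <- vapply(ls_nodes, function(x) x$group %||% "?", "")
  LS <- lapply(seq_len(4), function(i)
    spec_from_config(ls_nodes[[i]], paste0("LS[", groups[i], "]"),
                     paste0("recruitment$LS[", i, "]")))
  PR <- lapply(seq_len(4), function(i)
    spec_from_config(pr_nodes[[i]], paste0("PR[", pr_nodes[[i]]$group %||% "?", "]"),
                     paste0("recruitment$PR[", i, "]")))
  SP <- spec_from_config(need(rec, "SP", "recruitment"), "SP", "recruitment$SP")
  hier <- function(nm) spec_from_config(need(sur, nm, "survival"), nm,
                                        paste0("survival$", nm))
  ip <- need(cfg, "initial_population", "$")
  props <- need(ip, "age_sex_proportions", "initial_population")
  pm <- cbind(F = unlist(props$F), M = unlist(props$M))
  if (nrow(pm) != 10)
    stop_domain("prior config error: age_sex_proportions must have 10 age classes")
  ipp <- initial_population_prior(
    n_total = need(ip, "n_total", "initial_population"),
    age_sex_proportions = pm,
    dispersion = need(ip, "dispersion", "initial_population"))
  ao <- need(cfg, "age_offsets", "$")
  structure(list(
    LS = LS, PR = PR, SP = SP,
    CubSa = hier("CubSa"), CubSb = hier("CubSb"),
    HSm = hier("HSm"), HSf = hier("HSf"),
    NS = hier("NS"), Rep = hier("Rep"),
    age_offset_sd = need(ao, "prior_sd", "age_offsets"),
    n_age_offsets = need(ao, "n_free", "age_offsets"),
    initial_population = ipp,
    schema_version = cfg$schema_version %||% "1.0",
    fecundity_groups = vapply(ls_nodes, function(x) x$group %||% "?", "")),
    class = "demographic_priors")
}

#' Initial-population allocation prior
#'
#' Centres the year-1 abundance at `n_total` animals allocated across the
#' 10 age classes x 2 sexes by `age_sex_proportions`; `dispersion` is the
#' lognormal standard deviation of the year-1 total used by the sampler.
#'
#' @param n_total expected total abundance in year 1 (animals aged 1.5+).
#' @param age_sex_proportions 10 x 2 matrix (columns `F`, `M`) summing to 1.
#' @param dispersion positive; lognormal sd of the year-1 total.
#' @return an object of class `initial_population_prior`.
#' @export
initial_population_prior <- function(n_total, age_sex_proportions,
                                     dispersion = 0.15) {
  p <- as.matrix(age_sex_proportions)
  if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-9)
    stop_domain("age_sex_proportions must lie in [0,1] and sum to 1 (got sum ",
                format(sum(p), digits = 12), ")")
  if (n_total <= 0 || dispersion <= 0)
    stop_domain("n_total and dispersion must be positive")
  dimnames(p) <- list(AGE_CLASS_LABELS[seq_len(nrow(p))], SEX_LABELS)
  structure(list(n_total = n_total, age_sex_proportions = p,
                 dispersion = dispersion),
            class = "initial_population_prior")
}

#' @export
print.demographic_priors <- function(x, ...) {
  cat("<demographic_priors> schema", x$schema_version, "\n")
  specs <- all_prior_specs(x)
  for (s in specs)
    cat(sprintf("  %-10s %-26s mean %.4g\n", s$name, s$family, prior_mean(s)))
  cat(sprintf("  initial population: %g animals, dispersion %.3g\n",
              x$initial_population$n_total, x$initial_population$dispersion))
  invisible(x)
}

all_prior_specs <- function(priors) {
  c(priors$LS, priors$PR, list(priors$SP, priors$CubSa, priors$CubSb,
                               priors$HSm, priors$HSf, priors$NS, priors$Rep))
}
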