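## Deterministic skeleton of the population process: two-sex, ten-stage
## projection with harvest/non-harvest survival, age-specific fecundity with a
## two-year recruitment lag, an absorbing terminal class and cub
## back-calculation. Abundance is pre-season (immediately before the hunt).

#' Per-female cub production
#'
#' Fecundity of an age group is litter size times pregnancy rate; cub survival
#' to recruitment age is applied once, at recruitment (see
#' [project_abundance()]), not here.
#'
#' @param LS mean litter size (cubs per litter), positive.
#' @param PR pregnancy rate (annual probability of giving birth) in \[0,1\].
#' @return cubs produced per female, `LS * PR`. Vectorized.
#' @export
fecundity <- function(LS, PR) {
  if (any(LS < 0) || any(PR < 0) || any(PR > 1))
    stop_domain("fecundity: LS must be >= 0 and PR in [0,1]")
  LS * PR
}

#' Harvest rate from harvest-season survival and reporting rate
#'
#' The probability that a live pre-season animal is killed during the season
#' and registered: `HR = (1 - HS) * Rep`. The complement of hunting-season
#' mortality that goes unreported, `(1 - HS) * (1 - Rep)`, is lost to the
#' registry.
#'
#' @param HS harvest-season survival in \[0,1\].
#' @param Rep reporting (recovery) rate in \[0,1\].
#' @return harvest rate in \[0,1\]. Vectorized.
#' @export
harvest_rate <- function(HS, Rep) {
  if (any(HS < 0 | HS > 1) || any(Rep < 0 | Rep > 1))
    stop_domain("harvest_rate: HS and Rep must lie in [0,1]")
  (1 - HS) * Rep
}

#' Annual survival as the product of seasonal survivals
#'
#' @param HS harvest-season survival in \[0,1\].
#' @param NS non-harvest-season survival in \[0,1\].
#' @return `HS * NS`. Vectorized.
#' @export
annual_survival <- function(HS, NS) {
  if (any(HS < 0 | HS > 1) || any(NS < 0 | NS > 1))
    stop_domain("annual_survival: HS and NS must lie in [0,1]")
  HS * NS
}

#' Harvest-season survival from additive link-scale effects
#'
#' Survival is modelled on the complementary log-log mortality link:
#' `HS = exp(-exp(sex_mean_link + year_effect + age_offset))`, so each
#' positive additive term increases mortality and decreases survival; as
#' `year_effect` grows without bound survival tends to 0.
#'
#' @param sex_mean_link long-term sex-specific mean on the link scale.
#' @param year_effect annual deviation on the link scale.
#' @param age_offset age-class offset on the link scale (reference class 0).
#' @return survival probability in (0,1). Vectorized.
#' @export
survival_from_effects <- function(sex_mean_link, year_effect = 0,
                                  age_offset = 0) {
  survival_from_link(sex_mean_link + year_effect + age_offset)
}

#' Assemble a full set of vital rates
#'
#' Expands scalar/vector demographic parameters into the arrays the projection
#' needs: harvest-season survival `HS[a,s,y]` built from sex means, annual
#' link-scale deviations and age-class offsets; annual non-harvest survival
#' `NS[y]`; derived annual survival `S = HS * NS`, harvest rate
#' `HR = (1 - HS) * Rep_s`, and per-class fecundity `Fec[a] = LS * PR` mapped
#' from the four fecundity age groups (2.5, 3.5, 4.5, 5.5+) onto the ten
#' abundance classes (class 1, the 1.5-year-olds, reproduces nothing).
#'
#' @param LS,PR length-4 vectors for fecundity groups 2.5/3.5/4.5/5.5+.
#' @param SP_f proportion of newborns that are female.
#' @param CubSa,CubSb cub survival for birth->first season and first->second
#'   season.
#' @param hs_mu named link-scale long-term means, `c(F=, M=)`.
#' @param hs_year 2 x Y matrix (rows `F`, `M`) of link-scale annual deviations.
#' @param ns_mu link-scale long-term mean of non-harvest survival.
#' @param ns_year length-Y link-scale annual deviations.
#' @param rep named reporting rates `c(F=, M=)` on the probability scale.
#' @param lhr link-scale age offsets for classes 1..3 (1.5/2.5/3.5-year-olds);
#'   classes 4+ are the reference (offset 0).
#' @param n_age_classes number of age classes (default 10, terminal absorbing).
#' @return object of class `vital_rates` with elements `HS`, `NS`, `S`, `HR`
#'   (arrays/vectors over `n_age_classes` x 2 sexes x Y years), `Fec`, and the
#'   inputs.
#' @export
vital_rates <- function(LS, PR, SP_f, CubSa, CubSb,
                        hs_mu, hs_year, ns_mu, ns_year, rep,
                        lhr = c(0, 0, 0), n_age_classes = 10) {
  stopifnot(length(LS) == 4, length(PR) == 4)
  Y <- length(ns_year)
  hs_year <- matrix(hs_year, nrow = 2, ncol = Y,
                    dimnames = list(SEX_LABELS, NULL))
  A <- n_age_classes
  lhr_class <- numeric(A)
  lhr_class[seq_len(min(length(lhr), A))] <- lhr[seq_len(min(length(lhr), A))]
  HS <- array(0, dim = c(A, 2, Y))
  for (s in 1:2) for (y in seq_len(Y))
    HS[, s, y] <- survival_from_effects(hs_mu[[s]], hs_year[s, y], lhr_class)
  NS <- survival_from_link(ns_mu + ns_year)
  S <- sweep(HS, 3, NS, `*`)
  HR <- array(0, dim = dim(HS))
  for (s in 1:2) HR[, s, ] <- (1 - HS[, s, ]) * rep[[s]]
  fec_group <- fecundity_group_map(A)
  Fec <- ifelse(fec_group == 0, 0, fecundity(LS, PR)[pmax(fec_group, 1)])
  labs <- age_class_labels(A)
  dn <- list(labs, SEX_LABELS, NULL)
  dimnames(HS) <- dimnames(S) <- dimnames(HR) <- dn
  structure(list(LS = LS, PR = PR, SP_f = SP_f, CubSa = CubSa, CubSb = CubSb,
                 Rep = c(F = rep[["F"]], M = rep[["M"]]),
                 HS = HS, NS = NS, S = S, HR = HR, Fec = Fec,
                 lhr = lhr_class, n_years = Y, n_age_classes = A),
            class = "vital_rates")
}

# map abundance class index -> fecundity group (0 = non-reproducing)
fecundity_group_map <- function(A) {
  g <- c(0, 1, 2, 3, rep(4, max(0, A - 4)))
  g[seq_len(A)]
}

age_class_labels <- function(A) {
  if (A == 10) AGE_CLASS_LABELS
  else c(sprintf("%.1f", seq_len(A - 1) + 0.5), sprintf("%.1f+", A + 0.5))
}

#' Construct an abundance array
#'
#' @param values nonnegative array `A x 2 x Y` (age class, sex `F`/`M`, year).
#' @param start_year calendar year of the first layer (default 2009).
#' @return object of class `abundance_array`.
#' @export
abundance_array <- function(values, start_year = 2009) {
  v <- as.array(values)
  if (length(dim(v)) != 3 || dim(v)[2] != 2)
    stop_domain("abundance values must be an A x 2 x Y array")
  if (any(v < 0)) stop_domain("abundance must be nonnegative")
  dimnames(v) <- list(age_class_labels(dim(v)[1]), SEX_LABELS,
                      start_year + seq_len(dim(v)[3]) - 1)
  structure(list(values = v, start_year = start_year,
                 years = start_year + seq_len(dim(v)[3]) - 1),
            class = "abundance_array")
}

#' @export
print.abundance_array <- function(x, ...) {
  tot <- apply(x$values, 3, sum)
  cat("<abundance_array>", dim(x$values)[1], "age classes x 2 sexes x",
      dim(x$values)[3], "years\n")
  print(round(tot, 1))
  invisible(x)
}

#' Tidy data frame of an abundance array
#'
#' @param x an [abundance_array()].
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with columns `year`, `sex`, `age_class`, `N`.
#' @export
as.data.frame.abundance_array <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  d <- dim(x$values)
  expand <- expand.grid(age_class = dimnames(x$values)[[1]],
                        sex = SEX_LABELS, year = x$years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  expand$N <- as.vector(x$values)
  expand[, c("year", "sex", "age_class", "N")]
}

#' Allocate the initial population across age and sex classes
#'
#' @param prior an [initial_population_prior()].
#' @return `A x 2` matrix of year-1 abundance summing to `n_total`.
#' @export
initialize_abundance <- function(prior) {
  stopifnot(inherits(prior, "initial_population_prior"))
  prior$n_total * prior$age_sex_proportions
}

#' Project abundance forward through the stage-structured process
#'
#' Implements the deterministic population process on pre-season abundance:
#' for interior classes `N[a,s,y] = N[a-1,s,y-1] * S[a-1,s,y-1]`; the terminal
#' class is absorbing, `N[A,s,y] = N[A-1,s,y-1]*S[A-1,s,y-1] +
#' N[A,s,y-1]*S[A,s,y-1]`; recruits carry a two-year lag,
#' `N[1,s,y] = SP_s * CubSa * CubSb * sum_a N[a,F,y-2] * Fec[a]`, with the
#' year-2 boundary convention `N[.,F,0] := N[.,F,1]`. Cub survival enters the
#' recruitment equation exactly once (fecundity itself is `LS * PR`).
#'
#' @param initial `A x 2` nonnegative matrix of year-1 abundance.
#' @param vitals a [vital_rates()] object covering at least `n_years - 1`
#'   years of survival.
#' @param n_years number of years to produce (>= 2).
#' @param start_year calendar year of the first slice.
#' @return an [abundance_array()] with `n_years` layers.
#' @export
project_abundance <- function(initial, vitals, n_years,
                              start_year = 2009) {
  stopifnot(inherits(vitals, "vital_rates"))
  if (n_years < 2) stop_domain("project_abundance: n_years must be >= 2")
  initial <- as.matrix(initial)
  A <- nrow(initial)
  if (A != vitals$n_age_classes)
    stop_domain("initial slice has ", A, " classes but vitals have ",
                vitals$n_age_classes)
  if (any(initial < 0)) stop_domain("initial abundance must be nonnegative")
  if (vitals$n_years < n_years - 1)
    stop_domain("vitals cover ", vitals$n_years, " years; need ", n_years - 1)
  if (any(vitals$S < 0)) stop_domain("negative survival in vitals")
  N <- array(0, dim = c(A, 2, n_years))
  N[, , 1] <- initial
  recr <- vitals$SP_f * c(1, 0) + (1 - vitals$SP_f) * c(0, 1) # (F, M) split
  for (y in 2:n_years) {
    S <- vitals$S[, , y - 1]
    for (s in 1:2) {
      if (A > 2) N[2:(A - 1), s, y] <- N[1:(A - 2), s, y - 1] * S[1:(A - 2), s]
      N[A, s, y] <- N[A - 1, s, y - 1] * S[A - 1, s] +
        N[A, s, y - 1] * S[A, s]
    }
    lag_slice <- if (y == 2) N[, 1, 1] else N[, 1, y - 2]
    production <- sum(lag_slice * vitals$Fec)
    N[1, , y] <- recr * vitals$CubSa * vitals$CubSb * production
  }
  abundance_array(N, start_year = start_year)
}

#' Back-calculate cub abundance from next year's yearlings
#'
#' The model tracks animals from age 1.5; the 0.5-year-old cohort of year
#' `y - 1` is recovered as `N[1.5, s, y] / CubSb`.
#'
#' @param N_1p5_next yearling (1.5-year-old) abundance in year `y`.
#' @param CubSb cub survival from the first to the second harvest season, > 0.
#' @return cub abundance in year `y - 1`; always `>= N_1p5_next`.
#' @export
back_calculate_cubs <- function(N_1p5_next, CubSb) {
  if (any(CubSb <= 0)) stop_domain("back_calculate_cubs: CubSb must be > 0")
  if (any(N_1p5_next < 0)) stop_domain("abundance must be nonnegative")
  N_1p5_next / CubSb
}

#' Write an abundance posterior summary as tidy CSV
#'
#' @param summary_df data frame with columns `year`, `sex`, `age_class`,
#'   `mean`, `sd`, `q2.5`, `q97.5` (see [abundance_summary()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_abundance_csv <- function(summary_df, path) {
  utils::write.csv(summary_df, path, row.names = FALSE)
  invisible(path)
}
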