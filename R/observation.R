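## Two-part harvest observation model: Poisson likelihood for the total
## registered harvest O_y and a multinomial likelihood for the aged/sexed
## subset C[a,s,y], conditioned on the aged subset size.

#' Harvest registry data
#'
#' The model's only data: annual total registered harvest `O` (a complete
#' count of legal harvest) and the aged/sexed counts `C` for animals whose
#' age could be assigned (cementum annuli) and sex recorded. Cubs
#' (0.5-year-olds) are not legally harvestable and never appear.
#'
#' @param years calendar years (consecutive).
#' @param O nonnegative integer totals, one per year.
#' @param C nonnegative integer array `A x 2 x Y` (age class, sex `F`/`M`,
#'   year); must satisfy `sum(C[,,y]) <= O[y]` every year.
#' @param permits optional positive integer permit counts (CPUE only).
#' @return object of class `harvest_data`.
#' @export
harvest_data <- function(years, O, C, permits = NULL) {
  C <- as.array(C)
  Y <- length(years)
  if (length(O) != Y || dim(C)[3] != Y)
    stop_domain("harvest_data: years, O and C disagree on year count")
  if (any(O < 0) || any(O != round(O)))
    stop_domain("harvest_data: O must be nonnegative integers")
  if (any(C < 0) || any(C != round(C)))
    stop_domain("harvest_data: C must be nonnegative integers")
  aged <- apply(C, 3, sum)
  bad <- which(aged > O)
  if (length(bad))
    stop_domain("harvest_data: aged/sexed counts exceed total harvest in year ",
                years[bad[1]], " (sum C = ", aged[bad[1]], " > O = ",
                O[bad[1]], ")")
  if (!is.null(permits)) {
    if (length(permits) != Y || any(permits <= 0))
      stop_domain("harvest_data: permits must be positive, one per year")
  }
  dimnames(C) <- list(age_class_labels(dim(C)[1]), SEX_LABELS, years)
  structure(list(years = years, O = stats::setNames(as.numeric(O), years),
                 C = C, n_aged = stats::setNames(aged, years),
                 permits = permits),
            class = "harvest_data")
}

#' @export
print.harvest_data <- function(x, ...) {
  cat("<harvest_data>", length(x$years), "years (", min(x$years), "-",
      max(x$years), "), ", dim(x$C)[1], "age classes\n")
  cat("  O:", paste(x$O, collapse = " "), "\n")
  cat("  aged fraction:", round(mean(x$n_aged / pmax(x$O, 1)), 3), "\n")
  invisible(x)
}

#' Summary statistics of a harvest registry
#'
#' @param data a [harvest_data()].
#' @return list with `mean_O`, `se_O`, `range_O`, and `aged_fraction` (mean of
#'   the annual aged/sexed proportions of the harvest).
#' @export
harvest_summary <- function(data) {
  stopifnot(inherits(data, "harvest_data"))
  list(mean_O = mean(data$O),
       se_O = stats::sd(data$O) / sqrt(length(data$O)),
       range_O = range(data$O),
       aged_fraction = mean(data$n_aged / pmax(data$O, 1)))
}

## ---- registry CSV dialect --------------------------------------------------

#' Read and write the long-format harvest registry CSV
#'
#' Columns: `year`, `sex` in `{F, M, U}`, `age_class` in
#' `{1.5, 2.5, ..., 9.5, 10.5+, unknown}`, `count`. Rows with sex `U` or age
#' class `unknown` are animals that were registered but not successfully
#' aged/sexed; annual totals `O` are the sum over all rows including unknowns.
#' A separate totals CSV (`year`, `O`) may be supplied and is cross-checked.
#'
#' @param path registry CSV path.
#' @param totals_path optional totals CSV path.
#' @return a [harvest_data()].
#' @export
read_harvest_registry <- function(path, totals_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "sex", "age_class", "count")
  if (!all(need %in% names(df)))
    stop_domain("registry must have columns ", paste(need, collapse = ", "))
  bad <- which(!df$sex %in% c("F", "M", "U") |
                 is.na(suppressWarnings(as.numeric(df$count))) |
                 df$count < 0 | df$count != round(df$count))
  if (length(bad))
    stop_domain("registry validation error at data line ", bad[1],
                ": sex must be F/M/U and count a nonnegative integer")
  years <- sort(unique(df$year))
  known <- df$sex %in% c("F", "M") & df$age_class != "unknown"
  classes <- unique(df$age_class[known])
  A <- length(classes)
  # canonical ordering: numeric age, terminal "+" class last
  ord <- order(suppressWarnings(as.numeric(sub("\\+$", "", classes))))
  classes <- classes[ord]
  C <- array(0L, dim = c(A, 2, length(years)),
             dimnames = list(classes, SEX_LABELS, years))
  kd <- df[known, ]
  for (i in seq_len(nrow(kd)))
    C[as.character(kd$age_class[i]), kd$sex[i], as.character(kd$year[i])] <-
      C[as.character(kd$age_class[i]), kd$sex[i], as.character(kd$year[i])] +
      kd$count[i]
  O <- vapply(years, function(y) sum(df$count[df$year == y]), 0)
  if (!is.null(totals_path)) {
    tot <- utils::read.csv(totals_path)
    if (!all(c("year", "O") %in% names(tot)))
      stop_domain("totals CSV must have columns year, O")
    m <- match(years, tot$year)
    if (anyNA(m)) stop_domain("totals CSV missing year ", years[which(is.na(m))[1]])
    if (any(tot$O[m] != O))
      stop_domain("totals CSV disagrees with registry sums in year ",
                  years[which(tot$O[m] != O)[1]])
  }
  harvest_data(years, O, C)
}

#' @rdname read_harvest_registry
#' @param data a [harvest_data()] to serialize.
#' @return `write_harvest_registry` returns `path`, invisibly.
#' @export
write_harvest_registry <- function(data, path) {
  stopifnot(inherits(data, "harvest_data"))
  rows <- as.data.frame.table(data$C, stringsAsFactors = FALSE)
  names(rows) <- c("age_class", "sex", "year", "count")
  unk <- data.frame(age_class = "unknown", sex = "U",
                    year = as.character(data$years),
                    count = data$O - data$n_aged)
  out <- rbind(rows[, c("year", "sex", "age_class", "count")],
               unk[, c("year", "sex", "age_class", "count")])
  out <- out[out$count > 0 | out$age_class != "unknown", ]
  out <- out[order(out$year, out$sex, out$age_class), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

## ---- likelihood components -------------------------------------------------

#' Expected registered kills by age and sex
#'
#' @param N abundance slice (`A x 2` matrix) for one year.
#' @param HR harvest rates, same shape, each in \[0,1\].
#' @return elementwise `N * HR`.
#' @export
expected_harvest <- function(N, HR) {
  N <- as.matrix(N); HR <- as.matrix(HR)
  if (!all(dim(N) == dim(HR)))
    stop_domain("expected_harvest: N and HR shapes disagree")
  if (any(HR < 0 | HR > 1)) stop_domain("expected_harvest: HR must be in [0,1]")
  N * HR
}

#' Log-likelihood of the total registered harvest
#'
#' Default family is Poisson: `O_y ~ Poisson(sum of expected kills)`. A
#' binomial variant (`O_y ~ Binomial(round(N_total), H_total / N_total)`) is
#' available as a configuration switch; the construction of the original
#' analysis is not recoverable and Poisson is the standard choice for
#' age-at-harvest state-space models.
#'
#' @param O_y observed total (nonnegative integer).
#' @param H_total expected total kills (> 0 unless `O_y` is 0).
#' @param family `"poisson"` or `"binomial"`.
#' @param N_total total pre-season abundance (binomial family only).
#' @return log-likelihood contribution; `-Inf` when the data are impossible
#'   under the expectation.
#' @export
loglik_total <- function(O_y, H_total, family = c("poisson", "binomial"),
                         N_total = NULL) {
  family <- match.arg(family)
  if (O_y < 0) stop_domain("loglik_total: O_y must be nonnegative")
  if (H_total < 0) stop_domain("loglik_total: H_total must be nonnegative")
  if (H_total == 0) return(if (O_y == 0) 0 else -Inf)
  if (family == "poisson") return(stats::dpois(O_y, H_total, log = TRUE))
  if (is.null(N_total) || N_total < H_total)
    stop_domain("binomial family needs N_total >= H_total")
  n <- round(N_total)
  if (O_y > n) return(-Inf)
  stats::dbinom(O_y, n, H_total / N_total, log = TRUE)
}

#' Log-likelihood of the aged/sexed composition
#'
#' Conditional on the aged subset size `n_aged = sum(C_y)`, the counts are
#' multinomial with class probabilities proportional to expected kills, so
#' only sampling variation enters.
#'
#' @param C_y `A x 2` matrix of aged/sexed counts for one year.
#' @param H_y `A x 2` matrix of expected kills; must be positive wherever
#'   `C_y > 0`.
#' @return multinomial log-probability; `-Inf` on a zero-probability cell with
#'   a positive count.
#' @export
loglik_agesex <- function(C_y, H_y) {
  C_y <- as.matrix(C_y); H_y <- as.matrix(H_y)
  if (!all(dim(C_y) == dim(H_y)))
    stop_domain("loglik_agesex: shapes disagree")
  n <- sum(C_y)
  if (n == 0) return(0)
  tot <- sum(H_y)
  if (tot <= 0) return(-Inf)
  p <- H_y / tot
  if (any(C_y > 0 & p <= 0)) return(-Inf)
  keep <- C_y > 0
  lgamma(n + 1) - sum(lgamma(C_y[keep] + 1)) + sum(C_y[keep] * log(p[keep]))
}

#' Joint log-likelihood of a harvest registry
#'
#' Sums the Poisson total-harvest and multinomial composition contributions
#' over years; the likelihood factorizes across years given the latent
#' abundance trajectory.
#'
#' @param data a [harvest_data()].
#' @param N an [abundance_array()] covering (at least) the data years.
#' @param vitals a [vital_rates()] with harvest rates for the data years.
#' @param family total-harvest family, see [loglik_total()].
#' @return scalar log-likelihood.
#' @export
joint_loglik <- function(data, N, vitals, family = "poisson") {
  stopifnot(inherits(data, "harvest_data"), inherits(N, "abundance_array"),
            inherits(vitals, "vital_rates"))
  Y <- length(data$years)
  if (Y == 0) return(0)
  if (dim(N$values)[3] < Y || vitals$n_years < Y)
    stop_domain("joint_loglik: abundance/vitals cover fewer years than data")
  ll <- 0
  for (y in seq_len(Y)) {
    H <- expected_harvest(N$values[, , y], vitals$HR[, , y])
    ll <- ll + loglik_total(data$O[[y]], sum(H), family = family,
                            N_total = sum(N$values[, , y])) +
      loglik_agesex(data$C[, , y], H)
    if (!is.finite(ll)) return(-Inf)
  }
  ll
}
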