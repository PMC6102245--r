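#' @useDynLib harvestssm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta rgamma rnorm rbinom rpois rmultinom dbeta dgamma
#'   dnorm dpois quantile sd var lm coef pf runif
#' @importFrom utils read.csv write.csv packageVersion
NULL

# run `expr` under a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a stream-specific 31-bit seed from a base seed
derive_seed <- function(seed, stream) {
  (as.integer(seed) * 48271L + as.integer(stream) * 7919L) %% 2147483562L + 1L
}

#' Complementary log-log link applied to harvest mortality
#'
#' The survival scale used throughout the hierarchical survival priors:
#' `eta = log(-log(s))` maps a survival probability `s` in (0,1) to the real
#' line, and `survival_from_link()` inverts it, `s = exp(-exp(eta))`.
#' Positive shifts in `eta` increase mortality (decrease survival).
#'
#' @param s survival probability in (0,1)
#' @param eta link-scale value (any real)
#' @return `cloglog_mortality` returns the link-scale value; `survival_from_link`
#'   returns a survival probability in (0,1).
#' @examples
#' survival_from_link(cloglog_mortality(0.85))
#' @export
cloglog_mortality <- function(s) {
  stopifnot(all(s > 0 & s < 1))
  log(-log(s))
}

#' @rdname cloglog_mortality
#' @export
survival_from_link <- function(eta) exp(-exp(eta))

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

AGE_CLASS_LABELS <- c("1.5", "2.5", "3.5", "4.5", "5.5", "6.5", "7.5", "8.5",
                      "9.5", "10.5+")
SEX_LABELS <- c("F", "M")
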