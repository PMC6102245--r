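# shared fixtures, built in code at load time (cheap, deterministic)

default_priors_cached <- local({
  pr <- NULL
  function() {
    if (is.null(pr)) pr <<- build_default_priors()
    pr
  }
})

# small synthetic world used by many tests: 4 years, modest population
quick_world <- function(seed = 11, n_years = 4, initial_total = 4000, ...) {
  design <- simulation_design(n_years = n_years, initial_total = initial_total,
                              seed = seed, ...)
  truth <- simulate_truth(design)
  list(design = design, truth = truth,
       data = simulate_harvest(truth, design))
}

# independent dense-matrix oracle for the projection: stacked state
# x_y = (N_y flattened age-within-sex, previous year's female slice);
# one 3A x 3A matrix per step, recruitment read from the lag block
# (or, on the first step, from the current female block).
project_oracle <- function(initial, vitals, n_years) {
  A <- nrow(initial)
  x <- c(as.vector(initial), initial[, 1])
  out <- array(0, dim = c(A, 2, n_years))
  out[, , 1] <- initial
  recr_split <- c(vitals$SP_f, 1 - vitals$SP_f)
  for (y in 2:n_years) {
    M <- matrix(0, 3 * A, 3 * A)
    S <- vitals$S[, , y - 1]
    for (s in 1:2) {
      off <- (s - 1) * A
      for (a in 1:(A - 1)) M[off + a + 1, off + a] <- S[a, s]
      M[off + A, off + A] <- S[A, s]
    }
    fec_cols <- if (y == 2) seq_len(A) else 2 * A + seq_len(A)
    for (s in 1:2)
      M[(s - 1) * A + 1, fec_cols] <-
        recr_split[s] * vitals$CubSa * vitals$CubSb * vitals$Fec
    M[2 * A + seq_len(A), seq_len(A)] <- diag(A)   # lag register
    x <- as.vector(M %*% x)
    out[, , y] <- matrix(x[seq_len(2 * A)], A, 2)
  }
  out
}

# batch-means Monte-Carlo standard error of a chain mean
mcse_batch <- function(x, n_batch = 30) {
  n <- length(x)
  b <- n %/% n_batch
  means <- vapply(seq_len(n_batch), function(i) mean(x[((i - 1) * b + 1):(i * b)]), 0)
  stats::sd(means) / sqrt(n_batch)
}
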