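# Reference parameter set used throughout: a1 = a2 = 1, gamma = 1/3, so
# rho = 1.5, x_co = (0.75, 0.75), establishment probability 2/3.
p0_model <- function(K = 1e4) bb_model(1, 1, 1/3, K)

# Draw parameter sets satisfying the coexistence condition by rejection.
random_coexistence_params <- function(n, seed = 1L) {
  set.seed(seed)
  out <- vector("list", n)
  i <- 0L
  while (i < n) {
    a1 <- stats::runif(1, 0.2, 3)
    a2 <- stats::runif(1, 0.2, 3)
    g <- stats::runif(1, 0.05, 0.95)
    if (a1 - g * a2 > 0 && a2 - g * a1 > 0) {
      i <- i + 1L
      out[[i]] <- list(a1 = a1, a2 = a2, gamma = g)
    }
  }
  out
}

# Critical resident Galton-Watson ensemble (splitting probability 1/2),
# started at [a1 K]: independent oracle for the Y1 moment checks.
simulate_y1_ensemble <- function(K, a1, n_gens, reps, seed) {
  set.seed(seed)
  y <- rep(floor(a1 * K), reps)
  out <- matrix(0, nrow = reps, ncol = n_gens + 1)
  out[, 1] <- y
  for (n in seq_len(n_gens)) {
    y <- 2 * stats::rbinom(reps, y, 0.5)
    out[, n + 1] <- y
  }
  out
}

# Direct supercritical mutant-lineage Galton-Watson oracle (binomial draws),
# independent of the per-individual uniform construction.
simulate_y2_direct <- function(rho, n_gens, reps, seed) {
  set.seed(seed)
  y <- rep(1, reps)
  for (n in seq_len(n_gens)) y <- 2 * stats::rbinom(reps, y, rho / 2)
  y
}

# Asymptotic two-sample Kolmogorov-Smirnov critical value at level alpha.
ks_critical <- function(n1, n2, alpha = 0.01) {
  sqrt(-0.5 * log(alpha / 2)) * sqrt((n1 + n2) / (n1 * n2))
}
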