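# Coupling rates for the bounding Galton-Watson processes L and U.
# r-_K includes the mutant pressure term gamma * K^(alpha2 - 1); r+_K does
# not (the lower resident bound must absorb mutant competition, the upper
# one must not) -- the asymmetry is intrinsic to the construction.
coupling_rates <- function(mod, alphas) {
  K <- mod$K
  a1 <- mod$a1; a2 <- mod$a2; g <- mod$gamma
  a1l <- alphas[1]; a1u <- alphas[2]; a2e <- alphas[3]
  list(
    r_minus   = 2 * a1 / (a1 + a1 * (1 + K^(a1u - 1)) + g * K^(a2e - 1)),
    r_plus    = 2 * a1 / (a1 + a1 * (1 - K^(a1l - 1))),
    rho_minus = 2 * a2 / (a2 + g * a1 * (1 + K^(a1u - 1)) + K^(a2e - 1)),
    rho_plus  = 2 * a2 / (a2 + g * a1 * (1 - K^(a1l - 1)))
  )
}

check_alphas <- function(alphas, c) {
  if (!is.numeric(alphas) || length(alphas) != 3L || any(!is.finite(alphas)))
    stop("'alphas' must be three finite exponents (alpha_1l, alpha_1u, alpha_2)")
  if (any(alphas <= c) || any(alphas >= 1))
    stop("each exponent in 'alphas' must lie strictly in (c, 1)")
  invisible(alphas)
}

#' Exponent presets for the coupling construction
#'
#' The three exit-time arguments use different orderings of the exponents
#' \eqn{\alpha_{1\ell}, \alpha_{1u}, \alpha_2 \in (c, 1)}: all equal for the
#' mutant exit bound, \eqn{\alpha_{1u} = \alpha_2 < \alpha_{1\ell}} for the
#' lower resident bound, and \eqn{\alpha_2 = \alpha_{1\ell} < \alpha_{1u}}
#' for the upper resident bound.
#'
#' @param c growth-window constant in (1/2, 1).
#' @param which one of \code{"equal"}, \code{"resident_lower"},
#'   \code{"resident_upper"}.
#' @return Numeric length 3: \code{c(alpha_1l, alpha_1u, alpha_2)}.
#' @export
alpha_preset <- function(c = 0.9, which = c("equal", "resident_lower",
                                            "resident_upper")) {
  which <- match.arg(which)
  lo <- c + (1 - c) / 3
  hi <- c + 2 * (1 - c) / 3
  switch(which,
         equal          = c(hi, hi, hi),
         resident_lower = c(hi, lo, lo),
         resident_upper = c(lo, hi, lo))
}

#' One exact generation step of the two-type process
#'
#' Each resident individual \code{j} splits (leaves 2 children) iff its
#' uniform variate \code{u[j]} is at most
#' \eqn{a_1 K / (a_1 K + Z_1 + \gamma Z_2)}, and each mutant iff
#' \code{v[j]} is at most \eqn{a_2 K / (a_2 K + \gamma Z_1 + Z_2)};
#' otherwise it leaves none.
#'
#' @param state numeric length 2, current counts \code{c(Z1, Z2)}.
#' @param mod a \code{\link{bb_model}} with \code{K} set.
#' @param u uniform variates for residents, length at least \code{Z1}.
#' @param v uniform variates for mutants, length at least \code{Z2}.
#' @return Numeric length 2, the next counts (each even).
#' @export
step_populations <- function(state, mod, u, v) {
  stopifnot(inherits(mod, "bb_model"), !is.null(mod$K))
  if (any(state < 0) || any(state != floor(state)))
    stop("'state' must be a pair of nonnegative integers")
  if (length(u) < state[1] || length(v) < state[2])
    stop("insufficient uniform variates for the current population")
  K <- mod$K
  p1 <- mod$a1 * K / (mod$a1 * K + state[1] + mod$gamma * state[2])
  p2 <- mod$a2 * K / (mod$a2 * K + mod$gamma * state[1] + state[2])
  c(if (state[1] > 0) 2 * sum(u[seq_len(state[1])] <= p1) else 0,
    if (state[2] > 0) 2 * sum(v[seq_len(state[2])] <= p2) else 0)
}

#' Coupled simulation of Z, Y, L and U through shared uniforms
#'
#' Simulates the true two-type process \code{Z}, the approximating
#' Galton-Watson process \code{Y} (critical resident component started at
#' \code{[a1 K]} with splitting threshold 1/2; supercritical mutant
#' component started at 1 with threshold \eqn{\rho/2}), and optionally the
#' bounding processes \code{L} and \code{U} with rates
#' \eqn{r^\pm_K, \rho^\pm_K}.  All processes consume the \emph{same}
#' uniform variate for the same (generation, individual index), so that the
#' ordering of the splitting thresholds transfers to a pathwise ordering of
#' the populations: \eqn{L_2(n) \le Y_2(n) \le U_2(n)} always, and
#' \eqn{L \le Z \le U} componentwise on generations before the exit time
#' \eqn{\tau}.
#'
#' @param mod a \code{\link{bb_model}} with \code{K} set and coexistence.
#' @param horizon number of generations to simulate.
#' @param alphas exponents \code{c(alpha_1l, alpha_1u, alpha_2)}, each in
#'   \code{(c, 1)}; see \code{\link{alpha_preset}}.
#' @param c growth-window constant in (1/2, 1).
#' @param seed integer seed for the shared uniform stream.
#' @param include_bounds simulate L and U as well (default TRUE).
#' @param cap per-type population cap; exceeding it aborts with an error.
#' @return A data frame of class \code{"bb_coupled"} with columns
#'   \code{generation, Z1, Z2, Y1, Y2} and, if requested,
#'   \code{L1, L2, U1, U2}; attributes \code{seed, alphas, c, rates, model}.
#' @export
simulate_coupled <- function(mod, horizon, alphas = alpha_preset(c),
                             c = 0.9, seed, include_bounds = TRUE,
                             cap = 1e8) {
  stopifnot(inherits(mod, "bb_model"))
  if (is.null(mod$K)) stop("'K' must be set for stochastic simulation")
  if (!mod$coexistence) stop("the coexistence condition must hold")
  if (c <= 0.5 || c >= 1) stop("'c' must lie strictly in (1/2, 1)")
  check_alphas(alphas, c)
  stopifnot(horizon >= 1, horizon == floor(horizon))
  set.seed(as.integer(seed))

  K <- mod$K
  z0 <- c(floor(mod$a1 * K), 1)
  rates <- coupling_rates(mod, alphas)
  np <- if (include_bounds) 4L else 2L

  res <- matrix(NA_real_, nrow = horizon + 1, ncol = 2 * np)
  cols <- c("Z1", "Z2", "Y1", "Y2", "L1", "L2", "U1", "U2")[seq_len(2 * np)]
  colnames(res) <- cols
  res[1, ] <- rep(z0, np)

  Z <- z0; Y <- z0
  L <- z0; U <- z0
  for (n in seq_len(horizon)) {
    nres <- max(Z[1], Y[1], if (include_bounds) c(L[1], U[1]) else 0)
    nmut <- max(Z[2], Y[2], if (include_bounds) c(L[2], U[2]) else 0)
    u <- stats::runif(nres)
    v <- stats::runif(nmut)
    pz1 <- mod$a1 * K / (mod$a1 * K + Z[1] + mod$gamma * Z[2])
    pz2 <- mod$a2 * K / (mod$a2 * K + mod$gamma * Z[1] + Z[2])
    Z <- c(if (Z[1] > 0) 2 * sum(u[seq_len(Z[1])] <= pz1) else 0,
           if (Z[2] > 0) 2 * sum(v[seq_len(Z[2])] <= pz2) else 0)
    Y <- c(if (Y[1] > 0) 2 * sum(u[seq_len(Y[1])] <= 0.5) else 0,
           if (Y[2] > 0) 2 * sum(v[seq_len(Y[2])] <= mod$rho / 2) else 0)
    if (include_bounds) {
      L <- c(if (L[1] > 0) 2 * sum(u[seq_len(L[1])] <= rates$r_minus / 2) else 0,
             if (L[2] > 0) 2 * sum(v[seq_len(L[2])] <= rates$rho_minus / 2) else 0)
      U <- c(if (U[1] > 0) 2 * sum(u[seq_len(U[1])] <= rates$r_plus / 2) else 0,
             if (U[2] > 0) 2 * sum(v[seq_len(U[2])] <= rates$rho_plus / 2) else 0)
    }
    if (max(Z, Y, if (include_bounds) c(L, U) else 0) > cap)
      stop("population cap exceeded at generation ", n,
           "; partial trajectory discarded")
    res[n + 1, ] <- c(Z, Y, if (include_bounds) c(L, U))
  }
  out <- data.frame(generation = 0:horizon, res)
  class(out) <- c("bb_coupled", "data.frame")
  attr(out, "seed") <- as.integer(seed)
  attr(out, "alphas") <- alphas
  attr(out, "c") <- c
  attr(out, "rates") <- rates
  attr(out, "model") <- mod
  out
}

#' Fast ensemble simulation of the two-type process
#'
#' Distributionally equivalent alternative to composing
#' \code{\link{step_populations}}: per generation the number of splitting
#' individuals of each type is drawn directly from the binomial law with the
#' density-dependent splitting probability.  Suitable for Monte Carlo
#' ensembles; trajectories are not coupled to anything.
#'
#' @param mod a \code{\link{bb_model}} with \code{K} set.
#' @param horizon number of generations.
#' @param reps number of independent replicates.
#' @param seed integer seed.
#' @param start initial counts, default \code{c([a1 K], 1)}.
#' @return List of class \code{"bb_ensemble"} with integer matrices
#'   \code{Z1} and \code{Z2} of dimension \code{reps x (horizon + 1)}
#'   (column \code{n + 1} holds generation \code{n}).
#' @export
simulate_fast <- function(mod, horizon, reps, seed,
                          start = c(floor(mod$a1 * mod$K), 1)) {
  stopifnot(inherits(mod, "bb_model"))
  if (is.null(mod$K)) stop("'K' must be set for stochastic simulation")
  stopifnot(horizon >= 1, reps >= 1)
  set.seed(as.integer(seed))
  K <- mod$K
  Z1 <- matrix(0, nrow = reps, ncol = horizon + 1)
  Z2 <- matrix(0, nrow = reps, ncol = horizon + 1)
  Z1[, 1] <- start[1]; Z2[, 1] <- start[2]
  z1 <- rep(start[1], reps); z2 <- rep(start[2], reps)
  for (n in seq_len(horizon)) {
    p1 <- mod$a1 * K / (mod$a1 * K + z1 + mod$gamma * z2)
    p2 <- mod$a2 * K / (mod$a2 * K + mod$gamma * z1 + z2)
    z1 <- 2 * stats::rbinom(reps, z1, p1)
    z2 <- 2 * stats::rbinom(reps, z2, p2)
    Z1[, n + 1] <- z1; Z2[, n + 1] <- z2
  }
  structure(list(Z1 = Z1, Z2 = Z2, model = mod, seed = as.integer(seed)),
            class = "bb_ensemble")
}

#' Sample the martingale approximant of W
#'
#' Simulates the supercritical binary-splitting Galton-Watson mutant lineage
#' \eqn{Y_2} (one ancestor, splitting probability \eqn{\rho/2}) for
#' \code{n_gens} generations and returns the martingale values
#' \eqn{W(n) = \rho^{-n} Y_2(n)}.  The sample mean is 1 for every n; the
#' atom at 0 converges to the extinction probability \eqn{2/\rho - 1}.
#'
#' @param mod a \code{\link{bb_model}} (only \eqn{\rho} is used).
#' @param n_gens number of generations; \eqn{\rho^{-n}} should be small for
#'   the sample to approximate W.
#' @param reps number of independent lineages.
#' @param seed integer seed.
#' @return Numeric vector of length \code{reps}.
#' @export
martingale_limit_sample <- function(mod, n_gens = 40L, reps, seed) {
  stopifnot(inherits(mod, "bb_model"), n_gens >= 1, reps >= 1)
  set.seed(as.integer(seed))
  y <- rep(1, reps)
  p <- mod$rho / 2
  for (n in seq_len(n_gens)) {
    alive <- y > 0
    if (!any(alive)) break
    y[alive] <- 2 * stats::rbinom(sum(alive), y[alive], p)
  }
  y / mod$rho^n_gens
}

#' Exit times from the tube around the resident equilibrium
#'
#' First generations at which the true process \code{Z} leaves the
#' polynomially narrow tube:
#' \eqn{\tau^{1\ell} = \min\{n : Z_1(n) \le a_1(K - K^{\alpha_{1\ell}})\}},
#' \eqn{\tau^{1u} = \min\{n : Z_1(n) \ge a_1(K + K^{\alpha_{1u}})\}},
#' \eqn{\tau^{2} = \min\{n : Z_2(n) \ge K^{\alpha_2}\}}, and their minimum
#' \eqn{\tau}.  Times not reached within the trajectory's horizon are
#' reported as \code{NA}.
#'
#' @param traj a \code{\link{simulate_coupled}} result, or any data frame
#'   with columns \code{generation, Z1, Z2}.
#' @param mod a \code{\link{bb_model}} with \code{K} set.
#' @param alphas exponents \code{c(alpha_1l, alpha_1u, alpha_2)}; defaults
#'   to the trajectory's own \code{"alphas"} attribute.
#' @return List with integer (or NA) elements \code{tau_1l, tau_1u, tau_2,
#'   tau} and \code{horizon}.
#' @export
exit_times <- function(traj, mod, alphas = attr(traj, "alphas")) {
  stopifnot(is.data.frame(traj), all(c("generation", "Z1", "Z2") %in%
                                     names(traj)))
  if (is.null(alphas))
    stop("'alphas' must be supplied when the trajectory carries none")
  K <- mod$K
  thr_1l <- mod$a1 * (K - K^alphas[1])
  thr_1u <- mod$a1 * (K + K^alphas[2])
  thr_2  <- K^alphas[3]
  first_gen <- function(hit) {
    i <- which(hit)
    if (length(i)) traj$generation[i[1]] else NA_integer_
  }
  t1l <- first_gen(traj$Z1 <= thr_1l)
  t1u <- first_gen(traj$Z1 >= thr_1u)
  t2  <- first_gen(traj$Z2 >= thr_2)
  taus <- c(t1l, t1u, t2)
  tau <- if (all(is.na(taus))) NA_integer_ else min(taus, na.rm = TRUE)
  list(tau_1l = t1l, tau_1u = t1u, tau_2 = t2, tau = tau,
       horizon = max(traj$generation))
}

#' One-step noise ensemble at a fixed density state
#'
#' The density process decomposes as
#' \eqn{X(n+1) = f(X(n)) + \eta(n+1)/\sqrt{K}} where the perturbation
#' \eqn{\eta} has zero mean and per-coordinate variance
#' \eqn{4 x_i p_i(x)(1 - p_i(x))}.  This helper draws \code{reps}
#' independent one-step transitions from the integer state closest to
#' \code{x * K} and returns the realized \eqn{\eta} values together with
#' the theoretical variances.
#'
#' @param mod a \code{\link{bb_model}} with \code{K} set.
#' @param x conditioning density state (rounded to integer counts).
#' @param reps number of one-step replicates.
#' @param seed integer seed.
#' @return List with matrix \code{eta} (\code{reps x 2}), the exact
#'   conditioning density \code{x} used, and \code{var_theory} (length 2).
#' @export
noise_one_step <- function(mod, x, reps, seed) {
  stopifnot(inherits(mod, "bb_model"), !is.null(mod$K))
  check_state(x)
  K <- mod$K
  z <- round(x * K)
  xd <- z / K
  p <- splitting_probs(xd, mod)
  set.seed(as.integer(seed))
  z1n <- 2 * stats::rbinom(reps, z[1], p[1])
  z2n <- 2 * stats::rbinom(reps, z[2], p[2])
  fx <- f_map_(xd, mod)
  eta <- sqrt(K) * cbind(z1n / K - fx[1], z2n / K - fx[2])
  colnames(eta) <- c("eta1", "eta2")
  list(eta = eta, x = xd,
       var_theory = 4 * xd * p * (1 - p))
}

#' Per-generation noise residuals of a trajectory
#'
#' Recovers \eqn{\eta(n+1) = \sqrt{K}\,(X(n+1) - f(X(n)))} along a realized
#' trajectory and verifies the decomposition identity
#' \eqn{X(n+1) - f(X(n)) - \eta(n+1)/\sqrt{K} = 0}.
#'
#' @param traj data frame with columns \code{generation, Z1, Z2}.
#' @param mod a \code{\link{bb_model}} with \code{K} set.
#' @return Data frame with columns \code{generation} (of the arrival state),
#'   \code{eta1, eta2}, and \code{identity_gap} (machine-zero check).
#' @export
noise_residuals <- function(traj, mod) {
  stopifnot(is.data.frame(traj), nrow(traj) >= 2, !is.null(mod$K))
  K <- mod$K
  X <- cbind(traj$Z1, traj$Z2) / K
  n <- nrow(traj)
  out <- lapply(seq_len(n - 1), function(i) {
    fx <- f_map_(X[i, ], mod)
    eta <- sqrt(K) * (X[i + 1, ] - fx)
    gap <- max(abs(X[i + 1, ] - fx - eta / sqrt(K)))
    data.frame(generation = traj$generation[i + 1],
               eta1 = eta[1], eta2 = eta[2], identity_gap = gap)
  })
  do.call(rbind, out)
}
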