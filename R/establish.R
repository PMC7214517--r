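#' Establishment time indices
#'
#' The mutant needs about \eqn{b \log K} generations, \eqn{b = 1/\log\rho},
#' to grow from one individual to order \eqn{K}.  This returns the two
#' integer times used throughout the analysis: the establishment time
#' \eqn{n_1 = [\log_\rho K]}, the gluing time
#' \eqn{n_c = [\log_\rho K^c]} up to which the Galton-Watson approximation
#' is used, and the fractional part \eqn{\{\log_\rho K\} \in [0,1)} that
#' damps the argument of the scaling limit H.
#'
#' @param mod a \code{\link{bb_model}}.
#' @param K carrying capacity (defaults to \code{mod$K}).
#' @param c growth-window constant in (1/2, 1).
#' @return List with \code{n1}, \code{n_c}, \code{frac}.
#' @export
time_indices <- function(mod, K = mod$K, c = 0.9) {
  stopifnot(inherits(mod, "bb_model"), !is.null(K), K >= 2)
  if (c <= 0.5 || c >= 1) stop("'c' must lie strictly in (1/2, 1)")
  lrK <- log(K) / log(mod$rho)
  list(n1 = floor(lrK), n_c = floor(c * lrK), frac = lrK - floor(lrK))
}

#' Glued approximation of the density process
#'
#' Approximates the density \eqn{Z(n)/K} by the Galton-Watson density
#' \eqn{Y(n)/K} up to the gluing time \eqn{n_c}, and by the deterministic
#' flow started there afterwards:
#' \eqn{\tilde Z(n) = Y(n)/K} for \eqn{n \le n_c},
#' \eqn{\tilde Z(n) = f^{n - n_c}(Y(n_c)/K)} for \eqn{n > n_c}.
#'
#' @param traj a \code{\link{simulate_coupled}} result (needs the Y
#'   columns).
#' @param mod a \code{\link{bb_model}} with \code{K} set.
#' @param c growth-window constant in (1/2, 1).
#' @return Data frame with columns \code{generation, Zt1, Zt2} over the
#'   trajectory's horizon.
#' @export
glued_trajectory <- function(traj, mod, c = 0.9) {
  stopifnot(is.data.frame(traj), all(c("Y1", "Y2") %in% names(traj)),
            !is.null(mod$K))
  ti <- time_indices(mod, c = c)
  if (max(traj$generation) < ti$n_c)
    stop("trajectory horizon is shorter than the gluing time n_c = ", ti$n_c)
  K <- mod$K
  gens <- traj$generation
  zt <- matrix(NA_real_, nrow = length(gens), ncol = 2)
  early <- gens <= ti$n_c
  zt[early, ] <- cbind(traj$Y1[early], traj$Y2[early]) / K
  anchor <- c(traj$Y1[gens == ti$n_c], traj$Y2[gens == ti$n_c]) / K
  x <- anchor
  for (n in (ti$n_c + 1):max(gens)) {
    if (n > max(gens)) break
    x <- f_map_(x, mod)
    zt[gens == n, ] <- rep(x, each = sum(gens == n))
  }
  data.frame(generation = gens, Zt1 = zt[, 1], Zt2 = zt[, 2])
}

#' Random initial condition of the deterministic flow
#'
#' Evaluates \eqn{\chi(K) = H(\rho^{-\{\log_\rho K\}} (0, w))}, the random
#' initial condition of the deterministic dynamics describing the
#' population composition around establishment, for a realized value
#' \code{w} of the martingale limit W.  With \code{offset = n} the function
#' returns \eqn{f^n(\chi(K)) = H(\rho^{n - \{\log_\rho K\}} (0, w))}
#' (valid for negative n as well, by the Abel equation).
#'
#' @param w nonnegative realized value of W.
#' @param mod a \code{\link{bb_model}} with coexistence.
#' @param K carrying capacity (defaults to \code{mod$K}).
#' @param offset integer flow offset n (default 0).
#' @param tol tolerance passed to \code{\link{compute_H}}.
#' @return Numeric length 2, the density state.
#' @export
chi_K <- function(w, mod, K = mod$K, offset = 0L, tol = 1e-10) {
  stopifnot(is.numeric(w), length(w) == 1L, is.finite(w), w >= 0)
  ti <- time_indices(mod, K = K)
  if (w == 0) {
    # on extinction of the mutant lineage the flow sits at the resident
    # equilibrium at every offset
    return(mod$x_re)
  }
  compute_H(c(0, w * mod$rho^(offset - ti$frac)), mod, tol = tol)$value
}

#' Probability that the mutant establishes itself
#'
#' In the large-capacity limit the mutant establishes itself alongside the
#' resident with probability \eqn{2(1 - 1/\rho)}, the survival probability
#' of its approximating supercritical Galton-Watson lineage.  The Monte
#' Carlo mode simulates the finite-K process to the establishment time
#' \eqn{n_1 = [\log_\rho K]} and reports the fraction of replicates with
#' \eqn{Z_2(n_1) \ge K^{t}} (default threshold exponent \eqn{t = 1/2},
#' which separates the O(1) extinct cluster from the \eqn{\Theta(K)}
#' established cluster).
#'
#' @param mod a \code{\link{bb_model}} with coexistence (and \code{K} for
#'   Monte Carlo).
#' @param K carrying capacity (defaults to \code{mod$K}).
#' @param reps number of Monte Carlo replicates.
#' @param seed integer seed (Monte Carlo mode).
#' @param mode \code{"analytic"} or \code{"monte_carlo"}.
#' @param threshold_exp establishment threshold exponent in (0, 1).
#' @return List with \code{estimate}, \code{se} (0 for analytic),
#'   \code{mode}, \code{reps}, \code{K}, and optionally \code{warning}.
#' @export
establishment_probability <- function(mod, K = mod$K, reps = 2000L,
                                      seed = 1L,
                                      mode = c("analytic", "monte_carlo"),
                                      threshold_exp = 0.5) {
  stopifnot(inherits(mod, "bb_model"))
  if (!mod$coexistence) stop("the coexistence condition must hold")
  mode <- match.arg(mode)
  if (mode == "analytic")
    return(list(estimate = 2 * (1 - 1 / mod$rho), se = 0,
                mode = mode, reps = NA_integer_, K = NA_real_))
  if (is.null(K)) stop("'K' is required for Monte Carlo mode")
  stopifnot(threshold_exp > 0, threshold_exp < 1)
  modK <- if (!is.null(mod$K) && mod$K == K) mod else
    bb_model(mod$a1, mod$a2, mod$gamma, K)
  ti <- time_indices(modK, K = K)
  ens <- simulate_fast(modK, horizon = ti$n1, reps = reps, seed = seed)
  est <- ens$Z2[, ti$n1 + 1] >= K^threshold_exp
  p <- mean(est)
  out <- list(estimate = p, se = sqrt(p * (1 - p) / reps),
              mode = mode, reps = as.integer(reps), K = K)
  if (reps < 100)
    out$warning <- "fewer than 100 replicates; standard error unreliable"
  out
}

#' Deterministic-flow approximation error across carrying capacities
#'
#' For each K, simulates coupled replicates of the true process Z and the
#' approximating Galton-Watson process Y, extracts the per-replicate
#' martingale approximant \eqn{W \approx \rho^{-n_c} Y_2(n_c)}, and
#' compares the realized density \eqn{X(n_1 + n)} with the deterministic
#' flow \eqn{f^n(\chi(K))} started from the replicate's own random initial
#' condition, at every requested offset n (negative offsets use the Abel
#' equation).  Also reports the two-sample Kolmogorov-Smirnov distance
#' between the mutant densities \eqn{\{X_2(n_1)\}} and \eqn{\{\chi_2(K)\}}
#' across replicates.
#'
#' @param mod a \code{\link{bb_model}} (K taken from \code{K_list}).
#' @param K_list carrying capacities to compare.
#' @param reps replicates per K.
#' @param offsets integer offsets n; \code{n1 + n} must be >= 0.
#' @param seed integer seed.
#' @param c growth-window constant in (1/2, 1).
#' @param tol H-evaluation tolerance.
#' @return List with data frame \code{by_offset} (columns \code{K, offset,
#'   mean_sup_diff, se}), data frame \code{ks} (columns \code{K,
#'   ks_statistic}), and the call parameters.
#' @export
flow_discrepancy <- function(mod, K_list, reps = 300L,
                                 offsets = -2:3, seed = 1L, c = 0.9,
                                 tol = 1e-8) {
  stopifnot(inherits(mod, "bb_model"), all(K_list >= 2), reps >= 1)
  offsets <- sort(unique(as.integer(offsets)))
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L,
                          length(K_list) * reps)
  by_offset <- list(); ks_rows <- list()
  idx <- 0L
  for (ki in seq_along(K_list)) {
    K <- K_list[ki]
    modK <- bb_model(mod$a1, mod$a2, mod$gamma, K)
    ti <- time_indices(modK, c = c)
    if (ti$n1 + min(offsets) < 0)
      stop("offset ", min(offsets), " reaches below generation 0 at K = ", K)
    horizon <- ti$n1 + max(0L, max(offsets))
    diffs <- matrix(NA_real_, nrow = reps, ncol = length(offsets))
    x2_n1 <- numeric(reps); chi2 <- numeric(reps)
    for (r in seq_len(reps)) {
      idx <- idx + 1L
      traj <- simulate_coupled(modK, horizon = horizon,
                               c = c, seed = rep_seeds[idx],
                               include_bounds = FALSE)
      W <- traj$Y2[ti$n_c + 1] / modK$rho^ti$n_c
      # flow values at all offsets from a single H evaluation where possible
      neg <- offsets[offsets < 0]
      flow <- matrix(NA_real_, nrow = length(offsets), ncol = 2)
      chi0 <- chi_K(W, modK, K = K, offset = 0L, tol = tol)
      for (j in seq_along(offsets)) {
        n <- offsets[j]
        flow[j, ] <- if (n >= 0) f_iter(chi0, n, modK)
                     else chi_K(W, modK, K = K, offset = n, tol = tol)
      }
      for (j in seq_along(offsets)) {
        n <- offsets[j]
        Xn <- c(traj$Z1[ti$n1 + n + 1], traj$Z2[ti$n1 + n + 1]) / K
        diffs[r, j] <- max(abs(Xn - flow[j, ]))
      }
      x2_n1[r] <- traj$Z2[ti$n1 + 1] / K
      chi2[r] <- chi0[2]
    }
    for (j in seq_along(offsets))
      by_offset[[length(by_offset) + 1L]] <-
        data.frame(K = K, offset = offsets[j],
                   mean_sup_diff = mean(diffs[, j]),
                   se = stats::sd(diffs[, j]) / sqrt(reps))
    ks <- suppressWarnings(stats::ks.test(x2_n1, chi2)$statistic)
    ks_rows[[ki]] <- data.frame(K = K, ks_statistic = unname(ks))
  }
  list(by_offset = do.call(rbind, by_offset),
       ks = do.call(rbind, ks_rows),
       reps = reps, offsets = offsets, c = c, seed = as.integer(seed))
}
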