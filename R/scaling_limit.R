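#' Iterate the deterministic density map
#'
#' Returns the finite trajectory \eqn{x_0, f(x_0), \dots, f^n(x_0)}.
#'
#' @param x0 starting density state, numeric length 2, nonnegative.
#' @param n number of steps, nonnegative integer.
#' @param mod a \code{\link{bb_model}}.
#' @return A numeric matrix with \code{n + 1} rows and columns
#'   \code{x1, x2}; row \code{k} is \eqn{f^{k-1}(x_0)}.
#' @export
iterate_map <- function(x0, n, mod) {
  check_state(x0)
  stopifnot(length(n) == 1L, is.finite(n), n >= 0, n == floor(n))
  out <- matrix(NA_real_, nrow = n + 1, ncol = 2,
                dimnames = list(NULL, c("x1", "x2")))
  out[1, ] <- x0
  x <- x0
  if (n > 0) for (k in seq_len(n)) {
    x <- f_map_(x, mod)
    out[k + 1, ] <- x
  }
  out
}

# Smallest n >= 0 such that x_re + x / rho^n lies in the forward-invariant
# set [x_co1, Inf) x [0, x_co2] (absolute coordinates), together with the
# damped perturbation x / rho^n.  Returns NULL if no admissible n exists
# within the cap (only possible for x1 <= a1 * (x_co1/a1 - 1) ... i.e. never
# for finite x since the set is approached geometrically).
admissible_start <- function(x, mod, cap = 700L) {
  lo1 <- mod$x_co[1] - mod$a1        # negative under coexistence
  hi2 <- mod$x_co[2]
  scaled <- x
  n <- 0L
  while ((scaled[1] < lo1 || scaled[2] > hi2) && n < cap) {
    scaled <- scaled / mod$rho
    n <- n + 1L
  }
  if (scaled[1] < lo1 || scaled[2] > hi2) return(NULL)
  list(n0 = n, scaled = scaled)
}

#' Scaling limit H of the iterated map along the unstable direction
#'
#' Numerically evaluates
#' \eqn{H(x) = \lim_{n\to\infty} f^n(x_{re} + x/\rho^n)} for
#' \eqn{x \in R \times R_+}.  The limit exists uniformly on compacts and
#' maps the scaled early randomness of the invading mutant lineage to a
#' macroscopic density state; it solves the Abel functional equation
#' \eqn{H(x) = f(H(x/\rho))} with \eqn{H(0) = x_{re}}.
#'
#' The perturbation \eqn{x/\rho^n} is computed by repeated division (never
#' by forming \eqn{\rho^n}), and iteration starts from the smallest \eqn{n}
#' for which the start point lies in the forward-invariant set
#' \eqn{[x_{co,1}, \infty) \times [0, x_{co,2}]}; successive iterates
#' \eqn{f^n(x_{re} + x/\rho^n)} are compared in sup norm and the iteration
#' stops when the increment drops below \code{tol}.  The increments decay
#' geometrically at rate \eqn{1/\rho}.
#'
#' @param x perturbation, numeric length 2 with \code{x[2] >= 0} (the first
#'   coordinate may be negative).
#' @param mod a \code{\link{bb_model}} with \code{coexistence} TRUE.
#' @param tol stopping tolerance on the sup-norm of successive differences.
#' @param max_n iteration cap.
#' @return An object of class \code{"bb_H"}: list with \code{input},
#'   \code{value} (length-2 numeric, the H value), \code{iterations},
#'   \code{last_increment}, \code{converged}, and \code{increments} (the
#'   sup-norm successive differences indexed by n, useful for convergence
#'   diagnostics).
#' @export
compute_H <- function(x, mod, tol = 1e-10, max_n = 700L) {
  stopifnot(inherits(mod, "bb_model"))
  if (!mod$coexistence)
    stop("the coexistence condition must hold to evaluate H")
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop("'x' must be a finite numeric vector of length 2")
  if (x[2] < 0)
    stop("the mutant coordinate of 'x' must be nonnegative")

  adm <- admissible_start(x, mod, cap = max_n)
  if (is.null(adm))
    stop("no admissible start point x_re + x/rho^n within the iteration cap")
  n0 <- adm$n0
  scaled <- adm$scaled

  if (all(x == 0))
    return(structure(list(input = x, value = mod$x_re, iterations = n0,
                          last_increment = 0, converged = TRUE,
                          increments = numeric(0)),
                     class = "bb_H"))
  # value at n = n0
  prev <- f_iter(mod$x_re + scaled, n0, mod)
  increments <- numeric(0)
  converged <- FALSE
  n <- n0
  while (n < max_n) {
    n <- n + 1L
    scaled <- scaled / mod$rho
    cur <- f_iter(mod$x_re + scaled, n, mod)
    d <- max(abs(cur - prev))
    increments <- c(increments, d)
    prev <- cur
    if (d < tol) { converged <- TRUE; break }
  }
  structure(list(input = x, value = prev, iterations = n,
                 last_increment = if (length(increments))
                   increments[length(increments)] else 0,
                 converged = converged, increments = increments),
            class = "bb_H")
}

# n-fold application of f without validation
f_iter <- function(x, n, mod) {
  if (n > 0) for (k in seq_len(n)) x <- f_map_(x, mod)
  x
}

#' @export
print.bb_H <- function(x, ...) {
  cat(sprintf("H(%.6g, %.6g) = (%.10g, %.10g)\n",
              x$input[1], x$input[2], x$value[1], x$value[2]))
  cat(sprintf("  iterations %d, last increment %.3g, converged: %s\n",
              x$iterations, x$last_increment, x$converged))
  invisible(x)
}

#' Residual of the Abel functional equation for H
#'
#' Computes \eqn{\|H(x) - f(H(x/\rho))\|_\infty} with both H evaluations at
#' tolerance \code{tol}.  The theoretical value is 0 for every admissible x.
#'
#' @inheritParams compute_H
#' @return A nonnegative number.
#' @export
abel_residual <- function(x, mod, tol = 1e-10) {
  h1 <- compute_H(x, mod, tol = tol)
  h2 <- compute_H(x / mod$rho, mod, tol = tol)
  max(abs(h1$value - f_map_(h2$value, mod)))
}

#' Tabulate H on a grid of perturbations
#'
#' Evaluates H at every pair \code{(x1, w)} from the supplied grids, with
#' the mutant coordinate \code{w >= 0}.  The tabulation supports the
#' numerical observation that H is essentially flat in the resident
#' perturbation coordinate.
#'
#' @param w_values nonnegative mutant perturbations.
#' @param x1_values resident perturbations (may be negative).
#' @param mod a \code{\link{bb_model}} with coexistence.
#' @param tol per-evaluation tolerance passed to \code{\link{compute_H}}.
#' @return A data frame with columns \code{x1, w, H1, H2, iterations,
#'   last_increment, converged}; failed evaluations are flagged with
#'   \code{converged = NA} rather than aborting the grid.
#' @export
h_grid <- function(w_values, x1_values, mod, tol = 1e-10) {
  stopifnot(all(is.finite(w_values)), all(w_values >= 0),
            all(is.finite(x1_values)))
  gr <- expand.grid(x1 = x1_values, w = w_values)
  rows <- lapply(seq_len(nrow(gr)), function(i) {
    res <- tryCatch(compute_H(c(gr$x1[i], gr$w[i]), mod, tol = tol),
                    error = function(e) NULL)
    if (is.null(res))
      return(data.frame(x1 = gr$x1[i], w = gr$w[i], H1 = NA_real_,
                        H2 = NA_real_, iterations = NA_integer_,
                        last_increment = NA_real_, converged = NA))
    data.frame(x1 = gr$x1[i], w = gr$w[i],
               H1 = res$value[1], H2 = res$value[2],
               iterations = res$iterations,
               last_increment = res$last_increment,
               converged = res$converged)
  })
  do.call(rbind, rows)
}

#' Auxiliary one-dimensional quadratic recursion
#'
#' The triangular array \eqn{x_{m,n} = \rho x_{m-1,n}(1 + C x_{m-1,n})},
#' started from \eqn{x_{0,n} = x/\rho^n}, which dominates the sup norm of
#' the translated map's iterates and whose diagonal \eqn{x_{n,n}} converges
#' to \eqn{\phi^{-1}(x)} (for \eqn{C = 1}), where \eqn{\phi} is the
#' Schroeder function of \code{\link{schroeder_phi}}.
#'
#' @param x nonnegative start value.
#' @param C nonnegative quadratic coefficient.
#' @param rho growth rate, > 1.
#' @param n depth of the array.
#' @return Numeric vector of length \code{n + 1}: \eqn{x_{0,n}, \dots,
#'   x_{n,n}}.
#' @export
auxiliary_recursion <- function(x, C, rho, n) {
  stopifnot(is.finite(x), x >= 0, is.finite(C), C >= 0,
            is.finite(rho), rho > 1, n >= 0, n == floor(n))
  out <- numeric(n + 1)
  v <- x / rho^n
  out[1] <- v
  if (n > 0) for (m in seq_len(n)) {
    v <- rho * v * (1 + C * v)
    out[m + 1] <- v
  }
  out
}

#' Schroeder function of the inverse parabola
#'
#' For \eqn{s = 1/\rho \in (0,1)} and the inverse parabola
#' \eqn{f(x) = \sqrt{1/4 + s x} - 1/2} (the inverse of
#' \eqn{p(y) = \rho y (1 + y)} on the nonnegative half-line), the Schroeder
#' function \eqn{\phi(x) = \lim_n f^n(x)/s^n} solves
#' \eqn{\phi(f(x)) = s\,\phi(x)} with \eqn{\phi(0) = 0},
#' \eqn{\phi'(0+) = 1}, and is strictly increasing.  Its inverse gives the
#' conjugacy \eqn{p(y) = \phi^{-1}(\rho\,\phi(y))}, hence
#' \eqn{p^n(x/\rho^n) \to \phi^{-1}(x)}.
#'
#' @param x nonnegative evaluation point (vectorized).
#' @param rho growth rate, > 1.
#' @param tol relative stopping tolerance for the limit iteration.
#' @return Numeric vector, \eqn{\phi(x)}.
#' @export
schroeder_phi <- function(x, rho, tol = 1e-14) {
  stopifnot(all(is.finite(x)), all(x >= 0), is.finite(rho), rho > 1)
  s <- 1 / rho
  vapply(x, function(x0) {
    if (x0 == 0) return(0)
    y <- x0
    r <- x0                     # f^0(x)/s^0
    for (iter in 1:100000) {
      # f(y) = sqrt(1/4 + s y) - 1/2 written without cancellation:
      # f(y) = s y / (sqrt(1/4 + s y) + 1/2), so f(y)/(s y) is computed
      # stably even for tiny y
      ratio <- 1 / (sqrt(0.25 + s * y) + 0.5)   # = f(y) / (s y)
      rnew <- r * ratio
      if (abs(rnew - r) <= tol * abs(rnew)) return(rnew)
      y <- s * y * ratio
      r <- rnew
    }
    stop("Schroeder iteration failed to converge")
  }, numeric(1))
}

#' Inverse of the Schroeder function
#'
#' Monotone bisection for \eqn{\phi^{-1}(z)}, with the upper bracket grown
#' geometrically until it encloses \code{z}.
#'
#' @param z nonnegative value in the range of \eqn{\phi} (vectorized).
#' @inheritParams schroeder_phi
#' @param bisect_tol absolute tolerance of the bisection.
#' @return Numeric vector, \eqn{\phi^{-1}(z)}.
#' @export
schroeder_phi_inv <- function(z, rho, tol = 1e-14, bisect_tol = 1e-12) {
  stopifnot(all(is.finite(z)), all(z >= 0))
  vapply(z, function(z0) {
    if (z0 == 0) return(0)
    hi <- max(z0, 1)
    while (schroeder_phi(hi, rho, tol) < z0) hi <- 2 * hi
    lo <- 0
    # stop at the absolute tolerance or at floating-point bracket resolution,
    # whichever is reached first (phi^-1 grows super-exponentially, so large
    # values cannot be located to a fixed absolute tolerance)
    while (hi - lo > bisect_tol + 4 * .Machine$double.eps * hi) {
      mid <- (lo + hi) / 2
      if (mid <= lo || mid >= hi) break
      if (schroeder_phi(mid, rho, tol) < z0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
}
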