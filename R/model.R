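#' Two-type Bare Bones model with carrying capacity
#'
#' Constructs and validates the parameter set of the two-type binary-splitting
#' model and derives its basic constants: the mutant reproductive value
#' \eqn{\rho}, the time constant \eqn{b = 1/\log\rho}, the four fixed points
#' of the deterministic density map, the coexistence flag, and a numerical
#' bound \eqn{\tilde\rho} on the sup-norm of the Jacobian of the map over the
#' nonnegative quadrant.
#'
#' The model describes a resident population with carrying capacity
#' \code{a1 * K} and a mutant with carrying capacity \code{a2 * K}.  Each
#' individual splits into 0 or 2 children per generation; at density
#' \eqn{x = (x_1, x_2)} (populations per unit of \code{K}) the splitting
#' probabilities are \eqn{p_1 = a_1/(a_1 + x_1 + \gamma x_2)} and
#' \eqn{p_2 = a_2/(a_2 + \gamma x_1 + x_2)}.  The interaction coefficient
#' \eqn{\gamma \in (0,1)} means individuals compete more strongly within than
#' between types.
#'
#' At the resident equilibrium density \eqn{(a_1, 0)} the mutant's offspring
#' mean is \eqn{\rho = 2 a_2 / (a_2 + \gamma a_1) > 1} whenever
#' \eqn{a_2 > \gamma a_1}, so an invading mutant lineage is initially
#' supercritical.
#'
#' @param a1 resident carrying-capacity coefficient, positive.
#' @param a2 mutant carrying-capacity coefficient, positive.
#' @param gamma interaction coefficient, strictly between 0 and 1.
#' @param K carrying capacity, a positive integer, or \code{NULL} for purely
#'   deterministic computations.
#'
#' @return An object of class \code{"bb_model"}: a list with elements
#'   \code{a1}, \code{a2}, \code{gamma}, \code{K}, \code{rho}, \code{b},
#'   \code{x_ex}, \code{x_re}, \code{x_mu}, \code{x_co} (fixed points, each a
#'   length-2 numeric), \code{coexistence} (logical), and \code{rho_tilde}
#'   (numerical supremum of the row-sum norm of the Jacobian).
#'
#' @examples
#' mod <- bb_model(a1 = 1, a2 = 1, gamma = 1/3, K = 1e4)
#' mod$rho        # 1.5
#' mod$x_co       # (0.75, 0.75)
#' @export
bb_model <- function(a1, a2, gamma, K = NULL) {
  stopifnot(is.numeric(a1), length(a1) == 1L,
            is.numeric(a2), length(a2) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (!is.finite(a1) || a1 <= 0) stop("'a1' must be a positive number")
  if (!is.finite(a2) || a2 <= 0) stop("'a2' must be a positive number")
  if (!is.finite(gamma) || gamma <= 0 || gamma >= 1)
    stop("'gamma' must lie strictly in (0, 1)")
  if (!is.null(K)) {
    if (!is.numeric(K) || length(K) != 1L || !is.finite(K) ||
        K < 1 || K != floor(K))
      stop("'K' must be a positive integer (or NULL)")
    K <- as.numeric(K)
  }

  rho <- 2 * a2 / (a2 + gamma * a1)
  mod <- structure(list(
    a1 = a1, a2 = a2, gamma = gamma, K = K,
    rho = rho,
    b = 1 / log(rho),
    x_ex = c(0, 0),
    x_re = c(a1, 0),
    x_mu = c(0, a2),
    x_co = c((a1 - gamma * a2), (a2 - gamma * a1)) / (1 - gamma^2),
    coexistence = (a1 - gamma * a2 > 0) && (a2 - gamma * a1 > 0)
  ), class = "bb_model")
  mod$rho_tilde <- jacobian_sup_norm(mod)
  mod
}

#' @export
print.bb_model <- function(x, ...) {
  cat("Bare Bones two-type model\n")
  cat(sprintf("  a1 = %g, a2 = %g, gamma = %g, K = %s\n",
              x$a1, x$a2, x$gamma,
              if (is.null(x$K)) "<unset>" else format(x$K)))
  cat(sprintf("  rho = %.6g (mutant mean at resident equilibrium), b = 1/log rho = %.6g\n",
              x$rho, x$b))
  cat(sprintf("  coexistence condition: %s\n",
              if (x$coexistence) "satisfied" else "NOT satisfied"))
  cat(sprintf("  fixed points: x_ex = (0, 0), x_re = (%g, 0), x_mu = (0, %g), x_co = (%.6g, %.6g)\n",
              x$a1, x$a2, x$x_co[1], x$x_co[2]))
  cat(sprintf("  Jacobian sup-norm bound rho_tilde = %.6g\n", x$rho_tilde))
  invisible(x)
}

check_state <- function(x) {
  if (!is.numeric(x) || length(x) != 2L || any(!is.finite(x)))
    stop("a density state must be a finite numeric vector of length 2")
  if (any(x < 0))
    stop("density coordinates must be nonnegative")
  invisible(x)
}

#' Density-dependent splitting probabilities
#'
#' Per-individual probabilities of successful division at density state
#' \code{x}: \eqn{p_1 = a_1/(a_1 + x_1 + \gamma x_2)} for residents and
#' \eqn{p_2 = a_2/(a_2 + \gamma x_1 + x_2)} for mutants.  Both lie in
#' \eqn{(0, 1]} and are nonincreasing in each density coordinate.  At the
#' resident equilibrium \eqn{(a_1, 0)} the resident probability is exactly
#' 1/2 (critical reproduction) and the mutant probability is \eqn{\rho/2}.
#'
#' @param x density state, numeric length 2, nonnegative.
#' @param mod a \code{\link{bb_model}}.
#' @return Numeric length 2: \code{c(p1, p2)}.
#' @export
splitting_probs <- function(x, mod) {
  check_state(x)
  c(mod$a1 / (mod$a1 + x[1] + mod$gamma * x[2]),
    mod$a2 / (mod$a2 + mod$gamma * x[1] + x[2]))
}

#' Offspring means at a density state
#'
#' Mean number of children per individual, \eqn{m_i(x) = 2 p_i(x)}.  At the
#' coexistence equilibrium both means equal 1.
#'
#' @inheritParams splitting_probs
#' @return Numeric length 2: \code{c(m1, m2)}.
#' @export
offspring_means <- function(x, mod) 2 * splitting_probs(x, mod)

#' Deterministic density map
#'
#' One step of the deterministic dynamics on densities,
#' \eqn{f(x) = (x_1 m_1(x), x_2 m_2(x))}.  The map preserves the nonnegative
#' quadrant and each coordinate axis, and satisfies \eqn{f_1 < 2 a_1},
#' \eqn{f_2 < 2 a_2}.
#'
#' @inheritParams splitting_probs
#' @return Numeric length 2, the image density.
#' @export
f_map <- function(x, mod) {
  check_state(x)
  x * offspring_means(x, mod)
}

# f without input validation, for inner loops
f_map_ <- function(x, mod) {
  c(2 * x[1] * mod$a1 / (mod$a1 + x[1] + mod$gamma * x[2]),
    2 * x[2] * mod$a2 / (mod$a2 + mod$gamma * x[1] + x[2]))
}

#' Translated map around the resident equilibrium
#'
#' The translation \eqn{g(x) = f(x_{re} + x) - x_{re}} recentres the dynamics
#' at the resident equilibrium \eqn{x_{re} = (a_1, 0)}, so that \eqn{g(0)=0}
#' and the local behaviour is governed by the Jacobian
#' \eqn{A = Df(x_{re})}.
#'
#' @param x shifted density pair; \code{mod$x_re + x} must lie in the
#'   nonnegative quadrant.
#' @param mod a \code{\link{bb_model}}.
#' @return Numeric length 2.
#' @export
g_map <- function(x, mod) {
  y <- mod$x_re + x
  if (any(!is.finite(y)) || any(y < 0))
    stop("'x_re + x' must lie in the nonnegative quadrant")
  f_map_(y, mod) - mod$x_re
}

#' Analytic Jacobian of the density map
#'
#' Partial derivatives of \eqn{f} at \code{x}.  At the resident equilibrium
#' the Jacobian is upper triangular,
#' \eqn{A = [[1/2, -\gamma/2], [0, \rho]]}: the resident direction contracts
#' at rate 1/2 while the mutant direction expands at rate \eqn{\rho}.
#'
#' @inheritParams splitting_probs
#' @return A 2x2 numeric matrix.
#' @export
jacobian_f <- function(x, mod) {
  check_state(x)
  d1 <- mod$a1 + x[1] + mod$gamma * x[2]
  d2 <- mod$a2 + mod$gamma * x[1] + x[2]
  matrix(c(2 * mod$a1 * (mod$a1 + mod$gamma * x[2]) / d1^2,
           -2 * mod$a2 * mod$gamma * x[2] / d2^2,
           -2 * mod$a1 * mod$gamma * x[1] / d1^2,
           2 * mod$a2 * (mod$a2 + mod$gamma * x[1]) / d2^2),
         nrow = 2)
}

# Row-sum (l_inf operator) norms of Df on vectors of states; x1, x2 equal length
jacobian_row_norms <- function(x1, x2, mod) {
  d1 <- mod$a1 + x1 + mod$gamma * x2
  d2 <- mod$a2 + mod$gamma * x1 + x2
  r1 <- 2 * mod$a1 * (mod$a1 + mod$gamma * (x1 + x2)) / d1^2
  r2 <- 2 * mod$a2 * (mod$a2 + mod$gamma * (x1 + x2)) / d2^2
  pmax(r1, r2)
}

# Numerical supremum of ||Df(x)||_inf over the quadrant: coarse grid on
# [0, 4 a1] x [0, 4 a2] followed by local refinement around the best point.
# The row sums are bounded by 2 a_i / d_i <= 2, with equality approached at
# the origin, so the search domain provably contains the supremum.
jacobian_sup_norm <- function(mod, tol = 1e-6) {
  lo <- c(0, 0); hi <- c(4 * mod$a1, 4 * mod$a2)
  best <- -Inf; bx <- c(0, 0)
  for (pass in 1:20) {
    g1 <- seq(lo[1], hi[1], length.out = 41L)
    g2 <- seq(lo[2], hi[2], length.out = 41L)
    gr <- expand.grid(x1 = g1, x2 = g2)
    v <- jacobian_row_norms(gr$x1, gr$x2, mod)
    i <- which.max(v)
    if (v[i] > best) { best <- v[i]; bx <- c(gr$x1[i], gr$x2[i]) }
    h1 <- (hi[1] - lo[1]) / 40; h2 <- (hi[2] - lo[2]) / 40
    if (max(h1, h2) < tol) break
    lo <- pmax(c(0, 0), bx - c(h1, h2))
    hi <- bx + c(h1, h2)
  }
  best
}

#' Classify the fixed points of the density map
#'
#' Labels each of the four fixed points by the eigenvalue moduli of the
#' analytic Jacobian there: \emph{stable} (spectral radius < 1),
#' \emph{unstable} (all moduli > 1) or \emph{saddle} (one modulus on each
#' side of 1).  Under the coexistence condition, the coexistence equilibrium
#' is stable, total extinction is unstable, and the two monomorphic
#' equilibria are saddles.
#'
#' @param mod a \code{\link{bb_model}}.
#' @return A data frame with one row per fixed point: \code{point},
#'   \code{x1}, \code{x2}, \code{eig1}, \code{eig2} (moduli, decreasing) and
#'   \code{stability}.  When the coexistence condition fails, the
#'   coexistence row carries \code{NA} stability and a note is attached as
#'   attribute \code{"note"}.
#' @export
classify_fixed_points <- function(mod) {
  stopifnot(inherits(mod, "bb_model"))
  pts <- list(x_ex = mod$x_ex, x_re = mod$x_re, x_mu = mod$x_mu,
              x_co = mod$x_co)
  out <- lapply(names(pts), function(nm) {
    p <- pts[[nm]]
    if (nm == "x_co" && !mod$coexistence)
      return(data.frame(point = nm, x1 = p[1], x2 = p[2],
                        eig1 = NA_real_, eig2 = NA_real_,
                        stability = NA_character_))
    ev <- sort(Mod(eigen(jacobian_f(p, mod), only.values = TRUE)$values),
               decreasing = TRUE)
    lab <- if (ev[1] < 1) "stable" else if (ev[2] > 1) "unstable" else "saddle"
    data.frame(point = nm, x1 = p[1], x2 = p[2],
               eig1 = ev[1], eig2 = ev[2], stability = lab)
  })
  res <- do.call(rbind, out)
  if (!mod$coexistence)
    attr(res, "note") <- paste(
      "coexistence condition fails: the coexistence point lies outside the",
      "quadrant and its classification is suppressed")
  res
}

#' Serialize the derived model to JSON
#'
#' Flat JSON document with keys \code{a1, a2, gamma, K, rho, b, x_ex, x_re,
#' x_mu, x_co, coexistence, rho_tilde}.
#'
#' @param mod a \code{\link{bb_model}}.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to \code{path}.
#' @export
model_json <- function(mod, path = NULL) {
  stopifnot(inherits(mod, "bb_model"))
  doc <- mod[c("a1", "a2", "gamma", "K", "rho", "b",
               "x_ex", "x_re", "x_mu", "x_co", "coexistence", "rho_tilde")]
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
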