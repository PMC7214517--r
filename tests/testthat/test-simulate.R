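test_that("single-generation stepping follows the splitting thresholds", {
  m <- p0_model()
  # extinction is absorbing
  expect_equal(step_populations(c(0, 0), m, numeric(0), numeric(0)), c(0, 0))
  # at the resident equilibrium the per-individual threshold is exactly 1/2
  K <- m$K
  p1 <- m$a1 * K / (m$a1 * K + floor(m$a1 * K) + 0)
  expect_identical(p1, 0.5)
  # all uniforms below both thresholds force doubling
  nx <- step_populations(c(5, 3), m, rep(0.01, 5), rep(0.01, 3))
  expect_equal(nx, c(10, 6))
  # all uniforms above the thresholds force extinction (the thresholds are
  # strictly below 1 whenever anyone is alive)
  nx <- step_populations(c(5, 3), m, rep(1, 5), rep(1, 3))
  expect_equal(nx, c(0, 0))
  expect_error(step_populations(c(5, 3), m, rep(0.5, 4), rep(0.5, 3)),
               "insufficient")
})

test_that("coupled trajectories are deterministic in the seed and even after generation 0", {
  m <- p0_model(1000)
  a <- c(0.7, 0.7, 0.7)
  t1 <- simulate_coupled(m, horizon = 12, alphas = a, c = 0.55, seed = 99)
  t2 <- simulate_coupled(m, horizon = 12, alphas = a, c = 0.55, seed = 99)
  expect_identical(t1, t2)
  t3 <- simulate_coupled(m, horizon = 12, alphas = a, c = 0.55, seed = 100)
  expect_false(identical(t1$Z2, t3$Z2))
  counts <- as.matrix(t1[t1$generation >= 1, c("Z1", "Z2", "Y1", "Y2",
                                               "L1", "L2", "U1", "U2")])
  expect_true(all(counts %% 2 == 0))
})

test_that("the bounding rates bracket criticality and the mutant mean", {
  for (K in c(1e3, 1e4, 1e6)) {
    m <- p0_model(K)
    for (a in list(c(0.7, 0.7, 0.7), c(0.85, 0.7, 0.7), c(0.6, 0.9, 0.6))) {
      r <- barebones:::coupling_rates(m, a)
      expect_lt(r$r_minus, 1); expect_gt(r$r_plus, 1)
      expect_lt(r$rho_minus, m$rho); expect_gt(r$rho_plus, m$rho)
    }
  }
})

test_that("shared uniforms give the pathwise coupling order", {
  m <- p0_model()
  viol <- 0L
  for (s in 1:40) {
    tr <- simulate_coupled(m, horizon = 20, alphas = c(0.7, 0.7, 0.7),
                           c = 0.55, seed = 1000 + s)
    if (!all(tr$L2 <= tr$Y2 & tr$Y2 <= tr$U2)) viol <- viol + 1L
    et <- exit_times(tr, m)
    pre <- if (is.na(et$tau)) rep(TRUE, nrow(tr)) else tr$generation <= et$tau
    ok <- all(tr$L1[pre] <= tr$Z1[pre] & tr$Z1[pre] <= tr$U1[pre] &
              tr$L2[pre] <= tr$Z2[pre] & tr$Z2[pre] <= tr$U2[pre])
    if (!ok) viol <- viol + 1L
  }
  expect_identical(viol, 0L)
})

test_that("exit times implement the threshold definitions with NA sentinels", {
  m <- p0_model()
  a <- c(0.7, 0.7, 0.7)
  # constant trajectory at the start point never exits
  traj <- data.frame(generation = 0:10,
                     Z1 = rep(floor(m$a1 * m$K), 11), Z2 = rep(1, 11))
  et <- exit_times(traj, m, alphas = a)
  expect_true(is.na(et$tau_1l) && is.na(et$tau_1u) && is.na(et$tau_2) &&
              is.na(et$tau))
  # a jump of Z2 above K^alpha2 at generation 5 is picked up
  traj$Z2[6] <- ceiling(m$K^a[3])
  et <- exit_times(traj, m, alphas = a)
  expect_identical(et$tau_2, 5L)
  expect_lte(et$tau, 5L)
})

test_that("the Galton-Watson resident component is critical with linear variance", {
  m <- p0_model()
  reps <- 500
  Y1 <- simulate_y1_ensemble(m$K, m$a1, n_gens = 10, reps = reps, seed = 21)
  z0 <- floor(m$a1 * m$K)
  for (n in c(5, 10)) {
    se <- stats::sd(Y1[, n + 1]) / sqrt(reps)
    expect_lt(abs(mean(Y1[, n + 1]) - z0), 3 * se)
    # Var(Y1(n)) = n * [a1 K]; allow sampling error of the variance
    vr <- stats::var(Y1[, n + 1])
    expect_lt(vr, n * z0 * (1 + 3 * sqrt(2 / (reps - 1))))
  }
  # the coupled simulator's Y1 has the same one-step law: compare marginals
  y1_coupled <- replicate(200, {
    tr <- simulate_coupled(m, horizon = 3, alphas = c(0.7, 0.7, 0.7),
                           c = 0.55, seed = sample.int(1e6, 1))
    tr$Y1[4]
  })
  d <- suppressWarnings(stats::ks.test(y1_coupled, Y1[1:200, 4])$statistic)
  expect_lt(unname(d), ks_critical(200, 200))
})

test_that("fast and coupled modes have the same mutant marginal law", {
  m <- p0_model()
  reps <- 2000
  set.seed(31)
  seeds <- sample.int(1e7, reps)
  z2_coupled <- vapply(seeds, function(s) {
    tr <- simulate_coupled(m, horizon = 10, alphas = c(0.7, 0.7, 0.7),
                           c = 0.55, seed = s, include_bounds = FALSE)
    tr$Z2[11]
  }, numeric(1))
  ens <- simulate_fast(m, horizon = 10, reps = reps, seed = 77)
  z2_fast <- ens$Z2[, 11]
  d <- suppressWarnings(stats::ks.test(z2_coupled, z2_fast)$statistic)
  expect_lt(unname(d), ks_critical(reps, reps))
  # and the coupled Y2 matches a direct binomial Galton-Watson oracle
  y2_coupled <- vapply(seeds[1:800], function(s) {
    tr <- simulate_coupled(m, horizon = 10, alphas = c(0.7, 0.7, 0.7),
                           c = 0.55, seed = s, include_bounds = FALSE)
    tr$Y2[11]
  }, numeric(1))
  y2_direct <- simulate_y2_direct(m$rho, 10, 800, seed = 13)
  d2 <- suppressWarnings(stats::ks.test(y2_coupled, y2_direct)$statistic)
  expect_lt(unname(d2), ks_critical(800, 800))
})

test_that("one generation from the invasion start has mutant mean rho", {
  m <- p0_model()
  ens <- simulate_fast(m, horizon = 1, reps = 2000, seed = 5)
  z2 <- ens$Z2[, 2]
  se <- stats::sd(z2) / sqrt(length(z2))
  expect_lt(abs(mean(z2) - m$rho), 3 * se)
})

test_that("the martingale approximant has unit mean and the right atom at zero", {
  m <- p0_model()
  w <- martingale_limit_sample(m, n_gens = 40, reps = 2e4, seed = 19)
  se <- stats::sd(w) / sqrt(length(w))
  expect_lt(abs(mean(w) - 1), 3 * se)
  p0 <- mean(w == 0)
  se0 <- sqrt(p0 * (1 - p0) / length(w))
  expect_lt(abs(p0 - (2 / m$rho - 1)), 3 * se0)
  # rho -> 2 (gamma -> 0): extinction becomes rare
  m2 <- bb_model(1, 1, 0.01, 1e4)
  w2 <- martingale_limit_sample(m2, n_gens = 40, reps = 5e3, seed = 23)
  expect_lt(mean(w2 == 0), 0.02)
})

test_that("the classical bounded-horizon limit improves with K from a macroscopic start", {
  x0 <- c(0.5, 0.5)
  err <- vapply(c(1e3, 1e4, 1e5), function(K) {
    m <- bb_model(1, 1, 1/3, K)
    det <- iterate_map(x0, 10, m)
    ens <- simulate_fast(m, horizon = 10, reps = 30, seed = 41,
                         start = round(x0 * K))
    mean(vapply(1:30, function(r) {
      max(abs(cbind(ens$Z1[r, ], ens$Z2[r, ]) / K - det))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("the scaled resident deviation at the gluing time concentrates as K grows", {
  sdev <- vapply(c(1e3, 1e4, 1e5), function(K) {
    m <- bb_model(1, 1, 1/3, K)
    ti <- time_indices(m, c = 0.75)
    Y1 <- simulate_y1_ensemble(K, m$a1, ti$n_c, reps = 300, seed = 53)
    stats::sd(m$rho^(-ti$n_c) * (Y1[, ti$n_c + 1] - m$a1 * K))
  }, numeric(1))
  expect_true(all(diff(sdev) < 0))
})

test_that("noise residuals have the printed variance and the decomposition is exact", {
  m <- p0_model()
  states <- list(c(1, 0.05), c(0.75, 0.75), c(0.5, 0.25))
  for (i in seq_along(states)) {
    ns <- noise_one_step(m, states[[i]], reps = 1e4, seed = 60 + i)
    vhat <- apply(ns$eta, 2, stats::var)
    expect_lt(max(abs(vhat - ns$var_theory) / ns$var_theory), 0.05)
    expect_lt(max(abs(colMeans(ns$eta))), 3 * max(sqrt(ns$var_theory / 1e4)))
  }
  # no mutants, no mutant noise
  ns0 <- noise_one_step(m, c(1, 0), reps = 100, seed = 7)
  expect_true(all(ns0$eta[, "eta2"] == 0))
  # trajectory-level identity holds to machine precision
  tr <- simulate_coupled(m, horizon = 10, alphas = c(0.7, 0.7, 0.7),
                         c = 0.55, seed = 3, include_bounds = FALSE)
  res <- noise_residuals(tr, m)
  expect_lt(max(res$identity_gap), 1e-14)
})
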