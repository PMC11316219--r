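test_that("the initial population matches the complex-normal equilibrium", {
  cfg <- sim_config(population_size = 2e4, mode_cutoff = 64, seed = 1)
  pop <- init_population(cfg)
  P <- cfg$population_size
  expect_equal(pop$generation, 0L)
  expect_true(all(Im(pop$coeffs[1, ]) == 0))

  expect_lt(abs(pop$var_G - 1), 3 * sqrt(2 / P))            # Var(X_0) = 1
  expect_lt(abs(pop$mean_G), 3 / sqrt(P))
  v3 <- mean(Mod(pop$coeffs[4, ])^2)
  expect_lt(abs(v3 - 1), 3 / sqrt(P))                       # E|X_3|^2 = 1
  pv3 <- mean(pop$coeffs[4, ]^2)
  expect_lt(Mod(pv3), 3 * sqrt(2 / P))                      # pseudo-variance 0
})

test_that("genetic value is the mode-0 coefficient and is rotation invariant", {
  set.seed(2)
  x <- random_gamete(16)
  x[1] <- 0.7 + 0i
  expect_equal(genetic_value(x), 0.7)
  delta <- 1.23
  rot <- x * exp(-1i * (0:16) * delta)
  rot[1] <- x[1]
  expect_equal(genetic_value(rot), genetic_value(x))
})

test_that("rotating every gamete rotates the mode means and preserves the variances", {
  cfg <- sim_config(population_size = 500, mode_cutoff = 8, seed = 3)
  pop <- init_population(cfg)
  delta <- 0.9
  rotated <- pop$coeffs * exp(-1i * (0:8) * delta)
  expect_equal(rowMeans(rotated), rowMeans(pop$coeffs) * exp(-1i * (0:8) * delta),
               tolerance = 1e-12)
  expect_equal(rowMeans(Mod(rotated)^2), rowMeans(Mod(pop$coeffs)^2),
               tolerance = 1e-12)
})

test_that("recombination with identical parents is the identity", {
  set.seed(5)
  x <- random_gamete(32)
  for (psi in c(0, 0.4, pi, 2 * pi - 1e-6)) {
    expect_lt(max(Mod(recombine(x, x, psi, 255) - x)), 1e-13)
  }
})

test_that("recombination matches the grid-masking oracle", {
  set.seed(6)
  L <- 65536L
  for (rep in 1:3) {
    X <- random_gamete(64); Xp <- random_gamete(64)
    s <- sample.int(L, 1) - 1L
    got <- recombine(X, Xp, 2 * pi * s / L, 4095)
    want <- grid_recombine_oracle(X, Xp, s, L)
    expect_lt(max(Mod(got - want)), 1e-6)
  }
  expect_error(recombine(random_gamete(8), random_gamete(8), 1, 4), "odd")
})

test_that("averaging the child's genetic value over the crossover angle gives the parental mean", {
  set.seed(8)
  X <- random_gamete(32); Xp <- random_gamete(32)
  psis <- runif(5000, 0, 2 * pi)
  y0 <- vapply(psis, function(p) Re(recombine(X, Xp, p, 255)[1]), numeric(1))
  expect_lt(abs(mean(y0) - Re(X[1] + Xp[1]) / 2), 0.05)
})

test_that("the batched compiled generation equals the per-pair operator", {
  set.seed(9)
  K <- 16L
  co <- vapply(1:10, function(i) random_gamete(K), complex(K + 1))
  p1 <- c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)
  p2 <- c(2, 4, 6, 8, 10, 3, 5, 7, 9, 1)
  psi <- c(0, runif(9, 0, 2 * pi))
  for (J_r in c(7L, 255L)) {
    got <- linkinf:::cpp_next_generation(co, p1 - 1L, p2 - 1L, psi, J_r)
    want <- vapply(1:10, function(i) recombine(co[, p1[i]], co[, p2[i]], psi[i], J_r),
                   complex(K + 1))
    expect_lt(max(Mod(got - want)), 1e-12)
  }
})

test_that("hard-conditioning selection zeroes Var(G); window selection keeps the Gaussian mass", {
  cfg <- sim_config(population_size = 4e4, mode_cutoff = 16, seed = 10)
  pop <- init_population(cfg)
  sel <- select_gametes(pop, beta = 1, epsilon = 0)
  expect_equal(sel$var_G, 0)
  expect_equal(unique(Re(sel$coeffs[1, ])),
               pop$mean_G + 1 * sqrt(pop$var_G), tolerance = 1e-12)
  ## a degenerate population cannot be selected again
  expect_error(select_gametes(sel, 1, 0), "positive")

  eps <- 0.05
  selw <- select_gametes(pop, beta = 1, epsilon = eps)
  frac <- ncol(selw$coeffs) / ncol(pop$coeffs)
  expected <- stats::pnorm(1 + eps) - stats::pnorm(1 - eps)
  se <- sqrt(expected * (1 - expected) / ncol(pop$coeffs))
  expect_lt(abs(frac - expected), 3 * se + 1e-4)

  expect_error(select_gametes(pop, beta = 40, epsilon = 1e-9), "empty selection")
})

test_that("panmictic cycles preserve size, stay drift-free at beta 0, and gain mu + sigma at beta 1", {
  cfg0 <- sim_config(population_size = 5e3, mode_cutoff = 32,
                     recomb_truncation = 255, beta = 0, generations = 3, seed = 12)
  sim0 <- run_simulation(cfg0)
  expect_true(all(abs(sim0$trajectory$mu) < 0.1))

  cfg1 <- sim_config(population_size = 5e3, mode_cutoff = 32,
                     recomb_truncation = 255, beta = 1, generations = 1, seed = 13)
  pop <- init_population(cfg1)
  thr <- pop$mean_G + sqrt(pop$var_G)
  child <- advance_generation(select_gametes(pop, 1, 0), cfg1)
  expect_equal(ncol(child$coeffs), cfg1$population_size)
  expect_equal(child$generation, 1L)
  expect_lt(abs(child$mean_G - thr), 0.05)
})

test_that("estimate_spectrum recovers the one-cycle mode variances and diagonality", {
  cfg <- sim_config(population_size = 8e3, mode_cutoff = 32,
                    recomb_truncation = 255, seed = 14)
  pop <- init_population(cfg)
  child <- advance_generation(select_gametes(pop, 1, 0), cfg)
  est <- estimate_spectrum(child)
  sp <- est$spectrum
  P <- cfg$population_size
  expect_lt(abs(sp$emp_variance[sp$k == 0] - 0.5), 3 * 0.5 * sqrt(2 / P))
  for (k in c(1, 3, 5)) {
    expect_lt(abs(sp$emp_variance[sp$k == k] - (1 - 2 / (pi^2 * k^2))),
              4 / sqrt(P))
  }
  for (k in c(2, 4)) {
    expect_lt(abs(sp$emp_variance[sp$k == k] - 1), 4 / sqrt(P))
  }
  expect_true(all(est$offdiag$cov_magnitude < 6 / sqrt(P)))
  expect_error(estimate_spectrum(new_population_small <- structure(
    list(coeffs = pop$coeffs[, 1:50], generation = 0L), class = "gamete_population")),
    "100")
})

test_that("simulation runs are reproducible from their seed", {
  cfg <- sim_config(population_size = 400, mode_cutoff = 16,
                    recomb_truncation = 63, generations = 2, seed = 99,
                    replicates = 2)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$spectrum, b$spectrum)
})

test_that("the simulator tracks the mode-truncated projection recursion", {
  ## The deterministic reference sharing the simulator's truncation: modes
  ## beyond K carry no variance. The simulator must match it with no
  ## systematic trend; its offset from the untruncated recursion is the
  ## documented truncation bias.
  cfg <- sim_config(population_size = 2e4, mode_cutoff = 64,
                    recomb_truncation = 255, generations = 3, seed = 42,
                    replicates = 4)
  sim <- run_simulation(cfg)
  ref <- truncated_projection_sigma2(64L, 3L, J = 5001L)
  m <- colMeans(sim$replicate_sigma2_0)
  se <- apply(sim$replicate_sigma2_0, 2, stats::sd) / sqrt(cfg$replicates)
  for (g in 1:3) expect_lt(abs(m[g] - ref[g]), 3 * se[g])
})
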