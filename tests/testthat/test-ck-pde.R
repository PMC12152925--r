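test_that("fitness evaluation matches hand arithmetic", {
  h <- function(x) x
  # s = 0: independent of z, equals the local log-likelihood fitness
  fp0 <- fitness_params(2, 0)
  expect_equal(fitness_eval(fp0, h, ydot = 0.3, x = 1.2, z = -5),
               fitness_eval(fp0, h, ydot = 0.3, x = 1.2, z = 40))
  expect_equal(fitness_eval(fp0, h, ydot = 0.3, x = 1.2, z = 0),
               -1 * (1.2 - 0.3)^2)
  # h(x)=x, Xi=1, ydot=0, r=2, s=1: f(x,z) = -x^2 + xz, f(1,2) = 1
  fp <- fitness_params(2, 1)
  expect_equal(fitness_eval(fp, h, 0, 1, 2), 1)
  # on the diagonal f(x,x) = (s - r/2) u^2
  u <- 1.7 - 0.4
  expect_equal(fitness_eval(fp, h, 0.4, 1.7, 1.7), (1 - 1) * u^2)
  fp2 <- fitness_params(3, -2)
  expect_equal(fitness_eval(fp2, h, 0.4, 1.7, 1.7), (-2 - 1.5) * u^2)
  expect_error(fitness_eval(fp, h, 0, 1, 1, Xi = 0), "Xi")
})

test_that("grid moments recover known Gaussian moments", {
  g <- spatial_grid(-8, 8, 801)
  expect_equal(unname(grid_moments(gaussian_grid_density(g, 0, 1))),
               c(0, 1), tolerance = 1e-6)
  expect_equal(unname(grid_moments(gaussian_grid_density(g, 2, 0.3))),
               c(2, 0.3), tolerance = 1e-6)
  # symmetric density: mean 0 to rounding
  v <- exp(-abs(g$x))
  expect_lt(abs(grid_moments(grid_density(g, v))[["mean"]]), 1e-12)
  expect_error(grid_moments(grid_density(g, rep(0, g$n))), "zero mass")
})

test_that("density distances match closed forms", {
  g <- spatial_grid(-8, 8, 1601)
  d1 <- gaussian_grid_density(g, 0, 1)
  expect_equal(density_distance(d1, d1)$l1, 0)
  # disjoint unit boxes: L1 = 2
  b1 <- as.numeric(g$x > 0 & g$x < 1)
  b2 <- as.numeric(g$x > 2 & g$x < 3)
  expect_equal(density_distance(grid_density(g, b1), grid_density(g, b2))$l1,
               2, tolerance = 1e-2)
  # N(0,1) vs N(0.1,1): L1 = 2(2 Phi(0.05) - 1)
  d2 <- gaussian_grid_density(g, 0.1, 1)
  expect_equal(density_distance(d1, d2)$l1, 2 * (2 * stats::pnorm(0.05) - 1),
               tolerance = 1e-4)
  expect_error(density_distance(d1, gaussian_grid_density(spatial_grid(-7, 7, 1601), 0, 1)),
               "grids differ")
})

test_that("pure mutation conserves mass", {
  sys <- nl_system_1d(g = function(x) 0 * x, h = function(x) 0 * x,
                      Sigma = 0.5, Xi = 1, m0 = 0, P0 = 1)
  tg <- time_grid(1, 1e-4, 1e-2)
  tr <- ck_solve(sys, fitness_params(1, 0), 0, spatial_grid(-10, 10, 401),
                 tg, mode = "unnormalized")
  expect_lt(max(abs(tr$moments$log_mass)), 1e-8)
})

test_that("replicator flow with static driver equals the exponential tilt", {
  # g = 0, Sigma = 0, s = 0, constant ydot: closed form p_t ~ e^{t f} p_0
  sysl <- nl_system_1d(g = function(x) 0 * x, h = function(x) x,
                       Sigma = 0, Xi = 1, m0 = 0, P0 = 1)
  gd <- spatial_grid(-8, 8, 801)
  f <- -0.5 * (gd$x - 2)^2
  p0 <- stats::dnorm(gd$x)
  err_at <- function(dt, T) {
    tg <- time_grid(T, dt, T)
    tr <- ck_solve(sysl, fitness_params(1, 0), 2, gd, tg,
                   mode = "normalized", store_times = c(0, T))
    p1 <- exp(T * f) * p0
    p1 <- p1 / sum(gd$w * p1)
    density_distance(tr$densities[[2]], grid_density(gd, p1))$l1
  }
  e_coarse <- err_at(1e-4, 0.2)
  e_fine <- err_at(2e-6, 0.2)
  expect_lt(e_fine, 1e-6)
  # first-order-in-time convergence to the closed form
  expect_gt(e_coarse / e_fine, 20)
})

test_that("grid moments track the moment ODEs for a linear-Gaussian system", {
  tg <- time_grid(0.5, 5e-5, 1e-2)
  sp <- simulate_signal(sys_mild, tg, seed = 11)
  po <- observation_derivative(sp, sys_mild, tg, seed = 11)
  grid <- spatial_grid(-7, 7, 801)
  n <- tg$n_steps + 1L
  for (fp in list(fitness_params(1, 0), fitness_params(0.8, -0.4))) {
    tr <- ck_solve(sys_mild, fp, po, grid, tg, mode = "normalized",
                   store_times = c(0, 0.5))
    mt <- moment_filter(sys_mild, fp, po, tg)
    expect_lt(abs(tr$moments$mean[n] - mt$mean[n]) / max(1, abs(mt$mean[n])),
              1e-3)
    expect_lt(abs(tr$moments$var[n] - mt$cov[, , n]) / mt$cov[, , n], 1e-3)
  }
})

test_that("normalized and unnormalized solvers agree after normalization", {
  tg <- time_grid(0.25, 1e-4, 1e-2)
  sp <- simulate_signal(sys_mild, tg, seed = 4)
  po <- observation_derivative(sp, sys_mild, tg, seed = 4)
  grid <- spatial_grid(-7, 7, 801)
  trn <- ck_solve(sys_mild, fitness_params(1, 0), po, grid, tg,
                  mode = "normalized", store_times = c(0, 0.25))
  tru <- ck_solve(sys_mild, fitness_params(1, 0), po, grid, tg,
                  mode = "unnormalized", store_times = c(0, 0.25))
  expect_lt(density_distance(trn$densities[[2]], tru$densities[[2]])$l1,
            2e-3)
  expect_true(all(is.finite(tru$moments$log_mass)))
})

test_that("Ito and Stratonovich Zakai modes coincide exactly at (1,0)", {
  tg <- time_grid(0.2, 1e-4, 1e-2)
  sp <- simulate_signal(sys_mild, tg, seed = 8)
  io <- ito_observation(sp, sys_mild, tg, seed = 8)
  grid <- spatial_grid(-7, 7, 801)
  a <- zakai_solve(sys_mild, fitness_params(1, 0), io, grid, tg,
                   mode = "ito", store_times = c(0, 0.2))
  b <- zakai_solve(sys_mild, fitness_params(1, 0), io, grid, tg,
                   mode = "stratonovich", store_times = c(0, 0.2))
  expect_identical(a$moments$mean, b$moments$mean)
  expect_identical(a$densities[[2]]$values, b$densities[[2]]$values)
})

test_that("Zakai grid moments match the Kalman-Bucy filter", {
  tg <- time_grid(0.5, 2e-5, 1e-2)
  sp <- simulate_signal(sys_mild, tg, seed = 11)
  io <- ito_observation(sp, sys_mild, tg, seed = 11)
  grid <- spatial_grid(-7, 7, 801)
  tz <- zakai_solve(sys_mild, fitness_params(1, 0), io, grid, tg,
                    store_times = c(0, 0.5))
  mt <- moment_filter(sys_mild, fitness_params(1, 0), io, tg)
  n <- tg$n_steps + 1L
  expect_lt(abs(tz$moments$mean[n] - mt$mean[n]) / max(1, abs(mt$mean[n])),
            1e-3)
  expect_lt(abs(tz$moments$var[n] - mt$cov[, , n]) / mt$cov[, , n], 1e-3)
})

test_that("stability guards catch unstable configurations", {
  sys <- nl_system_1d(g = function(x) 0 * x, h = function(x) 0 * x,
                      Sigma = 5, Xi = 1, m0 = 0, P0 = 1)
  tg <- time_grid(0.1, 1e-2, 1e-2)
  expect_error(ck_solve(sys, fitness_params(1, 0), 0,
                        spatial_grid(-5, 5, 401), tg), "CFL")
})
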