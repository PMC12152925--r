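test_that("a single Euler step matches hand arithmetic", {
  tg <- time_grid(1e-3, 1e-3, 1e-3)
  fp <- fitness_params(0.8, -0.3)
  sysh <- lg_system(G = 0.4, H = 2, Sigma = 0.6, Xi = 1.5, b = 0,
                    m0 = 0.2, C0 = 0.5, P0 = 0.5)
  drv <- constant_driver(tg, 1.7)
  mt <- moment_filter(sysh, fp, drv, tg)
  dt <- 1e-3
  K0 <- 0.5 * 2 / 1.5
  m1 <- 0.2 + dt * (0.4 * 0.2) + (0.8 + 0.3) * K0 * (1.7 - 2 * 0.2) * dt
  C1 <- 0.5 + dt * (2 * 0.4 * 0.5 + 0.6 - 0.8 * 0.5^2 * 4 / 1.5)
  expect_equal(mt$mean[2], m1, tolerance = 1e-12)
  expect_equal(mt$cov[, , 2][1], C1, tolerance = 1e-12)
})

test_that("zero innovation reduces the mean to its prior drift", {
  # G = 0 keeps the mean fixed, so a driver pinned at H m0 never innovates
  tg <- time_grid(0.5, 1e-3, 1e-2)
  sys0 <- lg_system(G = 0, H = 2, Sigma = 0.3, Xi = 1, b = 0,
                    m0 = 1.5, C0 = 0.4, P0 = 0.4)
  drv <- constant_driver(tg, 2 * 1.5)
  mt <- moment_filter(sys0, fitness_params(1, 0), drv, tg)
  expect_equal(max(abs(mt$mean - 1.5)), 0)
})

test_that("steady-state covariance matches closed forms and an ODE oracle", {
  s <- lg_system(G = 0, H = 1, Sigma = 1, Xi = 1, m0 = 0, P0 = 1)
  expect_equal(riccati_steady_state(s, 1)[1], 1)
  s2 <- lg_system(G = -1, H = 1, Sigma = 0.5, Xi = 2, m0 = 0, P0 = 1)
  cs <- riccati_steady_state(s2, 2)[1]
  expect_equal(cs, closed_form_cinf(-1, 1, 0.5, 2, 2), tolerance = 1e-12)
  expect_equal(round(cs, 4), 0.2247)
  # independent forward-Euler integration of the covariance ODE
  C <- 1; dt <- 1e-4
  for (k in 1:200000) {
    dC <- 2 * (-1) * C + 0.5 - 2 * C^2 / 2
    C <- C + dt * dC
    if (abs(dC) < 1e-13) break
  }
  expect_equal(cs, C, tolerance = 1e-8)
  # matrix path on a block-diagonal system agrees with per-block closed forms
  sm <- lg_system(G = diag(c(-1, -0.5)), H = diag(2),
                  Sigma = diag(c(0.5, 0.3)), Xi = diag(c(2, 1)),
                  m0 = c(0, 0), P0 = diag(2))
  Cm <- riccati_steady_state(sm, 1.4)
  expect_equal(Cm[1, 1], closed_form_cinf(-1, 1, 0.5, 2, 1.4),
               tolerance = 1e-8)
  expect_equal(Cm[2, 2], closed_form_cinf(-0.5, 1, 0.3, 1, 1.4),
               tolerance = 1e-8)
  expect_equal(Cm[1, 2], 0, tolerance = 1e-8)
})

test_that("only r, never s, changes the covariance trajectory", {
  tg <- time_grid(0.5, 1e-3, 1e-2)
  sp <- simulate_signal(sys_mild, tg, seed = 3)
  po <- observation_derivative(sp, sys_mild, tg, seed = 3)
  a <- moment_filter(sys_mild, fitness_params(0.7, 0), po, tg, C0 = 0.4)
  b <- moment_filter(sys_mild, fitness_params(0.7, -1.2), po, tg, C0 = 0.4)
  expect_identical(a$cov, b$cov)
  expect_false(identical(a$mean, b$mean))
})

test_that("inflation maps match their definitions and invert", {
  expect_equal(unclass(inflation_map(0.1, "multiplicative"))[c("r", "s")],
               list(r = 1.1, s = 0))
  expect_equal(unclass(inflation_map(0.1, "additive"))[c("r", "s")],
               list(r = 0.8, s = -0.2))
  expect_equal(unclass(inflation_map(0, "multiplicative"))[c("r", "s")],
               list(r = 1, s = 0))
  expect_equal(unclass(inflation_map(0, "additive"))[c("r", "s")],
               list(r = 1, s = 0))
  inv <- inflation_invert(fitness_params(1.25, 0))
  expect_equal(inv$kind, "multiplicative")
  expect_equal(inv$epsilon, 0.25)
  inv2 <- inflation_invert(fitness_params(0.9, -0.1))
  expect_equal(inv2$kind, "additive")
  expect_equal(inv2$epsilon, 0.05)
  inv3 <- inflation_invert(fitness_params(0.9, -0.3))
  expect_equal(inv3$kind, "mixed")
  expect_error(inflation_map(0.6, "additive"), "epsilon")
})

test_that("with negligible gain the particles follow the deterministic drift", {
  sysk <- lg_system(G = -0.8, H = 1, Sigma = 1e-12, Xi = 1e8, b = 0,
                    m0 = 2, C0 = 0.5, P0 = 0.5)
  tg <- time_grid(0.5, 1e-3, 1e-2)
  sp <- simulate_signal(sysk, tg, seed = 5)
  io <- ito_observation(sp, sysk, tg, seed = 5)
  et <- ensemble_filter(sysk, fitness_params(1, 0), "deterministic_rough",
                        100, io, tg, seed = 6)
  # empirical mean follows Euler of dm = G m from its own starting point
  mref <- et$mean[1, 1] * (1 - 0.8 * 1e-3)^(0:tg$n_steps)
  expect_equal(et$mean[, 1], mref, tolerance = 1e-5)
})

test_that("ensemble moments converge to the moment ODEs as N grows", {
  fp <- fitness_params(0.8, -0.4)
  tg <- time_grid(1, 1e-3, 1e-2)
  sp <- simulate_signal(sys_mild, tg, seed = 12)
  po <- observation_derivative(sp, sys_mild, tg, seed = 12)
  mt <- moment_filter(sys_mild, fp, po, tg, C0 = 0.4)
  n <- tg$n_steps + 1L
  errs <- vapply(c(100L, 2000L), function(N) {
    et <- ensemble_filter(sys_mild, fp, "stochastic_smooth", N, po, tg,
                          seed = 13)
    mean(abs(et$mean[, 1] - mt$mean[, 1]))
  }, numeric(1))
  expect_lt(errs[2], errs[1])
  # final mean within 3 standard errors at N = 2000
  et <- ensemble_filter(sys_mild, fp, "stochastic_smooth", 2000L, po, tg,
                        seed = 13)
  se <- sqrt(et$cov[, , n][1] / 2000)
  expect_lt(abs(et$mean[n] - mt$mean[n]), 3 * se)
})

test_that("ensemble guards reject degenerate configurations", {
  tg <- time_grid(0.01, 1e-3, 1e-2)
  sp <- simulate_signal(sys_mild, tg, seed = 1)
  io <- ito_observation(sp, sys_mild, tg, seed = 1)
  expect_error(ensemble_filter(sys_mild, fitness_params(1, 0),
                               "stochastic_rough", 1, io, tg, seed = 1),
               "N must be")
  po <- observation_derivative(sp, sys_mild, tg, seed = 1)
  expect_error(ensemble_filter(sys_mild, fitness_params(1, 0),
                               "stochastic_rough", 10, po, tg, seed = 1),
               "rough variants")
  expect_error(ensemble_filter(sys_mild, fitness_params(1, 0),
                               "stochastic_smooth", 10, io, tg, seed = 1),
               "smooth variants")
})
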