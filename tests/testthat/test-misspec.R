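test_that("the steady-state error drift matches its closed forms", {
  # G = 0: A_inf = -((r-s)/r) sqrt(r H^2 Xi^{-1} Sigma)
  s0 <- lg_system(G = 0, H = 2, Sigma = 1.5, Xi = 3, b = 1, m0 = 0, P0 = 1)
  fp <- fitness_params(0.9, -0.4)
  wS <- 4 / 3 * 1.5
  expect_equal(a_infty(s0, fp)[1], -(1.3 / 0.9) * sqrt(0.9 * wS),
               tolerance = 1e-10)
  # system 1 at the Kalman point: -sqrt(G^2 + H^2 Xi^{-1} Sigma)
  a1 <- a_infty(sys1, fitness_params(1, 0))[1]
  expect_equal(a1, -sqrt(0.5^2 + 8.5^2 / 6.3 * 0.8), tolerance = 1e-10)
  expect_equal(round(a1, 4), -3.07)
})

test_that("error covariance is bias-blind and reduces to the filter covariance", {
  fp <- fitness_params(1, 0)
  # P_t does not depend on b
  e_b <- error_moments_solve(sys1, fp, T = 1, dt = 1e-3, C0 = 0.7, P0 = 0.7)
  sys1_b0 <- lg_system(G = 0.5, H = 8.5, Sigma = 0.8, Xi = 6.3, b = 0,
                       m0 = 0, P0 = 1)
  e_0 <- error_moments_solve(sys1_b0, fp, T = 1, dt = 1e-3, C0 = 0.7,
                             P0 = 0.7)
  expect_identical(e_b$P, e_0$P)
  # Kalman reduction: P_t == C_t when (r,s) = (1,0), b = 0, P0 = C0
  C <- 0.7
  dev <- 0
  for (k in seq_len(1000)) {
    C <- C + 1e-3 * (2 * 0.5 * C + 0.8 - C^2 * 8.5^2 / 6.3)
    dev <- max(dev, abs(C - e_0$P[, , k + 1L]))
  }
  expect_lt(dev, 1e-10)
})

test_that("the squared bias converges to its stationary value", {
  fp <- fitness_params(1, 0)
  er <- error_moments_solve(sys1, fp, T = 4, dt = 1e-3)
  target <- (9.9 / 3.0700)^2
  expect_equal(tail(er$nu, 1), target, tolerance = 1e-3)
  expect_equal(tail(er$nu, 1), nu_infty(sys1, fp), tolerance = 1e-3)
  # bias-variance identity holds exactly along the trajectory
  trP <- apply(er$P, 3, function(m) sum(diag(m)))
  expect_lt(max(abs(er$mse - (trP + er$nu))), 1e-10)
  # Gronwall bound dominates the MSE curve; in the scalar case the bound
  # is tight (every inequality in its derivation is an equality), so the
  # discrete curves may cross by O(dt) -- allow first-order slack
  expect_true(all(er$mse <= er$mse_bound + 10 * 1e-3 * max(er$mse)))
})

test_that("scalar and Lyapunov paths agree on asymptotic bias and MSE", {
  for (s in list(sys1, sys2)) {
    for (fp in list(fitness_params(1, 0), fitness_params(0.5, -0.8))) {
      cf <- as.numeric(e_infty(s, fp, method = "closed_form"))
      ly <- as.numeric(e_infty(s, fp, method = "lyapunov"))
      expect_equal(cf, ly, tolerance = 1e-8)
      expect_lte(cf, attr(e_infty(s, fp), "upper_bound") + 1e-8)
    }
  }
  # unbiased Kalman: nu = 0 and MSE equals the steady covariance
  s_b0 <- lg_system(G = -0.5, H = 1, Sigma = 0.5, Xi = 1, b = 0,
                    m0 = 0, P0 = 1)
  fp <- fitness_params(1, 0)
  expect_equal(nu_infty(s_b0, fp), 0)
  expect_equal(as.numeric(e_infty(s_b0, fp)),
               riccati_steady_state(s_b0, 1)[1], tolerance = 1e-10)
  # instability is rejected, not silently reported
  expect_error(e_infty(sys1, fitness_params(1, 0.99)), "not stable")
})

test_that("cubic branch formulas agree with the bisection oracle", {
  c1 <- a_star(sys1)
  expect_gt(c1$tau, 0)
  expect_equal(c1$a_star, -16.695, tolerance = 1e-4)
  expect_lt(c1$residual, 1e-9)
  c2 <- a_star(sys2)
  expect_lt(c2$tau, 0)
  expect_equal(c2$a_star, -3.549, tolerance = 1e-4)
  expect_lt(c2$residual, 1e-9)
  # zero bias: the root is -sqrt(-p)
  s0 <- lg_system(G = 1, H = 2, Sigma = 1, Xi = 2, b = 0, m0 = 0, P0 = 1)
  c0 <- a_star(s0)
  expect_equal(c0$a_star, -sqrt(-c0$p), tolerance = 1e-12)
  # property: both branches match bisection on 100 random biased systems
  # (a_star() itself aborts if the two roots differ by more than 1e-8)
  set.seed(314)
  for (i in seq_len(100)) {
    cs <- a_star(random_scalar_system())
    expect_lt(cs$residual, 1e-9 * max(1, abs(cs$a_star)^3))
  }
})

test_that("optimal s values and bounds match the printed study values", {
  expect_equal(round(as.numeric(s_opt(sys1, 0.13)), 2), -1.18)
  expect_equal(as.numeric(s_opt(sys1, 0.13)), -1.184, tolerance = 1e-3)
  expect_lt(abs(as.numeric(s_opt(sys2, 0.99)) - (-0.0135)), 1e-3)
  # the pure-multiplicative optimum sits exactly on s = 0
  for (s in list(sys1, sys2)) {
    expect_lt(abs(as.numeric(s_opt(s, r0_opt(s)))), 1e-8)
  }
  sb <- s_bounds(sys2)
  expect_lt(abs(sb[["s_l"]] - (-0.047)), 1e-3)
  # G > 0 on both systems: the upper end of the optimal-s range is 0
  expect_equal(s_bounds(sys1)[["s_u"]], 0)
  expect_equal(sb[["s_u"]], 0)
})

test_that("optimal r branches merge at s_l and match printed roots", {
  sl <- s_bounds(sys1)[["s_l"]]
  # just above s_l: two nearly equal roots
  rr <- r_opt(sys1, sl + 1e-10)
  expect_length(rr, 2L)
  expect_lt(abs(rr[2] - rr[1]) / rr[1], 1e-3)
  # at s_l the discriminant vanishes (single merged root)
  expect_length(r_opt(sys1, sl), 1L)
  # below s_l there is no admissible optimum
  expect_error(r_opt(sys1, sl - 1e-6), "below s_l")
  # r0_opt satisfies the closed form and its lower bound
  r0 <- r0_opt(sys1)
  expect_equal(r0, 30.35, tolerance = 1e-3)
  wS <- 8.5^2 / 6.3 * 0.8
  expect_gt(r0, 2 * (0.5^2 + wS) / wS)
  # golden-section style check: E_inf(r, 0) really is minimised near r0
  ei <- function(r) as.numeric(e_infty(sys1, fitness_params(r, 0)))
  expect_lt(ei(r0), ei(r0 * 0.9))
  expect_lt(ei(r0), ei(r0 * 1.1))
})

test_that("the joint optimum calibrates covariance to MSE", {
  jo1 <- joint_optimum(sys1)
  expect_equal(jo1$r, 0.129, tolerance = 2e-3)
  expect_equal(jo1$s, -1.178, tolerance = 2e-3)
  expect_lt(abs(jo1$C_inf - jo1$E_inf) / jo1$E_inf, 1e-6)
  expect_equal(jo1$E_inf, 1.148, tolerance = 0.01)
  jo2 <- joint_optimum(sys2)
  expect_equal(jo2$r, 0.993, tolerance = 2e-3)
  expect_lt(abs(jo2$s - (-0.0134)), 1e-3)
  expect_lt(abs(jo2$C_inf - jo2$E_inf) / jo2$E_inf, 1e-6)
  # s* coincides with s_opt at r*
  expect_equal(jo1$s, as.numeric(s_opt(sys1, jo1$r)), tolerance = 1e-10)
})

test_that("perfect-model covariance and overconfidence diagnostics", {
  expect_equal(perfect_covariance(sys1), riccati_steady_state(sys1, 1)[1],
               tolerance = 1e-10)
  expect_equal(round(perfect_covariance(sys1), 4), 0.3113)
  oc <- overconfidence(sys1)
  expect_true(oc$overconfident)
  expect_equal(oc$ratio, 0.0494 / 0.3113, tolerance = 1e-2)
  expect_lt(oc$ratio, 1)
})

test_that("MSE surfaces are minimised along the optimality curve", {
  # E_inf over a dense s-grid at fixed r is minimised at s_opt(r)
  for (r in c(0.5, 1, 5)) {
    so <- as.numeric(s_opt(sys1, r))
    sg <- seq(so - 0.5, min(r - 1e-3, so + 0.5), length.out = 101)
    vals <- vapply(sg, function(s) {
      fp <- fitness_params(r, s)
      A <- a_infty(sys1, fp)
      if (A[1] >= 0) return(NA_real_)
      as.numeric(e_infty(sys1, fp))
    }, numeric(1))
    expect_lt(abs(sg[which.min(vals)] - so), diff(sg[1:2]) + 1e-12)
  }
})
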