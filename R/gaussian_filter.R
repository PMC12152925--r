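# The linear-Gaussian (r,s) filter: moment ODE/SDEs, steady-state Riccati
# covariance, mean-field ensemble Kalman-Bucy variants, and the covariance
# inflation correspondence.

#' Moment filter for the linear-Gaussian (r,s) family
#'
#' Forward-Euler integration of the mean and covariance equations
#' \deqn{dm_t = G m_t\,dt + (r-s) K_t (dZ_t - H m_t\,dt)}
#' \deqn{dC_t/dt = G C_t + C_t G' + \Sigma - r\,C_t H' \Xi^{-1} H C_t}
#' with gain \eqn{K_t = C_t H' \Xi^{-1}}. For a smooth driver
#' (`piecewise_obs`) the innovation is \eqn{(\dot Z^d_t - H m_t)\,dt};
#' for a rough driver (`ito_obs`) it is \eqn{dZ_t - H m_t\,dt}
#' (Euler-Maruyama). At `(r,s) = (1,0)` with the rough driver this is the
#' Kalman-Bucy filter. Note that `s` enters only the mean equation: the
#' covariance depends on `r` alone.
#'
#' @param sys an [lg_system()].
#' @param fp a [fitness_params()].
#' @param driver a `piecewise_obs` or `ito_obs`.
#' @param tgrid a [time_grid()].
#' @param m0,C0 optional initial moments; default `sys$m0` and `sys$C0`
#'   (falling back to the steady-state covariance at this `r` if `sys$C0`
#'   is `NULL`).
#' @return Object of class `moment_traj` with `times`, `mean`
#'   (`(n_steps+1) x m`), `cov` (array `m x m x (n_steps+1)`), and `gain`.
#' @export
moment_filter <- function(sys, fp, driver, tgrid, m0 = NULL, C0 = NULL) {
  m <- sys$m; n <- sys$n
  smooth <- inherits(driver, "piecewise_obs")
  if (!smooth && !inherits(driver, "ito_obs")) {
    stop("driver must be a piecewise_obs or ito_obs", call. = FALSE)
  }
  mvec <- rep_len(as.numeric(m0 %||% sys$m0), m)
  C <- sys$C0 %||% riccati_steady_state(sys, fp$r)
  if (!is.null(C0)) C <- as_square_matrix(C0, "C0")
  C <- as_square_matrix(C, "C0")
  Xi_inv <- solve(sys$Xi)
  G <- sys$G; H <- sys$H; Sg <- sys$Sigma
  dt <- tgrid$dt
  rs <- fp$r - fp$s
  N <- tgrid$n_steps
  means <- matrix(NA_real_, N + 1L, m)
  covs <- array(NA_real_, c(m, m, N + 1L))
  gains <- array(NA_real_, c(m, n, N + 1L))
  means[1L, ] <- mvec; covs[, , 1L] <- C
  K <- C %*% t(H) %*% Xi_inv
  gains[, , 1L] <- K
  for (k in seq_len(N)) {
    innov <- if (smooth) {
      (driver$derivative[tgrid$window_of[k], ] - as.numeric(H %*% mvec)) * dt
    } else {
      driver$increments[k, ] - as.numeric(H %*% mvec) * dt
    }
    mvec <- mvec + dt * as.numeric(G %*% mvec) + rs * as.numeric(K %*% innov)
    C <- C + dt * (G %*% C + C %*% t(G) + Sg -
                     fp$r * C %*% t(H) %*% Xi_inv %*% H %*% C)
    C <- (C + t(C)) / 2
    if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop(sprintf("covariance lost positive definiteness at t=%g",
                   tgrid$times[k + 1L]), call. = FALSE)
    }
    K <- C %*% t(H) %*% Xi_inv
    means[k + 1L, ] <- mvec
    covs[, , k + 1L] <- C
    gains[, , k + 1L] <- K
  }
  structure(list(times = tgrid$times, mean = means, cov = covs,
                 gain = gains, fp = fp, driver = if (smooth) "smooth" else "rough"),
            class = "moment_traj")
}

#' Steady-state filter covariance
#'
#' Solves the algebraic Riccati equation
#' \eqn{0 = G C + C G' + \Sigma - r\,C H' \Xi^{-1} H C}. For scalar
#' systems the closed form
#' \eqn{C_\infty = (G + \sqrt{G^2 + r H^2 \Xi^{-1}\Sigma})/(r H^2 \Xi^{-1})}
#' is used; otherwise the covariance ODE is integrated from the identity
#' until \eqn{\|dC/dt\|_F < } `tol` (with a max-time guard).
#'
#' @param sys an [lg_system()].
#' @param r replication weight (`> 0`).
#' @param tol Frobenius tolerance on the derivative (matrix path).
#' @param max_time integration guard.
#' @return `C_inf` as an `m x m` matrix (1 x 1 for scalar systems).
#' @export
riccati_steady_state <- function(sys, r, tol = 1e-12, max_time = 1000) {
  stopifnot(r > 0)
  if (is_scalar_system(sys)) {
    G <- as.numeric(sys$G); w <- obs_weight(sys); S <- as.numeric(sys$Sigma)
    return(matrix((G + sqrt(G^2 + r * w * S)) / (r * w), 1L, 1L))
  }
  m <- sys$m
  Xi_inv <- solve(sys$Xi)
  deriv <- function(t, y, parms) {
    C <- matrix(y, m, m)
    dC <- sys$G %*% C + C %*% t(sys$G) + sys$Sigma -
      r * C %*% t(sys$H) %*% Xi_inv %*% sys$H %*% C
    list(as.vector(dC))
  }
  C <- diag(m)
  t0 <- 0
  repeat {
    sol <- deSolve::ode(y = as.vector(C), times = c(t0, t0 + 25),
                        func = deriv, parms = NULL, method = "lsoda")
    C <- matrix(sol[nrow(sol), -1L], m, m)
    nd <- sqrt(sum(unlist(deriv(0, as.vector(C), NULL))^2))
    t0 <- t0 + 25
    if (nd < tol) break
    if (t0 >= max_time) {
      stop("Riccati integration did not converge within the time guard",
           call. = FALSE)
    }
  }
  (C + t(C)) / 2
}

#' Mean-field ensemble (r,s) filter
#'
#' Interacting-particle implementation whose mean-field limit reproduces
#' the (r,s) moment equations. All four variants share the update
#' \deqn{dI_t = -\tfrac{s}{2} K_t H (\bar X_t - \hat m_t)\,dt
#'   + (r-s) K_t \times \mathrm{innovation} + \mathrm{noise},}
#' with the empirical gain \eqn{K_t = \hat C_t H' \Xi^{-1}} recomputed
#' every step from the `1/(N-1)` ensemble covariance:
#' \itemize{
#'   \item `stochastic_rough`: innovation \eqn{dZ_t - H\bar X_t\,dt},
#'     plus independent perturbation noise
#'     \eqn{\sqrt{r-s}\,K_t\,\Xi^{1/2} d\bar B_t} (covariance contribution
#'     \eqn{(r-s) K \Xi K'} per unit time);
#'   \item `deterministic_rough`: innovation
#'     \eqn{dZ_t - \tfrac12 H(\bar X_t + \hat m_t)\,dt}, no noise;
#'   \item `stochastic_smooth` / `deterministic_smooth`: as above with
#'     \eqn{\dot Z^d_t\,dt} in place of \eqn{dZ_t}.
#' }
#' At `(r,s) = (1,0)` these reduce to the standard stochastic /
#' deterministic ensemble Kalman-Bucy filters.
#'
#' @param sys an [lg_system()].
#' @param fp a [fitness_params()].
#' @param variant one of `"stochastic_rough"`, `"deterministic_rough"`,
#'   `"stochastic_smooth"`, `"deterministic_smooth"`.
#' @param N ensemble size, `>= 2`.
#' @param driver `ito_obs` (rough variants) or `piecewise_obs` (smooth
#'   variants).
#' @param tgrid a [time_grid()].
#' @param seed integer seed for mutation and perturbation noise.
#' @param store_particles times at which the full ensemble is stored
#'   (default none).
#' @return Object of class `ensemble_traj` with `times`, empirical `mean`
#'   and `cov` trajectories, and optionally `particles`.
#' @export
ensemble_filter <- function(sys, fp, variant, N, driver, tgrid, seed,
                            store_particles = NULL) {
  variant <- match.arg(variant, c("stochastic_rough", "deterministic_rough",
                                  "stochastic_smooth", "deterministic_smooth"))
  if (N < 2L) stop("N must be >= 2", call. = FALSE)
  smooth <- grepl("smooth$", variant)
  stochastic <- grepl("^stochastic", variant)
  if (smooth && !inherits(driver, "piecewise_obs")) {
    stop("smooth variants need a piecewise_obs driver", call. = FALSE)
  }
  if (!smooth && !inherits(driver, "ito_obs")) {
    stop("rough variants need an ito_obs driver", call. = FALSE)
  }
  m <- sys$m; n <- sys$n
  set.seed(seed)
  C0 <- sys$C0 %||% riccati_steady_state(sys, fp$r)
  X <- matrix(stats::rnorm(N * m), N, m) %*% t(mat_sqrt(C0))
  X <- sweep(X, 2L, sys$m0, `+`)
  S12 <- mat_sqrt(sys$Sigma)
  Xi12 <- mat_sqrt(sys$Xi)
  Xi_inv <- solve(sys$Xi)
  G <- sys$G; H <- sys$H
  dt <- tgrid$dt; sdt <- sqrt(dt)
  r <- fp$r; s <- fp$s; rs <- r - s
  Nsteps <- tgrid$n_steps
  means <- matrix(NA_real_, Nsteps + 1L, m)
  covs <- array(NA_real_, c(m, m, Nsteps + 1L))
  parts <- if (!is.null(store_particles)) list() else NULL
  emp <- function(X) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    list(mu = mu, C = crossprod(Xc) / (N - 1))
  }
  e <- emp(X)
  means[1L, ] <- e$mu; covs[, , 1L] <- e$C
  for (k in seq_len(Nsteps)) {
    e <- emp(X)
    if (m == 1L && e$C[1] <= 0) stop("ensemble covariance degenerate",
                                     call. = FALSE)
    K <- e$C %*% t(H) %*% Xi_inv          # m x n
    HX <- X %*% t(H)                      # N x n
    Hm <- as.numeric(H %*% e$mu)
    pre <- -(s / 2) * (X - matrix(e$mu, N, m, byrow = TRUE)) %*%
      t(H) %*% t(K) * dt                  # N x m
    innov <- if (smooth) {
      zd <- driver$derivative[tgrid$window_of[k], ]
      if (stochastic) {
        sweep(-HX, 2L, zd, `+`) * dt
      } else {
        sweep(-(HX + matrix(Hm, N, n, byrow = TRUE)) / 2, 2L, zd, `+`) * dt
      }
    } else {
      dZ <- driver$increments[k, ]
      if (stochastic) {
        sweep(-HX * dt, 2L, dZ, `+`)
      } else {
        sweep(-(HX + matrix(Hm, N, n, byrow = TRUE)) / 2 * dt, 2L, dZ, `+`)
      }
    }
    dI <- pre + innov %*% t(K) * rs
    if (stochastic) {
      dBbar <- matrix(stats::rnorm(N * n, sd = sdt), N, n)
      dI <- dI + sqrt(rs) * dBbar %*% t(Xi12) %*% t(K)
    }
    dW <- matrix(stats::rnorm(N * m, sd = sdt), N, m)
    X <- X + dt * X %*% t(G) + dW %*% t(S12) + dI
    e <- emp(X)
    means[k + 1L, ] <- e$mu
    covs[, , k + 1L] <- e$C
    if (!is.null(store_particles) &&
        any(abs(store_particles - tgrid$times[k + 1L]) < 1e-12)) {
      parts[[format(tgrid$times[k + 1L])]] <- X
    }
  }
  structure(list(times = tgrid$times, mean = means, cov = covs,
                 particles = parts, variant = variant, N = N, fp = fp,
                 seed = seed),
            class = "ensemble_traj")
}

#' Covariance inflation as fitness weights
#'
#' Maps an inflation strength `epsilon > 0` to the fitness pair it
#' corresponds to: multiplicative inflation is `(r, s) = (1 + eps, 0)`;
#' additive inflation is `(r, s) = (1 - 2 eps, -2 eps)`.
#' [inflation_invert()] recovers `epsilon` and the kind from a pair when
#' the pattern matches, else reports `"mixed"` with the residual.
#'
#' @param epsilon inflation strength (`>= 0`; must keep `r > 0`).
#' @param kind `"multiplicative"` or `"additive"`.
#' @return A [fitness_params()].
#' @export
inflation_map <- function(epsilon, kind = c("multiplicative", "additive")) {
  kind <- match.arg(kind)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  if (kind == "multiplicative") {
    fitness_params(r = 1 + epsilon, s = 0)
  } else {
    if (epsilon >= 0.5) stop("additive inflation needs epsilon < 0.5 (r > 0)",
                             call. = FALSE)
    if (epsilon == 0) fitness_params(1, 0)
    else fitness_params(r = 1 - 2 * epsilon, s = -2 * epsilon)
  }
}

#' @param fp a [fitness_params()].
#' @rdname inflation_map
#' @export
inflation_invert <- function(fp, tol = 1e-10) {
  if (abs(fp$s) <= tol) {
    list(kind = "multiplicative", epsilon = fp$r - 1, residual = 0)
  } else if (abs((fp$r - fp$s) - 1) <= tol) {
    list(kind = "additive", epsilon = -fp$s / 2, residual = 0)
  } else {
    list(kind = "mixed", epsilon = NA_real_,
         residual = c(r = fp$r, s = fp$s))
  }
}
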