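# Reference signals, Ito observation paths, and piecewise-linear smoothed
# observation derivatives. All generators are seedable and share one
# fine-resolution Brownian source so that the smooth and rough drivers of a
# run are coupled (common-noise construction).

#' Fine-resolution Brownian increments
#'
#' Generates `n x dim` Gaussian increments with variance `dt` under `seed`.
#' Both [ito_observation()] and [piecewise_linear_brownian()] consume this
#' object, so refining the window `delta_d` under a fixed seed reuses the
#' same underlying Brownian path (only the windowing changes).
#'
#' @param tgrid a [time_grid()].
#' @param seed integer seed.
#' @param dim number of Brownian components.
#' @return Object of class `brownian_path` with `increments`
#'   (`n_steps x dim`) and the generating `seed`.
#' @export
brownian_path <- function(tgrid, seed, dim = 1L) {
  set.seed(seed)
  inc <- matrix(stats::rnorm(tgrid$n_steps * dim, sd = sqrt(tgrid$dt)),
                nrow = tgrid$n_steps, ncol = dim)
  structure(list(increments = inc, tgrid = tgrid, dim = dim, seed = seed),
            class = "brownian_path")
}

#' Simulate the reference (true hidden state) trajectory
#'
#' Euler-Maruyama on \eqn{dX_t = G X_t dt + b\,dt + \Sigma^{1/2} dW_t}.
#' The initial state is drawn from `N(m0, P0)` unless `x0` fixes it.
#' `with_bias = FALSE` drops the bias term `b` (the assumed model).
#'
#' @param sys an [lg_system()] or [nl_system_1d()] (for the nonlinear case
#'   the drift is `g(x)` and there is no bias).
#' @param tgrid a [time_grid()].
#' @param seed integer seed.
#' @param with_bias include the constant bias `b`? Default `TRUE`.
#' @param x0 optional fixed initial state.
#' @return Object of class `signal_path` with `times` and `states`
#'   (`(n_steps+1) x m`).
#' @export
simulate_signal <- function(sys, tgrid, seed, with_bias = TRUE, x0 = NULL) {
  set.seed(seed)
  dt <- tgrid$dt
  if (inherits(sys, "lg_system")) {
    m <- sys$m
    S12 <- mat_sqrt(sys$Sigma)
    b <- if (with_bias) sys$b else rep(0, m)
    x <- if (is.null(x0)) {
      as.numeric(sys$m0 + mat_sqrt(sys$P0) %*% stats::rnorm(m))
    } else rep_len(as.numeric(x0), m)
    states <- matrix(NA_real_, tgrid$n_steps + 1L, m)
    states[1L, ] <- x
    dW <- matrix(stats::rnorm(tgrid$n_steps * m, sd = sqrt(dt)),
                 tgrid$n_steps, m)
    for (k in seq_len(tgrid$n_steps)) {
      x <- x + dt * (as.numeric(sys$G %*% x) + b) + as.numeric(S12 %*% dW[k, ])
      states[k + 1L, ] <- x
    }
  } else {
    x <- if (is.null(x0)) sys$m0 + sqrt(sys$P0) * stats::rnorm(1) else as.numeric(x0)
    states <- matrix(NA_real_, tgrid$n_steps + 1L, 1L)
    states[1L, ] <- x
    dW <- stats::rnorm(tgrid$n_steps, sd = sqrt(dt))
    sig <- sqrt(sys$Sigma)
    for (k in seq_len(tgrid$n_steps)) {
      x <- x + dt * sys$g(x) + sig * dW[k]
      states[k + 1L, ] <- x
    }
  }
  structure(list(times = tgrid$times, states = states, tgrid = tgrid,
                 seed = seed),
            class = "signal_path")
}

#' Piecewise-linear interpolant of a Brownian path
#'
#' Aggregates fine increments into knots \eqn{B_{t_i}} on the window grid;
#' within a window the interpolant has constant time derivative
#' \eqn{(B_{t_{i+1}} - B_{t_i})/\delta_d}.
#'
#' @inheritParams brownian_path
#' @param brownian optionally a precomputed [brownian_path()]; otherwise
#'   one is generated from `seed`.
#' @return Object of class `piecewise_obs` with window `boundaries`
#'   (length `d+1`), `knots` (Brownian values at boundaries, `(d+1) x dim`)
#'   and `derivative` (`d x dim`, constant on each window).
#' @export
piecewise_linear_brownian <- function(tgrid, seed = NULL, dim = 1L,
                                      brownian = NULL) {
  bp <- brownian %||% brownian_path(tgrid, seed, dim)
  spw <- tgrid$steps_per_window
  # window sums of fine increments
  wsum <- apply(bp$increments, 2L, function(col) {
    colSums(matrix(col, nrow = spw, ncol = tgrid$d))
  })
  wsum <- matrix(wsum, nrow = tgrid$d, ncol = bp$dim)
  knots <- rbind(0, apply(wsum, 2L, cumsum))
  knots <- matrix(knots, nrow = tgrid$d + 1L, ncol = bp$dim)
  structure(list(
    boundaries = seq(0, by = tgrid$delta_d, length.out = tgrid$d + 1L),
    knots = knots,
    derivative = wsum / tgrid$delta_d,
    tgrid = tgrid, dim = bp$dim, seed = bp$seed
  ), class = "piecewise_obs")
}

#' Smoothed observation derivative
#'
#' The per-window constant driver
#' \eqn{\xi_i = h(x^*_{t_i}) + \Xi^{1/2} (B_{t_{i+1}}-B_{t_i})/\delta_d},
#' sampling the reference signal at the left endpoint of each window.
#' This is the piecewise-smooth stand-in for the rough observation
#' increment that drives the Crow-Kimura solvers and the smooth-driver
#' moment filter.
#'
#' @param signal a [simulate_signal()] path aligned with `tgrid`.
#' @param sys the generating system (provides `h` and `Xi`).
#' @inheritParams piecewise_linear_brownian
#' @return A `piecewise_obs` whose `derivative` field holds `xi`
#'   (`d x n`); the raw Brownian window derivative is kept in
#'   `brownian_derivative`.
#' @export
observation_derivative <- function(signal, sys, tgrid, seed = NULL,
                                   brownian = NULL) {
  n <- sys$n
  plb <- piecewise_linear_brownian(tgrid, seed = seed, dim = n,
                                   brownian = brownian)
  left_idx <- 1L + (seq_len(tgrid$d) - 1L) * tgrid$steps_per_window
  xleft <- signal$states[left_idx, , drop = FALSE]
  hx <- eval_h(sys, xleft)
  Xi12 <- if (inherits(sys, "lg_system")) mat_sqrt(sys$Xi) else
    matrix(sqrt(sys$Xi), 1L, 1L)
  xi <- hx + plb$derivative %*% t(Xi12)
  out <- plb
  out$brownian_derivative <- plb$derivative
  out$derivative <- xi
  out
}

#' Ito observation path
#'
#' Euler increments \eqn{dZ_k = h(x^*_{t_k}) dt + \Xi^{1/2} \Delta B_k}
#' from the same fine Brownian source as the piecewise driver when a
#' shared [brownian_path()] is supplied, so rough and smoothed drivers are
#' coupled realisation by realisation.
#'
#' @inheritParams observation_derivative
#' @return Object of class `ito_obs` with `times`, cumulative `Z`
#'   (`(n_steps+1) x n`) and `increments` (`n_steps x n`).
#' @export
ito_observation <- function(signal, sys, tgrid, seed = NULL, brownian = NULL) {
  n <- sys$n
  bp <- brownian %||% brownian_path(tgrid, seed, n)
  hx <- eval_h(sys, signal$states[-nrow(signal$states), , drop = FALSE])
  Xi12 <- if (inherits(sys, "lg_system")) mat_sqrt(sys$Xi) else
    matrix(sqrt(sys$Xi), 1L, 1L)
  dZ <- hx * tgrid$dt + bp$increments %*% t(Xi12)
  Z <- rbind(0, apply(dZ, 2L, cumsum))
  Z <- matrix(Z, nrow = tgrid$n_steps + 1L, ncol = n)
  structure(list(times = tgrid$times, Z = Z, increments = dZ,
                 tgrid = tgrid, seed = bp$seed),
            class = "ito_obs")
}

# h applied row-wise to a state matrix.
eval_h <- function(sys, x) {
  if (inherits(sys, "lg_system")) {
    x %*% t(sys$H)
  } else {
    matrix(sys$h(as.numeric(x)), ncol = 1L)
  }
}
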