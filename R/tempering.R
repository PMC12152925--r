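# Continuous-time Bayesian inversion as a pure replicator flow: the
# prior-to-posterior homotopy, Fisher-Rao metric operators, the
# gradient-flow identity, and Eulerian velocity-field transport of samples.

#' Static fitness landscape
#'
#' Either a local fitness `f(x)` (for inversion, the log-likelihood
#' \eqn{-\tfrac12 (h(x)-y)^2/\Xi}) or a symmetric non-local kernel
#' `f(x, z)`. Asymmetric kernels are rejected: the gradient-flow identity
#' relies on symmetry.
#'
#' @param f local fitness function (vectorised), or `NULL`.
#' @param kernel symmetric two-argument kernel function, or `NULL`.
#' @param check_points points at which kernel symmetry is verified.
#' @return Object of class `static_fitness`.
#' @export
static_fitness <- function(f = NULL, kernel = NULL,
                           check_points = c(-2, -0.7, 0.3, 1.9)) {
  if (is.null(f) && is.null(kernel)) stop("supply f or kernel", call. = FALSE)
  if (!is.null(kernel)) {
    xz <- expand.grid(x = check_points, z = check_points)
    d <- kernel(xz$x, xz$z) - kernel(xz$z, xz$x)
    if (max(abs(d)) > 1e-10 * max(1, max(abs(kernel(xz$x, xz$z))))) {
      stop("non-local kernel must be symmetric: f(x,z) = f(z,x)",
           call. = FALSE)
    }
  }
  structure(list(f = f, kernel = kernel), class = "static_fitness")
}

#' Conjugate Gaussian posterior (closed-form oracle)
#'
#' Precision-form update for the linear-Gaussian inversion
#' `y = H x + e`, `e ~ N(0, Xi)`, prior `N(m0, C0)`:
#' posterior covariance `(C0^{-1} + H' Xi^{-1} H)^{-1}`, mean
#' `C1 (C0^{-1} m0 + H' Xi^{-1} y)`.
#'
#' @param m0,C0 prior moments (scalar or matrix).
#' @param H forward operator.
#' @param Xi observation noise covariance.
#' @param y observed data.
#' @return List with `mean` and `cov`.
#' @export
conjugate_posterior <- function(m0, C0, H, Xi, y) {
  C0 <- as.matrix(C0); H <- as.matrix(H); Xi <- as.matrix(Xi)
  prec <- solve(C0) + t(H) %*% solve(Xi, H)
  C1 <- solve(prec)
  m1 <- C1 %*% (solve(C0, as.matrix(m0)) + t(H) %*% solve(Xi, as.matrix(y)))
  list(mean = drop(m1), cov = if (length(C1) == 1L) drop(C1) else C1)
}

# Fitness values on the grid (local part, or the frequency-dependent net
# rate pi_p for a kernel).
fitness_on_grid <- function(fit, grid, p = NULL) {
  if (!is.null(fit$f)) return(fit$f(grid$x))
  stopifnot(!is.null(p))
  K <- outer(grid$x, grid$x, fit$kernel)
  as.numeric(K %*% (grid$w * p))
}

#' Prior-to-posterior homotopy as a pure replicator flow
#'
#' Euler integration over pseudo-time `t in [0, 1]` of
#' \eqn{\partial_t p = (f(x) - E_p[f]) p} (local fitness; for a kernel the
#' frequency-dependent rate \eqn{\pi_p(x) = \int f(x,z) p(z) dz} is used).
#' The closed-form endpoint of the local flow is the exponential tilt
#' \eqn{p_1 \propto e^{f} p_0}, computed in log space for comparison.
#'
#' @param prior a [grid_density()], normalised.
#' @param fit a [static_fitness()].
#' @param n_steps number of Euler steps (default 1000).
#' @param t_end endpoint in pseudo-time (default 1).
#' @return List of class `homotopy_trajectory`: `densities` (list of
#'   [grid_density()] at `times`), `times`, `mean_fitness` (the
#'   non-decreasing curve \eqn{E_{p_t}[f]}), `energy` (for kernels, the
#'   curve of the average-fitness energy \eqn{F(p_t)}), and `tilt`
#'   (closed-form endpoint, local case only).
#' @export
homotopy_solve <- function(prior, fit, n_steps = 1000L, t_end = 1) {
  grid <- prior$grid
  p <- prior$values / sum(grid$w * prior$values)
  dt <- t_end / n_steps
  store_every <- max(1L, n_steps %/% 20L)
  times <- 0; dens <- list(grid_density(grid, p, normalized = TRUE))
  mean_fit <- numeric(n_steps + 1L)
  energy <- if (is.null(fit$kernel)) NULL else numeric(n_steps + 1L)
  fvals_local <- if (!is.null(fit$f)) fit$f(grid$x) else NULL
  K <- if (!is.null(fit$kernel)) outer(grid$x, grid$x, fit$kernel) else NULL
  for (k in 0:n_steps) {
    rate <- if (!is.null(fvals_local)) fvals_local
            else as.numeric(K %*% (grid$w * p))
    Ef <- sum(grid$w * rate * p)
    mean_fit[k + 1L] <- Ef
    if (!is.null(energy)) energy[k + 1L] <- -0.5 * Ef
    if (k == n_steps) break
    p <- p + dt * (rate - Ef) * p
    p[p < 0] <- 0
    p <- p / sum(grid$w * p)
    if ((k + 1L) %% store_every == 0L || k + 1L == n_steps) {
      times <- c(times, (k + 1L) * dt)
      dens[[length(dens) + 1L]] <- grid_density(grid, p, normalized = TRUE)
    }
  }
  tilt <- NULL
  if (!is.null(fvals_local)) {
    lw <- t_end * fvals_local + log(pmax(prior$values, 1e-300))
    tv <- exp(lw - max(lw))
    tilt <- grid_density(grid, tv / sum(grid$w * tv), normalized = TRUE)
  }
  structure(list(densities = dens, times = times, mean_fitness = mean_fit,
                 energy = energy, tilt = tilt, grid = grid),
            class = "homotopy_trajectory")
}

#' Fisher-Rao metric tensor and its inverse
#'
#' `fisher_rao_apply` maps a tangent vector (zero-integral function
#' `sigma`) to a cotangent representative \eqn{\sigma/p - \int\sigma};
#' nodes with `p = 0` map to 0 (the 0/0 = 0 boundary convention).
#' `fisher_rao_inverse` maps a cotangent function `phi` back to the
#' tangent vector \eqn{(\phi - \int \phi\,p)\,p}, which integrates to zero
#' by construction; the additive-constant ambiguity of `phi` is resolved
#' by this centring.
#'
#' @param p a [grid_density()].
#' @param sigma,phi numeric node vectors.
#' @return Numeric node vector.
#' @rdname fisher_rao
#' @export
fisher_rao_apply <- function(p, sigma) {
  grid <- p$grid
  tot <- sum(grid$w * sigma)
  if (abs(tot) > 1e-6 * max(1, max(abs(sigma)))) {
    stop("sigma must integrate to 0 (tangent-space constraint)",
         call. = FALSE)
  }
  out <- ifelse(p$values > 0, sigma / p$values, 0)
  out - tot
}

#' @rdname fisher_rao
#' @export
fisher_rao_inverse <- function(p, phi) {
  grid <- p$grid
  (phi - sum(grid$w * phi * p$values)) * p$values
}

#' Gradient-flow identity residual
#'
#' The pure replicator flow with a symmetric time-independent kernel is
#' the Fisher-Rao gradient flow of the average-fitness energy
#' \eqn{F(p) = -\tfrac12 \iint f(x,z) p(x) p(z)\,dx\,dz}. This computes
#' both sides on the grid -- the replicator right-hand side
#' \eqn{p(\pi_p - E_p[\pi_p])} directly from the kernel, and
#' \eqn{-G^{-1}_{FR}(p) F'(p)} through the Frechet derivative
#' \eqn{F'(p) = -\pi_p} and [fisher_rao_inverse()] -- and returns the
#' sup-norm of their difference together with `F(p)` by double quadrature.
#'
#' @param p a [grid_density()].
#' @param fit a [static_fitness()] with a symmetric kernel.
#' @return List with `residual` (sup-norm) and `energy` (`F(p)`).
#' @export
gradient_flow_residual <- function(p, fit) {
  if (is.null(fit$kernel)) stop("a non-local kernel is required", call. = FALSE)
  grid <- p$grid
  K <- outer(grid$x, grid$x, fit$kernel)
  pv <- p$values
  pi_p <- as.numeric(K %*% (grid$w * pv))
  rhs_replicator <- pv * (pi_p - sum(grid$w * pi_p * pv))
  rhs_gradient <- fisher_rao_inverse(p, pi_p)  # -G^{-1} F' with F' = -pi_p
  Fp <- -0.5 * sum(grid$w * pv * pi_p)
  list(residual = max(abs(rhs_replicator - rhs_gradient)), energy = Fp)
}

#' Eulerian velocity field of the replicator flow
#'
#' Solves the 1-D continuity/Poisson equation
#' \eqn{-\partial_x (v p) = (f - E_p[f]) p} by cumulative quadrature:
#' \eqn{v(x) = -p(x)^{-1} \int_{-\infty}^{x} (f - E_p[f]) p\,dy}
#' (the unique solution with decaying flux).
#'
#' @param p a [grid_density()].
#' @param fit a [static_fitness()] with local part.
#' @return Numeric node vector `v`.
#' @export
velocity_field_1d <- function(p, fit) {
  grid <- p$grid
  fvals <- fit$f(grid$x)
  pv <- p$values
  Ef <- sum(grid$w * fvals * pv)
  flux <- cumtrapz(grid$x, (fvals - Ef) * pv)
  if (any(pv < 1e-300 & abs(flux) > 1e-12)) {
    stop("domain too wide: density underflows where the flux is non-zero",
         call. = FALSE)
  }
  ifelse(pv > 1e-300, -flux / pv, 0)
}

#' Transport samples along the replicator velocity field
#'
#' Integrates \eqn{\dot x = v(t, x)} for each sample while the density is
#' advanced in lockstep by the exponential tilt
#' \eqn{p_t \propto e^{t f} p_0} (the closed form of the local homotopy);
#' `v` is interpolated linearly between grid nodes at each step. The
#' transported ensemble at `t = 1` samples the posterior.
#'
#' @param samples numeric vector of initial samples from the prior.
#' @param prior a [grid_density()].
#' @param fit a [static_fitness()] with local part.
#' @param t_end endpoint in pseudo-time.
#' @param n_steps Euler steps.
#' @return Numeric vector of transported samples.
#' @export
transport_samples <- function(samples, prior, fit, t_end = 1,
                              n_steps = 200L) {
  grid <- prior$grid
  fvals <- fit$f(grid$x)
  lp0 <- log(pmax(prior$values, 1e-300))
  dt <- t_end / n_steps
  x <- as.numeric(samples)
  for (k in 0:(n_steps - 1L)) {
    t <- k * dt
    lw <- t * fvals + lp0
    pv <- exp(lw - max(lw))
    pv <- pv / sum(grid$w * pv)
    v <- velocity_field_1d(grid_density(grid, pv, normalized = TRUE), fit)
    vx <- stats::approx(grid$x, v, xout = x, rule = 2)$y
    x <- x + dt * vx
  }
  x
}
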