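# Asymptotic error analysis for biased linear-Gaussian filtering under the
# (r,s) family, and the closed-form optimal-(r,s) design: the depressed
# cubic for the optimal error drift, the s_opt(r) / r_opt(s) curves, and
# the calibrated joint optimum at which the reported covariance equals the
# asymptotic mean squared error.

#' Steady-state error drift matrix
#'
#' \eqn{A_\infty(r,s) = G - (r-s) C_\infty H' \Xi^{-1} H} with
#' \eqn{C_\infty} from [riccati_steady_state()]. For scalar systems the
#' result is cross-checked against the closed form
#' \eqn{A_\infty = \tfrac{s}{r} G - \tfrac{r-s}{r}\sqrt{G^2 + r H^2 \Xi^{-1}\Sigma}}.
#'
#' @param sys an [lg_system()].
#' @param fp a [fitness_params()].
#' @return `m x m` matrix.
#' @export
a_infty <- function(sys, fp) {
  C <- riccati_steady_state(sys, fp$r)
  A <- sys$G - (fp$r - fp$s) * C %*% t(sys$H) %*% solve(sys$Xi) %*% sys$H
  if (is_scalar_system(sys)) {
    G <- as.numeric(sys$G); wS <- obs_weight(sys) * as.numeric(sys$Sigma)
    closed <- (fp$s / fp$r) * G - ((fp$r - fp$s) / fp$r) * sqrt(G^2 + fp$r * wS)
    stopifnot(abs(A[1] - closed) < 1e-8 * max(1, abs(closed)))
  }
  A
}

#' Bias, error covariance and MSE trajectories
#'
#' Forward-Euler integration (step `dt`) of the error-moment system under
#' the biased truth and unbiased assumed model:
#' \deqn{d E[\varepsilon_t] = A_t E[\varepsilon_t]\,dt - b\,dt}
#' \deqn{dP_t/dt = A_t P_t + P_t A_t' + \Sigma + (r-s)^2 K_t \Xi K_t'}
#' \deqn{d\tilde P_t/dt = A_t \tilde P_t + \tilde P_t A_t' + \Sigma
#'   + (r-s)^2 K_t \Xi K_t' - E[\varepsilon_t] b' - b\,E[\varepsilon_t]'}
#' with \eqn{A_t = G - (r-s) K_t H} and the gain trajectory from the
#' covariance equation. Returns the squared bias
#' \eqn{\nu_t = \|E[\varepsilon_t]\|^2}, the MSE
#' \eqn{E_t = \mathrm{Tr}\,\tilde P_t}, and the Gronwall upper-bound
#' curve on \eqn{E_t}. The bias-variance identity
#' \eqn{E_t = \mathrm{Tr}\,P_t + \nu_t} holds along the trajectory. For
#' `(r,s) = (1,0)`, `b = 0`, `P0 = C0` the error covariance coincides
#' with the filter covariance at all times.
#'
#' @param sys an [lg_system()].
#' @param fp a [fitness_params()].
#' @param T horizon.
#' @param dt Euler step.
#' @param C0,P0,eps0 optional initial filter covariance, error covariance
#'   and expected error; defaults: steady-state covariance at this `r`,
#'   `P0 = C0`, `eps0 = 0`.
#' @return Object of class `error_traj` with `times`, `bias` (E[eps]),
#'   `P`, `P_tilde` (arrays), `nu`, `mse`, and `mse_bound`.
#' @export
error_moments_solve <- function(sys, fp, T, dt = 1e-3, C0 = NULL, P0 = NULL,
                                eps0 = NULL) {
  m <- sys$m
  C <- as_square_matrix(C0 %||% sys$C0 %||% riccati_steady_state(sys, fp$r), "C0")
  P <- as_square_matrix(P0 %||% C, "P0")
  Pt <- P
  eps <- rep_len(as.numeric(eps0 %||% 0), m)
  Xi_inv <- solve(sys$Xi)
  G <- sys$G; H <- sys$H; Sg <- sys$Sigma; b <- sys$b
  rs <- fp$r - fp$s
  n_steps <- as.integer(round(T / dt))
  times <- seq(0, by = dt, length.out = n_steps + 1L)
  bias <- matrix(NA_real_, n_steps + 1L, m)
  Parr <- array(NA_real_, c(m, m, n_steps + 1L))
  Ptarr <- array(NA_real_, c(m, m, n_steps + 1L))
  nu <- numeric(n_steps + 1L); mse <- numeric(n_steps + 1L)
  bound <- numeric(n_steps + 1L)
  bias[1L, ] <- eps; Parr[, , 1L] <- P; Ptarr[, , 1L] <- Pt
  nu[1L] <- sum(eps^2); mse[1L] <- sum(diag(Pt))
  bound[1L] <- mse[1L]
  Eb <- mse[1L]
  for (k in seq_len(n_steps)) {
    K <- C %*% t(H) %*% Xi_inv
    A <- G - rs * K %*% H
    KXK <- rs^2 * K %*% sys$Xi %*% t(K)
    eps_new <- eps + dt * (as.numeric(A %*% eps) - b)
    P_new <- P + dt * (A %*% P + P %*% t(A) + Sg + KXK)
    # P_tilde = P + E[eps] E[eps]' exactly (the continuous-time identity);
    # assembling it this way keeps the bias-variance decomposition exact
    # under the Euler discretisation as well
    Pt_new <- P_new + outer(eps_new, eps_new)
    # Gronwall differential inequality on E_t (Frobenius/eigen bound form)
    alpha_sym <- spectral_abscissa(A + t(A))
    Cnorm <- sum(C^2)  # Tr[C'C]: squared-Frobenius convention of the bound
    Eb <- Eb + dt * (alpha_sym * Eb - 2 * sum(eps * b) + sum(diag(Sg)) +
                       rs^2 * spectral_abscissa(t(H) %*% Xi_inv %*% H) * Cnorm)
    C <- C + dt * (G %*% C + C %*% t(G) + Sg -
                     fp$r * C %*% t(H) %*% Xi_inv %*% H %*% C)
    eps <- eps_new; P <- (P_new + t(P_new)) / 2; Pt <- Pt_new
    bias[k + 1L, ] <- eps
    Parr[, , k + 1L] <- P; Ptarr[, , k + 1L] <- Pt
    nu[k + 1L] <- sum(eps^2); mse[k + 1L] <- sum(diag(Pt))
    bound[k + 1L] <- Eb
  }
  structure(list(times = times, bias = bias, P = Parr, P_tilde = Ptarr,
                 nu = nu, mse = mse, mse_bound = bound, fp = fp),
            class = "error_traj")
}

#' Asymptotic squared bias and mean squared error
#'
#' With \eqn{C_0 = C_\infty} and stable error drift, the asymptotic
#' squared bias is \eqn{\nu_\infty = \|A_\infty^{-1} b\|^2} and the
#' asymptotic MSE is
#' \eqn{E_\infty = \mathrm{Tr}[(\Sigma + (r-s)(G - A_\infty) C_\infty
#'   - 2 A_\infty^{-1} b b') X_\infty]} with \eqn{X_\infty} solving the
#' Lyapunov equation \eqn{A_\infty' X + X A_\infty + I = 0}. For scalar
#' systems the closed form
#' \eqn{E_\infty = -\tfrac12(\Sigma + (G-A_\infty)^2 \Xi/H^2)/A_\infty +
#'   (b/A_\infty)^2} is used (and agrees with the Lyapunov path). The
#' returned attributes include the spectral upper bound on
#' \eqn{E_\infty}.
#'
#' @param sys an [lg_system()].
#' @param fp a [fitness_params()].
#' @param method `"auto"` (scalar closed form when available),
#'   `"closed_form"`, or `"lyapunov"`.
#' @return `nu_infty`: scalar. `e_infty`: scalar with attribute
#'   `upper_bound`.
#' @rdname asymptotic_error
#' @export
nu_infty <- function(sys, fp) {
  A <- a_infty(sys, fp)
  check_error_stability(A)
  sum(solve(A, sys$b)^2)
}

#' @rdname asymptotic_error
#' @export
e_infty <- function(sys, fp, method = c("auto", "closed_form", "lyapunov")) {
  method <- match.arg(method)
  A <- a_infty(sys, fp)
  check_error_stability(A)
  C <- riccati_steady_state(sys, fp$r)
  rs <- fp$r - fp$s
  if (method == "closed_form" ||
      (method == "auto" && is_scalar_system(sys))) {
    stopifnot(is_scalar_system(sys))
    a <- A[1]; G <- as.numeric(sys$G)
    S <- as.numeric(sys$Sigma); b <- sys$b[1]
    XiH2 <- as.numeric(sys$Xi) / as.numeric(sys$H)^2
    val <- -0.5 * (S + (G - a)^2 * XiH2) / a + (b / a)^2
  } else {
    X <- solve_lyapunov(A)
    M <- sys$Sigma + rs * (sys$G - A) %*% C -
      2 * solve(A) %*% outer(sys$b, sys$b)
    val <- sum(diag(M %*% X))
  }
  Xi_inv <- solve(sys$Xi)
  alpha_sym <- spectral_abscissa(A + t(A))
  ub <- -1 / alpha_sym *
    (-2 * sum(diag(solve(A) %*% outer(sys$b, sys$b))) +
       sum(diag(sys$Sigma)) +
       rs^2 * spectral_abscissa(t(sys$H) %*% Xi_inv %*% sys$H) *
         sum(C^2))  # Tr[C'C]
  if (val > ub + 1e-8 * max(1, abs(ub))) {
    warning("asymptotic MSE exceeds its spectral upper bound")
  }
  structure(val, upper_bound = ub)
}

check_error_stability <- function(A, tol = 1e-10) {
  if (spectral_abscissa(A) >= -tol ||
      spectral_abscissa(A + t(A)) >= -tol) {
    stop("error drift is not stable: alpha(A_inf) and alpha(A_inf+A_inf') must be < 0",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Optimal error drift from the depressed cubic
#'
#' The MSE-optimal steady-state error drift \eqn{A_\infty^*} is the
#' unique negative real root of
#' \eqn{g(A) = A^3 + pA + q} with \eqn{p = -(H^2\Xi^{-1}\Sigma + G^2)} and
#' \eqn{q = 4 b^2 H^2 \Xi^{-1}}. The root is computed twice: by the
#' printed branch formulas (Cardano for discriminant \eqn{\tau > 0},
#' the `k = 2` trigonometric branch for \eqn{\tau < 0}) and by a
#' bracketed bisection oracle on the negative axis; the two must agree to
#' 1e-8. The Cardano branch is evaluated through the cube-root product
#' identity \eqn{u v = -p/3} to avoid catastrophic cancellation when
#' \eqn{q^2/4 \gg |p^3/27|}.
#'
#' @param sys a scalar [lg_system()]; `b = 0` is allowed (the root is
#'   then \eqn{-\sqrt{-p}}).
#' @return List with `a_star`, `p`, `q`, `tau`, and `residual`
#'   (`|g(a_star)|`).
#' @export
a_star <- function(sys) {
  stopifnot(is_scalar_system(sys))
  G <- as.numeric(sys$G)
  w <- obs_weight(sys)
  S <- as.numeric(sys$Sigma)
  b <- sys$b[1]
  p <- -(w * S + G^2)
  q <- 4 * b^2 * w
  tau <- q^2 / 4 + p^3 / 27
  g <- function(a) a^3 + p * a + q
  if (q == 0) {
    root <- -sqrt(-p)
  } else if (tau > 0) {
    # one real root; u = cbrt(-q/2 - sqrt(tau)) is well conditioned,
    # v = cbrt(-q/2 + sqrt(tau)) recovered from u*v = -p/3
    u <- cbrt(-q / 2 - sqrt(tau))
    v <- (-p / 3) / u
    root <- u + v
  } else {
    root <- 2 * sqrt(-p / 3) *
      cos(acos((3 * q) / (2 * p) * sqrt(-3 / p)) / 3 - 4 * pi / 3)
  }
  # independent bracketed-bisection oracle on (-inf, 0)
  lo <- -1
  while (g(lo) >= 0) lo <- lo * 2
  hi <- if (q > 0) 0 else -1e-12
  if (q == 0) {
    bis <- root  # root is exactly -sqrt(-p); bisection bracket degenerates
  } else {
    bis <- stats::uniroot(g, c(lo, hi), tol = 1e-13 * max(1, abs(lo)))$root
  }
  if (abs(root - bis) > 1e-8 * max(1, abs(root))) {
    stop("cubic branch formula and bisection oracle disagree", call. = FALSE)
  }
  list(a_star = root, p = p, q = q, tau = tau, residual = abs(g(root)))
}

#' Optimal s for a given r, and the admissible-optimal s range
#'
#' \eqn{s_{opt}(r) = r\,(A_\infty^* + y)/(G + y)} with
#' \eqn{y = \sqrt{G^2 + r H^2 \Xi^{-1}\Sigma}}. The range of `s` values
#' attainable by the optimality curve is bounded below by
#' \eqn{s_l = -(G + A_\infty^*)^2/(4 H^2 \Xi^{-1}\Sigma)} (where the
#' two optimal `r` branches merge) and above by `s_u`, the value of
#' \eqn{s_{opt}} at `y = |G|` (the `r -> 0` edge; `s_u = 0` when
#' `G > 0`).
#'
#' @param sys a scalar [lg_system()].
#' @param r replication weight.
#' @return `s_opt`: scalar with attribute `admissible` (checked against
#'   the stability bound). `s_bounds`: named vector `c(s_l, s_u)`.
#' @rdname s_optimal
#' @export
s_opt <- function(sys, r) {
  stopifnot(is_scalar_system(sys), r > 0)
  G <- as.numeric(sys$G)
  wS <- obs_weight(sys) * as.numeric(sys$Sigma)
  astar <- a_star(sys)$a_star
  y <- sqrt(G^2 + r * wS)
  val <- r * (astar + y) / (G + y)
  bound <- min(r, r * y / (G + y))
  structure(val, admissible = val < bound)
}

#' @rdname s_optimal
#' @export
s_bounds <- function(sys) {
  G <- as.numeric(sys$G)
  wS <- obs_weight(sys) * as.numeric(sys$Sigma)
  astar <- a_star(sys)$a_star
  c(s_l = -(G + astar)^2 / (4 * wS),
    s_u = (abs(G) - G) * (astar + abs(G)) / wS)
}

#' Optimal r for a given s
#'
#' Solves the quadratic (in \eqn{y = \sqrt{G^2 + r H^2\Xi^{-1}\Sigma}})
#' stationarity condition; roots with `y <= |G|` are discarded (they
#' correspond to `r <= 0`). Between `s_l` and `s_u` there are two optimal
#' `r` values; at `s = s_l` they merge (zero discriminant); below `s_l`
#' the discriminant is negative and an error is raised.
#'
#' @param sys a scalar [lg_system()].
#' @param s interaction weight.
#' @return Sorted numeric vector of one or two `r` values.
#' @export
r_opt <- function(sys, s) {
  stopifnot(is_scalar_system(sys))
  G <- as.numeric(sys$G)
  wS <- obs_weight(sys) * as.numeric(sys$Sigma)
  astar <- a_star(sys)$a_star
  disc <- (G - astar)^2 + 4 * (G * astar + s * wS)
  scale <- max(1, (G - astar)^2)
  if (disc < -1e-12 * scale) {
    stop("discriminant negative: s is below s_l", call. = FALSE)
  }
  # at s = s_l the two branches merge: report the double root once
  y <- if (disc < 1e-12 * scale) {
    (G - astar) / 2
  } else {
    ((G - astar) + c(-1, 1) * sqrt(disc)) / 2
  }
  y <- y[y > abs(G) + 1e-12]
  if (length(y) == 0L) stop("no admissible root with y > |G|", call. = FALSE)
  sort((y^2 - G^2) / wS)
}

#' @rdname r_opt
#' @export
r0_opt <- function(sys) {
  stopifnot(is_scalar_system(sys))
  G <- as.numeric(sys$G)
  wS <- obs_weight(sys) * as.numeric(sys$Sigma)
  astar <- a_star(sys)$a_star
  (astar^2 - G^2) / wS
}

#' Calibrated joint optimum
#'
#' The unique `(r, s)` pair that simultaneously minimises the asymptotic
#' MSE and calibrates the reported covariance
#' (\eqn{C_\infty = \tilde P_\infty = E_\infty}). It satisfies
#' \eqn{s = s_{opt}(r)} together with
#' \deqn{r - s = \frac{(A_\infty^*)^2 (G - A_\infty^*)}
#'   {-\tfrac12 A_\infty^* (H^2\Xi^{-1}\Sigma + (G-A_\infty^*)^2)
#'    + b^2 H^2 \Xi^{-1}},}
#' solved for `r` by safeguarded root-finding (tolerance 1e-10). The
#' calibration \eqn{|C_\infty(r^*) - E_\infty(r^*, s^*)| / E_\infty <}
#' 1e-6 is verified before returning.
#'
#' @param sys a scalar [lg_system()].
#' @return List with `r`, `s`, `rhs` (the `r - s` target), `C_inf`,
#'   `E_inf`.
#' @export
joint_optimum <- function(sys) {
  stopifnot(is_scalar_system(sys))
  G <- as.numeric(sys$G)
  w <- obs_weight(sys)
  S <- as.numeric(sys$Sigma)
  b <- sys$b[1]
  astar <- a_star(sys)$a_star
  rhs <- astar^2 * (G - astar) /
    (-0.5 * astar * (w * S + (G - astar)^2) + b^2 * w)
  f <- function(r) r - as.numeric(s_opt(sys, r)) - rhs
  hi <- r0_opt(sys) + 1
  lo <- 1e-10
  while (f(lo) * f(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (f(lo) * f(hi) > 0) stop("no sign change bracketing the joint optimum",
                              call. = FALSE)
  rstar <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  sstar <- as.numeric(s_opt(sys, rstar))
  Cst <- riccati_steady_state(sys, rstar)[1]
  Est <- as.numeric(e_infty(sys, fitness_params(rstar, sstar)))
  if (abs(Cst - Est) / Est > 1e-6) {
    stop("joint optimum failed the C_inf = E_inf calibration check",
         call. = FALSE)
  }
  list(r = rstar, s = sstar, rhs = rhs, C_inf = Cst, E_inf = Est)
}

#' Perfect-model covariance and the overconfidence of pure multiplicative
#' inflation
#'
#' \eqn{\hat C_\infty = (G + \sqrt{G^2 + H^2\Xi^{-1}\Sigma})/(H^2\Xi^{-1})}
#' is the steady-state Kalman-Bucy covariance under a perfect model
#' (equal to the Riccati steady state at `r = 1`). `overconfidence`
#' returns the ratio \eqn{C_\infty(r_{0,opt}) / \hat C_\infty}; for an
#' unstable signal (`G > 0`) with a single-real-root cubic
#' (\eqn{\tau > 0}) the ratio is provably below 1: the MSE-optimal pure
#' multiplicative inflation is overconfident.
#'
#' @param sys a scalar [lg_system()].
#' @return `perfect_covariance`: scalar. `overconfidence`: list with
#'   `ratio`, `overconfident` flag, and the derivation-consistent
#'   informational `bound`.
#' @rdname perfect_cov
#' @export
perfect_covariance <- function(sys) {
  stopifnot(is_scalar_system(sys))
  G <- as.numeric(sys$G); w <- obs_weight(sys); S <- as.numeric(sys$Sigma)
  (G + sqrt(G^2 + w * S)) / w
}

#' @rdname perfect_cov
#' @export
overconfidence <- function(sys) {
  G <- as.numeric(sys$G); w <- obs_weight(sys); S <- as.numeric(sys$Sigma)
  r0 <- r0_opt(sys)
  ratio <- riccati_steady_state(sys, r0)[1] / perfect_covariance(sys)
  tau <- a_star(sys)$tau
  bnd <- (2 * abs(G) / r0 + sqrt(w * S / r0)) / (G + sqrt(G^2 + w * S))
  if (tau > 0 && G > 0 && ratio >= 1) {
    stop("overconfidence ratio >= 1 under tau > 0, G > 0", call. = FALSE)
  }
  list(ratio = ratio, overconfident = ratio < 1, bound = bnd, tau = tau)
}

#' Steady-state report
#'
#' Assembles the asymptotic quantities for one `(r, s)` pair on a scalar
#' system: error drift, covariance, gain, squared bias, MSE, Lyapunov
#' solution, the optimality-cubic data and the calibrated optima.
#'
#' @param sys a scalar [lg_system()].
#' @param fp a [fitness_params()].
#' @return List of class `steady_state_report`.
#' @export
steady_state_report <- function(sys, fp) {
  A <- a_infty(sys, fp)
  C <- riccati_steady_state(sys, fp$r)
  K <- C %*% t(sys$H) %*% solve(sys$Xi)
  X <- solve_lyapunov(A)
  ei <- e_infty(sys, fp)
  cub <- a_star(sys)
  structure(list(
    A_inf = A, C_inf = C, K_inf = K, X_inf = X,
    nu_inf = nu_infty(sys, fp), E_inf = as.numeric(ei),
    E_inf_bound = attr(ei, "upper_bound"),
    a_star = cub$a_star, p = cub$p, q = cub$q, tau = cub$tau,
    r = fp$r, s = fp$s
  ), class = "steady_state_report")
}

#' Optimal-design report
#'
#' @param sys a scalar [lg_system()].
#' @return List of class `optima_report` with `s_l`, `s_u`, `r0_opt`,
#'   the joint optimum, the perfect-model covariance and the
#'   overconfidence ratio.
#' @export
optima_report <- function(sys) {
  sb <- s_bounds(sys)
  jo <- joint_optimum(sys)
  oc <- overconfidence(sys)
  structure(list(
    s_l = sb[["s_l"]], s_u = sb[["s_u"]], r0_opt = r0_opt(sys),
    joint = jo, perfect_C = perfect_covariance(sys),
    overconfidence = oc
  ), class = "optima_report")
}
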