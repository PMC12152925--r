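#' Linear-Gaussian signal-observation system
#'
#' Defines the filtering problem: a linear signal
#' \eqn{dX_t = G X_t dt + b\,dt + \Sigma^{1/2} dW_t} observed through
#' \eqn{dZ_t = H X_t dt + \Xi^{1/2} dB_t}. The constant drift `b` is the
#' model bias: the assumed model used by the filter drops it, so `b != 0`
#' encodes misspecification. Initial moments: the filter starts from
#' `N(m0, C0)` while the true state starts from `N(m0, P0)` (the filter
#' covariance `C0` and the true-state spread `P0` are distinct objects and
#' stored separately).
#'
#' @param G signal drift matrix (m x m), units 1/time. Scalars are promoted
#'   to 1 x 1 matrices.
#' @param H observation matrix (n x m).
#' @param Sigma signal noise covariance (m x m), symmetric positive
#'   semi-definite.
#' @param Xi observation noise covariance (n x n), symmetric positive
#'   definite.
#' @param b constant signal bias vector (length m). Default 0 (perfect
#'   model).
#' @param m0 initial mean (length m).
#' @param C0 initial filter covariance (m x m), positive definite, or
#'   `NULL` to default at solve time to the steady-state covariance
#'   `riccati_steady_state(sys, r)` of the fitness pair in use.
#' @param P0 initial true-state covariance (m x m), positive definite.
#'
#' @return An object of class `lg_system`.
#' @seealso [builtin_fixture()], [validate_fitness()]
#' @export
lg_system <- function(G, H, Sigma, Xi, b = 0, m0 = 0, C0 = NULL, P0 = 1) {
  G <- as_square_matrix(G, "G")
  m <- nrow(G)
  H <- as.matrix(H)
  if (length(H) == 1L && m == 1L) H <- matrix(H, 1L, 1L)
  if (ncol(H) != m) stop("ncol(H) must equal nrow(G)", call. = FALSE)
  n <- nrow(H)
  Sigma <- as_square_matrix(Sigma, "Sigma")
  Xi <- as_square_matrix(Xi, "Xi")
  if (nrow(Sigma) != m) stop("Sigma must be m x m", call. = FALSE)
  if (nrow(Xi) != n) stop("Xi must be n x n", call. = FALSE)
  check_pd(Sigma, "Sigma", strict = FALSE)
  check_pd(Xi, "Xi", strict = TRUE)
  b <- rep_len(as.numeric(b), m)
  m0 <- rep_len(as.numeric(m0), m)
  if (!is.null(C0)) {
    C0 <- as_square_matrix(C0, "C0")
    check_pd(C0, "C0")
  }
  P0 <- as_square_matrix(P0, "P0")
  check_pd(P0, "P0")
  structure(
    list(G = G, H = H, Sigma = Sigma, Xi = Xi, b = b, m0 = m0,
         C0 = C0, P0 = P0, m = m, n = n),
    class = "lg_system"
  )
}

#' @export
print.lg_system <- function(x, ...) {
  cat(sprintf("<lg_system> m=%d state(s), n=%d observation(s)\n", x$m, x$n))
  if (x$m == 1L && x$n == 1L) {
    cat(sprintf("  G=%g H=%g Sigma=%g Xi=%g b=%g m0=%g P0=%g C0=%s\n",
                x$G, x$H, x$Sigma, x$Xi, x$b, x$m0, x$P0,
                if (is.null(x$C0)) "<steady state>" else format(x$C0[1])))
  }
  invisible(x)
}

is_scalar_system <- function(sys) sys$m == 1L && sys$n == 1L

# H^2 Xi^{-1} for scalar systems -- the recurring weight in closed forms.
obs_weight <- function(sys) {
  stopifnot(is_scalar_system(sys))
  as.numeric(sys$H)^2 / as.numeric(sys$Xi)
}

#' One-dimensional nonlinear system
#'
#' Signal drift `g` and observation function `h` as scalar callables, with
#' scalar noise intensities. Used by the grid PDE solvers, which accept
#' arbitrary Lipschitz drifts.
#'
#' @param g drift function of one numeric vector argument (vectorised).
#' @param h observation function, vectorised.
#' @param Sigma scalar signal noise variance rate, `>= 0`.
#' @param Xi scalar observation noise variance rate, `> 0`.
#' @param m0,P0 mean and variance of the Gaussian initial density.
#' @return An object of class `nl_system_1d`.
#' @export
nl_system_1d <- function(g, h, Sigma, Xi, m0 = 0, P0 = 1) {
  stopifnot(is.function(g), is.function(h))
  Sigma <- as.numeric(Sigma); Xi <- as.numeric(Xi)
  if (Sigma < 0) stop("Sigma must be >= 0", call. = FALSE)
  if (Xi <= 0) stop("Xi must be > 0", call. = FALSE)
  probe <- c(-1, 0, 1)
  if (!all(is.finite(g(probe))) || !all(is.finite(h(probe)))) {
    stop("g and h must return finite values", call. = FALSE)
  }
  structure(list(g = g, h = h, Sigma = Sigma, Xi = Xi, m0 = m0, P0 = P0,
                 m = 1L, n = 1L),
            class = "nl_system_1d")
}

# Promote a scalar lg_system to its nl_system_1d view (linear drifts).
as_nl_system <- function(sys) {
  if (inherits(sys, "nl_system_1d")) return(sys)
  stopifnot(inherits(sys, "lg_system"), is_scalar_system(sys))
  G <- as.numeric(sys$G); H <- as.numeric(sys$H)
  nl_system_1d(g = function(x) G * x, h = function(x) H * x,
               Sigma = as.numeric(sys$Sigma), Xi = as.numeric(sys$Xi),
               m0 = sys$m0, P0 = as.numeric(sys$P0))
}

#' Fitness weights of the non-local quadratic landscape
#'
#' The pair `(r, s)` parameterising the quadratic fitness
#' \deqn{f_t(x,z) = -\tfrac{r}{2}\|h(x)-\dot y_t\|^2_\Xi
#'   + s\langle h(x)-\dot y_t,\, h(z)-\dot y_t\rangle_\Xi,}
#' where \eqn{\|v\|^2_\Xi = v'\Xi^{-1}v}. `r` weights replication
#' (data misfit); `s` weights the population-interaction term (conformity
#' for `s > 0`, diversity pressure for `s < 0`). `s = 0` gives the local
#' log-likelihood fitness; `(r, s) = (1, 0)` recovers exact Bayesian
#' filtering.
#'
#' @param r replication weight, strictly positive.
#' @param s interaction weight, strictly less than `r`.
#' @return An object of class `fitness_params`.
#' @export
fitness_params <- function(r, s = 0) {
  r <- as.numeric(r); s <- as.numeric(s)
  if (!is.finite(r) || r <= 0) stop("r must be > 0", call. = FALSE)
  if (!is.finite(s) || s >= r) stop("s must be < r", call. = FALSE)
  structure(list(r = r, s = s), class = "fitness_params")
}

#' @export
print.fitness_params <- function(x, ...) {
  cat(sprintf("<fitness_params> r=%g s=%g\n", x$r, x$s)); invisible(x)
}

#' Time discretisation with observation windows
#'
#' A uniform simulation grid of step `dt` over `[0, T]`, partitioned into
#' `d` observation windows of width `delta_d` (the smoothing window of the
#' piecewise-linear observation derivative). `delta_d` must be an integer
#' multiple of `dt` and `T` of `delta_d`.
#'
#' @param T horizon.
#' @param dt simulation step.
#' @param delta_d observation window width; default `dt` (one step per
#'   window, the roughest smooth driver).
#' @return An object of class `time_grid` with fields `T`, `dt`,
#'   `delta_d`, `d` (number of windows), `n_steps`, `times`, and
#'   `window_of` (window index of each step).
#' @export
time_grid <- function(T, dt, delta_d = dt) {
  stopifnot(T > 0, dt > 0, delta_d > 0)
  spw <- delta_d / dt
  if (abs(spw - round(spw)) > 1e-8 * spw) {
    stop("delta_d must be an integer multiple of dt", call. = FALSE)
  }
  spw <- as.integer(round(spw))
  d <- T / delta_d
  if (abs(d - round(d)) > 1e-8 * d) {
    stop("T must be an integer multiple of delta_d", call. = FALSE)
  }
  d <- as.integer(round(d))
  n_steps <- d * spw
  structure(
    list(T = T, dt = dt, delta_d = delta_d, d = d,
         steps_per_window = spw, n_steps = n_steps,
         times = seq(0, by = dt, length.out = n_steps + 1L),
         window_of = rep(seq_len(d), each = spw)),
    class = "time_grid"
  )
}

#' Built-in example systems
#'
#' `"system1"` and `"system2"` are the two scalar biased systems used in
#' the misspecified-filtering experiments (system 1 has a single real
#' negative root of the optimality cubic, system 2 three real roots);
#' `"static1d"` is the static-signal configuration used for the
#' smooth-observation (Wong-Zakai) comparison: `g = 0`, `Sigma = 0`,
#' `h(x) = 2x`, `Xi = 1`, prior `N(0, 0.3)`, fixed true state
#' `x0_star = 5`, and window `delta_d = 500 dt`.
#'
#' @param name one of `"system1"`, `"system2"`, `"static1d"`.
#' @return For the scalar systems, an [lg_system()]. For `"static1d"`, a
#'   list with elements `sys` (an [nl_system_1d()]), `x0_star`, `H`, and
#'   `delta_d_steps = 500`.
#' @export
builtin_fixture <- function(name = c("system1", "system2", "static1d")) {
  name <- match.arg(name)
  # P0 defaults to the perfect-model steady-state covariance (a natural
  # stationary spread for the reference trajectory).
  chat <- function(G, H, Sigma, Xi) {
    w <- H^2 / Xi
    (G + sqrt(G^2 + w * Sigma)) / w
  }
  switch(name,
    system1 = lg_system(G = 0.5, H = 8.5, Sigma = 0.8, Xi = 6.3, b = 9.9,
                        m0 = 0, C0 = NULL, P0 = chat(0.5, 8.5, 0.8, 6.3)),
    system2 = lg_system(G = 2.5, H = 2.9, Sigma = 18, Xi = 26, b = 1.2,
                        m0 = 0, C0 = NULL, P0 = chat(2.5, 2.9, 18, 26)),
    static1d = {
      H <- 2
      list(
        sys = nl_system_1d(g = function(x) 0 * x, h = function(x) H * x,
                           Sigma = 0, Xi = 1, m0 = 0, P0 = 0.3),
        x0_star = 5, H = H, delta_d_steps = 500L
      )
    }
  )
}

#' Admissibility report for a fitness pair on a system
#'
#' Checks the parameter constraints (`r > 0`, `s < r`), the scalar
#' admissible-`s` bound guaranteeing a negative steady-state error drift,
#' the spectral stability of the steady-state error matrix
#' \eqn{A_\infty = G - (r-s) C_\infty H' \Xi^{-1} H} (both
#' \eqn{\alpha(A_\infty) < 0} and
#' \eqn{\alpha(A_\infty + A_\infty') < 0}), and the
#' observability/controllability rank conditions that guarantee a unique
#' steady-state covariance. Parameter violations raise errors; spectral
#' failures are reported in the returned flags, not raised.
#'
#' @param fp a [fitness_params()].
#' @param sys an [lg_system()].
#' @param tol strict-negativity tolerance for spectral abscissas.
#' @return A list of class `admissibility_report` with logical flags and
#'   the computed quantities (`A_inf`, `C_inf`, `s_bound`, abscissas).
#' @export
validate_fitness <- function(fp, sys, tol = 1e-10) {
  stopifnot(inherits(fp, "fitness_params"), inherits(sys, "lg_system"))
  m <- sys$m
  # rank conditions: controllability of (G, Sigma^{1/2}), observability of (G, H)
  S12 <- mat_sqrt(sys$Sigma)
  ctrb <- do.call(cbind, lapply(0:(m - 1L), function(k) {
    Reduce(`%*%`, c(list(diag(m)), rep(list(sys$G), k))) %*% S12
  }))
  obsv <- do.call(rbind, lapply(0:(m - 1L), function(k) {
    sys$H %*% Reduce(`%*%`, c(list(diag(m)), rep(list(sys$G), k)))
  }))
  rank_ok <- qr(ctrb)$rank == m && qr(obsv)$rank == m

  C_inf <- riccati_steady_state(sys, fp$r)
  A_inf <- a_infty(sys, fp)
  alpha_A <- spectral_abscissa(A_inf)
  alpha_sym <- spectral_abscissa(A_inf + t(A_inf))

  s_bound <- NA_real_
  s_bound_ok <- NA
  if (is_scalar_system(sys)) {
    G <- as.numeric(sys$G)
    y <- sqrt(G^2 + fp$r * obs_weight(sys) * as.numeric(sys$Sigma))
    s_bound <- min(fp$r, fp$r * y / (G + y))
    s_bound_ok <- fp$s < s_bound
  }

  structure(list(
    r_positive = fp$r > 0,
    s_below_r = fp$s < fp$r,
    s_bound = s_bound,
    s_below_bound = s_bound_ok,
    alpha_A_inf = alpha_A,
    alpha_A_sym = alpha_sym,
    stable = alpha_A < -tol,
    stable_sym = alpha_sym < -tol,
    rank_conditions = rank_ok,
    admissible = isTRUE(rank_ok) && alpha_A < -tol && alpha_sym < -tol &&
      (!isTRUE(!s_bound_ok)),
    A_inf = A_inf, C_inf = C_inf, r = fp$r, s = fp$s
  ), class = "admissibility_report")
}

#' @export
print.admissibility_report <- function(x, ...) {
  cat(sprintf("<admissibility_report> r=%g s=%g: %s\n", x$r, x$s,
              if (isTRUE(x$admissible)) "admissible" else "NOT admissible"))
  cat(sprintf("  alpha(A_inf)=%.6g alpha(A_inf+A_inf')=%.6g rank ok: %s\n",
              x$alpha_A_inf, x$alpha_A_sym, x$rank_conditions))
  if (!is.na(x$s_bound)) {
    cat(sprintf("  admissible s bound: s < %.6g (%s)\n", x$s_bound,
                if (isTRUE(x$s_below_bound)) "satisfied" else "violated"))
  }
  invisible(x)
}

#' Read / write a system as JSON
#'
#' JSON keys `G, H, Sigma, Xi, b, m0, C0, P0`, matrices as row-major
#' nested lists. `C0` may be absent or `null` (steady-state default).
#'
#' @param path file path.
#' @rdname system_json
#' @export
read_system_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyMatrix = TRUE)
  grab <- function(key, default = NULL) {
    if (is.null(x[[key]])) default else x[[key]]
  }
  lg_system(G = x$G, H = x$H, Sigma = x$Sigma, Xi = x$Xi,
            b = grab("b", 0), m0 = grab("m0", 0),
            C0 = grab("C0"), P0 = grab("P0", 1))
}

#' @param sys an [lg_system()].
#' @rdname system_json
#' @export
write_system_json <- function(sys, path) {
  x <- list(G = sys$G, H = sys$H, Sigma = sys$Sigma, Xi = sys$Xi,
            b = sys$b, m0 = sys$m0, C0 = sys$C0, P0 = sys$P0)
  jsonlite::write_json(x, path, matrix = "rowmajor", digits = NA,
                       auto_unbox = FALSE, null = "null")
  invisible(path)
}
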