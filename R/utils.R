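# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
as_square_matrix <- function(x, name = deparse(substitute(x))) {
  m <- as.matrix(x)
  if (nrow(m) != ncol(m)) stop(sprintf("'%s' must be square", name), call. = FALSE)
  storage.mode(m) <- "double"
  m
}

is_symmetric <- function(m, tol = 1e-10) {
  max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# Symmetric matrix square root via eigen decomposition; clips tiny negative
# eigenvalues arising from roundoff in PSD inputs.
mat_sqrt <- function(m) {
  if (length(m) == 1L) return(matrix(sqrt(max(0, m[1])), 1L, 1L))
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

spectral_abscissa <- function(m) max(Re(eigen(m, only.values = TRUE)$values))

# Trapezoid quadrature on a uniform grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * diff(x) / 2))
}

# Solve A' X + X A + Q = 0 for symmetric X (Lyapunov) via the Kronecker
# vectorisation (I (x) A' + A' (x) I) vec(X) = -vec(Q).
solve_lyapunov <- function(A, Q = diag(nrow(A))) {
  m <- nrow(A)
  lhs <- diag(m) %x% t(A) + t(A) %x% diag(m)
  X <- matrix(solve(lhs, -as.vector(Q)), m, m)
  (X + t(X)) / 2
}

# Real cube root.
cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

check_pd <- function(m, name, strict = TRUE, tol = 1e-12) {
  if (!is_symmetric(m)) stop(sprintf("'%s' must be symmetric", name), call. = FALSE)
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (strict && min(ev) <= tol * max(1, max(abs(ev)))) {
    stop(sprintf("'%s' must be positive definite", name), call. = FALSE)
  }
  if (!strict && min(ev) < -tol * max(1, max(abs(ev)))) {
    stop(sprintf("'%s' must be positive semi-definite", name), call. = FALSE)
  }
  invisible(TRUE)
}

# Deterministic substream seed for path/particle index i under master seed.
substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483647L)
}
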