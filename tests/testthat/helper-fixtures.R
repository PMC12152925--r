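# Shared fixtures and small oracles for the test suite.

sys1 <- builtin_fixture("system1")
sys2 <- builtin_fixture("system2")

# a stable scalar test system with modest signal-to-noise, used where the
# Table-2 systems' strong gains would need very fine steps
sys_mild <- lg_system(G = -0.5, H = 1, Sigma = 0.5, Xi = 1, b = 0,
                      m0 = 0.5, C0 = 0.4, P0 = 0.4)

# scalar steady-state covariance, written independently of the package path
closed_form_cinf <- function(G, H, Sigma, Xi, r) {
  w <- H^2 / Xi
  (G + sqrt(G^2 + r * w * Sigma)) / (r * w)
}

# draw a random admissible scalar biased system (for property tests)
random_scalar_system <- function() {
  lg_system(G = stats::runif(1, -3, 3), H = stats::runif(1, 0.5, 8),
            Sigma = stats::runif(1, 0.2, 15), Xi = stats::runif(1, 0.5, 25),
            b = stats::runif(1, 0.1, 8), m0 = 0, P0 = 1)
}

# manually-built piecewise observation with a prescribed constant driver
constant_driver <- function(tgrid, value, n = 1L) {
  structure(list(
    boundaries = seq(0, by = tgrid$delta_d, length.out = tgrid$d + 1L),
    knots = matrix(0, tgrid$d + 1L, n),
    derivative = matrix(value, tgrid$d, n),
    tgrid = tgrid, dim = n, seed = NA_integer_
  ), class = "piecewise_obs")
}
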