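---
title: "Replicator-mutator dynamics as sequential Bayesian filters: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator-mutator dynamics as sequential Bayesian filters: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmfilter)
```

## The model family

The package connects two dynamical descriptions of "learning from a stream
of data". The first is the continuous-trait **replicator-mutator
(Crow-Kimura) equation** for a trait density $\rho_t(x)$,

$$\partial_t \rho_t = L^*\rho_t
  + \rho_t\big(\mathbb E_{z\sim\rho_t}[f_t(x,z)] - \mathbb E_{\rho_t}[f_t]\big),$$

where the mutation operator $L^*\rho = -\nabla\cdot(\rho\,g)
+ \tfrac12\nabla\cdot(\Sigma\nabla\rho)$ is the forward operator of a
diffusion with drift $g$, and replication is driven by the deviation of a
trait's fitness from the population mean. The second is **stochastic
filtering**: the conditional density of a hidden diffusion
$dX_t = g(X_t)dt + \Sigma^{1/2}dW_t$ observed through
$dZ_t = h(X_t)dt + \Xi^{1/2}dB_t$ solves the Kushner-Stratonovich
equation, whose unnormalised form is the (linear) Zakai equation.

The bridge is a quadratic, possibly **non-local** fitness landscape

$$f_t(x,z) = -\tfrac{r}{2}\,\|h(x)-\dot Z^d_t\|^2_\Xi
  + s\,\langle h(x)-\dot Z^d_t,\ h(z)-\dot Z^d_t\rangle_\Xi,
  \qquad r > 0,\ s < r,$$

with $\|v\|^2_\Xi = v^\top\Xi^{-1}v$, where $\dot Z^d_t$ is the
**piecewise-constant derivative of a piecewise-linear smoothing of the
observation path** over windows of width $\delta_d$. The weight $r$
controls how strongly misfit to the data is penalised; $s$ weights a
population-interaction term ($s>0$ rewards conformity with the population
feature mean, $s<0$ rewards diversity). With $s = 0$ the fitness is the
local log-likelihood rate; with $(r,s)=(1,0)$ the construction recovers
exact Bayesian filtering.

As the window shrinks, the smoothed equation converges to a rough-path
SPDE in the **Stratonovich** interpretation, not the naive Ito one — the
classical smooth-approximation (Wong-Zakai) phenomenon. The package treats
this operationally: `zakai_solve()` exposes the modified Zakai equation in
its Ito form (`"ito"`, drift multiplier $-\tfrac{s}{2}h^\top\Xi^{-1}h$),
the Stratonovich-form equation realised through its Ito-corrected drift
(`"stratonovich"`, multiplier $\tfrac{(r-s)^2-r}{2}h^\top\Xi^{-1}h$), and
the deliberately wrong `"ito_naive"` mode (Stratonovich-form drift
$-\tfrac{r}{2}h^\top\Xi^{-1}h$ with uncorrected Ito increments), which
exists so that `smooth_limit_experiment()` can demonstrate the phenomenon:
under a shared Brownian source, the smoothed Crow-Kimura solution
approaches the Stratonovich solution as $\delta_d$ refines and stays far
from the naive Ito one. The two printed forms of the rough-limit drift are
mutually consistent only at $r-s \in \{0, 1\}$; we expose both modes
rather than silently reconciling them, and all smooth-limit claims are
tested against the Stratonovich mode (the two coincide exactly at
$(r,s)=(1,0)$, which the suite asserts bit-for-bit).

## Linear-Gaussian theory: the (r,s) filter

For linear drifts ($g(x)=Gx$, $h(x)=Hx$) and a Gaussian initial density
the trait density stays Gaussian, with moments

$$dm_t = Gm_t\,dt + (r-s)\,K_t\,(dZ_t - Hm_t\,dt), \qquad
  \dot C_t = GC_t + C_tG^\top + \Sigma - r\,C_tH^\top\Xi^{-1}HC_t,$$

and gain $K_t = C_tH^\top\Xi^{-1}$ (`moment_filter()`). Two structural
facts drive everything downstream: **only $r$ enters the covariance
equation** (the suite checks that changing $s$ leaves the covariance
trajectory bit-identical), and at $(r,s)=(1,0)$ the equations are the
Kalman-Bucy filter.

`ensemble_filter()` provides the interacting-particle (mean-field) form in
four variants (stochastic/deterministic x rough/smooth observations), all
sharing the update
$dI_t = -\tfrac{s}{2}K_tH(\bar X_t - \hat m_t)\,dt + (r-s)K_t \times
\text{innovation} + \text{noise}$, with perturbation-noise covariance
$(r-s)K_t\Xi K_t^\top$ per unit time in the stochastic variants. The
printed coefficients of the source material for these SDEs are
typographically ambiguous and not mutually consistent under Fokker-Planck
bookkeeping; the package implements the unique family that (a) reduces
exactly to the standard stochastic/deterministic ensemble Kalman-Bucy
filters at $(1,0)$ and (b) reproduces the moment equations above in the
mean-field limit — that moment contract, not any particular printed
factor, is what the theory actually uses, and it is what the acceptance
suite verifies at $N = 20000$ particles.

The correspondence with **covariance inflation** is exact
(`inflation_map()`): multiplicative inflation of strength $\epsilon$ is
$(r,s) = (1+\epsilon, 0)$; additive inflation is
$(r,s) = (1-2\epsilon, -2\epsilon)$. A general admissible pair mixes both.

## Misspecified filtering and the optimal (r,s)

The design problem that motivates $s \ne 0$: the true signal carries a
constant bias $b$ ($dX_t = GX_t\,dt + b\,dt + \Sigma^{1/2}dW_t$) that the
assumed model omits. The tracking error
$\varepsilon_t = m_t - x^*_t$ then has non-zero stationary mean, and the
asymptotic mean squared error decomposes as
$E_\infty = \mathrm{Tr}(P_\infty) + \nu_\infty$ (error variance plus
squared bias). With the filter covariance initialised at its steady state,
everything is governed by the error drift
$A_\infty(r,s) = G - (r-s)C_\infty H^\top\Xi^{-1}H$
(`a_infty()`, stability checked as $\alpha(A_\infty)<0$ and
$\alpha(A_\infty + A_\infty^\top)<0$), and for scalar systems:

- $\nu_\infty = (b/A_\infty)^2$ and
  $E_\infty = -\tfrac12\big(\Sigma + (G-A_\infty)^2\,\Xi/H^2\big)/A_\infty
  + (b/A_\infty)^2$ (`nu_infty()`, `e_infty()`). The quadratic term is
  implemented as $(G-A_\infty)^2\,\Xi/H^2$ — the only dimensionally
  consistent reading of the source expression, and the one under which the
  covariance-calibration identity below holds exactly. The matrix path
  evaluates the same quantity through the Lyapunov equation
  $A_\infty^\top X + XA_\infty + I = 0$; the suite requires the two routes
  to agree to $10^{-8}$.
- The MSE-optimal error drift $A_\infty^*$ is the unique negative root of
  the depressed cubic $A^3 + pA + q = 0$,
  $p = -(H^2\Xi^{-1}\Sigma + G^2)$, $q = 4b^2H^2\Xi^{-1}$ (`a_star()`).
  Both printed branch formulas (Cardano for $\tau > 0$, the $k=2$
  trigonometric branch for $\tau < 0$) are evaluated **and** compared
  against a bracketed bisection oracle; they must agree to $10^{-8}$.
  The Cardano branch is computed through the cube-root product identity
  $uv = -p/3$ because the textbook form loses seven digits to
  cancellation when $q^2/4 \gg |p^3|/27$.
- `s_opt(r)`, `r_opt(s)`, `s_bounds()` and `r0_opt()` give the optimality
  curves: for each $r$ there is one optimal $s$; for
  $s_l < s < s_u$ there are two optimal $r$; the branches merge at
  $s_l = -(G+A_\infty^*)^2/(4H^2\Xi^{-1}\Sigma)$. The upper end $s_u$ is
  evaluated as $s_{opt}$ at $y = |G|$ (the $r \to 0$ edge of the
  admissible parameterisation; for $G > 0$ this is 0) — the printed
  standalone formula for $s_u$ disagrees with its own derivation, and the
  derivation form is the one implemented.
- `joint_optimum()` returns the unique pair that both minimises
  $E_\infty$ and **calibrates** the reported covariance,
  $C_\infty = E_\infty$, by solving $s = s_{opt}(r)$ together with a
  closed-form expression for $r - s$ in terms of $A_\infty^*$; the result
  is accepted only if the calibration holds to a relative $10^{-6}$.
  `overconfidence()` quantifies why this matters: for an unstable signal
  the best pure multiplicative inflation ($s=0$) reports a covariance far
  below the perfect-model value $\hat C_\infty$ — confident and wrong —
  while the calibrated mixed inflation restores honest uncertainty.

Two bundled scalar systems (`builtin_fixture("system1")`, `"system2"`)
exercise the two discriminant signs of the cubic: system 1
($G=0.5, H=8.5, \Sigma=0.8, \Xi=6.3, b=9.9$) has $\tau>0$ and a strongly
non-local optimum near $(r,s) = (0.13, -1.18)$; system 2
($G=2.5, H=2.9, \Sigma=18, \Xi=26, b=1.2$) has $\tau<0$ and an optimum
$(0.99, -0.0134)$ close to plain filtering. Their initial true-state
spread `P0` is not part of the published configuration; we set it once to
the perfect-model steady covariance $\hat C_\infty$ (a natural stationary
choice) — the asymptotic quantities do not depend on it.

## Tempering: the static-data special case

With a static observation the same replicator structure performs
continuous-time Bayesian inversion: the pure replicator flow
$\partial_t p_t = (f - \mathbb E_{p_t}[f])\,p_t$ with log-likelihood
fitness transports the prior to the posterior over pseudo-time
$t \in [0,1]$, with closed form $p_t \propto e^{tf}p_0$
(`homotopy_solve()`, checked against `conjugate_posterior()`). The flow is
the **Fisher-Rao gradient flow** of the average-fitness energy
$F(p) = -\tfrac12\iint f(x,z)p(x)p(z)\,dx\,dz$ for symmetric kernels;
`fisher_rao_apply()` / `fisher_rao_inverse()` implement the metric tensor
and `gradient_flow_residual()` verifies the identity on the grid to
$10^{-10}$ (asymmetric kernels are rejected rather than symmetrised,
since the derivative computation relies on symmetry). The Eulerian view
solves the 1-D continuity equation by cumulative quadrature
(`velocity_field_1d()`) — the unique decaying-flux solution — and
`transport_samples()` moves particles along it while the density is
advanced by the exact tilt in lockstep. Multidimensional transport is out
of scope.

## Synthetic data: what is emulated, and what is not

All inputs are synthetic and seeded; there is no external data. The
generators emulate exactly three ingredients: a linear (optionally biased)
diffusion signal via Euler-Maruyama (`simulate_signal()`); Ito observation
paths $dZ_t = h(x^*_t)dt + \Xi^{1/2}dB_t$ (`ito_observation()`); and the
windowed smooth driver $\xi_i = h(x^*_{t_i}) + \Xi^{1/2}
(B_{t_{i+1}}-B_{t_i})/\delta_d$ with **left-endpoint** signal sampling
(`observation_derivative()`). The alternative smoothing that interpolates
the whole observation path (and hence time-integrates $h$ over the window)
is deliberately not implemented: the fitness construction above is built
on the left-endpoint form. Both drivers can share one fine-resolution
Brownian source (`brownian_path()`), so refining $\delta_d$ under a fixed
seed changes only the windowing — the coupling needed for a meaningful
smooth-limit comparison. Default study conditions follow the experimental
setup: $\delta_d = 10^{-3}$, simulation step $10^{-4}$, $N_s = 5000$
observation realisations (500 in reduced mode).

Passing tests on these generators say nothing about real data with
time-varying bias, non-Gaussian noise, or observation gaps that are long
relative to signal correlation times (where the integrated-observation
variant would be the honest model).

## Numerical choices

- **Grid solvers.** Uniform grid (default 801 nodes), Dirichlet-zero
  boundaries on a domain sized to $\pm 10$ standard deviations around the
  locations in play; forward Euler with CFL guards
  $dt \le 0.25\,dx^2/\Sigma$ and $dt \le 0.5\,dx/\max|g|$; trapezoid
  quadrature throughout (consistent with `grid_moments()`). Advection is
  differenced **centrally** (second order): the moment-tracking accuracy
  required of the solver (relative $10^{-3}$ against the moment ODEs) is
  unattainable with first-order upwinding, whose numerical diffusion
  $\approx |g|dx/2$ pollutes the variance; the diffusive mutation term
  keeps the central scheme stable whenever the cell Peclet number
  $|g|dx/\Sigma$ stays below 2, which the auto-sized domains satisfy.
  `scheme = "upwind"` remains available for advection-dominated cases.
  Negative values are never clipped during stepping; a detector aborts if
  negative mass exceeds $10^{-3}$ of the total (snapshot constructors clip
  roundoff-scale negatives only). Unnormalised solvers renormalise every
  step and accumulate the log-mass, so values never overflow.
- **Stratonovich stepping** is realised through the equivalent Ito drift
  rather than midpoint stepping — simpler, and exactly comparable with the
  Ito modes on a shared noise realisation.
- **Root-finding** uses safeguarded bracketing (`uniroot` with bracket
  expansion) at tolerance $10^{-10}$; no derivative-based iterations,
  which misbehave near the double root at $s_l$.
- **Riccati steady states**: scalar closed form; matrix path integrates
  the covariance ODE (via `deSolve`) until
  $\|\dot C\|_F < 10^{-12}$ with a time guard.
- **Bias-variance bookkeeping**: `error_moments_solve()` integrates the
  bias and error-covariance ODEs by Euler and assembles
  $\tilde P_t = P_t + \mathbb E[\varepsilon_t]\mathbb E[\varepsilon_t]^\top$
  from its exact continuous-time identity, so the decomposition
  $E_t = \mathrm{Tr}(P_t) + \nu_t$ holds to machine precision at every
  step rather than drifting at $O(dt)$. The spectral upper-bound curve
  uses the squared-Frobenius convention $\|C\|_F = \mathrm{Tr}(C^\top C)$
  under which, in the scalar case, the bound is exactly tight — discrete
  curves may therefore cross by $O(dt)$, which the tests allow for.

## The asymptotic-MSE estimator and its standard error

`empirical_mse()` reproduces the Monte-Carlo design of the study: one
fixed reference realisation $x^*$ (with bias), $N_s$ independent smoothed
observation realisations, each driving the smooth-driver moment filter
started at $C_0 = C_\infty$ (so the gain is stationary), and
$E_t = N_s^{-1}\sum_j (m^j_t - x^*_t)^2$. The asymptotic value is read
off as the time average of $E_t$ over the final third of the horizon
(default $T = 3$; the slowest relevant mode $e^{2A_\infty t}$ is below
$10^{-4}$ well before the window opens). Window-level observation noise
is sampled directly as $N(0, \delta_d)/\delta_d$ derivatives —
distributionally identical to aggregating fine-step increments.

Conditioning on a single reference path has a consequence the design must
own: the conditional bias $\mathbb E[\varepsilon_t \mid x^*]$ is an
Ornstein-Uhlenbeck process (mean $-b/A_\infty$, variance
$\Sigma/2|A_\infty|$, correlation time $1/|A_\infty|$), so the tail
average of its square fluctuates around $\nu_\infty$ with variance
$2(\sigma^4 + 4\mu^2\sigma^2)/(|A_\infty|W)$ for a window of length $W$.
A bootstrap over observation paths alone cannot see this term and
understates the estimator's error about $E_\infty$ by an order of
magnitude in unfavourable regimes. The reported `se` therefore combines
the path bootstrap with this analytic term; both components are also
returned separately (`se_paths`, `se_ref`). A faster equivalent error
recursion (`method = "error_sde"`) is kept as a cross-check and must
reproduce the full pipeline exactly.

## Problem sizes

The bundled experiments are desk-scale by construction: closed-form
design quantities are instantaneous; the smooth-limit comparison runs
three solvers on an 801-node grid for 5000 steps at three window widths
(seconds); the ensemble contract is checked at $N = 20000$ particles over
2000 steps; the Monte-Carlo MSE uses $N_s = 500$ reduced-scale
realisations over 30000 steps, vectorised across realisations. The
exponential-tilt oracle is verified at $dt = 2\times10^{-6}$ over a short
horizon, where first-order convergence brings the discretisation error
below $10^{-6}$.

## Known limitations

- The optimal-design formulas (`a_star()` through `joint_optimum()`) are
  scalar-only, matching the scope of the underlying analysis;
  `a_infty()`, `nu_infty()`, `e_infty()` accept matrices via the Lyapunov
  path.
- The PDE solvers are 1-D, explicit, fixed-grid; no implicit or spectral
  schemes, no adaptive meshing.
- Time-invariant $G$, $H$, $\Xi$, and a constant bias $b$ only;
  non-Gaussian priors enter only through the grid solvers.
- The smooth-observation driver uses left-endpoint sampling; integrated
  observations over long windows are not modelled.
- Ensemble variants implement neither localisation nor square-root
  transforms.
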