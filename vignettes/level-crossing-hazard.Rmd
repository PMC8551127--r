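---
title: "Level-crossing hazard rates for integrate-and-fire neurons with colored noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Level-crossing hazard rates for integrate-and-fire neurons with colored noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lchazard)
```

## The model and the mapping

A leaky integrate-and-fire (LIF) neuron with colored input noise obeys

$$\tau_m \dot V = -V + \mu(t) + \eta(t), \qquad
  \tau_s \dot\eta = -\eta + \sqrt{2\tau_s}\,\sigma_\eta\,\xi(t),$$

with threshold $V_T$, reset $V_R$, absolute refractory period
$t_{\mathrm{ref}}$, and an Ornstein–Uhlenbeck (OU) noise $\eta$ with
correlation time $\tau_s$. Spikes are emitted at threshold crossings.
The package maps this *input-noise* model onto an *escape-noise* model:
a deterministic membrane potential $u(t)$ (the noiseless solution of
the membrane equation) plus a hazard rate
$\Psi(u, \dot u, z, t - \hat t)$ that generates spikes stochastically.
Escape-noise models are attractive because their interval densities,
likelihoods and population equations are one-dimensional and cheap;
the hazard rate derived here is what makes the map quantitative.

Subtracting $u(t)$ turns the first-passage problem into a
time-homogeneous Gaussian process $x(t)$ ($\dot x = -\gamma x + y$,
$\gamma = 1/\tau_m$, $y$ an OU process with correlation time
$\tau_y = \tau_s$) below a moving boundary $b(t) = V_T - u(t)$. All
hazard approximations are built from the level-crossing statistics of
$x$ against $b$:

* **First order (independent upcrossings).** The hazard equals the
  Rice upcrossing rate $f_1(t) = \Phi_1(b, \dot b, t)$, an explicit
  expression in the non-stationary moments $\sigma_x^2(t)$,
  $\sigma_{xy}(t)$ of the free process (`upcrossing_rate_f1()`,
  `xmoments()`). It treats crossings as a Poisson process and is
  accurate when crossings are rare (subthreshold, low rate).
* **Second order (pair-correlated upcrossings).** Crossings of a
  doubly low-pass-filtered process are *not* independent at short
  lags: the zero-lag pair correlation
  $R_0 = f_2(t,t)/f_1^2(t) - 1$ has the closed stationary form
  $\beta\,(1+u)/\sqrt{u}\;e^{b^2/2\sigma_x^2} - 1$ with
  $u = \gamma\tau_y$ and $\beta = (3\sqrt3-\pi)/9 \approx 0.228284$.
  It is negative (repulsion) for low boundaries at intermediate $u$
  and positive (clustering) for high boundaries; notably it never
  reaches $-1$, so upcrossings are not "non-approaching" points — the
  most negative achievable value is $2\beta - 1 \approx -0.543431$, at
  $u = 1$. Feeding the exponential correlation ansatz
  $R(t,t') \approx R_0(t) e^{-|t-t'|/\tau_{\mathrm{corr}}}$,
  $\tau_{\mathrm{corr}} = \tau_m + \tau_s$, into the non-local
  Stratonovich survival formula and localizing gives
  $$\lambda(t) = \frac{\Phi_1(b,\dot b,t)}{1 + \hat R_0(b,\dot b,t)\,z(t)},
    \qquad \dot z = -z/\tau_{\mathrm{corr}} + \Phi_1,\; z(0)=0,$$
  one extra scalar ODE (`hazard_second_order()`, `z_dynamics()`).
  Repulsion ($R_0 < 0$) *raises* the hazard relative to the Poisson
  picture, which is exactly what restores the first peak of
  suprathreshold interval densities.

Given any hazard, `solve_fpt()` integrates $S' = -\lambda S$ and
returns the first-passage density $P = \lambda S$; `conditional_isi()`
assembles the conditional interspike-interval problem (refractory
clamp, link functions `link_psi1()`/`link_psi2()`), and
`solve_population()` propagates the renewal integral equation
$A(t) = P(t|t_0) + \int_{t_0^+}^{t} P(t|\hat t) A(\hat t)\, d\hat t$
for the activity of infinitely many unconnected neurons.

## Parameters

| parameter | meaning | default / typical |
|---|---|---|
| `tau_m` (ms) | membrane time constant | 10 |
| `tau_s` (ms) | noise correlation time | 4 |
| `sigma_V` | stationary SD of the free membrane potential, in units of $V_T - V_R$; alternative to `sigma_eta` via $\sigma_V^2 = \sigma_\eta^2 \tau_s/(\tau_m+\tau_s)$ | 0.25 |
| `V_T`, `V_R` | threshold and reset | 1, 0 (voltages measured in units of $V_T - V_R$) |
| `t_ref` (ms) | absolute refractory period | 0 (4 in the population examples) |
| `dt` (ms) | solver grid step | `min(tau_m, tau_s)/100`, resolving the fastest time scale and the hazard transient after a spike |
| `dt_sim` (ms) | Monte-Carlo step | `min(tau_m, tau_s)/50` |

The ratio $u = \gamma\tau_y = \tau_s/\tau_m$ controls the crossing
statistics: $R_0$ at zero boundary is positive for all boundary
heights when $u < 0.0583757$ or $u > 17.1304$ (the roots of
$\beta(1+u)/\sqrt u = 1$, `r0_positivity_roots()`); between them the
sign flips at the critical barrier
$b_{\mathrm{crit}}/\sigma_x = \sqrt{2\ln(\sqrt u / \beta(1+u))}$
(`critical_barrier()`).

## Numerical choices

* **Exact exponential integrators everywhere.** The membrane
  potential, the auxiliary variable $z$ and the survival update
  $S_{n+1} = S_n e^{-\Delta t(\lambda_n + \lambda_{n+1})/2}$ use exact
  per-step updates for piecewise-linear inputs, so there is no global
  integration drift; conservation
  $\int P\,dt + S(t_{\max}) = 1$ holds to the quadrature level of the
  grid (about $10^{-6}$ at the default step; the residual mass at the
  end of the window is always reported and never renormalized away).
* **Stable tails.** $H(x) = 1 - \sqrt\pi x e^{x^2}\mathrm{erfc}(x)$
  is evaluated through the scaled complementary error function, with
  an asymptotic continued-product branch above $x = 25$ where the
  library `erfcx` overflows; the rate assembly uses the identity
  $B - h^2 = b^2/2\sigma_x^2$ so that negative-argument branches never
  form $\infty \cdot 0$ products. The pair-correlation ratio
  $f_2/f_1^2$ is formed in log space so $R_0$ stays finite where $f_1$
  underflows.
* **Degenerate time-scale ratio.** At $\gamma\tau_y = 1$ the
  closed-form variance is a $0/0$ expression; the implementation
  switches to an `expm1` representation when $|t(2\gamma -
  1/\tilde\tau)| < 10^{-3}$, reproducing the analytic limit
  continuously (validated against the moment ODEs integrated with
  `deSolve`).
* **Start-of-interval degeneracy.** At $t \to 0$ the free process has
  zero variance; when the moment determinant
  $\sigma_x^2\sigma_y^2 - \sigma_{xy}^2$ falls below
  $10^{-14}\,\sigma_y^2\sigma_x^2(\infty)$ the hazard is 0 for
  $b > 0$ (the process is strictly below the boundary) and an error
  for $b \le 0$.
* **Validity clamp.** The second-order hazard requires
  $q = R_0 z > -1$. If $1 + q < 0.05$ the denominator is clamped at
  0.05 and the result flagged (`validity_diagnostics()`,
  `flags` attribute): the condition is an applicability statement,
  and downstream solvers need finite hazards.
* **Exponential-ansatz variant.** The ansatz pins $R_0$ at the
  unprimed time; the variant pinned at the primed time is exposed
  through `R_exponential(pin = "tprime")` but not validated.
* **Renewal march.** One cohort per grid bin, trapezoidal quadrature
  over last-spike times with the synchronized initial condition as an
  explicit point mass; cohorts are dropped once their survival falls
  below $10^{-10}$ (their neurons must have respiked), bounding the
  cost by the active-history length. The survival-weighted neuron
  count is monitored (`mass_residual` attribute, conserved to
  $10^{-3}$ or better in all shipped examples).
* **Crossing detection.** Monte-Carlo crossings are grid sign changes
  with no sub-grid interpolation; the $O(\sqrt{\Delta t_{\mathrm{sim}}})$
  detection bias is kept below the histogram bin width by the default
  step (halving the step moves the FPT survival by less than the
  Monte-Carlo error at $2\times10^4$ trials, asserted in the tests).
* **Two-time pair-rate oracle.** `f2_numeric()` builds the exact
  joint Gaussian of $(x, \dot x)$ at two times from the state
  transition of the linear system and integrates the generalized Rice
  integrand by two-dimensional Gauss–Legendre quadrature over the
  velocity quadrant, truncated at eight conditional standard
  deviations. It is an oracle (cost grows with the square of the
  grid for the non-local survival), not a production path. A direct
  analytic one-integral reduction of $f_2$ exists in the literature;
  the quadrature route was chosen because it is transparent and its
  error is controlled by the node count alone. The zero-lag limit is
  approached linearly in the lag, so tests Richardson-extrapolate two
  small lags.

## Synthetic data: what the generators emulate

The package is validated entirely against its own simulators — there
are no external datasets.

* `simulate_xy()` / `simulate_lif()` step the joint linear systems
  with the *exact* Gaussian transition (state-transition matrix plus
  step-noise Cholesky factor), so the ground truth carries no
  Euler-scheme drift. In `simulate_lif()` the colored noise is *not*
  reset at spikes — only the voltage is — which reproduces the real
  non-renewal microscopic dynamics that the renewal-based theory
  approximates.
* `gen_periodic_boundary()` produces $b(t) = 1 + \alpha\cos(2\pi f t)$:
  $\alpha = 0.25$ is the subthreshold regime (boundary stays
  positive), $\alpha = 1.2$ the suprathreshold regime (boundary dips
  below zero), both at $f = 0.5$, $\sigma_x(\infty) = 0.5$,
  $\tau_x = 1$, $\tau_y = 0.2$ in the validation suite.
* `gen_ou_stimulus()` draws stationary OU stimuli with mean
  $\bar\mu$, SD $\sqrt{1 + \tau_m/\tau_\mu}\,\bar\sigma$ and
  correlation time $\tau_\mu$, chosen so the free membrane potential
  responds with mean $\bar\mu$ and SD $\bar\sigma$.
* `gen_bandlimited_stimulus()` superposes equal-amplitude cosines with
  independent uniform phases up to a cut-off (0.1 cycles/ms = 100 Hz
  in the examples) — a frozen broadband stimulus. Any flat-spectrum
  construction would do; the theory consumes $\mu(t)$ as given.

What passing these tests shows — and does not show. The simulators
share the model's Gaussian/OU assumptions, so agreement demonstrates
the correctness of the level-crossing approximations *within* the
model class: it says nothing about non-Gaussian (shot) noise,
conductance dynamics, or adaptation, which are out of scope. One
genuine model mismatch *is* exercised: the simulated neuron is
non-renewal (noise survives the spike), while the theory assumes
stationary noise at each spike, so the ISI and population comparisons
quantify the renewal approximation itself, not merely numerics.

## Study conditions and problem sizes in the validation suite

The shipped tests solve: the periodic-boundary problems above with
$10^5$ Monte-Carlo trials (second-order KS distance below 0.02
subthreshold; suprathreshold the second order must beat the first);
a population run at $\tau_m = 10$ ms, $\tau_s = 4$ ms,
$t_{\mathrm{ref}} = 4$ ms, $\sigma_V = 0.25$, initialized at
$t_0 = -25$ ms, against $10^5$ simulated neurons, with the broadband
stimulus baselines $\mu_0 = 0.85$, SD $0.4$ chosen so the mean
potential crosses threshold episodically; and a
$5\times5$ $(\bar\mu, \bar\sigma)$ Kolmogorov–Smirnov sweep
($\bar\mu \in [0.6, 1.4]$, $\bar\sigma \in [0.1, 0.5]$,
$\tau_\mu = 10$ ms, 20 stimulus realizations, $10^4$ trials each,
100 ms windows) plus reduced $3\times3$ sweeps at
$\tau_\mu = 1$ and $100$ ms for the speed ordering. These sizes keep
the whole suite at desk scale while leaving the Monte-Carlo standard
errors well below the effects being asserted.

## Design decisions on genuinely open points

* **Post-spike noise distribution.** The true noise distribution at a
  spike is biased toward positive values; the theory (and the ISI
  simulators) use the stationary distribution, justified when
  $\tau_s$ is well below the mean ISI. No correction is attempted.
* **Conditional membrane dynamics.** Between spikes the conditional
  mean potential obeys the noiseless membrane equation
  $\dot u = (-u + \mu)/\tau_m$ relaxing from $V_R$ at the end of the
  refractory period, with the boundary derivative taken analytically
  as $\dot b = (u - \mu)/\tau_m$, never by finite differences.
* **Moment clock.** The moments entering $\Phi$ restart at each
  spike, evaluated at $t - \hat t - t_{\mathrm{ref}}$: the stochastic
  part of the interval begins after the refractory clamp.
* **$\tau_{\mathrm{corr}}$ is fixed at $\tau_m + \tau_s$** (the
  integral of the normalized stationary autocorrelation of $x$), not
  fitted.

## Known limitations

* The white-noise limit $\tau_s \to 0$ is outside the theory: the
  upcrossing rate diverges. Use $\tau_s$ of at least a few percent of
  $\tau_m$.
* The theory is renewal: serial interval correlations induced by the
  noise surviving the spike are not captured (they are small when
  $\tau_s$ is much shorter than the mean ISI, which is also when the
  stationary-reset assumption is good).
* The second-order hazard inherits two ad hoc localization steps
  (pulling the correction factor out of the Stratonovich integral and
  the exponential correlation ansatz). No sharp error bound exists;
  the non-local `stratonovich_survival()` oracle is shipped so the
  localization error can be measured directly, and the tests assert
  only the ordering (second order closer than first) plus a logged
  0.02 agreement level on the constant-boundary validation case.
* In the strongly mean-driven regime (tonic firing, $\bar\mu > 1$)
  both decoupling approximations degrade; a constant suprathreshold
  drive is harder for the second order than a fluctuating one. The
  sweep in the test suite documents this regime honestly rather than
  excluding it.
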