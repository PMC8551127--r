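#' Non-stationary second moments of the free process
#'
#' Closed-form time-dependent variance `sigma_x^2(t)` and covariance
#' `sigma_xy(t)` of the freely evolving boundary-view process
#' `xdot = -gamma x + y` started at `x(0) = 0` with stationary OU noise
#' `y(0) ~ N(0, sigma_y^2)`:
#' \deqn{\sigma_{xy}(t) = \tilde\tau\,\sigma_y^2 (1 - e^{-t/\tilde\tau}),}
#' \deqn{\sigma_x^2(t) = \frac{\tilde\tau\sigma_y^2}{\gamma}(1-e^{-2\gamma t})
#'   + \frac{2\tilde\tau\sigma_y^2}{2\gamma - 1/\tilde\tau}
#'     \left(e^{-2\gamma t} - e^{-t/\tilde\tau}\right).}
#' The second term is a 0/0 form when `gamma * tau_y = 1`
#' (`2 gamma = 1/tilde_tau`); it is evaluated through `expm1` so the
#' analytic limit `-t e^{-2 gamma t}` is reached continuously.
#'
#' @param params a [lif_params].
#' @param t time(s) since the start of the free motion, >= 0 (ms).
#'   `Inf` is allowed and returns the stationary values.
#' @return data.frame with columns `t`, `sigma_x2`, `sigma_xy`.
#' @seealso [xmoments_ode()] for the equivalent ODE integration.
#' @export
xmoments <- function(params, t) {
  stopifnot(inherits(params, "lif_params"), all(t >= 0))
  g  <- params$gamma
  tt <- params$tilde_tau
  sy2 <- params$sigma_y2
  sxy <- tt * sy2 * ifelse(is.infinite(t), 1, -expm1(-t / tt))
  d <- 2 * g - 1 / tt                     # vanishes when gamma*tau_y = 1
  e2g <- ifelse(is.infinite(t), 0, exp(-2 * g * t))
  ## C = (e^{-2 g t} - e^{-t/tt}) / d; the difference is a 0/0 form as
  ## d -> 0, so switch to the expm1 representation when |t d| is small
  ## (cancellation) and to the direct difference otherwise (no overflow).
  td <- t * d
  C_small <- if (d == 0) -t * e2g else -e2g * expm1(td) / d
  C_big <- (e2g - exp(-t / tt)) / (if (d == 0) 1 else d)
  C <- ifelse(is.infinite(t), 0, ifelse(abs(td) < 1e-3, C_small, C_big))
  sx2 <- (tt * sy2 / g) * ifelse(is.infinite(t), 1, -expm1(-2 * g * t)) +
    2 * tt * sy2 * C
  data.frame(t = t, sigma_x2 = pmax(sx2, 0), sigma_xy = sxy)
}

#' Second moments via their ordinary differential equations
#'
#' Integrates the standard second-moment equations of the linear system,
#' \deqn{d\sigma_x^2/dt = 2\sigma_{xy} - 2\gamma\sigma_x^2, \qquad
#'       d\sigma_{xy}/dt = \sigma_y^2 - (\gamma + 1/\tau_y)\sigma_{xy},}
#' from zero initial conditions (the noise variance stays at its
#' stationary value). Serves as the numerically robust cross-check of
#' the closed forms in [xmoments()], including the degenerate case
#' `gamma * tau_y = 1`.
#'
#' @param params a [lif_params].
#' @param grid time grid (ms), starting at 0.
#' @return data.frame with columns `t`, `sigma_x2`, `sigma_xy`.
#' @export
xmoments_ode <- function(params, grid) {
  stopifnot(grid[1] == 0)
  g <- params$gamma; a <- 1 / params$tau_y; sy2 <- params$sigma_y2
  rhs <- function(t, y, parms) {
    list(c(2 * y[2] - 2 * g * y[1],
           sy2 - (g + a) * y[2]))
  }
  sol <- deSolve::lsoda(c(sx2 = 0, sxy = 0), grid, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  data.frame(t = sol[, 1], sigma_x2 = sol[, 2], sigma_xy = sol[, 3])
}

#' Normalized stationary autocorrelation of the free process
#'
#' For the doubly low-pass-filtered noise `x(t)` in the stationary state,
#' the normalized autocorrelation is a mixture of the two filter decays,
#' \deqn{C_{xx}(\tau)/C_{xx}(0) =
#'   \frac{\alpha e^{-\gamma\tau} - \gamma e^{-\alpha\tau}}{\alpha-\gamma},
#'   \qquad \alpha = 1/\tau_y,}
#' with the analytic limit `(1 + gamma*tau) e^{-gamma*tau}` when
#' `gamma*tau_y = 1`. Its integral over `[0, Inf)` equals
#' `tau_m + tau_s`, the correlation time used by the exponential ansatz
#' for upcrossing correlations.
#'
#' @param params a [lif_params].
#' @param tau lag(s), >= 0 (ms).
#' @return numeric vector `C_xx(tau)/C_xx(0)`.
#' @export
stationary_autocorr <- function(params, tau) {
  stopifnot(all(tau >= 0))
  g <- params$gamma; a <- 1 / params$tau_y
  if (abs(a - g) < 1e-10 * (a + g)) {
    (1 + g * tau) * exp(-g * tau)
  } else {
    (a * exp(-g * tau) - g * exp(-a * tau)) / (a - g)
  }
}
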