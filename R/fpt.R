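## First-passage-time / interspike-interval densities from a hazard
## rate, and the link functions Psi_1 / Psi_2 of the escape-noise model.

#' Survival and first-passage density from a hazard series
#'
#' Integrates `dS/dt = -lambda(t) S`, `S(start) = 1`, with the exact
#' per-step exponential update and trapezoidal hazard accumulation
#' `S_{n+1} = S_n exp(-dt (lambda_n + lambda_{n+1})/2)`; the density is
#' `P = lambda S`.
#'
#' @param hazard_series nonnegative hazard on a uniform grid (1/ms).
#' @param grid uniform time grid (ms).
#' @param flags optional validity flags to carry through (attribute).
#' @return object of class `hazard_curves`: data.frame with columns
#'   `time`, `lam`, `S`, `P`; attribute `residual_mass` = `S(t_max)`,
#'   the probability mass beyond the solved window (reported, never
#'   renormalized away).
#' @examples
#' tg <- seq(0, 50, 0.01)
#' hc <- solve_fpt(rep(0.2, length(tg)), tg)
#' max(abs(hc$P - 0.2 * exp(-0.2 * tg)))  # constant hazard: exponential
#' @export
solve_fpt <- function(hazard_series, grid, flags = NULL) {
  check_uniform_grid(grid)
  if (any(hazard_series < 0) || any(!is.finite(hazard_series)))
    stop("hazard must be finite and nonnegative")
  dt <- grid[2] - grid[1]
  n <- length(grid)
  stopifnot(length(hazard_series) == n)
  cumhaz <- c(0, cumsum(dt * (hazard_series[-n] + hazard_series[-1L]) / 2))
  S <- exp(-cumhaz)
  out <- data.frame(time = grid, lam = hazard_series, S = S,
                    P = hazard_series * S)
  attr(out, "residual_mass") <- S[n]
  attr(out, "flags") <- flags
  class(out) <- c("hazard_curves", "data.frame")
  out
}

#' @export
print.hazard_curves <- function(x, ...) {
  cat(sprintf("hazard curves on [%g, %g] (%d points), residual mass %.3g\n",
              x$time[1], x$time[nrow(x)], nrow(x),
              attr(x, "residual_mass")))
  fl <- attr(x, "flags")
  if (!is.null(fl) && isTRUE(fl$any_clamped))
    cat("  note: second-order denominator clamped somewhere (q near -1)\n")
  invisible(x)
}

#' First-passage problem for an explicit moving boundary
#'
#' Solves the moving-boundary first-passage problem for the free
#' process started at `x(0) = 0` (zero variance) below `b(0) > 0`:
#' hazard from the first- or second-order decoupling approximation,
#' survival and density from [solve_fpt()].
#'
#' @param params a [lif_params].
#' @param boundary a [boundary_path] (its grid is the solver grid).
#' @param order 1 (independent upcrossings) or 2 (pair-correlated).
#' @return a `hazard_curves` object; for `order = 2` the columns `z`
#'   and `q` are included and the flags attribute reports clamping.
#' @export
boundary_fpt <- function(params, boundary, order = 2) {
  stopifnot(inherits(boundary, "boundary_path"), order %in% c(1, 2))
  if (boundary$b[1] <= 0)
    stop("b(0) must be > 0: the process starts strictly below the boundary")
  tg <- boundary$time - boundary$time[1]
  m <- moments_at(params, tg)
  core <- crossing_core(boundary$b, boundary$bdot, m$sx2, m$sxy, params)
  f1 <- core$f1
  if (order == 1) return(solve_fpt(f1, boundary$time))
  z <- z_dynamics(f1, boundary$time, params)
  res <- phi2_core(core, z)
  out <- solve_fpt(res$lambda, boundary$time,
                   flags = list(any_clamped = any(res$clamped),
                                min_q = suppressWarnings(
                                  min(res$q[is.finite(res$q)]))))
  out$z <- z
  out$q <- res$q
  out
}

#' First-order link function of the escape-noise model
#'
#' `Psi_1(u, udot, tau) = theta(tau - t_ref) Phi_1(V_T - u, -udot, tau - t_ref)`:
#' zero during the absolute refractory period, afterwards the upcrossing
#' rate with the boundary expressed through the mean membrane potential
#' and the moment clock restarted at the end of the refractory period.
#'
#' @param u,udot mean membrane potential and its time derivative.
#' @param tau_since_spike time since the last spike (ms), >= 0.
#' @param params a [lif_params].
#' @return rate (1/ms).
#' @export
link_psi1 <- function(u, udot, tau_since_spike, params) {
  s <- tau_since_spike - params$t_ref
  out <- numeric(max(length(u), length(s)))
  act <- rep_len(s, length(out)) >= 0
  if (any(act)) {
    su <- rep_len(s, length(out))[act]
    out[act] <- upcrossing_rate_f1(rep_len(params$V_T - u, length(out))[act],
                                   rep_len(-udot, length(out))[act],
                                   su, params)
  }
  out
}

#' Second-order link function of the escape-noise model
#'
#' `Psi_2(u, udot, z, tau) = theta(tau - t_ref) Phi_2(V_T - u, -udot, z, tau - t_ref)`,
#' where `z` follows `dz/dt = -z/(tau_m + tau_s) + Psi_1` from `z = 0`
#' at the last spike. Reduces to [link_psi1()] when `z = 0`.
#'
#' @inheritParams link_psi1
#' @param z auxiliary correlation variable.
#' @return rate (1/ms) with attributes as in [hazard_second_order()].
#' @export
link_psi2 <- function(u, udot, z, tau_since_spike, params) {
  s <- tau_since_spike - params$t_ref
  n <- max(length(u), length(s), length(z))
  out <- numeric(n); qout <- numeric(n); cl <- logical(n)
  act <- rep_len(s, n) >= 0
  if (any(act)) {
    lam <- hazard_second_order(rep_len(params$V_T - u, n)[act],
                               rep_len(-udot, n)[act],
                               rep_len(z, n)[act],
                               rep_len(s, n)[act], params)
    out[act] <- lam
    qout[act] <- attr(lam, "q")
    cl[act] <- attr(lam, "clamped")
  }
  attr(out, "q") <- qout
  attr(out, "clamped") <- cl
  out
}

#' Conditional interspike-interval problem
#'
#' Given a stimulus and a last spike time `t_hat`, integrates the mean
#' membrane potential `u(t|t_hat)` from the reset (clamped during the
#' absolute refractory period), evaluates the link function of the
#' requested order, and returns the conditional hazard, survival and
#' ISI density on `[t_hat, t_hat + t_max]`.
#'
#' @param params a [lif_params].
#' @param stimulus a [stimulus_path] covering `[t_hat, t_hat + t_max]`.
#' @param t_hat last spike time (must lie on the stimulus grid).
#' @param order 1 or 2.
#' @param t_max window length (ms); default 50 tau_m.
#' @return a `hazard_curves` object with extra columns `u` (and `z`,
#'   `q` for order 2); time is absolute.
#' @export
conditional_isi <- function(params, stimulus, t_hat = 0, order = 2,
                            t_max = 50 * params$tau_m) {
  stopifnot(inherits(stimulus, "stimulus_path"), order %in% c(1, 2))
  dt <- attr(stimulus, "dt")
  i0 <- which(abs(stimulus$time - t_hat) < dt / 2)
  if (length(i0) != 1L) stop("t_hat must lie on the stimulus grid")
  n_ref <- round(params$t_ref / dt)
  if (abs(n_ref * dt - params$t_ref) > 1e-8 * max(dt, params$t_ref))
    stop("t_ref must be a multiple of the stimulus grid step")
  n_win <- round(t_max / dt)
  if (i0 + n_win > nrow(stimulus))
    stop("stimulus too short: must cover [t_hat, t_hat + t_max]")

  idx <- i0:(i0 + n_win)
  tg <- stimulus$time[idx]
  mu <- stimulus$mu[idx]
  tau <- tg - t_hat

  ## u clamped at V_R through the refractory period, then relaxes
  u <- rep(params$V_R, n_win + 1L)
  if (n_ref < n_win) {
    rel <- (n_ref + 1L):(n_win + 1L)
    u[rel] <- expint_relax(params$V_R, mu[rel], dt, params$tau_m)
  }
  udot <- (mu - u) / params$tau_m
  udot[tau < params$t_ref] <- 0

  s <- tau - params$t_ref
  act <- s > 0
  b <- params$V_T - u
  bdot <- -udot
  f1 <- numeric(n_win + 1L)
  core <- NULL
  if (any(act)) {
    m <- moments_at(params, s[act])
    core <- crossing_core(b[act], bdot[act], m$sx2, m$sxy, params)
    f1[act] <- core$f1
  }
  if (order == 1) {
    out <- solve_fpt(f1, tg)
    out$u <- u
    return(out)
  }
  z <- z_dynamics(f1, tg, params)
  lam <- f1; q <- numeric(n_win + 1L); cl <- logical(n_win + 1L)
  if (any(act)) {
    res <- phi2_core(core, z[act])
    lam[act] <- res$lambda
    q[act] <- res$q
    cl[act] <- res$clamped
  }
  out <- solve_fpt(lam, tg,
                   flags = list(any_clamped = any(cl),
                                min_q = suppressWarnings(
                                  min(q[is.finite(q)], na.rm = TRUE))))
  out$u <- u
  out$z <- z
  out$q <- q
  out
}
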