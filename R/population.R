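## Deterministic population activity of infinitely many unconnected
## escape-noise neurons via the renewal integral equation
## A(t) = P(t|t0) + int_{t0+}^{t} P(t|that) A(that) dthat,
## marched forward with one cohort per grid bin. Each cohort carries
## (u, z, S) updated by one-step exponential integrators; the
## synchronized initial condition at t0 is an explicit point mass.

#' Population activity by the renewal integral equation
#'
#' Marches the renewal equation forward on the stimulus grid. The
#' population is initialized with a synchronized spike of every neuron
#' at `t0`; that cohort enters as the explicit `P(t|t0)` term. For every
#' later grid time a cohort of last-spikers is created, whose
#' conditional survival, membrane potential and (order 2) correlation
#' variable are advanced jointly; the integral over last-spike times is
#' a trapezoidal quadrature. Cohorts whose survival has decayed below
#' `s_floor` are dropped (their neurons have respiked, and their
#' conditional density can no longer contribute).
#'
#' @param params a [lif_params].
#' @param stimulus a [stimulus_path] covering `[t0, t_max]`.
#' @param order 1 or 2 (decoupling order of the hazard link).
#' @param t0 initialization time (synchronized spike).
#' @param t_max end of the solve window.
#' @param hazard optional override: a function `lambda(t, tau)` of
#'   absolute time and age giving the hazard directly (bypasses the
#'   LIF link; used for analytic renewal checks).
#' @param s_floor survival threshold for dropping exhausted cohorts.
#' @return object of class `population_result`: data.frame with columns
#'   `time`, `A` (1/ms) and `A_Hz`; attributes `mass_residual` (max
#'   deviation of the survival-weighted neuron count from 1 on sampled
#'   times) and `order`.
#' @export
solve_population <- function(params, stimulus, order = 2, t0, t_max,
                             hazard = NULL, s_floor = 1e-10) {
  stopifnot(inherits(stimulus, "stimulus_path"))
  dt <- attr(stimulus, "dt")
  i0 <- which(abs(stimulus$time - t0) < dt / 2)
  if (length(i0) != 1L) stop("t0 must lie on the stimulus grid")
  n <- round((t_max - t0) / dt)
  if (i0 + n > nrow(stimulus)) stop("stimulus too short for [t0, t_max]")
  idx <- i0:(i0 + n)
  tg <- stimulus$time[idx]
  mu <- stimulus$mu[idx]

  n_ref <- round(params$t_ref / dt)
  if (abs(n_ref * dt - params$t_ref) > 1e-8 * max(dt, params$t_ref))
    stop("t_ref must be a multiple of the stimulus grid step")

  ## per-cohort state, cohort k born at tg[k] (k = 1 is the t0 cohort)
  N <- n + 1L
  u <- rep(params$V_R, N); z <- numeric(N)
  S <- rep(1, N); lam_prev <- numeric(N); lam1_prev <- numeric(N)
  P <- numeric(N)
  A <- numeric(N)
  ## finite part of A at t0+ (the delta of the synchronized spike is
  ## carried separately): zero for the LIF link (refractoriness / zero
  ## start variance), lambda(t0, 0) for a custom hazard
  A[1L] <- if (is.null(hazard)) 0 else hazard(tg[1L], 0)
  lam_prev[1L] <- A[1L]                 # hazard of the t0 cohort at age 0
  alive_lo <- 1L

  Em <- exp(-dt / params$tau_m)
  use_link <- is.null(hazard)

  mass_dev <- 0
  for (step in seq_len(n)) {
    tnew <- tg[step + 1L]
    ks <- alive_lo:step                 # cohorts born before tnew
    age <- tnew - tg[ks]
    released <- age > params$t_ref + 1e-12

    if (use_link) {
      ## membrane potential: clamped during refractory, exact relax after
      rel <- ks[released]
      if (length(rel)) {
        mul <- mu[step]; mur <- mu[step + 1L]
        ## cohorts released exactly this step start from V_R at t - t_ref;
        ## sub-step handling is unnecessary because t_ref is a grid multiple
        cn <- mul * (1 - Em) + (mur - mul) * (1 - params$tau_m * (1 - Em) / dt)
        u[rel] <- Em * u[rel] + cn
      }
      s_clock <- age - params$t_ref
      lam_new <- numeric(length(ks))
      lam1_new <- numeric(length(ks))
      if (any(released)) {
        ua <- u[rel]
        udot <- (mu[step + 1L] - ua) / params$tau_m
        m <- moments_at(params, s_clock[released])
        core <- crossing_core(params$V_T - ua, -udot, m$sx2, m$sxy, params)
        lam1_new[released] <- core$f1
        if (order == 1) {
          lam_new[released] <- core$f1
        } else {
          ## z update driven by Psi_1 (exact exponential step, trapezoid)
          Ez <- exp(-dt / params$tau_corr)
          tc <- params$tau_corr
          gl <- lam1_prev[ks][released] * tc
          gr <- core$f1 * tc
          z[rel] <- Ez * z[rel] + gl * (1 - Ez) +
            (gr - gl) * (1 - tc * (1 - Ez) / dt)
          res <- phi2_core(core, z[rel])
          lam_new[released] <- res$lambda
        }
      }
    } else {
      lam_new <- hazard(tnew, age)
      lam1_new <- lam_new
    }

    S[ks] <- S[ks] * exp(-dt * (lam_prev[ks] + lam_new) / 2)
    P[ks] <- lam_new * S[ks]
    lam_prev[ks] <- lam_new
    lam1_prev[ks] <- lam1_new

    ## renewal quadrature over last-spike times: trapezoid on nodes
    ## t0..t with A(t0+) = 0 at the lower end and P(t|t) = 0 at the
    ## upper end, so only interior cohorts 2..step carry weight dt;
    ## the synchronized t0 cohort enters as the explicit point mass.
    ## trapezoid over last-spike times t0..t: node 1 carries the finite
    ## part A(t0+) at half weight, interior cohorts full weight, and the
    ## cohort born now enters implicitly via P(t|t) = lambda(t, 0)
    contrib <- if (alive_lo == 1L) dt / 2 * P[1L] * A[1L] else 0
    if (step >= 2L) {
      kk <- 2L:step
      Pk <- numeric(length(kk))
      sel <- kk >= alive_lo
      Pk[sel] <- P[kk[sel]]
      contrib <- contrib + dt * sum(Pk * A[kk])
    }
    lam_self <- if (use_link) 0 else hazard(tnew, 0)
    A[step + 1L] <- ((if (alive_lo == 1L) P[1L] else 0) + contrib) /
      (1 - dt / 2 * lam_self)
    lam_prev[step + 1L] <- lam_self     # age-0 hazard of the new cohort

    ## drop exhausted cohorts
    while (alive_lo <= step && S[alive_lo] < s_floor) alive_lo <- alive_lo + 1L

    if (step %% 50L == 0L || step == n) {
      ka <- alive_lo:(step + 1L)
      ka2 <- ka[ka >= 2L]
      mass <- (if (alive_lo == 1L) S[1L] else 0) +
        sum(dt * S[ka2] * A[ka2]) - dt / 2 * S[step + 1L] * A[step + 1L]
      mass_dev <- max(mass_dev, abs(mass - 1))
    }
  }

  out <- data.frame(time = tg, A = A, A_Hz = 1000 * A)
  attr(out, "mass_residual") <- mass_dev
  attr(out, "order") <- order
  class(out) <- c("population_result", "data.frame")
  out
}

#' @export
print.population_result <- function(x, ...) {
  cat(sprintf(
    "population activity on [%g, %g] (%d points), order %d\n",
    x$time[1], x$time[nrow(x)], nrow(x), attr(x, "order")))
  cat(sprintf("  max |survival-weighted mass - 1| on sampled times: %.3g\n",
              attr(x, "mass_residual")))
  invisible(x)
}
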