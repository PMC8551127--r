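## Level-crossing statistics of the free Gaussian process against a
## moving boundary: Rice upcrossing rate f1, zero-lag pair rate f2(t,t),
## zero-lag pair correlation R0, critical barrier, and a brute-force
## two-time pair-rate oracle.

## saddle-point constant of the zero-lag pair rate and its reduced form
.beta_const <- (3 * sqrt(3) - pi) / 9          # ~ 0.228284
.c2_const   <- (3 * sqrt(3) - pi) / (36 * pi^2) # ~ 0.0057838

#' Saddle-point constant of the zero-lag pair correlation
#'
#' `beta = (3*sqrt(3) - pi)/9`, the numerical constant in the stationary
#' zero-lag pair correlation `R0 = beta (1+u)/sqrt(u) exp(b^2/(2 sigma_x^2)) - 1`
#' with `u = gamma * tau_y`.
#' @return the constant (about 0.228284).
#' @export
beta_pair_constant <- function() .beta_const

## scaled complementary error function for x >= 0, with an asymptotic
## branch where exp(x^2) would overflow inside the library routine:
## erfcx(x) = (1/(x sqrt(pi))) * sum_n (-1)^n (2n-1)!!/(2x^2)^n
## (6 terms give ~1e-15 relative accuracy for x >= 25)
erfcx_safe <- function(x) {
  out <- numeric(length(x))
  small <- x < 25
  if (any(small)) out[small] <- pracma::erfcx(x[small])
  if (any(!small)) {
    xl <- x[!small]
    i2x2 <- 1 / (2 * xl^2)
    s <- 1 - i2x2 * (1 - 3 * i2x2 * (1 - 5 * i2x2 *
           (1 - 7 * i2x2 * (1 - 9 * i2x2))))
    out[!small] <- s / (xl * sqrt(pi))
  }
  out
}

#' Rice-rate auxiliary function H
#'
#' `H(x) = 1 - sqrt(pi) x exp(x^2) erfc(x)`, evaluated through the
#' scaled complementary error function so that neither tail overflows.
#' `H` is positive, decreasing, `H(0) = 1`, and `H(x) ~ 1/(2 x^2)` for
#' large `x`.
#'
#' @param x numeric vector.
#' @return `H(x)`.
#' @export
Hfun <- function(x) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (any(pos))
    out[pos] <- 1 - sqrt(pi) * x[pos] * erfcx_safe(x[pos])
  if (any(!pos)) {
    xm <- x[!pos]
    ## erfc(x) = 2 - erfc(-x);  e^{x^2} erfc(-x) = erfcx(-x)
    out[!pos] <- 1 - 2 * sqrt(pi) * xm * exp(xm^2) +
      sqrt(pi) * xm * erfcx_safe(-xm)
  }
  out
}

## vectorized core: f1, f2(t,t) and exponent B from raw moment values.
## Returns the pieces needed by all public wrappers, computed in a form
## stable for large |h| and large B (the identity B - h^2 = b^2/(2 sx2)
## holds for any valid moments).
crossing_core <- function(b, bdot, sx2, sxy, params, det_floor = NULL) {
  sy2 <- params$sigma_y2
  g <- params$gamma
  if (is.null(det_floor)) det_floor <- 1e-14 * sy2 * params$sigma_x2_inf
  Delta <- sx2 * sy2 - sxy^2
  ok <- Delta > det_floor & sx2 > 0
  n <- max(length(b), length(bdot), length(sx2))
  b <- rep_len(b, n); bdot <- rep_len(bdot, n)
  sx2 <- rep_len(sx2, n); sxy <- rep_len(sxy, n); Delta <- rep_len(Delta, n)
  ok <- rep_len(ok, n)

  f1 <- numeric(n); f2 <- numeric(n); B <- rep(NA_real_, n)
  logf1 <- rep(-Inf, n); logf2 <- rep(-Inf, n)
  if (any(!ok & b <= 0))
    stop("degenerate moments (t -> 0) with boundary b <= 0: hazard undefined")
  if (any(ok)) {
    i <- ok
    Qc <- g * sx2[i] - sxy[i]
    Pc <- g^2 * sx2[i] - 2 * g * sxy[i] + sy2
    D  <- Delta[i]
    Bi <- (Pc * b[i]^2 + 2 * Qc * b[i] * bdot[i] + sx2[i] * bdot[i]^2) /
      (2 * D)
    h  <- (Qc * b[i] + sx2[i] * bdot[i]) / (sqrt(2 * D) * sqrt(sx2[i]))
    pref <- sqrt(D) / (2 * pi * sx2[i])
    ## H(h) e^{-B} assembled stably; e^{h^2 - B} = e^{-b^2/(2 sx2)}
    HeB <- numeric(sum(i))
    hp <- h >= 0
    if (any(hp))
      HeB[hp] <- exp(-Bi[hp]) *
        (1 - sqrt(pi) * h[hp] * erfcx_safe(h[hp]))
    if (any(!hp)) {
      hm <- h[!hp]
      HeB[!hp] <- exp(-Bi[!hp]) * (1 + sqrt(pi) * hm * erfcx_safe(-hm)) -
        2 * sqrt(pi) * hm * exp(-b[i][!hp]^2 / (2 * sx2[i][!hp]))
    }
    f1[i] <- pref * HeB
    f2[i] <- .c2_const * (sy2 / params$tau_y) / sqrt(D) * exp(-Bi)
    B[i] <- Bi
    ## log forms for the pair-correlation ratio (avoid underflow of f1^2)
    logf1[i] <- log(pref) + log(pmax(HeB, 0)) ## HeB > 0 analytically
    logf2[i] <- log(.c2_const * (sy2 / params$tau_y) / sqrt(D)) - Bi
  }
  list(f1 = f1, f2 = f2, B = B, ok = ok, logf1 = logf1, logf2 = logf2)
}

moments_at <- function(params, t) {
  m <- xmoments(params, t)
  list(sx2 = m$sigma_x2, sxy = m$sigma_xy)
}

#' Exponent of the Gaussian level-crossing rate
#'
#' The quadratic form `B(b, bdot, t)` appearing in `f1` and `f2`:
#' \deqn{B = \frac{(\gamma^2\sigma_x^2 - 2\gamma\sigma_{xy} + \sigma_y^2) b^2
#'   + 2(\gamma\sigma_x^2 - \sigma_{xy}) b\dot b + \sigma_x^2 \dot b^2}
#'   {2(\sigma_x^2\sigma_y^2 - \sigma_{xy}^2)}.}
#' With stationary moments and `bdot = 0` it reduces to
#' `b^2 / (2 sigma_x^2)`.
#'
#' @param b,bdot boundary value and derivative.
#' @param t time since start of the free motion (> 0), or `Inf` for the
#'   stationary state.
#' @param params a [lif_params].
#' @return numeric vector `B`.
#' @export
exponent_B <- function(b, bdot, t, params) {
  m <- moments_at(params, t)
  res <- crossing_core(b, bdot, m$sx2, m$sxy, params)
  if (any(!res$ok))
    stop("moment determinant below tolerance (degenerate t -> 0 regime)")
  res$B
}

#' Upcrossing rate of the free process against a moving boundary
#'
#' The Rice rate `f1(t) = Phi_1(b(t), bdot(t), t)` of upcrossings of the
#' boundary by the freely evolving Gaussian process, which is also the
#' first-order decoupling approximation of the hazard rate.
#' At `t = 0` with `b(0) > 0` the process has zero variance strictly
#' below the boundary and the rate is 0.
#'
#' @inheritParams exponent_B
#' @return rate (1/ms), vectorized over the longest argument.
#' @examples
#' p <- lif_params(10, 4, sigma_V = 0.25)
#' upcrossing_rate_f1(0, 0, Inf, p) * 2 * pi * sqrt(10 * 4)  # = 1
#' @export
upcrossing_rate_f1 <- function(b, bdot, t, params) {
  m <- moments_at(params, t)
  crossing_core(b, bdot, m$sx2, m$sxy, params)$f1
}

#' Zero-lag pair rate of upcrossings
#'
#' Saddle-point limit `f2(t, t)` of the two-time pair rate as the lag
#' vanishes (continuous part; the singular self-correlation is
#' excluded):
#' \deqn{f_2(t,t) = \frac{3\sqrt3-\pi}{36\pi^2}
#'   \frac{\sigma_y^2/\tau_y}{\sqrt{\sigma_x^2\sigma_y^2-\sigma_{xy}^2}}
#'   e^{-B(b,\dot b,t)}.}
#'
#' @inheritParams exponent_B
#' @return pair rate (1/ms^2).
#' @export
pair_rate_zero_lag <- function(b, bdot, t, params) {
  m <- moments_at(params, t)
  crossing_core(b, bdot, m$sx2, m$sxy, params)$f2
}

#' Zero-lag pair correlation of upcrossings
#'
#' `R0(t) = f2(t,t)/f1(t)^2 - 1`. Negative values mean upcrossings repel
#' each other at small lags, positive values mean they cluster. The
#' ratio is computed in log space so that it stays finite where `f1`
#' underflows.
#'
#' @inheritParams exponent_B
#' @return dimensionless correlation; `NaN` where `f1 = 0`.
#' @export
R0_zero_lag <- function(b, bdot, t, params) {
  m <- moments_at(params, t)
  res <- crossing_core(b, bdot, m$sx2, m$sxy, params)
  lr <- res$logf2 - 2 * res$logf1
  out <- exp(lr) - 1
  out[!res$ok | res$logf1 == -Inf] <- NaN
  out
}

#' Stationary zero-lag pair correlation at given time-scale ratio
#'
#' Evaluates the stationary `R0` at barrier height `b` (in units of
#' `sigma_x`) for a time-scale ratio `u = gamma * tau_y`, by building a
#' parameter set with that ratio and calling the general machinery at
#' `t = Inf`. Closed form: `beta (1+u)/sqrt(u) exp(b_rel^2/2) - 1`.
#'
#' @param u time-scale ratio `gamma * tau_y` (> 0).
#' @param b_rel barrier height in units of the stationary `sigma_x`.
#' @return `R0` (dimensionless).
#' @export
r0_stationary <- function(u, b_rel = 0) {
  stopifnot(all(u > 0))
  vapply(u, function(ui) {
    p <- lif_params(tau_m = 1, tau_s = ui, sigma_V = 1)
    R0_zero_lag(b = b_rel * p$sigma_V, bdot = 0, t = Inf, p)
  }, numeric(length(b_rel)))
}

#' Positivity boundaries of the stationary zero-lag correlation
#'
#' Solves `beta (1+u)/sqrt(u) = 1` for `u = gamma*tau_y` by root-finding
#' on the stationary `R0(u, b = 0)` produced by the package itself.
#' Below the smaller root (near-white noise) and above the larger root
#' (strong friction / long noise correlation) `R0 > 0` for all barrier
#' heights; in between, low barriers give repulsive upcrossings.
#'
#' @param tol root-finding tolerance.
#' @return named numeric vector `c(lower=, upper=)`.
#' @export
r0_positivity_roots <- function(tol = 1e-12) {
  f <- function(u) r0_stationary(u, 0)
  c(lower = stats::uniroot(f, c(1e-4, 1), tol = tol)$root,
    upper = stats::uniroot(f, c(1, 1e3), tol = tol)$root)
}

#' Minimum of the stationary zero-lag correlation
#'
#' Minimizes the stationary `R0(u, b = 0)` over the time-scale ratio
#' `u = gamma*tau_y` (the minimum over barrier heights is at `b = 0`
#' since the barrier only contributes the factor `exp(b^2/(2 sigma_x^2))
#' >= 1`). The minimizer is `u = 1` and the minimum `2 beta - 1`.
#'
#' @return list with elements `u` (argmin) and `R0` (minimum value).
#' @export
r0_minimum <- function() {
  opt <- stats::optimize(function(u) r0_stationary(u, 0),
                         interval = c(0.05, 20), tol = 1e-10)
  list(u = opt$minimum, R0 = opt$objective)
}

#' Critical barrier separating repulsive from clustered upcrossings
#'
#' For `u = gamma*tau_y` strictly between the positivity roots, the
#' stationary `R0` changes sign at
#' \deqn{b_{crit}/\sigma_x = \sqrt{2\ln\frac{\sqrt{u}}{\beta(1+u)}};}
#' below `b_crit` upcrossings repel (`R0 < 0`), above they cluster.
#' Outside the interval the log argument is below 1 and `R0 > 0` for
#' every barrier.
#'
#' @param params a [lif_params] (only `gamma * tau_y` matters).
#' @return `b_crit / sigma_x`, or `NA` with a warning when there is no
#'   sign change.
#' @export
critical_barrier <- function(params) {
  u <- params$gamma * params$tau_y
  arg <- sqrt(u) / (.beta_const * (1 + u))
  if (arg <= 1) {
    warning("no sign change: R0 > 0 for all barrier heights at gamma*tau_y = ",
            signif(u, 6))
    return(NA_real_)
  }
  sqrt(2 * log(arg))
}

#' Exponential ansatz for the upcrossing pair correlation
#'
#' `R(t, t') ~ R0(t) exp(-|t - t'| / tau_corr)` with
#' `tau_corr = tau_m + tau_s`, the integral correlation time of the
#' stationary free process. The variant pinned at the primed time,
#' `R0(t') exp(-(t-t')/tau_corr)`, is available via `pin = "tprime"`
#' (not validated against figures).
#'
#' @param t,tprime times (ms).
#' @param R0t zero-lag correlation at the pinned time.
#' @param params a [lif_params].
#' @param pin which time carries `R0` (`"t"` default).
#' @return dimensionless correlation.
#' @export
R_exponential <- function(t, tprime, R0t, params, pin = c("t", "tprime")) {
  pin <- match.arg(pin)
  R0t * exp(-abs(t - tprime) / params$tau_corr)
}

#' Scan of zero-lag correlation over time-scale ratio and barrier
#'
#' Produces a tidy table of stationary `R0(u, b)` and the critical
#' barrier over a grid of `u = gamma*tau_y` and relative barrier
#' heights, for plotting or CSV export.
#'
#' @param u values of `gamma*tau_y`.
#' @param b_rel barrier heights in units of `sigma_x`.
#' @return data.frame with columns `u`, `b_rel`, `R0`, `b_crit`.
#' @export
crossing_scan <- function(u = 10^seq(-2, 2, length.out = 41),
                          b_rel = c(0, 0.5, 1, 2)) {
  grid <- expand.grid(u = u, b_rel = b_rel)
  grid$R0 <- mapply(function(ui, bi) r0_stationary(ui, bi), grid$u, grid$b_rel)
  grid$b_crit <- vapply(grid$u, function(ui) {
    p <- lif_params(1, ui, sigma_V = 1)
    suppressWarnings(critical_barrier(p))
  }, numeric(1))
  grid
}
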