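## Brute-force two-time pair rate of upcrossings: builds the joint
## 4-dimensional Gaussian of (x(t1), v(t1), x(t2), v(t2)) with
## v = dx/dt = -gamma x + y from the transition structure of the linear
## system, and evaluates the generalized Rice integral by 2-D
## Gauss-Legendre quadrature over the velocity quadrant. Used as the
## independent oracle for the saddle-point zero-lag limit and for the
## exponential correlation ansatz; not meant for production solves.

## state-transition matrix of (x, y) over a lag s
xy_transition <- function(params, s) {
  g <- params$gamma; a <- 1 / params$tau_y
  eg <- exp(-g * s); ea <- exp(-a * s)
  gxy <- if (abs(a - g) < 1e-10 * (a + g)) s * eg else (eg - ea) / (a - g)
  matrix(c(eg, 0, gxy, ea), 2, 2)   # column-major: [,1]=(eg,0), [,2]=(gxy,ea)
}

## single-time covariance matrix of (x, y)
xy_cov <- function(params, t) {
  m <- xmoments(params, t)
  matrix(c(m$sigma_x2, m$sigma_xy, m$sigma_xy, params$sigma_y2), 2, 2)
}

#' Two-time pair rate of upcrossings (numerical oracle)
#'
#' Computes `f2(t1, t2)`, the joint rate of finding upcrossings of the
#' moving boundary at both times, from the exact joint Gaussian law of
#' the free process and its velocity at the two times. The velocity
#' integrals run over `v_i > bdot(t_i)` with the quadrant truncated at
#' eight conditional standard deviations (Gaussian tails beyond are
#' negligible).
#'
#' @param t1,t2 times (> 0, distinct; `Inf` for `t1` selects the
#'   stationary state, in which case `t2` is interpreted as `t1 + lag`
#'   via `lag = t2 - t1` being passed directly, see `lag`).
#' @param boundary a [boundary_path], or a list with functions `b(t)`
#'   and `bdot(t)` (closed-form boundaries).
#' @param params a [lif_params].
#' @param n_nodes Gauss-Legendre nodes per velocity dimension.
#' @param lag optional: with `lag` given, the stationary pair rate at
#'   that lag is computed (`t1`, `t2` ignored; boundary evaluated at
#'   `t1` and `t2` if finite, else held at its value at time 0 of the
#'   supplied functions).
#' @return pair rate (1/ms^2).
#' @export
f2_numeric <- function(t1, t2, boundary, params, n_nodes = 48, lag = NULL) {
  bfun <- boundary_accessors(boundary)
  if (is.null(lag)) {
    stopifnot(t1 > 0, t2 > 0)
    if (t1 > t2) { tmp <- t1; t1 <- t2; t2 <- tmp }
    dlag <- t2 - t1
    tol <- 1e-9 * max(params$tau_m, params$tau_y)
    if (dlag < tol)
      stop("|t2 - t1| below tolerance: use the saddle-point limit ",
           "pair_rate_zero_lag() instead")
    S1 <- xy_cov(params, t1)
    b1 <- bfun$b(t1); bd1 <- bfun$bdot(t1)
    b2 <- bfun$b(t2); bd2 <- bfun$bdot(t2)
  } else {
    stopifnot(lag > 0)
    dlag <- lag
    S1 <- xy_cov(params, Inf)
    b1 <- bfun$b(t1); bd1 <- bfun$bdot(t1)
    b2 <- bfun$b(t1 + lag); bd2 <- bfun$bdot(t1 + lag)
  }
  Phi <- xy_transition(params, dlag)
  S2 <- if (is.null(lag)) xy_cov(params, t2) else S1
  C21 <- Phi %*% S1                     # Cov(xi(t2), xi(t1))

  ## joint covariance of (x1, y1, x2, y2), then map to (x1, v1, x2, v2)
  S4 <- rbind(cbind(S1, t(C21)), cbind(C21, S2))
  Tm <- matrix(c(1, -params$gamma, 0, 1), 2, 2)
  Tb <- rbind(cbind(Tm, matrix(0, 2, 2)), cbind(matrix(0, 2, 2), Tm))
  S4 <- Tb %*% S4 %*% t(Tb)

  ix <- c(1L, 3L); iv <- c(2L, 4L)
  Sxx <- S4[ix, ix]; Svv <- S4[iv, iv]; Svx <- S4[iv, ix]
  detx <- Sxx[1, 1] * Sxx[2, 2] - Sxx[1, 2]^2
  if (detx <= 0) stop("x-covariance not positive definite (lag too small)")
  Sxx_inv <- matrix(c(Sxx[2, 2], -Sxx[1, 2], -Sxx[1, 2], Sxx[1, 1]),
                    2, 2) / detx
  xb <- c(b1, b2)
  px <- exp(-0.5 * drop(xb %*% Sxx_inv %*% xb)) / (2 * pi * sqrt(detx))
  mc <- drop(Svx %*% Sxx_inv %*% xb)          # conditional mean of (v1, v2)
  Sc <- Svv - Svx %*% Sxx_inv %*% t(Svx)      # conditional covariance
  sd1 <- sqrt(Sc[1, 1]); sd2 <- sqrt(Sc[2, 2])

  lo1 <- bd1; hi1 <- mc[1] + 8 * sd1
  lo2 <- bd2; hi2 <- mc[2] + 8 * sd2
  if (lo1 >= hi1 || lo2 >= hi2) return(0)
  lo1 <- max(lo1, mc[1] - 8.5 * sd1)
  lo2 <- max(lo2, mc[2] - 8.5 * sd2)

  gl1 <- pracma::gaussLegendre(n_nodes, lo1, hi1)
  gl2 <- pracma::gaussLegendre(n_nodes, lo2, hi2)
  detc <- Sc[1, 1] * Sc[2, 2] - Sc[1, 2]^2
  if (detc <= 0) stop("conditional velocity covariance degenerate")
  Sc_inv <- matrix(c(Sc[2, 2], -Sc[1, 2], -Sc[1, 2], Sc[1, 1]), 2, 2) / detc

  d1 <- gl1$x - mc[1]; d2 <- gl2$x - mc[2]
  Q <- outer(d1^2 * Sc_inv[1, 1], d2^2 * Sc_inv[2, 2], `+`) +
    2 * Sc_inv[1, 2] * outer(d1, d2)
  dens <- exp(-0.5 * Q) / (2 * pi * sqrt(detc))
  wgt <- outer((gl1$x - bd1) * gl1$w, (gl2$x - bd2) * gl2$w)
  px * sum(wgt * dens)
}

boundary_accessors <- function(boundary) {
  if (inherits(boundary, "boundary_path")) {
    list(
      b = function(t) stats::approx(boundary$time, boundary$b, t,
                                    rule = 2)$y,
      bdot = function(t) stats::approx(boundary$time, boundary$bdot, t,
                                       rule = 2)$y
    )
  } else if (is.list(boundary) && is.function(boundary$b) &&
             is.function(boundary$bdot)) {
    boundary
  } else stop("boundary must be a boundary_path or list(b=, bdot=) of functions")
}

#' Constant boundary helper
#' @param b boundary height; `bdot` is 0.
#' @return list of closed-form accessors usable by [f2_numeric()] and
#'   [stratonovich_survival()].
#' @export
constant_boundary <- function(b)
  list(b = function(t) rep(b, length(t)), bdot = function(t) rep(0, length(t)))

#' Stationary pair correlation from the numerical oracle
#'
#' `R(lag) = f2(lag)/f1^2 - 1` for a constant boundary in the stationary
#' state, from [f2_numeric()].
#'
#' @param lag positive lag(s) (ms).
#' @param b constant boundary height.
#' @param params a [lif_params].
#' @param n_nodes quadrature nodes per dimension.
#' @return dimensionless correlation values.
#' @export
R_numeric_stationary <- function(lag, b, params, n_nodes = 48) {
  f1 <- upcrossing_rate_f1(b, 0, Inf, params)
  vapply(lag, function(l)
    f2_numeric(0, 0, constant_boundary(b), params,
               n_nodes = n_nodes, lag = l) / f1^2 - 1,
    numeric(1))
}
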