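## Local hazard-rate approximations for the moving-boundary
## first-passage problem: first-order decoupling (hazard = upcrossing
## rate), second-order decoupling (pair correlations via the
## exponential ansatz and the auxiliary variable z), plus the non-local
## Stratonovich survival oracle used to validate the localization.

#' First-order decoupling hazard rate
#'
#' Under the assumption of independent (Poissonian) upcrossings the
#' hazard rate equals the upcrossing rate: `lambda(t) = Phi_1(b, bdot, t)`.
#' Identical to [upcrossing_rate_f1()] by definition.
#'
#' @inheritParams exponent_B
#' @return rate (1/ms).
#' @export
hazard_first_order <- function(b, bdot, t, params)
  upcrossing_rate_f1(b, bdot, t, params)

#' Filtered upcrossing-rate variable z
#'
#' Solves `dz/dt = -z/tau_corr + f1(t)`, `z(0) = 0`, with
#' `tau_corr = tau_m + tau_s`, by the exact per-step exponential
#' integrator (`f1` piecewise linear on the grid). `z` accumulates the
#' recent upcrossing rate on the correlation time scale; together with
#' the zero-lag correlation it gives the correlation measure
#' `q(t) = R0(t) z(t)`.
#'
#' @param f1_series nonnegative rate series on a uniform grid.
#' @param grid uniform time grid (ms).
#' @param params a [lif_params].
#' @return numeric vector `z(t)` on the grid.
#' @export
z_dynamics <- function(f1_series, grid, params) {
  check_uniform_grid(grid)
  stopifnot(length(f1_series) == length(grid), all(f1_series >= 0))
  expint_relax(0, f1_series * params$tau_corr, grid[2] - grid[1],
               params$tau_corr)
}

## core of the second-order hazard: lambda2 = f1 / (1 + R0 z), with the
## f2/f1^2 ratio computed in log space and the denominator guarded.
phi2_core <- function(core, z, denom_floor = 0.05) {
  lr <- core$logf2 - 2 * core$logf1
  f1 <- core$f1
  n <- length(f1)
  lam <- numeric(n); q <- numeric(n)
  live <- core$ok & core$logf1 > -Inf
  if (any(live)) {
    rho <- exp(pmin(lr[live], 700))            # f2/f1^2 = 1 + R0
    qi <- (rho - 1) * z[live]
    qi[is.infinite(rho) & z[live] > 0] <- Inf  # hazard fully suppressed
    q[live] <- qi
  }
  clamped <- live & (1 + q) < denom_floor
  denom <- pmax(1 + q, denom_floor)
  lam[live] <- f1[live] / denom[live]
  lam[live & is.infinite(q)] <- 0
  list(lambda = lam, q = q, clamped = clamped)
}

#' Second-order decoupling hazard rate
#'
#' `Phi_2(b, bdot, z, t) = Phi_1 / (1 + R0_hat(b, bdot, t) z)`: pair
#' correlations between upcrossings rescale the Poisson hazard.
#' Repulsive upcrossings (`R0 < 0`, boundary near the mean) raise the
#' hazard; clustered upcrossings (`R0 > 0`, high boundary) lower it.
#' When `z = 0` or `R0 = 0` the first-order rate is recovered.
#'
#' The Stratonovich approximation requires `q = R0 z > -1`; if the
#' denominator falls below `denom_floor` it is clamped there and the
#' result flagged (attribute `"clamped"`), because the condition is an
#' applicability statement and downstream solvers need finite hazards.
#'
#' @inheritParams exponent_B
#' @param z filtered upcrossing-rate variable from [z_dynamics()].
#' @param denom_floor clamp for `1 + q` (default 0.05).
#' @return rate (1/ms) with attributes `q` and `clamped`.
#' @export
hazard_second_order <- function(b, bdot, z, t, params, denom_floor = 0.05) {
  m <- moments_at(params, t)
  core <- crossing_core(b, bdot, m$sx2, m$sxy, params)
  n <- max(length(core$f1), length(z))
  res <- phi2_core(core, rep_len(z, n), denom_floor)
  out <- res$lambda
  attr(out, "q") <- res$q
  attr(out, "clamped") <- res$clamped
  out
}

#' Non-local Stratonovich survival probability (oracle)
#'
#' Evaluates the non-local second-order survival
#' \deqn{S(t) \approx \exp\left\{-\int_0^t f_1(\tau)
#'   \frac{\ln[1+q(t,\tau)]}{q(t,\tau)} d\tau\right\}, \qquad
#'   q(t,\tau) = \int_0^t R(\tau,\tau') f_1(\tau') d\tau',}
#' with the pair correlation `R` taken from the numerical two-time
#' oracle [f2_numeric()] (zero lag from [R0_zero_lag()]). Cost is
#' cubic-ish in the grid size; intended for small validation grids, not
#' production solves. Aborts if `q <= -1` anywhere (approximation
#' inapplicable).
#'
#' @param boundary a [boundary_path] or `list(b=, bdot=)` of functions.
#' @param params a [lif_params].
#' @param t_max horizon (ms).
#' @param n grid size (keep modest; `f2_numeric` runs over all pairs).
#' @param force_R zero to force `R == 0` (reduces exactly to the
#'   first-order survival), `NULL` (default) to use the oracle.
#' @param n_nodes quadrature nodes for [f2_numeric()].
#' @return data.frame with columns `time`, `S`, plus attribute `q_range`.
#' @export
stratonovich_survival <- function(boundary, params, t_max, n = 60,
                                  force_R = NULL, n_nodes = 32) {
  bfun <- boundary_accessors(boundary)
  tg <- seq(0, t_max, length.out = n + 1L)[-1L]   # exclude t = 0 start
  h <- tg[2] - tg[1]
  f1 <- upcrossing_rate_f1(bfun$b(tg), bfun$bdot(tg), tg, params)

  R <- matrix(0, n, n)
  if (is.null(force_R)) {
    R0d <- R0_zero_lag(bfun$b(tg), bfun$bdot(tg), tg, params)
    ## times where f1 has underflowed contribute nothing to q (their
    ## weight f1 is zero); skip them to avoid 0/0 in the ratio
    floor_f1 <- max(f1) * 1e-10
    for (i in seq_len(n)) {
      R[i, i] <- if (is.finite(R0d[i])) R0d[i] else 0
      if (i < n) for (j in seq((i + 1L), n)) {
        if (f1[i] <= floor_f1 || f1[j] <= floor_f1) next
        f2 <- f2_numeric(tg[i], tg[j], boundary, params, n_nodes = n_nodes)
        r <- f2 / (f1[i] * f1[j]) - 1
        if (is.finite(r)) R[i, j] <- R[j, i] <- r
      }
    }
  }

  ## q(t_k, tau_j) = sum_{j' <= k} w R[j, j'] f1[j'] (trapezoid in tau')
  S <- numeric(n)
  Fq <- function(q) ifelse(abs(q) < 1e-12, 1 - q / 2, log1p(q) / q)
  qmin <- Inf; qmax <- -Inf
  acc <- 0
  Rf <- sweep(R, 2L, f1, `*`)          # R[j, j'] * f1[j']
  for (k in seq_len(n)) {
    w <- rep(h, k); w[1] <- w[k] <- h / 2
    qk <- drop(Rf[seq_len(k), seq_len(k), drop = FALSE] %*% w)
    if (any(qk <= -1))
      stop("q(t, tau) <= -1 encountered: Stratonovich approximation ",
           "inapplicable for this boundary")
    qmin <- min(qmin, qk); qmax <- max(qmax, qk)
    integrand <- f1[seq_len(k)] * Fq(qk)
    S[k] <- exp(-sum(w * integrand))
  }
  out <- data.frame(time = tg, S = S)
  attr(out, "q_range") <- c(qmin, qmax)
  out
}

#' Validity diagnostics for the decoupling approximations
#'
#' Summarizes the correlation measure `q(t) = R0(t) z(t)`: the
#' first-order approximation assumes `|q| << 1`; the second-order
#' (Stratonovich-based) hazard requires `q > -1`.
#'
#' @param q_series numeric vector of `q(t)` values.
#' @param first_order_tol threshold on `|q|` above which the first-order
#'   approximation is flagged as suspect (default 0.1).
#' @return list with `min_q`, `frac_large` (fraction with `|q| >`
#'   `first_order_tol`), `invalid` (any `q <= -1`), and a human-readable
#'   `verdict`.
#' @export
validity_diagnostics <- function(q_series, first_order_tol = 0.1) {
  q <- q_series[is.finite(q_series)]
  min_q <- if (length(q)) min(q) else NA_real_
  frac <- if (length(q)) mean(abs(q) > first_order_tol) else 0
  invalid <- any(q_series <= -1, na.rm = TRUE)
  verdict <- if (invalid) {
    "second-order DA invalid (q <= -1 encountered)"
  } else if (frac > 0) {
    "first-order DA inadequate; second-order DA valid"
  } else "first-order DA adequate"
  list(min_q = min_q, frac_large = frac, invalid = invalid,
       verdict = verdict)
}
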