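#' Stimulus on a uniform time grid
#'
#' A time-dependent mean drive `mu(t)` sampled on a strictly increasing,
#' uniform grid. Generators ([gen_ou_stimulus()], [gen_bandlimited_stimulus()],
#' constant stimuli) tag the object with their closed-form family and
#' parameters.
#'
#' @param time numeric vector, uniform strictly increasing grid (ms).
#' @param mu numeric vector of the same length, finite.
#' @param form optional tag, one of `"constant"`, `"periodic"`,
#'   `"ou-sample"`, `"bandlimited-sample"`, `"custom"`.
#' @param pars optional named list of the closed-form parameters.
#' @return object of class `stimulus_path` (a data.frame with columns
#'   `time`, `mu` and attributes `form`, `pars`, `dt`).
#' @export
stimulus_path <- function(time, mu, form = "custom", pars = list()) {
  check_uniform_grid(time)
  stopifnot(length(mu) == length(time), all(is.finite(mu)))
  out <- data.frame(time = time, mu = mu)
  attr(out, "form") <- form
  attr(out, "pars") <- pars
  attr(out, "dt") <- time[2L] - time[1L]
  class(out) <- c("stimulus_path", "data.frame")
  out
}

#' Constant stimulus
#' @param mu0 constant drive (voltage).
#' @param time uniform time grid (ms).
#' @return a [stimulus_path].
#' @export
constant_stimulus <- function(mu0, time)
  stimulus_path(time, rep(mu0, length(time)), form = "constant",
                pars = list(mu0 = mu0))

#' Moving boundary on a uniform time grid
#'
#' The boundary view of a first-passage problem: `b(t) = V_T - u(t)` in
#' units of `V_T - V_R`, together with its analytic derivative. `bdot`
#' must come from the governing ODE (or a closed form), never from
#' finite differences.
#'
#' @param time uniform time grid (ms).
#' @param b boundary values.
#' @param bdot boundary time derivative.
#' @return object of class `boundary_path`.
#' @export
boundary_path <- function(time, b, bdot) {
  check_uniform_grid(time)
  stopifnot(length(b) == length(time), length(bdot) == length(time),
            all(is.finite(b)), all(is.finite(bdot)))
  out <- data.frame(time = time, b = b, bdot = bdot)
  attr(out, "dt") <- time[2L] - time[1L]
  class(out) <- c("boundary_path", "data.frame")
  out
}

check_uniform_grid <- function(time, tol = 1e-8) {
  stopifnot(is.numeric(time), length(time) >= 2L, all(is.finite(time)))
  d <- diff(time)
  if (any(d <= 0)) stop("time grid must be strictly increasing")
  if (max(d) - min(d) > tol * max(d))
    stop("time grid must be uniform")
  invisible(time)
}

#' Read a stimulus or boundary series from CSV
#'
#' Expects exactly two columns `time,value` with a header, on a uniform
#' grid.
#'
#' @param file path to a CSV file.
#' @param as `"stimulus"` returns a [stimulus_path]; `"series"` returns
#'   the raw data.frame.
#' @return see `as`.
#' @export
read_stimulus_csv <- function(file, as = c("stimulus", "series")) {
  as <- match.arg(as)
  d <- utils::read.csv(file)
  if (!all(c("time", "value") %in% names(d)))
    stop("CSV must have columns 'time' and 'value'")
  check_uniform_grid(d$time)
  if (as == "series") return(d)
  stimulus_path(d$time, d$value)
}

## one step of the exact exponential integrator for tau * xdot = -x + g(t),
## g piecewise linear on the grid: x_{n+1} = E x_n + c_n with
## c_n = g_n (1-E) + (g_{n+1}-g_n) (1 - tau(1-E)/h),  E = exp(-h/tau).
## Returns the full trajectory via a linear recurrence.
expint_relax <- function(x0, g, h, tau) {
  E <- exp(-h / tau)
  n <- length(g)
  gl <- g[-n]; gr <- g[-1L]
  cn <- gl * (1 - E) + (gr - gl) * (1 - tau * (1 - E) / h)
  x <- stats::filter(cn, E, method = "recursive", init = x0)
  c(x0, as.numeric(x))
}

#' Mean membrane potential for a given stimulus
#'
#' Solves `tau_m * du/dt = -u + mu(t)` on the stimulus grid with an exact
#' per-step exponential integrator (`mu` treated as piecewise linear), so
#' the solution carries no global discretization drift.
#'
#' @param params a [lif_params].
#' @param stimulus a [stimulus_path].
#' @param u0 initial potential (use `params$V_R` for post-spike
#'   trajectories).
#' @return numeric vector `u(t)` on the stimulus grid, `u[1] = u0`.
#' @examples
#' p <- lif_params(10, 4, sigma_V = 0.25)
#' s <- constant_stimulus(0.8, seq(0, 100, 0.1))
#' u <- mean_potential(p, s, u0 = 0)
#' max(abs(u - (0.8 + (0 - 0.8) * exp(-s$time / 10))))  # ~ 0
#' @export
mean_potential <- function(params, stimulus, u0 = params$V_R) {
  stopifnot(inherits(params, "lif_params"), inherits(stimulus, "stimulus_path"),
            is.finite(u0))
  expint_relax(u0, stimulus$mu, attr(stimulus, "dt"), params$tau_m)
}

#' Boundary view of a first-passage problem
#'
#' Transforms the mean potential `u(t)` and stimulus into the moving
#' boundary `b(t) = V_T - u(t)` with analytic derivative
#' `db/dt = -du/dt = (u - mu)/tau_m` (never finite differences).
#'
#' @param params a [lif_params].
#' @param u mean potential on the stimulus grid (from [mean_potential()]).
#' @param stimulus the [stimulus_path] that produced `u`.
#' @return a [boundary_path].
#' @export
to_boundary <- function(params, u, stimulus) {
  stopifnot(length(u) == nrow(stimulus))
  boundary_path(stimulus$time,
                b = params$V_T - u,
                bdot = (u - stimulus$mu) / params$tau_m)
}
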