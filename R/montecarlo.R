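## Ground-truth stochastic simulators and synthetic stimulus/boundary
## generators. The (x, y) and (V, y) systems are stepped with the exact
## joint Gaussian transition (state-transition matrix + step-noise
## covariance), so there is no Euler discretization drift; the only
## grid artifact is sign-change crossing detection.

#' Simulation configuration
#'
#' @param params a [lif_params] (sets the default step).
#' @param dt_sim simulation step (ms); default `min(tau_m, tau_s)/50`.
#' @param n_trials number of trials / neurons.
#' @param seed integer seed applied via `set.seed()` at the start of
#'   each simulator call; `NA` leaves the current RNG stream untouched.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(params, dt_sim = min(params$tau_m, params$tau_s) / 50,
                       n_trials = 1e4, seed = 1L) {
  stopifnot(dt_sim > 0, n_trials >= 1)
  if (dt_sim > min(params$tau_m, params$tau_s) / 50 + 1e-12)
    stop("dt_sim must not exceed min(tau_m, tau_s)/50")
  structure(list(dt_sim = dt_sim, n_trials = as.integer(n_trials),
                 seed = seed),
            class = "sim_config")
}

## state-transition matrix entries and step-noise Cholesky for a step h
transition_structures <- function(params, h) {
  g <- params$gamma; a <- 1 / params$tau_y
  sy2 <- params$sigma_y2
  eg <- exp(-g * h); ea <- exp(-a * h)
  degen <- abs(a - g) < 1e-8 * (a + g)
  p12 <- if (degen) h * eg else (eg - ea) / (a - g)
  cc <- 2 * sy2 * a
  q22 <- sy2 * (1 - exp(-2 * a * h))
  if (degen) {
    q12 <- cc * (1 - (1 + 2 * g * h) * exp(-2 * g * h)) / (4 * g^2)
    q11 <- cc * (2 - exp(-2 * g * h) * (2 + 4 * g * h + 4 * g^2 * h^2)) /
      (8 * g^3)
  } else {
    e2g <- exp(-2 * g * h); ega <- exp(-(g + a) * h); e2a <- exp(-2 * a * h)
    q12 <- cc / (a - g) * ((1 - ega) / (g + a) - (1 - e2a) / (2 * a))
    q11 <- cc / (a - g)^2 * ((1 - e2g) / (2 * g) - 2 * (1 - ega) / (g + a) +
                               (1 - e2a) / (2 * a))
  }
  l11 <- sqrt(q11); l21 <- q12 / l11; l22 <- sqrt(max(q22 - l21^2, 0))
  ## stationary joint covariance (for stationary starts)
  sxyi <- params$tilde_tau * sy2
  sx2i <- params$sigma_x2_inf
  s11 <- sqrt(sx2i); s21 <- sxyi / s11
  s22 <- sqrt(max(sy2 - s21^2, 0))
  list(p11 = eg, p12 = p12, p22 = ea,
       l11 = l11, l21 = l21, l22 = l22,
       st_l11 = s11, st_l21 = s21, st_l22 = s22)
}

## deterministic potential increment per step for piecewise-linear mu
lif_force <- function(mu, h, params) {
  E <- exp(-h / params$tau_m)
  n <- length(mu)
  mul <- mu[-n]; mur <- mu[-1L]
  mul * (1 - E) + (mur - mul) * (1 - params$tau_m * (1 - E) / h)
}

maybe_seed <- function(seed) if (!is.na(seed)) set.seed(as.integer(seed))

#' First-passage times of the free process against a moving boundary
#'
#' Exact-update Monte-Carlo of `x(t)` started at `x(0) = 0` (or from the
#' joint stationary law) with stationary noise, recording the first grid
#' index at which `x >= b`. Trials with no crossing before the end of
#' the boundary grid are censored (`NA`).
#'
#' @param params a [lif_params].
#' @param boundary a [boundary_path]; its grid is resampled to the
#'   simulation step.
#' @param config a [sim_config].
#' @param stationary start from the joint stationary law instead of
#'   `x(0) = 0` (used for upcrossing-rate checks, not FPT problems).
#' @return list with `fpt` (vector, `NA` = censored), `censored`
#'   (fraction), `t_max`, `dt_sim`.
#' @export
simulate_xy <- function(params, boundary, config, stationary = FALSE) {
  stopifnot(inherits(boundary, "boundary_path"), inherits(config, "sim_config"))
  if (!stationary && boundary$b[1] <= 0)
    stop("b(0) must be > 0: the start must lie inside the domain")
  h <- config$dt_sim
  tg <- seq(boundary$time[1], boundary$time[nrow(boundary)], by = h)
  b <- stats::approx(boundary$time, boundary$b, tg, rule = 2)$y
  ts <- transition_structures(params, h)
  maybe_seed(config$seed)
  fpt <- cpp_xy_fpt(b, h, config$n_trials,
                    ts$p11, ts$p12, ts$p22, ts$l11, ts$l21, ts$l22,
                    sqrt(params$sigma_y2), stationary,
                    ts$st_l11, ts$st_l21, ts$st_l22)
  list(fpt = fpt, censored = mean(is.na(fpt)),
       t_max = tg[length(tg)] - tg[1], dt_sim = h)
}

#' Monte-Carlo simulation of the LIF model with colored input noise
#'
#' `mode = "isi"`: non-resetting first-passage trials from a last spike
#' at `t_hat` (refractory clamp, then free evolution until the first
#' threshold crossing); returns interspike-interval samples including
#' the refractory period. `mode = "population"`: `n_trials` unconnected
#' resetting neurons, all spiking at `t0`, with the colored noise
#' carried through spikes (non-renewal microscopic dynamics); returns
#' binned population activity.
#'
#' @param params a [lif_params].
#' @param stimulus a [stimulus_path]; resampled to the simulation step.
#' @param config a [sim_config].
#' @param mode `"isi"` or `"population"`.
#' @param t_hat last spike time for `mode = "isi"`.
#' @param t0 synchronized initialization time for `mode = "population"`.
#' @param t_max horizon (defaults to the end of the stimulus).
#' @param bin histogram bin width (ms) for the population activity.
#' @return for `"isi"`: list as in [simulate_xy()]; for `"population"`:
#'   data.frame with `time` (bin centers), `A` (1/ms), `se` plus
#'   attribute `n_neurons`.
#' @export
simulate_lif <- function(params, stimulus, config,
                         mode = c("isi", "population"),
                         t_hat = stimulus$time[1], t0 = stimulus$time[1],
                         t_max = NULL, bin = 0.5) {
  mode <- match.arg(mode)
  stopifnot(inherits(stimulus, "stimulus_path"), inherits(config, "sim_config"))
  h <- config$dt_sim
  start <- if (mode == "isi") t_hat else t0
  end <- if (is.null(t_max)) stimulus$time[nrow(stimulus)] else start + t_max
  if (end > stimulus$time[nrow(stimulus)] + 1e-9)
    stop("stimulus too short for the requested horizon")
  tg <- seq(start, end, by = h)
  mu <- stats::approx(stimulus$time, stimulus$mu, tg, rule = 2)$y
  force <- lif_force(mu, h, params)
  ts <- transition_structures(params, h)
  n_ref <- round(params$t_ref / h)
  maybe_seed(config$seed)
  if (mode == "isi") {
    fpt <- cpp_lif_isi(force, h, config$n_trials, n_ref,
                       params$V_R, params$V_T,
                       ts$p11, ts$p12, ts$p22, ts$l11, ts$l21, ts$l22,
                       sqrt(params$sigma_y2))
    return(list(fpt = fpt, censored = mean(is.na(fpt)),
                t_max = tg[length(tg)] - start, dt_sim = h))
  }
  counts <- cpp_lif_population(force, h, config$n_trials, n_ref,
                               params$V_R, params$V_T,
                               ts$p11, ts$p12, ts$p22,
                               ts$l11, ts$l21, ts$l22,
                               sqrt(params$sigma_y2))
  ## re-bin: the synchronized spikes at t0 itself are the initial
  ## condition, not part of A(t) for t > t0
  per <- max(1L, round(bin / h))
  nb <- floor((length(counts) - 1L) / per)
  idx <- rep(seq_len(nb), each = per)
  cs <- tapply(counts[1L + seq_len(nb * per)], idx, sum)
  A <- as.numeric(cs) / (config$n_trials * per * h)
  se <- sqrt(pmax(as.numeric(cs), 1)) / (config$n_trials * per * h)
  out <- data.frame(time = start + (seq_len(nb) - 0.5) * per * h,
                    A = A, se = se)
  attr(out, "n_neurons") <- config$n_trials
  out
}

#' Free-ensemble snapshots of the (x, y) process
#'
#' Pure-R exact stepping of the free process (no boundary), returning
#' samples of `x` and `y` at requested times; used to validate the
#' closed-form moments against simulation.
#'
#' @param params a [lif_params].
#' @param times snapshot times (>= 0, ms), snapped to the simulation grid.
#' @param config a [sim_config].
#' @return list with matrices `x`, `y` (`n_trials` rows) and `times`.
#' @export
free_ensemble <- function(params, times, config) {
  h <- config$dt_sim
  steps <- round(sort(unique(times)) / h)
  ts <- transition_structures(params, h)
  maybe_seed(config$seed)
  n <- config$n_trials
  x <- numeric(n); y <- sqrt(params$sigma_y2) * stats::rnorm(n)
  xs <- matrix(NA_real_, n, length(steps))
  ys <- matrix(NA_real_, n, length(steps))
  k <- 1L
  if (steps[1] == 0L) { xs[, 1] <- x; ys[, 1] <- y; k <- 2L }
  for (s in seq_len(max(steps))) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    xn <- ts$p11 * x + ts$p12 * y + ts$l11 * z1
    y <- ts$p22 * y + ts$l21 * z1 + ts$l22 * z2
    x <- xn
    if (k <= length(steps) && s == steps[k]) {
      xs[, k] <- x; ys[, k] <- y; k <- k + 1L
    }
  }
  list(x = xs, y = ys, times = steps * h)
}

#' Monte-Carlo upcrossing rate at a constant level
#'
#' Counts grid sign changes of `x(t) - b` from negative to nonnegative
#' in the stationary state and returns the rate with its standard
#' error (over trials); the independent check of the Rice rate.
#'
#' @param params a [lif_params].
#' @param b_level constant level.
#' @param T_obs observation window per trial (ms).
#' @param config a [sim_config].
#' @return list with `rate` (1/ms), `se`, `n_events`.
#' @export
count_upcrossings <- function(params, b_level, T_obs, config) {
  h <- config$dt_sim
  N <- round(T_obs / h)
  ts <- transition_structures(params, h)
  maybe_seed(config$seed)
  n <- config$n_trials
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  x <- ts$st_l11 * z1
  y <- ts$st_l21 * z1 + ts$st_l22 * z2
  cnt <- integer(n)
  for (s in seq_len(N)) {
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    xn <- ts$p11 * x + ts$p12 * y + ts$l11 * z1
    y <- ts$p22 * y + ts$l21 * z1 + ts$l22 * z2
    cnt <- cnt + (x < b_level & xn >= b_level)
    x <- xn
  }
  rates <- cnt / T_obs
  list(rate = mean(rates), se = stats::sd(rates) / sqrt(n),
       n_events = sum(cnt))
}

#' Periodically moving boundary
#'
#' `b(t) = 1 + alpha cos(2 pi f t)` with exact derivative
#' `bdot = -2 pi f alpha sin(2 pi f t)`. `alpha < 1` keeps the boundary
#' strictly positive (subthreshold regime); `alpha > 1` lets it dip
#' below zero (suprathreshold regime).
#'
#' @param alpha amplitude.
#' @param f frequency (cycles per ms for ms grids).
#' @param time uniform time grid.
#' @return a [boundary_path].
#' @export
gen_periodic_boundary <- function(alpha, f, time) {
  boundary_path(time,
                b = 1 + alpha * cos(2 * pi * f * time),
                bdot = -2 * pi * f * alpha * sin(2 * pi * f * time))
}

#' Ornstein-Uhlenbeck stimulus sample
#'
#' Stationary OU sample with mean `mu_bar`, standard deviation
#' `sqrt(1 + tau_m/tau_mu) * sigma_bar` and correlation time `tau_mu`,
#' via the exact update. The parametrization is chosen so that the free
#' membrane potential driven by the stimulus has stationary mean
#' `mu_bar` and standard deviation `sigma_bar` (on top of any intrinsic
#' noise).
#'
#' @param mu_bar target mean of the free membrane potential.
#' @param sigma_bar target standard deviation of the free membrane
#'   potential response.
#' @param tau_mu stimulus correlation time (ms).
#' @param params a [lif_params] (for `tau_m`).
#' @param time uniform time grid.
#' @param seed integer seed (`NA` = use current stream).
#' @return a [stimulus_path].
#' @export
gen_ou_stimulus <- function(mu_bar, sigma_bar, tau_mu, params, time,
                            seed = NA) {
  stopifnot(tau_mu > 0)
  maybe_seed(seed)
  h <- time[2] - time[1]
  sd_mu <- sqrt(1 + params$tau_m / tau_mu) * sigma_bar
  E <- exp(-h / tau_mu)
  n <- length(time)
  x0 <- sd_mu * stats::rnorm(1)         # stationary initial value
  innov <- sd_mu * sqrt(1 - E^2) * stats::rnorm(n - 1L)
  dev <- stats::filter(innov, E, method = "recursive", init = x0)
  mu <- mu_bar + c(x0, as.numeric(dev))
  stimulus_path(time, mu, form = "ou-sample",
                pars = list(mu_bar = mu_bar, sigma_bar = sigma_bar,
                            tau_mu = tau_mu, sd_mu = sd_mu))
}

#' Band-limited white-noise stimulus
#'
#' `mu(t) = mu0 +` a superposition of equal-amplitude cosines at
#' frequencies `k / T` up to the cut-off, with independent uniform
#' phases, scaled to the target standard deviation: a fixed "frozen"
#' broadband stimulus with a flat spectrum up to `f_cut`.
#'
#' @param mu0 baseline drive.
#' @param sd_mu target standard deviation of the fluctuating part.
#' @param f_cut cut-off frequency (cycles per ms; 100 Hz = 0.1).
#' @param time uniform time grid.
#' @param seed integer seed (`NA` = use current stream).
#' @return a [stimulus_path].
#' @export
gen_bandlimited_stimulus <- function(mu0, sd_mu, f_cut, time, seed = NA) {
  h <- time[2] - time[1]
  if (f_cut >= 0.5 / h) stop("f_cut must be below the Nyquist frequency")
  maybe_seed(seed)
  Tdur <- time[length(time)] - time[1]
  M <- floor(f_cut * Tdur)
  if (M < 1) stop("grid too short for the requested cut-off")
  if (sd_mu == 0) return(constant_stimulus(mu0, time))
  amp <- sd_mu * sqrt(2 / M)
  ph <- stats::runif(M, 0, 2 * pi)
  tt <- time - time[1]
  dev <- numeric(length(time))
  for (k in seq_len(M))
    dev <- dev + amp * cos(2 * pi * (k / Tdur) * tt + ph[k])
  stimulus_path(time, mu0 + dev, form = "bandlimited-sample",
                pars = list(mu0 = mu0, sd_mu = sd_mu, f_cut = f_cut, M = M))
}
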