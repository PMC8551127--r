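#' Model parameters for the LIF / Ornstein-Uhlenbeck system
#'
#' Collects the physical constants of a leaky integrate-and-fire neuron
#' driven by exponentially correlated (Ornstein-Uhlenbeck) noise and
#' precomputes the derived constants of the equivalent boundary-view
#' process `x(t)` (overdamped particle below a moving boundary).
#'
#' The noise strength can be given either as `sigma_eta` (standard
#' deviation of the OU current noise, in voltage units) or as `sigma_V`,
#' the stationary standard deviation of the free (non-resetting) membrane
#' potential; they are related by
#' `sigma_V^2 = sigma_eta^2 * tau_s / (tau_m + tau_s)`.
#'
#' Voltages are measured in units of `V_T - V_R`, with `V_R = 0` and
#' `V_T = 1` by default; times are in milliseconds (any consistent time
#' unit works, all rates are reciprocal time).
#'
#' @param tau_m membrane time constant (ms), > 0.
#' @param tau_s noise correlation time (ms), > 0.
#' @param sigma_eta OU noise standard deviation (voltage). Give exactly one
#'   of `sigma_eta`, `sigma_V`.
#' @param sigma_V stationary standard deviation of the free membrane
#'   potential (voltage).
#' @param V_T threshold voltage.
#' @param V_R reset voltage, must satisfy `V_R < V_T`.
#' @param t_ref absolute refractory period (ms), >= 0.
#'
#' @return An object of class `lif_params`: a list with the fields above
#'   plus derived constants `gamma = 1/tau_m`, `tau_y = tau_s`,
#'   `D = tau_s * sigma_eta^2 / tau_m^2`, `sigma_y2 = D / tau_y`,
#'   `tilde_tau` with `1/tilde_tau = gamma + 1/tau_y`,
#'   `tau_corr = tau_m + tau_s`, and `sigma_x2_inf`, the stationary
#'   variance of `x(t)`.
#'
#' @examples
#' p <- lif_params(tau_m = 10, tau_s = 4, sigma_V = 0.25)
#' p$sigma_x2_inf  # 0.25^2
#' @export
lif_params <- function(tau_m, tau_s, sigma_eta = NULL, sigma_V = NULL,
                       V_T = 1, V_R = 0, t_ref = 0) {
  stopifnot(is.numeric(tau_m), length(tau_m) == 1L, tau_m > 0,
            is.numeric(tau_s), length(tau_s) == 1L, tau_s > 0,
            is.numeric(t_ref), length(t_ref) == 1L, t_ref >= 0)
  if (V_R >= V_T) stop("V_R must be smaller than V_T")
  if (is.null(sigma_eta) == is.null(sigma_V))
    stop("give exactly one of 'sigma_eta' or 'sigma_V'")
  if (is.null(sigma_eta))
    sigma_eta <- sigma_V * sqrt((tau_m + tau_s) / tau_s)
  stopifnot(sigma_eta > 0)

  gamma  <- 1 / tau_m
  tau_y  <- tau_s
  D      <- tau_s * sigma_eta^2 / tau_m^2
  sigma_y2 <- D / tau_y            # = sigma_eta^2 / tau_m^2
  tilde_tau <- 1 / (gamma + 1 / tau_y)
  p <- list(
    tau_m = tau_m, tau_s = tau_s, sigma_eta = sigma_eta,
    V_T = V_T, V_R = V_R, t_ref = t_ref,
    gamma = gamma, tau_y = tau_y, D = D, sigma_y2 = sigma_y2,
    tilde_tau = tilde_tau, tau_corr = tau_m + tau_s,
    sigma_x2_inf = tilde_tau * sigma_y2 / gamma,
    sigma_V = sqrt(tilde_tau * sigma_y2 / gamma)
  )
  class(p) <- "lif_params"
  p
}

#' @export
print.lif_params <- function(x, ...) {
  cat("LIF / OU model parameters\n")
  cat(sprintf("  tau_m = %g ms, tau_s = %g ms (gamma*tau_y = %g)\n",
              x$tau_m, x$tau_s, x$gamma * x$tau_y))
  cat(sprintf("  sigma_eta = %g, sigma_V = sigma_x(inf) = %g\n",
              x$sigma_eta, x$sigma_V))
  cat(sprintf("  V_T = %g, V_R = %g, t_ref = %g ms\n", x$V_T, x$V_R, x$t_ref))
  cat(sprintf("  tau_corr = tau_m + tau_s = %g ms\n", x$tau_corr))
  invisible(x)
}

#' Default time step for a parameter set
#'
#' `min(tau_m, tau_s) / 100`: resolves the fastest intrinsic time scale
#' and the hazard transient near the start of a first-passage problem.
#'
#' @param params a [lif_params] object.
#' @return time step (ms).
#' @export
default_dt <- function(params) min(params$tau_m, params$tau_s) / 100

#' Read a run configuration from a YAML file
#'
#' Recognized keys: `tau_m`, `tau_s`, `sigma_eta` or `sigma_V`, `V_T`,
#' `V_R`, `t_ref`, `dt`, `seed`. Missing `V_T`/`V_R`/`t_ref` fall back to
#' the package defaults (1, 0, 0). Unknown keys are kept in the returned
#' list for downstream consumers (e.g. the command-line front end).
#'
#' @param file path to a YAML file.
#' @return list with elements `params` ([lif_params]), `dt`, `seed`, and
#'   `extra` (unrecognized keys).
#' @export
read_run_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  need <- c("tau_m", "tau_s")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("config is missing required field(s): ", paste(miss, collapse = ", "))
  if (is.null(cfg$sigma_eta) && is.null(cfg$sigma_V))
    stop("config is missing required field(s): sigma_eta (or sigma_V)")
  params <- lif_params(
    tau_m = cfg$tau_m, tau_s = cfg$tau_s,
    sigma_eta = cfg$sigma_eta, sigma_V = cfg$sigma_V,
    V_T = if (is.null(cfg$V_T)) 1 else cfg$V_T,
    V_R = if (is.null(cfg$V_R)) 0 else cfg$V_R,
    t_ref = if (is.null(cfg$t_ref)) 0 else cfg$t_ref
  )
  known <- c("tau_m", "tau_s", "sigma_eta", "sigma_V", "V_T", "V_R",
             "t_ref", "dt", "seed")
  list(params = params,
       dt = if (is.null(cfg$dt)) default_dt(params) else cfg$dt,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
       extra = cfg[setdiff(names(cfg), known)])
}
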