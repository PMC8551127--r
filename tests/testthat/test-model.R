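test_that("derived constants satisfy their defining identities", {
  p <- lif_params(tau_m = 10, tau_s = 4, sigma_eta = 0.3, t_ref = 2)
  expect_equal(p$gamma, 1 / p$tau_m)
  expect_equal(p$tau_y, p$tau_s)
  expect_equal(p$D, p$tau_s * p$sigma_eta^2 / p$tau_m^2)
  expect_equal(p$sigma_y2, p$D / p$tau_y)
  expect_equal(1 / p$tilde_tau, p$gamma + 1 / p$tau_y)
  expect_equal(p$tau_corr, p$tau_m + p$tau_s)
  expect_equal(p$sigma_x2_inf, p$tilde_tau * p$sigma_y2 / p$gamma)
  ## sigma_V parametrization inverts sigma_eta exactly
  p2 <- lif_params(10, 4, sigma_V = p$sigma_V)
  expect_equal(p2$sigma_eta, p$sigma_eta)
  expect_error(lif_params(10, 4, sigma_V = 0.2, V_R = 1, V_T = 0), "V_R")
  expect_error(lif_params(10, 4), "exactly one")
  expect_error(lif_params(10, 4, sigma_V = 0.2, sigma_eta = 0.3),
               "exactly one")
})

test_that("mean potential solves the membrane equation exactly", {
  p <- p_neuron()
  tg <- seq(0, 100, 0.05)
  ## constant drive: closed-form relaxation
  u <- mean_potential(p, constant_stimulus(0.8, tg), u0 = 0)
  expect_equal(u, 0.8 + (0 - 0.8) * exp(-tg / 10), tolerance = 1e-12)
  ## fixed point
  u2 <- mean_potential(p, constant_stimulus(0.4, tg), u0 = 0.4)
  expect_equal(u2, rep(0.4, length(tg)), tolerance = 1e-12)
  ## sine drive vs the analytic particular + homogeneous solution
  om <- 2 * pi / 20
  tg <- seq(0, 100, 0.002)
  s <- stimulus_path(tg, sin(om * tg))
  u3 <- mean_potential(p, s, u0 = 0)
  den <- 1 + om^2 * p$tau_m^2
  ua <- (sin(om * tg) - om * p$tau_m * cos(om * tg)) / den +
    om * p$tau_m / den * exp(-tg / p$tau_m)
  expect_lt(max(abs(u3 - ua)), 1e-6 * max(abs(ua)))
  ## non-uniform grid rejected
  expect_error(stimulus_path(c(0, 1, 3), c(0, 0, 0)), "uniform")
})

test_that("boundary view has b = V_T - u and the analytic derivative", {
  p <- p_neuron()
  tg <- seq(0, 60, 0.01)
  s <- stimulus_path(tg, 0.5 + 0.3 * sin(2 * pi * tg / 25))
  u <- mean_potential(p, s)
  bd <- to_boundary(p, u, s)
  expect_equal(bd$b, p$V_T - u)
  ## bdot agrees with central differences of b to O(dt^2)
  num <- (bd$b[-(1:2)] - bd$b[seq_len(length(tg) - 2L)]) / (2 * 0.01)
  expect_lt(max(abs(bd$bdot[-c(1, length(tg))] - num)), 1e-5)
  ## u at threshold means zero boundary
  bd2 <- to_boundary(p, rep(p$V_T, length(tg)), s)
  expect_true(all(bd2$b == 0))
})

test_that("closed-form moments match their defining ODEs", {
  tg <- seq(0, 20, 0.02)   # units of tau_m below
  for (u in c(0.1, 0.99, 1.0, 1.01, 10)) {
    p <- p_ratio(u)
    mc <- xmoments(p, tg)
    mo <- xmoments_ode(p, tg)
    scale <- p$sigma_x2_inf
    expect_lt(max(abs(mc$sigma_x2 - mo$sigma_x2)) / scale, 1e-6,
              label = sprintf("sigma_x2 mismatch at gamma*tau_y = %g", u))
    expect_lt(max(abs(mc$sigma_xy - mo$sigma_xy)) /
                (p$tilde_tau * p$sigma_y2), 1e-6)
    ## Cauchy-Schwarz on a dense grid
    expect_true(all(mc$sigma_x2 * p$sigma_y2 - mc$sigma_xy^2 >= -1e-12))
  }
})

test_that("moments hit their boundary and stationary values", {
  p <- p_neuron()
  m0 <- xmoments(p, 0)
  expect_equal(m0$sigma_x2, 0)
  expect_equal(m0$sigma_xy, 0)
  mi <- xmoments(p, Inf)
  expect_equal(mi$sigma_xy, p$tilde_tau * p$sigma_y2)
  expect_equal(mi$sigma_x2, p$tilde_tau * p$sigma_y2 / p$gamma)
  expect_error(xmoments(p, -1))
  ## degenerate ratio stays finite and smooth
  pd <- p_ratio(1)
  md <- xmoments(pd, seq(0, 10, 0.01))
  expect_true(all(is.finite(md$sigma_x2)))
  expect_true(all(diff(md$sigma_x2) > -1e-12))
})

test_that("stationary autocorrelation integrates to tau_m + tau_s", {
  p <- p_neuron()
  expect_equal(stationary_autocorr(p, 0), 1)
  ic <- stats::integrate(function(s) stationary_autocorr(p, s), 0, Inf,
                         rel.tol = 1e-10)$value
  expect_equal(ic, p$tau_m + p$tau_s, tolerance = 1e-6)
  ## degenerate ratio
  pd <- p_ratio(1)
  icd <- stats::integrate(function(s) stationary_autocorr(pd, s), 0, Inf,
                          rel.tol = 1e-10)$value
  expect_equal(icd, pd$tau_m + pd$tau_s, tolerance = 1e-6)
  ## short noise correlation: single-filter limit exp(-gamma tau)
  ps <- lif_params(tau_m = 1, tau_s = 1e-3, sigma_V = 1)
  tau <- seq(0.1, 3, 0.1)
  expect_lt(max(abs(stationary_autocorr(ps, tau) - exp(-tau))), 2e-3)
})

test_that("YAML config round-trips and reports missing fields", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("tau_m: 10", "tau_s: 4", "sigma_V: 0.25", "t_ref: 2",
               "dt: 0.05", "seed: 7"), f)
  cfg <- read_run_config(f)
  expect_s3_class(cfg$params, "lif_params")
  expect_equal(cfg$params$t_ref, 2)
  expect_equal(cfg$dt, 0.05)
  expect_equal(cfg$seed, 7L)
  f2 <- tempfile(fileext = ".yaml")
  writeLines(c("tau_s: 4", "sigma_V: 0.25"), f2)
  expect_error(read_run_config(f2), "tau_m")
  unlink(c(f, f2))
})

test_that("stimulus CSV reader enforces the two-column contract", {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(time = seq(0, 1, 0.1), value = 0.5), f,
                   row.names = FALSE)
  s <- read_stimulus_csv(f)
  expect_s3_class(s, "stimulus_path")
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(t = 1:3, v = 1:3), f2, row.names = FALSE)
  expect_error(read_stimulus_csv(f2), "columns")
  unlink(c(f, f2))
})
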