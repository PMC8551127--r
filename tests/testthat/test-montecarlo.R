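test_that("simulators are bit-reproducible from the seed", {
  p <- p_boundary()
  tg <- seq(0, 10, by = default_dt(p))
  bd <- gen_periodic_boundary(0.25, 0.5, tg)
  cfg <- sim_config(p, n_trials = 200, seed = 99)
  a <- simulate_xy(p, bd, cfg)
  b <- simulate_xy(p, bd, cfg)
  expect_identical(a$fpt, b$fpt)
  stim <- constant_stimulus(0.9, seq(0, 50, 0.1))
  pn <- p_neuron()
  cfgn <- sim_config(pn, n_trials = 200, seed = 13)
  expect_identical(simulate_lif(pn, stim, cfgn, mode = "isi")$fpt,
                   simulate_lif(pn, stim, cfgn, mode = "isi")$fpt)
})

test_that("free ensemble reproduces the stationary noise and moment curves", {
  p <- p_neuron()
  cfg <- sim_config(p, n_trials = 2e4, seed = 31)
  fe <- free_ensemble(p, times = c(0.5, 2, 10) * p$tau_m, cfg)
  m <- xmoments(p, fe$times)
  n <- nrow(fe$x)
  for (j in seq_along(fe$times)) {
    v <- stats::var(fe$x[, j])
    se <- m$sigma_x2[j] * sqrt(2 / (n - 1))
    expect_lt(abs(v - m$sigma_x2[j]), 3 * se,
              label = sprintf("Var[x] at t = %g", fe$times[j]))
    vy <- stats::var(fe$y[, j])
    expect_lt(abs(vy - p$sigma_y2), 3 * p$sigma_y2 * sqrt(2 / (n - 1)))
    ## covariance too
    cxy <- stats::cov(fe$x[, j], fe$y[, j])
    expect_lt(abs(cxy - m$sigma_xy[j]),
              4 * sqrt(m$sigma_x2[j] * p$sigma_y2 / n) + 4e-4)
  }
})

test_that("grid upcrossing counting matches the Rice rate", {
  p <- p_neuron()
  for (brel in c(0, 1, 2)) {
    b <- brel * sqrt(p$sigma_x2_inf)
    cfg <- sim_config(p, n_trials = 5e3, seed = 17 + brel)
    uc <- count_upcrossings(p, b, T_obs = 200, cfg)
    f1 <- upcrossing_rate_f1(b, 0, Inf, p)
    expect_lt(abs(uc$rate - f1), 3 * uc$se,
              label = sprintf("upcrossing rate at b = %g sigma", brel))
  }
})

test_that("periodic boundary generator produces the stated regimes", {
  tg <- seq(0, 4, 0.001)
  sub <- gen_periodic_boundary(0.25, 0.5, tg)
  expect_equal(min(sub$b), 0.75, tolerance = 1e-9)
  sup <- gen_periodic_boundary(1.2, 0.5, tg)
  expect_lt(min(sup$b), 0)
  flat <- gen_periodic_boundary(0, 0.5, tg)
  expect_true(all(flat$b == 1) && all(flat$bdot == 0))
  ## bdot is the exact derivative
  num <- diff(sub$b) / 0.001
  expect_lt(max(abs((sub$bdot[-length(tg)] + sub$bdot[-1]) / 2 - num)), 1e-4)
})

test_that("OU stimulus has the stated mean, variance and correlation time", {
  p <- p_neuron()
  tg <- seq(0, 2e4, 0.1)
  s <- gen_ou_stimulus(0.7, 0.3, 10, p, tg, seed = 23)
  sd_target <- sqrt(1 + p$tau_m / 10) * 0.3
  n_eff <- (max(tg) / 10)  # roughly independent samples
  expect_lt(abs(mean(s$mu) - 0.7), 3 * sd_target / sqrt(n_eff))
  expect_lt(abs(stats::sd(s$mu) - sd_target),
            3 * sd_target / sqrt(2 * n_eff))
  ## lag tau_mu autocorrelation near 1/e
  ac <- stats::acf(s$mu, lag.max = 100, plot = FALSE)$acf[101]
  expect_lt(abs(ac - exp(-1)), 3 / sqrt(n_eff))
})

test_that("band-limited stimulus has a flat spectrum up to the cut-off", {
  tg <- seq(0, 2000, 0.5)
  s <- gen_bandlimited_stimulus(0.3, 1, 0.1, tg, seed = 2)
  expect_equal(mean(s$mu), 0.3, tolerance = 0.05)
  expect_equal(stats::sd(s$mu), 1, tolerance = 0.05)
  dev <- s$mu[-length(s$mu)]          # integer number of periods
  sp <- stats::spec.pgram(stats::ts(dev - mean(dev), deltat = 0.5),
                          taper = 0, plot = FALSE)
  freq <- sp$freq / 0.5 * 0.5           # cycles per ms already
  inband <- mean(sp$spec[sp$freq > 0.005 & sp$freq < 0.095])
  outband <- mean(sp$spec[sp$freq > 0.12])
  expect_lt(outband / inband, 1e-4)     # -40 dB
  ## zero amplitude: constant stimulus
  s0 <- gen_bandlimited_stimulus(0.3, 0, 0.1, tg)
  expect_true(all(s0$mu == 0.3))
  ## determinism
  expect_identical(gen_bandlimited_stimulus(0, 1, 0.1, tg, seed = 4)$mu,
                   gen_bandlimited_stimulus(0, 1, 0.1, tg, seed = 4)$mu)
})

test_that("halving the simulation step leaves the FPT distribution unchanged", {
  p <- p_boundary()
  tg <- seq(0, 20, 0.002)
  bd <- gen_periodic_boundary(0.25, 0.5, tg)
  grid <- seq(0, 20, 0.01)
  ks <- vapply(c(0.004, 0.002), function(h) {
    cfg <- sim_config(p, dt_sim = h, n_trials = 2e4, seed = 5)
    mc <- simulate_xy(p, bd, cfg)
    th <- boundary_fpt(p, gen_periodic_boundary(0.25, 0.5, grid), order = 2)
    ks_distance(th$S, empirical_survival(mc$fpt, grid))
  }, numeric(1))
  ## the step-size effect is below the Monte-Carlo error at this n
  expect_lt(abs(ks[1] - ks[2]), 1 / sqrt(2e4) * 3)
})

test_that("simulator guards reject invalid configurations", {
  p <- p_boundary()
  expect_error(sim_config(p, dt_sim = 1), "dt_sim")
  tg <- seq(0, 5, 0.002)
  bd <- boundary_path(tg, rep(-1, length(tg)), rep(0, length(tg)))
  expect_error(simulate_xy(p, bd, sim_config(p, n_trials = 10)), "b\\(0\\)")
})
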