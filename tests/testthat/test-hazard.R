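test_that("first-order hazard is the upcrossing rate", {
  p <- p_boundary()
  b <- c(0.2, 0.8, 1.4); bd <- c(-0.3, 0, 0.3); tt <- c(0.5, 2, Inf)
  expect_identical(hazard_first_order(b, bd, tt, p),
                   upcrossing_rate_f1(b, bd, tt, p))
  expect_lt(hazard_first_order(60 * sqrt(p$sigma_x2_inf), 0, Inf, p), 1e-100)
})

test_that("z dynamics solve their linear ODE exactly", {
  p <- p_neuron()
  tg <- seq(0, 100, 0.05)
  expect_equal(z_dynamics(rep(0, length(tg)), tg, p), rep(0, length(tg)))
  ## constant drive closed form
  z <- z_dynamics(rep(0.03, length(tg)), tg, p)
  expect_equal(z, 0.03 * p$tau_corr * (1 - exp(-tg / p$tau_corr)),
               tolerance = 1e-10)
  ## linear drive: closed-form convolution
  z_lin <- z_dynamics(0.01 * tg, tg, p)
  tc <- p$tau_corr
  expect_lt(max(abs(z_lin - 0.01 * (tc * tg - tc^2 * (1 - exp(-tg / tc))))),
            1e-12)
  ## smooth sine drive on a fine grid vs the analytic convolution
  om <- 2 * pi / 30
  tf <- seq(0, 100, 0.002)
  zs <- z_dynamics(0.05 * (1 + sin(om * tf)), tf, p)
  zexact <- 0.05 * tc * (1 - exp(-tf / tc)) +
    0.05 * tc / (1 + om^2 * tc^2) *
      (sin(om * tf) - om * tc * cos(om * tf) + om * tc * exp(-tf / tc))
  expect_lt(max(abs(zs - zexact)), 1e-8)
})

test_that("second-order hazard rescales the first order by 1/(1+q)", {
  p <- p_boundary()
  ## z = 0 recovers the first order bit-exactly
  b <- seq(0.1, 1.5, 0.2)
  f1 <- hazard_first_order(b, 0, Inf, p)
  expect_identical(as.numeric(hazard_second_order(b, 0, 0, Inf, p)), f1)
  ## direct check through a constructed case: stationary b = 0 has known R0
  R0 <- r0_stationary(p$gamma * p$tau_y, 0)
  z0 <- 0.5
  lam2 <- hazard_second_order(0, 0, z0, Inf, p)
  expect_equal(as.numeric(lam2),
               hazard_first_order(0, 0, Inf, p) / (1 + R0 * z0),
               tolerance = 1e-10)
  ## monotone decreasing in q: repulsion raises, clustering lowers
  lam_rep <- hazard_second_order(0, 0, 1, Inf, p)        # R0 < 0 at b=0
  expect_gt(as.numeric(lam_rep), hazard_first_order(0, 0, Inf, p))
  bhi <- 2 * critical_barrier(p) * sqrt(p$sigma_x2_inf)
  lam_clu <- hazard_second_order(bhi, 0, 1, Inf, p)      # R0 > 0 high up
  expect_lt(as.numeric(lam_clu), hazard_first_order(bhi, 0, Inf, p))
})

test_that("denominator guard clamps and flags instead of aborting", {
  p <- p_ratio(1)            # R0 = -0.543 at b = 0 stationary
  lam <- hazard_second_order(0, 0, 3, Inf, p)   # q = -1.63 < -1
  expect_true(attr(lam, "clamped"))
  expect_true(is.finite(as.numeric(lam)))
  expect_equal(as.numeric(lam), hazard_first_order(0, 0, Inf, p) / 0.05)
})

test_that("validity diagnostics grade q as specified", {
  expect_match(validity_diagnostics(rep(0, 10))$verdict, "adequate")
  d <- validity_diagnostics(c(0, -0.5, -0.2))
  expect_match(d$verdict, "second-order DA valid")
  expect_equal(d$min_q, -0.5)
  expect_true(validity_diagnostics(c(0, -1.2))$invalid)
})

test_that("Stratonovich oracle reduces to first order when R is forced off", {
  p <- p_boundary()
  so <- stratonovich_survival(constant_boundary(1), p, t_max = 4, n = 40,
                              force_R = 0)
  tg <- seq(0, 4, by = default_dt(p))
  th1 <- boundary_fpt(p, boundary_path(tg, rep(1, length(tg)),
                                       rep(0, length(tg))), order = 1)
  S1 <- stats::approx(th1$time, th1$S, so$time)$y
  expect_lt(max(abs(so$S - S1)), 5e-4)
  expect_true(all(diff(so$S) <= 0))
  expect_true(all(so$S <= 1 & so$S >= 0))
})

test_that("local second order tracks the non-local oracle better than first", {
  p <- p_boundary()
  ## constant boundary (validation case of the localization steps)
  so <- stratonovich_survival(constant_boundary(1), p, t_max = 5, n = 50)
  tg <- seq(0, 5, by = default_dt(p))
  bp <- boundary_path(tg, rep(1, length(tg)), rep(0, length(tg)))
  S1 <- stats::approx(boundary_fpt(p, bp, order = 1)$time,
                      boundary_fpt(p, bp, order = 1)$S, so$time)$y
  S2 <- stats::approx(boundary_fpt(p, bp, order = 2)$time,
                      boundary_fpt(p, bp, order = 2)$S, so$time)$y
  expect_lt(max(abs(so$S - S2)), max(abs(so$S - S1)))
  expect_lt(max(abs(so$S - S2)), 0.02)   # logged cross-validation level
  ## suprathreshold boundary (crosses zero): same ordering
  so2 <- stratonovich_survival(
    list(b = function(t) 1 + 1.2 * cos(pi * t),
         bdot = function(t) -1.2 * pi * sin(pi * t)),
    p, t_max = 2.2, n = 44)
  bp2 <- gen_periodic_boundary(1.2, 0.5, seq(0, 2.2, by = default_dt(p)))
  S1 <- stats::approx(boundary_fpt(p, bp2, order = 1)$time,
                      boundary_fpt(p, bp2, order = 1)$S, so2$time)$y
  S2 <- stats::approx(boundary_fpt(p, bp2, order = 2)$time,
                      boundary_fpt(p, bp2, order = 2)$S, so2$time)$y
  expect_lt(max(abs(so2$S - S2)), max(abs(so2$S - S1)))
})
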