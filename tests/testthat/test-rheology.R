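test_that("stiffness and loss angle match their closed-form examples", {
  # Maxwell-fluid limit: c0 = 0, eps0 cancels
  expect_equal(stiffness(0.1, 0, 0, omega_bar = 2), 2 / sqrt(5))
  expect_equal(stiffness(1, 1, pi / 2, 1, 1, 1), sqrt(2))
  expect_equal(loss_angle(1, 1, pi / 2, 1, 1), pi / 4)
  # Maxwell limit across omega_bar to machine precision; tan crosses 1 at 1
  wb <- 10^seq(-1, 1, length.out = 21)
  expect_equal(stiffness(0.2, 0, 1.3, wb), wb / sqrt(1 + wb^2))
  expect_equal(loss_tangent(0.2, 0, 1.3, wb), 1 / wb)
  expect_equal(loss_tangent(0.2, 0, 0, 1), 1)
  # undefined components are masked, not infinite
  expect_true(is.na(stiffness(0, 0.2, 1, 1)))
  expect_true(is.na(loss_angle(0, 0, 1, 0)))
})

test_that("stiffness is homogeneous in kappa and amplitude-scale invariant,
           linear in tau_bar at large tau_bar", {
  e0 <- 0.07; c0 <- 0.22; dm <- 4.3; wb <- 0.8
  expect_equal(stiffness(e0, c0, dm, wb, 2, kappa = 5),
               5 * stiffness(e0, c0, dm, wb, 2, kappa = 1))
  expect_equal(stiffness(3 * e0, 3 * c0, dm, wb, 2),
               stiffness(e0, c0, dm, wb, 2))
  # doubling tau_bar at large tau_bar doubles E within 1 %
  expect_equal(stiffness(e0, c0, dm, wb, 100) / stiffness(e0, c0, dm, wb, 50),
               2, tolerance = 0.01)
  # loss angle largely insensitive to tau_bar at large tau_bar; the residual
  # difference is the O(eps0*omega_bar/(c0*tau_bar)) correction, 0.069 rad by
  # direct closed-form evaluation at these parameters
  expect_lt(abs(loss_angle(0.1, 0.1, 5 * pi / 4, 1, 100) -
                loss_angle(0.1, 0.1, 5 * pi / 4, 1, 10)), 0.08)
})

test_that("the stress ODE integrator reproduces decay, fixed points and the
           steady-state closed form", {
  tau_R <- 1; dt_s <- 0.05
  t <- seq(0, 20, by = dt_s)
  # homogeneous decay
  sig <- stress_series(rep(0, length(t)), rep(0, length(t)), dt_s,
                       tau_R = tau_R, sigma0 = 2)
  expect_equal(sig, 2 * exp(-t / tau_R), tolerance = 1e-9)
  # step in c_m -> sigma -> tau_bar * kappa * c_bar
  sigs <- stress_series(rep(0, length(t)), rep(0.3, length(t)), dt_s,
                        tau_R = 1, tau_bar = 2, kappa = 1.5)
  expect_equal(sigs[length(sigs)], 2 * 1.5 * 0.3, tolerance = 1e-6)
  # sinusoidal inputs: amplitude sqrt(2), phase pi/4 for the unit parameter set
  om <- 1; h <- 2 * pi / om / 200
  tt <- seq(0, 5 + 25 * 2 * pi / om, by = h)
  sig2 <- stress_series(cos(om * tt), cos(om * tt + pi / 2), h)
  sel <- tt > 5 + 5 * 2 * pi / om
  f <- sinusoid_fit(sig2[sel], tt[sel], om)
  expect_equal(f$amplitude, sqrt(2), tolerance = 0.01)
  expect_lt(abs(angle_diff(f$phase, pi / 4)), 0.01)
  expect_error(stress_series(c(1, NA), c(0, 0), 1), "NA")
})

test_that("ODE integration agrees with the closed forms over random
           parameter sets (consistency theorem)", {
  withr::with_seed(77, {
    for (i in 1:25) {
      e0 <- stats::runif(1, 0.01, 0.3); c0 <- stats::runif(1, 0.01, 0.5)
      dm <- stats::runif(1, 0, 2 * pi); wb <- stats::runif(1, 0.1, 10)
      tb <- 10^stats::runif(1, -1, 2)
      om <- wb; h <- (2 * pi / om) / 200
      tt <- seq(0, 5 + 25 * 2 * pi / om, by = h)
      sig <- stress_series(e0 * cos(om * tt), c0 * cos(om * tt + dm), h,
                           tau_R = 1, tau_bar = tb)
      sel <- tt > 5 + 5 * 2 * pi / om
      f <- sinusoid_fit(sig[sel], tt[sel], om)
      expect_equal(f$amplitude / e0, stiffness(e0, c0, dm, wb, tb),
                   tolerance = 0.01)
      expect_lt(abs(angle_diff(f$phase,
                               loss_angle(e0, c0, dm, wb, tb, "quadrature"))),
                0.02)
    }
  })
})

test_that("material_state averages components and respects stationarity", {
  # single component repeated -> bin mean equals the single value
  comp <- data.table::data.table(
    embryo_id = "e", cell_id = c("a", "b"), freq = 5e-3, t = c(120, 130),
    strain_amp = 0.05, myosin_amp = 0.2, lag = 4.2
  )
  cfg <- test_config(component_floor = 0)
  ms <- suppressWarnings(material_state(comp, cfg, ci = FALSE))
  expect_equal(nrow(ms), 1)
  expect_equal(ms$stiffness,
               stiffness(0.05, 0.2, 4.2, 2 * pi * 5e-3, 1, 1))
  expect_equal(ms$loss_tangent, loss_tangent(0.05, 0.2, 4.2, 2 * pi * 5e-3, 1))
  # stationary scenario -> flat E(t), tan(t)
  g <- generate_embryo(n_cells = 6, duration = 6000,
                       scenario = tone_scenario(lag = 5 * pi / 4), seed = 41)
  res <- suppressWarnings(run_pipeline(g$dataset, test_config(seed = 1)))
  m <- res$material
  rng <- range(m$t)
  m <- m[m$t > rng[1] + 150 & m$t < rng[2] - 150, ]   # interior bins
  expect_lt(diff(range(m$stiffness)) / mean(m$stiffness), 0.05)
  expect_lt(diff(range(m$loss_tangent)) / abs(mean(m$loss_tangent)), 0.1)
  # within its own bootstrap CI width
  expect_true(all(m$stiffness >= m$stiffness_lo - 0.05 * m$stiffness &
                  m$stiffness <= m$stiffness_hi + 0.05 * m$stiffness))
})

test_that("halving strain amplitude at constant myosin doubles stiffness", {
  wb <- 2 * pi * 5e-3
  E1 <- stiffness(0.08, 0.2, 5 * pi / 4, wb, 1)
  E2 <- stiffness(0.04, 0.2, 5 * pi / 4, wb, 1)
  expect_equal(E2 / E1, 2, tolerance = 0.05)
})

test_that("the tau_bar scan reduces to material_state at a single point and
           obeys the asymptotic slope", {
  g <- generate_embryo(n_cells = 4, duration = 6000,
                       scenario = clean_scenario(), seed = 42)
  cfg <- test_config(seed = 2)
  comps <- spectral_components(preprocess_dataset(g$dataset, cfg), cfg)
  ms <- suppressWarnings(material_state(comps, cfg, ci = FALSE))
  sc1 <- tau_scan(comps, cfg, tau_bar_grid = 1)
  expect_equal(sc1$stiffness, ms$stiffness)
  expect_error(tau_scan(comps, cfg, tau_bar_grid = c(0.01, 1)), "range")
  scan <- tau_scan(comps, cfg, tau_bar_grid = c(10, 31.6, 100))
  ag <- scan[, list(E = mean(stiffness)), by = "tau_bar"]
  slope <- stats::coef(stats::lm(log(E) ~ log(tau_bar), ag))[[2]]
  expect_equal(slope, 1, tolerance = 0.02)
})
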