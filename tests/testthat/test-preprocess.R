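dt <- 10

test_that("the boxcar trend reproduces constants, ramps and the Dirichlet
           attenuation of an in-band oscillation", {
  t <- seq(0, 8000, by = dt)
  expect_equal(stats::na.omit(area_trend(rep(7, 801), dt, 360)),
               rep(7, 801 - 36), ignore_attr = TRUE)
  ramp <- 100 + 0.01 * t
  tr <- area_trend(ramp, dt, 360)
  i <- 100:700
  expect_equal(tr[i], ramp[i], tolerance = 1e-12)
  # independent oracle: direct convolution of the 37-sample boxcar with the
  # cosine gives attenuation a = sin(N*pi*dt/P)/(N*sin(pi*dt/P)) = -0.0784355
  # at P = 200 s (frozen from the direct computation)
  P <- 200; A0 <- 100
  x <- A0 * (1 + 0.1 * cos(2 * pi * t / P))
  a_oracle <- mean(0.1 * cos(2 * pi * (t[300] + dt * (-18:18)) / P)) /
    (0.1 * cos(2 * pi * t[300] / P))
  expect_equal(a_oracle, -0.0784355, tolerance = 1e-6)
  tr2 <- area_trend(x, dt, 360)
  expect_equal(tr2[i], A0 * (1 + 0.1 * a_oracle * cos(2 * pi * t[i] / P)),
               tolerance = 1e-10)
  expect_error(area_trend(rep(1, 10), dt, 360), "shorter")
})

test_that("bandpass filter has the specified response and zero phase", {
  t <- seq(0, 8000, by = dt)
  # DC rejection
  y0 <- bandpass_filter(rep(0.5, length(t)), dt)
  expect_lt(max(abs(y0), na.rm = TRUE), 1e-3 * 0.5)
  # 5 mHz passband
  y5 <- bandpass_filter(cos(2 * pi * 5e-3 * t), dt)
  ok <- which(!is.na(y5))
  expect_gte(max(abs(y5[ok])), 0.99)
  # 25 mHz stopband
  y25 <- bandpass_filter(cos(2 * pi * 25e-3 * t), dt)
  expect_lte(max(abs(y25), na.rm = TRUE), 0.01)
  # zero phase: cross-correlation peak at lag 0 samples
  x <- cos(2 * pi * 5e-3 * t)
  cc <- stats::ccf(x[ok], y5[ok], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # idempotence: refiltering changes an in-band filtered signal < 0.5 % RMS
  y5b <- bandpass_filter(y5[ok], dt)
  ok2 <- which(!is.na(y5b))
  rel <- sqrt(mean((y5b[ok2] - y5[ok][ok2])^2)) / sqrt(mean(y5[ok][ok2]^2))
  expect_lt(rel, 0.005)
  expect_error(bandpass_filter(rep(0, 50), dt), "too short")
  expect_error(bandpass_filter(x, dt, low = 0.02, high = 0.06), "Nyquist")
})

test_that("strain recovery: amplitude within 2 %, trends rejected, gain invariant", {
  t <- seq(0, 8000, by = dt)
  cfg <- test_config()
  # constant area -> zero strain
  st0 <- compute_strain(rep(50, length(t)), dt, cfg)
  expect_lt(max(abs(st0$strain), na.rm = TRUE), 1e-9)
  # pure exponential contraction -> |eps| < 1e-3
  ste <- compute_strain(100 * exp(-t / 12000), dt, cfg)
  expect_lt(max(abs(ste$strain), na.rm = TRUE), 1e-3)
  # in-band oscillation at 5 mHz on a contracting trend
  A <- 100 * exp(-t / 12000) * (1 + 0.05 * cos(2 * pi * t / 200))
  st <- compute_strain(A, dt, cfg)
  ok <- which(!is.na(st$strain))
  amp <- sinusoid_fit(st$strain[ok], t[ok], 2 * pi / 200)$amplitude
  expect_equal(amp, 0.05, tolerance = 0.02)
  # gain invariance under rescaling of areas
  st2 <- compute_strain(3.7 * A, dt, cfg)
  expect_equal(st2$strain, st$strain, tolerance = 1e-10)
})

test_that("the myosin envelope tracks the baseline for flat, pulsed and
           photobleached signals", {
  t <- seq(0, 6000, by = dt)
  i <- 100:500
  # constant signal
  expect_equal(myosin_envelope(rep(1000, length(t)), dt), rep(1000, length(t)))
  # pulses riding on a flat baseline: envelope ~ B0 within 3 %
  me <- 1000 * (1 + 0.3 * (1 + cos(2 * pi * t / 200)) / 2)
  expect_equal(myosin_envelope(me, dt)[i] / 1000, rep(1, length(i)),
               tolerance = 0.03)
  # photobleached baseline: envelope tracks the decay within 5 %
  B <- 1000 * exp(-t / 6000)
  md <- B * (1 + 0.4 * (1 + cos(2 * pi * t / 200)))
  expect_equal(myosin_envelope(md, dt)[i] / B[i], rep(1, length(i)),
               tolerance = 0.05)
})

test_that("rescaled myosin recovers amplitude within 2 % and is gain invariant", {
  t <- seq(0, 8000, by = dt)
  cfg <- test_config()
  B <- 1000 * exp(-t / 6000)
  clean <- 200 + B * (1 + 0.2 * (1 + cos(2 * pi * t / 200)))
  # no oscillation -> c_m = 0 after filtering
  r0 <- rescale_myosin(200 + B, dt = dt, background = 200, config = cfg)
  expect_lt(max(abs(r0$myosin), na.rm = TRUE), 1e-6)
  rm1 <- rescale_myosin(clean, 200, dt, cfg)
  ok <- which(!is.na(rm1$myosin))
  amp <- sinusoid_fit(rm1$myosin[ok], t[ok], 2 * pi / 200)$amplitude
  expect_equal(amp, 0.2, tolerance = 0.02)
  # doubling the signal above background leaves c_m unchanged
  rm2 <- rescale_myosin(200 + 2 * (clean - 200), 200, dt, cfg)
  expect_equal(rm2$myosin[ok], rm1$myosin[ok], tolerance = 1e-9)
  # over-subtracted background is rejected
  expect_error(rescale_myosin(rep(100, length(t)), 200, dt, cfg),
               "envelope")
})

test_that("end-to-end preprocessing recovers ground truth within 5 % RMS", {
  g <- generate_embryo(n_cells = 3, duration = 6000,
                       scenario = clean_scenario(), seed = 21)
  cfg <- test_config()
  proc <- preprocess_dataset(g$dataset, cfg)
  expect_gt(nrow(proc), 0)
  for (cid in unique(proc$cell_id)) {
    p <- proc[proc$cell_id == cid, ]
    tt <- g$truth[g$truth$cell_id == cid, ]
    tru_strain <- tt$strain_amp * cos(tt$phase)
    tru_myosin <- tt$myosin_amp * cos(tt$phase + tt$lag)
    idx <- match(p$time_s, tt$time_s)
    rms <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
    expect_lt(rms(p$strain, tru_strain[idx]), 0.05)
    expect_lt(rms(p$myosin, tru_myosin[idx]), 0.05)
  }
  # processed signals are near zero-mean relative to their RMS (finite spans
  # of a band-limited oscillation retain a small residual mean)
  expect_lt(abs(mean(proc$strain)) / stats::sd(proc$strain), 0.05)
  expect_lt(abs(mean(proc$myosin)) / stats::sd(proc$myosin), 0.05)
})

test_that("preprocess failures are reported, not silent", {
  short <- cell_track("e", "s", seq(0, 400, 10), rep(10, 41), rep(5, 41))
  ds <- embryo_dataset(list(short))
  proc <- preprocess_dataset(ds, test_config())
  expect_equal(nrow(proc), 0)
  expect_match(attr(proc, "report"), "too short")
})
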